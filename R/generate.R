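#' Generate a synthetic trabecular geometry
#'
#' Draws a Gaussian random field on the core grid (white noise smoothed by an
#' isotropic Gaussian kernel of the requested correlation length), thresholds
#' it at the `1 - bvtv_target` quantile so the solid fraction matches the
#' target, wraps the core in the outer fluid margin, and applies connectivity
#' cleanup ([cleanup_connectivity()]) so that both phases are single
#' face-connected components suitable for the finite-element and Stokes
#' stencils.
#'
#' Because cleanup discards disconnected solid fragments, plain thresholding
#' can undershoot the target fraction badly at low BV/TV.  After cleanup the
#' generator therefore refines the structure voxel-by-voxel, ranked by field
#' value: pore voxels face-adjacent to the retained solid component with the
#' highest field values are converted to solid (or, on overshoot, surface
#' solid voxels with the lowest field values are released) until the core
#' solid fraction matches `bvtv_target` to within one voxel.  The refinement
#' only ever grows or erodes the connected component, so connectivity is
#' preserved, and it is driven purely by the field ordering, so the result
#' is deterministic for a fixed seed and isotropic.
#'
#' @param spec a [geometry_spec()].
#' @return a [voxel_domain()].
#' @export
generate_trabecular <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  n <- spec$grid_n
  field <- with_local_seed(spec$seed, {
    noise <- array(stats::rnorm(n^3), dim = c(n, n, n))
    gaussian_smooth_periodic(noise,
                             sigma_vox = 0.5 * spec$correlation_length_um /
                               spec$pitch_um)
  })
  thr <- stats::quantile(field, probs = 1 - spec$bvtv_target, names = FALSE)
  solid <- field >= thr
  m <- spec$margin_vox
  d <- n + 2L * m
  labels <- array(2L, dim = c(d, d, d))
  labels[(m + 1L):(m + n), (m + 1L):(m + n), (m + 1L):(m + n)] <-
    ifelse(solid, 1L, 0L)
  dom <- voxel_domain(labels, pitch_um = spec$pitch_um,
                      loading_axis = spec$loading_axis, margin_vox = m)
  dom <- cleanup_connectivity(dom)
  dom <- refine_bvtv(dom, field, spec$bvtv_target)
  dom <- ensure_spanning(dom, field, spec$bvtv_target)
  bv <- compute_bvtv(dom)
  if (bv <= 0 || bv >= 1 ||
      abs(bv - spec$bvtv_target) > max(0.02, 2 / spec$grid_n))
    stop(infeasible_geometry(sprintf(
      "cannot realise bvtv_target %.3f at this grid (achieved %.3f after cleanup)",
      spec$bvtv_target, bv)))
  if (!solid_spans_loading_axis(dom))
    stop(infeasible_geometry(
      "solid phase cannot be made to span the loading axis at this bvtv_target"))
  dom
}

# The scanned samples the generator emulates are load-bearing: their solid
# phase connects the loaded top face to the fixed bottom face.  Near the
# percolation threshold a thresholded random field often is not.  When the
# retained component misses a loading face, carve the highest-field ridge
# path (Dijkstra on the smoothed field) from the component to that face,
# solidify it, and re-balance the solid fraction.  Deterministic given the
# field.
ensure_spanning <- function(dom, field, target, max_attempts = 5L) {
  protect <- NULL
  for (att in seq_len(max_attempts)) {
    if (solid_spans_loading_axis(dom)) return(dom)
    br <- bridge_to_faces(dom, field)
    dom <- cleanup_connectivity(br$domain)
    protect <- union(protect, br$cells)
    dom <- refine_bvtv(dom, field, target, protect = protect)
  }
  dom
}

bridge_to_faces <- function(dom, field) {
  m <- dom$margin_vox
  a <- dom$loading_axis
  lab <- core_labels(dom)
  d <- dim(lab)
  solid <- lab == 1L
  nv <- prod(d)
  stride <- c(1L, d[1], d[1] * d[2])
  # lattice edges between all core cells
  ai <- arrayInd(seq_len(nv), d)
  from <- integer(0); to <- integer(0)
  for (ax in 1:3) {
    ok <- which(ai[, ax] < d[ax])
    from <- c(from, ok)
    to <- c(to, ok + stride[ax])
  }
  fmax <- max(field)
  vcost <- (fmax - field) + 1e-9
  vcost[solid] <- 0
  w <- (vcost[from] + vcost[to]) / 2
  src <- nv + 1L   # supernode for the solid component
  g_from <- c(from, rep(src, sum(solid)))
  g_to <- c(to, which(solid))
  g_w <- c(w, rep(0, sum(solid)))
  added <- integer(0)
  for (side in c(1L, d[a])) {
    face_cells <- which(slice_index_mask(d, a, side))
    if (any(solid[face_cells])) next
    g <- igraph::make_empty_graph(n = nv + 1L, directed = FALSE)
    g <- igraph::add_edges(g, rbind(g_from, g_to))
    igraph::E(g)$weight <- g_w
    dd <- igraph::distances(g, v = src, to = face_cells)
    tgt <- face_cells[which.min(dd)]
    path <- igraph::shortest_paths(g, from = src, to = tgt,
                                   output = "vpath")$vpath[[1]]
    cells <- setdiff(as.integer(path), src)
    lab[cells] <- 1L
    added <- c(added, cells)
  }
  full <- dom$labels
  ix <- lapply(1:3, function(ax2) (m + 1L):(m + d[ax2]))
  full[ix[[1]], ix[[2]], ix[[3]]] <- lab
  dom$labels <- full
  list(domain = dom, cells = added)
}

# logical mask (linear over array dims d) of layer k along axis a
slice_index_mask <- function(d, a, k) {
  out <- array(FALSE, dim = d)
  idx <- lapply(d, seq_len)
  idx[[a]] <- k
  out[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  out
}

# Connectivity-preserving adjustment of the core solid fraction towards the
# target: grow the retained component through its highest-field pore
# neighbours, or erode its lowest-field surface voxels, one batch at a time.
refine_bvtv <- function(dom, field, target, max_iter = 60L, protect = NULL) {
  m <- dom$margin_vox
  n_core <- prod(dom$core_dim)
  core_ix <- lapply(1:3, function(a) (m + 1L):(m + dom$core_dim[a]))
  for (it in seq_len(max_iter)) {
    bv <- compute_bvtv(dom)
    deficit <- round((target - bv) * n_core)
    if (abs(deficit) < 1) break
    lab <- dom$labels
    core <- lab[core_ix[[1]], core_ix[[2]], core_ix[[3]], drop = FALSE]
    solid <- core == 1L
    if (deficit > 0) {
      cand <- which(!solid & face_adjacent(solid))
      if (!length(cand)) break
      take <- cand[order(field[cand], decreasing = TRUE)]
      take <- take[seq_len(min(deficit, length(take)))]
      core[take] <- 1L
    } else {
      surf <- which(solid & face_adjacent(!solid))
      surf <- setdiff(surf, protect)
      if (!length(surf)) break
      take <- surf[order(field[surf], decreasing = FALSE)]
      take <- take[seq_len(min(-deficit, length(take)))]
      core[take] <- 0L
    }
    lab[core_ix[[1]], core_ix[[2]], core_ix[[3]]] <- core
    dom$labels <- lab
    dom <- cleanup_connectivity(dom)
  }
  dom
}

# logical mask of voxels with at least one TRUE face neighbour
face_adjacent <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (a in 1:3) {
    idx <- lapply(d, seq_len)
    lo <- idx; lo[[a]] <- seq_len(d[a] - 1L)
    hi <- idx; hi[[a]] <- 2:d[a]
    out_lo <- do.call(`[`, c(list(mask), hi, list(drop = FALSE)))
    out[lo[[1]], lo[[2]], lo[[3]]] <- out[lo[[1]], lo[[2]], lo[[3]], drop = FALSE] | out_lo
    out_hi <- do.call(`[`, c(list(mask), lo, list(drop = FALSE)))
    out[hi[[1]], hi[[2]], hi[[3]]] <- out[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] | out_hi
  }
  out
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# periodic Gaussian smoothing of a 3-D array via FFT; sigma in voxels
gaussian_smooth_periodic <- function(x, sigma_vox) {
  d <- dim(x)
  kern1 <- function(n) {
    # periodic distance to the origin along one axis
    i <- seq_len(n) - 1L
    r <- pmin(i, n - i)
    exp(-r^2 / (2 * sigma_vox^2))
  }
  kx <- kern1(d[1]); ky <- kern1(d[2]); kz <- kern1(d[3])
  kern <- outer(outer(kx, ky), kz)
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
  array(sm, dim = d)
}

#' Enforce phase connectivity of a voxel domain
#'
#' Reduces the solid phase to its largest face-connected (6-neighbour)
#' component, relabelling the remainder as pore, and then reassigns to solid
#' any pore voxels that are not face-connected to the outer fluid margin
#' (sealed cavities).  Both phases of the result are single face-connected
#' components; the operation is idempotent.
#'
#' @param domain a [voxel_domain()].
#' @return a cleaned [voxel_domain()]; possibly degenerate (a phase may be
#'   empty), which [generate_trabecular()] converts into an error.
#' @export
cleanup_connectivity <- function(domain) {
  lab <- domain$labels
  solid <- lab == 1L
  if (any(solid)) {
    comp <- label_components(solid)
    if (comp$ncomp > 1L) {
      keep <- which.max(tabulate(comp$membership, comp$ncomp))
      drop <- comp$idx[comp$membership != keep]
      lab[drop] <- 0L
    }
  }
  fluid <- lab != 1L
  comp <- label_components(fluid)
  if (comp$ncomp > 1L) {
    margin_comps <- unique(comp$membership[lab[comp$idx] == 2L])
    sealed <- comp$idx[!(comp$membership %in% margin_comps)]
    lab[sealed] <- 1L
  }
  domain$labels <- lab
  domain
}

# face-connected (6-neighbour) components of a logical 3-D mask.
# Returns idx (linear indices of TRUE voxels), membership (component id per
# TRUE voxel, in first-encounter order), ncomp.
label_components <- function(mask) {
  idx <- which(mask)
  nv <- length(idx)
  if (nv == 0L) return(list(idx = idx, membership = integer(0), ncomp = 0L))
  d <- dim(mask)
  map <- integer(length(mask))
  map[idx] <- seq_len(nv)
  ai <- arrayInd(idx, d)
  stride <- c(1L, d[1], d[1] * d[2])
  from <- integer(0); to <- integer(0)
  for (a in 1:3) {
    ok <- ai[, a] < d[a]
    nb <- idx[ok] + stride[a]
    hit <- mask[nb]
    from <- c(from, map[idx[ok][hit]])
    to <- c(to, map[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  cc <- igraph::components(g)
  list(idx = idx, membership = as.integer(cc$membership),
       ncomp = as.integer(cc$no))
}

# does the largest solid component reach both core faces along the loading
# axis? (needed for load transfer in the FE solve)
solid_spans_loading_axis <- function(domain) {
  lab <- core_labels(domain)
  a <- domain$loading_axis
  d <- dim(lab)
  bottom <- slice_layer(lab, a, 1L)
  top <- slice_layer(lab, a, d[a])
  any(bottom == 1L) && any(top == 1L)
}

# extract layer k of a 3-D array along axis a (as a matrix)
slice_layer <- function(x, a, k) {
  idx <- lapply(dim(x), seq_len)
  idx[[a]] <- k
  do.call(`[`, c(list(x), idx, list(drop = TRUE)))
}
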