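#' Labelled voxel domain for fluid-solid simulation
#'
#' A `voxel_domain` is a cuboidal 3-D integer label grid describing one
#' trabecular sample embedded in its marrow bath: label 1 is the solid
#' (trabecular bone) phase, label 0 the pore (marrow) space inside the core,
#' and label 2 the outer fluid margin shell that surrounds the core and
#' carries the open boundaries.  The solid phase only ever occupies the core
#' sub-box; the margin is a shell of constant thickness `margin_vox` on all
#' six sides.
#'
#' @param labels 3-D integer array with values in `{0, 1, 2}`.
#' @param pitch_um physical edge length of one voxel in micrometres.
#' @param origin_um physical coordinate (micrometres) of the outer grid
#'   corner, length-3 numeric.
#' @param loading_axis axis (1, 2 or 3) along which the displacement load is
#'   applied; the load acts on the top core face along this axis.
#' @param margin_vox thickness of the label-2 margin shell in voxels.
#'
#' @return an object of class `voxel_domain` with fields `labels`,
#'   `pitch_um`, `origin_um`, `loading_axis`, `margin_vox` and `core_dim`
#'   (voxel extent of the core along each axis).
#' @export
voxel_domain <- function(labels, pitch_um, origin_um = c(0, 0, 0),
                         loading_axis = 3L, margin_vox = 2L) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(labels %in% c(0L, 1L, 2L)))
    stop("voxel labels must be 0 (pore), 1 (solid) or 2 (margin)")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("pitch_um must be a single positive number")
  loading_axis <- as.integer(loading_axis)
  if (!loading_axis %in% 1:3) stop("loading_axis must be 1, 2 or 3")
  margin_vox <- as.integer(margin_vox)
  if (margin_vox < 1L) stop("margin_vox must be >= 1")
  d <- dim(labels)
  if (any(d <= 2L * margin_vox))
    stop("grid too small for the requested margin shell")
  dom <- structure(
    list(labels = labels,
         pitch_um = as.numeric(pitch_um),
         origin_um = as.numeric(origin_um),
         loading_axis = loading_axis,
         margin_vox = margin_vox,
         core_dim = d - 2L * margin_vox),
    class = "voxel_domain")
  chk <- check_margin_shell(dom)
  if (!isTRUE(chk)) stop(chk)
  dom
}

# margin shell must be exactly the outer margin_vox layers and nothing else;
# solid must be confined to the core
check_margin_shell <- function(dom) {
  sh <- shell_mask(dim(dom$labels), dom$margin_vox)
  if (any(dom$labels[sh] != 2L))
    return("all voxels in the outer margin shell must carry label 2")
  if (any(dom$labels[!sh] == 2L))
    return("label 2 must not occur inside the core")
  TRUE
}

# logical mask of the outer m-voxel shell of a grid with dims d
shell_mask <- function(d, m) {
  core <- core_mask(d, m)
  !core
}

# logical mask of the core (everything except the outer m-voxel shell)
core_mask <- function(d, m) {
  ix <- (seq_len(d[1]) > m) & (seq_len(d[1]) <= d[1] - m)
  iy <- (seq_len(d[2]) > m) & (seq_len(d[2]) <= d[2] - m)
  iz <- (seq_len(d[3]) > m) & (seq_len(d[3]) <= d[3] - m)
  outer(outer(ix, iy, "&"), iz, "&")
}

#' @export
print.voxel_domain <- function(x, ...) {
  d <- dim(x$labels)
  cat("<voxel_domain> ", paste(d, collapse = " x "),
      " voxels @ ", x$pitch_um, " um pitch\n", sep = "")
  cat("  core ", paste(x$core_dim, collapse = " x "),
      " (margin ", x$margin_vox, " vox), loading axis ", x$loading_axis,
      "\n", sep = "")
  nsolid <- sum(x$labels == 1L)
  cat("  solid voxels ", nsolid, ", BV/TV ",
      signif(compute_bvtv(x), 4), "\n", sep = "")
  invisible(x)
}

#' Specification of a synthetic trabecular geometry
#'
#' Parameters of the Gaussian-random-field generator that stands in for
#' segmented micro-CT cubes.  Defaults emulate the scanned samples: an
#' 18 um voxel pitch, a 0.8 mm solid core, and a margin shell completing a
#' slightly larger fluid bath.
#'
#' @param grid_n voxels per edge of the cubic solid core (>= 16).
#' @param bvtv_target target bone volume fraction in (0, 1).
#' @param correlation_length_um correlation length of the random field in
#'   micrometres; sets the trabecular strut scale.
#' @param pitch_um voxel pitch in micrometres.
#' @param margin_vox margin shell thickness in voxels (>= 1).
#' @param seed integer random seed; the generator is deterministic given the
#'   seed.
#' @param loading_axis loading axis passed through to the domain.
#' @return an object of class `geometry_spec`.
#' @export
geometry_spec <- function(grid_n = 48L, bvtv_target = 0.3,
                          correlation_length_um = 120,
                          pitch_um = 18, margin_vox = 2L, seed = 1L,
                          loading_axis = 3L) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 16L) stop("grid_n must be >= 16")
  if (!(bvtv_target > 0 && bvtv_target < 1))
    stop("bvtv_target must lie strictly between 0 and 1")
  if (correlation_length_um <= 0) stop("correlation_length_um must be > 0")
  if (pitch_um <= 0) stop("pitch_um must be > 0")
  margin_vox <- as.integer(margin_vox)
  if (margin_vox < 1L) stop("margin_vox must be >= 1")
  structure(
    list(grid_n = grid_n, bvtv_target = bvtv_target,
         correlation_length_um = correlation_length_um,
         pitch_um = pitch_um, margin_vox = margin_vox,
         seed = as.integer(seed), loading_axis = as.integer(loading_axis)),
    class = "geometry_spec")
}

#' Bone volume fraction (BV/TV) of a voxel domain
#'
#' Ratio of solid voxels to total voxels over the core region; the outer
#' fluid margin is excluded, mirroring standard morphometry on the scanned
#' cube itself.
#'
#' @param domain a [voxel_domain()].
#' @return the solid fraction of the core, a number in `[0, 1]`.
#' @export
compute_bvtv <- function(domain) {
  lab <- core_labels(domain)
  if (length(lab) == 0L) stop("empty core region")
  sum(lab == 1L) / length(lab)
}

# labels restricted to the core as a 3-D array
core_labels <- function(domain) {
  d <- dim(domain$labels)
  m <- domain$margin_vox
  domain$labels[(m + 1L):(d[1] - m), (m + 1L):(d[2] - m),
                (m + 1L):(d[3] - m), drop = FALSE]
}

#' Solid-pore interface area of a domain
#'
#' Total area of voxel faces separating solid (label 1) from fluid (labels 0
#' or 2), in square micrometres.  Used for morphometric sanity checks such as
#' isotropy of the synthetic generator.
#'
#' @param domain a [voxel_domain()].
#' @return interface area in um^2.
#' @export
surface_area <- function(domain) {
  lab <- domain$labels
  solid <- lab == 1L
  fluid <- !solid
  n <- 0L
  for (a in 1:3) {
    s1 <- slab(solid, a, "head"); f2 <- slab(fluid, a, "tail")
    s2 <- slab(solid, a, "tail"); f1 <- slab(fluid, a, "head")
    n <- n + sum(s1 & f2) + sum(s2 & f1)
  }
  n * domain$pitch_um^2
}

# drop the last (head) or first (tail) layer along axis a
slab <- function(x, a, which = c("head", "tail")) {
  which <- match.arg(which)
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[a]] <- if (which == "head") seq_len(d[a] - 1L) else 2:d[a]
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Physical extents of a voxel domain
#'
#' @param domain a [voxel_domain()].
#' @return list with `core_edge_um` (physical edge lengths of the solid
#'   core) and `total_edge_um` (full fluid box including the margin).
#' @export
domain_extent <- function(domain) {
  list(core_edge_um = domain$core_dim * domain$pitch_um,
       total_edge_um = dim(domain$labels) * domain$pitch_um)
}

# condition constructor for geometries that cannot support both phases
infeasible_geometry <- function(msg) {
  structure(class = c("marrowflow_infeasible_geometry", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
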