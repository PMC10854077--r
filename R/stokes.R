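#' Assemble the staggered-grid Stokes operator for the pore space
#'
#' Builds the marker-and-cell (MAC) finite-difference discretisation of
#' quasi-static incompressible Stokes flow, `mu lap(v) = grad(p)`,
#' `div(v) = 0`, on the pore + margin phase of a voxel domain.  Velocity
#' unknowns live on faces between fluid cells (including the outer open
#' boundary), pressures at fluid cell centres.  Faces between a fluid and a
#' solid cell are no-slip walls whose velocity is prescribed from the solid
#' motion; tangential no-slip at walls is imposed through second-order ghost
#' values.  The six outer faces of the box are open: a prescribed normal
#' pressure acts there and the tangential stress is free.
#'
#' The assembly also precomputes sparse incidence operators mapping wall
#' velocities and boundary pressure to the right-hand side, so that
#' [apply_fluid_bcs()] is cheap for every time step, plus gather operators
#' used by [wall_shear_stress()].
#'
#' @param domain a [voxel_domain()] (cleaned; the pore + margin phase must
#'   be a single connected component).
#' @param mat a [material_spec()] supplying the marrow viscosity.
#' @return a fluid system handle (class `fluid_system`).
#' @export
assemble_stokes <- function(domain, mat) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(mat, "material_spec"))
  lab <- domain$labels
  d <- dim(lab)
  fluid <- lab != 1L
  comp <- label_components(fluid)
  if (comp$ncomp != 1L)
    stop("pore phase contains sealed regions; run cleanup_connectivity() first")
  mu <- mat$mu_fluid_pa_s
  h <- domain$pitch_um * 1e-6

  # padded cell state: 0 fluid, 1 solid, 2 outside
  P <- array(2L, dim = d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ifelse(lab == 1L, 1L, 0L)

  Wst <- vector("list", 3); Est <- vector("list", 3)
  uid <- vector("list", 3); wid <- vector("list", 3)
  fdims <- vector("list", 3)
  n_u <- 0L; n_w <- 0L
  for (a in 1:3) {
    rngW <- list(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
    rngE <- rngW
    rngW[[a]] <- 1:(d[a] + 1)
    rngE[[a]] <- 2:(d[a] + 2)
    W <- P[rngW[[1]], rngW[[2]], rngW[[3]], drop = FALSE]
    E <- P[rngE[[1]], rngE[[2]], rngE[[3]], drop = FALSE]
    fd <- d; fd[a] <- d[a] + 1L
    unk <- (W == 0L & E == 0L) | (W == 0L & E == 2L) | (W == 2L & E == 0L)
    wal <- (W == 0L & E == 1L) | (W == 1L & E == 0L)
    ua <- array(0L, dim = fd); wa <- array(0L, dim = fd)
    ua[unk] <- n_u + seq_len(sum(unk))
    wa[wal] <- n_w + seq_len(sum(wal))
    n_u <- n_u + sum(unk); n_w <- n_w + sum(wal)
    Wst[[a]] <- W; Est[[a]] <- E; uid[[a]] <- ua; wid[[a]] <- wa
    fdims[[a]] <- fd
  }

  # wall face table
  wall_axis <- integer(n_w); wall_sign <- integer(n_w)
  wall_fluid <- integer(n_w); wall_solid <- integer(n_w)
  wall_ijk <- matrix(0L, n_w, 3)
  for (a in 1:3) {
    ids <- which(wid[[a]] > 0L)
    g <- wid[[a]][ids]
    fi <- arrayInd(ids, fdims[[a]])
    Wsolid <- Wst[[a]][ids] == 1L
    # cells in full-grid coords: W has a-coord fi[,a]-1, E has fi[,a]
    cw <- fi; cw[, a] <- cw[, a] - 1L
    ce <- fi
    lin <- function(cc) cc[, 1] + d[1] * ((cc[, 2] - 1L) + d[2] * (cc[, 3] - 1L))
    wall_axis[g] <- a
    wall_sign[g] <- ifelse(Wsolid, 1L, -1L)  # outward normal from solid
    wall_solid[g] <- ifelse(Wsolid, lin(cw), lin(ce))
    wall_fluid[g] <- ifelse(Wsolid, lin(ce), lin(cw))
    wall_ijk[g, ] <- fi
  }

  # cell (pressure) numbering over fluid cells
  cid <- array(0L, dim = d)
  fl <- which(fluid)
  cid[fl] <- seq_along(fl)
  n_c <- length(fl)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)     # A triplets
  bi <- integer(0); bj <- integer(0); bx <- numeric(0)     # Bw triplets
  pi_ <- integer(0); pj_ <- integer(0); px_ <- numeric(0)  # cP triplets
  diagc <- numeric(n_u)
  inv_h2 <- mu / h^2

  for (a in 1:3) {
    ua <- uid[[a]]; wa <- wid[[a]]; fd <- fdims[[a]]
    unk_idx <- which(ua > 0L)
    rows <- ua[unk_idx]
    # normal-direction neighbours (shift along a)
    for (s in c(-1L, 1L)) {
      nb_u <- shift0(ua, a, s)[unk_idx]
      nb_w <- shift0(wa, a, s)[unk_idx]
      has <- nb_u > 0L | nb_w > 0L
      diagc[rows[has]] <- diagc[rows[has]] + inv_h2
      off <- nb_u > 0L
      ti <- c(ti, rows[off]); tj <- c(tj, nb_u[off]); tx <- c(tx, rep(-inv_h2, sum(off)))
      wl <- nb_w > 0L
      bi <- c(bi, rows[wl])
      bj <- c(bj, (a - 1L) * n_w + nb_w[wl])
      bx <- c(bx, rep(inv_h2, sum(wl)))
    }
    # tangential directions
    for (b in setdiff(1:3, a)) {
      for (s in c(-1L, 1L)) {
        cW <- shift0(Wst[[a]], b, s, pad = 2L)[unk_idx]
        cE <- shift0(Est[[a]], b, s, pad = 2L)[unk_idx]
        ghost <- cW == 1L | cE == 1L
        open_edge <- cW == 2L & cE == 2L
        nb_u <- shift0(ua, b, s)[unk_idx]
        plain <- !ghost & !open_edge
        diagc[rows[plain]] <- diagc[rows[plain]] + inv_h2
        ti <- c(ti, rows[plain]); tj <- c(tj, nb_u[plain])
        tx <- c(tx, rep(-inv_h2, sum(plain)))
        if (any(ghost)) {
          diagc[rows[ghost]] <- diagc[rows[ghost]] + 2 * inv_h2
          # wall faces of axis b flanking the ghost: W-side and E-side
          offW <- c(0L, 0L, 0L); offW[a] <- -1L
          offE <- c(0L, 0L, 0L)
          if (s == 1L) { offW[b] <- 1L; offE[b] <- 1L }
          gW <- gather0(wid[[b]], fd, offW)[unk_idx]
          gE <- gather0(wid[[b]], fd, offE)[unk_idx]
          gWv <- ifelse(cW == 1L, gW, 0L)
          gEv <- ifelse(cE == 1L, gE, 0L)
          n_avail <- (gWv > 0L) + (gEv > 0L)
          sel <- ghost & gWv > 0L
          bi <- c(bi, rows[sel])
          bj <- c(bj, (a - 1L) * n_w + gWv[sel])
          bx <- c(bx, 2 * inv_h2 / n_avail[sel])
          sel <- ghost & gEv > 0L
          bi <- c(bi, rows[sel])
          bj <- c(bj, (a - 1L) * n_w + gEv[sel])
          bx <- c(bx, 2 * inv_h2 / n_avail[sel])
        }
      }
    }
    # prescribed outer pressure on boundary faces of this axis; boundary
    # pressure can differ per outer box face (columns: x-lo, x-hi, y-lo,
    # y-hi, z-lo, z-hi)
    Wout <- which(Wst[[a]][unk_idx] == 2L)
    Eout <- which(Est[[a]][unk_idx] == 2L)
    pi_ <- c(pi_, rows[Wout], rows[Eout])
    pj_ <- c(pj_, rep(2L * a - 1L, length(Wout)), rep(2L * a, length(Eout)))
    px_ <- c(px_, rep(1 / h, length(Wout)), rep(-1 / h, length(Eout)))
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(n_u)), j = c(tj, seq_len(n_u)),
                            x = c(tx, diagc), dims = c(n_u, n_u))
  Bw <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(n_u, 3L * n_w))
  cP <- Matrix::sparseMatrix(i = pi_, j = pj_, x = px_, dims = c(n_u, 6L))

  # divergence operator and wall contribution
  di <- integer(0); dj <- integer(0); dx <- numeric(0)
  wi <- integer(0); wj <- integer(0); wx <- numeric(0)
  cells <- arrayInd(fl, d)
  crow <- cid[fl]
  for (a in 1:3) {
    for (side in c(0L, 1L)) {     # 0 = lo face, 1 = hi face
      fc <- cells; fc[, a] <- fc[, a] + side
      flin <- fc[, 1] + fdims[[a]][1] * ((fc[, 2] - 1L) +
                                           fdims[[a]][2] * (fc[, 3] - 1L))
      fu <- uid[[a]][flin]; fw <- wid[[a]][flin]
      sgn <- if (side == 1L) 1 else -1
      selu <- fu > 0L
      di <- c(di, crow[selu]); dj <- c(dj, fu[selu])
      dx <- c(dx, rep(sgn / h, sum(selu)))
      selw <- fw > 0L
      wi <- c(wi, crow[selw]); wj <- c(wj, (a - 1L) * n_w + fw[selw])
      wx <- c(wx, rep(-sgn / h, sum(selw)))
    }
  }
  Dmat <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(n_c, n_u))
  Dw <- Matrix::sparseMatrix(i = wi, j = wj, x = wx, dims = c(n_c, 3L * n_w))

  # FSS gather operators: fluid-cell tangential velocity per wall face
  gi <- integer(0); gj <- integer(0); gx <- numeric(0)
  hi <- integer(0); hj <- integer(0); hx <- numeric(0)
  si <- integer(0); sj <- integer(0); sx <- numeric(0)
  for (g_axis in 1:3) {
    sel <- which(wall_axis == g_axis)
    if (!length(sel)) next
    tang <- setdiff(1:3, g_axis)
    fc_lin <- wall_fluid[sel]
    fc <- arrayInd(fc_lin, d)
    for (ti2 in 1:2) {
      b <- tang[ti2]
      row <- (ti2 - 1L) * n_w + sel
      for (side in c(0L, 1L)) {
        fcb <- fc; fcb[, b] <- fcb[, b] + side
        flin <- fcb[, 1] + fdims[[b]][1] * ((fcb[, 2] - 1L) +
                                              fdims[[b]][2] * (fcb[, 3] - 1L))
        fu <- uid[[b]][flin]; fw <- wid[[b]][flin]
        s1 <- fu > 0L
        gi <- c(gi, row[s1]); gj <- c(gj, fu[s1]); gx <- c(gx, rep(0.5, sum(s1)))
        s2 <- fw > 0L
        hi <- c(hi, row[s2]); hj <- c(hj, (b - 1L) * n_w + fw[s2])
        hx <- c(hx, rep(0.5, sum(s2)))
      }
      # wall's own tangential velocity component b
      si <- c(si, row); sj <- c(sj, (b - 1L) * n_w + sel)
      sx <- c(sx, rep(1, length(sel)))
    }
  }
  Tfl <- Matrix::sparseMatrix(i = gi, j = gj, x = gx, dims = c(2L * n_w, n_u))
  Tflw <- Matrix::sparseMatrix(i = hi, j = hj, x = hx, dims = c(2L * n_w, 3L * n_w))
  Twall <- Matrix::sparseMatrix(i = si, j = sj, x = sx, dims = c(2L * n_w, 3L * n_w))

  structure(
    list(A = A, D = Dmat, Bw = Bw, Dw = Dw, cP = cP,
         Tfl = Tfl, Tflw = Tflw, Twall = Twall,
         uid = uid, wid = wid, cid = cid, fdims = fdims,
         n_u = n_u, n_w = n_w, n_c = n_c,
         wall_axis = wall_axis, wall_sign = wall_sign,
         wall_fluid = wall_fluid, wall_solid = wall_solid,
         wall_ijk = wall_ijk,
         mu = mu, h = h, dims = d, domain = domain, mat = mat,
         cache = new.env(parent = emptyenv())),
    class = "fluid_system")
}

# shift an array along axis a by s, padding with `pad`
shift0 <- function(x, a, s, pad = 0L) {
  d <- dim(x)
  out <- array(pad, dim = d)
  src <- lapply(d, seq_len); dst <- src
  if (s > 0) { src[[a]] <- (1 + s):d[a]; dst[[a]] <- 1:(d[a] - s) }
  else { src[[a]] <- 1:(d[a] + s); dst[[a]] <- (1 - s):d[a] }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    x[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# gather src[idx + off] into an array of dims dout, zero outside
gather0 <- function(src, dout, off) {
  ds <- dim(src)
  out <- array(0L, dim = dout)
  dst <- vector("list", 3); srcr <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1L, 1L - off[a]); hi <- min(dout[a], ds[a] - off[a])
    if (lo > hi) return(out)
    dst[[a]] <- lo:hi
    srcr[[a]] <- (lo + off[a]):(hi + off[a])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    src[srcr[[1]], srcr[[2]], srcr[[3]], drop = FALSE]
  out
}

#' Set boundary data of the Stokes system for one time instant
#'
#' Combines the prescribed open-boundary pressure (the pressure waveform at
#' time `t`, identical on all six outer faces) with the no-slip wall
#' velocity field into the right-hand side of the saddle-point system.
#'
#' @param system a `fluid_system` from [assemble_stokes()].
#' @param t time in seconds.
#' @param load a [load_spec()] (supplies the pressure waveform).
#' @param wall_velocity `n_w x 3` matrix of wall-face velocities in m/s
#'   (columns are the x, y, z components; rows follow the system's wall
#'   face table).
#' @param pressure_pa optional explicit boundary pressure (Pa), overriding
#'   the waveform; either a scalar (all six outer faces) or a length-6
#'   vector ordered x-lo, x-hi, y-lo, y-hi, z-lo, z-hi.
#' @return a `fluid_system_bc` ready for [solve_stokes()].
#' @export
apply_fluid_bcs <- function(system, t, load = load_spec(), wall_velocity,
                            pressure_pa = NULL) {
  stopifnot(inherits(system, "fluid_system"))
  if (missing(wall_velocity) || is.null(wall_velocity))
    wall_velocity <- matrix(0, system$n_w, 3)
  if (!is.matrix(wall_velocity) ||
      nrow(wall_velocity) != system$n_w || ncol(wall_velocity) != 3L)
    stop("wall_velocity must be an n_w x 3 matrix (m/s)")
  if (anyNA(wall_velocity)) stop("wall_velocity contains missing values")
  if (is.null(pressure_pa)) pressure_pa <- pressure_waveform(t, load)
  if (length(pressure_pa) == 1L) pressure_pa <- rep(pressure_pa, 6L)
  if (length(pressure_pa) != 6L)
    stop("pressure_pa must be a scalar or a length-6 vector")
  wv <- as.vector(wall_velocity)  # stacked by component
  b_u <- as.numeric(system$Bw %*% wv) + as.numeric(system$cP %*% pressure_pa)
  b_d <- as.numeric(system$Dw %*% wv)
  structure(
    list(base = system, t = t, load = load, pressure_pa = pressure_pa,
         wall_velocity = wall_velocity, b_u = b_u, b_d = b_d),
    class = "fluid_system_bc")
}

#' Solve the constrained Stokes system
#'
#' Solves the saddle-point system by the Schur-complement (pressure) route:
#' the velocity Laplacian block is factorised once per geometry (sparse
#' Cholesky, cached on the handle) and conjugate gradients are run on the
#' pressure Schur complement `D A^-1 D'`, which for Stokes is spectrally
#' equivalent to a mass matrix, so the iteration count is small and
#' mesh-independent.  The returned divergence residual is exactly the CG
#' residual, so discrete incompressibility holds to the solver tolerance.
#'
#' @param system a `fluid_system_bc` from [apply_fluid_bcs()].
#' @param tol relative tolerance on the cell divergence residual.
#' @param maxit maximum CG iterations.
#' @return a `fluid_solution` with face velocities (m/s), cell pressures
#'   (Pa) and residual diagnostics.
#' @export
solve_stokes <- function(system, tol = 1e-10, maxit = 5000L) {
  stopifnot(inherits(system, "fluid_system_bc"))
  base <- system$base
  cache <- base$cache
  if (is.null(cache$cholA))
    cache$cholA <- Matrix::Cholesky(Matrix::forceSymmetric(base$A),
                                    LDL = FALSE, super = TRUE)
  Ainv <- function(x) as.numeric(Matrix::solve(cache$cholA, x, system = "A"))
  Dm <- base$D
  apply_S <- function(p) as.numeric(Dm %*% Ainv(as.numeric(Matrix::crossprod(Dm, p))))

  rhs <- system$b_d - as.numeric(Dm %*% Ainv(system$b_u))
  scale0 <- sqrt(sum(rhs^2))
  p <- numeric(base$n_c)
  iters <- 0L
  if (scale0 > 0) {
    r <- rhs
    z <- r
    rho <- sum(r * r)
    target <- tol * scale0
    repeat {
      iters <- iters + 1L
      q <- apply_S(z)
      alpha <- rho / sum(z * q)
      p <- p + alpha * z
      r <- r - alpha * q
      rho_new <- sum(r * r)
      if (sqrt(rho_new) <= target || iters >= maxit) break
      z <- r + (rho_new / rho) * z
      rho <- rho_new
    }
    if (iters >= maxit && sqrt(sum(r^2)) > target)
      stop(sprintf("Stokes Schur CG failed to converge (%d iterations, residual %.3e)",
                   iters, sqrt(sum(r^2))))
  }
  u <- Ainv(system$b_u + as.numeric(Matrix::crossprod(Dm, p)))
  div_res <- as.numeric(Dm %*% u) - system$b_d
  structure(
    list(u = u, p = p, t = system$t,
         wall_velocity = system$wall_velocity,
         pressure_pa = system$pressure_pa,
         div_residual = sqrt(sum(div_res^2)),
         div_residual_max = max(abs(div_res)),
         cg_iters = iters,
         base = base),
    class = "fluid_solution")
}

#' Wall fluid shear stress of a Stokes solution
#'
#' For every solid-fluid wall face, evaluates the tangential viscous
#' traction magnitude: the two tangential velocity components of the
#' adjacent fluid cell (face-averaged to the cell centre, half a voxel from
#' the wall) are differenced against the wall's own tangential velocity,
#' giving the one-sided normal gradient `mu * dv_t/dn` per component; the
#' FSS is the Euclidean magnitude of the two components.  This one-sided
#' extraction is exact for linear shear (Couette) profiles.
#'
#' @param sol a `fluid_solution`.
#' @return list with `fss` (Pa, per wall face), `components` (n_w x 2
#'   tangential traction components), and the wall-face table of the parent
#'   system.
#' @export
wall_shear_stress <- function(sol) {
  stopifnot(inherits(sol, "fluid_solution"))
  base <- sol$base
  comps <- fss_components(base, sol$u, sol$wall_velocity)
  list(fss = sqrt(comps[, 1]^2 + comps[, 2]^2),
       components = comps,
       wall_axis = base$wall_axis,
       wall_ijk = base$wall_ijk,
       wall_sign = base$wall_sign)
}

# tangential traction components (n_w x 2) from a velocity vector and the
# wall velocity matrix
fss_components <- function(base, u, wall_velocity) {
  wv <- as.vector(wall_velocity)
  vt_fluid <- as.numeric(base$Tfl %*% u) + as.numeric(base$Tflw %*% wv)
  vt_wall <- as.numeric(base$Twall %*% wv)
  tau <- (2 * base$mu / base$h) * (vt_fluid - vt_wall)
  matrix(tau, ncol = 2)
}

#' Mass balance diagnostics of a Stokes solution
#'
#' Net volume flux leaving through the six outer faces must balance the
#' volume displaced per unit time by the moving walls (incompressibility).
#'
#' @param sol a `fluid_solution`.
#' @return list with `outer_flux_m3_s`, `wall_flux_m3_s`, `gross_flux_m3_s`
#'   and `rel_imbalance` (|outer - wall| / gross).
#' @export
mass_balance <- function(sol) {
  base <- sol$base
  h <- base$h
  area <- h^2
  outer_flux <- 0; gross <- 0
  for (a in 1:3) {
    ua <- base$uid[[a]]; fd <- base$fdims[[a]]
    lo <- slice_layer(ua, a, 1L); hi <- slice_layer(ua, a, fd[a])
    v_lo <- sol$u[lo[lo > 0L]]; v_hi <- sol$u[hi[hi > 0L]]
    outer_flux <- outer_flux + sum(v_hi) * area - sum(v_lo) * area
    gross <- gross + (sum(abs(v_hi)) + sum(abs(v_lo))) * area
  }
  # volume per second pushed into the fluid by wall motion: for a wall face
  # with outward-from-solid normal n, the fluid gains volume at rate
  # -(v_wall . n) * area; a net balance requires outer_flux = wall source
  nsel <- cbind(seq_len(base$n_w), base$wall_axis)
  vn <- sol$wall_velocity[nsel] * base$wall_sign
  wall_flux <- sum(vn) * area
  gross <- max(gross, sum(abs(vn)) * area)
  list(outer_flux_m3_s = outer_flux, wall_flux_m3_s = wall_flux,
       gross_flux_m3_s = gross,
       rel_imbalance = abs(outer_flux - wall_flux) / max(gross, 1e-300))
}
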