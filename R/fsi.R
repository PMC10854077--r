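#' Run one quasi-static loading cycle of the coupled model
#'
#' Orchestrates the one-way coupled simulation over one period of the
#' displacement load: the solid displacement field is obtained from a single
#' unit micro-FE solve (the problem is linear and quasi-static, so the field
#' at any instant is the unit field scaled by the waveform), wall velocities
#' at the bone-marrow interface are the solid displacement rate, and the
#' Stokes problem is solved with those wall velocities plus the open
#' boundary pressure.
#'
#' With `fast_path = TRUE` (default) the fluid problem is solved twice --
#' one unit wall-driven mode and one unit pressure-driven mode -- and every
#' snapshot is reconstructed by scaling with the displacement rate and the
#' pressure waveform (superposition, exact for Stokes).  With `fast_path =
#' FALSE` every time step is solved independently; the two paths agree to
#' solver tolerance, which is asserted in the test suite.
#'
#' @param domain a [voxel_domain()].
#' @param mat a [material_spec()].
#' @param load a [load_spec()].
#' @param n_steps number of uniform time samples per cycle (>= 8).
#' @param fast_path logical; use the two-mode superposition.
#' @param stokes_tol relative divergence tolerance of the Stokes solves.
#' @return a `cycle_result` with fields `times`, `fss` (wall faces x
#'   times, Pa), `mean_fss`, `interface` (wall-face table), `solid_unit`
#'   (the unit solid solution and its scale), fluid mode fields, and
#'   per-step mass-balance diagnostics.
#' @export
run_cycle <- function(domain, mat, load = load_spec(), n_steps = 20L,
                      fast_path = TRUE, stokes_tol = 1e-10) {
  stopifnot(inherits(domain, "voxel_domain"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 8L) stop("n_steps must be >= 8")
  times <- seq(0, load$T_s, length.out = n_steps + 1L)[seq_len(n_steps)]

  esys <- assemble_elasticity(domain, mat)
  B_ref <- if (load$B_um > 0) load$B_um else 1
  ebc <- apply_solid_bcs(esys, t = NA_real_, load, u_top_um = B_ref)
  usol <- solve_solid(ebc)
  # the elasticity factorisation is not needed again (all later instants are
  # scalings of the unit solve); release it before the Stokes factorisation
  # so the two never coexist in memory
  rm(list = ls(envir = esys$cache), envir = esys$cache)
  invisible(gc(FALSE))

  fsys <- assemble_stokes(domain, mat)
  Wmap <- wall_node_map(fsys, esys)
  # wall velocity per unit top-face rate (1 um/s): dimensionless shape x 1e-6 m
  W_unit <- (Wmap %*% usol$u_um) / B_ref * 1e-6
  W_unit <- as.matrix(W_unit)

  rate <- displacement_rate(times, load)         # um/s
  pres <- pressure_waveform(times, load)         # Pa
  scale_u <- displacement_waveform(times, load) / B_ref

  zero_w <- matrix(0, fsys$n_w, 3)
  if (fast_path) {
    solW <- solve_stokes(apply_fluid_bcs(fsys, 0, load, W_unit,
                                         pressure_pa = 0), tol = stokes_tol)
    solP <- solve_stokes(apply_fluid_bcs(fsys, 0, load, zero_w,
                                         pressure_pa = 1), tol = stokes_tol)
    fssW <- fss_components(fsys, solW$u, W_unit)
    fssP <- fss_components(fsys, solP$u, zero_w)
    fss <- matrix(0, fsys$n_w, n_steps)
    for (j in seq_len(n_steps)) {
      cj <- rate[j] * fssW + pres[j] * fssP
      fss[, j] <- sqrt(cj[, 1]^2 + cj[, 2]^2)
    }
    mbW <- mass_balance(solW)
    balance <- data.frame(t_s = times,
                          rel_imbalance = rep(mbW$rel_imbalance, n_steps))
    modes <- list(wall = solW, pressure = solP,
                  fss_wall = fssW, fss_pressure = fssP)
    step_solutions <- NULL
  } else {
    fss <- matrix(0, fsys$n_w, n_steps)
    balance <- data.frame(t_s = times, rel_imbalance = NA_real_)
    step_solutions <- vector("list", n_steps)
    for (j in seq_len(n_steps)) {
      wj <- rate[j] * W_unit
      sj <- tryCatch(
        solve_stokes(apply_fluid_bcs(fsys, times[j], load, wj,
                                     pressure_pa = pres[j]), tol = stokes_tol),
        error = function(e)
          stop(sprintf("fluid solve failed at t = %.4f s: %s",
                       times[j], conditionMessage(e))))
      f <- wall_shear_stress(sj)
      fss[, j] <- f$fss
      balance$rel_imbalance[j] <- mass_balance(sj)$rel_imbalance
      step_solutions[[j]] <- sj
    }
    modes <- NULL
  }

  # release the cached factorisations: snapshots and FSS extraction only
  # need the (small) incidence operators, and batch runs over many
  # geometries would otherwise accumulate gigabytes of factor memory
  rm(list = ls(envir = fsys$cache), envir = fsys$cache)
  invisible(gc(FALSE))

  iface <- interface_table(fsys)
  structure(
    list(times = times, fss = fss,
         mean_fss = colMeans(fss),
         interface = iface,
         solid_unit = usol, solid_scale = scale_u, B_ref_um = B_ref,
         rate_um_s = rate, pressure_pa = pres,
         balance = balance,
         modes = modes, step_solutions = step_solutions,
         wall_unit_velocity = W_unit,
         esys = esys, fsys = fsys,
         load = load, mat = mat, n_steps = n_steps,
         fast_path = fast_path),
    class = "cycle_result")
}

#' Two-mode superposition fast path
#'
#' Convenience wrapper for [run_cycle()] with the superposition fast path
#' enabled: one unit solid solve, one wall-driven and one pressure-driven
#' Stokes mode reconstruct the whole cycle.
#'
#' @inheritParams run_cycle
#' @return a `cycle_result`.
#' @export
superposition_fast_path <- function(domain, mat, load = load_spec(),
                                    n_steps = 20L, stokes_tol = 1e-10) {
  run_cycle(domain, mat, load, n_steps = n_steps, fast_path = TRUE,
            stokes_tol = stokes_tol)
}

# sparse map averaging the 4 finite-element face nodes of every wall face
wall_node_map <- function(fsys, esys) {
  d <- fsys$dims
  nd <- esys$node_grid
  n_w <- fsys$n_w
  rows <- integer(0); cols <- integer(0)
  for (a in 1:3) {
    sel <- which(fsys$wall_axis == a)
    if (!length(sel)) next
    fi <- fsys$wall_ijk[sel, , drop = FALSE]
    tang <- setdiff(1:3, a)
    for (b1 in 0:1) for (b2 in 0:1) {
      ni <- fi
      ni[, tang[1]] <- ni[, tang[1]] + b1
      ni[, tang[2]] <- ni[, tang[2]] + b2
      lin <- ni[, 1] + nd[1] * ((ni[, 2] - 1L) + nd[2] * (ni[, 3] - 1L))
      cmp <- esys$nmap[lin]
      if (any(cmp == 0L))
        stop("internal error: wall face node missing from the solid mesh")
      rows <- c(rows, sel)
      cols <- c(cols, cmp)
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = 0.25,
                       dims = c(n_w, length(esys$nodes)))
}

# wall-face table with physical coordinates (face centroids, um)
interface_table <- function(fsys) {
  h <- fsys$domain$pitch_um
  fi <- fsys$wall_ijk
  ax <- fsys$wall_axis
  xyz <- matrix(0, nrow(fi), 3)
  for (a in 1:3) {
    s <- ax == a
    for (c0 in 1:3) {
      xyz[s, c0] <- if (c0 == a) (fi[s, c0] - 1) * h else (fi[s, c0] - 0.5) * h
    }
  }
  data.frame(face_id = seq_len(nrow(fi)),
             axis = ax, sign = fsys$wall_sign,
             x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
             area_um2 = rep(h^2, nrow(fi)))
}

#' Reconstruct the field snapshot at one sampled time
#'
#' Scales the unit solid solution and (on the fast path) the two fluid
#' modes to the requested sample, returning full displacement, stress, von
#' Mises, velocity and pressure fields.
#'
#' @param result a `cycle_result`.
#' @param j time index into `result$times`.
#' @return list with `t_s`, `solid` (displacement um, stress and von Mises
#'   MPa) and `fluid` (face velocities m/s, cell pressure Pa).
#' @export
get_snapshot <- function(result, j) {
  stopifnot(inherits(result, "cycle_result"))
  j <- as.integer(j)
  if (j < 1L || j > result$n_steps) stop("time index out of range")
  su <- result$solid_scale[j]
  solid <- list(u_um = result$solid_unit$u_um * su,
                stress_mpa = result$solid_unit$stress_mpa * su,
                von_mises_mpa = result$solid_unit$von_mises_mpa * su)
  if (result$fast_path) {
    u <- result$rate_um_s[j] * result$modes$wall$u +
      result$pressure_pa[j] * result$modes$pressure$u
    p <- result$rate_um_s[j] * result$modes$wall$p +
      result$pressure_pa[j] * result$modes$pressure$p
  } else {
    u <- result$step_solutions[[j]]$u
    p <- result$step_solutions[[j]]$p
  }
  list(t_s = result$times[j], solid = solid,
       fluid = list(u = u, p = p))
}

#' Write a cycle result to a directory of CSV files
#'
#' Serialises the portable content of a `cycle_result` (times, per-face FSS
#' series, interface table, mean-FSS series) as plain CSV so a cycle can be
#' archived and re-read without re-running the solvers.
#'
#' @param result a `cycle_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cycle_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t_s = result$times,
                              mean_fss_pa = result$mean_fss,
                              rate_um_s = result$rate_um_s,
                              pressure_pa = result$pressure_pa),
                   file.path(dir, "series.csv"), row.names = FALSE)
  utils::write.csv(result$interface, file.path(dir, "interface.csv"),
                   row.names = FALSE)
  fss <- as.data.frame(result$fss)
  names(fss) <- sprintf("t%03d", seq_along(result$times))
  utils::write.csv(fss, file.path(dir, "fss.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read back a cycle result written by [write_cycle_result()]
#'
#' @param dir directory written by [write_cycle_result()].
#' @return list with `times`, `mean_fss`, `fss` matrix and `interface`
#'   table (class `cycle_result_archive`).
#' @export
read_cycle_result <- function(dir) {
  series <- utils::read.csv(file.path(dir, "series.csv"))
  iface <- utils::read.csv(file.path(dir, "interface.csv"))
  fss <- as.matrix(utils::read.csv(file.path(dir, "fss.csv")))
  dimnames(fss) <- NULL
  structure(list(times = series$t_s, mean_fss = series$mean_fss_pa,
                 rate_um_s = series$rate_um_s,
                 pressure_pa = series$pressure_pa,
                 fss = fss, interface = iface),
            class = "cycle_result_archive")
}
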