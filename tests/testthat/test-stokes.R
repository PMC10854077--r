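test_that("hydrostatic equilibrium: equal pressure, static walls, zero flow", {
  dom <- cube_in_bath_domain(n = 10L, s = 4L)
  fs <- assemble_stokes(dom, material_spec())
  sol <- solve_stokes(apply_fluid_bcs(fs, t = 0, load_spec(),
                                      uniform_wall_velocity(fs),
                                      pressure_pa = 667))
  expect_lt(max(abs(sol$u)), 1e-10)
  expect_equal(range(sol$p), c(667, 667), tolerance = 1e-9)
  # and the t = 0 waveform value is zero pressure
  sol0 <- solve_stokes(apply_fluid_bcs(fs, t = 0, load_spec(),
                                       uniform_wall_velocity(fs)))
  expect_equal(sol0$pressure_pa, rep(0, 6))
  expect_lt(max(abs(sol0$u)), 1e-14)
})

test_that("plane Couette reproduces the analytic wall shear mu*U/h", {
  mu <- 85.5
  gap <- 16L
  dom <- couette_domain(n_lat = 32L, gap = gap, slab = 8L)
  fs <- assemble_stokes(dom, material_spec())
  m <- dom$margin_vox
  sc <- arrayInd(fs$wall_solid, dim(dom$labels))
  top <- sc[, 3] > m + 8L + gap
  H <- gap * 18e-6
  U <- H / mu                      # gives mu*U/H = 1 Pa exactly
  wv <- matrix(0, fs$n_w, 3); wv[top, 1] <- U
  sol <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(), wv,
                                      pressure_pa = 0))
  f <- wall_shear_stress(sol)
  ctr <- which(fs$wall_axis == 3 & sc[, 3] %in% c(m + 8L, m + 8L + gap + 1L) &
                 abs(f$wall_ijk[, 1] - (m + 16)) <= 4 &
                 abs(f$wall_ijk[, 2] - (m + 16)) <= 4)
  expect_gt(length(ctr), 50)
  expect_true(all(abs(f$fss[ctr] - 1) < 0.01))
  # the example magnitude: U/h = 0.011696 per second gives FSS ~ 1 Pa
  expect_equal(U / H, 0.011696, tolerance = 1e-3)
  # zero-flow FSS is identically zero
  szero <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(),
                                        uniform_wall_velocity(fs),
                                        pressure_pa = 0))
  expect_equal(max(wall_shear_stress(szero)$fss), 0)
})

test_that("square-duct Poiseuille matches the series solution and the
           wall force balance", {
  mu <- 85.5; h <- 18e-6
  a_cells <- 16L
  dom <- duct_domain(n = 24L, a = a_cells)
  dd <- dim(dom$labels)
  m <- dom$margin_vox
  o <- m + (24L - a_cells) %/% 2
  fs <- assemble_stokes(dom, material_spec())
  sol <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(),
                                      uniform_wall_velocity(fs),
                                      pressure_pa = c(100, 0, 0, 0, 0, 0)))
  duct <- (o + 1):(o + a_cells)
  pmean <- function(i) mean(sol$p[fs$cid[i, duct, duct]])
  x1 <- m + 6L; x2 <- m + 18L
  G <- (pmean(x1) - pmean(x2)) / ((x2 - x1) * h)
  expect_gt(G, 0)
  # centreline-region velocity against the duct series solution
  jj <- o + a_cells %/% 2
  fid <- fs$uid[[1]][m + 13L, jj, jj]
  u_series <- duct_series_velocity((jj - o - 0.5) * h, (jj - o - 0.5) * h,
                                   a_cells * h, G, mu)
  expect_lt(abs(sol$u[fid] - u_series) / u_series, 0.05)
  # momentum balance: mean wall FSS = G * A / P_wet over a mid section
  f <- wall_shear_stress(sol)
  fc <- arrayInd(fs$wall_fluid, dd)
  sel <- which(fc[, 1] > x1 & fc[, 1] <= x2 & fs$wall_axis != 1 &
                 fc[, 2] %in% duct & fc[, 3] %in% duct)
  expect_lt(abs(mean(f$fss[sel]) - G * a_cells * h / 4) / (G * a_cells * h / 4),
            0.05)
})

test_that("solution is linear in the boundary data (superposition)", {
  dom <- generate_trabecular(geometry_spec(grid_n = 16L, bvtv_target = 0.35,
                                           seed = 9L))
  fs <- assemble_stokes(dom, material_spec())
  wv <- matrix(1e-6, fs$n_w, 3)
  sP <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(),
                                     uniform_wall_velocity(fs),
                                     pressure_pa = c(3, 1, 4, 1, 5, 9)))
  sV <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(), wv,
                                     pressure_pa = 0))
  sBoth <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(), 2 * wv,
                                        pressure_pa = 3 * c(3, 1, 4, 1, 5, 9)))
  expect_equal(sBoth$u, 3 * sP$u + 2 * sV$u,
               tolerance = 1e-7)
  # doubling wall velocities doubles the field
  s2V <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(), 2 * wv,
                                      pressure_pa = 0))
  expect_equal(s2V$u, 2 * sV$u, tolerance = 1e-9)
})

test_that("discrete incompressibility and global mass conservation hold", {
  dom <- generate_trabecular(geometry_spec(grid_n = 16L, bvtv_target = 0.3,
                                           seed = 12L))
  fs <- assemble_stokes(dom, material_spec())
  # wall velocities from an actual solid solve
  es <- assemble_elasticity(dom, material_spec())
  us <- solve_solid(apply_solid_bcs(es, t = NA, load_spec(), u_top_um = 0.8))
  Wmap <- marrowflow:::wall_node_map(fs, es)
  wv <- as.matrix(Wmap %*% us$u_um) * 1e-6 * pi  # rate-like scale, m/s
  sol <- solve_stokes(apply_fluid_bcs(fs, 0.25, load_spec(), wv))
  # per-cell divergence residual small against the characteristic shear
  # rate |u|/h (floor set by factorisation roundoff, not the CG tolerance)
  expect_lt(sol$div_residual_max * fs$h, 1e-6 * max(abs(sol$u)))
  mb <- mass_balance(sol)
  expect_lt(mb$rel_imbalance, 1e-6)
  expect_gt(mb$gross_flux_m3_s, 0)
})

test_that("sealed pore space is rejected at assembly", {
  dom <- cube_in_bath_domain(n = 10L, s = 5L)
  lab <- dom$labels
  lab[7, 7, 7] <- 0L   # sealed cavity inside the solid cube
  dom$labels <- lab
  expect_error(assemble_stokes(dom, material_spec()), "sealed")
})

test_that("wall velocity input is validated", {
  dom <- cube_in_bath_domain(n = 8L, s = 3L)
  fs <- assemble_stokes(dom, material_spec())
  expect_error(apply_fluid_bcs(fs, 0, load_spec(),
                               matrix(0, fs$n_w - 1L, 3)), "n_w x 3")
  wv <- uniform_wall_velocity(fs); wv[1, 2] <- NA
  expect_error(apply_fluid_bcs(fs, 0, load_spec(), wv), "missing")
})

test_that("duct centreline velocity converges with cross-section refinement", {
  mu <- 85.5; h <- 18e-6
  err <- sapply(c(8L, 16L), function(a_cells) {
    dom <- duct_domain(n = 24L, a = a_cells)
    m <- dom$margin_vox
    o <- m + (24L - a_cells) %/% 2
    fs <- assemble_stokes(dom, material_spec())
    sol <- solve_stokes(apply_fluid_bcs(fs, 0, load_spec(),
                                        uniform_wall_velocity(fs),
                                        pressure_pa = c(100, 0, 0, 0, 0, 0)))
    duct <- (o + 1):(o + a_cells)
    pmean <- function(i) mean(sol$p[fs$cid[i, duct, duct]])
    x1 <- m + 6L; x2 <- m + 18L
    G <- (pmean(x1) - pmean(x2)) / ((x2 - x1) * h)
    jj <- o + a_cells %/% 2
    fid <- fs$uid[[1]][m + 13L, jj, jj]
    u_series <- duct_series_velocity((jj - o - 0.5) * h, (jj - o - 0.5) * h,
                                     a_cells * h, G, mu)
    abs(sol$u[fid] - u_series) / u_series
  })
  expect_lt(err[2], err[1])        # finer cross-section is more accurate
  expect_lt(err[2], 0.05)
})
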