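test_that("element stiffness has the rigid-body nullspace and symmetry", {
  Ke <- marrowflow:::hex_stiffness(15.08e9, 0.3, 18e-6)
  expect_equal(Ke, t(Ke))
  for (c0 in 1:3) {
    tr <- rep(0, 24); tr[seq(c0, 24, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% tr)) / max(abs(Ke)), 1e-12)
  }
  # assembled operator on a 2x2x2 block is symmetric too
  dom <- solid_block_domain(n = 2L)
  sys <- assemble_elasticity(dom, material_spec())
  expect_true(Matrix::isSymmetric(sys$K))
})

test_that("confined compression reproduces the constrained modulus", {
  # homogeneous cube, bottom fixed, top displaced, near-rigid lateral
  # springs: uniaxial strain, sigma_axial = E(1-nu)/((1+nu)(1-2nu)) * eps
  n <- 8L
  dom <- solid_block_domain(n = n)
  mat <- material_spec(E_gpa = 15.08, nu = 0.3)
  sys <- assemble_elasticity(dom, mat)
  sol <- solve_solid(apply_solid_bcs(sys, t = 0.5, load_spec()))
  eps <- 0.8e-6 / (n * 18e-6)
  Cm <- 15.08e9 * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3))
  szz <- mean(abs(sol$stress_mpa[, 3])) * 1e6
  expect_lt(abs(szz - Cm * eps) / (Cm * eps), 0.005)
  # interior stress homogeneous (patch test)
  expect_lt(stats::sd(sol$stress_mpa[, 3]) / mean(abs(sol$stress_mpa[, 3])),
            1e-4)
})

test_that("with k = 0 and free sides a nu = 0 block is exactly uniaxial", {
  n <- 6L
  dom <- solid_block_domain(n = n)
  mat <- material_spec(E_gpa = 10, nu = 0)
  sys <- assemble_elasticity(dom, mat)
  sol <- solve_solid(apply_solid_bcs(sys, t = 0.5, load_spec(k_value = 0)))
  sigma <- 10e9 * 0.8e-6 / (n * 18e-6) / 1e6
  expect_equal(mean(sol$stress_mpa[, 3]), sigma, tolerance = 1e-9)
  expect_lt(max(abs(sol$stress_mpa[, c(1, 2, 4, 5, 6)])), sigma * 1e-8)
})

test_that("solution is linear in the prescribed displacement", {
  dom <- generate_trabecular(geometry_spec(grid_n = 16L, bvtv_target = 0.4,
                                           seed = 6L))
  sys <- assemble_elasticity(dom, material_spec())
  s1 <- solve_solid(apply_solid_bcs(sys, t = NA, load_spec(),
                                    u_top_um = 0.4))
  s2 <- solve_solid(apply_solid_bcs(sys, t = NA, load_spec(),
                                    u_top_um = 0.8))
  expect_equal(s2$u_um, 2 * s1$u_um, tolerance = 1e-10)
  expect_equal(s2$von_mises_mpa, 2 * s1$von_mises_mpa, tolerance = 1e-10)
  # zero load -> identically zero
  s0 <- solve_solid(apply_solid_bcs(sys, t = 0, load_spec()))
  expect_equal(max(abs(s0$u_um)), 0)
})

test_that("strain energy balances the work of the reaction forces", {
  n <- 6L
  dom <- solid_block_domain(n = n)
  sys <- assemble_elasticity(dom, material_spec())
  bc <- apply_solid_bcs(sys, t = 0.5, load_spec())
  sol <- solve_solid(bc)
  u <- as.vector(t(sol$u_um)) * 1e-6
  Ks <- sys$K + Matrix::Diagonal(length(u), bc$spring)
  # for prescribed-displacement loading, work = 1/2 u_c' f_reaction
  f <- as.numeric(Ks %*% u)
  work <- 0.5 * sum(u[bc$fixed] * f[bc$fixed])
  expect_equal(strain_energy(bc, sol), work, tolerance = 1e-10)
})

test_that("strain energy converges under grid refinement of the same body", {
  # same physical cube discretised at two resolutions
  e <- sapply(c(8L, 16L), function(n) {
    d <- n + 4L
    labels <- array(2L, dim = c(d, d, d))
    labels[3:(2 + n), 3:(2 + n), 3:(2 + n)] <- 1L
    dom <- voxel_domain(labels, pitch_um = 144 / n, margin_vox = 2L)
    sys <- assemble_elasticity(dom, material_spec())
    bc <- apply_solid_bcs(sys, t = NA, load_spec(), u_top_um = 0.8)
    strain_energy(bc, solve_solid(bc))
  })
  expect_lt(abs(e[2] - e[1]) / e[1], 0.02)
})

test_that("von Mises matches its closed forms", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(diag(3) * 7), 0)                  # hydrostatic
  tau <- 2.5
  expect_equal(von_mises(c(0, 0, 0, tau, 0, 0)), sqrt(3) * tau)  # pure shear
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- tau
  expect_equal(von_mises(m), sqrt(3) * tau)
  vals <- matrix(stats::rnorm(30), 5, 6)
  expect_true(all(von_mises(vals) >= 0))
})

test_that("pathological geometries are rejected with diagnostics", {
  dom <- cube_in_bath_domain(n = 10L, s = 4L)  # floating cube: no face contact
  sys <- assemble_elasticity(dom, material_spec())
  expect_error(apply_solid_bcs(sys, 0.5, load_spec()), "top/bottom")
  # disconnected solid caught at assembly
  lab <- dom$labels
  lab[3, 3, 3] <- 1L
  dom$labels <- lab
  expect_error(assemble_elasticity(dom, material_spec()), "connected")
})
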