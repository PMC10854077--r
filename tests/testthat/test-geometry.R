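test_that("generator hits the target bone volume fraction deterministically", {
  spec <- geometry_spec(grid_n = 24L, bvtv_target = 0.30, seed = 1L)
  d1 <- generate_trabecular(spec)
  d2 <- generate_trabecular(spec)
  expect_identical(d1$labels, d2$labels)
  expect_lt(abs(compute_bvtv(d1) - 0.30), 0.02)

  # different seed gives a different structure at the same BV/TV
  d3 <- generate_trabecular(geometry_spec(grid_n = 24L, bvtv_target = 0.30,
                                          seed = 2L))
  expect_false(identical(d1$labels, d3$labels))
  expect_lt(abs(compute_bvtv(d3) - 0.30), 0.02)
})

test_that("generator covers the printed group BV/TV range within tolerance", {
  for (bv in c(0.1296, 0.237, 0.4906, 0.768)) {
    dom <- generate_trabecular(geometry_spec(grid_n = 24L, bvtv_target = bv,
                                             seed = 11L))
    expect_lt(abs(compute_bvtv(dom) - bv), 0.02)
    # both phases single face-connected components, solid spans the load axis
    expect_true(marrowflow:::solid_spans_loading_axis(dom))
    expect_identical(
      marrowflow:::label_components(dom$labels == 1L)$ncomp, 1L)
    expect_identical(
      marrowflow:::label_components(dom$labels != 1L)$ncomp, 1L)
  }
})

test_that("threshold at bvtv 0.5 is the median of the smoothed field", {
  n <- 16L
  field <- marrowflow:::with_local_seed(5L, {
    noise <- array(stats::rnorm(n^3), dim = c(n, n, n))
    marrowflow:::gaussian_smooth_periodic(noise, sigma_vox = 2)
  })
  thr <- stats::quantile(field, probs = 1 - 0.5, names = FALSE)
  expect_equal(thr, stats::median(field))
  expect_equal(mean(field >= thr), 0.5, tolerance = 1 / n^3 * 2)
})

test_that("compute_bvtv counts solid over the core only", {
  dom <- solid_block_domain(n = 6L)
  expect_equal(compute_bvtv(dom), 1.0)
  lab <- dom$labels
  core <- marrowflow:::core_labels(dom)
  # half-solid core
  half <- core
  half[seq_len(dim(core)[1] / 2), , ] <- 0L
  lab[3:8, 3:8, 3:8] <- half
  dom$labels <- lab
  expect_equal(compute_bvtv(dom), 0.5)
})

test_that("cleanup removes islands, fills sealed cavities, is idempotent", {
  dom <- cube_in_bath_domain(n = 10L, s = 4L)
  lab <- dom$labels
  lab[dom$margin_vox + 1L, dom$margin_vox + 1L, dom$margin_vox + 1L] <- 1L
  dom$labels <- lab
  cleaned <- cleanup_connectivity(dom)
  # isolated voxel relabelled pore (the big cube is the largest component)
  expect_identical(cleaned$labels[3, 3, 3], 0L)

  # sealed one-voxel cavity inside the solid cube becomes solid
  dom2 <- cube_in_bath_domain(n = 10L, s = 5L)
  lab <- dom2$labels
  lab[7, 7, 7] <- 0L  # centre voxel of the 5-cube spanning indices 5..9
  dom2$labels <- lab
  cleaned2 <- cleanup_connectivity(dom2)
  expect_identical(cleaned2$labels[7, 7, 7], 1L)

  # idempotence and component counts never increase
  again <- cleanup_connectivity(cleaned2)
  expect_identical(again$labels, cleaned2$labels)
  clean_generated <- generate_trabecular(
    geometry_spec(grid_n = 20L, bvtv_target = 0.3, seed = 3L))
  expect_identical(cleanup_connectivity(clean_generated)$labels,
                   clean_generated$labels)
})

test_that("extreme targets that empty a phase raise the infeasibility error", {
  # at 99.9% solid the few pore voxels are sealed cavities; cleanup fills
  # them, the pore phase of the core empties, and generation must fail
  expect_error(
    generate_trabecular(geometry_spec(grid_n = 16L, bvtv_target = 0.999,
                                      seed = 1L)),
    class = "marrowflow_infeasible_geometry")
})

test_that("generated morphometry is isotropic under axis permutation", {
  # same seed's field, loading axis permuted: BV/TV identical by
  # construction; interface area within 10%
  areas <- sapply(1:10, function(s) {
    dom <- generate_trabecular(geometry_spec(grid_n = 20L, bvtv_target = 0.3,
                                             seed = s))
    surface_area(dom)
  })
  domp <- lapply(1:10, function(s) {
    dom <- generate_trabecular(geometry_spec(grid_n = 20L, bvtv_target = 0.3,
                                             seed = s, loading_axis = 1L))
    surface_area(dom)
  })
  expect_true(all(abs(unlist(domp) / areas - 1) < 0.10))
})

test_that("physical extents follow pitch times voxel counts", {
  dom <- generate_trabecular(geometry_spec(grid_n = 45L, bvtv_target = 0.3,
                                           seed = 2L, pitch_um = 18))
  ext <- domain_extent(dom)
  expect_equal(ext$core_edge_um, rep(810, 3))       # 45 x 18 um
  expect_equal(ext$total_edge_um, rep(882, 3))      # margin 2 voxels per side
})

test_that("mask write/read round-trips the labels", {
  dom <- generate_trabecular(geometry_spec(grid_n = 16L, bvtv_target = 0.35,
                                           seed = 4L))
  f <- tempfile(fileext = ".tif")
  on.exit(unlink(f))
  write_voxel_mask(dom, f)
  back <- load_voxel_mask(f, pitch_um = dom$pitch_um,
                          margin_vox = dom$margin_vox)
  expect_identical(back$labels, dom$labels)
  expect_equal(compute_bvtv(back), compute_bvtv(dom))
})

test_that("degenerate or malformed masks are rejected", {
  f <- tempfile(fileext = ".tif")
  on.exit(unlink(f))
  pages <- lapply(1:8, function(k) matrix(0, 8, 8))
  tiff::writeTIFF(pages, f, bits.per.sample = 8L)
  expect_error(load_voxel_mask(f), class = "marrowflow_infeasible_geometry")
  expect_error(load_voxel_mask(tempfile(fileext = ".tif")), "not found")
})

test_that("vtk export writes a readable legacy header", {
  dom <- cube_in_bath_domain(n = 6L, s = 2L)
  f <- tempfile(fileext = ".vtk")
  on.exit(unlink(f))
  write_vtk_image(dom, f)
  head <- readLines(f, n = 8)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "STRUCTURED_POINTS")
  d <- dim(dom$labels)
  expect_match(head[5], sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1))
})
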