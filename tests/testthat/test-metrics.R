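test_that("central crop retains the centred sub-cube and nothing else", {
  dom <- generate_trabecular(geometry_spec(grid_n = 48L, bvtv_target = 0.3,
                                           seed = 2L, margin_vox = 2L))
  # voxel centroids of the whole core
  m <- dom$margin_vox; n <- 48L; h <- dom$pitch_um
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  xyz <- as.matrix(g + m - 0.5) * h
  keep <- crop_center(xyz, dom, core_fraction = 0.875)
  # 48 * 0.875 = 42 voxels per edge
  expect_equal(sum(keep), 42L^3)
  # identity at fraction 1
  expect_true(all(crop_center(xyz, dom, core_fraction = 1)))
  # a uniform field's summary is unchanged by cropping
  vals <- rep(3.7, nrow(xyz))
  s_all <- summarize_field(vals)
  s_crop <- summarize_field(vals, keep)
  expect_equal(s_crop$mean, s_all$mean)
  expect_equal(s_crop$sd, 0)
})

test_that("section slices pick the layer nearest the fractional height", {
  dom <- generate_trabecular(geometry_spec(grid_n = 48L, bvtv_target = 0.3,
                                           seed = 2L))
  m <- dom$margin_vox; n <- 48L; h <- dom$pitch_um
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  xyz <- as.matrix(g + m - 0.5) * h
  sl <- section_slices(xyz, dom, fractions = c(0.25, 0.5, 0.75))
  # fraction 1/2 of 48 layers is layer 24
  expect_equal(unique(g$z[sl[["0.5"]]]), 24L)
  expect_equal(unique(g$z[sl[["0.25"]]]), 12L)
  expect_equal(unique(g$z[sl[["0.75"]]]), 36L)
  # slice of a constant field is constant; a monotone-in-height field
  # yields ordered slice means, mirroring the expected section gradient
  fz <- g$z * 0.1
  means <- sapply(sl, function(k) mean(fz[k]))
  expect_true(means[["0.25"]] < means[["0.5"]] &&
                means[["0.5"]] < means[["0.75"]])
  cf <- rep(2, nrow(xyz))
  expect_equal(unique(cf[sl[["0.5"]]]), 2)
})

test_that("FSS band proportions partition the interface", {
  b <- fss_bin_proportions(rep(2, 10))
  expect_equal(b$proportions, c(0, 0, 1, 0))
  b2 <- fss_bin_proportions(c(0.05, 0.5, 2, 5))
  expect_equal(b2$proportions, rep(0.25, 4))
  # half-open edges: 0.1 goes up, 3 goes up
  b3 <- fss_bin_proportions(c(0.1, 3))
  expect_equal(b3$proportions, c(0, 0.5, 0, 0.5))
  # partition of unity on simulated values
  x <- abs(stats::rnorm(1000, 1.5, 2))
  expect_equal(sum(fss_bin_proportions(x)$proportions), 1, tolerance = 1e-12)
})

test_that("time-fraction-in-band matches analytic duty cycles", {
  expect_equal(time_fraction_in_band(matrix(2, 5, 10), c(1, 3), 0.5), 1)
  expect_equal(time_fraction_in_band(matrix(5, 5, 10), c(1, 3), 0.5), 0)
  # faces scaled off a rectified sinusoid with known duty cycle: a face
  # with peak FSS p spends the fraction of samples with p|cos| in band
  n_t <- 40L
  tt <- seq(0, 1, length.out = n_t + 1L)[seq_len(n_t)]
  duty <- abs(cos(2 * pi * tt))
  peaks <- c(0.5, 1.5, 2.0, 3.5, 8.0)
  fss <- outer(peaks, duty)
  frac_exp <- sapply(peaks, function(p)
    mean(p * duty >= 1 & p * duty < 3) > 0.5)
  expect_equal(time_fraction_in_band(fss, c(1, 3), 0.5), mean(frac_exp))
  # monotone non-increasing in min_fraction
  fr <- sapply(c(0.2, 0.4, 0.6, 0.8), function(mf)
    time_fraction_in_band(fss, c(1, 3), mf))
  expect_true(all(diff(fr) <= 0))
})

test_that("field summaries agree with a brute-force quantile oracle", {
  s <- summarize_field(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  x <- marrowflow:::with_local_seed(7L, stats::runif(1000) * 10)
  s2 <- summarize_field(x)
  xs <- sort(x)
  # type-7 linear interpolation oracle, computed from scratch
  qq <- function(p) {
    k <- (length(xs) - 1) * p
    lo <- floor(k)
    xs[lo + 1] * (1 - (k - lo)) + xs[lo + 2] * (k - lo)
  }
  expect_equal(s2$median, qq(0.5))
  expect_equal(s2$q1, qq(0.25))
  expect_equal(s2$q3, qq(0.75))
  expect_equal(s2$sd, sqrt(mean((x - mean(x))^2)))
  expect_error(summarize_field(numeric(0)), "empty")
})

test_that("peak_time recovers the rate peak and honours the tie rule", {
  tt <- seq(0, 0.95, by = 0.05)
  spec <- load_spec()
  expect_equal(peak_time(tt, displacement_rate(tt, spec), period = 1), 0.25)
  # constant series returns the first sample
  expect_equal(peak_time(tt, rep(1, 20), period = 1), 0)
  # quadratic refinement beats the sample spacing on a shifted parabola
  y <- -(tt - 0.337)^2
  expect_lt(abs(peak_time(tt, y, period = 1) - 0.337), 0.05 / 2)
})
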