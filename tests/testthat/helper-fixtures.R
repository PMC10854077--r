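# shared fixtures: small hand-built domains with known geometry

# empty fluid box with an all-solid cubic core
solid_block_domain <- function(n = 8L, m = 2L, pitch_um = 18) {
  d <- n + 2L * m
  labels <- array(2L, dim = c(d, d, d))
  labels[(m + 1):(m + n), (m + 1):(m + n), (m + 1):(m + n)] <- 1L
  voxel_domain(labels, pitch_um, margin_vox = m)
}

# fluid box with a floating solid cube of edge `s` centred in an n^3 core
cube_in_bath_domain <- function(n = 10L, s = 4L, m = 2L, pitch_um = 18) {
  d <- n + 2L * m
  labels <- array(2L, dim = c(d, d, d))
  labels[(m + 1):(m + n), (m + 1):(m + n), (m + 1):(m + n)] <- 0L
  o <- m + (n - s) %/% 2
  labels[(o + 1):(o + s), (o + 1):(o + s), (o + 1):(o + s)] <- 1L
  voxel_domain(labels, pitch_um, margin_vox = m)
}

# plane-Couette fixture: two slabs of thickness `slab` spanning the core,
# separated by a fluid gap of `gap` cells along z
couette_domain <- function(n_lat = 32L, gap = 16L, slab = 8L, m = 2L,
                           pitch_um = 18) {
  stopifnot(2L * slab + gap <= n_lat)
  n_z <- 2L * slab + gap
  d <- c(n_lat, n_lat, n_z) + 2L * m
  labels <- array(2L, dim = d)
  labels[(m + 1):(m + n_lat), (m + 1):(m + n_lat), (m + 1):(m + n_z)] <- 0L
  labels[(m + 1):(m + n_lat), (m + 1):(m + n_lat), (m + 1):(m + slab)] <- 1L
  labels[(m + 1):(m + n_lat), (m + 1):(m + n_lat),
         (m + slab + gap + 1):(m + n_z)] <- 1L
  voxel_domain(labels, pitch_um, margin_vox = m)
}

# square duct of side `a` cells along x through an otherwise solid core
duct_domain <- function(n = 24L, a = 16L, m = 2L, pitch_um = 18) {
  o <- m + (n - a) %/% 2
  d <- n + 2L * m
  labels <- array(2L, dim = c(d, d, d))
  labels[(m + 1):(m + n), (m + 1):(m + n), (m + 1):(m + n)] <- 1L
  labels[(m + 1):(m + n), (o + 1):(o + a), (o + 1):(o + a)] <- 0L
  voxel_domain(labels, pitch_um, margin_vox = m)
}

# analytic rectangular-duct axial velocity (square side a_m, gradient G Pa/m)
duct_series_velocity <- function(y_m, z_m, a_m, G, mu, n_terms = 199L) {
  s <- 0
  for (k in seq(1, n_terms, by = 2)) {
    s <- s + (1 / k^3) *
      (1 - cosh(k * pi * (z_m - a_m / 2) / a_m) / cosh(k * pi / 2)) *
      sin(k * pi * y_m / a_m)
  }
  4 * G * a_m^2 / (mu * pi^3) * s
}

# uniform wall-velocity matrix for a set of wall faces
uniform_wall_velocity <- function(fsys, v = c(0, 0, 0), faces = NULL) {
  wv <- matrix(0, fsys$n_w, 3)
  if (is.null(faces)) faces <- seq_len(fsys$n_w)
  wv[faces, ] <- matrix(v, length(faces), 3, byrow = TRUE)
  wv
}
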