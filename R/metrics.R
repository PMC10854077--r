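#' Restrict entities to a centred sub-cube of the core
#'
#' Retains entities whose centroids fall inside a centred sub-cube of the
#' solid core, discarding the near-boundary shell where edge effects
#' dominate.  The default fraction 0.875 corresponds to analysing a 0.7 mm
#' sub-cube of a 0.8 mm core.
#'
#' Index rounding: the sub-cube edge (in voxels) is the target length
#' rounded to the nearest integer with exact halves rounded down, and the
#' leading offset is `floor((n - s) / 2)`; this makes crops bit-reproducible.
#'
#' @param xyz_um n x 3 matrix (or data.frame columns `x_um`, `y_um`,
#'   `z_um`) of entity centroid coordinates in the domain's physical frame.
#' @param domain the [voxel_domain()] the coordinates refer to.
#' @param core_fraction fraction of the core edge retained, in (0, 1].
#' @return logical vector marking retained entities.
#' @export
crop_center <- function(xyz_um, domain, core_fraction = 0.875) {
  if (!(core_fraction > 0 && core_fraction <= 1))
    stop("core_fraction must lie in (0, 1]")
  if (is.data.frame(xyz_um))
    xyz_um <- cbind(xyz_um$x_um, xyz_um$y_um, xyz_um$z_um)
  xyz_um <- as.matrix(xyz_um)
  m <- domain$margin_vox
  h <- domain$pitch_um
  keep <- rep(TRUE, nrow(xyz_um))
  for (a in 1:3) {
    n <- domain$core_dim[a]
    s <- half_down(n * core_fraction)
    off <- floor((n - s) / 2)
    lo <- (m + off) * h
    hi <- (m + off + s) * h
    keep <- keep & xyz_um[, a] >= lo & xyz_um[, a] <= hi
  }
  if (!any(keep)) stop("central crop is empty")
  keep
}

# round to nearest integer, exact .5 towards the lower integer
half_down <- function(x) ceiling(x - 0.5)

#' Extract section slices along the loading axis
#'
#' Returns, for each requested fractional height, the indices of entities
#' whose centroid lies in the voxel layer nearest that fraction of the core
#' height (fraction 1/2 of a 48-layer core is layer 24).
#'
#' @inheritParams crop_center
#' @param fractions fractional heights in (0, 1), e.g. `c(0.25, 0.5, 0.75)`.
#' @return named list of logical vectors, one per fraction.
#' @export
section_slices <- function(xyz_um, domain, fractions = c(0.25, 0.5, 0.75)) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly in (0, 1)")
  if (is.data.frame(xyz_um))
    xyz_um <- cbind(xyz_um$x_um, xyz_um$y_um, xyz_um$z_um)
  xyz_um <- as.matrix(xyz_um)
  a <- domain$loading_axis
  m <- domain$margin_vox
  h <- domain$pitch_um
  n <- domain$core_dim[a]
  out <- list()
  for (f in fractions) {
    layer <- max(1L, half_down(n * f))
    lo <- (m + layer - 1L) * h
    hi <- (m + layer) * h
    out[[sprintf("%g", f)]] <- xyz_um[, a] >= lo & xyz_um[, a] <= hi
  }
  out
}

#' FSS band proportions at one sampled time
#'
#' Fraction of wall faces whose FSS falls into each of the mechanobiological
#' bands: below 0.1 Pa (osteoclast recruitment range), 0.1-1 Pa, 1-3 Pa
#' (osteoblast activation range), above 3 Pa.  Band edges are half-open
#' `[low, high)`; the top band is `[3, Inf)`.
#'
#' @param fss_t numeric vector of FSS values (Pa) at one time, one per wall
#'   face (e.g. a column of `cycle_result$fss`).
#' @param edges inner band edges in Pa.
#' @return list with `proportions` (named, sums to 1), `counts` and `n`.
#' @export
fss_bin_proportions <- function(fss_t, edges = c(0.1, 1, 3)) {
  if (!length(fss_t)) stop("empty interface")
  br <- c(-Inf, edges, Inf)
  labs <- c(sprintf("<%g", edges[1]),
            sprintf("%g-%g", edges[-length(edges)], edges[-1]),
            sprintf(">%g", edges[length(edges)]))
  cnt <- table(cut(fss_t, breaks = br, right = FALSE, labels = labs))
  list(proportions = as.numeric(cnt) / length(fss_t),
       band = labs, counts = as.integer(cnt), n = length(fss_t))
}

#' Fraction of the surface loaded in a band for most of the cycle
#'
#' Fraction of wall faces whose FSS lies within `[low, high)` for strictly
#' more than `min_fraction` of the sampled times -- e.g. the share of the
#' bone surface stimulated in the 1-3 Pa osteoblast band for more than half
#' of the loading cycle.
#'
#' @param fss wall-face FSS matrix (faces x times, Pa).
#' @param band length-2 numeric `(low, high)` in Pa.
#' @param min_fraction time-fraction threshold in (0, 1).
#' @return single proportion in `[0, 1]`.
#' @export
time_fraction_in_band <- function(fss, band = c(1, 3), min_fraction = 0.5) {
  if (band[1] >= band[2]) stop("band must satisfy low < high")
  if (!(min_fraction > 0 && min_fraction < 1))
    stop("min_fraction must lie in (0, 1)")
  inband <- fss >= band[1] & fss < band[2]
  frac <- rowMeans(inband)
  mean(frac > min_fraction)
}

#' Summary statistics of a scalar field over a region
#'
#' Mean, population standard deviation, median and quartiles (linear
#' interpolation) of a field restricted to a region.
#'
#' @param values numeric field values.
#' @param keep optional logical vector restricting the region.
#' @param region_label optional label carried through to the output.
#' @param time time stamp carried through to the output.
#' @return a one-row data.frame with columns `region`, `t_s`, `n`, `mean`,
#'   `sd`, `median`, `q1`, `q3`.
#' @export
summarize_field <- function(values, keep = NULL, region_label = "all",
                            time = NA_real_) {
  if (!is.null(keep)) values <- values[keep]
  if (!length(values)) stop("empty region")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(region = region_label, t_s = time, n = length(values),
             mean = mean(values),
             sd = sqrt(mean((values - mean(values))^2)),
             median = q[2], q1 = q[1], q3 = q[3])
}

#' Peak time of a periodic series by quadratic interpolation
#'
#' Returns the argmax of a series sampled uniformly over one period,
#' refined by fitting a parabola through the maximum sample and its two
#' (cyclic) neighbours.  Ties and constant series return the first sample
#' time.
#'
#' Samples within `tie_tol` (relative) of the maximum count as tied and the
#' earliest wins: a rectified shear series has two humps per period whose
#' heights agree to solver precision, and the physical peak is the first.
#'
#' @param times sample times spanning one period (uniform, length >= 8).
#' @param series values at those times.
#' @param period the period; defaults to `length(times) * dt`.
#' @param tie_tol relative height tolerance for declaring a tie.
#' @return interpolated peak time in `[0, period)`.
#' @export
peak_time <- function(times, series, period = NULL, tie_tol = 1e-3) {
  n <- length(times)
  if (n < 8L || length(series) != n)
    stop("need >= 8 samples spanning one period")
  dt <- times[2] - times[1]
  if (is.null(period)) period <- n * dt
  j <- peak_index(series, tie_tol)
  ym <- series[ifelse(j == 1L, n, j - 1L)]
  y0 <- series[j]
  yp <- series[ifelse(j == n, 1L, j + 1L)]
  den <- ym - 2 * y0 + yp
  delta <- if (den >= 0) 0 else 0.5 * (ym - yp) / den
  tpk <- times[j] + delta * dt
  tpk %% period
}

# earliest index among epsilon-tied maxima (shared tie rule with peak_time);
# the tie band is relative to the series range so constant series return 1
peak_index <- function(series, tie_tol = 1e-3) {
  rng <- max(series) - min(series)
  if (rng == 0) return(1L)
  min(which(series >= max(series) - tie_tol * rng))
}
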