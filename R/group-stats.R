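#' Kruskal-Wallis comparison of a per-sample statistic across groups
#'
#' Rank-based K-sample test with tie correction, with the p-value from the
#' chi-square approximation (K - 1 degrees of freedom).  With very few
#' samples per group -- the emulated study has three -- the chi-square
#' approximation is crude, so a Monte-Carlo permutation p-value can be
#' requested as a companion.
#'
#' @param values numeric vector of per-sample statistics.
#' @param groups group labels (factor or character), same length.
#' @param n_perm if > 0, also compute a permutation p-value with this many
#'   label permutations (seeded, reproducible).
#' @param perm_seed seed for the permutation draw.
#' @return list with `H`, `df`, `p_value`, optional `p_permutation`, `n`,
#'   and a small-sample flag.
#' @export
kruskal_wallis <- function(values, groups, n_perm = 0L, perm_seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) < 5L) stop("need total n >= 5")
  kt <- stats::kruskal.test(values, groups)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value, n = length(values),
              small_sample = min(table(groups)) < 5L)
  if (all(values == values[1])) {
    out$H <- 0; out$p_value <- 1; out$degenerate <- TRUE
  }
  if (n_perm > 0L) {
    obs <- out$H
    exceed <- with_local_seed(perm_seed, {
      cnt <- 0L
      for (i in seq_len(n_perm)) {
        Hp <- suppressWarnings(
          stats::kruskal.test(values, sample(groups))$statistic)
        if (Hp >= obs - 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
    out$p_permutation <- (exceed + 1) / (n_perm + 1)
  }
  out
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' two-sided p-values from the normal distribution, Bonferroni-adjusted
#' over the number of pairs.  The standard companion to the Kruskal-Wallis
#' test when the omnibus null is rejected.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return list with symmetric matrices `z`, `p_raw`, `p_adjusted`
#'   (unit diagonal) and the group sizes; groups with fewer than 2 samples
#'   have their comparisons set to `NA`.
#' @export
posthoc_pairwise <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  r <- rank(values)
  n <- length(values)
  nn <- tabulate(groups, k)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  z <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (nn[i] < 2L || nn[j] < 2L) next
    se <- sqrt(s2 * (1 / nn[i] + 1 / nn[j]))
    z[i, j] <- z[j, i] <- (rbar[i] - rbar[j]) / se
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  n_pairs <- k * (k - 1) / 2
  p_adj <- switch(adjust,
                  bonferroni = array(pmin(1, p_raw * n_pairs), dim(p_raw),
                                     dimnames(p_raw)),
                  none = p_raw,
                  stop("unknown adjustment: ", adjust))
  diag(z) <- 0; diag(p_raw) <- 1; diag(p_adj) <- 1
  list(z = z, p_raw = p_raw, p_adjusted = p_adj, n_per_group = nn,
       method = paste0("dunn_", adjust))
}

#' Per-group robust descriptives
#'
#' Median and quartiles per group with the same linear-interpolation
#' quantile rule as [summarize_field()].
#'
#' @inheritParams kruskal_wallis
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `q1`, `q3`.
#' @export
group_descriptives <- function(values, groups) {
  groups <- factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}
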