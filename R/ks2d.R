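#' Quadrant fractions around an origin
#'
#' Fractions of a bivariate sample falling in the four open quadrants around
#' an origin. Points exactly on either dividing line (or on the origin) are
#' excluded, so the four fractions sum to at most 1. Quadrants are ordered
#' (+,+), (-,+), (-,-), (+,-) relative to the origin.
#'
#' @param points two-column numeric matrix (or data.frame) of (x, y) pairs.
#' @param origin numeric length-2 vector (x, y).
#' @return Numeric vector of 4 fractions.
#' @export
quadrant_fractions <- function(points, origin) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, length(origin) == 2, nrow(points) >= 1)
  gx <- points[, 1] > origin[1]; lx <- points[, 1] < origin[1]
  gy <- points[, 2] > origin[2]; ly <- points[, 2] < origin[2]
  c(mean(gx & gy), mean(lx & gy), mean(lx & ly), mean(gx & ly))
}

# max over origins (rows of `orig`) of the max quadrant-fraction difference
# between samples a and b; strict inequalities throughout
max_quadrant_diff <- function(orig, a, b) {
  d <- 0
  gxa <- outer(orig[, 1], a[, 1], `<`); lxa <- outer(orig[, 1], a[, 1], `>`)
  gya <- outer(orig[, 2], a[, 2], `<`); lya <- outer(orig[, 2], a[, 2], `>`)
  gxb <- outer(orig[, 1], b[, 1], `<`); lxb <- outer(orig[, 1], b[, 1], `>`)
  gyb <- outer(orig[, 2], b[, 2], `<`); lyb <- outer(orig[, 2], b[, 2], `>`)
  na <- ncol(gxa); nb <- ncol(gxb)
  for (q in 1:4) {
    fa <- switch(q, rowSums(gxa & gya), rowSums(lxa & gya),
                 rowSums(lxa & lya), rowSums(gxa & lya)) / na
    fb <- switch(q, rowSums(gxb & gyb), rowSums(lxb & gyb),
                 rowSums(lxb & lyb), rowSums(gxb & lyb)) / nb
    d <- max(d, max(abs(fa - fb)))
  }
  d
}

#' Two-dimensional two-sample Kolmogorov-Smirnov statistic
#'
#' Quadrant statistic with origins at the sample points: for each data point
#' of a sample, the four open-quadrant fractions of both samples are compared
#' and the largest absolute difference kept; D is the mean of the two maxima
#' obtained with origins running over sample 1 and over sample 2.
#'
#' @param s1,s2 two-column numeric matrices/data.frames of (x, y) pairs.
#' @return D in \[0, 1\]; symmetric in its arguments and invariant under
#'   strictly monotone transformations applied jointly to one coordinate of
#'   both samples.
#' @export
ks2d_statistic <- function(s1, s2) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  stopifnot(ncol(s1) == 2, ncol(s2) == 2,
            all(is.finite(s1)), all(is.finite(s2)))
  (max_quadrant_diff(s1, s1, s2) + max_quadrant_diff(s2, s1, s2)) / 2
}

# standard KS tail series Q_KS(lambda) = 2 sum_j (-1)^(j-1) exp(-2 j^2 lambda^2)
ks_tail <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Analytic p-value for the 2D two-sample KS statistic
#'
#' Tail approximation in the style used for the sample-origin quadrant
#' statistic: \eqn{p = Q_{KS}(\lambda)} with
#' \deqn{\lambda = \frac{D \sqrt{n_{eff}}}{1 + \sqrt{1 - \bar r^2}\,(0.25 - 0.75/\sqrt{n_{eff}})}},
#' \eqn{n_{eff} = n_1 n_2 / (n_1 + n_2)}, and \eqn{\bar r} the mean of the two
#' samples' Pearson correlation coefficients.
#'
#' @param d_stat observed statistic D in \[0, 1\].
#' @param n1,n2 sample sizes (each >= 3).
#' @param r_mean mean Pearson correlation of the two samples (|r| < 1).
#' @return Approximate p-value in (0, 1\].
#' @export
ks2d_pvalue_analytic <- function(d_stat, n1, n2, r_mean = 0) {
  stopifnot(n1 >= 3, n2 >= 3, d_stat >= 0, d_stat <= 1)
  if (abs(r_mean) >= 1) stop("|r_mean| must be < 1")
  n_eff <- n1 * n2 / (n1 + n2)
  lambda <- d_stat * sqrt(n_eff) /
    (1 + sqrt(1 - r_mean^2) * (0.25 - 0.75 / sqrt(n_eff)))
  ks_tail(lambda)
}

#' Permutation p-value for the 2D two-sample KS statistic
#'
#' Label permutation of the pooled sample with the add-one estimator
#' \eqn{(1 + \#\{D^{perm} \ge D^{obs}\}) / (n_{perm} + 1)}, so the p-value is
#' always in (0, 1\].
#'
#' @param s1,s2 two-column numeric matrices/data.frames.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return Permutation p-value.
#' @export
ks2d_pvalue_permutation <- function(s1, s2, n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 100)
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  d_obs <- ks2d_statistic(s1, s2)
  pool <- rbind(s1, s2)
  n1 <- nrow(s1); n <- nrow(pool)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    d_b <- ks2d_statistic(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
    if (d_b >= d_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' Compares two bivariate samples (for the GF data: per-terminal latency or
#' following frequency paired with gap-junction occupancy) with the quadrant
#' statistic. The analytic tail approximation is the default; a seeded label
#' permutation p-value is available, and each comparison is reported
#' unadjusted (separate, independent tests).
#'
#' @param s1,s2 two-column numeric matrices/data.frames with >= 3 rows each.
#' @param method `"analytic"`, `"permutation"` or `"both"`.
#' @param n_perm permutations when a permutation p-value is requested.
#' @param seed seed for the permutation draw.
#' @return An object of classes `"ks2d_test"` and `"htest"` with `statistic`
#'   (D), `p.value` (per `method`; the analytic value when `method = "both"`),
#'   `p.analytic`/`p.permutation` as available, sample sizes and `r_mean`.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(40), ncol = 2)
#' b <- matrix(rnorm(40, mean = 1), ncol = 2)
#' ks2d_test(a, b)
#' @export
ks2d_test <- function(s1, s2, method = c("analytic", "permutation", "both"),
                      n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  stopifnot(nrow(s1) >= 3, nrow(s2) >= 3)
  short <- function(e) {
    txt <- deparse1(e)
    if (nchar(txt) > 40) paste0(substr(txt, 1, 37), "...") else txt
  }
  dname <- paste(short(substitute(s1)), "and", short(substitute(s2)))
  d <- ks2d_statistic(s1, s2)
  r_mean <- mean(c(stats::cor(s1[, 1], s1[, 2]), stats::cor(s2[, 1], s2[, 2])))
  if (!is.finite(r_mean)) r_mean <- 0  # degenerate (constant) coordinate
  p_an <- if (method %in% c("analytic", "both"))
    ks2d_pvalue_analytic(d, nrow(s1), nrow(s2), r_mean) else NULL
  p_pm <- if (method %in% c("permutation", "both"))
    ks2d_pvalue_permutation(s1, s2, n_perm, seed) else NULL
  structure(list(statistic = c(D = d),
                 p.value = if (method == "permutation") p_pm else p_an,
                 p.analytic = p_an, p.permutation = p_pm,
                 n1 = nrow(s1), n2 = nrow(s2), r_mean = r_mean,
                 method = "2D two-sample Kolmogorov-Smirnov (quadrant) test",
                 alternative = "the two bivariate distributions differ",
                 data.name = dname),
            class = c("ks2d_test", "htest"))
}
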