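#' Distributional recipe for one genotype
#'
#' Means, SDs and sample size of the three per-terminal measures (response
#' latency, 100 Hz following frequency, gap-junction % of terminal volume)
#' plus the correlations tying them together and the expected fraction of
#' bilateral terminals. Used by [generate_terminals()] to synthesize
#' per-terminal records with the summary structure of the measured genotypes.
#'
#' @param name genotype label.
#' @param n_terminals number of unit terminals to generate.
#' @param latency_mean,latency_sd latency average and SD (ms; mean > 0).
#' @param freq_mean,freq_sd 100 Hz following frequency average and SD (%).
#' @param gj_mean,gj_sd gap-junction occupancy average and SD (% volume).
#' @param rho_lat_gj,rho_freq_gj,rho_lat_freq pairwise correlations in (-1, 1);
#'   defaults -0.5, +0.5, -0.5 (lower occupancy goes with longer latency and
#'   lower following).
#' @param bilateral_fraction expected fraction of terminals belonging to
#'   bilateral GFs.
#' @param source `"printed"` when mean/SD/n are published values, `"assumed"`
#'   when filled in as declared assumptions.
#' @return An object of class `"genotype_spec"`.
#' @export
genotype_spec <- function(name, n_terminals, latency_mean, latency_sd,
                          freq_mean, freq_sd, gj_mean, gj_sd,
                          rho_lat_gj = -0.5, rho_freq_gj = 0.5,
                          rho_lat_freq = -0.5, bilateral_fraction = 0,
                          source = "printed") {
  stopifnot(n_terminals >= 1, latency_mean > 0, latency_sd >= 0,
            freq_mean >= 0, freq_mean <= 100, freq_sd >= 0,
            gj_mean >= 0, gj_mean <= 100, gj_sd >= 0,
            abs(rho_lat_gj) < 1, abs(rho_freq_gj) < 1, abs(rho_lat_freq) < 1,
            bilateral_fraction >= 0, bilateral_fraction <= 1)
  structure(list(name = name, n_terminals = as.integer(n_terminals),
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 freq_mean = freq_mean, freq_sd = freq_sd,
                 gj_mean = gj_mean, gj_sd = gj_sd,
                 rho_lat_gj = rho_lat_gj, rho_freq_gj = rho_freq_gj,
                 rho_lat_freq = rho_lat_freq,
                 bilateral_fraction = bilateral_fraction, source = source),
            class = "genotype_spec")
}

#' Default genotype table
#'
#' The twelve study groups: the LOF reference plus the eleven comparison
#' groups (control sibling, full-length and domain-dissected rescue
#' constructs, wild-type unablated/ablated, and the gap-junction-null
#' ablation groups), each with its latency / following / occupancy mean, SD
#' and terminal count. Groups whose occupancy or physiology summaries were
#' never published carry declared stand-in values and are flagged
#' `source = "assumed"` (or `"mixed"` when only part of the row is assumed);
#' see the package vignette for the reasoning behind each.
#'
#' @return List of [genotype_spec()] objects, named by genotype.
#' @examples
#' tab <- default_genotype_table()
#' tab$control_sibling$latency_mean   # 0.93 ms
#' @export
default_genotype_table <- function() {
  g <- list(
    genotype_spec("fra_LOF", 35, 1.18, 0.30, 68.55, 30.53, 5.31, 2.40,
                  bilateral_fraction = 0.45),
    genotype_spec("control_sibling", 16, 0.93, 0.07, 98.3, 2.44, 9.04, 1.33),
    genotype_spec("UAS_Frazzled", 38, 1.07, 0.20, 87.17, 22.90, 7.5, 2.5,
                  bilateral_fraction = 0.45, source = "mixed"),
    genotype_spec("UAS_FraICD", 23, 0.97, 0.06, 98.40, 3.16, 9.0, 1.5,
                  bilateral_fraction = 0.2, source = "mixed"),
    genotype_spec("UAS_FraE1354A", 13, 1.33, 0.60, 52.69, 38.72, 4.18, 2.75,
                  bilateral_fraction = 0.45),
    genotype_spec("UAS_FraDeltaP1", 7, 1.80, 0.61, 54.05, 29.14, 7.65, 2.53,
                  bilateral_fraction = 0.85),
    genotype_spec("UAS_FraDeltaP2", 20, 1.40, 0.25, 54.05, 29.14, 8.26, 3.85,
                  bilateral_fraction = 0.8),
    genotype_spec("UAS_FraDeltaP3", 12, 1.46, 0.69, 60.00, 31.67, 5.37, 1.41,
                  bilateral_fraction = 0.5),
    genotype_spec("wildtype_unablated", 8, 0.90, 0.08, 99.0, 1.5, 9.5, 1.5,
                  source = "assumed"),
    genotype_spec("wildtype_ablated", 22, 0.95, 0.10, 95.0, 5.0, 9.65, 5.76,
                  bilateral_fraction = 1, source = "mixed"),
    genotype_spec("shakB2_het_ablated", 14, 1.00, 0.15, 92.0, 8.0, 9.0, 3.0,
                  bilateral_fraction = 1, source = "assumed"),
    genotype_spec("shakB2_ablated", 10, 1.60, 0.50, 30.0, 20.0, 1.0, 0.5,
                  bilateral_fraction = 1, source = "mixed"))
  stats::setNames(g, vapply(g, `[[`, character(1), "name"))
}

#' Generate synthetic per-terminal records for one genotype
#'
#' Draws (latency, frequency, occupancy) triples from a correlated trivariate
#' Gaussian at the genotype's means/SDs, truncates latency and occupancy at
#' zero (rejection sampling) and clamps the following frequency into
#' \[0, 100\] so ceiling effects pile mass at 100%. The fraction of draws
#' altered by truncation or clamping is recorded in the `"clamp_fraction"`
#' attribute. Deterministic given `seed`.
#'
#' @param spec a [genotype_spec()] (or one element of
#'   [default_genotype_table()]).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return `data.frame` with columns `genotype`, `fly_id`, `side`,
#'   `phenotype_class`, `latency_ms`, `response_pct`, `gj_pct`; one row per
#'   unit terminal.
#' @export
generate_terminals <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"))
  R <- matrix(c(1, spec$rho_lat_freq, spec$rho_lat_gj,
                spec$rho_lat_freq, 1, spec$rho_freq_gj,
                spec$rho_lat_gj, spec$rho_freq_gj, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix (rho_lat_gj, rho_freq_gj, rho_lat_freq) is not positive semi-definite")
  mu <- c(spec$latency_mean, spec$freq_mean, spec$gj_mean)
  sd <- c(spec$latency_sd, spec$freq_sd, spec$gj_sd)
  Sigma <- diag(sd) %*% R %*% diag(sd)

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- spec$n_terminals
  x <- MASS::mvrnorm(n, mu, Sigma)
  if (n == 1) x <- matrix(x, nrow = 1)
  n_redrawn <- 0L
  repeat {  # truncate latency > 0 and occupancy >= 0 by redrawing
    bad <- which(x[, 1] <= 0 | x[, 3] < 0)
    if (length(bad) == 0) break
    n_redrawn <- n_redrawn + length(bad)
    x[bad, ] <- MASS::mvrnorm(length(bad), mu, Sigma)
  }
  freq_raw <- x[, 2]
  freq <- pmin(pmax(freq_raw, 0), 100)
  gj <- pmin(x[, 3], 100)
  n_clamped <- sum(freq_raw != freq) + sum(x[, 3] != gj)
  bilateral <- stats::runif(n) < spec$bilateral_fraction

  out <- data.frame(
    genotype = spec$name,
    fly_id = sprintf("%s_fly%02d", spec$name, (seq_len(n) + 1L) %/% 2L),
    side = rep_len(c("left", "right"), n),
    phenotype_class = ifelse(bilateral, "bilateral", "wild-type-appearing"),
    latency_ms = x[, 1], response_pct = freq, gj_pct = gj,
    stringsAsFactors = FALSE)
  attr(out, "clamp_fraction") <- (n_redrawn + n_clamped) / (3 * n)
  out
}

#' Generate terminals for every genotype in a table
#'
#' @param table list of [genotype_spec()]s, as from
#'   [default_genotype_table()].
#' @param seed master seed; each genotype uses a derived child seed.
#' @return Combined `data.frame` of terminal records.
#' @export
generate_all_terminals <- function(table = default_genotype_table(), seed = 1) {
  do.call(rbind, c(lapply(seq_along(table), function(i)
    generate_terminals(table[[i]], seed = child_seed(seed, 100L, i))),
    list(make.row.names = FALSE)))
}

#' Per-genotype summary of terminal records
#'
#' Grouped mean/SD/n of latency, following frequency and occupancy, in the
#' reporting format of the study (empty groups are omitted, not zero-filled).
#'
#' @param records terminal `data.frame` from [generate_terminals()] (possibly
#'   row-bound across genotypes).
#' @return `data.frame` with one row per genotype present.
#' @export
summarize_terminals <- function(records) {
  stopifnot(nrow(records) >= 1)
  split_by <- split(records, factor(records$genotype,
                                    levels = unique(records$genotype)))
  rows <- lapply(split_by, function(d) {
    sdv <- function(x) if (length(x) > 1) stats::sd(x) else 0
    data.frame(genotype = d$genotype[1], n = nrow(d),
               latency_mean = mean(d$latency_ms), latency_sd = sdv(d$latency_ms),
               freq_mean = mean(d$response_pct), freq_sd = sdv(d$response_pct),
               gj_mean = mean(d$gj_pct), gj_sd = sdv(d$gj_pct))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Genotype comparison table of 2D KS tests
#'
#' For every genotype other than the reference, tests (latency, occupancy)
#' and, separately, (following frequency, occupancy) against the reference
#' group with [ks2d_test()], flagging significance at `alpha`. This mirrors
#' the study's comparison layout: one row per non-reference genotype and two
#' p-value columns. Groups with fewer than 3 terminals are skipped with a
#' warning.
#'
#' @param records combined terminal `data.frame`.
#' @param reference reference genotype label (default `"fra_LOF"`).
#' @param alpha significance level; default 0.05.
#' @param method p-value method passed to [ks2d_test()].
#' @param n_perm,seed permutation settings when used.
#' @return `data.frame` with columns `genotype`, `n_ref`, `n`, `d_lat_gj`,
#'   `p_lat_gj`, `sig_lat_gj`, `d_freq_gj`, `p_freq_gj`, `sig_freq_gj`.
#' @export
table1_comparisons <- function(records, reference = "fra_LOF", alpha = 0.05,
                               method = "analytic", n_perm = 999, seed = NULL) {
  stopifnot(reference %in% records$genotype)
  ref <- records[records$genotype == reference, ]
  others <- setdiff(unique(records$genotype), reference)
  rows <- list()
  for (k in seq_along(others)) {
    g <- others[k]
    d <- records[records$genotype == g, ]
    if (nrow(d) < 3) {
      warning("genotype ", g, " has fewer than 3 terminals; skipped")
      next
    }
    t_lat <- ks2d_test(ref[, c("latency_ms", "gj_pct")],
                       d[, c("latency_ms", "gj_pct")],
                       method = method, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else child_seed(seed, 200L, k))
    t_frq <- ks2d_test(ref[, c("response_pct", "gj_pct")],
                       d[, c("response_pct", "gj_pct")],
                       method = method, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else child_seed(seed, 201L, k))
    rows[[g]] <- data.frame(
      genotype = g, n_ref = nrow(ref), n = nrow(d),
      d_lat_gj = unname(t_lat$statistic), p_lat_gj = t_lat$p.value,
      sig_lat_gj = t_lat$p.value < alpha,
      d_freq_gj = unname(t_frq$statistic), p_freq_gj = t_frq$p.value,
      sig_freq_gj = t_frq$p.value < alpha)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
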