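test_that("the default genotype table carries the published summary statistics", {
  tab <- default_genotype_table()
  expect_length(tab, 12)
  cs <- tab$control_sibling
  expect_equal(c(cs$latency_mean, cs$latency_sd, cs$n_terminals),
               c(0.93, 0.07, 16))
  expect_equal(c(cs$freq_mean, cs$freq_sd), c(98.3, 2.44))
  expect_equal(c(cs$gj_mean, cs$gj_sd), c(9.04, 1.33))
  lof <- tab$fra_LOF
  expect_equal(c(lof$gj_mean, lof$gj_sd, lof$n_terminals), c(5.31, 2.40, 35))
  expect_equal(c(lof$latency_mean, lof$latency_sd), c(1.18, 0.30))
  expect_equal(c(lof$freq_mean, lof$freq_sd), c(68.55, 30.53))
  icd <- tab$UAS_FraICD
  expect_equal(c(icd$freq_mean, icd$freq_sd, icd$n_terminals),
               c(98.40, 3.16, 23))
  # default correlation signs: low occupancy with long latency / low following
  expect_true(all(vapply(tab, `[[`, numeric(1), "rho_lat_gj") < 0))
  expect_true(all(vapply(tab, `[[`, numeric(1), "rho_freq_gj") > 0))
  # declared assumptions are flagged, printed rows are not
  expect_equal(tab$control_sibling$source, "printed")
  expect_true(tab$wildtype_unablated$source != "printed")
})

test_that("degenerate zero-SD specs reproduce the means exactly", {
  sp <- genotype_spec("degenerate", 5, 1.0, 0, 90, 0, 8, 0)
  rec <- generate_terminals(sp, seed = 1)
  expect_equal(rec$latency_ms, rep(1.0, 5))
  expect_equal(rec$response_pct, rep(90, 5))
  expect_equal(rec$gj_pct, rep(8, 5))
})

test_that("generation is reproducible from the seed and respects ranges", {
  sp <- default_genotype_table()$fra_LOF
  a <- generate_terminals(sp, seed = 42)
  b <- generate_terminals(sp, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 35)
  expect_true(all(a$latency_ms > 0))
  expect_true(all(a$response_pct >= 0 & a$response_pct <= 100))
  expect_true(all(a$gj_pct >= 0 & a$gj_pct <= 100))
  expect_true(is.numeric(attr(a, "clamp_fraction")))
  expect_named(a, c("genotype", "fly_id", "side", "phenotype_class",
                    "latency_ms", "response_pct", "gj_pct"))
})

test_that("large-n generation recovers the specified moments and correlation", {
  sp <- genotype_spec("big", 1e4, 0.93, 0.07, 80, 10, 9.04, 1.33)
  rec <- generate_terminals(sp, seed = 7)
  se <- function(s, n) s / sqrt(n)
  expect_lt(abs(mean(rec$latency_ms) - 0.93), 4 * se(0.07, 1e4))
  expect_lt(abs(mean(rec$gj_pct) - 9.04), 4 * se(1.33, 1e4))
  expect_lt(abs(mean(rec$response_pct) - 80), 4 * se(10, 1e4))
  expect_equal(sd(rec$latency_ms), 0.07, tolerance = 0.05)
  # correlation before truncation effects (none here: values far from bounds)
  expect_lt(abs(cor(rec$latency_ms, rec$gj_pct) - (-0.5)), 0.05)
  expect_lt(abs(cor(rec$response_pct, rec$gj_pct) - 0.5), 0.05)
})

test_that("an infeasible correlation matrix is rejected", {
  sp <- genotype_spec("bad", 10, 1, 0.1, 80, 5, 9, 1,
                      rho_lat_gj = -0.9, rho_freq_gj = 0.9,
                      rho_lat_freq = 0.9)
  expect_error(generate_terminals(sp, seed = 1), "positive semi-definite")
})

test_that("summaries match the reporting format and omit empty groups", {
  sp <- genotype_spec("solo", 1, 1.1, 0, 90, 0, 8, 0)
  one <- generate_terminals(sp, seed = 1)
  s <- summarize_terminals(one)
  expect_equal(s$latency_mean, 1.1)
  expect_equal(s$latency_sd, 0)
  expect_equal(s$n, 1)
  rec <- generate_all_terminals(seed = 2)
  s2 <- summarize_terminals(rec)
  expect_equal(nrow(s2), 12)          # only genotypes present, none zero-filled
  expect_equal(sort(s2$genotype), sort(unique(rec$genotype)))
})

test_that("comparison table has one row per non-reference genotype", {
  rec <- generate_all_terminals(seed = 5)
  tab <- table1_comparisons(rec)
  expect_equal(nrow(tab), 11)
  expect_false("fra_LOF" %in% tab$genotype)
  expect_true(all(tab$p_lat_gj > 0 & tab$p_lat_gj <= 1))
})

test_that("a genotype compared with itself is not flagged", {
  sp <- default_genotype_table()$fra_LOF
  a <- generate_terminals(sp, seed = 21)
  b <- generate_terminals(sp, seed = 22)
  b$genotype <- "fra_LOF_twin"
  tab <- table1_comparisons(rbind(a, b))
  expect_false(tab$sig_lat_gj)
  expect_gt(tab$p_lat_gj, 0.05)
})

test_that("undersized groups are skipped with a warning", {
  rec <- generate_all_terminals(seed = 6)
  tiny <- generate_terminals(genotype_spec("tiny", 2, 1, 0.1, 90, 5, 9, 1),
                             seed = 1)
  expect_warning(tab <- table1_comparisons(rbind(rec, tiny)), "tiny")
  expect_false("tiny" %in% tab$genotype)
})
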