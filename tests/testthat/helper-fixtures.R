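# shared fixtures: noise-free protocols and small bivariate samples

quiet_single <- function(...) single_pulse_spec(noise_sd = 0, ...)
quiet_train <- function(...) train_spec(noise_sd = 0, ...)

# deterministic calibrated circuit at a given occupancy
fixture_circuit <- function(occupancy = 9.04, ...) {
  gf_circuit(occupancy = occupancy, ...)
}

# seeded bivariate normal sample
rbvn <- function(n, mean = c(0, 0), rho = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cbind(mean[1] + x, mean[2] + y)
}

# brute-force 2D KS oracle: explicit loops over origins and quadrants,
# independent of the vectorized implementation
ks2d_brute <- function(s1, s2) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  qfrac <- function(s, ox, oy, q) {
    n <- nrow(s); cnt <- 0
    for (i in seq_len(n)) {
      x <- s[i, 1]; y <- s[i, 2]
      inq <- switch(q, x > ox && y > oy, x < ox && y > oy,
                    x < ox && y < oy, x > ox && y < oy)
      if (inq) cnt <- cnt + 1
    }
    cnt / n
  }
  dmax <- function(orig) {
    d <- 0
    for (i in seq_len(nrow(orig)))
      for (q in 1:4) {
        diff <- abs(qfrac(s1, orig[i, 1], orig[i, 2], q) -
                      qfrac(s2, orig[i, 1], orig[i, 2], q))
        if (diff > d) d <- diff
      }
    d
  }
  (dmax(s1) + dmax(s2)) / 2
}
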