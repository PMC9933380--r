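# Shared fixtures and independent oracles for the suite.

# Prolate reference phantom used across tests: a = b = 20, c = 40 mm.
prolate_phantom <- function(theta = 0, lambda = 0, ...) {
  make_phantom(20, 20, 40, theta_deg = theta, lambda = lambda, ...)
}

# Spherical static phantom (constant volume curve) of radius r.
static_sphere <- function(r, ...) {
  make_phantom(r, r, r, volume_curve_params = list(
    lavmin = 4 / 3 * pi * r^3, lavmax = 4 / 3 * pi * r^3), ...)
}

# Textbook Bland-Altman recomputation with explicit sums.
ba_oracle <- function(m, r) {
  d <- m - r
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  mm <- sum(m) / n; rr <- sum(r) / n
  rho <- sum((m - mm) * (r - rr)) /
    sqrt(sum((m - mm)^2) * sum((r - rr)^2))
  list(bias = bias, sd = sdd, lo = bias - 1.96 * sdd, hi = bias + 1.96 * sdd,
       r = rho)
}

# ICC(A,1) recomputed from scratch through an aov() two-way decomposition.
icc_oracle <- function(Y) {
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(nrow(Y)), ncol(Y))),
                   rater = factor(rep(seq_len(ncol(Y)), each = nrow(Y))))
  ms <- anova(stats::aov(y ~ subj + rater, data = df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(Y); k <- ncol(Y)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# The default simulated study is expensive; compute it once per test run.
.study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.study_cache$res)) .study_cache$res <- run_study(study_config())
  .study_cache$res
}
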