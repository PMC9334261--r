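# Independent oracles used across the suite. These deliberately re-derive
# quantities by a different route than the package implementation.

# direct evaluation of the Marko-Siggia interpolation formula
oracle_ms_force <- function(z, Lc, Lp, kBT) {
  (kBT / Lp) * (0.25 * (1 - z / Lc)^-2 - 0.25 + z / Lc)
}

# thermal energy at the default bath temperature
oracle_kBT <- 0.0138065 * 296.15

# batch-means Monte-Carlo standard error of the chain mean, and an effective
# sample size derived from it
mc_error <- function(x, n_batches = 100) {
  n <- length(x)
  batch <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * batch + 1):(b * batch)])
  }, numeric(1))
  se_mean <- stats::sd(means) / sqrt(n_batches)
  n_eff <- max(4, (stats::sd(x) / se_mean)^2)
  list(se_mean = se_mean, n_eff = n_eff, se_sd = stats::sd(x) / sqrt(2 * n_eff))
}

# total-variation distance between a sample and a quadrature summary over a
# common set of bins
tv_distance <- function(values, summary, bin_width = 0.5) {
  lo <- summary$range[1]
  hi <- summary$range[2]
  edges <- seq(lo, hi + bin_width, by = bin_width)
  p_model <- summary$cdf(pmin(edges[-1], hi)) - summary$cdf(edges[-length(edges)])
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p_emp <- tabulate(idx, nbins = length(edges) - 1L) / length(values)
  0.5 * sum(abs(p_model - p_emp))
}
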