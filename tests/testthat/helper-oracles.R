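# Independent oracles and fixture builders shared across the suite.
# Every oracle is a deliberately naive implementation kept separate from the
# package's own code paths.

# brute-force BH step-up: q_i = min over { j : p_(j) >= p_i-rank } of k p_(j)/j
brute_force_bh <- function(p) {
  k <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(k), function(i) {
    min(pmin(k * p[ord][i:k] / (i:k), 1))
  }, numeric(1))
  q <- numeric(k)
  q[ord] <- q_sorted
  q
}

# the published short-form FIQT transform (p.adjust + signed quantile)
reference_fiqt <- function(z, min_p = 1e-300) {
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  p[p < min_p] <- min_p
  q <- p.adjust(p, method = "fdr")
  sign(z) * qnorm(q / 2, lower.tail = FALSE)
}

# grid-search maximizer of the two-sided truncated-normal conditional
# log-likelihood; the independent check for the TA conditional MLE
grid_search_ta <- function(z, c, step = 1e-4) {
  az <- abs(z)
  grid <- seq(-az - 1, az + 1, by = step)
  ll <- dnorm(az - grid, log = TRUE) -
    log(pnorm(grid - c) + pnorm(-grid - c))
  sign(z) * grid[which.max(ll)]
}

# ARMA autocorrelations from the MA(infinity) psi-weight convolution:
# rho(h) = sum_j psi_j psi_{j+h} / sum_j psi_j^2, psi_0 = 1.
# Independent route from the autocovariance recursion the package uses.
psi_weight_acf <- function(ar, ma, max_lag, trunc = 50000) {
  psi <- c(1, ARMAtoMA(ar = ar, ma = ma, lag.max = trunc))
  g0 <- sum(psi^2)
  vapply(0:max_lag, function(h) {
    sum(psi[1:(trunc + 1 - h)] * psi[(1 + h):(trunc + 1)]) / g0
  }, numeric(1))
}

# Monte-Carlo standard error of the mean of a correlated sequence via
# non-overlapping batch means
batch_means_se <- function(x, n_batches = 100) {
  b <- floor(length(x) / n_batches)
  bm <- vapply(seq_len(n_batches), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  sd(bm) / sqrt(n_batches)
}

# small delimited sumstats fixture on disk; returns the path (the file lives
# as long as `envir`, by default the calling test)
write_sumstats_fixture <- function(df, sep = "\t", envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

desk_config <- function(...) simulation_config(...)
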