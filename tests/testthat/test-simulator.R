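# Genome-scan simulator: ARMA residual process, theoretical ACF, causal-
# effect placement with LD-shaped decay.

test_that("the ARMA spec enforces stationarity at construction", {
  expect_s3_class(arma_spec(), "arma_spec")
  expect_error(arma_spec(ar = c(1.2)), class = "wincurse_config_error")
  expect_error(arma_spec(ar = c(0.6, 0.6)), class = "wincurse_config_error")
})

test_that("theoretical ACF matches closed forms and the psi-weight oracle", {
  # white noise
  wn <- arma_spec(ar = numeric(0), ma = numeric(0))
  expect_equal(theoretical_acf(wn, 5), c(1, 0, 0, 0, 0, 0))
  # AR(1): rho(h) = phi^h
  ar1 <- arma_spec(ar = 0.5, ma = numeric(0))
  expect_equal(theoretical_acf(ar1, 8), 0.5^(0:8), tolerance = 1e-10)
  # default spec: strong local correlation, agreement with independent route
  spec <- arma_spec()
  rho <- theoretical_acf(spec, 10)
  expect_gt(rho[2], 0.5)
  expect_equal(rho, psi_weight_acf(spec$ar, spec$ma, 10), tolerance = 1e-8)
})

test_that("residuals have unit variance and the theoretical autocorrelation", {
  k <- 1e6
  x <- simulate_arma_residuals(k, seed = 51)
  se_var <- batch_means_se(x^2)                  # MC s.e. of the variance
  expect_lt(abs(mean(x^2) - 1), 3 * se_var)

  rho_hat <- drop(acf(x, lag.max = 10, plot = FALSE, demean = TRUE)$acf)[-1]
  rho <- theoretical_acf(arma_spec(), 10)[-1]
  for (h in 1:10) {
    se_h <- batch_means_se(x[-seq_len(h)] * x[seq_len(k - h)])
    expect_lt(abs(rho_hat[h] - rho[h]), 3 * se_h)
  }
})

test_that("residual generation is deterministic given a seed", {
  expect_identical(simulate_arma_residuals(5000, seed = 52),
                   simulate_arma_residuals(5000, seed = 52))
  expect_false(identical(simulate_arma_residuals(5000, seed = 52),
                         simulate_arma_residuals(5000, seed = 53)))
})

test_that("true means honour the causal fraction, spacing and sqrt(n) scaling", {
  spec <- arma_spec()
  # gamma_c = 0: pure null
  mu0 <- build_true_means(simulation_config(k = 5e4, gamma_c = 0), spec, seed = 54)
  expect_true(all(mu0 == 0))

  # gamma_c = 1 on a scan big enough for 180 loci 1 Mb apart
  cfg1 <- simulation_config(k = 4e5, gamma_c = 1)
  mu1 <- build_true_means(cfg1, spec, seed = 55)
  idx <- attr(mu1, "causal_index")
  expect_length(idx, 180)
  expect_true(all(diff(sort(idx)) >= 1000))        # 1 Mb at 1 SNP/kbp
  expect_true(all(attr(mu1, "causal_mu") >= 5.45)) # genome-wide significant peaks

  # sqrt(gamma_s) scaling: 2 vs 1/2 gives exactly double, same support
  cfg_hi <- simulation_config(k = 1e5, gamma_c = 1 / 4, gamma_s = 2)
  cfg_lo <- simulation_config(k = 1e5, gamma_c = 1 / 4, gamma_s = 1 / 2)
  hi <- build_true_means(cfg_hi, spec, seed = 56)
  lo <- build_true_means(cfg_lo, spec, seed = 56)
  nz <- lo != 0
  expect_identical(which(hi != 0), which(nz))
  expect_equal(hi[nz] / lo[nz], rep(2, sum(nz)))
})

test_that("neighbors of a causal locus inherit ACF-decayed means", {
  spec <- arma_spec()
  cfg <- simulation_config(k = 1e5, gamma_c = 1 / 32)   # m1 = 6
  mu <- build_true_means(cfg, spec, seed = 57)
  all_idx <- attr(mu, "causal_index")
  # pick a locus > 3 kernel-widths from every other locus and both scan ends
  iso <- which(vapply(seq_along(all_idx), function(j) {
    d <- abs(all_idx[j] - all_idx[-j])
    all(d > 3000) && all_idx[j] > 3000 && all_idx[j] < cfg$k - 3000
  }, logical(1)))[1]
  expect_false(is.na(iso))
  idx <- all_idx[iso]
  peak <- attr(mu, "causal_mu")[iso]
  rho <- theoretical_acf(spec, 10)
  # isolated locus: neighbor means are exactly peak * rho(lag)
  expect_equal(mu[idx + 1], peak * rho[2], tolerance = 1e-8)
  expect_equal(mu[idx - 5], peak * rho[6], tolerance = 1e-8)
  # beyond the truncated kernel the contribution vanishes
  expect_equal(mu[c(idx - 2000, idx + 2000)], c(0, 0))
})

test_that("unattainable spacing is a configuration error", {
  expect_error(build_true_means(simulation_config(k = 5e4, gamma_c = 1),
                                seed = 58),
               class = "wincurse_config_error")
})

test_that("simulated null scans are calibrated and seed-reproducible", {
  cfg <- simulation_config(k = 1e5, gamma_c = 0)
  s <- simulate_scan(cfg, seed = 59)
  expect_true(all(s$true_mu == 0))
  frac <- mean(abs(s$z) > 1.96)
  se <- batch_means_se(abs(s$z) > 1.96)
  expect_lt(abs(frac - 0.05), 3 * se)

  s2 <- simulate_scan(cfg, seed = 59)
  expect_identical(s$z, s2$z)

  # different master seeds, pinned mean seed: same truth, different noise
  cfg_a <- simulation_config(k = 1e5, gamma_c = 1 / 4)
  a <- simulate_scan(cfg_a, seed = 60, mean_seed = 99)
  b <- simulate_scan(cfg_a, seed = 61, mean_seed = 99)
  expect_identical(a$true_mu, b$true_mu)
  expect_false(identical(a$z, b$z))
  # causal statistics sit far from zero: peaks are >= 5.45 by construction
  expect_gt(mean(a$z[a$causal_index]), 3)
})

test_that("a simulated scan converts to a scan_stats table", {
  s <- simulate_scan(simulation_config(k = 2000, gamma_c = 0), seed = 62)
  st <- as_scan_stats(s)
  expect_s3_class(st, "scan_stats")
  expect_equal(nrow(st), 2000)
  expect_equal(attr(st, "true_mu"), s$true_mu)
  expect_equal(diff(st$pos_bp), rep(1000, 1999))
})
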