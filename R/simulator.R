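# Genome-scan simulator: height-patterned causal effects with LD-shaped
# decay in neighboring SNPs, plus ARMA(3,4)-correlated unit-variance
# residuals standing in for linkage disequilibrium among null statistics.
#
# The default ARMA coefficients describe a near-unit-root process whose
# lag-1 autocorrelation exceeds 0.5 - the empirical correlation profile of
# scan statistics at a marker density of ~1 SNP per kbp.

#' ARMA residual specification
#'
#' @param ar AR coefficients (default the calibrated ARMA(3,4) values
#'   `c(0.8716, 0.9782, -0.851)`).
#' @param ma MA coefficients (default `c(-0.665, -0.998, 0.659, 0.025)`).
#' @return An `arma_spec` object.  Construction fails if any root of the AR
#'   characteristic polynomial lies inside or on the unit circle
#'   (non-stationary process).
#' @export
arma_spec <- function(ar = c(0.8716, 0.9782, -0.851),
                      ma = c(-0.665, -0.998, 0.659, 0.025)) {
  ar <- as.numeric(ar); ma <- as.numeric(ma)
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1 + 1e-6))
    abort_config("non-stationary ARMA spec: AR characteristic roots must lie outside the unit circle")
  structure(list(ar = ar, ma = ma), class = "arma_spec")
}

#' @export
print.arma_spec <- function(x, ...) {
  cat(sprintf("arma_spec: ARMA(%d,%d); ar = (%s), ma = (%s)\n",
              length(x$ar), length(x$ma),
              paste(x$ar, collapse = ", "), paste(x$ma, collapse = ", ")))
  invisible(x)
}

#' Theoretical autocorrelation function of an ARMA spec
#'
#' Exact autocorrelations rho(0..max_lag) of the stationary ARMA process,
#' via the standard autocovariance recursion (`stats::ARMAacf`).
#'
#' @param spec an [arma_spec].
#' @param max_lag largest lag.
#' @return numeric vector of length `max_lag + 1`, `rho[1] = rho(0) = 1`.
#' @export
theoretical_acf <- function(spec, max_lag) {
  stopifnot(inherits(spec, "arma_spec"))
  if (!length(spec$ar) && !length(spec$ma))   # white noise
    return(c(1, rep(0, max_lag)))
  unname(stats::ARMAacf(ar = spec$ar, ma = spec$ma, lag.max = max_lag))
}

# stationary variance of the ARMA process per unit innovation variance:
# 1 + sum(psi_j^2) with psi the MA(inf) weights, truncated adaptively
arma_stationary_variance <- function(spec, tol = 1e-10) {
  lag <- 2048L
  repeat {
    psi <- stats::ARMAtoMA(ar = spec$ar, ma = spec$ma, lag.max = lag)
    tail_mass <- sum(psi[(lag %/% 2 + 1):lag]^2)
    total <- 1 + sum(psi^2)
    if (tail_mass < tol * total || lag >= 2^20) return(total)
    lag <- lag * 2L
  }
}

#' Simulate unit-variance ARMA residuals
#'
#' Generates a stationary realization of the ARMA process with Gaussian
#' innovations.  The innovation standard deviation is set from the
#' theoretical stationary variance (not by empirical rescaling) so the
#' marginal variance of the output is exactly 1; a burn-in prefix is
#' discarded to wash out initialization (the default spec is near unit
#' root, so the default burn-in is long).
#'
#' @param k number of residuals to return.
#' @param spec an [arma_spec].
#' @param seed integer seed; same seed gives a bit-identical realization.
#' @param burn_in discarded warm-up length (default 10000).
#' @return numeric vector of length `k`.
#' @export
simulate_arma_residuals <- function(k, spec = arma_spec(), seed = NULL,
                                    burn_in = 10000) {
  stopifnot(inherits(spec, "arma_spec"))
  if (k < 1) abort_domain("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sd_innov <- 1 / sqrt(arma_stationary_variance(spec))
  as.numeric(stats::arima.sim(model = list(ar = spec$ar, ma = spec$ma),
                              n = k, n.start = burn_in, sd = sd_innov))
}

#' Simulation configuration
#'
#' Study-design parameters of the simulated genome scan: `k` SNPs laid out
#' at 1 per kbp, `m1 = round(gamma_c * m_base)` causal loci whose
#' noncentralities scale with the square root of the relative sample size
#' `gamma_s`.
#'
#' @param k SNP count (default 2,866,105, one SNP per kbp over the
#'   autosomes; scale down for desk-size runs).
#' @param gamma_s relative sample size (design levels 1/8, 1/4, 1/2, 1, 2);
#'   noncentralities scale by `sqrt(gamma_s)`.
#' @param gamma_c causal fraction of the `m_base` reference loci (design
#'   levels 0, 1/32, 1/16, 1/8, 1/4, 1/2, 1); `gamma_c = 0` is the pure
#'   null scan.
#' @param m_base number of reference significant loci patterning the effect
#'   profile (default 180, the height mega-analysis count).
#' @param n_reps replicate count for evaluation runs (default 250).
#' @param burn_in ARMA warm-up length (default 10000).
#' @param ld_decay_floor smallest autocorrelation at which a causal locus
#'   still contributes mean to a neighboring SNP (default 0.01).
#' @param min_spacing_bp minimum distance between causal loci (default 1 Mb).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(k = 2866105L, gamma_s = 1, gamma_c = 0,
                              m_base = 180L, n_reps = 250L,
                              burn_in = 10000L, ld_decay_floor = 0.01,
                              min_spacing_bp = 1e6) {
  if (gamma_s <= 0) abort_config("gamma_s must be > 0")
  if (gamma_c < 0 || gamma_c > 1) abort_config("gamma_c must lie in [0, 1]")
  m1 <- as.integer(round(gamma_c * m_base))
  if (m1 > k) abort_config("more causal loci than SNPs")
  structure(list(k = as.integer(k), gamma_s = gamma_s, gamma_c = gamma_c,
                 m_base = as.integer(m_base), m1 = m1,
                 n_reps = as.integer(n_reps), burn_in = as.integer(burn_in),
                 ld_decay_floor = ld_decay_floor,
                 min_spacing_bp = min_spacing_bp),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: k = %d SNPs, gamma_s = %.4g, gamma_c = %.4g (m1 = %d causal), %d reps\n",
              x$k, x$gamma_s, x$gamma_c, x$m1, x$n_reps))
  invisible(x)
}

#' Reference effect-size profile for causal loci
#'
#' Noncentralities (at relative sample size 1) emulating the top hits of a
#' large height mega-analysis: all genome-wide significant, with a
#' realistically decaying tail above the significance quantile.  Drawn once
#' from 5.45 + Exponential(mean 1.5) under a fixed internal seed, so the
#' profile is a package constant; supply your own vector to
#' [build_true_means()] to use real reported effect sizes instead.
#'
#' @param m_base number of loci (default 180).
#' @return numeric vector of length `m_base`, all >= 5.45.
#' @export
reference_effect_profile <- function(m_base = 180L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20160513L)  # package constant: the profile is data, not a dial
  5.45 + stats::rexp(m_base, rate = 1 / 1.5)
}

#' Ground-truth mean vector of a simulated scan
#'
#' Builds the length-`k` vector of true noncentralities: `m1` causal loci
#' drawn at random from the reference profile, scaled by `sqrt(gamma_s)`,
#' placed at uniformly random SNP indices at least `min_spacing_bp` apart,
#' each spreading mean into its neighbors with the theoretical ARMA
#' autocorrelation as the LD decay kernel (truncated where it drops below
#' `ld_decay_floor`).
#'
#' @param config a [simulation_config].
#' @param spec an [arma_spec] supplying the decay kernel.
#' @param seed integer seed controlling locus subset and placement.
#' @param profile optional replacement effect profile (length
#'   `config$m_base`).
#' @return numeric vector of length `config$k`; all zero when
#'   `gamma_c = 0`.  Attribute `causal_index` holds the causal SNP indices,
#'   `causal_mu` their peak noncentralities.
#' @export
build_true_means <- function(config, spec = arma_spec(), seed = NULL,
                             profile = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$k
  mu <- numeric(k)
  if (config$m1 == 0L) {
    attr(mu, "causal_index") <- integer(0)
    attr(mu, "causal_mu") <- numeric(0)
    return(mu)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile)) profile <- reference_effect_profile(config$m_base)
  if (length(profile) != config$m_base)
    abort_config("effect profile length must equal m_base")

  spacing_snps <- ceiling(config$min_spacing_bp / 1000)  # 1 SNP per kbp
  if (config$m1 * spacing_snps > k)
    abort_config(sprintf("cannot place %d loci %d SNPs apart in a %d-SNP scan",
                         config$m1, spacing_snps, k))

  picked <- sort(sample.int(config$m_base, config$m1))
  peak <- profile[picked] * sqrt(config$gamma_s)

  # uniform placement with minimum spacing, via the standard offset trick:
  # choose m1 ordered free positions then add back the reserved gaps
  free <- k - (config$m1 - 1L) * spacing_snps
  idx <- sort(sample.int(free, config$m1)) +
    (seq_len(config$m1) - 1L) * spacing_snps
  idx <- idx[sample.int(config$m1)]  # decouple locus order from position order

  rho <- theoretical_acf(spec, max_lag = spacing_snps * 2L)
  width <- max(which(abs(rho) >= config$ld_decay_floor)) - 1L
  kernel <- rho[seq_len(width + 1L)]

  for (j in seq_len(config$m1)) {
    lo <- max(1L, idx[j] - width); hi <- min(k, idx[j] + width)
    off <- abs(seq(lo, hi) - idx[j]) + 1L
    mu[lo:hi] <- mu[lo:hi] + peak[j] * kernel[off]
  }
  attr(mu, "causal_index") <- idx
  attr(mu, "causal_mu") <- peak
  mu
}

#' Simulate a genome scan
#'
#' Draws one replicate: ground-truth means from [build_true_means()] plus a
#' unit-variance ARMA residual realization.  Positions are laid out at one
#' SNP per kbp on a single synthetic chromosome.  The mean structure and
#' the residuals use separate sub-seeds derived from `seed` (and the mean
#' sub-seed can be pinned via `mean_seed` so that replicates share a truth
#' vector while varying the noise).
#'
#' @param config a [simulation_config].
#' @param spec an [arma_spec].
#' @param seed master integer seed.
#' @param mean_seed optional explicit seed for the truth vector.
#' @return A `simulated_scan` object: list with `chrom`, `pos_bp`,
#'   `true_mu`, `z`, and the generating `config`.
#' @export
simulate_scan <- function(config, spec = arma_spec(), seed = NULL,
                          mean_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2)
  if (is.null(mean_seed)) mean_seed <- sub[1]
  mu <- build_true_means(config, spec, seed = mean_seed)
  resid <- simulate_arma_residuals(config$k, spec, seed = sub[2],
                                   burn_in = config$burn_in)
  structure(list(chrom = "1",
                 pos_bp = seq(1, by = 1000, length.out = config$k),
                 true_mu = as.numeric(mu), z = as.numeric(mu) + resid,
                 causal_index = attr(mu, "causal_index"),
                 config = config),
            class = "simulated_scan")
}

#' @export
print.simulated_scan <- function(x, ...) {
  cat(sprintf("simulated_scan: %d SNPs, %d causal loci, max |z| = %.3g\n",
              length(x$z), length(x$causal_index), max(abs(x$z))))
  invisible(x)
}

#' Convert a simulated scan to a scan-statistics table
#'
#' @param x a `simulated_scan`.
#' @return A [scan_stats] table with variant IDs `snp1..snpk`; the truth
#'   vector rides along as attribute `true_mu`.
#' @export
as_scan_stats <- function(x) {
  stopifnot(inherits(x, "simulated_scan"))
  out <- scan_stats(variant_id = paste0("snp", seq_along(x$z)),
                    chrom = x$chrom, pos_bp = x$pos_bp, z = x$z)
  attr(out, "true_mu") <- x$true_mu
  out
}
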