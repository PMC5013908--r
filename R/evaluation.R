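# Scoring estimators against simulated ground truth.
#
# Performance is reported cumulatively over p-value thresholds: at each grid
# point t (on the -log10 p scale) metrics are computed over the SNP set
# S(t) = { i : p_i <= 10^-t }, i.e. all statistics at least as significant
# as the threshold.  MSE decomposes exactly into bias^2 + variance because
# the variance of the errors uses the population (1/n) denominator.

default_thresholds <- function() seq(0, 8, by = 0.5)

#' Cumulative accuracy metrics over p-value thresholds
#'
#' For each threshold t, computes over S(t) = { i : p_i <= 10^-t }:
#' MSE = mean((mu_hat - mu)^2), R^2 = squared Pearson correlation of
#' (mu_hat, mu), bias = mean(mu_hat - mu) and variance = population variance
#' of the errors (so MSE = bias^2 + variance exactly).  Thresholds whose
#' SNP set is empty give `NA` rows; R^2 is `NA` when the truth (or the
#' estimate) has zero variance in the set.
#'
#' @param true_mu ground-truth noncentralities.
#' @param estimates a `noncentrality_estimates` object (or bare numeric
#'   vector) aligned to `true_mu`.
#' @param p two-sided p-values of the raw statistics, aligned.
#' @param thresholds ascending -log10 p grid (default 0, 0.5, ..., 8).
#' @param r2_type `"pearson"` (squared correlation, default) or
#'   `"one_minus_ss"` (1 - SSres/SStot).
#' @return data.frame with columns `threshold`, `n_snps`, `mse`, `r2`,
#'   `bias`, `variance`.
#' @export
cumulative_metrics <- function(true_mu, estimates, p,
                               thresholds = default_thresholds(),
                               r2_type = c("pearson", "one_minus_ss")) {
  r2_type <- match.arg(r2_type)
  est <- if (inherits(estimates, "noncentrality_estimates")) estimates$values else as.numeric(estimates)
  if (length(est) != length(true_mu) || length(p) != length(true_mu))
    abort_input("true_mu, estimates and p must be aligned (equal length)")

  rows <- lapply(thresholds, function(t) {
    s <- which(p <= 10^(-t))
    if (!length(s))
      return(data.frame(threshold = t, n_snps = 0L, mse = NA_real_,
                        r2 = NA_real_, bias = NA_real_, variance = NA_real_))
    e <- est[s] - true_mu[s]
    bias <- mean(e)
    variance <- mean((e - bias)^2)
    r2 <- if (r2_type == "pearson") {
      if (length(s) < 2 || stats::sd(true_mu[s]) == 0 || stats::sd(est[s]) == 0)
        NA_real_
      else stats::cor(est[s], true_mu[s])^2
    } else {
      sstot <- sum((true_mu[s] - mean(true_mu[s]))^2)
      if (sstot == 0) NA_real_ else 1 - sum(e^2) / sstot
    }
    data.frame(threshold = t, n_snps = length(s), mse = mean(e^2),
               r2 = r2, bias = bias, variance = variance)
  })
  do.call(rbind, rows)
}

# method label -> estimator closure; TA is threshold-dependent and handled
# separately inside compare_methods
resolve_method <- function(label) {
  key <- toupper(label)
  if (key == "MLE") return(function(z) mle_estimate(z))
  if (key == "FIQT") return(function(z) fiqt(z))
  if (key %in% c("FIQT-BONFERRONI", "FIQT-HOLM"))
    return(function(z) fiqt_with_mta(z, tolower(sub("FIQT-", "", key))))
  m <- regmatches(key, regexec("^EB-([0-9]+)$", key))[[1]]
  if (length(m) == 2)
    return(function(z) eb_n(z, n_sets = as.integer(m[2])))
  if (key == "TA") return("TA")
  abort_config(sprintf("unknown method '%s'; valid: MLE, FIQT, FIQT-bonferroni, FIQT-holm, EB-<n>, TA", label))
}

#' Compare estimators on replicated simulated scans
#'
#' Runs `config$n_reps` independent scan simulations, applies every
#' requested estimator to each replicate, scores it with
#' [cumulative_metrics()], and averages the per-threshold metrics across
#' replicates (with Monte-Carlo standard errors).  `"TA"` follows the
#' cumulative protocol: at each grid threshold it re-adjusts all statistics
#' whose |z| exceeds that threshold's Z-quantile.  A method failure on one
#' replicate excludes that replicate for that method only.
#'
#' @param config a [simulation_config]; `n_reps` replicates are drawn.
#' @param methods character vector of method labels: `"MLE"`, `"FIQT"`,
#'   `"FIQT-bonferroni"`, `"FIQT-holm"`, `"EB-<n>"` (e.g. `"EB-1"`,
#'   `"EB-100"`), `"TA"`.
#' @param thresholds -log10 p grid (default 0, 0.5, ..., 8).
#' @param seed master seed; replicate r uses sub-seed r of a sequence drawn
#'   from it, so results are reproducible and replicates independent.
#' @param spec an [arma_spec] for the residual process.
#' @param ta_grid interpolation grid size passed to [ta_adjust()] for the
#'   TA method on large scans.
#' @return An `evaluation_report`: data.frame with columns `method`,
#'   `threshold`, `n_snps`, `mse`, `r2`, `bias`, `variance`, their `_se`
#'   Monte-Carlo standard errors, and `n_reps_used`; attribute `failures`
#'   lists per-method replicate failures.
#' @export
compare_methods <- function(config, methods, thresholds = default_thresholds(),
                            seed = NULL, spec = arma_spec(), ta_grid = 200) {
  stopifnot(inherits(config, "simulation_config"))
  if (!length(methods)) abort_config("need at least one method")
  fns <- lapply(methods, resolve_method)
  names(fns) <- methods
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_reps)

  acc <- list()      # per method: list of per-rep metric frames
  failures <- list()
  for (r in seq_len(config$n_reps)) {
    scan <- simulate_scan(config, spec, seed = rep_seeds[r])
    pvals <- pvalue_from_z(scan$z)
    for (m in methods) {
      res <- tryCatch({
        if (identical(fns[[m]], "TA")) {
          ta_cumulative_metrics(scan, pvals, thresholds, ta_grid)
        } else {
          est <- fns[[m]](scan$z)
          cumulative_metrics(scan$true_mu, est, pvals, thresholds)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[m]] <- c(failures[[m]], sprintf("rep %d: %s", r, conditionMessage(res)))
      } else {
        acc[[m]] <- c(acc[[m]], list(res))
      }
    }
  }

  out <- do.call(rbind, lapply(methods, function(m) {
    reps <- acc[[m]]
    if (is.null(reps))
      abort_numerical(sprintf("method '%s' failed on every replicate", m))
    arr <- array(unlist(lapply(reps, function(d) as.matrix(d[-1]))),
                 dim = c(nrow(reps[[1]]), ncol(reps[[1]]) - 1, length(reps)))
    mean_mat <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    se_mat <- apply(arr, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    })
    colnames(mean_mat) <- names(reps[[1]])[-1]
    colnames(se_mat) <- paste0(names(reps[[1]])[-1], "_se")
    data.frame(method = m, threshold = reps[[1]]$threshold,
               mean_mat, se_mat[, -1, drop = FALSE],
               n_reps_used = length(reps), row.names = NULL)
  }))
  structure(out, class = c("evaluation_report", "data.frame"),
            failures = failures, n_reps = config$n_reps)
}

# TA under the cumulative protocol: re-adjust per threshold
ta_cumulative_metrics <- function(scan, pvals, thresholds, ta_grid) {
  rows <- lapply(thresholds, function(t) {
    c_t <- max(stats::qnorm(1 - 10^(-t) / 2), 1e-8)
    est <- ta_adjust(scan$z, ta_config(c_t), approx_grid = ta_grid)
    cumulative_metrics(scan$true_mu, est, pvals, thresholds = t)
  })
  do.call(rbind, rows)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d method(s) x %d threshold(s), %d replicates\n",
              length(unique(x$method)), length(unique(x$threshold)),
              attr(x, "n_reps")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
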