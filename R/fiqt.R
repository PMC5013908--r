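# FIQT: FDR inverse quantile transformation.
#
# Winner's curse adjustment shrinks Z-scores toward 0; multiple-testing
# adjustment shrinks p-values toward 1, which is the same point on the other
# scale.  FIQT exploits this: adjust the two-sided p-values for multiple
# testing (BH/FDR by default), then back-transform the q-values to signed
# Z-scores: mu_hat_i = sign(z_i) * qnorm(1 - q_i / 2).

noncentrality_estimates <- function(method, values) {
  structure(list(method = method, values = values),
            class = "noncentrality_estimates")
}

#' @export
print.noncentrality_estimates <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("noncentrality_estimates [%s]: %d values (%d missing), |est| range [%.3g, %.3g]\n",
              x$method, length(x$values), sum(is.na(x$values)),
              if (length(v)) min(abs(v)) else NA, if (length(v)) max(abs(v)) else NA))
  invisible(x)
}

#' FIQT noncentrality estimates
#'
#' Estimates the true mean (noncentrality) of each Z-score in a genome scan
#' by FDR inverse quantile transformation: two-sided p-values p_i =
#' 2*pnorm(-|z_i|) are Benjamini-Hochberg adjusted across the whole scan,
#' and the q-values are mapped back to the Z scale as
#' sign(z_i) * qnorm(1 - q_i/2).  Since q_i >= p_i the estimates are always
#' shrunk toward zero, and a q-value of 1 maps to exactly 0.  With a single
#' test the transform is the identity.
#'
#' @param z vector of Z-scores (unit sampling variance assumed; no genomic
#'   control rescaling is applied).  `NA` entries are excluded from the FDR
#'   pool and receive `NA` estimates.
#' @param mta_method multiple-testing adjustment: `"fdr"` (default, the FIQT
#'   method proper), `"bonferroni"` or `"holm"`.
#' @return A `noncentrality_estimates` object (fields `method`, `values`).
#' @examples
#' fiqt(c(3, 1))$values       # c(2.7822, 1): only the large score is shrunk
#' fiqt(2.5)$values           # 2.5: single test, identity
#' @export
fiqt <- function(z, mta_method = "fdr") {
  if (!is.numeric(z) || length(z) < 1L)
    abort_domain("z must be a non-empty numeric vector")
  bad <- which(!is.na(z) & !is.finite(z))
  if (length(bad))
    abort_domain(sprintf("non-finite z at index(es) %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  ok <- !is.na(z)
  values <- rep(NA_real_, length(z))
  if (any(ok)) {
    zz <- z[ok]
    p <- pvalue_from_z(zz)
    q <- mta_qvalues(p, mta_method)$values
    # back-transform in log space: finite output even for q near 0
    est <- sign(zz) * stats::qnorm(log(q) - log(2),
                                   lower.tail = FALSE, log.p = TRUE)
    est[q >= 1] <- 0          # q = 1 is the null point, exactly 0
    est[q == p] <- zz[q == p] # unadjusted entries invert exactly (k = 1 case)
    values[ok] <- est
  }
  label <- if (mta_method == "fdr") "FIQT" else paste0("FIQT-", mta_method)
  noncentrality_estimates(label, values)
}

#' FIQT with an explicit multiple-testing adjustment
#'
#' Same pipeline as [fiqt()] with the adjustment chosen by label;
#' `mta_method = "fdr"` is identical to [fiqt()].
#'
#' @inheritParams fiqt
#' @return A `noncentrality_estimates` object.
#' @export
fiqt_with_mta <- function(z, mta_method = c("fdr", "bonferroni", "holm")) {
  if (!mta_method[1] %in% c("fdr", "bonferroni", "holm"))
    abort_config(sprintf("unknown MTA method '%s'; valid: fdr, bonferroni, holm",
                         mta_method[1]))
  fiqt(z, mta_method = match.arg(mta_method))
}

#' Naive (maximum-likelihood) noncentrality estimates
#'
#' The observed statistics themselves: mu_hat_i = z_i.  The unbiased-looking
#' but winner's-curse-afflicted baseline every adjustment is compared to.
#'
#' @param z vector of Z-scores.
#' @return A `noncentrality_estimates` object with method label `"MLE"`.
#' @export
mle_estimate <- function(z) {
  noncentrality_estimates("MLE", as.numeric(z))
}
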