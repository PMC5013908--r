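# Multiple-testing adjustment of p-values.  Benjamini-Hochberg FDR is the
# adjustment the FIQT transform is built on; Bonferroni and Holm are exposed
# as family-wise alternatives but are not benchmarked.  All three delegate to
# stats::p.adjust.

qvalues_obj <- function(values, method, k) {
  structure(list(values = values, method = method, k = k),
            class = "qvalues")
}

check_p <- function(p) {
  if (length(p) < 1L) abort_domain("need at least one p-value")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    abort_domain("all p-values must lie in (0, 1]")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: for sorted p, q_(i) = min over j >= i of
#' k p_(j) / j, clipped at 1 and mapped back to input order.
#'
#' @param p vector of p-values in (0, 1].
#' @return A `qvalues` object with fields `values` (aligned to `p`),
#'   `method` and `k` (number of tests).
#' @export
bh_qvalues <- function(p) {
  check_p(p)
  qvalues_obj(stats::p.adjust(p, method = "BH"), "fdr", length(p))
}

#' Bonferroni-adjusted p-values
#'
#' q_i = min(k p_i, 1).
#'
#' @inheritParams bh_qvalues
#' @return A `qvalues` object.
#' @export
bonferroni_qvalues <- function(p) {
  check_p(p)
  qvalues_obj(stats::p.adjust(p, method = "bonferroni"), "bonferroni", length(p))
}

#' Holm step-down adjusted p-values
#'
#' q_(i) = max over j <= i of min((k - j + 1) p_(j), 1) on the sorted scale.
#'
#' @inheritParams bh_qvalues
#' @return A `qvalues` object.
#' @export
holm_qvalues <- function(p) {
  check_p(p)
  qvalues_obj(stats::p.adjust(p, method = "holm"), "holm", length(p))
}

mta_qvalues <- function(p, method = c("fdr", "bonferroni", "holm")) {
  if (!method[1] %in% c("fdr", "bonferroni", "holm"))
    abort_config(sprintf("unknown MTA method '%s'; valid: fdr, bonferroni, holm",
                         method[1]))
  switch(match.arg(method),
         fdr = bh_qvalues(p),
         bonferroni = bonferroni_qvalues(p),
         holm = holm_qvalues(p))
}

#' @export
print.qvalues <- function(x, ...) {
  cat(sprintf("qvalues: %d tests adjusted by '%s'; range [%.3g, %.3g]\n",
              x$k, x$method, min(x$values), max(x$values)))
  invisible(x)
}
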