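# Predicting genome-wide-significant regions in a larger future cohort.
#
# A Z-score's noncentrality grows with the square root of the sample size,
# so winner's-curse-adjusted estimates from the current cohort, multiplied
# by sqrt(n_future / n_current), are point predictions of the future
# noncentralities.  Variants whose predicted two-sided p-value falls below
# the genome-wide threshold are clumped into regions by single-linkage
# clustering within a base-pair gap.

#' Scale noncentrality estimates to a larger sample size
#'
#' Multiplies every estimate by `sqrt(n_ratio)`; e.g. a four-fold larger
#' cohort doubles every predicted noncentrality.
#'
#' @param estimates a `noncentrality_estimates` object (or numeric vector).
#' @param n_ratio ratio of future to current sample size (> 0).
#' @return object of the same shape with scaled values.
#' @export
scale_noncentrality <- function(estimates, n_ratio) {
  if (!is.numeric(n_ratio) || length(n_ratio) != 1L || n_ratio <= 0)
    abort_domain("n_ratio must be a single positive number")
  if (inherits(estimates, "noncentrality_estimates")) {
    estimates$values <- estimates$values * sqrt(n_ratio)
    estimates
  } else {
    as.numeric(estimates) * sqrt(n_ratio)
  }
}

#' Predict which variants reach genome-wide significance
#'
#' Computes the two-sided p-value implied by each scaled noncentrality,
#' p_i = 2*pnorm(-|mu_hat_i|), and flags variants with p_i strictly below
#' `alpha`.  This is a point prediction, not a test: no error rate is
#' attached.
#'
#' @param scaled scaled noncentrality estimates (object or numeric vector).
#' @param alpha significance threshold (default 5e-8, genome-wide).
#' @return list with `predicted_p` (numeric) and `significant` (logical
#'   mask; strict inequality, so p exactly equal to `alpha` is NOT called).
#' @export
predict_significant <- function(scaled, alpha = 5e-8) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort_domain("alpha must lie in (0, 1)")
  v <- if (inherits(scaled, "noncentrality_estimates")) scaled$values else as.numeric(scaled)
  p <- 2 * stats::pnorm(-abs(v))
  list(predicted_p = p, significant = !is.na(p) & p < alpha)
}

#' Cluster predicted-significant variants into regions
#'
#' Single-linkage clumping per chromosome: consecutive flagged variants at
#' most `gap_bp` apart join one region.  Region bounds are the min/max
#' positions of members (1-based, closed); the lead variant carries the
#' largest |scaled estimate| (ties broken by smaller position).
#'
#' @param stats a [scan_stats] table sorted by (chrom, pos_bp).
#' @param mask logical vector aligned to `stats` flagging predicted-
#'   significant variants.
#' @param values scaled noncentrality estimates aligned to `stats`
#'   (object or numeric); used for lead-variant choice and minimum
#'   predicted p.  Defaults to the raw `z` column.
#' @param gap_bp linkage distance in base pairs (default 250000).
#' @return data.frame of class `wc_regions`: columns `chrom`, `start_bp`,
#'   `end_bp`, `lead_variant`, `min_predicted_p`, `n_variants`.
#' @export
cluster_regions <- function(stats, mask, values = NULL, gap_bp = 250000) {
  stopifnot(inherits(stats, "scan_stats"))
  if (length(mask) != nrow(stats))
    abort_input("mask not aligned to stats")
  ord <- order(chrom_key(stats$chrom), stats$chrom, stats$pos_bp)
  if (!identical(ord, seq_len(nrow(stats))))
    abort_input("stats must be sorted by (chrom, pos_bp)")
  if (is.null(values)) values <- stats$z
  if (inherits(values, "noncentrality_estimates")) values <- values$values
  if (length(values) != nrow(stats))
    abort_input("values not aligned to stats")

  idx <- which(mask)
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), lead_variant = character(0),
                      min_predicted_p = numeric(0), n_variants = integer(0))
  if (!length(idx)) return(structure(empty, class = c("wc_regions", "data.frame")))

  chrom <- stats$chrom[idx]; pos <- stats$pos_bp[idx]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                           diff(pos) > gap_bp)
  cl <- cumsum(new_cluster)
  rows <- lapply(split(seq_along(idx), cl), function(members) {
    gi <- idx[members]
    av <- abs(values[gi])
    lead <- gi[order(-av, stats$pos_bp[gi])][1]
    data.frame(chrom = stats$chrom[gi[1]],
               start_bp = min(stats$pos_bp[gi]),
               end_bp = max(stats$pos_bp[gi]),
               lead_variant = stats$variant_id[lead],
               min_predicted_p = 2 * stats::pnorm(-max(av)),
               n_variants = length(gi))
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("wc_regions", "data.frame"))
}

#' Count overlaps between predicted and reported regions
#'
#' A predicted region overlaps a reported locus iff their closed intervals
#' intersect on the same chromosome.  Optionally tallies predicted regions
#' falling inside a special interval (e.g. the extended MHC,
#' chr6:25-33 Mb), and how many overlapping regions lie outside it.
#'
#' @param predicted a `wc_regions` data.frame (or any data.frame with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param reported data.frame of reported loci with columns `chrom`,
#'   `start_bp`, `end_bp` (1-based closed).
#' @param special optional single interval `list(chrom=, start_bp=, end_bp=)`.
#' @return list with `n_predicted`, `n_overlapping`, and (when `special`
#'   given) `n_in_special`, `n_overlapping_outside_special`.
#' @export
overlap_regions <- function(predicted, reported, special = NULL) {
  need <- c("chrom", "start_bp", "end_bp")
  if (!all(need %in% names(predicted)) || !all(need %in% names(reported)))
    abort_input("regions need columns chrom, start_bp, end_bp")
  if (any(predicted$start_bp > predicted$end_bp) ||
      any(reported$start_bp > reported$end_bp))
    abort_input("malformed interval: start_bp > end_bp")

  hits_any <- function(chrom, s, e, tab) {
    any(tab$chrom == chrom & tab$start_bp <= e & tab$end_bp >= s)
  }
  overlapping <- vapply(seq_len(nrow(predicted)), function(i)
    hits_any(predicted$chrom[i], predicted$start_bp[i], predicted$end_bp[i],
             reported), logical(1))
  out <- list(n_predicted = nrow(predicted),
              n_overlapping = sum(overlapping))
  if (!is.null(special)) {
    in_special <- vapply(seq_len(nrow(predicted)), function(i)
      predicted$chrom[i] == special$chrom &&
        predicted$start_bp[i] <= special$end_bp &&
        predicted$end_bp[i] >= special$start_bp, logical(1))
    out$n_in_special <- sum(in_special)
    out$n_overlapping_outside_special <- sum(overlapping & !in_special)
  }
  out
}

#' Write regions as a BED file
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention on write.
#'
#' @param regions a `wc_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
                    name = regions$lead_variant,
                    score = format(regions$min_predicted_p, digits = 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based closed regions
#'
#' @param path BED file path (0-based half-open).
#' @return data.frame with `chrom`, `start_bp`, `end_bp` (1-based closed).
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]),
             start_bp = as.numeric(bed[[2]]) + 1,
             end_bp = as.numeric(bed[[3]]))
}
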