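# Reading, validating and scale-converting GWAS summary statistics.
#
# The central quantity is the per-variant Z-score X ~ N(mu, 1); the package
# estimates mu (the noncentrality).  Files rarely report Z directly, so this
# module derives it from whichever combination is present: Z itself,
# beta + SE, OR + SE, or p-value + effect direction.  All p-values are
# two-sided: p = 2 * pnorm(-|z|).

#' Construct a scan-statistics table
#'
#' Builds the validated per-variant container used throughout the package:
#' one row per variant with a Z-score and two-sided p-value, sorted by
#' genomic position.  Whichever of `z` and `p` is missing is derived from
#' the other (or from `effect`/`se`).
#'
#' @param variant_id character vector of unique variant identifiers.
#' @param chrom chromosome labels (character or integer-like).
#' @param pos_bp 1-based base-pair positions.
#' @param z Z-scores (statistics with unit sampling variance), or `NULL`.
#' @param p two-sided p-values in (0, 1], or `NULL`.
#' @param effect optional effect sizes (beta or log odds ratio).
#' @param se optional standard errors (> 0).
#' @param direction optional effect-direction vector (+1/-1, or "+"/"-"),
#'   used only when `z` must be derived from `p`.
#' @return A `scan_stats` object: a `data.frame` with columns `variant_id`,
#'   `chrom`, `pos_bp`, `z`, `p` and, when supplied, `effect` and `se`,
#'   sorted by (chrom, pos_bp).  Attribute `load_report` records dropped
#'   rows and any z/p inconsistencies.
#' @export
scan_stats <- function(variant_id, chrom, pos_bp, z = NULL, p = NULL,
                       effect = NULL, se = NULL, direction = NULL) {
  n <- length(variant_id)
  variant_id <- as.character(variant_id)
  chrom <- as.character(chrom)
  # double, not integer: synthetic single-chromosome layouts can exceed 2^31
  pos_bp <- as.numeric(pos_bp)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(pos_bp) != n)
    abort_input("variant_id, chrom and pos_bp must have equal length")

  z <- if (is.null(z)) rep(NA_real_, n) else as.numeric(z)
  p <- if (is.null(p)) rep(NA_real_, n) else as.numeric(p)
  effect <- if (is.null(effect)) rep(NA_real_, n) else as.numeric(effect)
  se <- if (is.null(se)) rep(NA_real_, n) else as.numeric(se)

  # invalid domains are dropped, not repaired
  bad_p <- !is.na(p) & (p <= 0 | p > 1)
  bad_se <- !is.na(se) & se <= 0
  bad_pos <- is.na(pos_bp) | pos_bp < 1

  # derive z where absent
  need_z <- is.na(z)
  from_eff <- need_z & !is.na(effect) & !is.na(se) & !bad_se
  z[from_eff] <- effect[from_eff] / se[from_eff]
  still <- is.na(z) & !is.na(p) & !bad_p
  if (any(still)) {
    sgn <- rep(1, n)
    if (!is.null(direction)) sgn <- parse_direction(direction)
    z[still] <- z_from_pvalue_sign(p[still], sgn[still])
  }

  usable <- !is.na(z) & is.finite(z) & !bad_p & !bad_se & !bad_pos
  n_dropped <- sum(!usable)
  if (sum(usable) == 0L)
    abort_input("no usable rows after validation (all rows missing a statistic or out of domain)")

  # z/p consistency: report, never silently overwrite
  both <- usable & !is.na(p)
  p_implied <- pvalue_from_z(z)
  incons <- both & abs(p - p_implied) / p >= 1e-3
  if (any(incons))
    warning(sprintf("%d row(s) have p inconsistent with z (|p - 2*pnorm(-|z|)|/p >= 1e-3); kept as reported",
                    sum(incons)))
  p[usable & is.na(p)] <- p_implied[usable & is.na(p)]

  out <- data.frame(variant_id = variant_id, chrom = chrom, pos_bp = pos_bp,
                    z = z, p = p, stringsAsFactors = FALSE)
  if (any(!is.na(effect))) out$effect <- effect
  if (any(!is.na(se))) out$se <- se
  out <- out[usable, , drop = FALSE]

  if (anyDuplicated(out$variant_id))
    abort_input(sprintf("duplicate variant IDs (e.g. %s)",
                        out$variant_id[duplicated(out$variant_id)][1]))

  out <- out[order(chrom_key(out$chrom), out$chrom, out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_stats", "data.frame")
  attr(out, "load_report") <- list(n_input = n, n_kept = nrow(out),
                                   n_dropped = n_dropped,
                                   n_inconsistent_p = sum(incons))
  out
}

# numeric-first chromosome ordering (1..22 before X, Y, MT)
chrom_key <- function(chrom) {
  k <- suppressWarnings(as.numeric(sub("^chr", "", chrom, ignore.case = TRUE)))
  k[is.na(k)] <- Inf
  k
}

parse_direction <- function(direction) {
  if (is.numeric(direction)) return(ifelse(direction < 0, -1, 1))
  d <- trimws(as.character(direction))
  ifelse(d %in% c("-", "-1"), -1, 1)
}

#' @export
print.scan_stats <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("scan_stats: %d variants on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (!is.null(rep) && rep$n_dropped > 0)
    cat(sprintf("  (%d input row(s) dropped during loading)\n", rep$n_dropped))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# default header aliases for the de facto sumstats format
.default_aliases <- list(
  snp = c("SNP", "RSID", "ID", "MARKERNAME", "VARIANT_ID"),
  chr = c("CHR", "CHROM", "CHROMOSOME", "HG19CHR", "HG19CHRC"),
  bp = c("BP", "POS", "POSITION", "POS_BP", "BASE_PAIR_LOCATION"),
  z = c("Z", "ZSCORE", "Z_SCORE", "STAT"),
  beta = c("BETA", "B", "EFFECT", "LOG_ODDS"),
  se = c("SE", "STDERR", "STANDARD_ERROR"),
  or = c("OR", "ODDS_RATIO", "ODDSRATIO"),
  p = c("P", "PVAL", "PVALUE", "P_VALUE", "P.VALUE"),
  direction = c("DIRECTION", "DIR", "SIGN")
)

#' Read a summary-statistics file
#'
#' Reads delimited text with a header row (tab, comma or whitespace
#' delimiters are auto-detected) and assembles a [scan_stats] table.  The
#' Z-score is taken directly from a Z column when present, otherwise derived
#' from beta/SE, OR/SE (via log OR), or p-value plus effect direction, in
#' that order of preference.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping logical names
#'   (`snp`, `chr`, `bp`, `z`, `beta`, `se`, `or`, `p`, `direction`) to the
#'   actual column names in the file.  Unmapped logical columns are matched
#'   case-insensitively against common aliases (SNP/CHR/BP/Z/BETA/SE/OR/P).
#' @return A [scan_stats] object; attribute `load_report` counts rows
#'   dropped for unparseable or out-of-domain values.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) abort_input("zero usable rows: file has no data rows")

  resolve <- function(logical_name) {
    if (!is.null(column_map) && logical_name %in% names(column_map)) {
      actual <- column_map[[logical_name]]
      if (!actual %in% names(dt))
        abort_config(sprintf("column '%s' (mapped for '%s') not present in file",
                             actual, logical_name))
      return(actual)
    }
    hit <- match(.default_aliases[[logical_name]], toupper(names(dt)))
    hit <- hit[!is.na(hit)]
    if (length(hit)) names(dt)[hit[1]] else NA_character_
  }
  col <- vapply(names(.default_aliases), resolve, character(1))

  for (req in c("snp", "chr", "bp"))
    if (is.na(col[[req]]))
      abort_config(sprintf("missing required logical column '%s' (map it via column_map)", req))

  has <- function(nm) !is.na(col[[nm]])
  if (!has("z") && !(has("beta") && has("se")) && !(has("or") && has("se")) &&
      !(has("p") && has("direction")))
    abort_config(paste("no usable statistic combination: need one of",
                       "{z}, {beta, se}, {or, se}, {p, direction}"))

  num <- function(nm) if (has(nm)) suppressWarnings(as.numeric(dt[[col[[nm]]]])) else NULL
  effect <- num("beta")
  if (is.null(effect) && has("or")) {
    or <- num("or")
    effect <- ifelse(!is.na(or) & or > 0, log(or), NA_real_)
  }

  scan_stats(variant_id = dt[[col[["snp"]]]],
             chrom = dt[[col[["chr"]]]],
             pos_bp = suppressWarnings(as.numeric(dt[[col[["bp"]]]])),
             z = num("z"), p = num("p"), effect = effect, se = num("se"),
             direction = if (has("direction")) dt[[col[["direction"]]]] else NULL)
}

#' Z-score from effect size and standard error
#'
#' @param effect effect size (beta or log odds ratio).
#' @param se standard error, strictly positive.
#' @return `effect / se`, vectorized.
#' @export
z_from_effect_se <- function(effect, se) {
  if (any(!is.na(se) & se <= 0)) abort_domain("se must be > 0")
  effect / se
}

#' Two-sided p-value of a Z-score
#'
#' @param z Z-score vector.
#' @return `2 * pnorm(-|z|)`, floored at the smallest positive double so the
#'   result is never exactly zero.
#' @export
pvalue_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

#' Signed Z-score from a two-sided p-value
#'
#' Inverts the two-sided p-value convention: returns
#' `sign * qnorm(1 - p/2)`.  The quantile is evaluated through the
#' log-probability path so that arbitrarily small representable p-values
#' (down to ~1e-308, |z| ~ 37.5) give a finite Z without overflow.
#'
#' @param p two-sided p-values in (0, 1].
#' @param sign effect directions (+1/-1); recycled.
#' @return signed Z-scores.
#' @export
z_from_pvalue_sign <- function(p, sign = 1) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    abort_domain("p must lie in (0, 1]")
  sgn <- parse_direction(sign)
  # upper-tail quantile at p/2, via log space: qnorm(log(p) - log(2))
  sgn * stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

#' Back-transform an adjusted Z-score to the effect-size scale
#'
#' Converts a winner's-curse-adjusted Z-score (noncentrality estimate) back
#' to beta / log-OR scale, either by multiplying by the reported standard
#' error (`se_scale`: beta* = se * z_adj) or by scaling the raw effect by
#' the ratio of adjusted to raw Z (`ratio_scale`: beta* = (z_adj/z) * beta).
#' The two agree exactly when beta = se * z.
#'
#' @param z_adj adjusted Z-score(s).
#' @param se standard error(s) (> 0); required for `mode = "se_scale"`.
#' @param mode `"se_scale"` or `"ratio_scale"`.
#' @param z_raw raw Z-score(s); required for `ratio_scale`, must be nonzero.
#' @param effect_raw raw effect(s); required for `ratio_scale`.
#' @return adjusted effect size(s).
#' @export
adjusted_effect_from_z <- function(z_adj, se = NULL,
                                   mode = c("se_scale", "ratio_scale"),
                                   z_raw = NULL, effect_raw = NULL) {
  mode <- match.arg(mode)
  if (mode == "se_scale") {
    if (is.null(se)) abort_domain("se_scale mode requires se")
    if (any(!is.na(se) & se <= 0)) abort_domain("se must be > 0")
    return(se * z_adj)
  }
  if (is.null(z_raw) || is.null(effect_raw))
    abort_domain("ratio_scale mode requires z_raw and effect_raw")
  if (any(!is.na(z_raw) & z_raw == 0))
    abort_domain("ratio_scale undefined for z_raw = 0")
  (z_adj / z_raw) * effect_raw
}

#' Write summary statistics with adjusted-Z columns
#'
#' Writes a tab-delimited file containing the scan-statistics columns plus
#' one column per estimator, named by its method label.  Values keep full
#' double precision, so a round-trip read recovers them to at least six
#' significant digits.
#'
#' @param stats a [scan_stats] table.
#' @param estimates a single [noncentrality_estimates] object or a list of
#'   them, each aligned to `stats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjusted <- function(stats, estimates, path) {
  if (inherits(estimates, "noncentrality_estimates")) estimates <- list(estimates)
  out <- as.data.frame(stats)
  for (est in estimates) {
    stopifnot(inherits(est, "noncentrality_estimates"))
    if (length(est$values) != nrow(out))
      abort_input(sprintf("estimate vector '%s' (length %d) not aligned to stats (%d rows)",
                          est$method, length(est$values), nrow(out)))
    out[[est$method]] <- est$values
  }
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
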