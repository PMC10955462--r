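# GATK-style hard filtering of variant records.

#' Hard-filter thresholds for variant records
#'
#' Defaults follow the standard GATK hard-filter recipe used for the
#' S-locus call set: QD > 2, MQ > 40, FS < 60, MQRankSum > -12.5,
#' ReadPosRankSum > -8, depth within (0.5x, 3x) of the mean site depth, and
#' removal of fixed-heterozygosity artifacts (InbreedingCoeff < -0.99).
#' The printed depth rule "(DP > 1/2 X) || (DP < 3X)" is tautological as a
#' disjunction and is applied as the conjunction.
#'
#' @param qd_min,mq_min,fs_max,mqranksum_min,readpos_min Annotation cutoffs.
#' @param dp_low_factor,dp_high_factor Depth window as multiples of the mean.
#' @param inbreeding_min Records with `InbreedingCoeff` below this are dropped.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                              mqranksum_min = -12.5, readpos_min = -8.0,
                              dp_low_factor = 0.5, dp_high_factor = 3.0,
                              inbreeding_min = -0.99) {
  if (dp_low_factor >= dp_high_factor) {
    abort("`dp_low_factor` must be below `dp_high_factor`")
  }
  structure(as.list(environment()), class = "filter_thresholds")
}

#' Apply hard filters to variant records
#'
#' Variant records are rows of a tibble carrying the usual INFO annotations
#' as numeric columns (`QD`, `MQ`, `FS`, `MQRankSum`, `ReadPosRankSum`,
#' `DP`, `InbreedingCoeff`). A record is retained when every available
#' annotation passes its threshold; a missing (NA or absent) annotation
#' passes its sub-filter, since e.g. rank-sum annotations are undefined at
#' sites without heterozygotes.
#'
#' @param variants Tibble of variant records.
#' @param thresholds A [filter_thresholds()] object.
#' @param mean_depth Mean site depth `X` anchoring the DP window; defaults
#'   to the cohort mean of the `DP` column.
#' @return The retained records, with attributes `"n_removed"` and
#'   `"n_malformed"` (rows with no usable `chrom`/`pos`, logged and skipped).
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds(),
                               mean_depth = NULL) {
  v <- as_tibble(variants)
  malformed <- rep(FALSE, nrow(v))
  if (all(c("chrom", "pos") %in% names(v))) {
    malformed <- is.na(v$chrom) | is.na(v$pos)
  }
  if (any(malformed)) {
    warn(sprintf("skipping %d malformed record(s)", sum(malformed)))
    v <- v[!malformed, ]
  }
  col_or_na <- function(nm) if (nm %in% names(v)) v[[nm]] else rep(NA_real_, nrow(v))
  pass <- function(x, f) is.na(x) | f(x)

  if (is.null(mean_depth)) {
    dp <- col_or_na("DP")
    mean_depth <- if (all(is.na(dp))) NA_real_ else mean(dp, na.rm = TRUE)
  }
  th <- thresholds
  keep <- pass(col_or_na("QD"), function(x) x > th$qd_min) &
    pass(col_or_na("MQ"), function(x) x > th$mq_min) &
    pass(col_or_na("FS"), function(x) x < th$fs_max) &
    pass(col_or_na("MQRankSum"), function(x) x > th$mqranksum_min) &
    pass(col_or_na("ReadPosRankSum"), function(x) x > th$readpos_min) &
    pass(col_or_na("InbreedingCoeff"), function(x) x >= th$inbreeding_min)
  if (!is.na(mean_depth)) {
    keep <- keep & pass(col_or_na("DP"), function(x)
      x > th$dp_low_factor * mean_depth & x < th$dp_high_factor * mean_depth)
  }
  out <- v[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_malformed") <- sum(malformed)
  out
}
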