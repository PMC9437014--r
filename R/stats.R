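# Cohort-level summaries: printed-percentage arithmetic, diagnostic yield
# by stratum, variant-type breakdowns, treatable fraction and
# diagnostic-odyssey summaries.

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up (0.5 always rounds
#' away from zero) to the requested number of decimals — the convention of
#' clinical summary tables, where e.g. 505/1232 prints as 41% and 645/1122
#' as 57.5%.
#'
#' @param numerator,denominator Non-negative counts, numerator <=
#'   denominator, denominator > 0.
#' @param decimals Decimal places (default 0).
#' @return Numeric percentage.
#' @export
percent <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must be in [0, denominator]")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  floor(x * f + 0.5 + 1e-9) / f
}

report_field <- function(reports, field) {
  vapply(reports, function(r) {
    v <- r[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_character_
    else as.character(v)
  }, character(1))
}

#' Diagnostic yield, overall or stratified
#'
#' Fraction of cases with a positive report, optionally split by region,
#' consanguinity or family history. Cases with unknown stratum values are
#' never dropped silently — they form their own row.
#'
#' @param reports List of `metpanel_report` objects.
#' @param by `"none"`, `"region"`, `"consanguinity"` or `"family_history"`.
#' @param decimals Decimals of the printed percentage.
#' @return data.frame: `stratum`, `n_positive`, `n_total`, `percent`.
#' @export
diagnostic_yield <- function(reports, by = c("none", "region",
                                             "consanguinity",
                                             "family_history"),
                             decimals = 0L) {
  by <- match.arg(by)
  status <- report_field(reports, "status")
  strata <- if (by == "none") rep("all", length(reports)) else {
    s <- report_field(reports, by)
    ifelse(is.na(s), "unknown", s)
  }
  out <- lapply(sort(unique(strata)), function(s) {
    n_total <- sum(strata == s)
    n_pos <- sum(strata == s & status == "positive")
    data.frame(stratum = s, n_positive = n_pos, n_total = n_total,
               percent = if (n_total > 0) percent(n_pos, n_total, decimals)
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variant-level summary over reported findings
#'
#' Counts P/LP variant occurrences (with multiplicity across cases),
#' unique variants (by variant key), the SNV/CNV split, the CNV
#' deletion/duplication split, and lists recurrent variants ordered by
#' occurrence count (ties broken by key).
#'
#' @param reports List of `metpanel_report` objects.
#' @param classes Final classes counted (default P and LP).
#' @return List of counts and the `recurrent` data.frame.
#' @export
variant_summary <- function(reports, classes = c("P", "LP")) {
  keys <- character(); types <- character()
  for (r in reports) {
    f <- r$findings
    if (is.null(f) || nrow(f) == 0L) next
    sel <- f$final_class %in% classes
    keys <- c(keys, f$variant_key[sel])
    types <- c(types, f$type[sel])
  }
  occurrences <- length(keys)
  uni <- !duplicated(keys)
  unique_n <- sum(uni)
  utypes <- types[uni]
  n_snv <- sum(utypes == "snv")
  n_cnv <- sum(utypes != "snv")
  n_del <- sum(utypes == "cnv_del")
  n_dup <- sum(utypes == "cnv_dup")
  tab <- table(keys)
  rec <- data.frame(variant_key = as.character(names(tab) %||% character()),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  rec <- rec[order(-rec$count, rec$variant_key), , drop = FALSE]
  rownames(rec) <- NULL
  list(occurrences = occurrences, unique = unique_n,
       snv_unique = n_snv, cnv_unique = n_cnv,
       snv_share_percent = if (unique_n) percent(n_snv, unique_n) else NA_real_,
       cnv_del = n_del, cnv_dup = n_dup,
       cnv_deletion_share_percent = if (n_cnv) percent(n_del, n_cnv) else NA_real_,
       recurrent = rec[rec$count > 1L, , drop = FALSE])
}

#' Fraction of diagnosed cases with a treatable disease
#'
#' @param reports List of `metpanel_report` objects.
#' @param decimals Decimals of the printed percentage.
#' @return List: `n_treatable`, `n_positive`, `percent`.
#' @export
treatable_fraction <- function(reports, decimals = 0L) {
  n_pos <- 0L; n_treat <- 0L
  for (r in reports) {
    if (!identical(r$status, "positive")) next
    n_pos <- n_pos + 1L
    f <- r$findings[r$findings$outcome == "positive", , drop = FALSE]
    if (any(f$treatable)) n_treat <- n_treat + 1L
  }
  list(n_treatable = n_treat, n_positive = n_pos,
       percent = if (n_pos) percent(n_treat, n_pos, decimals) else NA_real_)
}

#' Diagnostic-odyssey summary
#'
#' Time from symptom onset to diagnosis over positive reports with both
#' ages documented; cases lacking either age are excluded and counted.
#'
#' @param reports List of `metpanel_report` objects (or any records with
#'   `age_onset_years` / `age_testing_years` and `status`).
#' @param over_threshold_years Count cases waiting longer than this many
#'   years (default 10).
#' @return List: `n`, `n_excluded`, `mean_years`, `min_years`,
#'   `max_years`, `n_over_threshold`.
#' @export
odyssey_summary <- function(reports, over_threshold_years = 10) {
  pos <- Filter(function(r) identical(r$status, "positive"), reports)
  onset <- vapply(pos, function(r) r$age_onset_years %||% NA_real_, numeric(1))
  testing <- vapply(pos, function(r) r$age_testing_years %||% NA_real_, numeric(1))
  ok <- !is.na(onset) & !is.na(testing)
  gaps <- testing[ok] - onset[ok]
  if (any(gaps < 0)) stop("negative onset-to-diagnosis gap")
  list(
    n = sum(ok), n_excluded = sum(!ok),
    mean_years = if (sum(ok)) mean(gaps) else NA_real_,
    min_years = if (sum(ok)) min(gaps) else NA_real_,
    max_years = if (sum(ok)) max(gaps) else NA_real_,
    n_over_threshold = sum(gaps > over_threshold_years))
}
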