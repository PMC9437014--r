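# Five-class variant classification combining genetic and biochemical
# evidence, phase inference for compound heterozygotes, and the
# positive/unclear/negative case report decision table.

FIVE_CLASSES <- c("P", "LP", "VUS", "LB", "B")

#' Pre-biochemistry (base) variant classification
#'
#' A deliberately small, transparent ACMG-style rule subset sufficient for
#' panel triage: curated assertions are honored (prior internal P/LP/VUS,
#' external disease-causing assertions); exon-level deletions are
#' pathogenic and duplications likely pathogenic in loss-of-function
#' mechanism genes; a rare high-impact (LoF) variant in an LoF-mechanism
#' gene is likely pathogenic; everything else retained by triage (novel
#' missense, splice-score candidates) starts as a VUS awaiting functional
#' evidence.
#'
#' @param variants data.frame of retained variants of one gene (from
#'   [triage_case()]).
#' @param gene Single-row panel gene record.
#' @param thresholds Threshold list.
#' @return data.frame classification state: `variant_key`, `base_class`,
#'   `final_class`, `evidence`, `reportable`, `curated` plus genotype
#'   columns carried through.
#' @export
base_classify <- function(variants, gene, thresholds = default_thresholds()) {
  v <- variants
  n <- nrow(v)
  maf_max <- pmax(ifelse(is.na(v$maf_external), 0, v$maf_external),
                  ifelse(is.na(v$maf_internal), 0, v$maf_internal))
  rare <- maf_max < thresholds$maf_snv
  prior <- v$prior_internal_class
  base <- rep("VUS", n)
  for (i in seq_len(n)) {
    base[i] <-
      if (prior[i] %in% FIVE_CLASSES) prior[i]
      else if (v$type[i] == "cnv_del") "P"
      else if (v$type[i] == "cnv_dup") "LP"
      else if (identical(v$external_assertion[i], "disease_causing")) "LP"
      else if (identical(v$impact[i], "high") && rare[i] &&
               isTRUE(gene$lof_mechanism)) "LP"
      else "VUS"
  }
  curated <- prior %in% c("P", "LP") |
    v$external_assertion == "disease_causing" |
    v$type %in% c("cnv_del", "cnv_dup")
  data.frame(
    variant_key = v$variant_key, gene = gene$symbol,
    disease_id = gene$disease_id, type = v$type, zygosity = v$zygosity,
    base_class = base, final_class = base,
    evidence = "", reportable = TRUE, curated = curated,
    conflicting_evidence = v$conflicting_evidence %||% rep(FALSE, n),
    stringsAsFactors = FALSE)
}

add_evidence <- function(evidence, tag) {
  ifelse(!nzchar(evidence), tag,
         ifelse(grepl(tag, evidence, fixed = TRUE), evidence,
                paste(evidence, tag, sep = ",")))
}

aggregate_biochem <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) "absent"
  else if (any(calls$call == "pathologic")) "pathologic"
  else if (any(calls$call == "normal")) "normal"
  else "borderline"
}

#' Fold biochemical results into the variant classification
#'
#' A pathologic enzymatic/biomarker result adds strong functional evidence:
#' VUS upgrade to LP unless the variant carries contradictory evidence (it
#' then stays VUS). A normal result adds benign functional evidence; its
#' force depends on the assay: a normal *enzyme activity* directly measures
#' the gene product and excludes non-curated candidate variants from
#' reporting (curated P/LP and confirmed CNVs are never silently dropped —
#' they stay reportable, flagged `biochem_discordant`), while a normal
#' downstream *biomarker* is weaker — the VUS stays reportable with
#' recommendations for parental testing and biomarker follow-up. Borderline
#' results change nothing but recommend biomarker follow-up. Class moves
#' are bounded to one step of the five-class scale.
#'
#' @param states Classification states from [base_classify()].
#' @param calls Biochemical calls (from [interpret_biochem()]) belonging to
#'   the assays linked to the variants' gene.
#' @param assays Assay records of the panel (used for the assay kind).
#' @return List: updated `states`, `recommendations` (character).
#' @export
apply_biochem <- function(states, calls, assays) {
  recs <- character()
  if (!is.null(calls) && nrow(calls)) {
    linked <- assays$assay_id[assays$assay_id %in% calls$assay_id]
    if (length(linked) < length(unique(calls$assay_id)))
      stop("biochemical call for an assay not in the panel registry")
  }
  agg <- aggregate_biochem(calls)
  if (agg == "pathologic") {
    states$evidence <- add_evidence(states$evidence, "functional_pathologic")
    upgrade <- states$final_class == "VUS" & !states$conflicting_evidence
    states$final_class[upgrade] <- "LP"
    stays <- states$final_class == "VUS" & states$conflicting_evidence
    states$evidence[stays] <- add_evidence(states$evidence[stays],
                                           "conflicting_evidence")
  } else if (agg == "normal") {
    states$evidence <- add_evidence(states$evidence, "functional_normal")
    kinds <- assays$kind[match(calls$assay_id, assays$assay_id)]
    enzyme_normal <- any(calls$call == "normal" & kinds == "enzyme_activity")
    if (enzyme_normal) {
      states$reportable[!states$curated] <- FALSE
      states$evidence[states$curated] <-
        add_evidence(states$evidence[states$curated], "biochem_discordant")
    } else {
      recs <- c("parental_testing", "biomarker_followup")
    }
  } else if (agg == "borderline") {
    recs <- "biomarker_followup"
  }
  list(states = states, recommendations = recs)
}

#' Infer the phase of two heterozygous variants from biochemistry
#'
#' For an autosomal recessive gene carrying two heterozygous variants of
#' unknown phase, a normal activity of the gene's own enzyme implies at
#' least one functional allele, i.e. the variants sit on the same allele
#' (cis) and the genotype is no longer disease-consistent. A pathologic
#' result supports the trans configuration. A borderline result, a normal
#' downstream biomarker, or no available assay leaves the phase unknown.
#'
#' @param genotype_pattern Genotype pattern from [match_inheritance()].
#' @param calls Biochemical calls for the gene's assays.
#' @param assays Panel assay records.
#' @return `"cis"`, `"trans_supported"` or `"unknown"`.
#' @export
infer_phase <- function(genotype_pattern, calls, assays) {
  if (!identical(genotype_pattern, "comp_het_phase_unknown")) return("unknown")
  if (is.null(calls) || nrow(calls) == 0L) return("unknown")
  if (any(calls$call == "pathologic")) return("trans_supported")
  kinds <- assays$kind[match(calls$assay_id, assays$assay_id)]
  if (any(calls$call == "normal" & kinds == "enzyme_activity")) return("cis")
  "unknown"
}

#' Per-gene decision outcome
#'
#' The atomic cell of the reporting decision table: given one finding's
#' final class, the case's aggregated biochemical call, genotype
#' eligibility and reportability, returns its contribution to the report
#' status. Every combination maps to exactly one outcome.
#'
#' @param final_class One of P/LP/VUS/LB/B.
#' @param biochem_call `"pathologic"`, `"normal"`, `"borderline"` or
#'   `"absent"`.
#' @param eligible Does the genotype satisfy the inheritance mode?
#' @param reportable Is the variant still reportable?
#' @return `"positive"`, `"unclear"`, `"carrier"` or `"none"`.
#' @export
decision_outcome <- function(final_class, biochem_call, eligible, reportable) {
  stopifnot(final_class %in% FIVE_CLASSES,
            biochem_call %in% c("pathologic", "normal", "borderline", "absent"))
  if (!isTRUE(reportable)) return("none")
  if (final_class %in% c("P", "LP")) {
    if (!isTRUE(eligible)) return("carrier")
    if (biochem_call == "normal") return("unclear")
    return("positive")
  }
  if (final_class == "VUS") return("unclear")
  "none"
}

#' Assemble the case report
#'
#' Combines the per-gene classification results into a single
#' positive/unclear/negative report. A case is positive when at least one
#' reportable P/LP finding has an inheritance-consistent genotype and no
#' contradicting normal biochemistry; unclear when the best reportable
#' finding is a VUS (including pathologic biochemistry with only-VUS
#' genetics, and residual VUS after a normal biomarker) or a
#' biochemistry-discordant P/LP; negative when nothing reportable remains.
#' Carrier-level P/LP findings (single heterozygous allele in an AR
#' disease) and biochemistry-excluded candidates are kept in the `excluded`
#' audit trail, never among the findings.
#'
#' @param case A `metpanel_case`.
#' @param gene_results List of per-gene-entry results (internal layout, see
#'   [run_case()]).
#' @param panel A `metpanel_panel`.
#' @param syndromic Any multi-gene CNV retained?
#' @return A `metpanel_report`.
#' @export
assign_report <- function(case, gene_results, panel, syndromic = FALSE) {
  findings <- list()
  excluded <- list()
  all_calls <- list()
  recommendations <- character()

  for (res in gene_results) {
    st <- res$states
    if (!is.null(res$calls) && nrow(res$calls))
      all_calls[[length(all_calls) + 1L]] <- res$calls
    recommendations <- c(recommendations, res$recommendations)
    agg <- aggregate_biochem(res$calls)
    entry <- panel$genes[panel$genes$symbol == st$gene[1L] &
                         panel$genes$disease_id == st$disease_id[1L], ,
                         drop = FALSE]
    for (i in seq_len(nrow(st))) {
      out <- decision_outcome(st$final_class[i], agg,
                              res$eligibility$eligible, st$reportable[i])
      row <- data.frame(
        variant_key = st$variant_key[i], gene = st$gene[i],
        disease_id = st$disease_id[i],
        disease_name = entry$disease_name[1L],
        type = st$type[i], zygosity = st$zygosity[i],
        base_class = st$base_class[i], final_class = st$final_class[i],
        evidence = st$evidence[i],
        genotype_pattern = res$eligibility$genotype_pattern,
        phase = res$phase, treatable = entry$treatable[1L],
        outcome = out, stringsAsFactors = FALSE)
      if (out %in% c("positive", "unclear")) {
        findings[[length(findings) + 1L]] <- row
      } else {
        row$reason <- if (!st$reportable[i]) {
          if (identical(res$phase, "cis")) "phase_cis"
          else "biochem_normal_exclusion"
        } else if (out == "carrier") "carrier_only" else "not_reportable"
        excluded[[length(excluded) + 1L]] <- row
      }
    }
  }

  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(variant_key = character(), gene = character(),
               disease_id = character(), disease_name = character(),
               type = character(), zygosity = character(),
               base_class = character(), final_class = character(),
               evidence = character(), genotype_pattern = character(),
               phase = character(), treatable = logical(),
               outcome = character(), stringsAsFactors = FALSE)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(variant_key = character(), gene = character(),
               reason = character(), stringsAsFactors = FALSE)

  if (nrow(findings)) {
    rank <- match(findings$final_class, FIVE_CLASSES)
    allele_rank <- match(findings$genotype_pattern,
                         c("hom", "comp_het_phase_unknown", "hemi",
                           "het_x_female", "het_single", "none"))
    ord <- order(rank, allele_rank, findings$gene, findings$variant_key)
    findings <- findings[ord, , drop = FALSE]
    rownames(findings) <- NULL
  }

  status <- if (any(findings$outcome == "positive")) "positive"
    else if (any(findings$outcome == "unclear")) "unclear"
    else "negative"

  biochem_summary <- if (length(all_calls)) {
    b <- do.call(rbind, all_calls)
    b <- b[!duplicated(b$assay_id), , drop = FALSE]
    b[order(b$assay_id), , drop = FALSE]
  } else {
    data.frame(assay_id = character(), value = numeric(), call = character(),
               stringsAsFactors = FALSE)
  }
  rownames(biochem_summary) <- NULL

  structure(list(
    case_id = case$case_id %||% NA_character_,
    status = status,
    sex = case$sex %||% "unknown",
    region = case$region %||% NA_character_,
    consanguinity = case$consanguinity %||% NA_character_,
    family_history = case$family_history %||% NA_character_,
    age_onset_years = case$age_onset_years %||% NA_real_,
    age_testing_years = case$age_testing_years %||% NA_real_,
    findings = findings,
    excluded = excluded,
    biochem_summary = biochem_summary,
    syndromic_flag = isTRUE(syndromic),
    recommendations = sort(unique(recommendations))
  ), class = "metpanel_report")
}

#' Cross-tabulate biochemistry result against report status
#'
#' The 2x3 table of cases with at least one biochemical call: rows
#' pathologic/normal (case-level aggregate), columns
#' positive/negative/inconclusive. The decision table enforces two
#' structural zeros: a pathologic result never accompanies a negative
#' report (the supported candidate is at least a reportable VUS) and a
#' normal result never accompanies a positive one.
#'
#' @param reports List of `metpanel_report` objects.
#' @return 2x3 integer matrix.
#' @export
biochem_crosstab <- function(reports) {
  tab <- matrix(0L, nrow = 2L, ncol = 3L,
                dimnames = list(c("pathologic", "normal"),
                                c("positive", "negative", "inconclusive")))
  for (r in reports) {
    b <- r$biochem_summary
    if (is.null(b) || nrow(b) == 0L) next
    agg <- aggregate_biochem(b)
    if (!agg %in% c("pathologic", "normal")) next
    col <- switch(r$status, positive = "positive", negative = "negative",
                  unclear = "inconclusive")
    tab[agg, col] <- tab[agg, col] + 1L
  }
  tab
}

#' @export
print.metpanel_report <- function(x, ...) {
  cat("<metpanel report> case ", x$case_id, ": ", toupper(x$status), "\n",
      sep = "")
  if (nrow(x$findings)) {
    cat("  findings:\n")
    for (i in seq_len(nrow(x$findings))) {
      f <- x$findings[i, ]
      cat("   - ", f$gene, " ", f$variant_key, " [", f$final_class, "] ",
          f$genotype_pattern, " — ", f$disease_name,
          if (isTRUE(f$treatable)) " (treatable)" else "", "\n", sep = "")
    }
  }
  if (nrow(x$biochem_summary)) {
    cat("  biochemistry: ",
        paste(x$biochem_summary$assay_id, x$biochem_summary$call,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (length(x$recommendations))
    cat("  recommendations:", paste(x$recommendations, collapse = ", "), "\n")
  invisible(x)
}
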