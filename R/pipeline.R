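# End-to-end per-case pipeline: triage -> inheritance matching -> reflex
# biochemistry -> classification -> report.

#' Construct a patient case
#'
#' Bundles one patient's inputs: annotated SNVs, CNV calls, available
#' biochemical measurements, specimen QC and metadata.
#'
#' @param case_id Case identifier.
#' @param snvs data.frame of annotated SNVs (see [read_snvs()]); may be
#'   `NULL`.
#' @param cnvs data.frame of CNV calls (see [read_cnvs()]); may be `NULL`.
#' @param biochem data.frame of measured analytes (`assay_id`, `value`,
#'   optionally `units`); measurements are interpreted only when the
#'   corresponding assay is reflex-ordered.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param region,consanguinity,family_history,hpo Optional metadata.
#' @param age_onset_years,age_testing_years Ages in years (`NA` = unknown).
#' @param qc Optional list(`coverage_fraction_at_min_depth`, `min_depth`).
#' @return A `metpanel_case`.
#' @export
patient_case <- function(case_id, snvs = NULL, cnvs = NULL, biochem = NULL,
                         sex = "unknown", region = NA_character_,
                         consanguinity = NA_character_,
                         family_history = NA_character_, hpo = character(),
                         age_onset_years = NA_real_,
                         age_testing_years = NA_real_, qc = NULL) {
  structure(list(
    case_id = case_id, snvs = snvs, cnvs = cnvs, biochem = biochem,
    sex = sex, region = region, consanguinity = consanguinity,
    family_history = family_history, hpo = hpo,
    age_onset_years = age_onset_years, age_testing_years = age_testing_years,
    qc = qc), class = "metpanel_case")
}

#' Run the full diagnostic workflow on one case
#'
#' Triage the case's variants against the panel, match zygosity to each
#' candidate disease's inheritance mode, order and interpret reflex
#' biochemical assays, fold the biochemical evidence into the five-class
#' variant classification (including phase inference for compound
#' heterozygotes), and assemble the positive/unclear/negative report.
#'
#' @param case A `metpanel_case`.
#' @param panel A `metpanel_panel`.
#' @param grey_zone Borderline band of [interpret_biochem()].
#' @param c2_literal Passed to [evaluate_snv()].
#' @param reflex_single_het Also order reflex assays for single
#'   heterozygous candidates in AR diseases (carrier-level findings);
#'   off by default.
#' @return A `metpanel_report`.
#' @export
run_case <- function(case, panel, grey_zone = 0.1, c2_literal = FALSE,
                     reflex_single_het = FALSE) {
  th <- panel$thresholds
  qc_status <- if (!is.null(case$qc)) specimen_qc(case$qc, th) else NA_character_
  tri <- triage_case(case, panel, c2_literal = c2_literal)

  gene_results <- list()
  eligibility <- list()
  if (nrow(tri$variants)) {
    for (g in unique(tri$variants$gene)) {
      v <- tri$variants[tri$variants$gene == g, , drop = FALSE]
      entries <- lookup_gene(panel, g)
      for (j in seq_len(nrow(entries))) {
        entry <- entries[j, , drop = FALSE]
        states <- base_classify(v, entry, th)
        elig <- match_inheritance(v, entry, case$sex %||% "unknown")
        # a multi-gene (syndromic) CNV is a dosage lesion: one het copy
        # suffices irrespective of the single-disease inheritance mode
        if (any(v$syndromic)) elig$eligible <- TRUE
        reflex_ok <- elig$eligible ||
          (reflex_single_het && elig$allele_count >= 1L)
        eligibility[[length(eligibility) + 1L]] <-
          utils::modifyList(elig, list(eligible = reflex_ok))
        gene_results[[length(gene_results) + 1L]] <- list(
          entry = entry, variants = v, states = states, eligibility = elig)
      }
    }
  }

  orders <- trigger_reflex(eligibility, panel, case_id = case$case_id)
  calls <- interpret_orders(orders, case$biochem, panel, grey_zone)

  for (k in seq_along(gene_results)) {
    res <- gene_results[[k]]
    ids <- assay_id_vector(res$entry$assay_ids[1L])
    gene_calls <- calls[calls$assay_id %in% ids, , drop = FALSE]
    ab <- apply_biochem(res$states, gene_calls, panel$assays)
    res$states <- ab$states
    res$recommendations <- ab$recommendations
    res$calls <- gene_calls
    res$phase <- infer_phase(res$eligibility$genotype_pattern, gene_calls,
                             panel$assays)
    if (identical(res$phase, "cis")) {
      # cis configuration: genotype no longer disease-consistent; candidate
      # variants are dropped, curated assertions stay (flagged upstream)
      res$eligibility$eligible <- FALSE
      drop <- !res$states$curated
      res$states$reportable[drop] <- FALSE
      res$states$evidence[drop] <-
        add_evidence(res$states$evidence[drop], "phase_inferred_cis")
    }
    gene_results[[k]] <- res
  }

  report <- assign_report(case, gene_results, panel,
                          syndromic = tri$syndromic)
  report$qc <- qc_status
  report
}

# Interpret measured values for the ordered assays (internal).
interpret_orders <- function(orders, biochem, panel, grey_zone) {
  empty <- data.frame(assay_id = character(), value = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  if (is.null(biochem) || !nrow(orders)) return(empty)
  out <- list()
  for (i in seq_len(nrow(orders))) {
    id <- orders$assay_id[i]
    m <- biochem[biochem$assay_id == id, , drop = FALSE]
    if (!nrow(m)) next
    assay <- panel$assays[panel$assays$assay_id == id, , drop = FALSE]
    units <- if ("units" %in% names(m)) m$units[1L] else NULL
    out[[length(out) + 1L]] <-
      interpret_biochem(m$value[1L], assay, grey_zone, units = units)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Run the workflow over a cohort
#'
#' @param cases List of `metpanel_case` objects.
#' @param panel A `metpanel_panel`.
#' @param ... Passed to [run_case()].
#' @return List of `metpanel_report` objects.
#' @export
run_cohort <- function(cases, panel, ...) {
  lapply(cases, run_case, panel = panel, ...)
}
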