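# Inheritance-mode zygosity matching, reflex assay ordering, and
# interpretation of biochemical measurements against reference intervals.

#' Match variant zygosity against a disease's mode of inheritance
#'
#' Counts alleles over all retained variants of one gene entry (hom and
#' homozygous-deletion CNVs count 2; each het SNV/CNV and each hemizygous
#' call counts 1; SNV and CNV alleles combine, so a het SNV plus a het
#' exon deletion forms a potential compound heterozygote of unknown phase).
#' Eligibility: AR requires 2 alleles; AD requires at least 1; XL requires
#' a hemizygous male, a homozygous female, or — for diseases where
#' heterozygous females are reportable — a het female.
#'
#' @param variants data.frame of retained variants in one gene (columns
#'   `zygosity`, optionally `type`).
#' @param gene Single-row gene record from the panel.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return List: `gene`, `disease_id`, `eligible`, `genotype_pattern`
#'   (`hom`, `comp_het_phase_unknown`, `het_single`, `hemi`,
#'   `het_x_female`, `none`), `allele_count` (0, 1 or 2).
#' @export
match_inheritance <- function(variants, gene, sex = "unknown") {
  stopifnot(nrow(gene) == 1L)
  zyg <- variants$zygosity
  if (any(zyg == "hemi") && identical(sex, "female"))
    stop("data inconsistency: hemizygous variant in a female case")
  per_allele <- c(het = 1L, hom = 2L, hemi = 1L)
  count <- sum(per_allele[zyg])
  allele_count <- min(2L, count)

  pattern <- if (length(zyg) == 0L) "none"
    else if (any(zyg == "hom")) "hom"
    else if (any(zyg == "hemi")) "hemi"
    else if (sum(zyg == "het") >= 2L) "comp_het_phase_unknown"
    else if (gene$inheritance == "XL" && identical(sex, "female")) "het_x_female"
    else "het_single"

  eligible <- switch(gene$inheritance,
    AR = allele_count >= 2L,
    AD = allele_count >= 1L,
    XL = {
      if (any(zyg == "hom")) TRUE
      else if (any(zyg == "hemi")) TRUE
      else if (length(zyg) >= 1L && identical(sex, "female"))
        isTRUE(gene$female_het_reportable)
      # het X variants in males are treated as effectively hemizygous only
      # when called hemi by the caller; an unknown-sex het is not eligible
      else FALSE
    },
    FALSE)

  list(gene = gene$symbol, disease_id = gene$disease_id,
       eligible = isTRUE(eligible), genotype_pattern = pattern,
       allele_count = allele_count)
}

#' Order reflex biochemical assays for eligible genotypes
#'
#' One order per (eligible gene entry, linked assay), for gene entries
#' whose candidate variants are provisionally P/LP/VUS and whose zygosity
#' corresponds to the mode of inheritance. Genes without a linked assay
#' produce no order; duplicate orders (two eligible diseases sharing an
#' assay) are collapsed.
#'
#' @param eligibility List of [match_inheritance()] results (one per gene
#'   entry with candidate variants).
#' @param panel A `metpanel_panel`.
#' @param case_id Case identifier carried into the order table.
#' @return data.frame of orders: `case_id`, `gene`, `disease_id`,
#'   `assay_id`.
#' @export
trigger_reflex <- function(eligibility, panel, case_id = NA_character_) {
  orders <- list()
  for (e in eligibility) {
    if (!isTRUE(e$eligible)) next
    entry <- panel$genes[panel$genes$symbol == e$gene &
                         panel$genes$disease_id == e$disease_id, , drop = FALSE]
    if (!nrow(entry)) next
    for (id in assay_id_vector(entry$assay_ids[1L])) {
      orders[[length(orders) + 1L]] <- data.frame(
        case_id = case_id, gene = e$gene, disease_id = e$disease_id,
        assay_id = id, stringsAsFactors = FALSE)
    }
  }
  if (!length(orders)) {
    return(data.frame(case_id = character(), gene = character(),
                      disease_id = character(), assay_id = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, orders)
  res[!duplicated(res$assay_id), , drop = FALSE]
}

#' Interpret a biochemical measurement
#'
#' Calls a measured analyte pathologic, normal or borderline against the
#' assay's reference interval. The call is made relative to the reference
#' bound in the assay's pathologic direction (reference_low for
#' deficiency-type assays, reference_high for accumulation biomarkers),
#' with a symmetric grey zone of `grey_zone` times that bound: values
#' beyond the bound by more than the grey zone are pathologic, values on
#' the safe side by more than the grey zone are normal, values inside the
#' band (including exactly at the bound) are borderline.
#'
#' @param value Numeric measurement(s), in the assay's units.
#' @param assay Single-row assay record.
#' @param grey_zone Relative width of the borderline band (default 0.10).
#' @param units Optional unit string; must match the assay's units.
#' @return data.frame with `assay_id`, `value`, `call`.
#' @export
interpret_biochem <- function(value, assay, grey_zone = 0.1, units = NULL) {
  stopifnot(nrow(assay) == 1L, grey_zone >= 0)
  if (!is.null(units) && !identical(units, assay$units))
    stop("unit mismatch for assay ", assay$assay_id, ": got '", units,
         "', expected '", assay$units, "'")
  bound <- if (assay$pathologic_direction == "below_range")
    assay$reference_low else assay$reference_high
  band <- grey_zone * abs(bound)
  call <- if (assay$pathologic_direction == "below_range") {
    ifelse(value < bound - band, "pathologic",
           ifelse(value > bound + band, "normal", "borderline"))
  } else {
    ifelse(value > bound + band, "pathologic",
           ifelse(value < bound - band, "normal", "borderline"))
  }
  data.frame(assay_id = assay$assay_id, value = value, call = call,
             stringsAsFactors = FALSE)
}
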