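# Semi-automated variant triage: the six-criterion SNV filter cascade, the
# CNV selection rules, and flagging of variants needing orthogonal
# confirmation.

SNV_CRITERIA <- c("C1_prior_PLP_VUS", "C2_unclassified", "C3_rare_high_moderate",
                  "C4_external_disease_causing", "C5_splice_scores")
CNV_CRITERIA <- c("CNV_hom_del", "CNV_het_multiexon", "CNV_confirmed")

#' Evaluate SNVs/indels against the filter cascade
#'
#' A variant is retained when it is not previously classified (likely)
#' benign and at least one inclusion criterion fires:
#' \describe{
#'   \item{C1}{prior internal classification P, LP or VUS}
#'   \item{C2}{previously unclassified variant (gated by the same rarity
#'     test as C3 unless `c2_literal = TRUE`)}
#'   \item{C3}{MAF < 1% in both external and internal healthy-cohort
#'     frequencies (absent counts as 0) with high/moderate predicted impact}
#'   \item{C4}{asserted disease-causing by external databases}
#'   \item{C5}{dbscSNV ADA and RF splice scores both > 0.6}
#' }
#' Prior (likely) benign classification dominates all inclusion criteria.
#' Retained variants with a failed quality flag are marked for Sanger
#' confirmation.
#'
#' @param snvs data.frame of annotated SNVs (one or more rows).
#' @param thresholds Threshold list, see [default_thresholds()].
#' @param c2_literal Take criterion C2 literally (retain every unclassified
#'   variant regardless of frequency). Off by default: an ungated C2 would
#'   retain every novel common variant that the semi-automated workflow's
#'   human review absorbs.
#' @return data.frame with one decision per input row: `retained`,
#'   `criteria_hit` (comma-joined), `excluded_by`, `confirmation`.
#' @export
evaluate_snv <- function(snvs, thresholds = default_thresholds(),
                         c2_literal = FALSE) {
  s <- as.data.frame(snvs, stringsAsFactors = FALSE)
  n <- nrow(s)
  num <- function(x) {
    if (is.null(x)) rep(NA_real_, n) else suppressWarnings(as.numeric(x))
  }
  maf_ext <- num(s$maf_external)
  maf_int <- num(s$maf_internal)
  maf_max <- pmax(ifelse(is.na(maf_ext), 0, maf_ext),
                  ifelse(is.na(maf_int), 0, maf_int))
  prior <- as.character(s$prior_internal_class)
  prior[is.na(prior)] <- "absent"
  assertion <- as.character(s$external_assertion %||% rep("none", n))
  assertion[is.na(assertion)] <- "none"
  impact <- as.character(s$impact)
  ada <- num(s$ada_score)
  rf <- num(s$rf_score)
  quality_ok <- if (is.null(s$quality_ok)) rep(TRUE, n) else
    !(s$quality_ok %in% FALSE)

  rare <- maf_max < thresholds$maf_snv
  c1 <- prior %in% c("P", "LP", "VUS")
  c2 <- prior == "unclassified" & (c2_literal | rare)
  c3 <- rare & impact %in% c("high", "moderate")
  c4 <- assertion == "disease_causing"
  c5 <- !is.na(ada) & !is.na(rf) &
    ada > thresholds$splice_score_min & rf > thresholds$splice_score_min
  benign <- prior %in% c("LB", "B")
  retained <- !benign & (c1 | c2 | c3 | c4 | c5)

  hits <- cbind(c1, c2, c3, c4, c5)
  criteria_hit <- apply(hits, 1L, function(h)
    paste(SNV_CRITERIA[h], collapse = ","))
  criteria_hit[benign] <- ""
  data.frame(
    retained = retained,
    criteria_hit = criteria_hit,
    excluded_by = ifelse(benign, "prior_benign", "none"),
    confirmation = ifelse(retained & !quality_ok, "sanger", "none"),
    stringsAsFactors = FALSE)
}

#' Evaluate CNV calls against the selection rules
#'
#' Retained when the CNV is rare (MAF < 2%, absent counting as 0) and is
#' either (i) a homozygous deletion (copy number 0, any span) or (ii) a
#' heterozygous deletion (1 copy) or duplication (> 2 copies) affecting
#' more than 2 exons. A heterozygous deletion/duplication already confirmed
#' by an orthogonal method (`confirmed_by` of qPCR/MLPA/CMA) is retained
#' regardless of span: the span cut-off is a screening heuristic for
#' unconfirmed NGS calls, not a property of the lesion. Retained
#' non-homozygous CNVs are flagged for orthogonal confirmation; homozygous
#' deletions need none.
#'
#' @param cnvs data.frame of CNV calls (columns `copy_number`,
#'   `exon_start`, `exon_end`, `maf`, optionally `confirmed_by`).
#' @param gene Optional single-row gene record for exon-span validation.
#' @param thresholds Threshold list.
#' @return data.frame of decisions, same layout as [evaluate_snv()].
#' @export
evaluate_cnv <- function(cnvs, gene = NULL, thresholds = default_thresholds()) {
  c_ <- as.data.frame(cnvs, stringsAsFactors = FALSE)
  n <- nrow(c_)
  if (!is.null(gene) && nrow(gene) == 1L &&
      any(c_$exon_end > gene$exon_count))
    stop("CNV exon span exceeds exon count of gene ", gene$symbol)
  maf <- suppressWarnings(as.numeric(c_$maf))
  maf <- ifelse(is.na(maf), 0, maf)
  cn <- as.integer(c_$copy_number)
  span <- as.integer(c_$exon_end) - as.integer(c_$exon_start) + 1L
  confirmed <- if (is.null(c_$confirmed_by)) rep(FALSE, n) else
    !(c_$confirmed_by %in% c("none", "", NA))

  rare <- maf < thresholds$maf_cnv
  hom_del <- cn == 0L
  het_amp <- cn == 1L | cn > 2L
  multiexon <- het_amp & span >= thresholds$het_cnv_min_exons
  confirmed_het <- het_amp & confirmed
  retained <- rare & (hom_del | multiexon | confirmed_het)

  hits <- cbind(hom_del, multiexon, confirmed_het)
  criteria_hit <- apply(hits, 1L, function(h)
    paste(CNV_CRITERIA[h], collapse = ","))
  data.frame(
    retained = retained,
    criteria_hit = criteria_hit,
    excluded_by = rep("none", n),
    confirmation = ifelse(retained & !hom_del, "orthogonal_cnv", "none"),
    stringsAsFactors = FALSE)
}

snv_variant_key <- function(snvs) {
  paste0(snvs$chrom, ":", snvs$pos, ":", snvs$ref, ">", snvs$alt)
}

cnv_variant_key <- function(cnvs) {
  paste0("CNV:", cnvs$genes, ":CN", cnvs$copy_number, ":ex",
         cnvs$exon_start, "-", cnvs$exon_end)
}

#' Triage all variants of one case against the panel
#'
#' Deduplicates SNVs by (chrom, pos, ref, alt, zygosity), restricts to
#' panel genes, runs [evaluate_snv()] and [evaluate_cnv()], and groups the
#' retained variants by gene. A multi-gene CNV is retained when any of its
#' constituent panel genes passes the selection, and marks the case
#' syndromic (large chromosomal lesion, e.g. a whole-arm trisomy).
#'
#' @param case A `metpanel_case` (list with `snvs`, `cnvs`, `sex`, ...).
#' @param panel A `metpanel_panel`.
#' @param c2_literal Passed to [evaluate_snv()].
#' @return List with `variants` (data.frame of retained variants: gene,
#'   variant_key, type, zygosity, annotations, confirmation) and
#'   `syndromic` (logical).
#' @export
triage_case <- function(case, panel, c2_literal = FALSE) {
  th <- panel$thresholds
  out <- list()
  syndromic <- FALSE

  snvs <- case$snvs
  if (!is.null(snvs) && nrow(snvs)) {
    dup <- duplicated(paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt,
                            snvs$zygosity))
    snvs <- snvs[!dup & snvs$gene %in% panel$genes$symbol, , drop = FALSE]
    if (nrow(snvs)) {
      dec <- evaluate_snv(snvs, th, c2_literal = c2_literal)
      keep <- dec$retained
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          gene = snvs$gene[keep],
          variant_key = snv_variant_key(snvs[keep, , drop = FALSE]),
          type = "snv",
          zygosity = snvs$zygosity[keep],
          impact = snvs$impact[keep],
          prior_internal_class = snvs$prior_internal_class[keep],
          external_assertion = snvs$external_assertion[keep],
          maf_external = snvs$maf_external[keep],
          maf_internal = snvs$maf_internal[keep],
          ada_score = snvs$ada_score[keep],
          rf_score = snvs$rf_score[keep],
          hgvs = snvs$hgvs[keep],
          exon_start = NA_integer_, exon_end = NA_integer_,
          copy_number = NA_integer_,
          conflicting_evidence = if (is.null(snvs$conflicting_evidence))
            FALSE else snvs$conflicting_evidence[keep],
          confirmation = dec$confirmation[keep],
          criteria_hit = dec$criteria_hit[keep],
          syndromic = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }

  cnvs <- case$cnvs
  if (!is.null(cnvs) && nrow(cnvs)) {
    for (i in seq_len(nrow(cnvs))) {
      genes_i <- strsplit(cnvs$genes[i], ",", fixed = TRUE)[[1]]
      panel_genes <- intersect(genes_i, panel$genes$symbol)
      if (!length(panel_genes)) next
      dec <- evaluate_cnv(cnvs[i, , drop = FALSE], thresholds = th)
      if (!dec$retained) next
      multi <- length(genes_i) > 1L
      if (multi) syndromic <- TRUE
      # single-gene CNVs attach to each panel disease entry of that gene;
      # multi-gene CNVs attach to every constituent panel gene
      for (g in panel_genes) {
        out[[length(out) + 1L]] <- data.frame(
          gene = g,
          variant_key = cnv_variant_key(cnvs[i, , drop = FALSE]),
          type = if (cnvs$copy_number[i] > 2L) "cnv_dup" else "cnv_del",
          zygosity = if (cnvs$copy_number[i] == 0L) "hom" else "het",
          impact = "high",
          prior_internal_class = "absent",
          external_assertion = "none",
          maf_external = cnvs$maf[i], maf_internal = NA_real_,
          ada_score = NA_real_, rf_score = NA_real_,
          hgvs = NA_character_,
          exon_start = cnvs$exon_start[i], exon_end = cnvs$exon_end[i],
          copy_number = cnvs$copy_number[i],
          conflicting_evidence = FALSE,
          confirmation = dec$confirmation,
          criteria_hit = dec$criteria_hit,
          syndromic = multi,
          stringsAsFactors = FALSE)
      }
    }
  }

  variants <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(variants)) {
    variants <- data.frame(gene = character(), variant_key = character(),
                           type = character(), zygosity = character(),
                           stringsAsFactors = FALSE)
  } else {
    variants <- variants[order(variants$gene, variants$variant_key), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  }
  list(variants = variants, syndromic = syndromic)
}
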