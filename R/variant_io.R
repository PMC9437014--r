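# Reading annotated SNVs (VCF) and CNV calls (TSV), the specimen-level QC
# gate, and machine-readable case report output.

SNV_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "zygosity", "impact",
                 "maf_external", "maf_internal", "prior_internal_class",
                 "external_assertion", "ada_score", "rf_score", "quality_ok",
                 "hgvs")
PRIOR_CLASSES <- c("P", "LP", "VUS", "LB", "B", "unclassified", "absent")
IMPACT_TIERS <- c("high", "moderate", "low", "modifier")

#' Default VCF annotation field mapping
#'
#' Names the INFO fields that carry each annotation consumed by the triage
#' cascade and classifier. Override entries to adapt to another annotation
#' pipeline's tag names.
#'
#' @return Named list mapping record fields to INFO keys.
#' @export
snv_field_mapping <- function() {
  list(gene = "GENE", impact = "IMPACT", maf_external = "MAF_EXT",
       maf_internal = "MAF_INT", prior_internal_class = "PRIOR_CLASS",
       external_assertion = "EXT_ASSERT", ada_score = "ADA", rf_score = "RF",
       quality_ok = "QUAL_OK", hgvs = "HGVS")
}

#' Read annotated SNVs/indels from a VCF file
#'
#' Produces one record per ALT allele for every genotype that is not
#' homozygous reference. Multi-allelic sites are decomposed (the filter
#' cascade is per-allele); per-allele (`Number=A`) INFO values are split
#' accordingly. Absent annotations stay absent (`NA`) — never 0.
#'
#' @param path VCF 4.x file (plain text or bgzip).
#' @param mapping Annotation field mapping, see [snv_field_mapping()].
#' @param sex Case sex (`"male"`, `"female"`, `"unknown"`), used to check
#'   hemizygous calls.
#' @return data.frame of annotated SNVs (see package docs for columns).
#' @export
read_snvs <- function(path, mapping = snv_field_mapping(), sex = "unknown") {
  unknown <- setdiff(names(mapping), names(snv_field_mapping()))
  if (length(unknown)) {
    stop("unknown annotation mapping key(s): ", paste(unknown, collapse = ", "))
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) return(empty_snvs())
  gt <- vcfR::extract.gt(vcf)
  gt <- if (is.null(gt)) rep("1/1", n_rec) else gt[, 1L]
  info_field <- function(key) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = key))
    if (is.null(v)) rep(NA_character_, n_rec) else as.character(v)
  }
  raw <- lapply(mapping, info_field)
  out <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("|", "/", gt[i], fixed = TRUE), "/", fixed = TRUE)[[1]]
    alleles <- alleles[alleles != "."]
    if (!length(alleles)) next
    per_a <- lapply(raw, function(x) {
      parts <- strsplit(x[i] %||% NA_character_, ",", fixed = TRUE)[[1]]
      if (length(parts) == 0L) parts <- NA_character_
      if (length(parts) == 1L) rep(parts, length(alts)) else parts
    })
    for (a in seq_along(alts)) {
      n_alt <- sum(alleles == as.character(a))
      if (n_alt == 0L) next
      zyg <- if (length(alleles) == 1L) "hemi" else if (n_alt >= 2L) "hom" else "het"
      val <- function(f) per_a[[f]][a]
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a], gene = val("gene"),
        zygosity = zyg, impact = val("impact"),
        maf_external = suppressWarnings(as.numeric(val("maf_external"))),
        maf_internal = suppressWarnings(as.numeric(val("maf_internal"))),
        prior_internal_class = val("prior_internal_class") %|na|% "absent",
        external_assertion = val("external_assertion") %|na|% "none",
        ada_score = suppressWarnings(as.numeric(val("ada_score"))),
        rf_score = suppressWarnings(as.numeric(val("rf_score"))),
        quality_ok = !identical(val("quality_ok"), "0"),
        hgvs = val("hgvs"),
        stringsAsFactors = FALSE)
    }
  }
  snvs <- if (length(out)) do.call(rbind, out) else empty_snvs()
  validate_snvs(snvs, sex = sex)
  snvs
}

`%|na|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

empty_snvs <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), zygosity = character(),
             impact = character(), maf_external = numeric(),
             maf_internal = numeric(), prior_internal_class = character(),
             external_assertion = character(), ada_score = numeric(),
             rf_score = numeric(), quality_ok = logical(), hgvs = character(),
             stringsAsFactors = FALSE)
}

validate_snvs <- function(snvs, sex = "unknown") {
  if (!nrow(snvs)) return(invisible(snvs))
  stopifnot(all(snvs$pos >= 1L))
  if (!all(snvs$zygosity %in% c("het", "hom", "hemi")))
    stop("invalid zygosity value(s)")
  frac_cols <- c("maf_external", "maf_internal", "ada_score", "rf_score")
  for (f in frac_cols) {
    v <- snvs[[f]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(f, " outside [0, 1]")
  }
  hemi <- snvs$zygosity == "hemi"
  if (any(hemi)) {
    on_xy <- grepl("^(chr)?[XY]$", snvs$chrom[hemi])
    if (!all(on_xy))
      stop("hemizygous call on autosome: ",
           paste(unique(snvs$chrom[hemi][!on_xy]), collapse = ", "))
    if (identical(sex, "female"))
      stop("data inconsistency: hemizygous X/Y call in a female case")
  }
  invisible(snvs)
}

#' Write annotated SNVs as a VCF 4.2 file
#'
#' Plain-text output carrying every annotation of the record in INFO tags,
#' re-readable by [read_snvs()] (round-trip stable for all fields the
#' downstream cascade consumes).
#'
#' @param snvs data.frame as returned by [read_snvs()].
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param mapping Annotation field mapping.
#' @return `path`, invisibly.
#' @export
write_snvs_vcf <- function(snvs, path, sample_id = "SAMPLE",
                           mapping = snv_field_mapping()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=metpanel",
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="%s">',
            unlist(mapping, use.names = FALSE), names(mapping)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, format(x, scientific = FALSE, trim = TRUE))
  body <- character(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    vals <- c(gene = snvs$gene[i], impact = snvs$impact[i],
              maf_external = fmt_num(snvs$maf_external[i]),
              maf_internal = fmt_num(snvs$maf_internal[i]),
              prior_internal_class = snvs$prior_internal_class[i],
              external_assertion = snvs$external_assertion[i],
              ada_score = fmt_num(snvs$ada_score[i]),
              rf_score = fmt_num(snvs$rf_score[i]),
              quality_ok = if (isTRUE(snvs$quality_ok[i])) "1" else "0",
              hgvs = snvs$hgvs[i])
    keep <- !is.na(vals) & !(names(vals) %in% c("prior_internal_class") & vals == "absent") &
      !(names(vals) %in% c("external_assertion") & vals == "none")
    info <- paste(paste0(unlist(mapping[names(vals)[keep]]), "=", vals[keep]),
                  collapse = ";")
    if (!nzchar(info)) info <- "."
    gt <- switch(snvs$zygosity[i], hom = "1/1", het = "0/1", hemi = "1")
    body[i] <- paste(snvs$chrom[i], snvs$pos[i], ".", snvs$ref[i],
                     snvs$alt[i], ".", "PASS", info, "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

CNV_TSV_HEADER <- c("sample", "genes", "copy_number", "exon_start",
                    "exon_end", "maf", "confirmed_by")

#' Read CNV calls from a tab-separated file
#'
#' Expected header: `sample genes copy_number exon_start exon_end maf
#' confirmed_by`; `genes` holds one or more comma-separated symbols. Exon
#' indices are 1-based inclusive on the panel transcript. When a panel is
#' supplied, exon spans are validated against each panel gene's exon count.
#'
#' @param path TSV file path.
#' @param panel Optional `metpanel_panel` for exon-span validation.
#' @return data.frame of CNV calls with a computed `multi_gene` column.
#' @export
read_cnvs <- function(path, panel = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(CNV_TSV_HEADER, names(df))
  if (length(missing))
    stop("CNV table missing column(s): ", paste(missing, collapse = ", "))
  cnvs <- data.frame(
    sample = df$sample, genes = df$genes,
    copy_number = as.integer(df$copy_number),
    exon_start = as.integer(df$exon_start),
    exon_end = as.integer(df$exon_end),
    maf = suppressWarnings(as.numeric(df$maf)),
    confirmed_by = ifelse(is.na(df$confirmed_by) | !nzchar(df$confirmed_by),
                          "none", df$confirmed_by),
    stringsAsFactors = FALSE)
  cnvs$multi_gene <- vapply(strsplit(cnvs$genes, ",", fixed = TRUE),
                            function(g) length(g) > 1L, logical(1))
  validate_cnvs(cnvs, panel)
  cnvs
}

validate_cnvs <- function(cnvs, panel = NULL) {
  if (!nrow(cnvs)) return(invisible(cnvs))
  if (any(cnvs$copy_number < 0L)) stop("copy_number must be >= 0")
  if (any(cnvs$exon_start > cnvs$exon_end))
    stop("exon_start must be <= exon_end")
  if (any(cnvs$exon_start < 1L)) stop("exon indices are 1-based")
  if (!is.null(panel)) {
    for (i in seq_len(nrow(cnvs))) {
      for (g in strsplit(cnvs$genes[i], ",", fixed = TRUE)[[1]]) {
        rows <- lookup_gene(panel, g)
        if (nrow(rows) && !cnvs$multi_gene[i] &&
            cnvs$exon_end[i] > max(rows$exon_count))
          stop("CNV exon_end ", cnvs$exon_end[i], " exceeds exon count ",
               max(rows$exon_count), " of gene ", g)
      }
    }
  }
  invisible(cnvs)
}

#' Write CNV calls to TSV
#'
#' @param cnvs data.frame of CNV calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvs_tsv <- function(cnvs, path) {
  utils::write.table(cnvs[, CNV_TSV_HEADER, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Specimen-level sequencing QC gate
#'
#' Passes when the fraction of targeted bases covered at the minimum read
#' depth reaches the configured bound (defaults: 99.5% at >= 20x).
#'
#' @param qc List with `coverage_fraction_at_min_depth` and `min_depth`.
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return `"pass"` or `"fail"`.
#' @export
specimen_qc <- function(qc, thresholds = default_thresholds()) {
  stopifnot(qc$coverage_fraction_at_min_depth >= 0,
            qc$coverage_fraction_at_min_depth <= 1)
  ok <- qc$coverage_fraction_at_min_depth >= thresholds$qc_min_coverage_fraction &&
    qc$min_depth >= thresholds$qc_min_depth
  if (ok) "pass" else "fail"
}

#' Write a case report to disk
#'
#' JSON output is bit-stable for identical inputs: fixed key order, fixed
#' numeric formatting. The TSV format emits the findings table with the
#' case-level fields repeated per row.
#'
#' @param report A `metpanel_report` from [run_case()] / [assign_report()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                             na = "null", null = "null", dataframe = "rows")
    writeLines(json, path)
  } else {
    f <- report$findings
    if (nrow(f) == 0L) {
      f <- data.frame(variant_key = NA_character_)
    }
    f$case_id <- report$case_id
    f$status <- report$status
    utils::write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON case report written by [write_report()]
#'
#' @param path JSON report path.
#' @return A `metpanel_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = TRUE)
  for (slot in c("findings", "excluded", "biochem_summary")) {
    if (is.null(x[[slot]]) || length(x[[slot]]) == 0L ||
        !is.data.frame(x[[slot]])) {
      x[[slot]] <- as.data.frame(x[[slot]] %||% list())
    }
  }
  x$recommendations <- as.character(unlist(x$recommendations))
  structure(x, class = "metpanel_report")
}
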