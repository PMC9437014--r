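# Panel knowledge base: genes, diseases, inheritance modes, metabolic
# categories, treatability and linked biochemical assays, plus the numeric
# thresholds driving triage and QC.

# Closed set of metabolic category labels used by the panel.
PANEL_CATEGORIES <- c(
  "lysosomal", "carbohydrate", "amino_acid_peptide", "organic_acid",
  "fatty_acid_oxidation", "mitochondrial_energy", "peroxisomal",
  "metal_metabolism", "purine_pyrimidine", "glycosylation",
  "lipid_lipoprotein", "vitamin_cofactor", "neurotransmitter",
  "urea_cycle", "porphyrin_heme_bilirubin", "steroid_bile_acid",
  "creatine_metabolism", "other_metabolic"
)

INHERITANCE_MODES <- c("AR", "AD", "XL")
ASSAY_KINDS <- c("enzyme_activity", "biomarker")
ASSAY_DIRECTIONS <- c("below_range", "above_range")

#' Metabolic category labels
#'
#' The closed set of 18 metabolic disease categories a panel gene entry may
#' carry (lysosomal, carbohydrate, amino acid/peptide metabolism, ...).
#'
#' @return Character vector of length 18.
#' @export
panel_categories <- function() PANEL_CATEGORIES

#' Default triage and QC thresholds
#'
#' Numeric cut-offs of the diagnostic workflow: SNV rarity gate (MAF < 1%,
#' external and internal healthy-cohort frequencies combined), CNV rarity
#' gate (MAF < 2%), dbscSNV splice-score cut-off (ADA and RF > 0.6),
#' minimum exon span for heterozygous CNVs (3, i.e. "more than 2 exons"),
#' and the specimen QC gate (99.5% of target covered at >= 20x). The
#' healthy reference cohort size (~24,000 adults) is carried as metadata.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    maf_snv = 0.01,
    maf_cnv = 0.02,
    splice_score_min = 0.6,
    het_cnv_min_exons = 3L,
    qc_min_coverage_fraction = 0.995,
    qc_min_depth = 20L,
    healthy_cohort_size = 24000L
  )
}

#' Path to the packaged default panel configuration
#'
#' A surrogate 206-gene IMD panel configuration with 25 linked biochemical
#' assays. Entries marked `placeholder: true` pad the gene list to the full
#' panel size and carry no curated biology; all genes that matter for the
#' packaged examples are real entries with their usual inheritance modes.
#'
#' @return File path of the YAML configuration.
#' @export
metpanel_panel_file <- function() {
  system.file("extdata", "panel_default.yaml", package = "metpanel",
              mustWork = TRUE)
}

panel_gene_columns <- function() {
  c("symbol", "transcript", "exon_count", "inheritance", "disease_id",
    "disease_name", "category", "treatable", "assay_ids",
    "female_het_reportable", "lof_mechanism", "placeholder")
}

#' Load and validate a panel configuration
#'
#' Reads a YAML panel configuration with `genes:`, `assays:` and
#' `thresholds:` sections (see the packaged default for the dialect),
#' applies threshold defaults for absent entries, resolves assay
#' cross-references and validates the result.
#'
#' @param path Path to a YAML panel configuration. Defaults to the packaged
#'   surrogate panel.
#' @return A `metpanel_panel` object: list with `genes` (data.frame, one
#'   row per gene-disease entry), `assays` (data.frame), `thresholds`
#'   (list) and `meta` (list).
#' @export
load_panel <- function(path = metpanel_panel_file()) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("panel config parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  panel <- panel_from_config(cfg, source = path)
  issues <- validate_panel(panel)
  if (nrow(issues) > 0L) {
    stop("invalid panel config '", path, "':\n  ",
         paste(issues$message, collapse = "\n  "), call. = FALSE)
  }
  panel
}

# Build a metpanel_panel from a parsed config list (internal).
panel_from_config <- function(cfg, source = "<config>") {
  if (is.null(cfg$genes) || length(cfg$genes) == 0L) {
    stop("invalid panel config '", source, "': no genes defined",
         call. = FALSE)
  }
  gene_row <- function(g) {
    data.frame(
      symbol = as.character(g$symbol),
      transcript = as.character(g$transcript %||% NA_character_),
      exon_count = as.integer(g$exon_count %||% NA_integer_),
      inheritance = as.character(g$inheritance %||% NA_character_),
      disease_id = as.character(g$disease_id %||% NA_character_),
      disease_name = as.character(g$disease_name %||% NA_character_),
      category = as.character(g$category %||% NA_character_),
      treatable = isTRUE(g$treatable),
      assay_ids = paste(unlist(g$assays), collapse = ","),
      female_het_reportable = isTRUE(g$female_het_reportable),
      lof_mechanism = !isFALSE(g$lof_mechanism),
      placeholder = isTRUE(g$placeholder),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, lapply(cfg$genes, gene_row))
  assay_row <- function(a) {
    data.frame(
      assay_id = as.character(a$assay_id),
      kind = as.character(a$kind %||% NA_character_),
      analyte = as.character(a$analyte %||% NA_character_),
      pathologic_direction = as.character(a$pathologic_direction %||% NA_character_),
      reference_low = as.numeric(a$reference_low %||% NA_real_),
      reference_high = as.numeric(a$reference_high %||% NA_real_),
      units = as.character(a$units %||% NA_character_),
      stringsAsFactors = FALSE
    )
  }
  assays <- if (length(cfg$assays)) {
    do.call(rbind, lapply(cfg$assays, assay_row))
  } else {
    data.frame(assay_id = character(), kind = character(),
               analyte = character(), pathologic_direction = character(),
               reference_low = numeric(), reference_high = numeric(),
               units = character(), stringsAsFactors = FALSE)
  }
  thresholds <- utils::modifyList(default_thresholds(),
                                  as.list(cfg$thresholds %||% list()))
  structure(
    list(genes = genes, assays = assays, thresholds = thresholds,
         meta = as.list(cfg$panel %||% list())),
    class = "metpanel_panel"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a panel configuration
#'
#' Enumerates every violation of the panel invariants: exon counts,
#' inheritance modes, category membership, assay reference intervals and
#' directions, dangling assay references, duplicated (gene, disease)
#' entries and threshold ranges.
#'
#' @param panel A `metpanel_panel`.
#' @return data.frame with columns `scope`, `id`, `message`; zero rows iff
#'   the panel is valid.
#' @export
validate_panel <- function(panel) {
  bad <- list()
  note <- function(scope, id, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      scope = scope, id = id, message = message, stringsAsFactors = FALSE)
  }
  g <- panel$genes
  a <- panel$assays
  if (is.null(g) || nrow(g) == 0L) {
    note("panel", "genes", "panel defines no genes")
  } else {
    for (i in seq_len(nrow(g))) {
      sym <- g$symbol[i]
      if (is.na(g$exon_count[i]) || g$exon_count[i] < 1L)
        note("gene", sym, paste0("gene ", sym, ": exon_count must be >= 1"))
      if (!g$inheritance[i] %in% INHERITANCE_MODES)
        note("gene", sym, paste0("gene ", sym, ": inheritance '",
                                 g$inheritance[i], "' not one of AR/AD/XL"))
      if (!g$category[i] %in% PANEL_CATEGORIES)
        note("gene", sym, paste0("gene ", sym, ": category '", g$category[i],
                                 "' not in the 18-label category set"))
      ids <- assay_id_vector(g$assay_ids[i])
      missing <- setdiff(ids, a$assay_id)
      if (length(missing))
        note("gene", sym, paste0("gene ", sym, ": unknown assay id(s) ",
                                 paste(missing, collapse = ", ")))
    }
    dup <- duplicated(paste(g$symbol, g$disease_id))
    if (any(dup))
      note("panel", "genes", paste0("duplicated (gene, disease) entries: ",
        paste(unique(g$symbol[dup]), collapse = ", ")))
  }
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      id <- a$assay_id[i]
      if (!a$kind[i] %in% ASSAY_KINDS)
        note("assay", id, paste0("assay ", id, ": kind '", a$kind[i],
                                 "' not enzyme_activity/biomarker"))
      if (!a$pathologic_direction[i] %in% ASSAY_DIRECTIONS)
        note("assay", id, paste0("assay ", id, ": bad pathologic_direction"))
      if (is.na(a$reference_low[i]) || is.na(a$reference_high[i]) ||
          !(a$reference_low[i] < a$reference_high[i]))
        note("assay", id, paste0("assay ", id,
                                 ": reference_low must be < reference_high"))
      if (identical(a$kind[i], "enzyme_activity") &&
          !identical(a$pathologic_direction[i], "below_range"))
        note("assay", id, paste0("assay ", id,
          ": enzyme_activity assays must be below_range"))
    }
    if (anyDuplicated(a$assay_id))
      note("panel", "assays", "duplicated assay ids")
  }
  th <- panel$thresholds
  for (f in c("maf_snv", "maf_cnv", "splice_score_min",
              "qc_min_coverage_fraction")) {
    v <- th[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      note("thresholds", f, paste0("threshold ", f, " must be in (0, 1]"))
  }
  for (f in c("het_cnv_min_exons", "qc_min_depth", "healthy_cohort_size")) {
    v <- th[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1)
      note("thresholds", f, paste0("threshold ", f, " must be >= 1"))
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(scope = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Look up all disease entries for a gene symbol
#'
#' A gene may carry several disease entries (e.g. distinct AR and AD
#' phenotypes); each entry is matched independently downstream.
#'
#' @param panel A `metpanel_panel`.
#' @param symbol Gene symbol.
#' @return data.frame of gene entries (possibly zero rows).
#' @export
lookup_gene <- function(panel, symbol) {
  panel$genes[panel$genes$symbol == symbol, , drop = FALSE]
}

#' Assays linked to a gene entry
#'
#' @param panel A `metpanel_panel`.
#' @param symbol Gene symbol.
#' @return data.frame of assay records linked to any disease entry of the
#'   gene (zero rows when none).
#' @export
gene_assays <- function(panel, symbol) {
  rows <- lookup_gene(panel, symbol)
  ids <- unique(unlist(lapply(rows$assay_ids, assay_id_vector)))
  panel$assays[panel$assays$assay_id %in% ids, , drop = FALSE]
}

assay_id_vector <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Serialize a panel configuration to YAML
#'
#' Writes the compact flow-style dialect read by [load_panel()]; loading,
#' writing and reloading yields an identical panel.
#'
#' @param panel A `metpanel_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  q <- function(x) {
    x <- ifelse(is.na(x), "~", paste0('"', gsub('"', '\\\\"', x), '"'))
    x
  }
  yn <- function(x) ifelse(x, "true", "false")
  lines <- character()
  if (length(panel$meta)) {
    lines <- c(lines, "panel:")
    for (k in names(panel$meta)) {
      lines <- c(lines, paste0("  ", k, ": ", q(as.character(panel$meta[[k]]))))
    }
  }
  th <- panel$thresholds
  lines <- c(lines, "thresholds:",
             vapply(names(th), function(k)
               paste0("  ", k, ": ", format(th[[k]], scientific = FALSE)),
               character(1)))
  a <- panel$assays
  lines <- c(lines, "assays:")
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, sprintf(
      "  - {assay_id: %s, kind: %s, analyte: %s, pathologic_direction: %s, reference_low: %s, reference_high: %s, units: %s}",
      a$assay_id[i], a$kind[i], q(a$analyte[i]), a$pathologic_direction[i],
      format(a$reference_low[i]), format(a$reference_high[i]), q(a$units[i])))
  }
  g <- panel$genes
  lines <- c(lines, "genes:")
  for (i in seq_len(nrow(g))) {
    ids <- assay_id_vector(g$assay_ids[i])
    extra <- ""
    if (g$female_het_reportable[i]) extra <- paste0(extra, ", female_het_reportable: true")
    if (!g$lof_mechanism[i]) extra <- paste0(extra, ", lof_mechanism: false")
    if (g$placeholder[i]) extra <- paste0(extra, ", placeholder: true")
    lines <- c(lines, sprintf(
      "  - {symbol: %s, transcript: %s, exon_count: %d, inheritance: %s, disease_id: %s, disease_name: %s, category: %s, treatable: %s, assays: [%s]%s}",
      g$symbol[i], g$transcript[i], g$exon_count[i], g$inheritance[i],
      g$disease_id[i], q(g$disease_name[i]), g$category[i],
      yn(g$treatable[i]), paste(ids, collapse = ", "), extra))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.metpanel_panel <- function(x, ...) {
  cat("<metpanel panel>", "\n")
  cat("  genes:  ", length(unique(x$genes$symbol)), " symbols (",
      nrow(x$genes), " disease entries, ",
      sum(x$genes$placeholder), " placeholders)\n", sep = "")
  cat("  assays: ", nrow(x$assays), " (",
      sum(x$assays$kind == "enzyme_activity"), " enzyme activities, ",
      sum(x$assays$kind == "biomarker"), " biomarkers)\n", sep = "")
  cat("  thresholds: SNV MAF <", x$thresholds$maf_snv,
      "| CNV MAF <", x$thresholds$maf_cnv,
      "| splice >", x$thresholds$splice_score_min, "\n")
  invisible(x)
}
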