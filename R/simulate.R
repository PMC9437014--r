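# Seeded synthetic-cohort generator with ground truth. The defaults emulate
# the cohort structure of a global IMD gene-panel referral population:
# region mix, missingness of consanguinity/family history, diagnosable-case
# prevalence, SNV/CNV lesion mix and the disease spectrum dominated by
# lysosomal storage disorders.

#' Cohort simulation parameters
#'
#' Defaults describe the emulated referral cohort: region weights
#' (Africa 33%, Asia 30%, Europe 24%, Latin America 6%, Middle East 6%,
#' North America 1%), 50% missing consanguinity with 61% consanguineous
#' among known (30.4% of all cases), 76.7% missing family history,
#' diagnosable prevalence 37%, 94% of causal lesions SNVs, 85% of CNV
#' lesions deletions, and perfect reflex assays. `vus_rate` is the
#' fraction of non-diagnosable cases carrying an uncertain (VUS-level)
#' finding that yields an unclear report; `excluded_candidate_rate` the
#' fraction whose candidate is excluded by a normal enzyme result.
#'
#' @param n_patients Number of cases.
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @param region_weights,disease_weights Named sampling weights (sum 1).
#' @param consanguinity_rate Consanguinity rate among cases with known
#'   status.
#' @param consanguinity_unknown,family_history_unknown Missingness rates.
#' @param family_history_positive Positive rate among known family
#'   histories.
#' @param true_positive_rate Prevalence of genetically diagnosable cases.
#' @param snv_fraction_among_unique P(causal lesion is an SNV).
#' @param cnv_deletion_fraction P(CNV lesion is a deletion).
#' @param assay_sensitivity P(pathologic result | true enzyme deficiency).
#' @param assay_specificity P(normal result | no deficiency).
#' @param vus_rate,excluded_candidate_rate See above.
#' @param prior_known_rate P(causal variant already curated P/LP).
#' @param benign_background_rate P(case carries incidental common variants
#'   that triage must discard).
#' @param onset_known_rate P(age at onset documented).
#' @return A validated `metpanel_cohort_params` list.
#' @export
cohort_params <- function(n_patients = 100L, seed = 1L,
                          region_weights = c(Africa = 0.33, Asia = 0.30,
                                             Europe = 0.24,
                                             LatinAmerica = 0.06,
                                             MiddleEast = 0.06,
                                             NorthAmerica = 0.01),
                          disease_weights = NULL,
                          consanguinity_rate = 0.61,
                          consanguinity_unknown = 0.50,
                          family_history_unknown = 0.767,
                          family_history_positive = 0.844,
                          true_positive_rate = 0.37,
                          snv_fraction_among_unique = 0.94,
                          cnv_deletion_fraction = 0.85,
                          assay_sensitivity = 1.0,
                          assay_specificity = 1.0,
                          vus_rate = 0.24,
                          excluded_candidate_rate = 0.008,
                          prior_known_rate = 0.6,
                          benign_background_rate = 0.3,
                          onset_known_rate = 0.102) {
  p <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
            region_weights = region_weights,
            disease_weights = disease_weights,
            consanguinity_rate = consanguinity_rate,
            consanguinity_unknown = consanguinity_unknown,
            family_history_unknown = family_history_unknown,
            family_history_positive = family_history_positive,
            true_positive_rate = true_positive_rate,
            snv_fraction_among_unique = snv_fraction_among_unique,
            cnv_deletion_fraction = cnv_deletion_fraction,
            assay_sensitivity = assay_sensitivity,
            assay_specificity = assay_specificity,
            vus_rate = vus_rate,
            excluded_candidate_rate = excluded_candidate_rate,
            prior_known_rate = prior_known_rate,
            benign_background_rate = benign_background_rate,
            onset_known_rate = onset_known_rate)
  validate_cohort_params(p)
  structure(p, class = "metpanel_cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n_patients < 1L) stop("n_patients must be >= 1")
  if (abs(sum(p$region_weights) - 1) > 1e-9)
    stop("region_weights must sum to 1")
  if (!is.null(p$disease_weights) && abs(sum(p$disease_weights) - 1) > 1e-9)
    stop("disease_weights must sum to 1")
  fracs <- c("consanguinity_rate", "consanguinity_unknown",
             "family_history_unknown", "family_history_positive",
             "true_positive_rate", "snv_fraction_among_unique",
             "cnv_deletion_fraction", "assay_sensitivity",
             "assay_specificity", "vus_rate", "excluded_candidate_rate",
             "prior_known_rate", "benign_background_rate",
             "onset_known_rate")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(f, " must be a fraction in [0, 1]")
  }
  invisible(p)
}

#' Default disease sampling weights
#'
#' Spectrum of diagnosed diseases peaking at Gaucher disease, Niemann-Pick
#' A/B, mucopolysaccharidosis I, phenylketonuria and Wilson disease, with
#' a long tail over the rest of the panel. Restricted to non-placeholder
#' panel entries; normalized to sum 1.
#'
#' @param panel A `metpanel_panel`.
#' @return Named numeric vector over disease ids.
#' @export
default_disease_weights <- function(panel = load_panel()) {
  w <- c(GAUCHER = 9.0, NPD_AB = 6.5, MPS1 = 5.8, PKU = 5.5, WILSON = 5.0,
         MPS4A = 3.6, MPS2 = 3.0, NPC1_D = 2.8, POMPE = 2.5, GM1 = 2.2,
         FABRY = 2.0, CAH_21OH = 2.0, MCADD = 2.0, FH1 = 1.8, MLD = 1.8,
         MPS3A = 1.5, GALACTOSEMIA1 = 1.5, HOMOCYSTINURIA = 1.5,
         KRABBE = 1.5, GA1 = 1.5, MMA_MUT = 1.5, CLN2 = 1.4, TYR1 = 1.4,
         CYSTINURIA_A = 1.4, MPS6 = 1.2, BIOTINIDASE_DEF = 1.2,
         GSD3 = 1.2, XALD = 1.2, PA_PCCA = 1.2, OTC_DEF = 1.2,
         TAY_SACHS = 1.5, CITRULLINEMIA1 = 1.2, MPS3B = 1.0, LPI = 1.0,
         MSUD2 = 1.0, LALD = 1.0, HFI = 1.0, IVA = 1.0, CYSTINOSIS = 1.0,
         ASA_LYASE_DEF = 1.0, PMM2_CDG = 1.0, ZSD_PEX12 = 1.0,
         MPS3C = 0.8, MENKES = 0.8, CRIGLER_NAJJAR1 = 0.8,
         NKH_GLDC = 0.8, AIP = 0.6, CTX = 0.6, ZSD_PEX1 = 0.6, MPS7 = 0.6,
         CANAVAN = 0.6, HYPOPHOSPHATASIA = 0.6, ALKAPTONURIA = 0.5,
         DUBIN_JOHNSON = 0.5, FUCOSIDOSIS = 0.4, PCD = 0.8, VLCADD = 0.8,
         GALACTOSIALIDOSIS = 0.4, SANDHOFF = 0.6, ARGININEMIA = 0.5,
         CBLC = 0.8, PDE = 0.6, GAMT_DEF = 0.4, AADC_DEF = 0.4,
         GSD1A = 0.8, GSD1B = 0.5, REFSUM = 0.3, SIALIDOSIS = 0.3,
         MKD = 0.4, EPP = 0.3, WILSON_LIKE = 0)
  w <- w[w > 0]
  keep <- names(w) %in% panel$genes$disease_id[!panel$genes$placeholder]
  w <- w[keep]
  w / sum(w)
}

rcap_lnorm <- function(n, meanlog, sdlog, cap) {
  pmin(rlnorm(n, meanlog, sdlog), cap)
}

#' Generate a synthetic cohort with ground truth
#'
#' Fully reproducible under a fixed seed: diagnosable cases receive
#' inheritance-consistent genotypes built from annotated SNV and/or CNV
#' lesions that pass triage, plus biochemical values drawn pathologic with
#' probability `assay_sensitivity` for the affected gene's assays;
#' non-diagnosable cases carry VUS-level, biochemistry-excludable, benign
#' or no variants. All continuous annotations are rounded so that emitted
#' fixture files round-trip exactly.
#'
#' @param params A `metpanel_cohort_params`.
#' @param panel A `metpanel_panel`.
#' @return List with `cases` (list of `metpanel_case`), `truth`
#'   (data.frame) and `params`.
#' @export
generate_cohort <- function(params = cohort_params(), panel = load_panel()) {
  validate_cohort_params(params)
  set.seed(params$seed)
  dw <- params$disease_weights %||% default_disease_weights(panel)
  if (!all(names(dw) %in% panel$genes$disease_id))
    stop("disease_weights refer to unknown disease ids")
  genes_real <- panel$genes[!panel$genes$placeholder, , drop = FALSE]
  ar_genes <- genes_real[genes_real$inheritance == "AR", , drop = FALSE]
  has_assay <- nzchar(genes_real$assay_ids)
  assay_kind_of <- function(ids)
    panel$assays$kind[match(ids, panel$assays$assay_id)]
  enzyme_ar <- ar_genes[vapply(ar_genes$assay_ids, function(x) {
    ids <- assay_id_vector(x)
    length(ids) > 0 && any(assay_kind_of(ids) == "enzyme_activity")
  }, logical(1)), , drop = FALSE]
  biomarker_only_ar <- ar_genes[vapply(ar_genes$assay_ids, function(x) {
    ids <- assay_id_vector(x)
    length(ids) > 0 && all(assay_kind_of(ids) == "biomarker")
  }, logical(1)), , drop = FALSE]

  cases <- vector("list", params$n_patients)
  truth <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    g <- simulate_one_case(i, params, panel, dw, ar_genes, enzyme_ar,
                           biomarker_only_ar)
    cases[[i]] <- g$case
    truth[[i]] <- g$truth
  }
  list(cases = cases, truth = do.call(rbind, truth), params = params)
}

simulate_one_case <- function(i, p, panel, dw, ar_genes, enzyme_ar,
                              biomarker_only_ar) {
  case_id <- sprintf("case-%05d", i)
  region <- sample(names(p$region_weights), 1L, prob = p$region_weights)
  sex <- sample(c("male", "female"), 1L)
  consanguinity <- if (runif(1) < p$consanguinity_unknown) "unknown"
    else if (runif(1) < p$consanguinity_rate) "yes" else "no"
  family_history <- if (runif(1) < p$family_history_unknown) "unknown"
    else if (runif(1) < p$family_history_positive) "positive" else "negative"
  onset <- round(rcap_lnorm(1, log(0.7), 0.9, 34), 2)
  gap <- round(rcap_lnorm(1, log(1.2), 1.0, 20), 2)
  testing <- round(min(onset + gap, 38), 2)
  onset_known <- runif(1) < p$onset_known_rate
  qc <- list(coverage_fraction_at_min_depth = round(runif(1, 0.995, 1), 4),
             min_depth = sample(20:40, 1L))

  snvs <- list(); cnvs <- list(); biochem <- list()
  diagnosable <- runif(1) < p$true_positive_rate
  subtype <- "none"; disease <- NA_character_; pattern <- NA_character_
  classes <- ""

  if (diagnosable) {
    disease <- sample(names(dw), 1L, prob = dw)
    entry <- panel$genes[panel$genes$disease_id == disease, , drop = FALSE][1L, ]
    if (entry$inheritance == "XL") sex <- "male"
    pattern <- switch(entry$inheritance,
                      AR = if (runif(1) < 0.55) "hom" else "comp_het_phase_unknown",
                      AD = "het_single", XL = "hemi")
    lesions <- switch(pattern, hom = 1L, comp_het_phase_unknown = 2L, 1L)
    zygs <- switch(pattern, hom = "hom", comp_het_phase_unknown = c("het", "het"),
                   het_single = "het", hemi = "hemi")
    gene_assay_ids <- assay_id_vector(entry$assay_ids)
    cls <- character(lesions)
    for (l in seq_len(lesions)) {
      if (runif(1) < p$snv_fraction_among_unique) {
        curated <- runif(1) < p$prior_known_rate
        novel_missense <- length(gene_assay_ids) > 0 && runif(1) < 0.7
        snvs[[length(snvs) + 1L]] <- simulate_snv(
          entry, zygs[l],
          prior = if (curated) sample(c("P", "LP"), 1L) else "unclassified",
          impact = if (curated || novel_missense) sample(c("high", "moderate"), 1L,
                                                         prob = c(0.4, 0.6))
                   else "high")
        cls[l] <- if (curated) "P/LP" else "novel"
      } else {
        deletion <- runif(1) < p$cnv_deletion_fraction
        # male X: a single-copy gene, so the causal CNV is a 0-copy deletion
        cn <- if (zygs[l] == "hom" || entry$inheritance == "XL") 0L
              else if (deletion) 1L else 3L
        cnvs[[length(cnvs) + 1L]] <- simulate_cnv(entry, cn)
        cls[l] <- "cnv"
      }
    }
    classes <- paste(cls, collapse = ",")
    for (id in gene_assay_ids) {
      assay <- panel$assays[panel$assays$assay_id == id, , drop = FALSE]
      pathologic <- runif(1) < p$assay_sensitivity
      biochem[[length(biochem) + 1L]] <- simulate_measurement(assay, pathologic)
    }
    subtype <- "diagnosable"
  } else {
    r <- runif(1)
    if (r < p$vus_rate) {
      u <- runif(1)
      if (u < 0.70) {
        subtype <- "vus_single_het"
        entry <- ar_genes[sample(nrow(ar_genes), 1L), , drop = FALSE]
        snvs[[length(snvs) + 1L]] <- simulate_snv(entry, "het",
                                                  prior = "VUS",
                                                  impact = "moderate")
      } else if (u < 0.85) {
        subtype <- "vus_biomarker_normal"
        entry <- biomarker_only_ar[sample(nrow(biomarker_only_ar), 1L), ,
                                   drop = FALSE]
        for (z in c("het", "het"))
          snvs[[length(snvs) + 1L]] <- simulate_snv(entry, z,
                                                    prior = "unclassified",
                                                    impact = "moderate")
        for (id in assay_id_vector(entry$assay_ids)) {
          assay <- panel$assays[panel$assays$assay_id == id, , drop = FALSE]
          pathologic <- runif(1) >= p$assay_specificity
          biochem[[length(biochem) + 1L]] <- simulate_measurement(assay, pathologic)
        }
      } else {
        subtype <- "vus_conflicting_pathologic"
        entry <- enzyme_ar[sample(nrow(enzyme_ar), 1L), , drop = FALSE]
        s <- simulate_snv(entry, "hom", prior = "VUS", impact = "moderate")
        s$conflicting_evidence <- TRUE
        snvs[[length(snvs) + 1L]] <- s
        for (id in assay_id_vector(entry$assay_ids)) {
          assay <- panel$assays[panel$assays$assay_id == id, , drop = FALSE]
          biochem[[length(biochem) + 1L]] <- simulate_measurement(assay, TRUE)
        }
      }
    } else if (r < p$vus_rate + p$excluded_candidate_rate) {
      subtype <- "excluded_by_normal_enzyme"
      entry <- enzyme_ar[sample(nrow(enzyme_ar), 1L), , drop = FALSE]
      s <- simulate_snv(entry, "hom", prior = "unclassified", impact = "low")
      s$ada_score <- round(runif(1, 0.65, 0.95), 3)
      s$rf_score <- round(runif(1, 0.65, 0.95), 3)
      snvs[[length(snvs) + 1L]] <- s
      for (id in assay_id_vector(entry$assay_ids)) {
        assay <- panel$assays[panel$assays$assay_id == id, , drop = FALSE]
        pathologic <- runif(1) >= p$assay_specificity
        biochem[[length(biochem) + 1L]] <- simulate_measurement(assay, pathologic)
      }
    } else {
      subtype <- "no_relevant_variant"
    }
  }

  if (runif(1) < p$benign_background_rate) {
    entry <- ar_genes[sample(nrow(ar_genes), 1L), , drop = FALSE]
    b <- simulate_snv(entry, "het", prior = "absent", impact = "low")
    b$maf_external <- round(runif(1, 0.02, 0.3), 4)
    snvs[[length(snvs) + 1L]] <- b
  }

  case <- patient_case(
    case_id = case_id,
    snvs = if (length(snvs)) do.call(rbind, snvs) else NULL,
    cnvs = if (length(cnvs)) do.call(rbind, cnvs) else NULL,
    biochem = if (length(biochem)) do.call(rbind, biochem) else NULL,
    sex = sex, region = region, consanguinity = consanguinity,
    family_history = family_history,
    age_onset_years = if (onset_known) onset else NA_real_,
    age_testing_years = testing, qc = qc)
  truth <- data.frame(
    case_id = case_id,
    true_status = if (diagnosable) "diagnosable" else "not_diagnosable",
    true_disease = disease, true_genotype_pattern = pattern,
    true_variant_classes = classes, subtype = subtype,
    stringsAsFactors = FALSE)
  list(case = case, truth = truth)
}

simulate_snv <- function(entry, zygosity, prior, impact) {
  chrom <- if (entry$inheritance == "XL") "X" else
    as.character(sample(1:22, 1L))
  pos <- sample(10000:9999999, 1L)
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  rare_or_na <- function(hi) if (runif(1) < 0.5) NA_real_ else
    round(runif(1, 0, hi), 5)
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = entry$symbol,
    zygosity = zygosity, impact = impact,
    maf_external = rare_or_na(0.005), maf_internal = rare_or_na(0.004),
    prior_internal_class = prior,
    external_assertion = if (prior %in% c("P", "LP") && runif(1) < 0.5)
      "disease_causing" else "none",
    ada_score = NA_real_, rf_score = NA_real_,
    quality_ok = runif(1) < 0.97,
    hgvs = paste0(entry$transcript, ":c.", sample(1:5000, 1L), ref, ">", alt),
    conflicting_evidence = FALSE,
    stringsAsFactors = FALSE)
}

simulate_cnv <- function(entry, copy_number) {
  max_span <- min(entry$exon_count, 6L)
  span <- if (copy_number == 0L) sample(1:max_span, 1L) else
    sample(3:max(3L, max_span), 1L)
  start <- sample(seq_len(max(1L, entry$exon_count - span + 1L)), 1L)
  data.frame(
    sample = NA_character_, genes = entry$symbol, copy_number = copy_number,
    exon_start = start, exon_end = min(start + span - 1L, entry$exon_count),
    maf = NA_real_, confirmed_by = "none", multi_gene = FALSE,
    stringsAsFactors = FALSE)
}

simulate_measurement <- function(assay, pathologic) {
  lo <- assay$reference_low; hi <- assay$reference_high
  value <- if (assay$pathologic_direction == "below_range") {
    if (pathologic) runif(1, 0.02, 0.85) * lo else runif(1, lo * 1.2, hi * 0.95)
  } else {
    if (pathologic) runif(1, hi * 1.3, hi * 3) else
      runif(1, lo + 0.15 * (hi - lo), lo + 0.85 * (hi - lo))
  }
  data.frame(assay_id = assay$assay_id, value = round(value, 3),
             units = assay$units, stringsAsFactors = FALSE)
}

#' Emit per-case fixture files
#'
#' Writes, for every case, a VCF of annotated SNVs, a CNV TSV, a
#' biochemistry TSV and a metadata TSV — all plain text and re-readable by
#' [read_case()] into equal records.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
emit_fixture_files <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (case in cohort$cases) {
    id <- case$case_id
    base <- file.path(out_dir, id)
    write_snvs_vcf(case$snvs %||% empty_snvs(), paste0(base, ".vcf"),
                   sample_id = id)
    cnvs <- case$cnvs
    if (is.null(cnvs)) {
      cnvs <- data.frame(sample = character(), genes = character(),
                         copy_number = integer(), exon_start = integer(),
                         exon_end = integer(), maf = numeric(),
                         confirmed_by = character(), stringsAsFactors = FALSE)
    }
    cnvs$sample <- rep(id, nrow(cnvs))
    write_cnvs_tsv(cnvs, paste0(base, ".cnv.tsv"))
    biochem <- case$biochem %||%
      data.frame(assay_id = character(), value = numeric(),
                 units = character(), stringsAsFactors = FALSE)
    utils::write.table(biochem, paste0(base, ".biochem.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- data.frame(
      key = c("case_id", "sex", "region", "consanguinity", "family_history",
              "age_onset_years", "age_testing_years", "qc_coverage",
              "qc_min_depth"),
      value = c(id, case$sex, case$region, case$consanguinity,
                case$family_history, as.character(case$age_onset_years),
                as.character(case$age_testing_years),
                as.character(case$qc$coverage_fraction_at_min_depth),
                as.character(case$qc$min_depth)),
      stringsAsFactors = FALSE)
    utils::write.table(meta, paste0(base, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, paste0(base, c(".vcf", ".cnv.tsv", ".biochem.tsv",
                                     ".meta.tsv")))
  }
  invisible(paths)
}

#' Read one emitted case back from fixture files
#'
#' @param dir Directory written by [emit_fixture_files()].
#' @param case_id Case identifier.
#' @return A `metpanel_case`.
#' @export
read_case <- function(dir, case_id) {
  base <- file.path(dir, case_id)
  meta <- utils::read.delim(paste0(base, ".meta.tsv"),
                            colClasses = "character")
  m <- setNames(meta$value, meta$key)
  sex <- m[["sex"]]
  snvs <- read_snvs(paste0(base, ".vcf"), sex = sex)
  cnvs <- read_cnvs(paste0(base, ".cnv.tsv"))
  biochem <- utils::read.delim(paste0(base, ".biochem.tsv"),
                               stringsAsFactors = FALSE)
  patient_case(
    case_id = m[["case_id"]],
    snvs = if (nrow(snvs)) snvs else NULL,
    cnvs = if (nrow(cnvs)) cnvs else NULL,
    biochem = if (nrow(biochem)) biochem else NULL,
    sex = sex, region = m[["region"]], consanguinity = m[["consanguinity"]],
    family_history = m[["family_history"]],
    age_onset_years = as.numeric(m[["age_onset_years"]]),
    age_testing_years = as.numeric(m[["age_testing_years"]]),
    qc = list(coverage_fraction_at_min_depth = as.numeric(m[["qc_coverage"]]),
              min_depth = as.integer(m[["qc_min_depth"]])))
}
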