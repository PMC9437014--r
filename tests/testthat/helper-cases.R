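# Shared fixtures: the packaged panel and hand-encoded worked cases
# (compound-het SNV+CNV diagnoses, biomarker-vs-enzyme normal results,
# phase inference), built in code so tests carry no binary data.

test_panel <- function() {
  if (is.null(.test_env$panel)) .test_env$panel <- load_panel()
  .test_env$panel
}
.test_env <- new.env()

snv_row <- function(gene, zygosity, chrom = "1", pos = 1000L, ref = "A",
                    alt = "G", impact = "moderate", maf_external = NA_real_,
                    maf_internal = NA_real_, prior = "unclassified",
                    assertion = "none", ada = NA_real_, rf = NA_real_,
                    quality_ok = TRUE, hgvs = NA_character_,
                    conflicting = FALSE) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, zygosity = zygosity, impact = impact,
             maf_external = maf_external, maf_internal = maf_internal,
             prior_internal_class = prior, external_assertion = assertion,
             ada_score = ada, rf_score = rf, quality_ok = quality_ok,
             hgvs = hgvs, conflicting_evidence = conflicting,
             stringsAsFactors = FALSE)
}

cnv_row <- function(genes, copy_number, exon_start, exon_end,
                    maf = NA_real_, confirmed_by = "none") {
  data.frame(sample = NA_character_, genes = genes,
             copy_number = as.integer(copy_number),
             exon_start = as.integer(exon_start),
             exon_end = as.integer(exon_end), maf = maf,
             confirmed_by = confirmed_by,
             multi_gene = grepl(",", genes, fixed = TRUE),
             stringsAsFactors = FALSE)
}

biochem_row <- function(assay_id, value, units = NULL) {
  p <- test_panel()
  u <- units %||% p$assays$units[p$assays$assay_id == assay_id]
  data.frame(assay_id = assay_id, value = value, units = u,
             stringsAsFactors = FALSE)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Maple syrup urine disease type II: het frameshift + het confirmed
# deletion of exons 2-3 of DBT; no biochemical assay linked.
case_dbt <- function() {
  patient_case(
    case_id = "fx-dbt", sex = "male", age_testing_years = 0.25,
    snvs = snv_row("DBT", "het", chrom = "1", pos = 100500, ref = "C",
                   alt = "CA", impact = "high",
                   hgvs = "NM_001918.5:c.123dup"),
    cnvs = cnv_row("DBT", 1, 2, 3, confirmed_by = "MLPA"))
}

# Gaucher disease: het pathogenic missense + het deletion of exons 8-10 of
# GBA; deficient enzyme and raised lyso-Gb1.
case_gba <- function() {
  patient_case(
    case_id = "fx-gba", sex = "male", age_testing_years = 2,
    snvs = snv_row("GBA", "het", chrom = "1", pos = 155235000, ref = "T",
                   alt = "C", prior = "P",
                   hgvs = "NM_000157.4:c.1448T>C"),
    cnvs = cnv_row("GBA", 1, 8, 10),
    biochem = rbind(biochem_row("GBA_ENZ", 0.3),
                    biochem_row("LYSO_GB1", 150)))
}

# GM1 gangliosidosis: het deletion of exons 1-17 of GLB1 plus a frameshift
# on the remaining allele (hemizygous-appearing, encoded het); deficient
# beta-galactosidase.
case_glb1 <- function() {
  patient_case(
    case_id = "fx-glb1", sex = "male", age_testing_years = 1,
    snvs = snv_row("GLB1", "het", chrom = "3", pos = 33100000, ref = "G",
                   alt = "GA", impact = "high"),
    cnvs = cnv_row("GLB1", 1, 1, 17),
    biochem = biochem_row("BGAL_ENZ", 0.4))
}

# Two heterozygous PSAP missense VUS with a normal lyso-Gb1 biomarker:
# reported unclear with parental-testing / biomarker follow-up.
case_psap <- function() {
  patient_case(
    case_id = "fx-psap", sex = "female", age_testing_years = 1,
    snvs = rbind(
      snv_row("PSAP", "het", chrom = "10", pos = 71816000, ref = "C",
              alt = "T", prior = "VUS"),
      snv_row("PSAP", "het", chrom = "10", pos = 71820000, ref = "G",
              alt = "A", prior = "VUS")),
    biochem = biochem_row("LYSO_GB1", 3.0))
}

# Homozygous deep-intronic GALNS candidate retained on splice scores;
# normal enzyme activity excludes it from reporting.
case_galns <- function() {
  patient_case(
    case_id = "fx-galns", sex = "female",
    snvs = snv_row("GALNS", "hom", chrom = "16", pos = 88880000, ref = "G",
                   alt = "C", impact = "modifier", ada = 0.82, rf = 0.71,
                   hgvs = "NM_001323544.1:c.1020+307G>C"),
    biochem = biochem_row("GALNS_ENZ", 5.0))
}

# Two heterozygous TPP1 missense variants with a normal enzyme: phase
# inferred cis, variants excluded.
case_tpp1 <- function() {
  patient_case(
    case_id = "fx-tpp1", sex = "male",
    snvs = rbind(
      snv_row("TPP1", "het", chrom = "11", pos = 6617000, ref = "G",
              alt = "A", prior = "VUS", hgvs = "NM_000391.3:c.340G>A"),
      snv_row("TPP1", "het", chrom = "11", pos = 6615000, ref = "A",
              alt = "C", prior = "VUS", hgvs = "NM_000391.3:c.1033A>C")),
    biochem = biochem_row("TPP1_ENZ", 8.0))
}
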