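triaged <- function(case) triage_case(case, test_panel())$variants

test_that("base classification honors curation and LoF mechanism", {
  panel <- test_panel()
  th <- panel$thresholds
  dbt <- lookup_gene(panel, "DBT")
  v <- triaged(case_dbt())
  st <- base_classify(v[v$type == "snv", ], dbt, th)
  expect_equal(st$base_class, "LP")   # novel frameshift in LoF-mechanism gene
  st <- base_classify(v[v$type == "cnv_del", ], dbt, th)
  expect_equal(st$base_class, "P")    # exon-level deletion

  gba <- lookup_gene(panel, "GBA")
  v <- triaged(case_gba())
  st <- base_classify(v[v$type == "snv", ], gba, th)
  expect_equal(st$base_class, "P")    # prior curated class honored

  psap <- lookup_gene(panel, "PSAP")
  st <- base_classify(triaged(case_psap()), psap, th)
  expect_equal(st$base_class, c("VUS", "VUS"))  # novel missense
})

test_that("pathologic results upgrade VUS unless evidence conflicts", {
  panel <- test_panel()
  st <- base_classify(triaged(case_psap()), lookup_gene(panel, "PSAP"),
                      panel$thresholds)
  path_call <- data.frame(assay_id = "LYSO_GB1", value = 150,
                          call = "pathologic", stringsAsFactors = FALSE)
  up <- apply_biochem(st, path_call, panel$assays)
  expect_equal(up$states$final_class, c("LP", "LP"))
  expect_match(up$states$evidence[1], "functional_pathologic")

  st$conflicting_evidence <- TRUE
  kept <- apply_biochem(st, path_call, panel$assays)
  expect_equal(kept$states$final_class, c("VUS", "VUS"))
  expect_match(kept$states$evidence[1], "conflicting_evidence")
})

test_that("a normal enzyme excludes candidates but flags curated findings", {
  panel <- test_panel()
  galns <- lookup_gene(panel, "GALNS")
  v <- triaged(case_galns())
  st <- base_classify(v, galns, panel$thresholds)
  norm_enz <- data.frame(assay_id = "GALNS_ENZ", value = 5, call = "normal",
                         stringsAsFactors = FALSE)
  res <- apply_biochem(st, norm_enz, panel$assays)
  expect_false(res$states$reportable)

  st$curated <- TRUE
  res <- apply_biochem(st, norm_enz, panel$assays)
  expect_true(res$states$reportable)
  expect_match(res$states$evidence, "biochem_discordant")

  # a normal downstream biomarker is weaker: VUS stays, follow-up advised
  psap <- base_classify(triaged(case_psap()), lookup_gene(panel, "PSAP"),
                        panel$thresholds)
  norm_bio <- data.frame(assay_id = "LYSO_GB1", value = 3, call = "normal",
                         stringsAsFactors = FALSE)
  res <- apply_biochem(psap, norm_bio, panel$assays)
  expect_true(all(res$states$reportable))
  expect_setequal(res$recommendations,
                  c("parental_testing", "biomarker_followup"))

  borderline <- data.frame(assay_id = "GALNS_ENZ", value = 1.05,
                           call = "borderline", stringsAsFactors = FALSE)
  res <- apply_biochem(st, borderline, panel$assays)
  expect_equal(res$recommendations, "biomarker_followup")
  expect_equal(res$states$final_class, st$final_class)
})

test_that("classification moves are bounded to one step of the scale", {
  panel <- test_panel()
  five <- c("P", "LP", "VUS", "LB", "B")
  for (cls in five) {
    for (call in c("pathologic", "normal", "borderline")) {
      st <- data.frame(variant_key = "k", gene = "GALNS",
                       disease_id = "MPS4A", type = "snv", zygosity = "hom",
                       base_class = cls, final_class = cls, evidence = "",
                       reportable = TRUE, curated = FALSE,
                       conflicting_evidence = FALSE, stringsAsFactors = FALSE)
      calls <- data.frame(assay_id = "GALNS_ENZ", value = 1,
                          call = call, stringsAsFactors = FALSE)
      out <- apply_biochem(st, calls, panel$assays)$states
      expect_lte(abs(match(out$final_class, five) - match(cls, five)), 1L)
    }
  }
})

test_that("phase inference uses the enzyme, not the biomarker", {
  panel <- test_panel()
  enz_norm <- data.frame(assay_id = "TPP1_ENZ", value = 8, call = "normal",
                         stringsAsFactors = FALSE)
  bio_norm <- data.frame(assay_id = "LYSO_GB1", value = 3, call = "normal",
                         stringsAsFactors = FALSE)
  path <- data.frame(assay_id = "GBA_ENZ", value = 0.3, call = "pathologic",
                     stringsAsFactors = FALSE)
  expect_equal(infer_phase("comp_het_phase_unknown", enz_norm, panel$assays),
               "cis")
  expect_equal(infer_phase("comp_het_phase_unknown", bio_norm, panel$assays),
               "unknown")
  expect_equal(infer_phase("comp_het_phase_unknown", path, panel$assays),
               "trans_supported")
  expect_equal(infer_phase("comp_het_phase_unknown", NULL, panel$assays),
               "unknown")
  expect_equal(infer_phase("hom", path, panel$assays), "unknown")
})

test_that("the report decision table is total and single-valued", {
  for (cls in c("P", "LP", "VUS", "LB", "B")) {
    for (call in c("pathologic", "normal", "borderline", "absent")) {
      for (eligible in c(TRUE, FALSE)) {
        for (reportable in c(TRUE, FALSE)) {
          out <- decision_outcome(cls, call, eligible, reportable)
          expect_length(out, 1L)
          expect_true(out %in% c("positive", "unclear", "carrier", "none"))
          if (!reportable) expect_equal(out, "none")
          if (reportable && cls %in% c("P", "LP") && eligible &&
              call != "normal")
            expect_equal(out, "positive")
          if (reportable && cls %in% c("P", "LP") && eligible &&
              call == "normal")
            expect_equal(out, "unclear")  # discordant biochemistry
        }
      }
    }
  }
})

test_that("no positive report rests on a non-reportable or carrier finding", {
  panel <- test_panel()
  co <- generate_cohort(cohort_params(n_patients = 150, seed = 99,
                                      assay_sensitivity = 0.9,
                                      assay_specificity = 0.9), panel)
  for (r in run_cohort(co$cases, panel)) {
    if (identical(r$status, "positive")) {
      expect_true(any(r$findings$outcome == "positive"))
      expect_true(all(r$findings$final_class %in% c("P", "LP", "VUS")))
    }
    if (identical(r$status, "negative")) expect_equal(nrow(r$findings), 0L)
    if (identical(r$status, "unclear"))
      expect_false(any(r$findings$outcome == "positive"))
  }
})

test_that("the biochemistry cross-tab counts cases with structural zeros", {
  expect_true(all(biochem_crosstab(list()) == 0L))
  reports <- run_cohort(list(case_gba(), case_psap(), case_galns(),
                             case_tpp1(), case_dbt()), test_panel())
  tab <- biochem_crosstab(reports)
  expect_equal(sum(tab), 4L)  # DBT has no biochemical call
  expect_equal(tab["pathologic", "positive"], 1L)  # GBA
  expect_equal(tab["normal", "inconclusive"], 1L)  # PSAP
  expect_equal(tab["normal", "negative"], 2L)      # GALNS, TPP1
  expect_equal(tab["pathologic", "negative"], 0L)
  expect_equal(tab["normal", "positive"], 0L)
})
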