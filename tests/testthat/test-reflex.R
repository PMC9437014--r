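# Independent truth-table oracle for the mode/zygosity matcher: eligibility
# written as one direct expression over the allele multiset.
oracle_eligible <- function(mode, zygs, sex, female_het_reportable = FALSE) {
  count <- min(2, sum(c(het = 1, hom = 2, hemi = 1)[zygs]))
  switch(mode,
    AR = count >= 2,
    AD = count >= 1,
    XL = any(zygs == "hom") || any(zygs == "hemi") ||
      (length(zygs) >= 1 && sex == "female" && female_het_reportable))
}

test_that("inheritance matching agrees with the exhaustive truth-table oracle", {
  panel <- test_panel()
  zyg_sets <- list(character(0))
  for (size in 1:3) {
    combos <- expand.grid(rep(list(c("het", "hom", "hemi")), size),
                          stringsAsFactors = FALSE)
    zyg_sets <- c(zyg_sets, split(as.matrix(combos), seq_len(nrow(combos))))
  }
  for (mode in c("AR", "AD", "XL")) {
    for (fhr in c(FALSE, TRUE)) {
      gene <- data.frame(symbol = "GENE", disease_id = "D",
                         inheritance = mode, female_het_reportable = fhr,
                         stringsAsFactors = FALSE)
      for (zygs in zyg_sets) {
        zygs <- as.character(zygs)
        for (sex in c("male", "female", "unknown")) {
          variants <- data.frame(zygosity = zygs, stringsAsFactors = FALSE)
          if (any(zygs == "hemi") && sex == "female") {
            expect_error(match_inheritance(variants, gene, sex),
                         "inconsistency")
            next
          }
          got <- match_inheritance(variants, gene, sex)
          expect_identical(
            got$eligible, oracle_eligible(mode, zygs, sex, fhr),
            label = paste("eligible for", mode, paste(zygs, collapse = "+"),
                          sex, "fhr =", fhr))
          expect_true(got$allele_count <= 2L)
        }
      }
    }
  }
})

test_that("genotype patterns describe the allele configuration", {
  panel <- test_panel()
  gba <- lookup_gene(panel, "GBA")
  two_het <- data.frame(zygosity = c("het", "het"))
  m <- match_inheritance(two_het, gba, "male")
  expect_true(m$eligible)
  expect_equal(m$genotype_pattern, "comp_het_phase_unknown")

  one_het <- data.frame(zygosity = "het")
  m <- match_inheritance(one_het, gba, "male")
  expect_false(m$eligible)
  expect_equal(m$genotype_pattern, "het_single")

  ids <- lookup_gene(panel, "IDS")
  m <- match_inheritance(data.frame(zygosity = "hemi"), ids, "male")
  expect_true(m$eligible)
  expect_equal(m$genotype_pattern, "hemi")

  # het female in an XL disease is reportable only when configured
  m <- match_inheritance(data.frame(zygosity = "het"), ids, "female")
  expect_false(m$eligible)
  expect_equal(m$genotype_pattern, "het_x_female")
  gla <- lookup_gene(panel, "GLA")  # female_het_reportable
  expect_true(match_inheritance(data.frame(zygosity = "het"), gla,
                                "female")$eligible)
})

test_that("reflex orders cover linked assays once and only for eligible genes", {
  panel <- test_panel()
  elig <- function(gene, eligible = TRUE) {
    entry <- lookup_gene(panel, gene)[1L, ]
    list(gene = gene, disease_id = entry$disease_id, eligible = eligible,
         genotype_pattern = "hom", allele_count = 2L)
  }
  orders <- trigger_reflex(list(elig("GBA")), panel, "c1")
  expect_setequal(orders$assay_id, c("GBA_ENZ", "LYSO_GB1"))

  expect_equal(nrow(trigger_reflex(list(elig("GBA", eligible = FALSE)),
                    panel)), 0L)
  expect_equal(nrow(trigger_reflex(list(elig("SGSH")), panel)), 0L)

  # ATP7B and CP share the ceruloplasmin biomarker: one order
  orders <- trigger_reflex(list(elig("ATP7B"), elig("CP")), panel)
  expect_equal(sum(orders$assay_id == "CER_MS"), 1L)
})

test_that("biochemical calls follow the pathologic direction with a grey zone", {
  enz <- data.frame(assay_id = "E", kind = "enzyme_activity", analyte = "e",
                    pathologic_direction = "below_range", reference_low = 2,
                    reference_high = 10, units = "u",
                    stringsAsFactors = FALSE)
  bio <- data.frame(assay_id = "B", kind = "biomarker", analyte = "b",
                    pathologic_direction = "above_range", reference_low = 0,
                    reference_high = 6, units = "u", stringsAsFactors = FALSE)
  expect_equal(interpret_biochem(0.3, enz)$call, "pathologic")
  expect_equal(interpret_biochem(5.0, bio)$call, "normal")
  # exactly at the pathologic bound is borderline, just outside the grey
  # band is not
  expect_equal(interpret_biochem(2.0, enz)$call, "borderline")
  expect_equal(interpret_biochem(2.2 + 1e-9, enz)$call, "normal")
  expect_equal(interpret_biochem(1.8 - 1e-9, enz)$call, "pathologic")
  expect_equal(interpret_biochem(6.6 + 1e-9, bio)$call, "pathologic")
  expect_error(interpret_biochem(1, enz, units = "other"), "unit mismatch")
})

test_that("deficiency calls are monotone in the measured value", {
  enz <- data.frame(assay_id = "E", kind = "enzyme_activity", analyte = "e",
                    pathologic_direction = "below_range", reference_low = 2,
                    reference_high = 10, units = "u",
                    stringsAsFactors = FALSE)
  calls <- interpret_biochem(seq(0, 4, by = 0.05), enz)$call
  rank <- match(calls, c("pathologic", "borderline", "normal"))
  expect_false(is.unsorted(rank))
})
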