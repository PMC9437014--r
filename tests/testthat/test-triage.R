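test_that("SNV cascade retains and excludes per the six criteria", {
  th <- default_thresholds()
  d <- evaluate_snv(snv_row("GBA", "het", prior = "P", maf_external = 0.003), th)
  expect_true(d$retained)
  expect_match(d$criteria_hit, "C1_prior_PLP_VUS")

  d <- evaluate_snv(snv_row("GBA", "het", maf_external = 0.005,
                            impact = "high", prior = "absent"), th)
  expect_true(d$retained)
  expect_match(d$criteria_hit, "C3_rare_high_moderate")

  # same record but previously unclassified also hits the gated C2
  d <- evaluate_snv(snv_row("GBA", "het", maf_external = 0.005,
                            impact = "high", prior = "unclassified"), th)
  expect_setequal(strsplit(d$criteria_hit, ",")[[1]],
                  c("C2_unclassified", "C3_rare_high_moderate"))

  d <- evaluate_snv(snv_row("GBA", "het", maf_external = 0.05, impact = "low",
                            prior = "absent", ada = 0.3, rf = 0.2), th)
  expect_false(d$retained)
  expect_equal(d$criteria_hit, "")

  d <- evaluate_snv(snv_row("GBA", "het", prior = "LB",
                            assertion = "disease_causing"), th)
  expect_false(d$retained)
  expect_equal(d$excluded_by, "prior_benign")

  d <- evaluate_snv(snv_row("GBA", "het", maf_external = 0.009,
                            impact = "low", ada = 0.7, rf = 0.61,
                            prior = "absent"), th)
  expect_true(d$retained)
  expect_match(d$criteria_hit, "C5_splice_scores")

  # both splice scores must exceed the cut-off; an absent score fails C5
  d <- evaluate_snv(snv_row("GBA", "het", impact = "low", maf_external = 0.05,
                            ada = 0.9, rf = NA_real_, prior = "absent"), th)
  expect_false(d$retained)
})

test_that("retained low-quality variants are flagged for Sanger confirmation", {
  d <- evaluate_snv(snv_row("GBA", "het", prior = "P", quality_ok = FALSE))
  expect_equal(d$confirmation, "sanger")
  d <- evaluate_snv(snv_row("GBA", "het", prior = "B", quality_ok = FALSE))
  expect_equal(d$confirmation, "none")
})

test_that("prior benign classification dominates every inclusion criterion", {
  set.seed(11)
  for (i in 1:200) {
    v <- snv_row("GBA", "het",
                 prior = sample(c("LB", "B"), 1),
                 impact = sample(c("high", "moderate", "low", "modifier"), 1),
                 maf_external = sample(c(NA, runif(1, 0, 0.02)), 1),
                 assertion = sample(c("none", "disease_causing"), 1),
                 ada = sample(c(NA, runif(1)), 1),
                 rf = sample(c(NA, runif(1)), 1))
    d <- evaluate_snv(v)
    expect_false(d$retained)
    expect_equal(d$excluded_by, "prior_benign")
  }
})

test_that("retention is monotone in rarity and splice scores", {
  set.seed(12)
  for (i in 1:200) {
    v <- snv_row("GBA", "het",
                 prior = sample(c("absent", "unclassified"), 1),
                 impact = sample(c("high", "moderate", "low"), 1),
                 maf_external = runif(1, 0, 0.03),
                 ada = runif(1), rf = runif(1))
    d1 <- evaluate_snv(v)$retained
    v2 <- v; v2$maf_external <- v$maf_external / 2
    expect_true(evaluate_snv(v2)$retained >= d1)   # rarer never drops out
    v3 <- v; v3$ada <- min(1, v$ada + 0.2); v3$rf <- min(1, v$rf + 0.2)
    expect_true(evaluate_snv(v3)$retained >= d1)   # stronger splice support
  }
})

test_that("CNV selection applies copy-number, span and frequency rules", {
  d <- evaluate_cnv(cnv_row("GBA", 1, 8, 10))
  expect_true(d$retained)
  expect_equal(d$confirmation, "orthogonal_cnv")

  expect_false(evaluate_cnv(cnv_row("GBA", 1, 2, 3))$retained)  # 2 exons

  d <- evaluate_cnv(cnv_row("GBA", 0, 5, 5, maf = 0.001))
  expect_true(d$retained)                       # hom deletion, any span
  expect_equal(d$confirmation, "none")
  expect_match(d$criteria_hit, "CNV_hom_del")

  expect_false(evaluate_cnv(cnv_row("GBA", 3, 1, 5, maf = 0.03))$retained)
  expect_false(evaluate_cnv(cnv_row("GBA", 2, 1, 10))$retained)  # normal CN

  # an orthogonally confirmed het deletion is kept regardless of span
  d <- evaluate_cnv(cnv_row("DBT", 1, 2, 3, confirmed_by = "MLPA"))
  expect_true(d$retained)
  expect_match(d$criteria_hit, "CNV_confirmed")
  expect_false(
    evaluate_cnv(cnv_row("DBT", 1, 2, 3, maf = 0.05,
                         confirmed_by = "MLPA"))$retained)  # MAF gate stays
})

test_that("case triage restricts to panel genes, dedupes and groups by gene", {
  panel <- test_panel()
  off <- patient_case("t1", snvs = snv_row("NOT_A_PANEL_GENE", "het",
                                           prior = "P"))
  expect_equal(nrow(triage_case(off, panel)$variants), 0L)

  dup <- snv_row("GBA", "het", prior = "P")
  both <- patient_case("t2", snvs = rbind(dup, dup),
                       cnvs = cnv_row("GBA", 1, 8, 10))
  tri <- triage_case(both, panel)
  expect_equal(nrow(tri$variants), 2L)          # duplicate SNV collapsed
  expect_setequal(tri$variants$type, c("snv", "cnv_del"))
  expect_true(all(tri$variants$gene == "GBA"))
  expect_false(tri$syndromic)
})

test_that("multi-gene CNVs are retained syndromic when any panel gene passes", {
  panel <- test_panel()
  genes <- paste(c("GBA", "SMPD1", sprintf("OFFPANEL%02d", 1:38)),
                 collapse = ",")
  case <- patient_case("t3", cnvs = cnv_row(genes, 1, 1, 5))
  tri <- triage_case(case, panel)
  expect_true(tri$syndromic)
  expect_setequal(tri$variants$gene, c("GBA", "SMPD1"))
  expect_true(all(tri$variants$syndromic))
  report <- run_case(case, panel)
  expect_equal(report$status, "positive")
  expect_true(report$syndromic_flag)
})
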