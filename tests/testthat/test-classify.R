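t_def <- sft_thresholds()

test_that("the global MAF gate is strict at 2%", {
  expect_true(passes_global_maf(0.019, t_def))
  expect_false(passes_global_maf(0.02, t_def))
  expect_true(passes_global_maf(0, t_def))
})

test_that("benign rejection covers B, LB and B/LB but lets absent proceed", {
  expect_true(reject_benign("LB"))
  expect_true(reject_benign("B"))
  expect_true(reject_benign("B/LB"))
  expect_false(reject_benign("VUS"))
  expect_false(reject_benign(NA))
})

test_that("P1 requires ClinVar P/LP with HGMD DM; conflicts are excluded from P entirely", {
  expect_equal(classify_p(ann_row(clinvar_significance = "P",
                                  hgmd_class = "DM"), t_def), "P1")
  expect_equal(classify_p(ann_row(clinvar_significance = "LP",
                                  clinvar_stars = 2L), t_def), "P2")
  expect_equal(classify_p(ann_row(clinvar_significance = "P",
                                  clinvar_stars = 3L,
                                  hgmd_class = "other"), t_def), "conflict")
  expect_equal(classify_p(ann_row(clinvar_significance = "P",
                                  clinvar_stars = 1L), t_def), "none")
  expect_equal(classify_p(ann_row(clinvar_significance = "VUS"), t_def), "none")
})

test_that("LP1 needs LOF class, PVS1 VeryStrong, HIGH impact, rarity and a LOF gene", {
  lof <- ann_row(consequence = "stop_gained", impact = "HIGH",
                 pvs1_strength = "VeryStrong", gnomad_af = 2e-4)
  expect_true(classify_lp1(lof, 5e-4, t_def, lof_gene = TRUE))
  expect_false(classify_lp1(lof, 5e-3, t_def, TRUE))             # not rare
  expect_false(classify_lp1(modifyList(lof, list(pvs1_strength = "Moderate")),
                            5e-4, t_def, TRUE))
  expect_false(classify_lp1(modifyList(lof, list(impact = "MODERATE")),
                            5e-4, t_def, TRUE))
  expect_false(classify_lp1(lof, 5e-4, t_def, lof_gene = FALSE))
  expect_false(classify_lp1(modifyList(lof, list(gnomad_af = 5e-3)),
                            5e-4, t_def, TRUE))
  # unseen in gnomAD counts as rare there
  expect_true(classify_lp1(modifyList(lof, list(gnomad_af = NA)),
                           5e-4, t_def, TRUE))
})

test_that("LP2 and pVUS split on the external verdict; REVEL boundary is strict", {
  base <- ann_row(revel = 0.82, external_verdict = "LP")  # novel missense
  expect_equal(classify_lp2_pvus(base, 4e-4, 3L, t_def, "cardiovascular", TRUE),
               "LP2")
  expect_equal(classify_lp2_pvus(modifyList(base, list(external_verdict = "VUS")),
                                 4e-4, 3L, t_def, "cardiovascular", TRUE),
               "pVUS")
  expect_equal(classify_lp2_pvus(modifyList(base, list(revel = 0.7)),
                                 4e-4, 3L, t_def, "cardiovascular", TRUE),
               "none")
  expect_equal(classify_lp2_pvus(base, 4e-4, 1L, t_def, "cardiovascular", TRUE),
               "none")  # more than one carrier required
  expect_equal(classify_lp2_pvus(base, 4e-4, 3L, t_def, "miscellaneous", TRUE),
               "none")
  expect_equal(classify_lp2_pvus(base, 4e-4, 3L, t_def, "cardiovascular", FALSE),
               "none")
  # dbSNP entry alone breaks novelty when ClinVar is absent
  expect_equal(classify_lp2_pvus(modifyList(base, list(dbsnp_id = "rs1")),
                                 4e-4, 3L, t_def, "cardiovascular", TRUE),
               "none")
  # but a reported VUS with a dbSNP id stays eligible
  expect_equal(classify_lp2_pvus(modifyList(base, list(dbsnp_id = "rs1",
                                   clinvar_significance = "VUS")),
                                 4e-4, 3L, t_def, "cardiovascular", TRUE),
               "LP2")
})

test_that("the master tree applies rules in precedence order", {
  ge <- list(category = "cardiovascular", lof_gene = TRUE)
  p1 <- classify_variant(ann_row(clinvar_significance = "P", hgmd_class = "DM"),
                         0.001, 5L, t_def, ge, FALSE)
  expect_equal(p1$list, "P1")
  expect_true("p1_clinvar_plp_hgmd_dm" %in% p1$reasons)

  benign_lof <- ann_row(clinvar_significance = "B", consequence = "stop_gained",
                        impact = "HIGH", pvs1_strength = "VeryStrong")
  expect_equal(classify_variant(benign_lof, 5e-4, 5L, t_def, ge, TRUE)$list,
               "rejected")

  common <- classify_variant(ann_row(clinvar_significance = "P",
                                     hgmd_class = "DM"), 0.05, 5L, t_def, ge,
                             FALSE)
  expect_equal(common$list, "rejected")
  expect_equal(common$reasons, "global_maf_fail")

  conflict <- classify_variant(ann_row(clinvar_significance = "P",
                                       hgmd_class = "other",
                                       consequence = "stop_gained",
                                       impact = "HIGH",
                                       pvs1_strength = "VeryStrong"),
                               5e-4, 5L, t_def, ge, FALSE)
  expect_equal(conflict$list, "unclassified")
  expect_true("clinvar_hgmd_conflict_excluded" %in% conflict$reasons)
})

test_that("every variant lands in exactly one list and reasons accompany assignments", {
  set.seed(99)
  ge <- list(category = "cancer", lof_gene = TRUE)
  for (i in 1:200) {
    ann <- ann_row(
      consequence = sample(c("missense_variant", "stop_gained",
                             "synonymous_variant"), 1),
      impact = sample(c("HIGH", "MODERATE", "LOW"), 1),
      clinvar_significance = sample(c("P", "LP", "VUS", "conflicting", "B",
                                      "LB", NA), 1),
      clinvar_stars = sample(c(0L, 1L, 2L, 3L, NA), 1),
      hgmd_class = sample(c("DM", "other", NA), 1),
      revel = sample(c(0.2, 0.71, 0.95, NA), 1),
      pvs1_strength = sample(c("VeryStrong", "Moderate", NA), 1),
      external_verdict = sample(c("P", "LP", "VUS", NA), 1),
      gnomad_af = sample(c(NA, 1e-5, 0.01), 1),
      dbsnp_id = sample(c(NA, "rs1"), 1))
    res <- classify_variant(ann, sample(c(1e-4, 5e-3, 0.03), 1),
                            sample(0:4, 1), t_def, ge, sample(c(TRUE, FALSE), 1))
    expect_true(res$list %in% c("P1", "P2", "LP1", "LP2", "pVUS", "rejected",
                                "unclassified"))
    expect_length(res$list, 1)
    if (res$list != "unclassified") expect_gt(length(res$reasons), 0)
  }
})
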