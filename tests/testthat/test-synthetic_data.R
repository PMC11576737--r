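test_that("genotype draws respect Hardy-Weinberg limits with and without inbreeding", {
  # F = 0: plain HWE within sampling error
  d <- simulate_genotypes(one_variant_cfg(0.2, 0, 10000L, seed = 2L))
  q <- 0.2
  frac <- tabulate(d[, 1] + 1L, 3) / nrow(d)
  exp_frac <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (k in 1:3)
    expect_lt(abs(frac[k] - exp_frac[k]),
              3 * sqrt(exp_frac[k] * (1 - exp_frac[k]) / nrow(d)))
  # F = 1: no heterozygotes at all
  d1 <- simulate_genotypes(one_variant_cfg(0.3, 1 - 1e-12, 5000L, seed = 3L))
  expect_equal(sum(d1[, 1] == 1L), 0)
})

test_that("excess homozygosity matches q^2 + Fq(1-q)", {
  q <- 0.01; f <- 0.0625; n <- 100000L
  d <- simulate_genotypes(one_variant_cfg(q, f, n, seed = 4L))
  hom_exp <- q^2 + f * q * (1 - q)   # 7.1875e-4
  hom_obs <- mean(d[, 1] == 2L)
  expect_lt(abs(hom_obs - hom_exp), 3 * sqrt(hom_exp * (1 - hom_exp) / n))
})

test_that("planted phenotype odds ratios reproduce the odds algebra", {
  # planted_or = 1: carriers and non-carriers indistinguishable in expectation
  cfg <- one_variant_cfg(0.3, 0, 20000L, seed = 5L, planted_or = 1,
                         evidence_type = "CVD")
  d <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, d)
  ev <- derive_evidence(ph)
  carrier <- d[, 1] >= 1
  expect_lt(abs(mean(ev$cvd[carrier]) - mean(ev$cvd[!carrier])), 0.01)
  # planted_or = 5, p0 = 0.05: carrier prevalence ~ 0.2083
  cfg5 <- one_variant_cfg(0.3, 0, 20000L, seed = 6L, planted_or = 5,
                          evidence_type = "CVD")
  d5 <- simulate_genotypes(cfg5)
  ph5 <- simulate_phenotypes(cfg5, d5)
  ev5 <- derive_evidence(ph5)
  carrier5 <- d5[, 1] >= 1
  p_exp <- 5 * (0.05 / 0.95) / (1 + 5 * (0.05 / 0.95))
  expect_lt(abs(mean(ev5$cvd[carrier5]) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / sum(carrier5)))
  # p0 = 0: no non-carrier evidence ever
  cfg0 <- one_variant_cfg(0.1, 0, 5000L, seed = 7L, p0 = 0)
  d0 <- simulate_genotypes(cfg0)
  ph0 <- simulate_phenotypes(cfg0, d0)
  ev0 <- derive_evidence(ph0)
  expect_false(any(ev0$cvd | ev0$cancer | ev0$fh))
})

test_that("annotation recipes drive the classifier to their truth labels", {
  cfg <- sim_config(seed = 11L)
  b <- write_fixture_bundle(cfg, file.path(tempdir(), "fx_recipes"))
  ann <- load_annotation_table(b$files$annotation)
  selected <- select_transcripts(ann)
  catalog <- acmg_sf_catalog()
  tr <- b$truth$variants
  for (i in seq_len(nrow(tr))) {
    if (!tr$variant_id[i] %in% rownames(selected)) next
    v <- tr[i, ]
    ge <- catalog[catalog$symbol == v$gene, ]
    maf <- min(v$allele_count / v$allele_number,
               1 - v$allele_count / v$allele_number)
    evid <- v$expected_list %in% c("LP2", "pVUS")
    res <- classify_variant(selected[v$variant_id, ], maf, v$carriers,
                            sft_thresholds(), ge, cohort_evidence = evid)
    if (v$expected_list %in% c("P1", "P2", "LP1", "LP2", "pVUS", "rejected"))
      expect_equal(res$list, v$expected_list, info = v$id)
  }
})

test_that("fixture bundles are complete, sized as configured, and seed-reproducible", {
  d1 <- file.path(tempdir(), "fx_demo1")
  d2 <- file.path(tempdir(), "fx_demo2")
  b1 <- write_fixture_bundle(demo_config(seed = 9L), d1)
  b2 <- write_fixture_bundle(demo_config(seed = 9L), d2)
  for (f in c("vcf", "annotation", "phenotypes", "catalog", "region_map"))
    expect_true(file.exists(b1$files[[f]]))
  expect_equal(nrow(b1$truth$variants), 12)
  expect_equal(b1$truth$n_participants, 500)
  for (f in c("vcf", "annotation", "phenotypes", "truth", "reference"))
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]))
  b3 <- write_fixture_bundle(demo_config(seed = 10L), file.path(tempdir(), "fx3"))
  expect_false(identical(readLines(b1$files$vcf), readLines(b3$files$vcf)))
})
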