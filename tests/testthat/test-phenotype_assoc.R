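test_that("evidence derivations OR their components and are monotone", {
  ph <- blank_phenotype(c("S1", "S2", "S3", "S4"))
  expect_false(any(derive_cvd_evidence(ph)))
  expect_false(any(derive_cancer_evidence(ph)))
  ph$family_heart_disease[2] <- TRUE
  ph$ecg_abnormal[3] <- TRUE
  expect_equal(derive_cvd_evidence(ph), c(FALSE, TRUE, TRUE, FALSE))
  ph$tumor_surgery[1] <- TRUE
  ph$early_screening[4] <- TRUE
  expect_equal(derive_cancer_evidence(ph), c(TRUE, FALSE, FALSE, TRUE))
  # monotone: switching any single flag on never turns evidence off
  set.seed(41)
  flags <- c("ecg_abnormal", "self_heart_disease", "revascularization",
             "family_heart_disease")
  for (i in 1:20) {
    base <- blank_phenotype("X")
    for (fl in flags) base[[fl]] <- sample(c(TRUE, FALSE), 1)
    before <- derive_cvd_evidence(base)
    fl <- sample(flags, 1)
    base[[fl]] <- TRUE
    expect_true(derive_cvd_evidence(base) >= before)
  }
})

test_that("FH evidence uses diagnosis or LDL at or above the threshold", {
  ph <- blank_phenotype(c("S1", "S2", "S3", "S4"))
  ph$hypercholesterolemia_dx[1] <- TRUE
  ph$ldl <- c(NA, 3.0, 4.9, 5.4)
  ev <- derive_fh_evidence(ph, 4.9)
  expect_equal(ev, c(TRUE, FALSE, TRUE, TRUE))  # boundary inclusive
})

test_that("candidate selection needs two evidenced CVD carriers or one cancer carrier", {
  cat5 <- tiny_catalog()
  ph <- blank_phenotype(paste0("S", 1:6))
  ph$self_heart_disease[1:2] <- TRUE
  ph$self_cancer[5] <- TRUE
  ev <- derive_evidence(ph)
  carriers <- list(vT = c("S1", "S2", "S3"),   # TTN: 2 evidenced CVD carriers
                   vT2 = c("S1", "S4"),        # TTN: 1 evidenced carrier
                   vB = "S5",                  # BRCA2: 1 evidenced cancer
                   vB2 = "S6")                 # BRCA2: 0 evidenced
  genes <- c(vT = "TTN", vT2 = "TTN", vB = "BRCA2", vB2 = "BRCA2")
  cand <- select_candidates(carriers, genes, ev, cat5)
  expect_equal(cand$candidate[match(c("vT", "vT2", "vB", "vB2"),
                                    cand$variant_id)],
               c(TRUE, FALSE, TRUE, FALSE))
  # looser reading counts carriers irrespective of evidence
  cand2 <- select_candidates(carriers, genes, ev, cat5, rule = "any_carrier")
  expect_true(cand2$candidate[cand2$variant_id == "vT2"])
})

test_that("Fisher association handles flat, extreme and untestable tables", {
  flat <- fisher_association(1, 1, 1, 1)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(flat$stars, "ns")

  skew <- fisher_association(2, 0, 98, 900)
  expect_equal(skew$p_value, oracle_fisher_p(2, 0, 98, 900), tolerance = 1e-12)
  expect_true(skew$one_sided_ci)

  x <- fisher_association(0, 5, 5, 0)
  expect_equal(x$p_value, oracle_fisher_p(0, 5, 5, 0), tolerance = 1e-12)
  expect_true(x$one_sided_ci)
  expect_equal(fisher_association(0, 5, 5, 0, or_method = "sample")$odds_ratio, 0)
  expect_equal(fisher_association(5, 0, 0, 5, or_method = "sample")$odds_ratio, Inf)

  u <- fisher_association(0, 0, 3, 7)
  expect_equal(u$status, "untestable")
  expect_true(is.na(u$p_value))
})

test_that("the Fisher p-value is invariant to transposing the table", {
  set.seed(53)
  for (i in 1:50) {
    tb <- sample(0:12, 4, TRUE)
    if (sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0 ||
        tb[1] + tb[3] == 0 || tb[2] + tb[4] == 0) next
    p1 <- fisher_association(tb[1], tb[2], tb[3], tb[4])$p_value
    p2 <- fisher_association(tb[1], tb[3], tb[2], tb[4])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("significance stars are strict at every boundary", {
  expect_equal(significance_stars(0.02), "*")
  expect_equal(significance_stars(0.05), "ns")
  expect_equal(significance_stars(0.006), "**")
  expect_equal(significance_stars(c(0.04999, 0.01, 0.0009999, 1e-4, 9e-5)),
               c("*", "*", "***", "***", "****"))
})

test_that("association driver builds carrier x evidence tables over phenotyped participants", {
  cat5 <- tiny_catalog()
  ph <- blank_phenotype(paste0("S", 1:10))
  ph$self_cancer[1:2] <- TRUE
  ev <- derive_evidence(ph)
  carriers <- list(vB = c("S1", "S2", "S3"))
  cand <- select_candidates(carriers, c(vB = "BRCA2"), ev, cat5)
  res <- associate_candidates(cand, carriers, ev)
  expect_equal(nrow(res), 1)
  expect_equal(unname(unlist(res[1, c("a", "b", "c", "d")])), c(2, 1, 0, 7))
  expect_equal(res$p_value, fisher_association(2, 1, 0, 7)$p_value)
  expect_equal(res$p_adj_bh, res$p_value)  # single test, BH is identity
})
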