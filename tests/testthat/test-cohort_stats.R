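mk_classified <- function(keys, genes, lists) {
  df <- data.frame(gene = genes, list = lists,
                   reasons = "x", stringsAsFactors = FALSE)
  rownames(df) <- keys
  df
}

test_that("GPP identification matches a brute-force double loop", {
  cl <- mk_classified(c("v1", "v2", "v3"), c("BRCA2", "ATP7B", "TTN"),
                      c("P1", "LP1", "pVUS"))
  # all-zero matrix gives no findings
  zero <- matrix(0L, 4, 3, dimnames = list(paste0("S", 1:4), c("v1", "v2", "v3")))
  expect_equal(nrow(identify_gpps(cl, zero)), 0)
  # one homozygote
  one <- zero; one["S2", "v1"] <- 2L
  f <- identify_gpps(cl, one)
  expect_equal(nrow(f), 1)
  expect_equal(f$zygosity, "HOM")
  # random matrices agree with the exhaustive loop
  set.seed(5)
  for (i in 1:10) {
    d <- matrix(sample(c(0L, 1L, 2L, NA), 15, TRUE, prob = c(.6, .2, .1, .1)),
                5, 3, dimnames = list(paste0("S", 1:5), c("v1", "v2", "v3")))
    f <- identify_gpps(cl, d)
    o <- oracle_gpp(cl, d)
    if (is.null(o)) {
      expect_equal(nrow(f), 0)
    } else {
      expect_equal(nrow(f), nrow(o))
      expect_setequal(paste(f$participant, f$variant_id, f$zygosity),
                      paste(o$participant, o$variant_id, o$zygosity))
    }
  }
  # unknown variant key errors
  cl2 <- mk_classified("v9", "BRCA2", "P1")
  expect_error(identify_gpps(cl2, zero), "absent")
})

test_that("reportability: dominant carriers yes, recessive heterozygotes no, biallelic yes", {
  cat5 <- tiny_catalog()
  f <- data.frame(
    participant = c("S1", "S2", "S3", "S4", "S4", "S5"),
    variant_id = c("vB", "vA1", "vA2", "vA1", "vA2", "vP"),
    gene = c("BRCA2", "ATP7B", "ATP7B", "ATP7B", "ATP7B", "ATP7B"),
    list = c("P1", "P1", "P1", "P1", "P1", "pVUS"),
    zygosity = c("HET", "HET", "HOM", "HET", "HET", "HOM"),
    dosage = c(1L, 1L, 2L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  r <- reportable_under_acmg(f, cat5)
  expect_true(r$reportable[1])                       # AD het
  expect_false(r$reportable[2])                      # AR het single hit
  expect_true(r$carrier_only[2])
  expect_true(r$reportable[3])                       # AR hom
  expect_true(all(r$reportable[4:5]))                # AR compound het
  expect_true(all(r$phase_unknown[4:5]))
  expect_false(r$reportable[6])                      # pVUS never reportable
  expect_false(r$carrier_only[6])
})

test_that("semidominant and X-linked genes report heterozygous carriers", {
  cat5 <- tiny_catalog()
  f <- data.frame(participant = c("S1", "S2"), variant_id = c("vL", "vG"),
                  gene = c("LDLR", "GLA"), list = c("P2", "LP1"),
                  zygosity = "HET", dosage = 1L, stringsAsFactors = FALSE)
  r <- reportable_under_acmg(f, cat5)
  expect_true(all(r$reportable))
})

test_that("pVUS findings are never reportable over random inputs", {
  set.seed(17)
  cat5 <- tiny_catalog()
  f <- data.frame(
    participant = sample(paste0("S", 1:6), 40, TRUE),
    variant_id = sample(paste0("v", 1:8), 40, TRUE),
    gene = sample(cat5$symbol, 40, TRUE),
    list = sample(c("P1", "LP1", "pVUS"), 40, TRUE),
    zygosity = sample(c("HET", "HOM"), 40, TRUE),
    dosage = 1L, stringsAsFactors = FALSE)
  f <- f[!duplicated(paste(f$participant, f$variant_id)), ]
  r <- reportable_under_acmg(f, cat5)
  expect_false(any(r$reportable[r$list == "pVUS"]))
  expect_false(any(r$carrier_only & r$reportable))
})

test_that("prevalence reproduces the Wald closed form and clamps at zero", {
  pr <- prevalence(509, 14392)
  expect_equal(pr$proportion, 509 / 14392)
  expect_equal(format_percent(pr$proportion, 1), 3.5)
  # closed form evaluated independently
  p <- 509 / 14392
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 14392)
  expect_equal(pr$ci_low, p - half, tolerance = 1e-12)
  expect_equal(pr$ci_high, p + half, tolerance = 1e-12)
  z <- prevalence(0, 1000)
  expect_equal(z$proportion, 0)
  expect_equal(z$ci_low, 0)
  expect_error(prevalence(1, 0), "positive")
  # wilson option matches prop.test without continuity correction
  w <- prevalence(50, 1000, method = "wilson")
  pt <- prop.test(50, 1000, correct = FALSE)$conf.int
  expect_equal(c(w$ci_low, w$ci_high), as.numeric(pt))
})

test_that("the prevalence interval shrinks monotonically with the denominator", {
  widths <- sapply(c(100, 1000, 10000, 100000), function(n)
    with(prevalence(round(0.035 * n), n), ci_high - ci_low))
  expect_true(all(diff(widths) < 0))
})

test_that("category summaries match a brute-force group-by", {
  cat5 <- tiny_catalog()
  f <- data.frame(
    participant = c("S1", "S2", "S3", "S1", "S2"),
    variant_id = c("v1", "v1", "v2", "v3", "v4"),
    gene = c("TTN", "TTN", "TTN", "BRCA2", "ATP7B"),
    list = c("LP1", "LP1", "LP1", "P1", "P1"),
    zygosity = c("HET", "HET", "HET", "HET", "HET"),
    dosage = 1L, stringsAsFactors = FALSE)
  f <- reportable_under_acmg(f, cat5)
  s <- summarize_by_category(f, cat5)
  ttn <- s$by_gene[s$by_gene$gene == "TTN", ]
  expect_equal(ttn$variants, 2)
  expect_equal(ttn$gpp, 3)
  expect_equal(ttn$het, 3)
  expect_equal(ttn$hom, 0)
  # S1 carries cardiovascular and cancer variants: once per category,
  # once overall
  expect_equal(s$by_category$gpp[s$by_category$category == "cancer"], 1)
  expect_equal(s$by_category$gpp[s$by_category$category == "cardiovascular"], 3)
  expect_equal(s$distinct_gpp, 3)
  # random fixture vs independent group-by
  set.seed(23)
  f2 <- data.frame(
    participant = sample(paste0("S", 1:9), 60, TRUE),
    variant_id = sample(paste0("v", 1:10), 60, TRUE),
    gene = sample(cat5$symbol, 60, TRUE),
    list = sample(c("P1", "LP1", "pVUS"), 60, TRUE),
    zygosity = sample(c("HET", "HOM"), 60, TRUE, prob = c(.9, .1)),
    dosage = 1L, stringsAsFactors = FALSE)
  f2 <- f2[!duplicated(paste(f2$participant, f2$variant_id)), ]
  f2$gene <- cat5$symbol[match(f2$variant_id, paste0("v", 1:10)) %% 5 + 1]
  f2 <- reportable_under_acmg(f2, cat5)
  s2 <- summarize_by_category(f2, cat5)
  for (g in unique(f2$gene)) {
    sub <- f2[f2$gene == g, ]
    expect_equal(s2$by_gene$variants[s2$by_gene$gene == g],
                 length(unique(sub$variant_id)))
    expect_equal(s2$by_gene$gpp[s2$by_gene$gene == g],
                 length(unique(sub$participant)))
  }
  expect_equal(s2$distinct_gpp, length(unique(f2$participant)))
})

test_that("distinct GPP count never exceeds the sum of per-list counts", {
  set.seed(29)
  cat5 <- tiny_catalog()
  f <- data.frame(
    participant = sample(paste0("S", 1:12), 50, TRUE),
    variant_id = sample(paste0("v", 1:6), 50, TRUE),
    gene = "TTN", list = sample(c("P1", "LP1", "pVUS"), 50, TRUE),
    zygosity = "HET", dosage = 1L, stringsAsFactors = FALSE)
  f <- f[!duplicated(paste(f$participant, f$variant_id)), ]
  per_list <- sapply(unique(f$list), function(l)
    length(unique(f$participant[f$list == l])))
  expect_lte(length(unique(f$participant)), sum(per_list))
})

test_that("multi-gene carriers require reportable findings in distinct genes", {
  cat5 <- tiny_catalog()
  f <- data.frame(
    participant = c("Q1", "Q1", "Q2", "Q2", "Q3"),
    variant_id = c("vBRCA2", "vLDLR", "vT1", "vT2", "vX"),
    gene = c("BRCA2", "LDLR", "TTN", "TTN", "BRCA2"),
    list = c("P1", "P2", "LP1", "LP1", "pVUS"),
    zygosity = "HET", dosage = 1L, stringsAsFactors = FALSE)
  f <- reportable_under_acmg(f, cat5)
  m <- multi_variant_carriers(f)
  expect_equal(unique(m$participant), "Q1")   # Q2 has two hits in one gene
  expect_equal(nrow(m), 2)
  # no reportable findings at all
  f2 <- f; f2$list <- "pVUS"
  f2 <- reportable_under_acmg(f2, cat5)
  expect_equal(nrow(multi_variant_carriers(f2)), 0)
})
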