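test_that("consequence ranking follows the packaged severity order", {
  expect_lt(rank_consequence("stop_gained"),
            rank_consequence("missense_variant"))
  expect_equal(rank_consequence("missense_variant"),
               rank_consequence("missense_variant"))
  expect_error(rank_consequence("made_up_term"), "made_up_term")
})

test_that("the packaged severity table gives a strict total order", {
  tab <- consequence_severity_table()
  r <- rank_consequence(tab)
  expect_equal(anyDuplicated(r), 0)           # antisymmetric
  expect_equal(sort(r), seq_along(tab))       # total
  # transitive by construction of integer ranks: check all pairs brute-force
  for (i in seq_along(tab)) {
    lower <- tab[r < r[i]]
    if (length(lower) > 0)
      expect_true(all(rank_consequence(lower) < r[i]))
  }
})

test_that("a MANE transcript is always preferred", {
  ann <- rbind(
    ann_df_row(transcript_id = "T1", is_mane = FALSE,
               consequence = "stop_gained", transcript_length = 1000L),
    ann_df_row(transcript_id = "T2", is_mane = TRUE,
               consequence = "missense_variant", transcript_length = 500L))
  ann$variant_id <- "v"
  expect_equal(select_transcript(ann)$transcript_id, "T2")
  two_mane <- ann; two_mane$is_mane <- TRUE
  expect_error(select_transcript(two_mane), "MANE")
})

test_that("without MANE, severity wins, then length, then transcript id", {
  sev <- rbind(
    ann_df_row(transcript_id = "T1", is_mane = FALSE,
               consequence = "missense_variant", transcript_length = 3000L),
    ann_df_row(transcript_id = "T2", is_mane = FALSE,
               consequence = "stop_gained", transcript_length = 1000L))
  sev$variant_id <- "v"
  expect_equal(select_transcript(sev)$transcript_id, "T2")

  len <- rbind(
    ann_df_row(transcript_id = "T1", is_mane = FALSE,
               transcript_length = 2000L),
    ann_df_row(transcript_id = "T2", is_mane = FALSE,
               transcript_length = 3500L))
  len$variant_id <- "v"
  expect_equal(select_transcript(len)$transcript_id, "T2")

  tie <- len; tie$transcript_length <- 2000L
  expect_equal(select_transcript(tie)$transcript_id, "T1")
})

test_that("multi-term consequence fields use their most severe term", {
  ann <- rbind(
    ann_df_row(transcript_id = "T1", is_mane = FALSE,
               consequence = "splice_region_variant&stop_gained",
               transcript_length = 100L),
    ann_df_row(transcript_id = "T2", is_mane = FALSE,
               consequence = "missense_variant", transcript_length = 9000L))
  ann$variant_id <- "v"
  expect_equal(select_transcript(ann)$transcript_id, "T1")
})

test_that("selection is order-insensitive and trivial for a single row", {
  set.seed(31)
  ann <- rbind(
    ann_df_row(transcript_id = "T1", is_mane = FALSE,
               consequence = "stop_gained", transcript_length = 900L),
    ann_df_row(transcript_id = "T2", is_mane = FALSE,
               consequence = "stop_gained", transcript_length = 900L),
    ann_df_row(transcript_id = "T3", is_mane = FALSE,
               consequence = "missense_variant", transcript_length = 5000L))
  ann$variant_id <- "v"
  ref_choice <- select_transcript(ann)$transcript_id
  for (i in 1:10) {
    perm <- ann[sample(nrow(ann)), , drop = FALSE]
    expect_equal(select_transcript(perm)$transcript_id, ref_choice)
  }
  single <- ann[3, , drop = FALSE]
  expect_equal(select_transcript(single)$transcript_id, "T3")
})
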