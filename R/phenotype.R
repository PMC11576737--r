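PHENOTYPE_COLUMNS <- c("participant", "ecg_abnormal", "self_heart_disease",
                       "revascularization", "family_heart_disease",
                       "self_cancer", "parent_cancer", "tumor_surgery",
                       "early_screening", "total_chol", "hdl", "ldl",
                       "hypercholesterolemia_dx", "age", "sex")

#' Read a participant phenotype table
#'
#' @param path TSV with the columns in `PHENOTYPE_COLUMNS`: logical disease
#'   flags, lipid concentrations (empty = not measured), age in years and
#'   sex (`F`/`M`).
#' @return data.frame, one row per participant.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(PHENOTYPE_COLUMNS, names(ph))
  if (length(missing_cols) > 0)
    stopf("phenotype table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  flag_cols <- c("ecg_abnormal", "self_heart_disease", "revascularization",
                 "family_heart_disease", "self_cancer", "parent_cancer",
                 "tumor_surgery", "early_screening", "hypercholesterolemia_dx")
  for (cl in flag_cols) ph[[cl]] <- as.logical(ph[[cl]])
  for (cl in c("total_chol", "hdl", "ldl")) ph[[cl]] <- as.numeric(ph[[cl]])
  ph$age <- as.numeric(ph$age)
  if (anyDuplicated(ph$participant)) stopf("duplicate participant id(s)")
  bad <- c("total_chol", "hdl", "ldl")[vapply(c("total_chol", "hdl", "ldl"),
             function(cl) any(!is.na(ph[[cl]]) & ph[[cl]] <= 0), logical(1))]
  if (length(bad) > 0)
    stopf("non-positive lipid value(s) in column(s): %s", paste(bad, collapse = ", "))
  ph[PHENOTYPE_COLUMNS]
}

#' Cardiovascular disease evidence
#'
#' Logical OR of abnormal ECG, self-reported heart disease, heart
#' revascularization (bypass, angioplasty or coronary atherectomy) and
#' parents' or siblings' history of heart disease.
#'
#' @param ph Phenotype data.frame.
#' @return Logical vector.
#' @export
derive_cvd_evidence <- function(ph) {
  with(ph, ecg_abnormal | self_heart_disease | revascularization |
         family_heart_disease)
}

#' Cancer evidence
#'
#' Logical OR of personal cancer history, parents' cancer history (or
#' cancer as cause of death), tumor-related surgery, and cancer screening
#' performed below the recommended sex-specific age.
#'
#' @param ph Phenotype data.frame.
#' @return Logical vector.
#' @export
derive_cancer_evidence <- function(ph) {
  with(ph, self_cancer | parent_cancer | tumor_surgery | early_screening)
}

#' Familial-hypercholesterolemia evidence
#'
#' A hypercholesterolemia diagnosis, or a measured LDL at or above the
#' threshold (inclusive boundary).
#'
#' @param ph Phenotype data.frame.
#' @param ldl_threshold High-LDL cutoff, mmol/L (default 4.9).
#' @return Logical vector.
#' @export
derive_fh_evidence <- function(ph, ldl_threshold = 4.9) {
  ph$hypercholesterolemia_dx | (!is.na(ph$ldl) & ph$ldl >= ldl_threshold)
}

#' Per-participant evidence flags for all three phenotype domains
#'
#' @param ph Phenotype data.frame.
#' @param ldl_threshold High-LDL cutoff for FH evidence.
#' @return data.frame: participant, cvd, cancer, fh.
#' @export
derive_evidence <- function(ph, ldl_threshold = 4.9) {
  data.frame(participant = ph$participant,
             cvd = derive_cvd_evidence(ph),
             cancer = derive_cancer_evidence(ph),
             fh = derive_fh_evidence(ph, ldl_threshold),
             stringsAsFactors = FALSE)
}

# Evidence domain a gene's carriers are screened against: FH for
# hypercholesterolemia genes, CVD for other cardiovascular genes, cancer
# for cancer genes; NA elsewhere.
gene_evidence_type <- function(genes, catalog) {
  idx <- match(genes, catalog$symbol)
  type <- ifelse(catalog$category[idx] == "cancer", "cancer",
          ifelse(catalog$category[idx] == "cardiovascular",
                 ifelse(grepl("hypercholesterolemia", catalog$phenotype[idx],
                              ignore.case = TRUE), "FH", "CVD"),
                 NA_character_))
  type
}

#' Select candidate variants for phenotype review
#'
#' A variant is a candidate iff it lies in a cardiovascular gene and at
#' least `min_cvd_carriers` of its carriers show CVD or FH evidence, or in
#' a cancer gene and at least `min_cancer_carriers` carriers show cancer
#' evidence. The stricter reading (evidenced carriers, not just carriers)
#' is the default; `rule = "any_carrier"` requires the carrier count only.
#'
#' @param carriers_by_variant Named list: variant key -> participant ids.
#' @param genes Named character: variant key -> gene symbol.
#' @param evidence data.frame from [derive_evidence()].
#' @param catalog Gene catalog data.frame.
#' @param min_cvd_carriers,min_cancer_carriers Carrier-evidence minima
#'   (defaults 2 and 1).
#' @param rule `"evidenced_carriers"` or `"any_carrier"`.
#' @return data.frame: variant_id, gene, evidence_type, carriers,
#'   evidenced_carriers, candidate.
#' @export
select_candidates <- function(carriers_by_variant, genes, evidence, catalog,
                              min_cvd_carriers = 2L, min_cancer_carriers = 1L,
                              rule = c("evidenced_carriers", "any_carrier")) {
  rule <- match.arg(rule)
  keys <- names(carriers_by_variant) %||% character()
  if (length(keys) == 0)
    return(data.frame(variant_id = character(), gene = character(),
                      evidence_type = character(), carriers = integer(),
                      evidenced_carriers = integer(), candidate = logical(),
                      stringsAsFactors = FALSE))
  etype <- gene_evidence_type(genes[keys], catalog)
  out <- data.frame(variant_id = keys, gene = unname(genes[keys]),
                    evidence_type = etype,
                    carriers = lengths(carriers_by_variant),
                    evidenced_carriers = 0L, candidate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    if (is.na(etype[i])) next
    ids <- carriers_by_variant[[i]]
    ev <- evidence[match(ids, evidence$participant), , drop = FALSE]
    has_ev <- switch(etype[i],
                     cancer = ev$cancer,
                     CVD = ev$cvd | ev$fh,
                     FH = ev$fh | ev$cvd)
    has_ev[is.na(has_ev)] <- FALSE
    out$evidenced_carriers[i] <- sum(has_ev)
    need <- if (etype[i] == "cancer") min_cancer_carriers else min_cvd_carriers
    n_eff <- if (rule == "evidenced_carriers") out$evidenced_carriers[i]
             else out$carriers[i]
    out$candidate[i] <- n_eff >= need
  }
  rownames(out) <- NULL
  out
}

#' Significance star tier for a p-value
#'
#' Strict at each boundary: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of tiers.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

# Two-sided Fisher exact p-value: sum, over tables with the observed
# margins, of hypergeometric probabilities no larger than the observed
# one (with the customary 1 + 1e-7 relative tolerance for ties).
fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Fisher exact carrier-phenotype association for one 2x2 table
#'
#' Rows are carrier/non-carrier, columns evidence/no-evidence. The
#' two-sided p-value comes from the hypergeometric null; the odds ratio is
#' the conditional maximum-likelihood estimate with its exact confidence
#' interval (the convention of the statistical environment the analysis
#' standardizes on), with the sample (cross-product) odds ratio available
#' as an alternative. A zero cell yields an infinite or zero OR estimate
#' and a one-sided-informative CI, flagged. A zero row or column margin is
#' untestable and returned as such, never as a silent p = 1.
#'
#' @param carriers_with,carriers_without Carriers with / without evidence.
#' @param noncarriers_with,noncarriers_without Non-carriers likewise.
#' @param confidence Confidence level (default 0.95).
#' @param or_method `"conditional"` (CMLE, default) or `"sample"`.
#' @return List: table (a,b,c,d), status (`"ok"` or `"untestable"`),
#'   p_value, odds_ratio, ci_low, ci_high, one_sided_ci flag, stars.
#' @export
fisher_association <- function(carriers_with, carriers_without,
                               noncarriers_with, noncarriers_without,
                               confidence = 0.95,
                               or_method = c("conditional", "sample")) {
  or_method <- match.arg(or_method)
  a <- carriers_with; b <- carriers_without
  c <- noncarriers_with; d <- noncarriers_without
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  tab <- c(a = a, b = b, c = c, d = d)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(list(table = tab, status = "untestable", p_value = NA_real_,
                odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                one_sided_ci = NA, stars = NA_character_))
  p <- fisher_p_twosided(a, b, c, d)
  ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                           conf.level = confidence)
  if (or_method == "conditional") {
    or <- unname(ft$estimate)
  } else {
    or <- if (b * c == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * c)
  }
  ci <- ft$conf.int
  list(table = tab, status = "ok", p_value = p, odds_ratio = or,
       ci_low = ci[1], ci_high = ci[2],
       one_sided_ci = (a == 0 || b == 0 || c == 0 || d == 0),
       stars = significance_stars(p))
}

#' Carrier-phenotype association for all candidate variants
#'
#' Builds each variant's 2x2 table over the phenotyped participants
#' (carriers vs non-carriers crossed with matching disease evidence) and
#' runs [fisher_association()]. Raw p-values are starred, mirroring
#' screening practice; a Benjamini-Hochberg adjusted column is emitted
#' alongside for transparency but never alters the star tier.
#'
#' @param candidates data.frame from [select_candidates()] (only rows with
#'   `candidate = TRUE` are tested).
#' @param carriers_by_variant Named list: variant key -> participant ids.
#' @param evidence data.frame from [derive_evidence()].
#' @param confidence Confidence level.
#' @param or_method Passed to [fisher_association()].
#' @return data.frame: variant_id, gene, evidence_type, a, b, c, d,
#'   odds_ratio, ci_low, ci_high, p_value, p_adj_bh, stars, status.
#' @export
associate_candidates <- function(candidates, carriers_by_variant, evidence,
                                 confidence = 0.95,
                                 or_method = c("conditional", "sample")) {
  or_method <- match.arg(or_method)
  cand <- candidates[isTRUE_vec(candidates$candidate), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    key <- cand$variant_id[i]
    ids <- carriers_by_variant[[key]]
    carrier <- evidence$participant %in% ids
    ev <- switch(cand$evidence_type[i],
                 cancer = evidence$cancer,
                 CVD = evidence$cvd | evidence$fh,
                 FH = evidence$fh | evidence$cvd)
    fa <- fisher_association(sum(carrier & ev), sum(carrier & !ev),
                             sum(!carrier & ev), sum(!carrier & !ev),
                             confidence, or_method)
    data.frame(variant_id = key, gene = cand$gene[i],
               evidence_type = cand$evidence_type[i],
               a = fa$table[["a"]], b = fa$table[["b"]],
               c = fa$table[["c"]], d = fa$table[["d"]],
               odds_ratio = fa$odds_ratio, ci_low = fa$ci_low,
               ci_high = fa$ci_high, p_value = fa$p_value,
               stars = fa$stars, status = fa$status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(variant_id = character(), gene = character(),
               evidence_type = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), odds_ratio = numeric(),
               ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
               stars = character(), status = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
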