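CLASSIFICATION_LISTS <- c("P1", "P2", "LP1", "LP2", "pVUS", "rejected",
                          "unclassified")

# Consequence classes counted as loss-of-function for the LP1 rule:
# nonsense, frameshift, canonical splice site, insertion/deletion.
LOF_CONSEQUENCES <- c("stop_gained", "frameshift_variant",
                      "splice_acceptor_variant", "splice_donor_variant",
                      "inframe_insertion", "inframe_deletion")

#' Classification thresholds
#'
#' All comparisons are strict in the stated direction: cohort MAF < 2%
#' overall, MAF < 0.1% for the rare (LP1/LP2/pVUS) rules, REVEL > 0.7,
#' carriers > 1, ClinVar review stars >= 2 for P2.
#'
#' @param global_maf_max Cohort minor-allele-frequency ceiling for any
#'   variant to enter classification (default 0.02).
#' @param rare_maf_max Rarity ceiling (cohort and gnomAD) for LP1/LP2/pVUS
#'   (default 0.001).
#' @param revel_min REVEL score that missense variants must exceed
#'   (default 0.7).
#' @param min_carriers_lp2 Minimum distinct genotype-positive participants
#'   for LP2/pVUS (default 2, i.e. "more than one").
#' @param min_stars_p2 Minimum ClinVar gold stars for P2 (default 2).
#' @return An object of class `sft_thresholds`.
#' @export
sft_thresholds <- function(global_maf_max = 0.02, rare_maf_max = 0.001,
                           revel_min = 0.7, min_carriers_lp2 = 2L,
                           min_stars_p2 = 2L) {
  stopifnot(rare_maf_max > 0, rare_maf_max < global_maf_max,
            global_maf_max < 0.5, revel_min > 0, revel_min < 1,
            min_carriers_lp2 >= 1, min_stars_p2 >= 0)
  structure(list(global_maf_max = global_maf_max, rare_maf_max = rare_maf_max,
                 revel_min = revel_min,
                 min_carriers_lp2 = as.integer(min_carriers_lp2),
                 min_stars_p2 = as.integer(min_stars_p2)),
            class = "sft_thresholds")
}

#' @export
#' @method print sft_thresholds
print.sft_thresholds <- function(x, ...) {
  cat("Classification thresholds:\n")
  cat(sprintf("  global cohort MAF   < %g\n", x$global_maf_max))
  cat(sprintf("  rare MAF (cohort and gnomAD) < %g\n", x$rare_maf_max))
  cat(sprintf("  REVEL               > %g\n", x$revel_min))
  cat(sprintf("  LP2/pVUS carriers  >= %d\n", x$min_carriers_lp2))
  cat(sprintf("  P2 ClinVar stars   >= %d\n", x$min_stars_p2))
  invisible(x)
}

#' Global minor-allele-frequency gate
#'
#' @param cohort_maf Cohort minor allele frequency.
#' @param t Thresholds from [sft_thresholds()].
#' @return TRUE iff `cohort_maf < t$global_maf_max` (strict).
#' @export
passes_global_maf <- function(cohort_maf, t = sft_thresholds()) {
  cohort_maf < t$global_maf_max
}

#' Benign rejection rule
#'
#' @param clinvar_significance ClinVar-style significance (NA = absent).
#' @return TRUE iff significance is B, LB or B/LB; absent values proceed.
#' @export
reject_benign <- function(clinvar_significance) {
  !is.na(clinvar_significance) & clinvar_significance %in% c("B", "LB", "B/LB")
}

clinvar_plp <- function(sig) !is.na(sig) & sig %in% c("P", "LP", "P/LP")

# "Novel" = absent from dbSNP, gnomAD, ClinVar and HGMD, all four.
is_novel <- function(ann) {
  is.na(ann$dbsnp_id) && is.na(ann$gnomad_af) &&
    is.na(ann$clinvar_significance) && is.na(ann$hgmd_class)
}

#' Validated-pathogenic (P1/P2) rule
#'
#' P1: ClinVar P/LP and HGMD DM. A ClinVar P/LP variant with a non-DM HGMD
#' entry has conflicting pathogenicity annotation and is excluded from both
#' P sub-lists (and, downstream, from LP evaluation). P2: ClinVar P/LP, no
#' HGMD entry, and at least `min_stars_p2` review stars.
#'
#' @param ann One-row annotation (selected transcript).
#' @param t Thresholds.
#' @return `"P1"`, `"P2"`, `"conflict"` or `"none"`.
#' @export
classify_p <- function(ann, t = sft_thresholds()) {
  if (!clinvar_plp(ann$clinvar_significance)) return("none")
  if (!is.na(ann$hgmd_class)) {
    if (ann$hgmd_class == "DM") return("P1")
    return("conflict")
  }
  if (!is.na(ann$clinvar_stars) && ann$clinvar_stars >= t$min_stars_p2)
    return("P2")
  "none"
}

#' Likely-pathogenic loss-of-function (LP1) rule
#'
#' Rare high-impact loss-of-function variants: consequence in the LOF
#' class, PVS1 at Very Strong, VEP impact HIGH, cohort MAF and gnomAD AF
#' below the rarity ceiling (a variant unseen in gnomAD counts as rare
#' there), in a gene where loss of function is a known disease mechanism.
#'
#' @param ann One-row annotation (selected transcript).
#' @param cohort_maf Cohort minor allele frequency.
#' @param t Thresholds.
#' @param lof_gene Catalog flag: LOF is a known mechanism for this gene.
#' @return TRUE/FALSE.
#' @export
classify_lp1 <- function(ann, cohort_maf, t = sft_thresholds(), lof_gene = TRUE) {
  terms <- split_consequences(ann$consequence)
  is_lof <- any(terms %in% LOF_CONSEQUENCES)
  is_lof &&
    !is.na(ann$pvs1_strength) && ann$pvs1_strength == "VeryStrong" &&
    !is.na(ann$impact) && ann$impact == "HIGH" &&
    cohort_maf < t$rare_maf_max &&
    (is.na(ann$gnomad_af) || ann$gnomad_af < t$rare_maf_max) &&
    isTRUE(lof_gene)
}

#' Rare-missense (LP2 / pVUS) rule
#'
#' Applies to missense variants that are ClinVar VUS, have conflicting
#' interpretation, or are novel. When the variant is rare (cohort and
#' gnomAD), carried by more than one participant, REVEL-predicted
#' deleterious, in a cancer or cardiovascular gene, and its carriers show
#' the matching disease evidence, the external combinatory verdict decides:
#' P/LP verdict gives LP2, anything else gives pVUS.
#'
#' @param ann One-row annotation (selected transcript).
#' @param cohort_maf Cohort minor allele frequency.
#' @param carriers Distinct genotype-positive participants for the variant.
#' @param t Thresholds.
#' @param gene_category Catalog disease category of the gene.
#' @param cohort_evidence TRUE when carriers show matching disease evidence
#'   (see [select_candidates()]).
#' @return `"LP2"`, `"pVUS"` or `"none"`.
#' @export
classify_lp2_pvus <- function(ann, cohort_maf, carriers, t = sft_thresholds(),
                              gene_category = NA_character_,
                              cohort_evidence = FALSE) {
  terms <- split_consequences(ann$consequence)
  if (!"missense_variant" %in% terms) return("none")
  sig <- ann$clinvar_significance
  eligible_sig <- (!is.na(sig) && sig %in% c("VUS", "conflicting")) || is_novel(ann)
  if (!eligible_sig) return("none")
  ok <- cohort_maf < t$rare_maf_max &&
    (is.na(ann$gnomad_af) || ann$gnomad_af < t$rare_maf_max) &&
    carriers >= t$min_carriers_lp2 &&
    !is.na(ann$revel) && ann$revel > t$revel_min &&
    !is.na(gene_category) && gene_category %in% c("cancer", "cardiovascular") &&
    isTRUE(cohort_evidence)
  if (!ok) return("none")
  if (!is.na(ann$external_verdict) && ann$external_verdict %in% c("P", "LP"))
    "LP2" else "pVUS"
}

#' Master classification decision tree
#'
#' Applies, in order: global MAF gate, benign rejection, validated-
#' pathogenic (P1/P2), loss-of-function LP1, rare-missense LP2/pVUS; a
#' variant surviving all rules without a list is `unclassified`. Every rule
#' fired is recorded in `reasons`.
#'
#' @param ann One-row annotation (selected transcript).
#' @param cohort_maf Cohort minor allele frequency.
#' @param carriers Distinct genotype-positive participants.
#' @param t Thresholds.
#' @param gene_entry One-row catalog entry for the variant's gene (used for
#'   `category` and `lof_gene`); may be NULL if unknown.
#' @param cohort_evidence Disease-evidence flag for LP2/pVUS.
#' @return List with `list` (one of P1, P2, LP1, LP2, pVUS, rejected,
#'   unclassified) and `reasons` (character vector of rule ids).
#' @export
classify_variant <- function(ann, cohort_maf, carriers, t = sft_thresholds(),
                             gene_entry = NULL, cohort_evidence = FALSE) {
  reasons <- character()
  if (!passes_global_maf(cohort_maf, t))
    return(list(list = "rejected", reasons = "global_maf_fail"))
  reasons <- c(reasons, "global_maf_pass")
  if (reject_benign(ann$clinvar_significance))
    return(list(list = "rejected", reasons = c(reasons, "clinvar_benign")))
  p <- classify_p(ann, t)
  if (p == "P1")
    return(list(list = "P1", reasons = c(reasons, "p1_clinvar_plp_hgmd_dm")))
  if (p == "P2")
    return(list(list = "P2", reasons = c(reasons, "p2_clinvar_plp_stars")))
  if (p == "conflict")
    return(list(list = "unclassified",
                reasons = c(reasons, "clinvar_hgmd_conflict_excluded")))
  lof_gene <- if (is.null(gene_entry)) TRUE else isTRUE(gene_entry$lof_gene)
  category <- if (is.null(gene_entry)) NA_character_ else gene_entry$category
  if (classify_lp1(ann, cohort_maf, t, lof_gene))
    return(list(list = "LP1", reasons = c(reasons, "lp1_rare_high_impact_lof")))
  lp2 <- classify_lp2_pvus(ann, cohort_maf, carriers, t, category, cohort_evidence)
  if (lp2 == "LP2")
    return(list(list = "LP2", reasons = c(reasons, "lp2_rare_missense_verdict_plp")))
  if (lp2 == "pVUS")
    return(list(list = "pVUS", reasons = c(reasons, "pvus_rare_missense_no_plp_verdict")))
  list(list = "unclassified", reasons = reasons)
}

#' Classify every variant of a cohort
#'
#' Vectorized driver over [classify_variant()].
#'
#' @param variants data.frame from [cohort_variants()] (rownames = keys).
#' @param selected data.frame of selected transcript annotations
#'   (rownames = variant keys, as from [select_transcripts()]).
#' @param carriers Named integer vector: distinct genotype-positive
#'   participants per variant key.
#' @param catalog Gene catalog data.frame.
#' @param t Thresholds.
#' @param cohort_evidence Named logical vector per variant key (default all
#'   FALSE, i.e. no phenotype data available).
#' @return data.frame: variant columns + `list` + `reasons`
#'   (semicolon-joined).
#' @export
classify_cohort <- function(variants, selected, carriers, catalog,
                            t = sft_thresholds(), cohort_evidence = NULL) {
  keys <- rownames(variants)
  out_list <- character(length(keys))
  out_reasons <- character(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% rownames(selected)) {
      out_list[i] <- "unclassified"
      out_reasons[i] <- "no_annotation"
      next
    }
    ann <- selected[k, , drop = FALSE]
    ge <- catalog[catalog$symbol == variants$gene[i], , drop = FALSE]
    carr <- if (k %in% names(carriers)) carriers[[k]] else 0L
    evid <- !is.null(cohort_evidence) && k %in% names(cohort_evidence) &&
      isTRUE(cohort_evidence[[k]])
    res <- classify_variant(
      ann, variants$cohort_maf[i], carr, t,
      gene_entry = if (nrow(ge) == 1) ge else NULL,
      cohort_evidence = evid)
    out_list[i] <- res$list
    out_reasons[i] <- paste(res$reasons, collapse = ";")
  }
  cbind(variants,
        data.frame(list = out_list, reasons = out_reasons,
                   stringsAsFactors = FALSE))
}
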