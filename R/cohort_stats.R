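REPORTABLE_LISTS <- c("P1", "P2", "LP1", "LP2")

#' Identify genotype-positive participants
#'
#' One finding per (participant, variant) pair with dosage >= 1 at a
#' variant assigned to the P, LP or pVUS lists. Zygosity is HOM for
#' dosage 2, HET for dosage 1.
#'
#' @param classified data.frame from [classify_cohort()] (rownames = keys).
#' @param dosage Integer matrix, samples x variants (colnames = keys).
#' @return data.frame: participant, variant_id, gene, list, zygosity,
#'   dosage.
#' @export
identify_gpps <- function(classified, dosage) {
  keys <- rownames(classified)[classified$list %in% c(REPORTABLE_LISTS, "pVUS")]
  missing_keys <- setdiff(keys, colnames(dosage))
  if (length(missing_keys) > 0)
    stopf("classified variant(s) absent from genotype matrix: %s",
          paste(missing_keys, collapse = ", "))
  out <- list()
  for (k in keys) {
    d <- dosage[, k]
    hit <- which(!is.na(d) & d >= 1)
    if (length(hit) == 0) next
    out[[k]] <- data.frame(
      participant = rownames(dosage)[hit],
      variant_id = k,
      gene = classified[k, "gene"],
      list = classified[k, "list"],
      zygosity = ifelse(d[hit] == 2, "HOM", "HET"),
      dosage = as.integer(d[hit]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(participant = character(), variant_id = character(),
                      gene = character(), list = character(),
                      zygosity = character(), dosage = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the ACMG secondary-findings reportability rule
#'
#' A finding is reportable iff its variant is P or LP (never pVUS) and the
#' inheritance supports it: dominant and semidominant genes report
#' heterozygous carriers; recessive genes report only biallelic
#' participants, i.e. homozygotes or carriers of two distinct P/LP
#' variants in the same gene (treated as biallelic without phase, flagged
#' `phase_unknown`). Heterozygous single-variant carriers in recessive
#' genes are flagged `carrier_only`. X-linked genes are treated like
#' dominant ones here (no hemizygous logic is modeled).
#'
#' @param findings data.frame from [identify_gpps()].
#' @param catalog Gene catalog data.frame.
#' @return `findings` with added columns `inheritance`, `reportable`,
#'   `carrier_only`, `phase_unknown`.
#' @export
reportable_under_acmg <- function(findings, catalog) {
  if (nrow(findings) == 0) {
    findings$inheritance <- character(0)
    findings$reportable <- logical(0)
    findings$carrier_only <- logical(0)
    findings$phase_unknown <- logical(0)
    return(findings)
  }
  inh <- catalog$inheritance[match(findings$gene, catalog$symbol)]
  if (anyNA(inh))
    stopf("finding(s) in gene(s) absent from catalog: %s",
          paste(unique(findings$gene[is.na(inh)]), collapse = ", "))
  findings$inheritance <- inh
  is_plp <- findings$list %in% REPORTABLE_LISTS
  dominant_like <- inh %in% c("AD", "SD", "XL")
  # second distinct P/LP variant in the same gene for the same participant
  pg <- paste(findings$participant, findings$gene, sep = "\r")
  plp_variants_pg <- tapply(ifelse(is_plp, findings$variant_id, NA_character_),
                            pg, function(v) length(unique(stats::na.omit(v))))
  n_plp_same_gene <- as.integer(plp_variants_pg[pg])
  second_hit <- is_plp & (n_plp_same_gene >= 2L)
  biallelic <- findings$zygosity == "HOM" | second_hit
  findings$reportable <- is_plp & (dominant_like | (inh == "AR" & biallelic))
  findings$carrier_only <- is_plp & inh == "AR" & !biallelic
  findings$phase_unknown <- findings$reportable & inh == "AR" &
    findings$zygosity == "HET" & second_hit
  findings
}

#' One-proportion prevalence estimate with confidence interval
#'
#' The default interval is the Wald form of the one-proportion z-test,
#' `p +/- z * sqrt(p(1-p)/n)`, clamped to \[0, 1\]; a Wilson score interval
#' (via [stats::prop.test()] without continuity correction) is available.
#'
#' @param numerator Count of genotype-positive participants.
#' @param denominator Cohort size (> 0).
#' @param confidence Confidence level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return Object of class `sft_prevalence`: numerator, denominator,
#'   proportion, ci_low, ci_high, confidence, method.
#' @export
prevalence <- function(numerator, denominator, confidence = 0.95,
                       method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (denominator <= 0) stopf("prevalence denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stopf("numerator must lie in [0, denominator]")
  p <- numerator / denominator
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    half <- z * sqrt(p * (1 - p) / denominator)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    ci <- stats::prop.test(numerator, denominator, conf.level = confidence,
                           correct = FALSE)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  structure(list(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 proportion = p, ci_low = lo, ci_high = hi,
                 confidence = confidence, method = method),
            class = "sft_prevalence")
}

#' @export
#' @method print sft_prevalence
print.sft_prevalence <- function(x, digits = 1, ...) {
  cat(sprintf("%d / %d = %s%% (%d%% CI %s-%s%%, %s)\n",
              x$numerator, x$denominator,
              format_percent(x$proportion, digits),
              round(100 * x$confidence),
              format_percent(x$ci_low, digits + 1),
              format_percent(x$ci_high, digits + 1),
              x$method))
  invisible(x)
}

#' Per-gene and per-category summary of findings
#'
#' Distinct variant and participant counts per gene (with a HET/HOM split
#' of participants; a participant is HOM for a gene if any finding there is
#' homozygous) and per disease category. A participant carrying variants in
#' two categories counts once per category but once in the overall distinct
#' count.
#'
#' @param findings data.frame from [reportable_under_acmg()].
#' @param catalog Gene catalog data.frame.
#' @return List with `by_gene`, `by_category` data.frames and
#'   `distinct_gpp` (overall distinct participants).
#' @export
summarize_by_category <- function(findings, catalog) {
  cat_of <- function(g) catalog$category[match(g, catalog$symbol)]
  by_gene <- do.call(rbind, lapply(split(findings, findings$gene), function(fg) {
    zyg <- tapply(fg$zygosity == "HOM", fg$participant, any)
    data.frame(gene = fg$gene[1],
               inheritance = catalog$inheritance[match(fg$gene[1], catalog$symbol)],
               category = cat_of(fg$gene[1]),
               variants = length(unique(fg$variant_id)),
               gpp = length(unique(fg$participant)),
               het = sum(!zyg), hom = sum(zyg),
               phenotype = catalog$phenotype[match(fg$gene[1], catalog$symbol)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_gene))
    by_gene <- data.frame(gene = character(), inheritance = character(),
                          category = character(), variants = integer(),
                          gpp = integer(), het = integer(), hom = integer(),
                          phenotype = character(), stringsAsFactors = FALSE)
  rownames(by_gene) <- NULL
  findings$category <- cat_of(findings$gene)
  rep_f <- findings[isTRUE_vec(findings$reportable), , drop = FALSE]
  total_rep_gpp <- length(unique(rep_f$participant))
  total_rep_var <- length(unique(rep_f$variant_id))
  by_category <- do.call(rbind, lapply(split(findings, findings$category), function(fc) {
    rc <- fc[isTRUE_vec(fc$reportable), , drop = FALSE]
    data.frame(category = fc$category[1],
               variants = length(unique(fc$variant_id)),
               gpp = length(unique(fc$participant)),
               reportable_variants = length(unique(rc$variant_id)),
               reportable_gpp = length(unique(rc$participant)),
               share_reportable_gpp_pct = if (total_rep_gpp > 0)
                 format_percent(length(unique(rc$participant)) / total_rep_gpp, 1)
                 else NA_real_,
               share_reportable_variants_pct = if (total_rep_var > 0)
                 format_percent(length(unique(rc$variant_id)) / total_rep_var, 1)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_category))
    by_category <- data.frame(category = character(), variants = integer(),
                              gpp = integer(), reportable_variants = integer(),
                              reportable_gpp = integer(),
                              share_reportable_gpp_pct = numeric(),
                              share_reportable_variants_pct = numeric(),
                              stringsAsFactors = FALSE)
  rownames(by_category) <- NULL
  list(by_gene = by_gene, by_category = by_category,
       distinct_gpp = length(unique(findings$participant)))
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Participants with reportable findings in several genes
#'
#' @param findings data.frame from [reportable_under_acmg()].
#' @return data.frame (participant, gene, variant_id, list) restricted to
#'   participants with reportable findings in >= 2 distinct genes.
#' @export
multi_variant_carriers <- function(findings) {
  rep_f <- findings[isTRUE_vec(findings$reportable), , drop = FALSE]
  genes_per <- tapply(rep_f$gene, rep_f$participant,
                      function(g) length(unique(g)))
  multi <- names(genes_per)[genes_per >= 2]
  out <- rep_f[rep_f$participant %in% multi,
               c("participant", "gene", "variant_id", "list"), drop = FALSE]
  out <- out[order(out$participant, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
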