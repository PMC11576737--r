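TRUTH_CLASSES <- c("P1", "P2", "LP1", "LP2", "pVUS", "benign", "common",
                   "unclassified")

expected_list_for <- function(truth) {
  ifelse(truth %in% c("benign", "common"), "rejected",
  ifelse(truth %in% c("P1", "P2", "LP1", "LP2", "pVUS", "unclassified"),
         truth, "filtered"))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the cohort the simulator emulates: size, a cohort-wide
#' inbreeding coefficient F inflating homozygosity (`q^2 + Fq(1-q)` for
#' the alternate homozygote), planted variants with truth classes covering
#' every classification branch, and phenotype baselines with planted
#' carrier-phenotype odds ratios.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; every draw derives from it.
#' @param inbreeding_f Inbreeding coefficient in \[0, 1).
#' @param variant_specs data.frame as from [default_variant_specs()].
#' @param phenotype_baseline Named baseline prevalences for the composite
#'   CVD, cancer and FH evidence flags among non-carriers.
#' @param missing_rate Per-call genotype missingness (never applied to the
#'   deterministically planted carriers of rare variants).
#' @param ldl_threshold High-LDL cutoff (mmol/L) used for FH evidence.
#' @param screening_age Sex-specific recommended cancer-screening ages.
#' @return List of class `sft_sim_config`.
#' @export
sim_config <- function(n_participants = 2000L, seed = 1L,
                       inbreeding_f = 0.0625,
                       variant_specs = default_variant_specs(),
                       phenotype_baseline = c(CVD = 0.10, cancer = 0.05, FH = 0.05),
                       missing_rate = 0.001,
                       ldl_threshold = 4.9,
                       screening_age = c(F = 45, M = 50)) {
  stopifnot(n_participants >= 2, inbreeding_f >= 0, inbreeding_f < 1,
            all(variant_specs$af > 0), all(variant_specs$af <= 0.5),
            all(c("CVD", "cancer", "FH") %in% names(phenotype_baseline)))
  bad_or <- !is.na(variant_specs$planted_or) &
    !(variant_specs$evidence_type %in% c("CVD", "cancer", "FH"))
  if (any(bad_or)) stopf("planted_or requires an evidence_type")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), inbreeding_f = inbreeding_f,
                 variant_specs = variant_specs,
                 phenotype_baseline = phenotype_baseline,
                 missing_rate = missing_rate, ldl_threshold = ldl_threshold,
                 screening_age = screening_age),
            class = "sft_sim_config")
}

spec_row <- function(gene, truth, af, recipe = truth, type = "snv",
                     consequence = NA, planted_or = NA_real_,
                     evidence_type = NA_character_, mode = NA_character_,
                     site_group = NA_character_, force_hom_n = 0L,
                     comphet_with = NA_character_,
                     force_evidence = "auto", mane = TRUE,
                     write_style = "plain", filter = "PASS",
                     off_gene = FALSE, id = NA_character_) {
  if (is.na(mode))
    mode <- if (truth %in% c("benign", "common")) "hw" else "planted"
  data.frame(id = id, gene = gene, truth = truth, recipe = recipe, af = af,
             type = type, consequence = consequence, planted_or = planted_or,
             evidence_type = evidence_type, mode = mode,
             site_group = site_group, force_hom_n = force_hom_n,
             comphet_with = comphet_with, force_evidence = force_evidence,
             mane = mane, write_style = write_style, filter = filter,
             off_gene = off_gene, stringsAsFactors = FALSE)
}

#' Default planted-variant specification (40 variants)
#'
#' Spans every truth class, adversarial near-misses (one field off the
#' LP1/LP2 recipes), a recessive homozygote, a compound heterozygote, a
#' multi-allelic site, a spanning-deletion allele, padded and right-shifted
#' indel representations, and off-gene / non-PASS decoy sites.
#'
#' @return data.frame of variant specifications.
#' @export
default_variant_specs <- function() {
  rows <- list(
    spec_row("BRCA1", "P1", 0.002),
    spec_row("ATP7B", "P1", 0.003, force_hom_n = 1L, id = "atp7b_a"),
    spec_row("ATP7B", "P1", 0.002, comphet_with = "atp7b_a"),
    spec_row("MUTYH", "P1", 0.005),
    spec_row("MSH6", "P2", 0.004),
    spec_row("LDLR", "P2", 0.003),
    spec_row("TTN", "LP1", 4e-4, consequence = "stop_gained", mane = FALSE),
    spec_row("TTN", "LP1", 3e-4, consequence = "frameshift_variant",
             type = "del", write_style = "padded"),
    spec_row("KCNQ1", "LP1", 4e-4, consequence = "splice_acceptor_variant"),
    spec_row("TTN", "LP1", 3e-4, consequence = "frameshift_variant",
             type = "del", write_style = "right_shifted"),
    spec_row("MYH7", "LP2", 5e-4, planted_or = 6, evidence_type = "CVD"),
    spec_row("MSH2", "LP2", 4e-4, planted_or = 8, evidence_type = "cancer"),
    spec_row("LDLR", "LP2", 5e-4, planted_or = 6, evidence_type = "FH"),
    spec_row("DSG2", "pVUS", 5e-4, recipe = "pVUS_novel", planted_or = 4,
             evidence_type = "CVD"),
    spec_row("LMNA", "pVUS", 5e-4, planted_or = 4, evidence_type = "CVD"),
    spec_row("MSH6", "pVUS", 4e-4, recipe = "pVUS_verdict_b", planted_or = 6,
             evidence_type = "cancer"),
    spec_row("TSC2", "pVUS", 4e-4, recipe = "pVUS_novel", planted_or = 6,
             evidence_type = "cancer"),
    spec_row("BRCA2", "benign", 0.002, recipe = "benign_decoy_transcript"),
    spec_row("TTN", "benign", 0.010),
    spec_row("RYR1", "benign", 0.012, recipe = "benign_blb"),
    spec_row("APC", "benign", 0.004),
    spec_row("SCN5A", "benign", 0.008),
    spec_row("TTN", "common", 0.05),
    spec_row("ATP7B", "common", 0.08),
    spec_row("RYR1", "unclassified", 4e-4, recipe = "lp1_nolof_gene",
             consequence = "stop_gained"),
    spec_row("TTN", "unclassified", 4e-4, recipe = "lp1_impact_moderate",
             consequence = "stop_gained"),
    spec_row("TTN", "unclassified", 4e-4, recipe = "lp1_pvs1_moderate",
             consequence = "stop_gained"),
    spec_row("TTN", "unclassified", 5e-3, recipe = "lp1_common",
             consequence = "stop_gained", mode = "hw"),
    spec_row("MYH7", "unclassified", 5e-4, recipe = "lp2_revel_low"),
    spec_row("MSH2", "unclassified", 4e-4, recipe = "lp2_revel_boundary"),
    spec_row("DSG2", "unclassified", 2.5e-4, recipe = "lp2_single_carrier"),
    spec_row("BRCA1", "unclassified", 0.003, recipe = "p_conflict"),
    spec_row("MYH7", "unclassified", 5e-4, recipe = "lp2_no_evidence",
             force_evidence = "none"),
    spec_row("HNF1A", "unclassified", 5e-4, recipe = "lp2_misc_gene"),
    spec_row("DSC2", "P1", 0.004, mode = "hw", site_group = "mg1"),
    spec_row("DSC2", "benign", 0.008, site_group = "mg1"),
    spec_row("PKP2", "benign", 0.005, site_group = "mg2"),
    spec_row("PKP2", "star", 0.001, recipe = "star", type = "star",
             mode = "zero", site_group = "mg2"),
    spec_row("BRCA2", "nonpass", 0.004, recipe = "benign", mode = "hw",
             filter = "LowQual"),
    spec_row("TTN", "offgene", 0.004, recipe = "benign", mode = "hw",
             off_gene = TRUE))
  specs <- do.call(rbind, rows)
  specs$id <- ifelse(is.na(specs$id),
                     sprintf("v%02d_%s_%s", seq_len(nrow(specs)), specs$gene,
                             specs$truth),
                     specs$id)
  specs
}

#' A small demonstration configuration
#'
#' 500 participants and 12 variants drawn from the classes a cohort this
#' small can express: at 1000 alleles no variant can sit strictly below
#' the 0.1% rarity ceiling, so the rare LP/pVUS classes are left to
#' full-size configurations.
#'
#' @param seed Integer seed.
#' @return `sft_sim_config` with 500 participants and 12 variants.
#' @export
demo_config <- function(seed = 42L) {
  specs <- default_variant_specs()
  keep <- specs$truth %in% c("P1", "P2", "benign", "common")
  specs <- specs[keep, ][1:12, ]
  specs$comphet_with <- NA_character_
  specs$site_group <- NA_character_
  sim_config(n_participants = 500L, seed = seed, variant_specs = specs)
}

# Gene layout on a single synthetic chromosome: 2 kb per catalog gene,
# 1 kb spacers, 1-based closed intervals.
sim_layout <- function(catalog) {
  n <- nrow(catalog)
  width <- 2000L; gap <- 1000L
  start <- gap + (seq_len(n) - 1L) * (width + gap) + 1L
  data.frame(chrom = "chr1", start = start, end = start + width - 1L,
             symbol = catalog$symbol, stringsAsFactors = FALSE)
}

sim_reference <- function(cfg, layout) {
  set.seed(cfg$seed + 2L)
  len <- max(layout$end) + 2000L
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  c(chr1 = seq)
}

# Assign genomic coordinates and written/normalized representations to all
# variant specs, editing the reference where repeat context is needed.
place_variants <- function(specs, layout, reference) {
  seqs <- reference
  chrom <- "chr1"
  specs$pos_truth <- NA_integer_; specs$ref_truth <- NA_character_
  specs$alt_truth <- NA_character_
  specs$pos_w <- NA_integer_; specs$ref_w <- NA_character_
  specs$alt_w <- NA_character_
  sub_base <- function(s, at, base) {
    substr(s, at, at + nchar(base) - 1L) <- base
    s
  }
  other_base <- function(b) c(A = "C", C = "A", G = "T", T = "G", N = "A")[[b]]
  offset_in_gene <- stats::ave(seq_len(nrow(specs)), specs$gene,
                               FUN = seq_along)
  for (i in seq_len(nrow(specs))) {
    g <- layout[layout$symbol == specs$gene[i], ]
    pos <- if (specs$off_gene[i]) max(layout$end) + 500L
           else g$start + 150L + 60L * offset_in_gene[i]
    if (!is.na(specs$site_group[i])) {
      prev <- which(!is.na(specs$site_group) &
                    specs$site_group == specs$site_group[i])
      prev <- prev[prev < i]
      if (length(prev) > 0) pos <- specs$pos_truth[prev[1]]
    }
    style <- specs$write_style[i]
    if (specs$type[i] == "star") {
      specs$pos_truth[i] <- pos
      specs$ref_truth[i] <- substr(seqs[[chrom]], pos, pos)
      specs$alt_truth[i] <- "*"
      specs$pos_w[i] <- pos; specs$ref_w[i] <- specs$ref_truth[i]
      specs$alt_w[i] <- "*"
      next
    }
    if (specs$type[i] == "snv") {
      ref <- substr(seqs[[chrom]], pos, pos)
      alt <- other_base(ref)
      if (!is.na(specs$site_group[i])) {
        sibs <- which(!is.na(specs$site_group) &
                      specs$site_group == specs$site_group[i] &
                      seq_len(nrow(specs)) < i & specs$type == "snv")
        taken <- c(ref, specs$alt_truth[sibs])
        alt <- setdiff(c("A", "C", "G", "T"), taken)[1]
      }
      specs$pos_truth[i] <- pos; specs$ref_truth[i] <- ref
      specs$alt_truth[i] <- alt
      specs$pos_w[i] <- pos; specs$ref_w[i] <- ref; specs$alt_w[i] <- alt
      next
    }
    # single-base deletion; reference locally rewritten for the style
    if (style == "right_shifted") {
      # G AAAAAA C : truth = GA>G at the anchor, written 5 bases right
      seqs[[chrom]] <- sub_base(seqs[[chrom]], pos, "GAAAAAAC")
      specs$pos_truth[i] <- pos
      specs$ref_truth[i] <- "GA"; specs$alt_truth[i] <- "G"
      specs$pos_w[i] <- pos + 5L
      specs$ref_w[i] <- "AA"; specs$alt_w[i] <- "A"
    } else {
      # non-repeat context: T C A G -> deletion CA>C, optionally written
      # with a shared trailing G
      seqs[[chrom]] <- sub_base(seqs[[chrom]], pos - 1L, "TCAG")
      specs$pos_truth[i] <- pos
      specs$ref_truth[i] <- "CA"; specs$alt_truth[i] <- "C"
      if (style == "padded") {
        specs$pos_w[i] <- pos; specs$ref_w[i] <- "CAG"; specs$alt_w[i] <- "CG"
      } else {
        specs$pos_w[i] <- pos; specs$ref_w[i] <- "CA"; specs$alt_w[i] <- "C"
      }
    }
  }
  specs$variant_id <- variant_key(chrom, specs$pos_truth, specs$ref_truth,
                                  specs$alt_truth)
  list(specs = specs, reference = seqs)
}

# Draw one site group's dosages under HWE with inbreeding: with
# probability F one parental allele is copied (identical by descent),
# otherwise two independent draws from the allele frequencies.
draw_site_group <- function(n, afs, f) {
  k <- length(afs)
  probs <- c(1 - sum(afs), afs)
  a1 <- sample.int(k + 1L, n, replace = TRUE, prob = probs) - 1L
  a2 <- sample.int(k + 1L, n, replace = TRUE, prob = probs) - 1L
  ibd <- stats::runif(n) < f
  a2[ibd] <- a1[ibd]
  vapply(seq_len(k), function(j) (a1 == j) + (a2 == j), integer(n))
}

#' Simulate cohort genotypes
#'
#' Hardy-Weinberg draws with a cohort-wide inbreeding coefficient for
#' `mode = "hw"` specs (genotype probabilities `q^2 + Fq(1-q)`,
#' `2q(1-q)(1-F)`, `(1-q)^2 + Fq(1-q)`), deterministic carrier planting for
#' `mode = "planted"` rare specs (allele count bounded so each truth class
#' keeps its rarity guarantees), and zero dosage for decoy alleles. Specs
#' sharing a `site_group` are drawn jointly from one allele pool.
#'
#' @param cfg [sim_config()] object.
#' @return Integer matrix, participants x specs (colnames = spec ids,
#'   NA = missing call).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  specs <- cfg$variant_specs
  n <- cfg$n_participants
  dosage <- matrix(0L, nrow = n, ncol = nrow(specs),
                   dimnames = list(sprintf("P%05d", seq_len(n)), specs$id))
  group <- ifelse(is.na(specs$site_group),
                  paste0("solo", seq_len(nrow(specs))), specs$site_group)
  for (gids in split(seq_len(nrow(specs)), group)) {
    sub <- specs[gids, , drop = FALSE]
    hw <- sub$mode == "hw"
    if (any(hw)) {
      d <- draw_site_group(n, sub$af[hw], cfg$inbreeding_f)
      dosage[, gids[hw]] <- d
    }
    for (j in gids[specs$mode[gids] == "planted"]) {
      ac <- planted_allele_count(specs[j, ], n)
      hom <- specs$force_hom_n[j]
      n_het <- ac - 2L * hom
      carriers <- sample.int(n, hom + n_het)
      if (hom > 0) dosage[carriers[seq_len(hom)], j] <- 2L
      if (n_het > 0) dosage[carriers[hom + seq_len(n_het)], j] <- 1L
    }
    # mode "zero": stays 0 everywhere (decoy allele)
  }
  # forced compound heterozygotes share one carrier with their partner
  for (j in which(!is.na(specs$comphet_with))) {
    partner <- which(specs$id == specs$comphet_with[j])
    het_partner <- which(dosage[, partner] == 1L)
    mine <- which(dosage[, j] >= 1L)
    if (length(het_partner) > 0 && !any(mine %in% het_partner)) {
      dosage[mine[1], j] <- 0L
      dosage[het_partner[1], j] <- 1L
    }
  }
  if (cfg$missing_rate > 0) {
    protect <- matrix(FALSE, n, nrow(specs))
    for (j in which(specs$mode == "planted"))
      protect[dosage[, j] >= 1L, j] <- TRUE
    miss <- matrix(stats::runif(n * nrow(specs)) < cfg$missing_rate,
                   n, nrow(specs)) & !protect
    dosage[miss] <- NA_integer_
  }
  dosage
}

# Allele-count bounds per truth class: rare classes stay strictly under
# the 0.1% rarity ceiling whatever the seed; LP2/pVUS keep >= 2 carriers.
planted_allele_count <- function(spec, n) {
  an_min <- 2L * n - ceiling(0.01 * 2 * n)  # generous missingness allowance
  rare_max <- max(1L, as.integer(floor(0.001 * an_min * 0.98)))
  target <- max(1L, round(spec$af * 2 * n))
  ac <- switch(spec$truth,
    LP1 = min(max(1L, target), rare_max),
    LP2 = min(max(2L + 2L * spec$force_hom_n, target), rare_max),
    pVUS = min(max(2L + 2L * spec$force_hom_n, target), rare_max),
    unclassified = if (spec$recipe == "lp2_single_carrier") 1L
                   else min(max(1L, target), rare_max),
    target)
  if (spec$truth %in% c("LP2", "pVUS") && rare_max < 2L)
    stopf("cohort too small to plant an LP2/pVUS variant")
  as.integer(min(ac, floor(0.019 * 2 * n)))
}

recipe_fields <- function(recipe, consequence) {
  f <- list(consequence = if (!is.na(consequence)) consequence else "missense_variant",
            impact = "MODERATE", clinvar_significance = NA, clinvar_stars = NA,
            hgmd_class = NA, revel = NA, pvs1_strength = NA,
            external_verdict = NA, gnomad_af = NA, dbsnp_id = NA)
  set <- function(f, ...) { f[names(list(...))] <- list(...); f }
  switch(recipe,
    P1 = set(f, clinvar_significance = "P", clinvar_stars = 1L,
             hgmd_class = "DM", gnomad_af = 2e-4, dbsnp_id = "rs1001",
             revel = 0.9),
    P2 = set(f, clinvar_significance = "LP", clinvar_stars = 2L,
             gnomad_af = 3e-4, dbsnp_id = "rs1002", revel = 0.85),
    LP1 = set(f, impact = "HIGH", pvs1_strength = "VeryStrong"),
    LP2 = set(f, clinvar_significance = "VUS", clinvar_stars = 1L,
              revel = 0.82, external_verdict = "LP", gnomad_af = 5e-5,
              dbsnp_id = "rs1003"),
    pVUS = set(f, clinvar_significance = "conflicting", clinvar_stars = 1L,
               revel = 0.78, external_verdict = "VUS", gnomad_af = 6e-5,
               dbsnp_id = "rs1004"),
    pVUS_novel = set(f, revel = 0.76, external_verdict = "VUS"),
    pVUS_verdict_b = set(f, clinvar_significance = "VUS", clinvar_stars = 0L,
                         revel = 0.8, external_verdict = "B",
                         gnomad_af = 4e-5, dbsnp_id = "rs1005"),
    benign = set(f, clinvar_significance = "LB", clinvar_stars = 1L,
                 revel = 0.2, gnomad_af = 0.005, dbsnp_id = "rs2001"),
    benign_blb = set(f, clinvar_significance = "B/LB", clinvar_stars = 2L,
                     revel = 0.1, gnomad_af = 0.01, dbsnp_id = "rs2002"),
    benign_decoy_transcript = set(f, clinvar_significance = "LB",
                                  clinvar_stars = 1L, revel = 0.15,
                                  gnomad_af = 0.004, dbsnp_id = "rs2003"),
    common = set(f, revel = 0.3, gnomad_af = 0.06, dbsnp_id = "rs2004"),
    lp1_nolof_gene = set(f, impact = "HIGH", pvs1_strength = "VeryStrong"),
    lp1_impact_moderate = set(f, impact = "MODERATE",
                              pvs1_strength = "VeryStrong"),
    lp1_pvs1_moderate = set(f, impact = "HIGH", pvs1_strength = "Moderate"),
    lp1_common = set(f, impact = "HIGH", pvs1_strength = "VeryStrong"),
    lp2_revel_low = set(f, clinvar_significance = "VUS", revel = 0.65,
                        external_verdict = "LP", gnomad_af = 5e-5,
                        dbsnp_id = "rs3001"),
    lp2_revel_boundary = set(f, clinvar_significance = "VUS", revel = 0.7,
                             external_verdict = "LP", gnomad_af = 5e-5,
                             dbsnp_id = "rs3002"),
    lp2_single_carrier = set(f, clinvar_significance = "VUS", revel = 0.8,
                             external_verdict = "LP", gnomad_af = 5e-5,
                             dbsnp_id = "rs3003"),
    p_conflict = set(f, clinvar_significance = "P", clinvar_stars = 3L,
                     hgmd_class = "other", gnomad_af = 2e-4,
                     dbsnp_id = "rs3004", revel = 0.9),
    lp2_no_evidence = set(f, clinvar_significance = "VUS", revel = 0.8,
                          external_verdict = "LP", gnomad_af = 5e-5,
                          dbsnp_id = "rs3005"),
    lp2_misc_gene = set(f, clinvar_significance = "VUS", revel = 0.8,
                        external_verdict = "LP", gnomad_af = 5e-5,
                        dbsnp_id = "rs3006"),
    stopf("unknown annotation recipe: %s", recipe))
}

#' Emit an annotation table consistent with the planted truth classes
#'
#' Each surviving variant receives fields guaranteed to drive the
#' classifier to its truth label; near-miss variants differ in exactly one
#' field. Most variants get one MANE transcript; a few get competing
#' non-MANE transcripts (including an adversarial more-severe decoy next
#' to a MANE row) to exercise transcript selection materially.
#'
#' @param cfg [sim_config()] object.
#' @param placed data.frame of placed specs (from the bundle writer).
#' @return data.frame in the annotation-table schema.
#' @export
emit_annotations <- function(cfg, placed) {
  keep <- !(placed$truth %in% c("star", "nonpass", "offgene"))
  rows <- list()
  gene_idx <- match(placed$gene, sort(unique(placed$gene)))
  for (i in which(keep)) {
    s <- placed[i, ]
    f <- recipe_fields(s$recipe, s$consequence)
    base <- data.frame(chrom = "chr1", pos = s$pos_truth, ref = s$ref_truth,
                       alt = s$alt_truth, gene = s$gene,
                       transcript_id = sprintf("ENST%03d001", gene_idx[i]),
                       is_mane = s$mane,
                       consequence = f$consequence, impact = f$impact,
                       transcript_length = 4000L + 10L * i,
                       clinvar_significance = f$clinvar_significance,
                       clinvar_stars = f$clinvar_stars,
                       hgmd_class = f$hgmd_class, revel = f$revel,
                       pvs1_strength = f$pvs1_strength,
                       external_verdict = f$external_verdict,
                       gnomad_af = f$gnomad_af, dbsnp_id = f$dbsnp_id,
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- base
    if (!s$mane) {
      # competitor: less severe consequence on a longer transcript; the
      # severity rule must still pick the base row
      alt_row <- base
      alt_row$transcript_id <- sprintf("ENST%03d002", gene_idx[i])
      alt_row$consequence <- "synonymous_variant"
      alt_row$impact <- "LOW"
      alt_row$transcript_length <- base$transcript_length + 5000L
      alt_row[c("clinvar_stars", "revel", "pvs1_strength")] <- NA
      alt_row$clinvar_significance <- NA
      rows[[length(rows) + 1]] <- alt_row
    }
    if (s$recipe == "benign_decoy_transcript") {
      # adversarial non-MANE decoy that would classify LP1 if the MANE
      # rule were ignored
      decoy <- base
      decoy$transcript_id <- sprintf("ENST%03d009", gene_idx[i])
      decoy$is_mane <- FALSE
      decoy$consequence <- "stop_gained"
      decoy$impact <- "HIGH"
      decoy$pvs1_strength <- "VeryStrong"
      decoy$clinvar_significance <- NA
      decoy$clinvar_stars <- NA
      decoy$gnomad_af <- NA
      decoy$dbsnp_id <- NA
      decoy$revel <- NA
      rows[[length(rows) + 1]] <- decoy
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Simulate participant phenotypes with planted carrier effects
#'
#' For each evidence domain the composite flag has baseline prevalence
#' `p0` among non-carriers; carriers of an OR-planted variant get odds
#' `OR x p0/(1-p0)`. The composite is then decomposed into the individual
#' questionnaire/laboratory components. Baseline LDL values are drawn
#' truncated below the diagnostic threshold so the composite FH flag fully
#' controls FH evidence.
#'
#' @param cfg [sim_config()] object.
#' @param dosage Genotype matrix from [simulate_genotypes()].
#' @return data.frame in the phenotype-table schema.
#' @export
simulate_phenotypes <- function(cfg, dosage) {
  set.seed(cfg$seed + 1L)
  specs <- cfg$variant_specs
  n <- nrow(dosage)
  ids <- rownames(dosage)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(stats::runif(n, 18, 70))
  composite <- sapply(c("CVD", "cancer", "FH"), function(type) {
    p0 <- unname(cfg$phenotype_baseline[[type]])
    or <- rep(1, n)
    for (j in which(specs$evidence_type %in% type & !is.na(specs$planted_or))) {
      carrier <- !is.na(dosage[, specs$id[j]]) & dosage[, specs$id[j]] >= 1
      or[carrier] <- pmax(or[carrier], specs$planted_or[j])
    }
    odds <- or * p0 / (1 - p0)
    stats::runif(n) < odds / (1 + odds)
  })
  # deterministic guarantees for truth classes that require evidenced
  # carriers, and suppression for the no-evidence near miss
  for (j in seq_len(nrow(specs))) {
    type <- specs$evidence_type[j]
    carriers <- which(!is.na(dosage[, specs$id[j]]) & dosage[, specs$id[j]] >= 1)
    if (specs$force_evidence[j] == "none") {
      composite[carriers, ] <- FALSE
      next
    }
    if (is.na(type) || !specs$truth[j] %in% c("LP2", "pVUS")) next
    need <- if (type == "cancer") 1L else 2L
    if (length(carriers) > 0)
      composite[carriers[seq_len(min(need, length(carriers)))], type] <- TRUE
  }
  cvd_comp <- matrix(FALSE, n, 4,
                     dimnames = list(NULL, c("ecg_abnormal", "self_heart_disease",
                                             "revascularization",
                                             "family_heart_disease")))
  pick <- sample.int(4, n, replace = TRUE)
  for (i in which(composite[, "CVD"])) cvd_comp[i, pick[i]] <- TRUE
  can_comp <- matrix(FALSE, n, 4,
                     dimnames = list(NULL, c("self_cancer", "parent_cancer",
                                             "tumor_surgery", "early_screening")))
  pick_c <- sample.int(4, n, replace = TRUE)
  for (i in which(composite[, "cancer"])) {
    ch <- pick_c[i]
    if (ch == 4 && age[i] >= cfg$screening_age[[sex[i]]]) ch <- 1L
    can_comp[i, ch] <- TRUE
  }
  thr <- cfg$ldl_threshold
  ldl <- pmin(pmax(stats::rnorm(n, 3.0, 0.8), 0.6), thr - 0.01)
  hchol_dx <- rep(FALSE, n)
  fh_route_dx <- stats::runif(n) < 0.5
  fh_true <- composite[, "FH"]
  hchol_dx[fh_true & fh_route_dx] <- TRUE
  high <- fh_true & !fh_route_dx
  ldl[high] <- thr + abs(stats::rnorm(sum(high), 0.6, 0.5))
  hdl <- 0.3 + abs(stats::rnorm(n, 1.1, 0.3))
  total_chol <- ldl + hdl + abs(stats::rnorm(n, 0.8, 0.3))
  no_lipids <- stats::runif(n) < 0.05 & !fh_true
  ldl[no_lipids] <- NA; hdl[no_lipids] <- NA; total_chol[no_lipids] <- NA
  data.frame(participant = ids,
             ecg_abnormal = cvd_comp[, 1], self_heart_disease = cvd_comp[, 2],
             revascularization = cvd_comp[, 3],
             family_heart_disease = cvd_comp[, 4],
             self_cancer = can_comp[, 1], parent_cancer = can_comp[, 2],
             tumor_surgery = can_comp[, 3], early_screening = can_comp[, 4],
             total_chol = round(total_chol, 2), hdl = round(hdl, 2),
             ldl = round(ldl, 2), hypercholesterolemia_dx = hchol_dx,
             age = age, sex = sex, stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture bundle
#'
#' Produces, in `dir`: cohort VCF (plain text, with multi-allelic sites,
#' spanning-deletion alleles, padded/right-shifted indel representations
#' and decoy sites), annotation TSV, phenotype TSV, catalog TSV, region
#' map TSV, reference FASTA, a truth JSON, and a ready-to-run pipeline
#' config YAML. Regenerating with the same seed is byte-identical.
#'
#' @param cfg [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the truth table.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- acmg_sf_catalog()
  bad_gene <- setdiff(cfg$variant_specs$gene, catalog$symbol)
  if (length(bad_gene) > 0)
    stopf("spec gene(s) not in catalog: %s", paste(bad_gene, collapse = ", "))
  layout <- sim_layout(catalog)
  reference <- sim_reference(cfg, layout)
  pl <- place_variants(cfg$variant_specs, layout, reference)
  placed <- pl$specs; reference <- pl$reference
  dosage <- simulate_genotypes(cfg)
  colnames(dosage) <- placed$id

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    region_map = file.path(dir, "region_map.tsv"),
    reference = file.path(dir, "reference.fa"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))

  vcf_vars <- data.frame(chrom = "chr1", pos = placed$pos_w,
                         ref = placed$ref_w, alt = placed$alt_w,
                         filter = placed$filter, stringsAsFactors = FALSE)
  site_group <- ifelse(is.na(placed$site_group),
                       paste0("solo", seq_len(nrow(placed))),
                       placed$site_group)
  write_cohort_vcf(vcf_vars, dosage, paths$vcf, site_group = site_group)

  ann <- emit_annotations(cfg, placed)
  write_tsv(ann, paths$annotation)
  pheno <- simulate_phenotypes(cfg, dosage)
  write_tsv(pheno, paths$phenotypes)
  write_tsv(catalog, paths$catalog)
  write_tsv(layout[c("chrom", "start", "end", "symbol")], paths$region_map)
  write_fasta(reference, paths$reference)

  expected <- expected_list_for(placed$truth)
  carriers <- vapply(seq_len(nrow(placed)), function(j)
    sum(!is.na(dosage[, j]) & dosage[, j] >= 1), integer(1))
  ac <- vapply(seq_len(nrow(placed)), function(j)
    sum(dosage[, j], na.rm = TRUE), integer(1))
  an <- vapply(seq_len(nrow(placed)), function(j)
    2L * sum(!is.na(dosage[, j])), integer(1))
  truth <- data.frame(id = placed$id, variant_id = placed$variant_id,
                      gene = placed$gene, truth = placed$truth,
                      expected_list = expected, af = placed$af,
                      allele_count = ac, allele_number = an,
                      carriers = carriers, planted_or = placed$planted_or,
                      evidence_type = placed$evidence_type,
                      stringsAsFactors = FALSE)
  in_lists <- truth$expected_list %in% c("P1", "P2", "LP1", "LP2", "pVUS")
  gpp <- unique(unlist(lapply(which(in_lists), function(j)
    rownames(dosage)[!is.na(dosage[, j]) & dosage[, j] >= 1])))
  truth_obj <- list(n_participants = cfg$n_participants, seed = cfg$seed,
                    inbreeding_f = cfg$inbreeding_f,
                    distinct_gpp = length(gpp), variants = truth)
  jsonlite::write_json(truth_obj, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  config <- list(vcf = "cohort.vcf", annotation = "annotation.tsv",
                 phenotypes = "phenotypes.tsv", catalog = "catalog.tsv",
                 region_map = "region_map.tsv", reference = "reference.fa",
                 association = TRUE)
  yaml::write_yaml(config, paths$config)
  invisible(list(files = paths, truth = truth_obj, dosage = dosage,
                 placed = placed))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}
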