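# Independent oracles. Each reimplements, from scratch and in a different
# structure than the package, a computation the package performs, so tests
# can compare two routes to the same answer.

# --- brute-force classifier ------------------------------------------------
# Flat predicate table following the published flow chart; deliberately not
# a call into the package's rule functions.
oracle_classify <- function(ann, maf, carriers, category, evidence, lof_gene,
                            g_max = 0.02, r_max = 0.001, rev_min = 0.7,
                            min_carriers = 2, min_stars = 2) {
  sig <- ann$clinvar_significance
  has <- function(x) !is.null(x) && !is.na(x)
  if (!(maf < g_max)) return("rejected")
  if (has(sig) && sig %in% c("B", "LB", "B/LB")) return("rejected")
  plp <- has(sig) && sig %in% c("P", "LP", "P/LP")
  if (plp && has(ann$hgmd_class) && ann$hgmd_class == "DM") return("P1")
  if (plp && has(ann$hgmd_class)) return("unclassified")  # conflict
  if (plp && has(ann$clinvar_stars) && ann$clinvar_stars >= min_stars)
    return("P2")
  terms <- strsplit(ann$consequence, "[&,]")[[1]]
  lof <- any(terms %in% c("stop_gained", "frameshift_variant",
                          "splice_acceptor_variant", "splice_donor_variant",
                          "inframe_insertion", "inframe_deletion"))
  rare <- maf < r_max && (!has(ann$gnomad_af) || ann$gnomad_af < r_max)
  if (lof && rare && lof_gene &&
      has(ann$pvs1_strength) && ann$pvs1_strength == "VeryStrong" &&
      has(ann$impact) && ann$impact == "HIGH") return("LP1")
  novel <- !has(ann$dbsnp_id) && !has(ann$gnomad_af) && !has(sig) &&
    !has(ann$hgmd_class)
  eligible <- (has(sig) && sig %in% c("VUS", "conflicting")) || novel
  if ("missense_variant" %in% terms && eligible && rare &&
      carriers >= min_carriers &&
      has(ann$revel) && ann$revel > rev_min &&
      !is.na(category) && category %in% c("cancer", "cardiovascular") &&
      evidence) {
    if (has(ann$external_verdict) && ann$external_verdict %in% c("P", "LP"))
      return("LP2")
    return("pVUS")
  }
  "unclassified"
}

# --- Fisher exact enumeration ----------------------------------------------
# Full enumeration of tables with the observed margins; probabilities from
# raw binomial coefficients, not dhyper.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  prob <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- prob[match(a, xs)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# --- normalization equivalence search --------------------------------------
# Enumerates every (pos, ref, alt) triple over a window that reproduces the
# same alternate haplotype, keeps the minimal representations (no shared
# suffix; shared leading base only as an indel anchor), and returns the one
# at the smallest position.
oracle_normalize <- function(S, pos, ref, alt) {
  H <- paste0(substr(S, 1, pos - 1), alt,
              substr(S, pos + nchar(ref), nchar(S)))
  best <- NULL
  lo <- max(1, pos - 25)
  hi <- min(nchar(S), pos + nchar(ref) + 25)
  for (p in lo:hi) {
    for (rl in 1:12) {
      if (p + rl - 1 > nchar(S)) next
      r <- substr(S, p, p + rl - 1)
      tail_len <- nchar(S) - (p + rl - 1)
      al <- nchar(H) - (p - 1) - tail_len
      if (al < 1) next
      a <- substr(H, p, p + al - 1)
      cand_H <- paste0(substr(S, 1, p - 1), a,
                       substr(S, p + rl, nchar(S)))
      if (cand_H != H || r == a) next
      # minimal: no shared suffix; shared first base only as anchor
      if (substr(r, rl, rl) == substr(a, al, al) && (rl > 1 || al > 1)) next
      if (substr(r, 1, 1) == substr(a, 1, 1) && rl > 1 && al > 1) next
      if (is.null(best) || p < best$pos ||
          (p == best$pos && nchar(r) < nchar(best$ref)))
        best <- list(pos = p, ref = r, alt = a)
    }
  }
  best
}

# random indel (or SNV) in a repeat-rich sequence; returns the sequence and
# a VCF-style anchored representation, possibly padded with extra shared
# suffix bases
random_repeat_variant <- function() {
  unit <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                collapse = "")
  run <- strrep(unit, sample(2:6, 1))
  flank_l <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  flank_r <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  S <- paste0(flank_l, run, flank_r)
  p <- sample(10:(nchar(flank_l) + nchar(run)), 1)
  kind <- sample(c("del", "ins", "snv"), 1)
  if (kind == "snv") {
    ref <- substr(S, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[sample(1:3, 1)]
  } else if (kind == "del") {
    len <- sample(1:4, 1)
    if (p + len > nchar(S) - 4) len <- 1
    ref <- substr(S, p, p + len)
    alt <- substr(S, p, p)
  } else {
    ins <- substr(paste0(run, "ACGT"), 1, sample(1:4, 1))
    ref <- substr(S, p, p)
    alt <- paste0(ref, ins)
  }
  pad <- sample(0:2, 1)
  if (pad > 0 && p + nchar(ref) + pad - 1 <= nchar(S)) {
    extra <- substr(S, p + nchar(ref), p + nchar(ref) + pad - 1)
    ref <- paste0(ref, extra)
    alt <- paste0(alt, extra)
  }
  list(S = S, pos = p, ref = ref, alt = alt)
}

# --- exhaustive GPP double loop --------------------------------------------
oracle_gpp <- function(classified, dosage) {
  rows <- list()
  for (s in rownames(dosage)) {
    for (k in colnames(dosage)) {
      if (!k %in% rownames(classified)) next
      lst <- classified[k, "list"]
      if (!lst %in% c("P1", "P2", "LP1", "LP2", "pVUS")) next
      d <- dosage[s, k]
      if (is.na(d) || d < 1) next
      rows[[length(rows) + 1]] <- data.frame(
        participant = s, variant_id = k, list = lst,
        zygosity = if (d == 2) "HOM" else "HET", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
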