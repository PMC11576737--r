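#' Read a multisample VCF restricted to catalog genes
#'
#' Parses a VCF v4.2 with per-sample GT fields, keeps only sites that pass
#' the caller's filter (`FILTER == "PASS"`) and fall inside a catalog gene
#' interval, and returns raw sites with their genotype strings. Non-PASS
#' and off-gene sites are tallied in the skip log rather than silently
#' dropped.
#'
#' @param path Path to a (plain or bgzipped) VCF file.
#' @param region_map data.frame from [read_region_map()]; 1-based closed
#'   intervals.
#' @param catalog Optional catalog data.frame; if given, the region map is
#'   restricted to catalog genes and must cover all of them.
#' @return List with `sites` (data.frame: chrom, pos, id, ref, alt, filter,
#'   gene), `gt` (character matrix, sites x samples, e.g. `"0/1"`),
#'   `samples`, and `skipped` (data.frame: chrom, pos, reason).
#' @export
read_multisample_vcf <- function(path, region_map, catalog = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  if (!is.null(catalog)) {
    region_map <- read_region_map_checked(region_map, catalog)
  }
  validate_vcf_structure(path)

  empty <- list(
    sites = data.frame(chrom = character(), pos = integer(), id = character(),
                       ref = character(), alt = character(), filter = character(),
                       gene = character(), stringsAsFactors = FALSE),
    gt = matrix(character(), nrow = 0, ncol = 0),
    samples = character(),
    skipped = data.frame(chrom = character(), pos = integer(),
                         reason = character(), stringsAsFactors = FALSE))

  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  samples <- colnames(vcf@gt)[-1]
  empty$samples <- samples %||% character()
  if (nrow(vcf@fix) == 0) return(empty)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt)))
    stopf("VCF format error: GT missing from FORMAT at %d site(s)",
          sum(!grepl("(^|:)GT(:|$)", fmt)))
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  gt_raw <- vcf@gt[, -1, drop = FALSE]
  gt <- matrix(NA_character_, nrow = nrow(gt_raw), ncol = ncol(gt_raw),
               dimnames = list(NULL, samples))
  for (i in seq_len(nrow(gt_raw))) {
    cells <- strsplit(gt_raw[i, ], ":", fixed = TRUE)
    gt[i, ] <- vapply(cells, `[`, character(1), gt_idx[i])
  }

  gene <- rep(NA_character_, nrow(fix))
  for (i in seq_len(nrow(fix))) {
    hit <- which(region_map$chrom == fix$CHROM[i] &
                 fix$POS[i] >= region_map$start &
                 fix$POS[i] <= region_map$end)
    if (length(hit) > 0) gene[i] <- region_map$symbol[hit[1]]
  }

  pass <- !is.na(fix$FILTER) & fix$FILTER == "PASS"
  on_gene <- !is.na(gene)
  keep <- pass & on_gene
  reason <- ifelse(!pass, "non_pass", "off_gene")
  skipped <- data.frame(chrom = fix$CHROM[!keep], pos = fix$POS[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)

  list(sites = data.frame(chrom = fix$CHROM[keep], pos = fix$POS[keep],
                          id = fix$ID[keep], ref = fix$REF[keep],
                          alt = fix$ALT[keep], filter = fix$FILTER[keep],
                          gene = gene[keep], stringsAsFactors = FALSE),
       gt = gt[keep, , drop = FALSE],
       samples = samples,
       skipped = skipped)
}

read_region_map_checked <- function(region_map, catalog) {
  uncovered <- setdiff(catalog$symbol, region_map$symbol)
  if (length(uncovered) > 0)
    stopf("region map does not cover catalog gene(s): %s",
          paste(uncovered, collapse = ", "))
  region_map[region_map$symbol %in% catalog$symbol, , drop = FALSE]
}

# Light structural pass over the VCF text: header presence, constant field
# count, GT announced in FORMAT. Gives errors that name the offending line,
# which the full parser does not.
validate_vcf_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0) stopf("malformed VCF: no #CHROM header line in %s", path)
  hdr <- hdr[1]
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10)
    stopf("VCF format error: no sample/FORMAT columns (GT required)")
  body <- seq.int(hdr + 1, length.out = max(0, length(lines) - hdr))
  for (i in body) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields)
      stopf("malformed VCF line %d: %d fields, expected %d", i, nf, n_fields)
  }
  invisible(TRUE)
}

# Parse diploid GT strings into two integer allele vectors. Any missing
# allele ('.') marks the whole call missing, so AN = 2 x (called samples)
# holds exactly. Haploid calls are doubled (warning), as no sex-chromosome
# logic is exercised downstream.
parse_genotypes <- function(gt_strings) {
  gt_strings[is.na(gt_strings)] <- "./."  # parsers may pre-convert missing
  parts <- strsplit(gt_strings, "[/|]")
  lens <- lengths(parts)
  if (any(lens > 2)) stopf("polyploid genotype call encountered")
  if (any(lens == 1)) {
    warnf("haploid genotype call(s) doubled to diploid (%d)", sum(lens == 1))
    parts[lens == 1] <- lapply(parts[lens == 1], function(p) c(p, p))
  }
  a1 <- vapply(parts, `[`, character(1), 1)
  a2 <- vapply(parts, `[`, character(1), 2)
  miss <- a1 == "." | a2 == "." | is.na(a1) | is.na(a2)
  a1 <- suppressWarnings(as.integer(a1)); a1[miss] <- NA_integer_
  a2 <- suppressWarnings(as.integer(a2)); a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' Decompose a (possibly multi-allelic) site into biallelic records
#'
#' One record per ALT allele. A sample's dosage for ALT k is the number of
#' its called alleles equal to k; alleles of other ALTs count as reference
#' for that record. AN counts all called alleles at the original site, so
#' minor-allele frequencies remain comparable across the decomposed
#' records. Spanning-deletion ALTs (`*`) are dropped and logged; a record
#' whose site has AN = 0 is dropped and logged.
#'
#' @param chrom,pos,ref Site coordinates and reference allele.
#' @param alt ALT field string (comma-separated) or character vector.
#' @param gt_strings Per-sample GT strings (e.g. `"0/1"`, `"./."`).
#' @return List with `records` (list of `variant` = one-row data.frame with
#'   chrom, pos, ref, alt, allele_count, allele_number, cohort_maf, and
#'   `dosage` = integer vector, NA for missing) and `dropped`
#'   (data.frame: alt, reason).
#' @export
decompose_multiallelic <- function(chrom, pos, ref, alt, gt_strings) {
  alts <- if (length(alt) == 1) strsplit(alt, ",", fixed = TRUE)[[1]] else alt
  if (length(alts) < 1) stopf("site %s:%d has no ALT allele", chrom, pos)
  g <- parse_genotypes(gt_strings)
  called <- !is.na(g$a1)
  an <- 2L * sum(called)
  records <- list()
  dropped <- data.frame(alt = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (k in seq_along(alts)) {
    if (alts[k] == "*") {
      dropped <- rbind(dropped, data.frame(alt = "*", reason = "spanning_deletion",
                                           stringsAsFactors = FALSE))
      next
    }
    if (an == 0L) {
      dropped <- rbind(dropped, data.frame(alt = alts[k], reason = "an_zero",
                                           stringsAsFactors = FALSE))
      next
    }
    dosage <- (g$a1 == k) + (g$a2 == k)
    dosage <- as.integer(dosage)
    ac <- sum(dosage[called])
    af <- ac / an
    records[[length(records) + 1]] <- list(
      variant = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                           alt = alts[k], allele_count = ac, allele_number = an,
                           cohort_maf = min(af, 1 - af), stringsAsFactors = FALSE),
      dosage = dosage)
  }
  list(records = records, dropped = dropped)
}

#' Decompose and normalize every site of a cohort read
#'
#' Drives [decompose_multiallelic()] and [normalize_variant()] over the
#' output of [read_multisample_vcf()] and assembles the cohort genotype
#' matrix. Records that normalize to the same key are merged by taking the
#' per-sample maximum dosage (logged).
#'
#' @param vcfdat List from [read_multisample_vcf()].
#' @param ref_fetch Reference oracle for left-alignment (see
#'   [normalize_variant()]); NULL skips left-alignment with a warning for
#'   indels.
#' @return List with `variants` (data.frame: chrom, pos, ref, alt, gene,
#'   allele_count, allele_number, cohort_maf; rownames are variant keys),
#'   `dosage` (integer matrix, samples x variants, NA = missing call) and
#'   `dropped` (data.frame: chrom, pos, alt, reason).
#' @export
cohort_variants <- function(vcfdat, ref_fetch = NULL) {
  n_samp <- length(vcfdat$samples)
  vars <- list(); dose <- list(); genes <- character()
  dropped <- data.frame(chrom = character(), pos = integer(), alt = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vcfdat$sites))) {
    s <- vcfdat$sites[i, ]
    dec <- decompose_multiallelic(s$chrom, s$pos, s$ref, s$alt, vcfdat$gt[i, ])
    if (nrow(dec$dropped) > 0)
      dropped <- rbind(dropped, data.frame(chrom = s$chrom, pos = s$pos,
                                           alt = dec$dropped$alt,
                                           reason = dec$dropped$reason,
                                           stringsAsFactors = FALSE))
    for (rec in dec$records) {
      v <- rec$variant
      nv <- normalize_variant(v$chrom, v$pos, v$ref, v$alt, ref_fetch)
      v$pos <- nv$pos; v$ref <- nv$ref; v$alt <- nv$alt
      v$gene <- s$gene
      vars[[length(vars) + 1]] <- v
      dose[[length(dose) + 1]] <- rec$dosage
      genes[length(genes) + 1] <- s$gene
    }
  }
  if (length(vars) == 0) {
    return(list(variants = data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      gene = character(), allele_count = integer(),
                                      allele_number = integer(), cohort_maf = numeric(),
                                      stringsAsFactors = FALSE),
                dosage = matrix(integer(), nrow = n_samp, ncol = 0,
                                dimnames = list(vcfdat$samples, NULL)),
                dropped = dropped))
  }
  variants <- do.call(rbind, vars)
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  dosage <- do.call(cbind, dose)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    for (k in dup) {
      idx <- which(keys == k)
      merged <- do.call(pmax, c(lapply(idx, function(j) dosage[, j]), na.rm = TRUE))
      dosage[, idx[1]] <- as.integer(merged)
      variants$allele_count[idx[1]] <- sum(merged, na.rm = TRUE)
      af <- variants$allele_count[idx[1]] / variants$allele_number[idx[1]]
      variants$cohort_maf[idx[1]] <- min(af, 1 - af)
      dropped <- rbind(dropped, data.frame(chrom = variants$chrom[idx[-1]],
                                           pos = variants$pos[idx[-1]],
                                           alt = variants$alt[idx[-1]],
                                           reason = "duplicate_key_merged",
                                           stringsAsFactors = FALSE))
    }
    keep <- !duplicated(keys)
    variants <- variants[keep, , drop = FALSE]
    dosage <- dosage[, keep, drop = FALSE]
    keys <- keys[keep]
  }
  rownames(variants) <- keys
  dimnames(dosage) <- list(vcfdat$samples, keys)
  variants <- variants[c("chrom", "pos", "ref", "alt", "gene",
                         "allele_count", "allele_number", "cohort_maf")]
  list(variants = variants, dosage = dosage, dropped = dropped)
}

#' Write a cohort genotype matrix as a plain-text VCF v4.2
#'
#' Used by the simulator and for round-trip testing. Variants sharing a
#' `site_group` value are emitted as one multi-allelic site; their per-
#' sample dosages must then sum to at most 2, and a missing call in any
#' member marks the whole genotype missing.
#'
#' @param variants data.frame with chrom, pos, ref, alt (and optionally
#'   `filter`, default `"PASS"`).
#' @param dosage Integer matrix, samples x variants (NA = missing).
#' @param path Output path (plain text).
#' @param site_group Optional vector grouping variants into shared sites.
#' @export
write_cohort_vcf <- function(variants, dosage, path, site_group = NULL) {
  stopifnot(nrow(variants) == ncol(dosage))
  if (is.null(site_group)) site_group <- seq_len(nrow(variants))
  filt <- variants$filter %||% rep("PASS", nrow(variants))
  samples <- rownames(dosage) %||% paste0("S", seq_len(nrow(dosage)))
  groups <- split(seq_len(nrow(variants)), site_group)
  ord <- order(vapply(groups, function(ix) variants$chrom[ix[1]], character(1)),
               vapply(groups, function(ix) variants$pos[ix[1]], numeric(1)))
  groups <- groups[ord]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (ix in groups) {
    v <- variants[ix, , drop = FALSE]
    if (length(unique(v$chrom)) != 1 || length(unique(v$pos)) != 1 ||
        length(unique(v$ref)) != 1)
      stopf("site_group members must share chrom/pos/ref")
    d <- dosage[, ix, drop = FALSE]
    gt <- apply(d, 1, function(dk) {
      if (anyNA(dk)) return("./.")
      tot <- sum(dk)
      if (tot > 2) stopf("dosages at one site exceed ploidy")
      alleles <- c(unlist(mapply(rep, seq_along(dk), dk, SIMPLIFY = FALSE)),
                   rep(0L, 2L - tot))
      paste(sort(alleles), collapse = "/")
    })
    lines <- c(lines, paste(c(v$chrom[1], v$pos[1], ".", v$ref[1],
                              paste(v$alt, collapse = ","), ".", filt[ix[1]],
                              ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
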