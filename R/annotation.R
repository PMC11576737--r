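ANNOTATION_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "transcript_id",
                        "is_mane", "consequence", "impact", "transcript_length",
                        "clinvar_significance", "clinvar_stars", "hgmd_class",
                        "revel", "pvs1_strength", "external_verdict",
                        "gnomad_af", "dbsnp_id")

CLINVAR_LEVELS <- c("P", "LP", "P/LP", "VUS", "conflicting", "B", "LB", "B/LB")
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
PVS1_LEVELS <- c("VeryStrong", "Strong", "Moderate", "Supporting", "Unset")
VERDICT_LEVELS <- c("P", "LP", "VUS", "LB", "B")

#' Load a per-transcript variant annotation table
#'
#' One row per (variant, transcript) carrying all external evidence the
#' classifier consumes: ClinVar-style significance and review stars,
#' HGMD-style class, VEP-style consequence/impact/MANE flag and transcript
#' length, REVEL score, PVS1 strength, an external combinatory verdict and
#' a gnomAD-style allele frequency. Empty cells become explicit NA
#' ("absent") values, never defaults; unknown columns are ignored.
#'
#' @param path TSV with (at least) the mandatory columns listed in
#'   `ANNOTATION_COLUMNS`.
#' @return data.frame keyed by (variant key, transcript_id); duplicates are
#'   an error.
#' @export
load_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols) > 0)
    stopf("annotation table is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  ann <- ann[ANNOTATION_COLUMNS]
  ann$pos <- as.integer(ann$pos)
  ann$is_mane <- toupper(ann$is_mane) %in% c("TRUE", "T", "1", "YES")
  ann$transcript_length <- as.integer(ann$transcript_length)
  ann$clinvar_stars <- as.integer(ann$clinvar_stars)
  ann$revel <- as.numeric(ann$revel)
  ann$gnomad_af <- as.numeric(ann$gnomad_af)
  bad_sig <- setdiff(stats::na.omit(unique(ann$clinvar_significance)), CLINVAR_LEVELS)
  if (length(bad_sig) > 0)
    stopf("unknown clinvar_significance value(s): %s", paste(bad_sig, collapse = ", "))
  bad_imp <- setdiff(stats::na.omit(unique(ann$impact)), IMPACT_LEVELS)
  if (length(bad_imp) > 0)
    stopf("unknown impact value(s): %s", paste(bad_imp, collapse = ", "))
  if (any(!is.na(ann$clinvar_stars) & is.na(ann$clinvar_significance)))
    stopf("clinvar_stars present without clinvar_significance")
  key <- paste(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt),
               ann$transcript_id, sep = "|")
  if (anyDuplicated(key))
    stopf("duplicate (variant, transcript) annotation row(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  ann$variant_id <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

#' The packaged consequence severity table
#'
#' @return Character vector of sequence-ontology terms, most severe first.
#' @export
consequence_severity_table <- function() {
  lines <- readLines(system.file("extdata", "consequence_severity.txt",
                                 package = "sftriage", mustWork = TRUE))
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Severity rank of sequence-ontology consequence terms
#'
#' Lower rank = more severe; the order is the packaged frozen table, so it
#' is total, antisymmetric and stable across runs. Unknown terms are an
#' error, never silently least-severe.
#'
#' @param term Character vector of consequence terms.
#' @param table Severity table (default the packaged one).
#' @return Integer ranks.
#' @export
rank_consequence <- function(term, table = consequence_severity_table()) {
  r <- match(term, table)
  if (anyNA(r))
    stopf("unknown consequence term(s): %s",
          paste(unique(term[is.na(r)]), collapse = ", "))
  r
}

# A transcript's consequence field may hold several '&'-separated terms;
# its severity is the best (minimum) rank among them.
split_consequences <- function(consequence) {
  strsplit(consequence, "[&,]")[[1]]
}

most_severe_rank <- function(consequence, table = consequence_severity_table()) {
  min(rank_consequence(split_consequences(consequence), table))
}

#' Select the transcript annotation used for classification
#'
#' The MANE transcript if one is flagged; otherwise the transcript whose
#' most severe consequence ranks best; rank ties broken by the longest
#' transcript; remaining ties by the lexicographically smallest
#' transcript_id, so the choice is deterministic and order-insensitive.
#'
#' @param ann data.frame of annotation rows for one variant.
#' @return The selected row (one-row data.frame).
#' @export
select_transcript <- function(ann) {
  if (nrow(ann) == 0) stopf("no annotation rows to select from")
  if (length(unique(ann$variant_id %||% "")) > 1)
    stopf("select_transcript expects rows for a single variant")
  mane <- which(ann$is_mane)
  if (length(mane) > 1)
    stopf("multiple MANE transcripts for one variant: %s",
          paste(ann$transcript_id[mane], collapse = ", "))
  if (length(mane) == 1) return(ann[mane, , drop = FALSE])
  tab <- consequence_severity_table()
  ranks <- vapply(ann$consequence, most_severe_rank, integer(1), table = tab)
  cand <- which(ranks == min(ranks))
  if (length(cand) > 1) {
    len <- ann$transcript_length[cand]
    cand <- cand[len == max(len)]
  }
  if (length(cand) > 1)
    cand <- cand[order(ann$transcript_id[cand])][1]
  ann[cand, , drop = FALSE]
}

#' Select one transcript per variant across an annotation table
#'
#' @param ann data.frame from [load_annotation_table()].
#' @return data.frame with one row per distinct variant.
#' @export
select_transcripts <- function(ann) {
  pieces <- lapply(split(ann, ann$variant_id), select_transcript)
  out <- do.call(rbind, pieces)
  rownames(out) <- out$variant_id
  out
}
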