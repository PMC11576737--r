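#' Build a reference-base oracle
#'
#' Normalization needs random access to reference bases for indel
#' left-alignment. Accepts a `function(chrom, start, end)`, a named
#' character vector of chromosome sequences, a `Biostrings::DNAStringSet`,
#' or a FASTA path, and returns a uniform fetch function.
#'
#' @param x Reference source (see description), or NULL.
#' @return `function(chrom, start, end) -> string`, or NULL.
#' @export
make_ref_fetch <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) return(x)
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    x <- seqs
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    x <- read_reference_fasta(x)
  }
  if (!is.character(x) || is.null(names(x)))
    stopf("cannot interpret reference source")
  seqs <- x
  function(chrom, start, end) {
    if (!chrom %in% names(seqs)) stopf("chromosome %s not in reference", chrom)
    if (start < 1 || end > nchar(seqs[[chrom]]))
      stopf("reference fetch out of range: %s:%d-%d", chrom, start, end)
    substr(seqs[[chrom]], start, end)
  }
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector, one element per sequence (names cut at
#'   the first whitespace).
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Normalize a variant to its minimal left-aligned representation
#'
#' Trims shared trailing bases, left-aligns indels through repeat context
#' (extending with reference bases whenever an allele would become empty),
#' then trims shared leading bases down to the single anchor base indels
#' require. The result is the unique minimal representation at the smallest
#' possible position; applying the function twice gives the same answer.
#'
#' Without a reference oracle only trimming is performed; indels then stay
#' where they are, with a warning, since left-alignment needs flanking
#' sequence.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Allele strings (A/C/G/T/N, non-empty, `ref != alt`).
#' @param ref_fetch Reference oracle accepted by [make_ref_fetch()].
#' @return List with `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, ref_fetch = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stopf("empty allele at %s:%d", chrom, pos)
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
    stopf("non-ACGTN allele at %s:%d (%s>%s)", chrom, pos, ref, alt)
  if (ref == alt) stopf("ref equals alt at %s:%d", chrom, pos)
  fetch <- make_ref_fetch(ref_fetch)
  pos <- as.integer(pos)
  if (!is.null(fetch)) {
    seen <- fetch(chrom, pos, pos + nchar(ref) - 1L)
    if (!identical(toupper(seen), ref))
      stopf("reference mismatch at %s:%d: VCF says %s, reference says %s",
            chrom, pos, ref, seen)
  } else if (nchar(ref) != nchar(alt)) {
    warnf("no reference available: indel at %s:%d trimmed but not left-aligned",
          chrom, pos)
  }
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (substr(ref, lr, lr) == substr(alt, la, la) && (lr > 1 || la > 1)) {
      if (lr == 1 || la == 1) {
        if (is.null(fetch) || pos == 1L) break
        base <- fetch(chrom, pos - 1L, pos - 1L)
        ref <- paste0(base, substr(ref, 1, lr - 1L))
        alt <- paste0(base, substr(alt, 1, la - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1, lr - 1L)
        alt <- substr(alt, 1, la - 1L)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}
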