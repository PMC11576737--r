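# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  data.frame(
    symbol = c("BRCA2", "ATP7B", "LDLR", "TTN", "GLA"),
    inheritance = c("AD", "AR", "SD", "AD", "XL"),
    category = c("cancer", "miscellaneous", "cardiovascular",
                 "cardiovascular", "miscellaneous"),
    phenotype = c("Hereditary breast and/or ovarian cancer", "Wilson disease",
                  "Familial hypercholesterolemia", "Dilated cardiomyopathy",
                  "Fabry disease"),
    sf_version = "v3.1", lof_gene = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

tiny_region_map <- function() {
  data.frame(chrom = "chr1",
             start = c(100L, 1000L, 2000L, 3000L, 4000L),
             end = c(900L, 1900L, 2900L, 3900L, 4900L),
             symbol = c("BRCA2", "ATP7B", "LDLR", "TTN", "GLA"),
             stringsAsFactors = FALSE)
}

# writes a VCF from raw body rows (each a character vector of fields)
write_test_vcf <- function(body_rows, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf")) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (r in body_rows) lines <- c(lines, paste(r, collapse = "\t"))
  writeLines(lines, path)
  path
}

vcf_row <- function(pos, ref, alt, gts, filter = "PASS", chrom = "chr1") {
  c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gts)
}

# one-row annotation as a list (classify_* access fields by name)
ann_row <- function(consequence = "missense_variant", impact = "MODERATE",
                    clinvar_significance = NA, clinvar_stars = NA,
                    hgmd_class = NA, revel = NA, pvs1_strength = NA,
                    external_verdict = NA, gnomad_af = NA, dbsnp_id = NA,
                    is_mane = TRUE, transcript_id = "T1",
                    transcript_length = 2000L) {
  list(consequence = consequence, impact = impact,
       clinvar_significance = clinvar_significance,
       clinvar_stars = clinvar_stars, hgmd_class = hgmd_class, revel = revel,
       pvs1_strength = pvs1_strength, external_verdict = external_verdict,
       gnomad_af = gnomad_af, dbsnp_id = dbsnp_id, is_mane = is_mane,
       transcript_id = transcript_id, transcript_length = transcript_length)
}

annotation_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

ann_df_row <- function(chrom = "chr1", pos = 150L, ref = "A", alt = "G",
                       gene = "BRCA2", transcript_id = "T1", is_mane = TRUE,
                       consequence = "missense_variant", impact = "MODERATE",
                       transcript_length = 2000L, clinvar_significance = NA,
                       clinvar_stars = NA, hgmd_class = NA, revel = NA,
                       pvs1_strength = NA, external_verdict = NA,
                       gnomad_af = NA, dbsnp_id = NA) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             transcript_id = transcript_id, is_mane = is_mane,
             consequence = consequence, impact = impact,
             transcript_length = transcript_length,
             clinvar_significance = clinvar_significance,
             clinvar_stars = clinvar_stars, hgmd_class = hgmd_class,
             revel = revel, pvs1_strength = pvs1_strength,
             external_verdict = external_verdict, gnomad_af = gnomad_af,
             dbsnp_id = dbsnp_id, stringsAsFactors = FALSE)
}

blank_phenotype <- function(ids) {
  data.frame(participant = ids, ecg_abnormal = FALSE,
             self_heart_disease = FALSE, revascularization = FALSE,
             family_heart_disease = FALSE, self_cancer = FALSE,
             parent_cancer = FALSE, tumor_surgery = FALSE,
             early_screening = FALSE, total_chol = 4.5, hdl = 1.2, ldl = 2.8,
             hypercholesterolemia_dx = FALSE, age = 40, sex = "F",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
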