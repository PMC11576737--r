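resolve_path <- function(p, base) {
  if (is.null(p) || is.na(p)) return(NULL)
  if (file.exists(p) || grepl("^/", p)) p else file.path(base, p)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    base <- dirname(normalizePath(config, mustWork = TRUE))
    cfg <- yaml::read_yaml(config)
    for (f in c("vcf", "annotation", "phenotypes", "catalog", "region_map",
                "reference"))
      if (!is.null(cfg[[f]])) cfg[[f]] <- resolve_path(cfg[[f]], base)
    cfg
  } else if (is.list(config)) config
  else stopf("config must be a YAML path or a list")
}

#' Run the full secondary-findings triage pipeline
#'
#' Executes read, decompose/normalize, cohort allele frequencies, transcript
#' selection, classification, genotype-positive-participant identification,
#' reportability, category summaries with prevalence estimates, and (when
#' phenotype data is supplied) candidate selection and Fisher association.
#' All output tables are written as TSV plus a JSON report; re-running on
#' identical inputs yields byte-identical outputs.
#'
#' @param config YAML path or list with fields `vcf`, `annotation`,
#'   `catalog`, `region_map` and optionally `phenotypes`, `reference`,
#'   `thresholds` (named overrides for [sft_thresholds()]), `association`
#'   (logical), `ldl_threshold`, `or_method`, `percent_mode`.
#' @param out_dir Output directory for TSVs and `report.json` (NULL skips
#'   writing).
#' @return Object of class `sft_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  for (f in c("vcf", "annotation", "catalog", "region_map"))
    if (is.null(cfg[[f]])) stopf("config is missing required field '%s'", f)
  log <- new_log()
  t <- do.call(sft_thresholds, cfg$thresholds %||% list())

  catalog <- read_gene_catalog(cfg$catalog)
  region_map <- read_region_map(cfg$region_map, catalog)
  log_add(log, "catalog", "genes", nrow(catalog))

  vcfdat <- read_multisample_vcf(cfg$vcf, region_map, catalog)
  log_add(log, "read_vcf", "sites_kept", nrow(vcfdat$sites))
  log_add(log, "read_vcf", "sites_skipped_non_pass",
          sum(vcfdat$skipped$reason == "non_pass"))
  log_add(log, "read_vcf", "sites_skipped_off_gene",
          sum(vcfdat$skipped$reason == "off_gene"))

  ref_fetch <- if (!is.null(cfg$reference)) make_ref_fetch(cfg$reference) else NULL
  cv <- cohort_variants(vcfdat, ref_fetch)
  log_add(log, "decompose_normalize", "biallelic_records", nrow(cv$variants))
  log_add(log, "decompose_normalize", "records_dropped", nrow(cv$dropped))

  ann <- load_annotation_table(cfg$annotation)
  selected <- select_transcripts(ann)
  log_add(log, "transcript_selection", "variants_annotated", nrow(selected))

  keys <- rownames(cv$variants)
  carriers_by_variant <- lapply(keys, function(k) {
    d <- cv$dosage[, k]
    rownames(cv$dosage)[!is.na(d) & d >= 1]
  })
  names(carriers_by_variant) <- keys
  carriers_n <- lengths(carriers_by_variant)
  genes <- stats::setNames(cv$variants$gene, keys)

  phenotypes <- NULL; evidence <- NULL
  do_assoc <- isTRUE(cfg$association %||% !is.null(cfg$phenotypes))
  if (do_assoc && is.null(cfg$phenotypes))
    stopf("phenotype_assoc stage requested but config names no phenotype file")
  if (!is.null(cfg$phenotypes)) {
    phenotypes <- read_phenotypes(cfg$phenotypes)
    evidence <- derive_evidence(phenotypes, cfg$ldl_threshold %||% 4.9)
    log_add(log, "phenotypes", "participants", nrow(phenotypes))
  }

  cohort_evidence <- stats::setNames(rep(FALSE, length(keys)), keys)
  candidates <- NULL
  if (!is.null(evidence)) {
    candidates <- select_candidates(carriers_by_variant, genes, evidence,
                                    catalog)
    cohort_evidence[candidates$variant_id] <- candidates$candidate
    log_add(log, "candidate_selection", "candidates",
            sum(candidates$candidate))
  }

  classified <- classify_cohort(cv$variants, selected, carriers_n, catalog,
                                t, cohort_evidence)
  for (lst in CLASSIFICATION_LISTS)
    log_add(log, "classification", lst, sum(classified$list == lst))

  findings <- identify_gpps(classified, cv$dosage)
  findings <- reportable_under_acmg(findings, catalog)
  log_add(log, "gpp", "findings", nrow(findings))
  log_add(log, "gpp", "distinct_gpp", length(unique(findings$participant)))

  n_cohort <- length(vcfdat$samples)
  summary <- summarize_by_category(findings, catalog)
  rep_gpp <- unique(findings$participant[findings$reportable])
  carrier_only_f <- findings[findings$carrier_only, , drop = FALSE]
  carrier_only_gpp <- setdiff(unique(carrier_only_f$participant), rep_gpp)
  prevalences <- if (n_cohort > 0) list(
    gpp_all = prevalence(length(unique(findings$participant)), n_cohort),
    reportable = prevalence(length(rep_gpp), n_cohort),
    carrier_only = prevalence(length(carrier_only_gpp), n_cohort)
  ) else list()

  associations <- NULL
  if (do_assoc && !is.null(candidates)) {
    eligible <- rownames(classified)[classified$list %in% c("LP2", "pVUS")]
    cand_tested <- candidates[candidates$variant_id %in% eligible, , drop = FALSE]
    associations <- associate_candidates(cand_tested, carriers_by_variant,
                                         evidence,
                                         or_method = cfg$or_method %||% "conditional")
    log_add(log, "association", "variants_tested", nrow(associations))
  }

  multi <- multi_variant_carriers(findings)

  per_list <- vapply(CLASSIFICATION_LISTS, function(l)
    sum(classified$list == l), integer(1))
  gpp_per_list <- vapply(CLASSIFICATION_LISTS, function(l)
    length(unique(findings$participant[findings$list == l])), integer(1))

  report <- structure(list(
    thresholds = unclass(t),
    n_participants = n_cohort,
    variant_counts = as.list(per_list),
    gpp_counts = as.list(gpp_per_list),
    distinct_gpp = length(unique(findings$participant)),
    reportable_gpp = length(rep_gpp),
    reportable_variants = length(unique(findings$variant_id[findings$reportable])),
    carrier_only_gpp = length(carrier_only_gpp),
    carrier_only_variants = length(unique(carrier_only_f$variant_id)),
    prevalences = prevalences,
    summary = summary,
    classified = classified,
    findings = findings,
    candidates = candidates,
    associations = associations,
    multi_gene_carriers = multi,
    skipped = vcfdat$skipped,
    dropped = cv$dropped,
    log = log$entries), class = "sft_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$classified, file.path(out_dir, "classification.tsv"))
  write_tsv(report$findings, file.path(out_dir, "findings.tsv"))
  write_tsv(report$summary$by_gene, file.path(out_dir, "summary_by_gene.tsv"))
  write_tsv(report$summary$by_category,
            file.path(out_dir, "summary_by_category.tsv"))
  if (!is.null(report$associations))
    write_tsv(report$associations, file.path(out_dir, "associations.tsv"))
  json <- report[c("thresholds", "n_participants", "variant_counts",
                   "gpp_counts", "distinct_gpp", "reportable_gpp",
                   "reportable_variants", "carrier_only_gpp",
                   "carrier_only_variants")]
  json$schema_version <- "1.0"
  json$prevalences <- lapply(report$prevalences, unclass)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
#' @method print sft_report
print.sft_report <- function(x, ...) {
  cat("Secondary-findings triage report\n")
  cat(sprintf("  cohort: %d participants\n", x$n_participants))
  vc <- x$variant_counts
  cat(sprintf("  variants: P1 %d | P2 %d | LP1 %d | LP2 %d | pVUS %d | rejected %d | unclassified %d\n",
              vc$P1, vc$P2, vc$LP1, vc$LP2, vc$pVUS, vc$rejected,
              vc$unclassified))
  cat(sprintf("  distinct GPPs: %d (reportable %d, AR carrier-only %d)\n",
              x$distinct_gpp, x$reportable_gpp, x$carrier_only_gpp))
  if (length(x$prevalences) > 0) {
    cat("  reportable prevalence: ")
    print(x$prevalences$reportable)
  }
  invisible(x)
}

#' Validate pipeline inputs without running the analysis
#'
#' Checks catalog size and codes, annotation columns, and sample-identifier
#' concordance between VCF and phenotype table; returns findings rather
#' than erroring, distinguishing warnings from fatal problems.
#'
#' @param config YAML path or list (see [run_pipeline()]).
#' @return data.frame with columns `level` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows means fully consistent inputs.
#' @export
validate_inputs <- function(config) {
  cfg <- load_run_config(config)
  out <- data.frame(level = character(), message = character(),
                    stringsAsFactors = FALSE)
  note <- function(level, msg) {
    out <<- rbind(out, data.frame(level = level, message = msg,
                                  stringsAsFactors = FALSE))
  }
  catalog <- tryCatch(read_gene_catalog(cfg$catalog),
                      error = function(e) { note("fatal", conditionMessage(e)); NULL })
  if (!is.null(catalog)) {
    if (nrow(catalog) != 78)
      note("warning", sprintf("catalog has %d genes (SF v3.1 has 78)",
                              nrow(catalog)))
    rmap <- tryCatch(read_region_map(cfg$region_map, catalog),
                     error = function(e) { note("fatal", conditionMessage(e)); NULL })
  }
  ann_ok <- tryCatch({ load_annotation_table(cfg$annotation); TRUE },
                     error = function(e) { note("fatal", conditionMessage(e)); FALSE })
  samples <- tryCatch({
    validate_vcf_structure(cfg$vcf)
    hdr <- grep("^#CHROM\t", readLines(cfg$vcf), value = TRUE)[1]
    strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
  }, error = function(e) { note("fatal", conditionMessage(e)); NULL })
  if (!is.null(cfg$phenotypes) && !is.null(samples)) {
    ph <- tryCatch(read_phenotypes(cfg$phenotypes),
                   error = function(e) { note("fatal", conditionMessage(e)); NULL })
    if (!is.null(ph)) {
      missing_ph <- setdiff(samples, ph$participant)
      if (length(missing_ph) > 0)
        note("warning", sprintf("%d VCF sample(s) missing from phenotype table: %s",
                                length(missing_ph),
                                paste(utils::head(missing_ph, 10), collapse = ", ")))
    }
  }
  out
}
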