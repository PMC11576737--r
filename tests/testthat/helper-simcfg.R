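# single-variant simulation config used by simulator and recovery tests
one_variant_cfg <- function(q, f, n, seed = 1L, truth = "common",
                            planted_or = NA_real_, evidence_type = NA_character_,
                            p0 = 0.05) {
  specs <- data.frame(id = "v1", gene = "TTN", truth = truth, recipe = truth,
                      af = q, type = "snv", consequence = NA,
                      planted_or = planted_or, evidence_type = evidence_type,
                      mode = "hw", site_group = NA, force_hom_n = 0L,
                      comphet_with = NA, force_evidence = "auto", mane = TRUE,
                      write_style = "plain", filter = "PASS", off_gene = FALSE,
                      stringsAsFactors = FALSE)
  sim_config(n_participants = n, seed = seed, inbreeding_f = f,
             variant_specs = specs, missing_rate = 0,
             phenotype_baseline = c(CVD = p0, cancer = p0, FH = p0))
}
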