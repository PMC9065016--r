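# Small study configurations reused across tests. Sizes are kept small so a
# full suite run stays fast; power-sensitive checks build their own larger
# worlds.

tiny_config <- function(...) {
  defaults <- list(n_cohorts = 2L, n_samples_per_cohort = 120L,
                   n_cpgs = 60L, n_snps = 60L, n_prs_snps = 10L,
                   frac_crp_responsive = 0.1, frac_cpg_causal = 0.05,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# An all-null world: no CRP-CpG effects in either direction.
null_config <- function(...) {
  tiny_config(frac_crp_responsive = 0, frac_cpg_causal = 0,
              gamma_range = c(0, 0), ...)
}

# Per-cohort EWAS summaries for a study, with the standard filters applied.
study_summaries <- function(study, covariates = ewas_covariates("base")) {
  lapply(study$cohorts, function(co) {
    ph <- exclude_crp_outliers(co$phenotypes)
    fit_cpg_associations(co$methylation[ph$sample_id, , drop = FALSE], ph,
                         covariates = covariates,
                         probes = filter_probes(co$annotation),
                         cohort = co$cohort)
  })
}

# A toy GRanges track covering given 1-based CpG positions.
track_for_positions <- function(chrom, pos1based) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = pos1based, width = 1))
}
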