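# Pipeline driver: ties the stages together on a simulated (or loaded)
# multi-cohort study and records a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage threshold with its study default: discovery
#' `P < 1e-7`, ancestry replication `P < 0.05`, genome-wide instrument
#' `P < 5e-8`, cis window 500,000 bp, pruning window 5,000 bp, 10,000
#' permutations with 0.005-wide SE bins, mediation gate alpha 0.05.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param discovery_p,replication_p,instrument_p,cis_window,prune_window
#'   stage thresholds.
#' @param n_perm,se_bin_width enrichment permutation settings.
#' @param mediation_alpha mediation gate level.
#' @param cluster_k,cluster_min_pts,cluster_eps correlation-cluster settings.
#' @param seed master seed for the randomized stages.
#' @param chr_dialect `"plain"` or `"chr"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            discovery_p = 1e-7, replication_p = 0.05,
                            instrument_p = 5e-8, cis_window = 5e5,
                            prune_window = 5000, n_perm = 10000,
                            se_bin_width = 0.005, mediation_alpha = 0.05,
                            cluster_k = 35, cluster_min_pts = 35,
                            cluster_eps = 7, seed = 1,
                            chr_dialect = "plain") {
  structure(list(sim = sim, discovery_p = discovery_p,
                 replication_p = replication_p, instrument_p = instrument_p,
                 cis_window = cis_window, prune_window = prune_window,
                 n_perm = n_perm, se_bin_width = se_bin_width,
                 mediation_alpha = mediation_alpha, cluster_k = cluster_k,
                 cluster_min_pts = cluster_min_pts, cluster_eps = cluster_eps,
                 seed = seed, chr_dialect = chr_dialect),
            class = "pipeline_config")
}

#' Run the pipeline end to end on a synthetic study
#'
#' Stages, in dependency order: simulate the study; per-cohort EWAS with
#' probe and CRP-outlier filters; IVW meta-analysis with genomic control in
#' and out; 5 kb locus pruning of the discovery hits; per-cohort
#' residualization and correlation meta-analysis over the pruned loci;
#' BMI-exposure mediation with pooled paths; CpG-to-CRP MR on the combined
#' samples; SE-matched permutation enrichment against a feature track (when
#' supplied); methylation risk score built from the discovery coefficients.
#' A manifest records package version, seeds, thresholds and per-stage
#' output sizes so a rerun with the same config reproduces the run exactly.
#'
#' @param config a [pipeline_config()].
#' @param track optional `GRanges` feature track for the enrichment stage.
#' @param stages character subset of
#'   `c("ewas", "meta", "prune", "correlation", "mediation", "mr",
#'   "enrichment", "score")`; earlier stages required by a requested stage
#'   are run automatically.
#' @param out_dir optional directory for TSV outputs.
#' @return List of class `pipeline_result` with per-stage outputs and
#'   `manifest`.
#' @export
run_pipeline <- function(config, track = NULL,
                         stages = c("ewas", "meta", "prune", "correlation",
                                    "mediation", "mr", "score"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("ewas", "meta", "prune", "correlation", "mediation", "mr",
                  "enrichment", "score")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # close over dependencies
  need <- function(s) match(s, all_stages)
  stages <- all_stages[all_stages %in% all_stages[seq_len(max(need(stages)))]]
  if ("enrichment" %in% stages && is.null(track))
    stages <- setdiff(stages, "enrichment")

  study <- simulate_study(config$sim)
  keep_probes <- filter_probes(study$cohorts[[1]]$annotation)
  ann <- study$cohorts[[1]]$annotation

  res <- list(config = config, truth = study$truth)

  # per-cohort EWAS
  summaries <- lapply(study$cohorts, function(co) {
    ph <- exclude_crp_outliers(co$phenotypes)
    meth <- co$methylation[ph$sample_id, , drop = FALSE]
    fit_cpg_associations(meth, ph, probes = keep_probes, cohort = co$cohort)
  })
  res$ewas <- summaries

  meta <- meta_ewas(summaries, gc = c("in", "out"))
  res$meta <- meta
  if (!"meta" %in% stages) return(finish_pipeline(res, out_dir))

  hits <- meta[meta$p_gc < config$discovery_p, , drop = FALSE]
  res$hits <- hits

  if ("prune" %in% stages) {
    hdf <- data.frame(cpg = hits$cpg,
                      chromosome = ann$chromosome[match(hits$cpg, ann$cpg)],
                      position = ann$position[match(hits$cpg, ann$cpg)],
                      p = hits$p_gc, stringsAsFactors = FALSE)
    res$loci <- prune_5kb(hdf, window = config$prune_window)
  }

  resid <- lapply(study$cohorts, function(co) {
    qn <- quantile_normalize(co$methylation)
    residualize_methylation(qn, co$phenotypes)
  })

  if ("correlation" %in% stages && length(res$loci$retained) >= 2) {
    corr <- do.call(rbind, lapply(names(resid), function(nm)
      pairwise_correlations(resid[[nm]], probes = res$loci$retained,
                            cohort = nm)))
    res$correlation <- meta_correlation(corr)
    res$distance_profile <- bin_by_distance(res$correlation, ann)
  }

  if ("mediation" %in% stages && nrow(hits) > 0) {
    med <- lapply(study$cohorts, function(co) {
      ph <- exclude_bmi_outliers(exclude_crp_outliers(co$phenotypes))
      rm <- resid[[co$cohort]][ph$sample_id,
                               intersect(hits$cpg, colnames(resid[[1]])),
                               drop = FALSE]
      baron_kenny_paths(ph$bmi, ph$lncrp, rm, model = "model1")
    })
    res$mediation <- meta_mediation(med, alpha = config$mediation_alpha)
  }

  if ("mr" %in% stages && nrow(hits) > 0) {
    geno <- do.call(rbind, lapply(study$cohorts, `[[`, "genotypes"))
    rmeth <- do.call(rbind, resid)
    lncrp <- unlist(lapply(study$cohorts,
                           function(co) co$phenotypes$lncrp))
    res$mr <- mr_cpg_to_crp(intersect(hits$cpg, colnames(rmeth)), geno,
                            rmeth, study$cohorts[[1]]$snp_map, ann, lncrp,
                            window = config$cis_window,
                            instrument_p = config$instrument_p)
  }

  if ("enrichment" %in% stages && nrow(hits) > 0) {
    universe <- data.frame(cpg = meta$cpg, se = meta$se,
                           stringsAsFactors = FALSE)
    res$enrichment <- enrichment_test(universe, hits$cpg, ann, track,
                                      n_perm = config$n_perm,
                                      bin_width = config$se_bin_width,
                                      seed = config$seed)
  }

  if ("score" %in% stages && nrow(hits) > 0) {
    weights <- data.frame(cpg = hits$cpg, coefficient = hits$effect,
                          subset = "all", stringsAsFactors = FALSE)
    res$score <- lapply(study$cohorts, function(co)
      methylation_risk_score(co$methylation, weights))
  }

  finish_pipeline(res, out_dir)
}

finish_pipeline <- function(res, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("inflamethyl")),
    seed = res$config$seed, sim_seed = res$config$sim$seed,
    thresholds = res$config[c("discovery_p", "replication_p", "instrument_p",
                              "cis_window", "prune_window", "n_perm",
                              "se_bin_width", "mediation_alpha")],
    stage_sizes = list(
      cohorts = length(res$ewas),
      cpgs_tested = if (!is.null(res$meta)) nrow(res$meta) else 0L,
      discovery_hits = if (!is.null(res$hits)) nrow(res$hits) else 0L,
      independent_loci = length(res$loci$retained),
      mediation_eligible = if (!is.null(res$mediation))
        sum(res$mediation$gate_status == "eligible") else 0L,
      mr_instruments = if (!is.null(res$mr)) nrow(res$mr) else 0L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(res$ewas))
      write_summary_tsv(res$ewas[[i]],
                        file.path(out_dir, paste0("ewas_",
                                                  res$ewas[[i]]$cohort[1],
                                                  ".tsv")))
    if (!is.null(res$meta))
      utils::write.table(as.data.frame(res$meta),
                         file.path(out_dir, "meta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  ss <- x$manifest$stage_sizes
  cat("inflamethyl pipeline run\n")
  cat(sprintf("  cohorts: %d, CpGs tested: %d\n", ss$cohorts, ss$cpgs_tested))
  cat(sprintf("  discovery hits: %d -> independent loci: %d\n",
              ss$discovery_hits, ss$independent_loci))
  cat(sprintf("  mediation eligible: %d; MR instruments: %d\n",
              ss$mediation_eligible, ss$mr_instruments))
  invisible(x)
}
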