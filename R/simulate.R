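# Multi-cohort synthetic data generator with a known causal graph.
#
# The generative model mirrors the structure of a large multi-cohort EWAS of
# serum CRP: BMI, smoking and a polygenic score drive ln(CRP); the dominant
# arm of the graph is CRP -> CpG (crp_responsive CpGs respond to ln CRP on
# the logit-methylation scale); a minority arm is CpG -> CRP, where cis-SNP
# driven methylation feeds back into ln CRP (cpg_causal CpGs). Cell-type
# composition, batch, a technical covariate and local "block" correlation
# confound methylation. Everything needed for parameter-recovery tests is
# recorded in a truth table shared across cohorts.

#' Configuration for the synthetic multi-cohort study
#'
#' Defaults describe the simulated study conditions: a 30-cohort design with
#' per-cohort sample sizes drawn between 150 and 2,700, beta-value
#' methylation in (0,1) generated on the logit scale, log-normal CRP driven
#' by BMI, smoking and a genetic score, and ancestry-specific scaling of the
#' CRP-to-CpG effects.
#'
#' @param n_cohorts number of cohorts.
#' @param n_samples_per_cohort integer vector (recycled) of per-cohort sample
#'   sizes, or `NULL` to draw sizes uniformly in \[150, 2700\].
#' @param n_cpgs number of CpG probes (>= 10).
#' @param n_snps total number of SNPs; must cover one cis-SNP per causal CpG
#'   plus `n_prs_snps`.
#' @param n_prs_snps number of SNPs forming the CRP polygenic score.
#' @param frac_crp_responsive fraction of CpGs whose methylation responds to
#'   ln CRP (the dominant direction).
#' @param frac_cpg_causal fraction of CpGs causal for CRP via a cis-SNP.
#' @param effect_bmi_on_lncrp ln mg/L CRP per kg/m^2 BMI.
#' @param effect_smoke_on_lncrp ln mg/L CRP per smoking-status category
#'   (never/former/current coded 0/1/2).
#' @param effect_prs_on_lncrp ln mg/L CRP per SD of the true polygenic score.
#' @param gamma_range range of the CRP-to-CpG slope gamma (methylation beta
#'   units per ln mg/L, evaluated at each CpG's baseline mean).
#' @param delta_range range of the CpG-to-CRP slope for causal CpGs
#'   (ln mg/L per methylation unit).
#' @param maf_range minor allele frequency range, within (0, 0.5].
#' @param cell_fraction_dirichlet named Dirichlet concentration vector for the
#'   six leukocyte fractions (CD4T, NK, Bcell, Mono, Neu, Eos).
#' @param batch_sd SD of batch shifts on the logit-methylation scale (>= 0).
#' @param noise_sd_meth SD of per-CpG noise on the logit scale (> 0).
#' @param noise_sd_lncrp SD of the residual ln CRP noise.
#' @param ancestry_scaling per-cohort multiplier on gamma (recycled).
#' @param frac_probe_snp fraction of probes flagged as having a SNP in the
#'   last 10 bp of the probe sequence.
#' @param frac_cross_reactive fraction of probes flagged cross-reactive.
#' @param frac_sex_chr fraction of probes placed on a sex chromosome.
#' @param block_prob probability that a CpG is part of a tight (< 5 kb)
#'   correlated block rather than an isolated locus.
#' @param seed integer RNG seed; per-cohort substreams are derived as
#'   `seed + cohort_index`.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cohorts = 2, n_samples_per_cohort = 100, n_cpgs = 50,
#'                   n_snps = 60, seed = 7)
sim_config <- function(n_cohorts = 30L,
                       n_samples_per_cohort = NULL,
                       n_cpgs = 2000L,
                       n_snps = 150L,
                       n_prs_snps = 52L,
                       frac_crp_responsive = 0.05,
                       frac_cpg_causal = 0.01,
                       effect_bmi_on_lncrp = 0.08,
                       effect_smoke_on_lncrp = 0.15,
                       effect_prs_on_lncrp = 0.25,
                       gamma_range = c(0.01, 0.05),
                       delta_range = c(2, 6),
                       maf_range = c(0.1, 0.4),
                       cell_fraction_dirichlet = c(CD4T = 9, NK = 2, Bcell = 3,
                                                   Mono = 4, Neu = 30, Eos = 1),
                       batch_sd = 0.1,
                       noise_sd_meth = 0.3,
                       noise_sd_lncrp = 0.8,
                       ancestry_scaling = 1,
                       frac_probe_snp = 0.03,
                       frac_cross_reactive = 0.03,
                       frac_sex_chr = 0.02,
                       block_prob = 0.2,
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples_per_cohort = n_samples_per_cohort,
              n_cpgs = as.integer(n_cpgs), n_snps = as.integer(n_snps),
              n_prs_snps = as.integer(n_prs_snps),
              frac_crp_responsive = frac_crp_responsive,
              frac_cpg_causal = frac_cpg_causal,
              effect_bmi_on_lncrp = effect_bmi_on_lncrp,
              effect_smoke_on_lncrp = effect_smoke_on_lncrp,
              effect_prs_on_lncrp = effect_prs_on_lncrp,
              gamma_range = gamma_range, delta_range = delta_range,
              maf_range = maf_range,
              cell_fraction_dirichlet = cell_fraction_dirichlet,
              batch_sd = batch_sd, noise_sd_meth = noise_sd_meth,
              noise_sd_lncrp = noise_sd_lncrp,
              ancestry_scaling = ancestry_scaling,
              frac_probe_snp = frac_probe_snp,
              frac_cross_reactive = frac_cross_reactive,
              frac_sex_chr = frac_sex_chr,
              block_prob = block_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_crp_responsive, cfg$frac_cpg_causal, cfg$frac_probe_snp,
          cfg$frac_cross_reactive, cfg$frac_sex_chr, cfg$block_prob)
  n_causal <- round(cfg$frac_cpg_causal * cfg$n_cpgs)
  stop_unless(
    "n_cohorts must be >= 1" = cfg$n_cohorts >= 1L,
    "n_cpgs must be >= 10" = cfg$n_cpgs >= 10L,
    "all fractions must lie in [0,1]" = all(fr >= 0 & fr <= 1),
    "frac_crp_responsive + frac_cpg_causal must be <= 1" =
      cfg$frac_crp_responsive + cfg$frac_cpg_causal <= 1,
    "maf_range must lie within (0, 0.5]" =
      length(cfg$maf_range) == 2L && cfg$maf_range[1] > 0 &&
      cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
    "gamma_range must be a non-decreasing pair" =
      length(cfg$gamma_range) == 2L && diff(cfg$gamma_range) >= 0,
    "cell_fraction_dirichlet must be positive (degenerate concentration)" =
      all(cfg$cell_fraction_dirichlet > 0) &&
      length(cfg$cell_fraction_dirichlet) == 6L,
    "batch_sd must be >= 0" = cfg$batch_sd >= 0,
    "noise_sd_meth must be > 0" = cfg$noise_sd_meth > 0,
    "n_snps too small for the causal CpGs plus the polygenic score" =
      cfg$n_snps >= n_causal + cfg$n_prs_snps,
    "n_samples_per_cohort must be positive" =
      is.null(cfg$n_samples_per_cohort) || all(cfg$n_samples_per_cohort >= 2)
  )
  invisible(cfg)
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Ground truth shared by all simulated cohorts
#'
#' Builds the probe annotation, SNP map, CpG class labels
#' (`crp_responsive` / `cpg_causal` / `null`), planted slopes and the
#' polygenic-score weights. Deterministic in `config$seed` and identical for
#' every cohort of a study.
#'
#' @param config a [sim_config()].
#' @return A data frame of class `truth_table` (one row per CpG) with
#'   attributes `snp_map`, `annotation`, `prs_weights`, `lncrp_model`,
#'   `n_per_cohort`, `ancestry_scaling` and `cell_effects`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    p <- config$n_cpgs
    cpg_id <- sprintf("cg%07d", seq_len(p))

    # two synthetic autosomes plus a small sex-chromosome contingent
    chrom <- sample(c("1", "2"), p, replace = TRUE)
    on_x <- stats::runif(p) < config$frac_sex_chr
    chrom[on_x] <- "X"

    # genomic placement: isolated loci plus tight blocks within < 5 kb
    position <- integer(p)
    block <- integer(p)
    next_block <- 0L
    i <- 1L
    while (i <= p) {
      in_block <- stats::runif(1) < config$block_prob && i < p
      base <- sample.int(2e8L, 1L)
      if (in_block) {
        size <- min(sample(2:3, 1L), p - i + 1L)
        next_block <- next_block + 1L
        idx <- i:(i + size - 1L)
        position[idx] <- base + c(0L, cumsum(sample(300:1800, size - 1L,
                                                    replace = TRUE)))
        chrom[idx] <- chrom[i]
        block[idx] <- next_block
        i <- i + size
      } else {
        position[i] <- base
        i <- i + 1L
      }
    }

    snp_in_probe <- stats::runif(p) < config$frac_probe_snp
    cross_reactive <- stats::runif(p) < config$frac_cross_reactive
    annotation <- data.frame(
      cpg = cpg_id, chromosome = chrom, position = position,
      is_autosomal = chrom %in% c("1", "2"),
      snp_in_last10bp = snp_in_probe, cross_reactive = cross_reactive,
      island_relation = sample(c("island", "shore", "shelf", "open_sea"), p,
                               replace = TRUE, prob = c(.15, .2, .1, .55)),
      stringsAsFactors = FALSE)

    # planted classes live on clean autosomal probes only
    eligible <- which(annotation$is_autosomal & !snp_in_probe & !cross_reactive)
    n_resp <- round(config$frac_crp_responsive * p)
    n_causal <- round(config$frac_cpg_causal * p)
    planted <- sample(eligible, n_resp + n_causal)
    class <- rep("null", p)
    class[planted[seq_len(n_resp)]] <- "crp_responsive"
    if (n_causal > 0)
      class[planted[n_resp + seq_len(n_causal)]] <- "cpg_causal"

    gamma <- rep(0, p)
    gamma[class == "crp_responsive"] <-
      stats::runif(n_resp, config$gamma_range[1], config$gamma_range[2]) *
      sample(c(-1, 1), n_resp, replace = TRUE)
    delta <- rep(0, p)
    delta[class == "cpg_causal"] <-
      stats::runif(n_causal, config$delta_range[1], config$delta_range[2]) *
      sample(c(-1, 1), n_causal, replace = TRUE)

    # baseline methylation kept off the boundaries
    mu <- stats::runif(p, 0.15, 0.85)

    # SNP map: one cis-SNP per causal CpG, the polygenic-score SNPs, then
    # background SNPs scattered over the two autosomes
    n_snps <- config$n_snps
    snp_id <- sprintf("rs%06d", seq_len(n_snps))
    snp_chr <- sample(c("1", "2"), n_snps, replace = TRUE)
    snp_pos <- sample.int(2e8L, n_snps, replace = TRUE)
    causal_idx <- which(class == "cpg_causal")
    cis_snp <- rep(NA_character_, p)
    if (n_causal > 0) {
      for (k in seq_len(n_causal)) {
        j <- causal_idx[k]
        snp_chr[k] <- annotation$chromosome[j]
        snp_pos[k] <- max(1L, annotation$position[j] +
                            sample(seq(-4e5L, 4e5L), 1L))
        cis_snp[j] <- snp_id[k]
      }
    }
    is_prs <- seq_len(n_snps) > n_causal &
      seq_len(n_snps) <= n_causal + config$n_prs_snps
    maf <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
    snp_map <- data.frame(snp = snp_id, chromosome = snp_chr,
                          position = snp_pos, effect_allele = "A", maf = maf,
                          in_prs = is_prs, stringsAsFactors = FALSE)

    cis_beta <- rep(0, p)
    cis_beta[causal_idx] <- stats::runif(n_causal, 0.35, 0.6) *
      sample(c(-1, 1), n_causal, replace = TRUE)

    prs_weights <- stats::rnorm(sum(is_prs), 0, 1)
    names(prs_weights) <- snp_id[is_prs]

    # nuisance structure: leukocyte-composition and technical loadings
    cell_effects <- matrix(stats::rnorm(p * 6, 0, 0.5), nrow = p,
                           dimnames = list(cpg_id,
                                           names(config$cell_fraction_dirichlet)))
    tech_effects <- stats::rnorm(p, 0, 0.1)

    n_per_cohort <- if (is.null(config$n_samples_per_cohort))
      sample(150:2700, config$n_cohorts, replace = TRUE)
    else
      as.integer(rep_len(config$n_samples_per_cohort, config$n_cohorts))

    truth <- data.frame(cpg = cpg_id, class = class, gamma = gamma, mu = mu,
                        delta = delta, cis_snp = cis_snp, cis_beta = cis_beta,
                        block = block, stringsAsFactors = FALSE)
    attr(truth, "annotation") <- annotation
    attr(truth, "snp_map") <- snp_map
    attr(truth, "prs_weights") <- prs_weights
    attr(truth, "cell_effects") <- cell_effects
    attr(truth, "tech_effects") <- tech_effects
    attr(truth, "n_per_cohort") <- n_per_cohort
    attr(truth, "ancestry_scaling") <-
      rep_len(config$ancestry_scaling, config$n_cohorts)
    attr(truth, "lncrp_model") <- list(
      intercept = 0.3,
      bmi = config$effect_bmi_on_lncrp,
      smoking = config$effect_smoke_on_lncrp,
      prs = config$effect_prs_on_lncrp,
      neutrophil = 1.5,   # cell-composition confounding of ln CRP
      noise_sd = config$noise_sd_lncrp)
    class(truth) <- c("truth_table", "data.frame")
    truth
  })
}

#' Simulate one cohort of the synthetic study
#'
#' Draws phenotypes, genotypes and methylation for a single cohort from the
#' shared causal graph. ln CRP is
#' `intercept + b_BMI (BMI - 27) + b_smoke status + b_PRS PRS + sum_j
#' delta_j (beta_ij - mu_j) + cell term + noise`; responsive CpGs shift on
#' the logit scale by `gamma_j / (mu_j (1 - mu_j)) * (lnCRP - E lnCRP)`, so
#' that the slope of beta on ln CRP at the baseline mean equals `gamma_j`
#' (times the cohort's ancestry scaling). Identical `(config, cohort_index)`
#' yield byte-identical output.
#'
#' @param config a [sim_config()].
#' @param cohort_index 1-based cohort number, `<= config$n_cohorts`.
#' @param truth optionally a precomputed [simulate_truth()] table (it is
#'   deterministic, so passing it merely avoids recomputation).
#' @return A list of class `cohort_data` with elements `methylation`
#'   (samples x CpGs beta matrix), `phenotypes`, `genotypes` (0/1/2 dosages),
#'   `annotation`, `snp_map` and `cohort`.
#' @export
simulate_cohort <- function(config, cohort_index, truth = NULL) {
  validate_sim_config(config)
  if (cohort_index < 1L || cohort_index > config$n_cohorts)
    stop("cohort_index must be between 1 and n_cohorts")
  if (is.null(truth)) truth <- simulate_truth(config)
  ann <- attr(truth, "annotation")
  snp_map <- attr(truth, "snp_map")
  lnm <- attr(truth, "lncrp_model")
  n <- attr(truth, "n_per_cohort")[cohort_index]
  if (n < 2) stop("non-positive or degenerate cohort sample size")
  scaling <- attr(truth, "ancestry_scaling")[cohort_index]
  p <- nrow(truth)

  with_seed(config$seed + cohort_index, {
    sample_id <- sprintf("c%02d_s%05d", cohort_index, seq_len(n))
    age <- round(stats::rnorm(n, 50, 10))
    sex <- stats::rbinom(n, 1, 0.5)
    bmi <- stats::rnorm(n, 27, 4.5)
    smoking_status <- sample(0:2, n, replace = TRUE, prob = c(.5, .3, .2))
    packyears <- ifelse(smoking_status > 0,
                        stats::rgamma(n, shape = 2, scale = 8), 0)
    cells <- rdirichlet(n, config$cell_fraction_dirichlet)
    batch <- factor(sample(paste0("b", 1:3), n, replace = TRUE))
    tech1 <- stats::rnorm(n)

    geno <- vapply(snp_map$maf,
                   function(q) stats::rbinom(n, 2L, q), integer(n))
    dimnames(geno) <- list(sample_id, snp_map$snp)

    prs_w <- attr(truth, "prs_weights")
    prs_true <- drop(geno[, names(prs_w), drop = FALSE] %*% prs_w)
    prs_z <- if (stats::sd(prs_true) > 0)
      (prs_true - mean(prs_true)) / stats::sd(prs_true) else prs_true * 0

    # logit-scale nuisance shared by all CpGs
    cell_eff <- attr(truth, "cell_effects")       # p x 6
    tech_eff <- attr(truth, "tech_effects")
    cells_c <- sweep(cells, 2, colMeans(cells))
    nuisance <- tcrossprod(cells_c, cell_eff) +   # n x p
      outer(tech1, tech_eff)
    if (config$batch_sd > 0) {
      bshift <- matrix(stats::rnorm(nlevels(batch) * p, 0, config$batch_sd),
                       nrow = nlevels(batch))
      nuisance <- nuisance + bshift[as.integer(batch), , drop = FALSE]
    }
    # tight genomic blocks share a latent factor (local co-methylation)
    if (any(truth$block > 0)) {
      nb <- max(truth$block)
      u <- matrix(stats::rnorm(n * nb, 0, config$noise_sd_meth), nrow = n)
      inblk <- truth$block > 0
      nuisance[, inblk] <- nuisance[, inblk] + u[, truth$block[inblk]]
    }
    noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd_meth), nrow = n)

    base_logit <- matrix(logit(truth$mu), n, p, byrow = TRUE)

    # causal CpGs first: methylation driven by the cis-SNP, then feeds CRP
    causal <- which(truth$class == "cpg_causal")
    cis_term <- matrix(0, n, p)
    if (length(causal)) {
      dos <- geno[, truth$cis_snp[causal], drop = FALSE]
      cis_term[, causal] <- sweep(dos, 2, truth$cis_beta[causal], `*`)
    }
    meth_logit <- base_logit + nuisance + noise + cis_term
    meth <- stats::plogis(meth_logit)

    lncrp_mean <- lnm$intercept + lnm$bmi * (bmi - 27) +
      lnm$smoking * smoking_status + lnm$prs * prs_z +
      lnm$neutrophil * (cells[, "Neu"] - mean(cells[, "Neu"]))
    if (length(causal))
      lncrp_mean <- lncrp_mean +
        drop((meth[, causal, drop = FALSE] -
                matrix(truth$mu[causal], n, length(causal), byrow = TRUE)) %*%
               truth$delta[causal])
    lncrp <- lncrp_mean + stats::rnorm(n, 0, lnm$noise_sd)

    # responsive CpGs shift with (centred) ln CRP on the logit scale
    resp <- which(truth$class == "crp_responsive")
    if (length(resp)) {
      slope_logit <- scaling * truth$gamma[resp] /
        (truth$mu[resp] * (1 - truth$mu[resp]))
      shift <- outer(lncrp - mean(lncrp), slope_logit)
      meth[, resp] <- stats::plogis(meth_logit[, resp, drop = FALSE] + shift)
    }
    dimnames(meth) <- list(sample_id, truth$cpg)

    pheno <- data.frame(sample_id = sample_id, age = age, sex = sex,
                        bmi = bmi, smoking_status = smoking_status,
                        packyears = packyears, lncrp = lncrp,
                        cells, batch = batch, tech1 = tech1,
                        stringsAsFactors = FALSE)
    rownames(pheno) <- sample_id

    structure(list(methylation = meth, phenotypes = pheno, genotypes = geno,
                   annotation = ann, snp_map = snp_map,
                   cohort = sprintf("cohort%02d", cohort_index)),
              class = "cohort_data")
  })
}

#' Simulate the full multi-cohort study
#'
#' @inheritParams simulate_cohort
#' @return A list of class `sim_study` with elements `cohorts` (list of
#'   [simulate_cohort()] results) and `truth` (the shared [simulate_truth()]
#'   table).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_cohorts = 2, n_samples_per_cohort = 80,
#'                                    n_cpgs = 40, n_snps = 60, seed = 3))
#' length(study$cohorts)
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(i)
    simulate_cohort(config, i, truth = truth))
  names(cohorts) <- vapply(cohorts, `[[`, "", "cohort")
  structure(list(cohorts = cohorts, truth = truth), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  ns <- vapply(x$cohorts, function(co) nrow(co$methylation), 0L)
  cat(sprintf("Synthetic methylation study: %d cohorts, %d CpGs, %d SNPs\n",
              length(x$cohorts), nrow(x$truth),
              nrow(attr(x$truth, "snp_map"))))
  cat(sprintf("  samples per cohort: %s (total %d)\n",
              paste(ns, collapse = ", "), sum(ns)))
  cat(sprintf("  CpG classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort %s: %d samples x %d CpGs, %d SNPs\n", x$cohort,
              nrow(x$methylation), ncol(x$methylation), ncol(x$genotypes)))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Methylation and phenotypes as TSV with samples in rows, genotypes as a
#' PLINK-`.raw`-style 0/1/2 dosage TSV, and the SNP map / CpG annotation as
#' TSV; the generating configuration is written as YAML.
#'
#' @param cohort a `cohort_data` object.
#' @param dir output directory (created if needed).
#' @param config optional [sim_config()] to serialize alongside.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(methylation = file.path(dir, "methylation.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             snp_map = file.path(dir, "snp_map.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_tsv_matrix(cohort$methylation, paths["methylation"], "sample_id")
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(cohort$genotypes, paths["genotypes"], "sample_id")
  utils::write.table(cohort$snp_map, paths["snp_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfgpath <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfgpath)
    paths <- c(paths, config = cfgpath)
  }
  invisible(paths)
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
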