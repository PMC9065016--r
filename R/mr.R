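# Bidirectional two-sample Mendelian randomization: cis-instrument
# discovery under a dominant model, direct-effect exclusion, Wald-ratio
# estimation, the CRP polygenic score arm, and triangulation of predicted
# against observed effects.

#' Dominant recoding of allele dosages
#'
#' @param dosages 0/1/2 dosage vector or matrix.
#' @return Same shape with 1 and 2 collapsed to 1 (carrier indicator).
#' @export
dominant_recode <- function(dosages) {
  out <- (dosages > 0) * 1L
  dimnames(out) <- dimnames(dosages)
  out
}

#' Find cis-SNP instruments for a CpG
#'
#' Scans SNPs within `window` bp of the CpG position on the same chromosome,
#' recodes genotypes to a dominant carrier indicator, and regresses the
#' residualized methylation on each recoded SNP. A candidate is a valid
#' instrument when its association reaches genome-wide significance
#' (`P < 5e-8`); when several qualify, the lowest-P SNP is the instrument.
#'
#' @param cpg probe id.
#' @param genotypes samples x SNPs dosage matrix.
#' @param resid_meth samples x CpGs residualized methylation.
#' @param snp_map data frame `snp`, `chromosome`, `position`.
#' @param annotation CpG annotation (for the CpG position).
#' @param window cis window in bp (+/- 500 kb).
#' @param p_threshold instrument significance threshold.
#' @return Data frame of candidates (`snp`, `cpg`, `beta_snp_cpg`, `se`,
#'   `p`, `valid`) sorted by p, or a zero-row frame when no SNP lies in the
#'   window.
#' @export
find_cis_instruments <- function(cpg, genotypes, resid_meth, snp_map,
                                 annotation, window = 5e5,
                                 p_threshold = 5e-8) {
  j <- match(cpg, annotation$cpg)
  if (is.na(j)) stop("CpG not found in annotation: ", cpg)
  chr <- normalize_chr(annotation$chromosome[j])
  pos <- annotation$position[j]
  insel <- normalize_chr(snp_map$chromosome) == chr &
    abs(snp_map$position - pos) <= window
  empty <- data.frame(snp = character(), cpg = character(),
                      beta_snp_cpg = numeric(), se = numeric(), p = numeric(),
                      valid = logical(), stringsAsFactors = FALSE)
  if (!any(insel)) return(empty)
  snps <- snp_map$snp[insel]
  G <- dominant_recode(genotypes[, snps, drop = FALSE])
  y <- resid_meth[, cpg]
  Z <- matrix(1, length(y), 1)
  fit <- scan_predictors(y, G, Z)
  out <- data.frame(snp = snps, cpg = cpg, beta_snp_cpg = fit$effect,
                    se = fit$se, p = fit$p,
                    valid = !is.na(fit$p) & fit$p < p_threshold,
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Direct-effect exclusion for an instrument
#'
#' Regresses the outcome on the SNP adjusting for the exposure; the
#' instrument fails (is excluded) when the conditional SNP association is
#' significant at `threshold`, evidence of a path to the outcome that does
#' not run through the exposure. Default thresholds are the Bonferroni
#' levels for the two MR directions: `0.05/1511` for CpG instruments
#' against CRP and `0.05/(52*1511)` for CRP-score SNPs against CpGs, both
#' recomputable via [bonferroni_threshold()].
#'
#' @param snp dosage (or carrier) vector for the instrument.
#' @param exposure exposure values (e.g. residualized methylation).
#' @param outcome outcome values (e.g. lnCRP).
#' @param threshold conditional significance level.
#' @return List with `pass` (logical), `p_direct`, and the conditional
#'   `beta`.
#' @export
direct_effect_filter <- function(snp, exposure, outcome,
                                 threshold = bonferroni_threshold(1511)) {
  if (is.null(exposure) || all(is.na(exposure))) stop("exposure missing")
  fit <- stats::lm(outcome ~ snp + exposure)
  cf <- summary(fit)$coefficients
  p_direct <- cf["snp", 4]
  list(pass = p_direct >= threshold, p_direct = p_direct,
       beta = cf["snp", 1])
}

#' Wald ratio MR estimate
#'
#' `estimate = beta_outcome / beta_exposure`, with the first-order delta
#' SE `SE_outcome / |beta_exposure|` and a two-sided normal p-value.
#'
#' @param beta_outcome,se_outcome instrument-outcome path.
#' @param beta_exposure,se_exposure instrument-exposure path.
#' @return Data frame `estimate`, `se`, `z`, `p` (vectorized).
#' @export
#' @examples
#' wald_ratio(0.2, 0.05, 0.1, 0.01)$estimate  # 2
wald_ratio <- function(beta_outcome, se_outcome, beta_exposure,
                       se_exposure = NULL) {
  if (any(beta_exposure == 0, na.rm = TRUE))
    stop("zero exposure-path effect: Wald ratio undefined")
  est <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  z <- est / se
  data.frame(estimate = est, se = se, z = z, p = z_to_p(z))
}

#' Beta-weighted polygenic risk score
#'
#' `score_s = sum_j dosage_sj * beta_j` over the weight table's SNPs
#' (additive coding). SNPs absent from the genotype matrix are skipped with
#' a warning.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param weights named numeric vector (SNP -> beta) or data frame with
#'   `snp` and `beta` columns.
#' @return Per-sample score vector.
#' @export
build_prs <- function(genotypes, weights) {
  if (is.data.frame(weights)) {
    w <- weights$beta
    names(w) <- weights$snp
  } else w <- weights
  present <- intersect(names(w), colnames(genotypes))
  if (!length(present)) stop("none of the weight SNPs present in genotypes")
  if (length(present) < length(w))
    warning(length(w) - length(present), " weight SNP(s) missing; skipped")
  drop(genotypes[, present, drop = FALSE] %*% w[present])
}

#' Association of the CRP polygenic score with each CpG
#'
#' Per-CpG OLS of residualized methylation on the score (additive model),
#' adjusting for the supplied covariates; the p-values come from the t
#' distribution as in the EWAS scan. Bonferroni significance is judged at
#' `0.05 / n_cpgs_tested`.
#'
#' @param prs per-sample score from [build_prs()].
#' @param resid_meth samples x CpGs residualized methylation.
#' @param pheno phenotype table for covariates.
#' @param covariates phenotype columns to adjust for (genetic PCs etc.);
#'   empty for pre-residualized input.
#' @return Data frame `cpg`, `effect`, `se`, `p`, `bonferroni`.
#' @export
prs_cpg_association <- function(prs, resid_meth, pheno = NULL,
                                covariates = character()) {
  if (stats::sd(prs) == 0) {
    warning("constant polygenic score; associations undefined")
    return(data.frame(cpg = colnames(resid_meth), effect = NA_real_,
                      se = NA_real_, p = NA_real_, bonferroni = FALSE,
                      stringsAsFactors = FALSE))
  }
  Z <- if (length(covariates)) covariate_design(pheno, covariates)
       else matrix(1, length(prs), 1)
  fit <- scan_outcomes(resid_meth, prs, Z)
  thr <- bonferroni_threshold(ncol(resid_meth))
  data.frame(cpg = colnames(resid_meth), effect = fit$effect, se = fit$se,
             p = fit$p, bonferroni = !is.na(fit$p) & fit$p < thr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclude polygenic-score SNPs with direct CpG effects
#'
#' Regresses every tested CpG on each score SNP with lnCRP as a covariate;
#' a SNP conditionally associated with any CpG below `threshold` (default
#' the Bonferroni level for 52 SNPs x 1511 CpGs) has a path to methylation
#' that does not run through CRP and is removed from the score weights
#' before re-scoring.
#'
#' @param weights named numeric vector or data frame (`snp`, `beta`) of
#'   score weights.
#' @param genotypes samples x SNPs dosage matrix.
#' @param resid_meth samples x CpGs residualized methylation.
#' @param lncrp lnCRP vector (the conditioning covariate).
#' @param threshold direct-effect significance level.
#' @return The weights restricted to retained SNPs, with the dropped SNP
#'   ids in attribute `"excluded"`.
#' @export
filter_prs_snps <- function(weights, genotypes, resid_meth, lncrp,
                            threshold = bonferroni_threshold(52 * 1511)) {
  if (is.data.frame(weights)) {
    w <- weights$beta
    names(w) <- weights$snp
  } else w <- weights
  snps <- intersect(names(w), colnames(genotypes))
  Zc <- cbind(1, lncrp)
  direct <- vapply(snps, function(s) {
    fit <- scan_outcomes(resid_meth, genotypes[, s], Zc)
    any(fit$p < threshold, na.rm = TRUE)
  }, TRUE)
  kept <- w[setdiff(names(w), snps[direct])]
  attr(kept, "excluded") <- snps[direct]
  kept
}

#' MR triangulation of predicted versus observed effects
#'
#' For each CpG the predicted instrument-outcome effect is the product of
#' the instrument-exposure and exposure-outcome path estimates; agreement
#' with the observed instrument-outcome effect (Pearson correlation with a
#' two-sided p, plus an exact two-sided binomial sign test on sign
#' concordance at null probability 0.5) supports the tested causal
#' direction.
#'
#' @param path1 instrument-exposure estimates (aligned numeric vector).
#' @param path2 exposure-outcome estimates.
#' @param observed observed instrument-outcome estimates.
#' @param direction label, `"cpg_to_crp"` or `"crp_to_cpg"`.
#' @return A `triangulation_result` list: per-CpG `table` (predicted,
#'   observed, concordant), `rho`, `rho_p`, `sign_p`, `n`, `direction`.
#' @export
#' @examples
#' # 400 concordant of 709 gives two-sided binomial P ~ 7e-4
#' stats::binom.test(400, 709)$p.value
triangulate <- function(path1, path2, observed,
                        direction = c("crp_to_cpg", "cpg_to_crp")) {
  direction <- match.arg(direction)
  ok <- is.finite(path1) & is.finite(path2) & is.finite(observed)
  predicted <- path1 * path2
  if (sum(ok) < 3) stop("fewer than 3 complete points: correlation undefined")
  if (sum(ok) < 10)
    warning("fewer than 10 points; triangulation correlation is unstable")
  ct <- stats::cor.test(predicted[ok], observed[ok])
  conc <- sign(predicted[ok]) == sign(observed[ok])
  bt <- stats::binom.test(sum(conc), length(conc), p = 0.5)
  structure(list(table = data.frame(predicted = predicted,
                                    observed = observed,
                                    concordant = sign(predicted) ==
                                      sign(observed)),
                 rho = unname(ct$estimate), rho_p = ct$p.value,
                 sign_p = bt$p.value, n = sum(ok),
                 n_concordant = sum(conc), direction = direction),
            class = "triangulation_result")
}

#' @export
print.triangulation_result <- function(x, ...) {
  cat(sprintf("MR triangulation (%s): n = %d\n", x$direction, x$n))
  cat(sprintf("  Pearson rho = %.3f (P = %.3g); sign concordance %d/%d (P = %.3g)\n",
              x$rho, x$rho_p, x$n_concordant, x$n, x$sign_p))
  invisible(x)
}

#' Run the CpG-to-CRP MR arm on individual-level data
#'
#' For every candidate CpG: discover the best cis instrument under the
#' dominant model ([find_cis_instruments()]), drop instruments with a direct
#' effect on lnCRP ([direct_effect_filter()]), estimate the instrument-lnCRP
#' path, and form the Wald ratio (CRP path over methylation path). Both
#' orientations of the printed ratio are emitted with labels.
#'
#' @param cpgs candidate probe ids.
#' @param genotypes,resid_meth,snp_map,annotation as in
#'   [find_cis_instruments()].
#' @param lncrp outcome vector aligned with the rows.
#' @param window,instrument_p cis window and instrument threshold.
#' @param direct_p direct-effect exclusion threshold.
#' @return Data frame with one row per CpG with a valid instrument:
#'   instrument paths, the Wald ratio (`mr_estimate`, `mr_se`, `mr_p`), the
#'   inverted orientation `mr_estimate_inverted`, and `bonferroni` at
#'   `0.05 / n` valid instruments.
#' @export
mr_cpg_to_crp <- function(cpgs, genotypes, resid_meth, snp_map, annotation,
                          lncrp, window = 5e5, instrument_p = 5e-8,
                          direct_p = bonferroni_threshold(1511)) {
  rows <- lapply(cpgs, function(cg) {
    cand <- find_cis_instruments(cg, genotypes, resid_meth, snp_map,
                                 annotation, window, instrument_p)
    cand <- cand[cand$valid, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    best <- cand[1, ]
    g <- dominant_recode(genotypes[, best$snp])
    de <- direct_effect_filter(g, resid_meth[, cg], lncrp,
                               threshold = direct_p)
    if (!de$pass) return(NULL)
    crp_fit <- stats::lm(lncrp ~ g)
    cf <- summary(crp_fit)$coefficients
    data.frame(cpg = cg, snp = best$snp,
               beta_snp_cpg = best$beta_snp_cpg, se_snp_cpg = best$se,
               p_snp_cpg = best$p,
               beta_snp_crp = cf["g", 1], se_snp_crp = cf["g", 2],
               p_snp_crp = cf["g", 4], p_direct = de$p_direct,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(rows)
  wr <- wald_ratio(rows$beta_snp_crp, rows$se_snp_crp, rows$beta_snp_cpg)
  rows$mr_estimate <- wr$estimate
  rows$mr_se <- wr$se
  rows$mr_p <- wr$p
  rows$mr_estimate_inverted <- rows$beta_snp_cpg / rows$beta_snp_crp
  rows$bonferroni <- rows$mr_p < bonferroni_threshold(nrow(rows))
  rows
}
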