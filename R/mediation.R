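# Baron-Kenny four-path mediation with the Aroian-Sobel test, eligibility
# gating, six-model selection logic and cross-cohort meta-mediation.

#' Baron-Kenny path estimates for many CpGs
#'
#' Four OLS fits per CpG outcome:
#' a-path `mediator ~ exposure + covariates`;
#' b-path and c'-path from `CpG ~ exposure + mediator + covariates`
#' (mediator and exposure terms respectively);
#' c-path `CpG ~ exposure + covariates` (total effect).
#' For linear models on one dataset the indirect effect satisfies
#' `a*b = c - c'` exactly (up to floating point).
#'
#' @param exposure exposure vector (e.g. BMI or smoking status).
#' @param mediator mediator vector (e.g. lnCRP).
#' @param outcomes samples x CpGs matrix of (residualized) methylation; a
#'   plain vector is treated as a single outcome.
#' @param pheno phenotype table for covariates (optional).
#' @param covariates phenotype columns to adjust every path for.
#' @param model identifier stamped on the output.
#' @return A `mediation_record` data frame with per-CpG columns `a`, `se_a`,
#'   `p_a`, `b`, `se_b`, `p_b`, `c`, `se_c`, `p_c`, `cprime`, `se_cprime`,
#'   `p_cprime`, `indirect_ab`, `indirect_diff`.
#' @export
baron_kenny_paths <- function(exposure, mediator, outcomes, pheno = NULL,
                              covariates = character(), model = "model1") {
  if (is.null(dim(outcomes)))
    outcomes <- matrix(outcomes, ncol = 1,
                       dimnames = list(NULL, "outcome"))
  if (is.null(colnames(outcomes)))
    colnames(outcomes) <- paste0("outcome", seq_len(ncol(outcomes)))
  n <- length(exposure)
  stopifnot(length(mediator) == n, nrow(outcomes) == n)
  Z <- if (length(covariates)) covariate_design(pheno, covariates)
       else matrix(1, n, 1)
  qz <- qr(Z)
  ex <- qr.resid(qz, exposure)
  em <- qr.resid(qz, mediator)
  EY <- qr.resid(qz, outcomes)
  sxx <- sum(ex^2)
  if (sxx <= n * 1e-12) stop("exposure collinear with covariates")

  # a-path: single regression of the mediator on the exposure
  a <- sum(ex * em) / sxx
  rss_a <- sum(em^2) - a * sum(ex * em)
  df1 <- n - qz$rank - 1L
  se_a <- sqrt(max(rss_a, 0) / df1 / sxx)
  p_a <- 2 * stats::pt(-abs(a / se_a), df1)

  # c-path: outcome on exposure
  sxy <- drop(crossprod(EY, ex))
  cpath <- sxy / sxx
  rss_c <- pmax(colSums(EY^2) - cpath * sxy, 0)
  se_c <- sqrt(rss_c / df1 / sxx)
  p_c <- 2 * stats::pt(-abs(cpath / se_c), df1)

  # b-path and c'-path: outcome on exposure + mediator (2x2 normal equations)
  smm <- sum(em^2)
  sxm <- sum(ex * em)
  det <- sxx * smm - sxm^2
  if (det <= n^2 * 1e-14) stop("mediator collinear with exposure/covariates")
  smy <- drop(crossprod(EY, em))
  cprime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  df2 <- n - qz$rank - 2L
  rss2 <- pmax(colSums(EY^2) - cprime * sxy - b * smy, 0)
  sigma2 <- rss2 / df2
  se_cprime <- sqrt(sigma2 * smm / det)
  se_b <- sqrt(sigma2 * sxx / det)
  p_b <- 2 * stats::pt(-abs(b / se_b), df2)
  p_cprime <- 2 * stats::pt(-abs(cprime / se_cprime), df2)

  out <- data.frame(cpg = colnames(outcomes), model = model,
                    a = a, se_a = se_a, p_a = p_a,
                    b = b, se_b = se_b, p_b = p_b,
                    c = cpath, se_c = se_c, p_c = p_c,
                    cprime = cprime, se_cprime = se_cprime,
                    p_cprime = p_cprime,
                    indirect_ab = a * b, indirect_diff = cpath - cprime,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("mediation_record", "data.frame")
  out
}

#' Aroian-Sobel test for the indirect effect
#'
#' `Z = a b / sqrt(b^2 SE_a^2 + a^2 SE_b^2 + SE_a^2 SE_b^2)` with a
#' two-sided normal p-value. The `"as_printed"` variant places the product
#' of the SEs outside the square root and unsquared
#' (`ab/sqrt(b^2 SE_a^2 + a^2 SE_b^2) + SE_a SE_b`), a dimensionally
#' inconsistent form retained only for comparison.
#'
#' @param a,se_a exposure-to-mediator path estimate and SE.
#' @param b,se_b mediator-to-outcome path estimate and SE.
#' @param variant `"aroian"` (default) or `"as_printed"`.
#' @return Data frame `z`, `p` (vectorized).
#' @export
#' @examples
#' aroian_sobel(0.5, 0.1, 0.4, 0.1)$z  # 3.086
aroian_sobel <- function(a, se_a, b, se_b,
                         variant = c("aroian", "as_printed")) {
  variant <- match.arg(variant)
  if (any(se_a <= 0 | se_b <= 0, na.rm = TRUE))
    stop("standard errors must be positive")
  z <- switch(variant,
    aroian = (a * b) / sqrt(b^2 * se_a^2 + a^2 * se_b^2 + se_a^2 * se_b^2),
    as_printed = (a * b) / sqrt(b^2 * se_a^2 + a^2 * se_b^2) + se_a * se_b)
  z[a == 0 | b == 0] <- 0
  data.frame(z = z, p = z_to_p(z))
}

#' Eligibility gate for mediation records
#'
#' Baron-Kenny preconditions: a nominally significant total effect (c-path)
#' and exposure-mediator association (a-path), and an attenuating indirect
#' effect -- the direct effect must be closer to zero than the total effect
#' (`|c'| < |c|`; under full mediation `c'` hovers around zero and may cross
#' it, which still counts as attenuation). Suppression cases (`c'` farther
#' from zero than `c`) are labelled `positive_indirect` and excluded. The
#' Sobel test is computed only for eligible records.
#'
#' @param record a `mediation_record` data frame.
#' @param alpha gate significance level.
#' @param variant forwarded to [aroian_sobel()].
#' @return `record` with added `gate_status`, `sobel_z`, `sobel_p` columns.
#' @export
mediation_gate <- function(record, alpha = 0.05, variant = "aroian") {
  status <- rep("eligible", nrow(record))
  status[record$p_a >= alpha | is.na(record$p_a)] <- "fail_a_path"
  status[record$p_c >= alpha | is.na(record$p_c)] <- "fail_c_path"
  atten <- abs(record$cprime) < abs(record$c)
  status[status == "eligible" & !atten] <- "positive_indirect"
  record$gate_status <- status
  record$sobel_z <- record$sobel_p <- NA_real_
  el <- status == "eligible"
  if (any(el)) {
    st <- aroian_sobel(record$a[el], record$se_a[el], record$b[el],
                       record$se_b[el], variant = variant)
    record$sobel_z[el] <- st$z
    record$sobel_p[el] <- st$p
  }
  record
}

#' Six-model mediation selection
#'
#' Given the gated records of the six candidate causal orderings evaluated
#' on one dataset, a model is admissible when at least one tested locus
#' passes every Baron-Kenny precondition (significant a-path and c-path,
#' attenuating indirect effect). The report lists, per model, the count of
#' loci at each gate status and the dominant violation for rejected models.
#'
#' @param records named list of gated `mediation_record` data frames, one
#'   per model.
#' @return Data frame with per-model eligibility counts, the dominant
#'   violation label, and an `admissible` flag (any eligible locus).
#' @export
select_model <- function(records) {
  rows <- lapply(names(records), function(nm) {
    r <- records[[nm]]
    if (is.null(r) || !nrow(r))
      return(data.frame(model = nm, n = 0L, n_eligible = 0L,
                        n_fail_a = 0L, n_fail_c = 0L, n_positive_indirect = 0L,
                        dominant_violation = "no_results", admissible = FALSE,
                        stringsAsFactors = FALSE))
    tab <- table(factor(r$gate_status,
                        levels = c("eligible", "fail_a_path", "fail_c_path",
                                   "positive_indirect")))
    viol <- tab[-1]
    data.frame(model = nm, n = nrow(r), n_eligible = tab[["eligible"]],
               n_fail_a = tab[["fail_a_path"]],
               n_fail_c = tab[["fail_c_path"]],
               n_positive_indirect = tab[["positive_indirect"]],
               dominant_violation = if (tab[["eligible"]] > 0) "none"
                 else names(viol)[which.max(viol)],
               admissible = tab[["eligible"]] > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Meta-analyzed mediation across cohorts
#'
#' Pools each of the four path estimates across cohorts by inverse-variance
#' weighting ([ivw_meta()]) and applies the gate and Sobel test to the
#' pooled paths. Unlike the single-cohort case, the pooled `a*b` and
#' `c - c'` need not agree exactly; both are reported.
#'
#' @param records list of per-cohort `mediation_record` data frames.
#' @param alpha,variant forwarded to [mediation_gate()].
#' @return A gated `mediation_record` of pooled paths with `k` cohorts.
#' @export
meta_mediation <- function(records, alpha = 0.05, variant = "aroian") {
  if (is.data.frame(records)) records <- list(records)
  pool_path <- function(est, se) {
    ivw_meta(lapply(records, function(r)
      data.frame(cpg = r$cpg, effect = r[[est]], se = r[[se]], n = NA)))
  }
  pa <- pool_path("a", "se_a")
  pb <- pool_path("b", "se_b")
  pc <- pool_path("c", "se_c")
  pcp <- pool_path("cprime", "se_cprime")
  stopifnot(identical(pa$cpg, pb$cpg), identical(pa$cpg, pc$cpg),
            identical(pa$cpg, pcp$cpg))
  out <- data.frame(cpg = pa$cpg, model = records[[1]]$model[1] %||% "pooled",
                    a = pa$effect, se_a = pa$se, p_a = pa$p,
                    b = pb$effect, se_b = pb$se, p_b = pb$p,
                    c = pc$effect, se_c = pc$se, p_c = pc$p,
                    cprime = pcp$effect, se_cprime = pcp$se,
                    p_cprime = pcp$p,
                    indirect_ab = pa$effect * pb$effect,
                    indirect_diff = pc$effect - pcp$effect,
                    k = pa$k, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("mediation_record", "data.frame")
  mediation_gate(out, alpha = alpha, variant = variant)
}
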