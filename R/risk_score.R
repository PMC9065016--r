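# Beta-weighted methylation risk score, association with clinical
# phenotypes, and the odds-ratio to adjusted-relative-risk transformation.

#' Lifetime risks used for the relative-risk transformation
#'
#' Literature lifetime risks for the cardiometabolic outcomes scored by the
#' pipeline: COPD 11.45%, type-2 diabetes 39.9%, myocardial infarction
#' 24.8%, coronary artery disease 40.15%, hypertension 81%.
#'
#' @return Named numeric vector of proportions.
#' @export
lifetime_risks <- function() {
  c(COPD = 0.1145, T2D = 0.399, MI = 0.248, CAD = 0.4015,
    Hypertension = 0.81)
}

#' Beta-weighted methylation risk score
#'
#' `score_s = sum_j beta_methylation(s, j) * w_j` over the weighted CpGs
#' present in the matrix, with no rescaling for missing CpGs (a plain
#' weighted sum, as for a polygenic score). Set `rescale_missing = TRUE` to
#' scale by the fraction of weights available (sensitivity option).
#'
#' @param meth samples x CpGs beta matrix.
#' @param weights data frame `cpg`, `coefficient` (discovery effects, ln
#'   mg/L per methylation unit) and optional `subset` label, or a named
#'   numeric vector.
#' @param subset restrict to one subset label (e.g. `"cluster1"`).
#' @param rescale_missing divide by the fraction of weight mass available.
#' @return Per-sample score vector.
#' @export
#' @examples
#' m <- matrix(0.5, 1, 2, dimnames = list("s1", c("cg1", "cg2")))
#' w <- data.frame(cpg = c("cg1", "cg2"), coefficient = c(2, -1))
#' methylation_risk_score(m, w)  # 0.5
methylation_risk_score <- function(meth, weights, subset = NULL,
                                   rescale_missing = FALSE) {
  if (is.data.frame(weights)) {
    if (!is.null(subset))
      weights <- weights[weights$subset == subset, , drop = FALSE]
    w <- weights$coefficient
    names(w) <- weights$cpg
  } else w <- weights
  present <- intersect(names(w), colnames(meth))
  if (!length(present)) stop("no weighted CpG present in the matrix")
  if (length(present) < length(w))
    message(length(w) - length(present), " weighted CpG(s) missing; skipped")
  score <- drop(meth[, present, drop = FALSE] %*% w[present])
  if (rescale_missing && length(present) < length(w))
    score <- score * length(w) / length(present)
  score
}

#' Associate a risk score with a phenotype
#'
#' Binary outcomes: logistic regression, effect on the log-odds scale per
#' unit score. Continuous outcomes: OLS. Covariates are passed through to
#' the model. Complete or quasi-complete separation is flagged and the
#' estimate set to `NA`.
#'
#' @param score per-sample risk score.
#' @param outcome outcome vector (0/1 or continuous).
#' @param family `"binary"` or `"continuous"`.
#' @param covariates optional data frame of covariates.
#' @param phenotype label stamped on the result.
#' @return A one-row data frame: `phenotype`, `family`, `estimate`
#'   (logOdds or linear beta), `se`, `p`, `n`.
#' @export
score_phenotype_association <- function(score, outcome,
                                        family = c("binary", "continuous"),
                                        covariates = NULL,
                                        phenotype = "phenotype") {
  family <- match.arg(family)
  if (stats::sd(score, na.rm = TRUE) == 0 ||
      length(unique(stats::na.omit(outcome))) < 2) {
    warning("degenerate score or outcome; estimate NA")
    return(data.frame(phenotype = phenotype, family = family,
                      estimate = NA_real_, se = NA_real_, p = NA_real_,
                      n = sum(stats::complete.cases(score, outcome)),
                      stringsAsFactors = FALSE))
  }
  dat <- data.frame(.y = outcome, .s = score)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  form <- stats::reformulate(setdiff(names(dat), ".y"), response = ".y")
  fit <- if (family == "binary")
    stats::glm(form, data = dat, family = stats::binomial())
  else stats::lm(form, data = dat)
  cf <- summary(fit)$coefficients
  est <- cf[".s", 1]; se <- cf[".s", 2]
  p <- cf[".s", 4]
  if (family == "binary" && (!fit$converged || abs(est) > 50 || se > 50)) {
    warning("possible separation in logistic fit; estimate NA")
    est <- se <- p <- NA_real_
  }
  data.frame(phenotype = phenotype, family = family, estimate = est,
             se = se, p = p, n = length(fit$residuals),
             stringsAsFactors = FALSE)
}

#' Meta-analyze per-cohort risk-score associations
#'
#' Inverse-variance pooling of the per-cohort estimates (delegates to
#' [ivw_meta()], treating each phenotype as a marker).
#'
#' @param estimates list of per-cohort data frames from
#'   [score_phenotype_association()].
#' @return Pooled data frame with `phenotype`, `estimate`, `se`, `z`, `p`,
#'   `n`, `direction`.
#' @export
meta_risk_associations <- function(estimates) {
  if (is.data.frame(estimates)) estimates <- list(estimates)
  res <- ivw_meta(lapply(estimates, function(e)
    data.frame(cpg = e$phenotype, effect = e$estimate, se = e$se, n = e$n)))
  names(res)[names(res) == "cpg"] <- "phenotype"
  names(res)[names(res) == "effect"] <- "estimate"
  as.data.frame(res)[, c("phenotype", "estimate", "se", "z", "p", "n",
                         "direction")]
}

#' Odds ratio to adjusted relative risk
#'
#' `RR = OR / (1 - LR + LR * OR)` with `LR` the outcome's lifetime risk.
#' Maps OR 1 to RR 1 for any LR, is monotone in OR, and pulls the estimate
#' towards 1 for LR > 0.
#'
#' @param odds_ratio positive odds ratio(s).
#' @param lifetime_risk lifetime risk in `[0, 1]`.
#' @return Relative risk(s).
#' @export
#' @examples
#' or_to_rr(2, 0.248)  # 1.6026 (myocardial infarction lifetime risk)
or_to_rr <- function(odds_ratio, lifetime_risk) {
  if (any(odds_ratio <= 0, na.rm = TRUE)) stop("odds ratio must be positive")
  if (any(lifetime_risk < 0 | lifetime_risk > 1, na.rm = TRUE))
    stop("lifetime risk must lie in [0, 1]")
  odds_ratio / (1 - lifetime_risk + lifetime_risk * odds_ratio)
}

#' Relative risk per unit change of the risk score
#'
#' The full-score log-odds describe the 0-to-1 (100% methylation) swing of
#' every weighted CpG; the per-unit risk rescales on the log-odds scale:
#' `OR_unit = exp(logOdds_full * unit_fraction)`, then [or_to_rr()]. A
#' linear-odds alternative (`OR_unit = 1 + (OR_full - 1) * unit_fraction`)
#' is available via `scaling = "linear_odds"`.
#'
#' @param log_odds_full log-odds for the full score swing.
#' @param lifetime_risk lifetime risk in `[0, 1]`.
#' @param unit_fraction fraction of the full swing (0.01 = one percent).
#' @param scaling `"log_odds"` (default) or `"linear_odds"`.
#' @return Relative risk per unit.
#' @export
rr_per_unit <- function(log_odds_full, lifetime_risk, unit_fraction = 0.01,
                        scaling = c("log_odds", "linear_odds")) {
  scaling <- match.arg(scaling)
  or_unit <- switch(scaling,
    log_odds = exp(log_odds_full * unit_fraction),
    linear_odds = 1 + (exp(log_odds_full) - 1) * unit_fraction)
  or_to_rr(or_unit, lifetime_risk)
}
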