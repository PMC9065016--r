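# Cohort-level EWAS: sample/probe filters, per-CpG regression of ln CRP on
# methylation, quantile normalization, and residualization of methylation
# for the individual-level downstream stages.

#' Exclude CRP outliers
#'
#' Drops samples whose ln CRP falls outside median +/- 4 SD, with the SD
#' taken on the pre-exclusion values (plain sample standard deviation).
#' Bounds are inclusive.
#'
#' @param pheno phenotype data frame with an `lncrp` column.
#' @return `pheno` restricted to retained samples, with the excluded sample
#'   ids in attribute `"excluded"`.
#' @export
#' @examples
#' ph <- data.frame(sample_id = letters[1:5], lncrp = c(0, 0, 0, 0, 5))
#' nrow(exclude_crp_outliers(ph))  # SD 2.236 -> bound 8.94, none excluded
exclude_crp_outliers <- function(pheno) {
  exclude_pheno_outliers(pheno, "lncrp", center = "median")
}

#' Exclude BMI outliers
#'
#' Drops samples with BMI outside mean +/- 4 SD (inclusive bounds), the
#' mean-centred analogue of [exclude_crp_outliers()] used before mediation.
#'
#' @param pheno phenotype data frame with a `bmi` column.
#' @return Filtered `pheno` with attribute `"excluded"`.
#' @export
exclude_bmi_outliers <- function(pheno) {
  exclude_pheno_outliers(pheno, "bmi", center = "mean")
}

exclude_pheno_outliers <- function(pheno, col, center = c("median", "mean")) {
  center <- match.arg(center)
  x <- pheno[[col]]
  if (is.null(x)) stop(sprintf("phenotype column '%s' not found", col))
  ok_finite <- is.finite(x)
  if (sum(ok_finite) < 2) stop("need >= 2 samples with finite values")
  ctr <- if (center == "median") stats::median(x[ok_finite])
         else mean(x[ok_finite])
  s <- stats::sd(x[ok_finite])
  keep <- ok_finite & x >= ctr - 4 * s & x <= ctr + 4 * s
  if (!any(keep)) stop("all samples excluded by the outlier rule")
  out <- pheno[keep, , drop = FALSE]
  attr(out, "excluded") <- pheno$sample_id[!keep] %||% which(!keep)
  out
}

#' Probe-level filters for the meta-analysis
#'
#' Keeps autosomal probes that are neither flagged as having a SNP in the
#' last 10 bp of the probe sequence nor flagged cross-reactive. Order of the
#' annotation is preserved.
#'
#' @param annotation CpG annotation data frame (see [simulate_truth()] for
#'   the expected columns).
#' @return character vector of retained probe ids.
#' @export
filter_probes <- function(annotation) {
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("empty probe annotation")
  keep <- annotation$is_autosomal & !annotation$snp_in_last10bp &
    !annotation$cross_reactive
  annotation$cpg[keep]
}

# Build the covariate design matrix from phenotype columns. Factors and
# characters expand to dummies; an intercept is always included. Aliased
# nuisance columns (e.g. cell fractions summing to one against the
# intercept) are resolved by qr pivoting, as lm() does.
covariate_design <- function(pheno, covariates) {
  if (length(covariates) == 0)
    return(matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)")))
  missing <- setdiff(covariates, names(pheno))
  if (length(missing))
    stop("covariates not in phenotype table: ", paste(missing, collapse = ", "))
  Z <- stats::model.matrix(stats::reformulate(covariates), data = pheno)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
  Z
}

#' Default EWAS covariate sets
#'
#' The base model adjusts for age, sex, the six leukocyte fractions, batch
#' and the technical covariate; named augmented models add risk factors for
#' the sensitivity analyses (`"smoking"` expands to ordinal status plus
#' packyears; `"full"` combines BMI, smoking, waist and hip when present).
#'
#' @param model one of `"base"`, `"bmi"`, `"smoking"`, `"waist"`, `"hip"`,
#'   `"cholesterol"`, `"triglycerides"`, `"insulin"`, `"full"`.
#' @return character vector of phenotype column names.
#' @export
ewas_covariates <- function(model = "base") {
  base <- c("age", "sex", "CD4T", "NK", "Bcell", "Mono", "Neu", "Eos",
            "batch", "tech1")
  extra <- switch(model,
    base = character(),
    bmi = "bmi",
    smoking = c("smoking_status", "packyears"),
    waist = "waist", hip = "hip", cholesterol = "cholesterol",
    triglycerides = "triglycerides", insulin = "insulin",
    full = c("bmi", "smoking_status", "packyears", "waist", "hip"),
    stop("unknown model id: ", model))
  c(base, extra)
}

# Fast massively-univariate OLS by Frisch-Waugh-Lovell: residualize the
# outcome and each focal predictor on the shared covariate design once, then
# fit the per-CpG simple regression on the residuals. Identical to per-CpG
# stats::lm() coefficients, SEs and t-based p-values.
scan_predictors <- function(y, X, Z) {
  n <- length(y)
  qz <- qr(Z)
  df <- n - qz$rank - 1L
  if (df < 1) stop("fewer samples than covariates + 2")
  ey <- qr.resid(qz, y)
  EX <- qr.resid(qz, X)
  sxx <- colSums(EX^2)
  sxy <- drop(crossprod(EX, ey))
  ok <- sxx > n * 1e-12
  b <- se <- p <- rep(NA_real_, ncol(X))
  b[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(ey^2) - b[ok] * sxy[ok]
  sigma2 <- pmax(rss, 0) / df
  se[ok] <- sqrt(sigma2 / sxx[ok])
  tstat <- b[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  if (any(!ok))
    warning(sum(!ok), " predictor(s) collinear with covariates; set to NA")
  list(effect = b, se = se, p = p, df = df)
}

# The transpose problem: one focal predictor, many outcomes.
scan_outcomes <- function(Y, x, Z) {
  n <- length(x)
  qz <- qr(Z)
  df <- n - qz$rank - 1L
  if (df < 1) stop("fewer samples than covariates + 2")
  ex <- qr.resid(qz, x)
  sxx <- sum(ex^2)
  if (sxx <= n * 1e-12) {
    warning("focal predictor collinear with covariates; all results NA")
    nc <- ncol(Y)
    return(list(effect = rep(NA_real_, nc), se = rep(NA_real_, nc),
                p = rep(NA_real_, nc), df = df))
  }
  EY <- qr.resid(qz, Y)
  sxy <- drop(crossprod(EY, ex))
  b <- sxy / sxx
  rss <- pmax(colSums(EY^2) - b * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, b / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df)
  list(effect = b, se = se, p = p, df = df)
}

#' Per-cohort CpG association scan
#'
#' Fits `lncrp ~ CpG + covariates` by OLS for every CpG column, with
#' two-sided p-values from the t distribution on the residual degrees of
#' freedom. Effects are on the ln mg/L CRP per methylation-unit scale. The
#' per-CpG methylation SD and the cohort lnCRP SD are recorded for
#' coefficient standardization and for the enrichment null matching.
#'
#' @param meth samples x CpGs beta matrix.
#' @param pheno phenotype table aligned with `meth` rows.
#' @param covariates character vector of phenotype columns (see
#'   [ewas_covariates()]).
#' @param probes optional probe subset (e.g. from [filter_probes()]).
#' @param cohort,model identifiers stamped on the output.
#' @return A `cohort_summary` data frame: `cpg`, `effect`, `se`, `p`, `n`,
#'   `meth_sd`, `cohort`, `model`, with the outcome SD in attribute
#'   `"lncrp_sd"`.
#' @export
fit_cpg_associations <- function(meth, pheno,
                                 covariates = ewas_covariates("base"),
                                 probes = NULL, cohort = "cohort",
                                 model = "base") {
  if (!is.null(probes)) meth <- meth[, intersect(probes, colnames(meth)),
                                     drop = FALSE]
  stopifnot(nrow(meth) == nrow(pheno))
  y <- pheno$lncrp
  if (is.null(y)) stop("phenotype table lacks 'lncrp'")
  Z <- covariate_design(pheno, covariates)
  fit <- scan_predictors(y, meth, Z)
  out <- data.frame(cpg = colnames(meth), effect = fit$effect, se = fit$se,
                    p = fit$p, n = nrow(meth),
                    meth_sd = apply(meth, 2, stats::sd),
                    cohort = cohort, model = model,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lncrp_sd") <- stats::sd(y)
  attr(out, "df") <- fit$df
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Quantile-normalize a methylation matrix
#'
#' Classical across-sample quantile normalization: each sample's sorted
#' values are replaced by the across-sample mean of the order statistics,
#' preserving ranks within each sample and averaging ties (delegated to
#' limma's implementation).
#'
#' @param meth samples x CpGs matrix.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m)  # both samples become 2.5, 3.5, 4.5
quantile_normalize <- function(meth) {
  if (nrow(meth) == 1L) return(meth)
  if (any(apply(meth, 1, function(r) all(is.na(r)))))
    stop("sample with all-missing methylation values")
  out <- t(limma::normalizeQuantiles(t(meth), ties = TRUE))
  dimnames(out) <- dimnames(meth)
  out
}

#' Residualize methylation on nuisance covariates
#'
#' Per-CpG OLS residuals of (quantile-normalized) beta values on
#' `age + sex + CD4T + NK + Bcell + Mono + Neu + Eos + batch` (plus any
#' further technical covariates supplied). Residuals have zero mean and are
#' exactly orthogonal to every covariate column; they feed the mediation,
#' MR, correlation and risk-score stages.
#'
#' @param meth samples x CpGs matrix (normalize first if desired).
#' @param pheno phenotype table aligned with `meth` rows.
#' @param covariates character vector of phenotype columns; the default is
#'   the residualization covariate set.
#' @return Residual matrix with the dimnames of `meth`.
#' @export
residualize_methylation <- function(meth, pheno,
                                    covariates = c("age", "sex", "CD4T", "NK",
                                                   "Bcell", "Mono", "Neu",
                                                   "Eos", "batch")) {
  stopifnot(nrow(meth) == nrow(pheno))
  Z <- covariate_design(pheno, covariates)
  res <- qr.resid(qr(Z), meth)
  dimnames(res) <- dimnames(meth)
  res
}
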