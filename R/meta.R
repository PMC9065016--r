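# Fixed-effect meta-analysis of cohort summaries with double genomic
# control, standardized coefficients, ancestry replication and the
# model-comparison sensitivity statistics.

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines per-cohort effect/SE pairs per CpG with weights `1/SE^2`
#' (the METAL-style scheme): combined effect `sum(w b)/sum(w)`, combined SE
#' `1/sqrt(sum(w))`, `Z = effect/SE` and a two-sided normal p-value. Each
#' cohort contributes one character to the direction string: `+`, `-`, or
#' `?` when the CpG is missing in that cohort. Cochran's Q heterogeneity is
#' computed where at least two cohorts report.
#'
#' @param summaries list of `cohort_summary` data frames (or a single one).
#' @return A `meta_result` data frame: `cpg`, `effect`, `se`, `z`, `p`,
#'   `direction`, `q`, `p_het`, `k`, `n`.
#' @export
#' @examples
#' s1 <- data.frame(cpg = "cg1", effect = 1, se = 1, p = 0.32, n = 100)
#' s2 <- data.frame(cpg = "cg1", effect = 3, se = 1, p = 0.003, n = 100)
#' ivw_meta(list(s1, s2))  # effect 2, se 0.7071
ivw_meta <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  summaries <- lapply(summaries, function(s) {
    bad <- !is.na(s$se) & s$se <= 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with non-positive SE rejected")
      s <- s[!bad, , drop = FALSE]
    }
    s
  })
  cpgs <- unique(unlist(lapply(summaries, `[[`, "cpg")))
  k_coh <- length(summaries)
  B <- SE <- N <- matrix(NA_real_, length(cpgs), k_coh,
                         dimnames = list(cpgs, NULL))
  for (i in seq_len(k_coh)) {
    s <- summaries[[i]]
    idx <- match(s$cpg, cpgs)
    B[idx, i] <- s$effect
    SE[idx, i] <- s$se
    N[idx, i] <- s$n %||% NA_real_
  }
  W <- 1 / SE^2
  use <- is.finite(B) & is.finite(W)
  W[!use] <- NA
  sw <- rowSums(W, na.rm = TRUE)
  eff <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  z <- eff / se
  direction <- apply(ifelse(use, ifelse(B >= 0, "+", "-"), "?"), 1, paste,
                     collapse = "")
  k <- rowSums(use)
  q <- rowSums(W * (B - eff)^2, na.rm = TRUE)
  p_het <- ifelse(k >= 2, stats::pchisq(q, k - 1, lower.tail = FALSE),
                  NA_real_)
  q[k < 2] <- NA_real_
  out <- data.frame(cpg = cpgs, effect = eff, se = se, z = z, p = z_to_p(z),
                    direction = direction, q = q, p_het = p_het, k = k,
                    n = rowSums(N, na.rm = TRUE),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[k > 0, , drop = FALSE]
  class(out) <- c("meta_result", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW meta-analysis of %d CpGs across up to %d cohorts\n",
              nrow(x), max(nchar(x$direction))))
  pcol <- if ("p_gc" %in% names(x)) x$p_gc else x$p
  cat(sprintf("  lambda-corrected: %s;  min P = %.3g\n",
              if ("p_gc" %in% names(x)) "yes" else "no",
              suppressWarnings(min(pcol, na.rm = TRUE))))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Genomic-control inflation factor and correction
#'
#' Estimates the inflation factor `lambda` as the median of the squared Z
#' statistics divided by 0.4549364 (the median of a 1-df chi-square). In
#' `"out"` mode the chi-square statistics are divided by lambda and the
#' p-values recomputed; following GWAS convention, deflation (`lambda <= 1`)
#' is reported but not amplified, i.e. correction is skipped.
#'
#' @param z vector of Z statistics (or chi-square values with
#'   `stat = "chisq"`).
#' @param mode `"out"` corrects the supplied statistics; `"in"` only
#'   estimates lambda (callers inflate cohort SEs by `sqrt(lambda)`).
#' @param stat whether `z` holds Z or chi-square statistics.
#' @return List with `lambda`, corrected `z`, `chisq`, `p`, and a `report`
#'   data frame (lambda, stage, n_tests).
#' @export
genomic_control <- function(z, mode = c("out", "in"), stat = c("z", "chisq")) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  z <- z[is.finite(z)]
  if (!length(z)) stop("no finite statistics supplied")
  if (length(z) < 100)
    warning("genomic control estimated from fewer than 100 statistics")
  chisq <- if (stat == "z") z^2 else z
  lambda <- stats::median(chisq) / 0.4549364
  corrected <- if (mode == "out" && lambda > 1) chisq / lambda else chisq
  list(lambda = lambda,
       chisq = corrected,
       z = sqrt(corrected) * if (stat == "z") sign(z) else 1,
       p = stats::pchisq(corrected, 1, lower.tail = FALSE),
       report = data.frame(lambda = lambda,
                           stage = if (mode == "in") "gc_in" else "gc_out",
                           n_tests = length(chisq)))
}

#' Meta-analysis with genomic control in and out
#'
#' The double-genomic-control procedure: per-cohort lambdas are estimated
#' from each cohort's Z statistics and the cohort SEs inflated by
#' `sqrt(lambda)` before the inverse-variance meta-analysis ("GC in"); the
#' meta-analysis chi-squares are then deflated by the meta-level lambda and
#' p-values recomputed ("GC out"). Lambdas below 1 leave statistics
#' untouched at both stages.
#'
#' @param summaries list of `cohort_summary` data frames.
#' @param gc character subset of `c("in", "out")`.
#' @return A `meta_result` with columns `p` (raw) and `p_gc`, plus a
#'   `gc_report` attribute holding all estimated lambdas.
#' @export
meta_ewas <- function(summaries, gc = c("in", "out")) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  reports <- list()
  if ("in" %in% gc) {
    summaries <- lapply(seq_along(summaries), function(i) {
      s <- summaries[[i]]
      g <- genomic_control(s$effect / s$se, mode = "in")
      rep_i <- g$report
      rep_i$stage <- "gc_in"
      rep_i$unit <- s$cohort[1] %||% paste0("cohort", i)
      reports[[length(reports) + 1L]] <<- rep_i
      if (g$lambda > 1) s$se <- s$se * sqrt(g$lambda)
      s
    })
  }
  res <- ivw_meta(summaries)
  if ("out" %in% gc) {
    g <- genomic_control(res$z, mode = "out")
    res$p_gc <- stats::pchisq(res$z^2 / max(g$lambda, 1), 1,
                              lower.tail = FALSE)
    rep_o <- g$report
    rep_o$unit <- "meta"
    reports[[length(reports) + 1L]] <- rep_o
  } else res$p_gc <- res$p
  attr(res, "gc_report") <- do.call(rbind, reports)
  res
}

#' Bonferroni threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @param format if `TRUE`, round to the two significant figures used in
#'   study reports.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(1511, format = TRUE)        # 3.3e-05
#' bonferroni_threshold(52 * 1511, format = TRUE)   # 6.4e-07
bonferroni_threshold <- function(n_tests, alpha = 0.05, format = FALSE) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  if (format) format_threshold(thr) else thr
}

#' Pooled standard deviation across cohorts
#'
#' Square root of the sample-size-weighted mean of cohort variances, used to
#' pool CpG and lnCRP SDs for coefficient standardization.
#'
#' @param sds per-cohort standard deviations (vector or matrix with cohorts
#'   in columns).
#' @param ns per-cohort sample sizes.
#' @return Pooled SD (scalar, or per-row vector for a matrix input).
#' @export
pooled_sd <- function(sds, ns) {
  if (is.matrix(sds)) {
    w <- matrix(ns, nrow(sds), length(ns), byrow = TRUE)
    w[!is.finite(sds)] <- NA
    sqrt(rowSums(w * sds^2, na.rm = TRUE) / rowSums(w, na.rm = TRUE))
  } else {
    ok <- is.finite(sds)
    sqrt(sum(ns[ok] * sds[ok]^2) / sum(ns[ok]))
  }
}

#' Standardized regression coefficients
#'
#' `effect * SD_CpG / SD_lnCRP`: the change in lnCRP standard deviations per
#' standard deviation of methylation.
#'
#' @param effects raw meta-analyzed effects (lnCRP per methylation unit).
#' @param sd_cpg pooled per-CpG methylation SD (recycled).
#' @param sd_lncrp pooled lnCRP SD (scalar).
#' @return Standardized coefficients.
#' @export
standardize_coefficients <- function(effects, sd_cpg, sd_lncrp) {
  if (any(sd_cpg <= 0) || sd_lncrp <= 0) stop("pooled SDs must be positive")
  effects * sd_cpg / sd_lncrp
}

#' Ancestry replication check
#'
#' A discovery CpG replicates in an ancestry-specific meta-analysis when its
#' p-value there is below `alpha` and the effect direction agrees with the
#' discovery direction.
#'
#' @param discovery `meta_result` (or data frame with `cpg`, `effect`)
#'   restricted to discovery hits.
#' @param ancestry ancestry-specific `meta_result` over the same CpGs.
#' @param alpha replication p-value threshold.
#' @return List with the per-CpG logical `replicated` table, the count, and
#'   `rate_percent` (one decimal).
#' @export
replication_check <- function(discovery, ancestry, alpha = 0.05) {
  shared <- intersect(discovery$cpg, ancestry$cpg)
  if (!length(shared)) stop("no shared CpGs between discovery and ancestry")
  d <- discovery[match(shared, discovery$cpg), ]
  a <- ancestry[match(shared, ancestry$cpg), ]
  pa <- if ("p_gc" %in% names(a)) a$p_gc else a$p
  flag <- pa < alpha & sign(a$effect) == sign(d$effect)
  flag[is.na(flag)] <- FALSE
  list(table = data.frame(cpg = shared, replicated = flag,
                          stringsAsFactors = FALSE),
       n_replicated = sum(flag), n_total = length(shared),
       rate_percent = round(100 * sum(flag) / length(shared), 1))
}

#' Cochran heterogeneity test
#'
#' `Q = sum w_i (b_i - b_hat)^2` with `w_i = 1/SE_i^2` and the IVW pooled
#' `b_hat`; p-value from a chi-square with `k - 1` df.
#'
#' @param effects,ses per-study estimates and standard errors (>= 2).
#' @return List with `q` and `p_het`.
#' @export
#' @examples
#' heterogeneity_test(c(0, 3), c(1, 1))  # Q = 4.5, P = 0.0339
heterogeneity_test <- function(effects, ses) {
  ok <- is.finite(effects) & is.finite(ses) & ses > 0
  if (sum(ok) < 2) stop("heterogeneity needs >= 2 estimates")
  w <- 1 / ses[ok]^2
  bhat <- sum(w * effects[ok]) / sum(w)
  q <- sum(w * (effects[ok] - bhat)^2)
  list(q = q, p_het = stats::pchisq(q, sum(ok) - 1, lower.tail = FALSE))
}

#' Sensitivity comparison of two meta-analysis models
#'
#' Compares the base-model meta-analysis against a covariate-augmented one
#' over the shared CpGs: Pearson correlation of Z-scores, the CpGs whose
#' effect direction flips, and a per-CpG two-estimate Cochran Q treating the
#' two models' estimates as independent (a documented approximation -- the
#' estimates share samples, so the covariance is ignored).
#'
#' @param base,adjusted `meta_result` data frames.
#' @param bonferroni_n number of tests for the Bonferroni count (defaults to
#'   the number of shared CpGs).
#' @return List with `z_correlation`, `sign_flips`, a per-CpG `table`
#'   (`q`, `p_het`), and counts at the nominal and Bonferroni levels.
#' @export
compare_models <- function(base, adjusted, bonferroni_n = NULL) {
  shared <- intersect(base$cpg, adjusted$cpg)
  if (!length(shared)) stop("no shared CpGs between the two models")
  b <- base[match(shared, base$cpg), ]
  a <- adjusted[match(shared, adjusted$cpg), ]
  w1 <- 1 / b$se^2; w2 <- 1 / a$se^2
  pool <- (w1 * b$effect + w2 * a$effect) / (w1 + w2)
  q <- w1 * (b$effect - pool)^2 + w2 * (a$effect - pool)^2
  p_het <- stats::pchisq(q, 1, lower.tail = FALSE)
  flips <- shared[sign(b$effect) != sign(a$effect)]
  nb <- bonferroni_n %||% length(shared)
  list(z_correlation = stats::cor(b$z, a$z, use = "complete.obs"),
       sign_flips = flips,
       table = data.frame(cpg = shared, q = q, p_het = p_het,
                          stringsAsFactors = FALSE),
       n_nominal_het = sum(p_het < 0.05, na.rm = TRUE),
       n_bonferroni_het = sum(p_het < 0.05 / nb, na.rm = TRUE))
}
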