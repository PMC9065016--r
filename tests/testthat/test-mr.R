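test_that("dominant recoding collapses carriers", {
  expect_equal(unname(dominant_recode(c(0, 1, 2, 2))), c(0, 1, 1, 1))
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("s1", "s2"),
                                                c("rs1", "rs2")))
  expect_identical(dimnames(dominant_recode(m)), dimnames(m))
})

test_that("Wald ratio matches the closed form and is scale-equivariant", {
  w <- wald_ratio(0.2, 0.05, 0.1)
  expect_equal(w$estimate, 2)
  expect_equal(w$se, 0.5)
  expect_equal(w$p, 2 * pnorm(-4), tolerance = 1e-12)

  z <- wald_ratio(0, 0.05, 0.1)
  expect_equal(z$estimate, 0)
  expect_equal(z$p, 1)

  # multiplying the exposure path by c divides the ratio by c
  for (cc in c(0.5, 2, -3)) {
    expect_equal(wald_ratio(0.2, 0.05, 0.1 * cc)$estimate, 2 / cc)
  }
  # sign(ratio) = sign(out) * sign(exp)
  expect_lt(wald_ratio(-0.2, 0.05, 0.1)$estimate, 0)
  expect_lt(wald_ratio(0.2, 0.05, -0.1)$estimate, 0)
  expect_gt(wald_ratio(-0.2, 0.05, -0.1)$estimate, 0)
  expect_error(wald_ratio(0.2, 0.05, 0), "undefined")
})

test_that("polygenic score is the weighted dosage sum", {
  g <- matrix(c(1, 2, 0, 1), 2, dimnames = list(c("s1", "s2"),
                                                c("rs1", "rs2")))
  w <- c(rs1 = 0.5, rs2 = -0.25)
  expect_equal(unname(build_prs(g, w)), c(0.5 - 0, 1 - 0.25))
  expect_equal(unname(build_prs(g["s1", , drop = FALSE],
                                c(rs1 = 0.5, rs2 = -0.25))), 0.5)
  # (1,2) x (0.5, -0.25) = 0
  g2 <- matrix(c(1, 2), 1, dimnames = list("s", c("rs1", "rs2")))
  expect_equal(unname(build_prs(g2, w)), 0)
  # linearity
  expect_equal(build_prs(g, w * 2), build_prs(g, w) * 2)
  expect_warning(build_prs(g, c(rs1 = 1, rs9 = 1)), "missing")
  expect_error(build_prs(g, c(rs8 = 1)), "none")
})

test_that("cis scan finds the planted instrument and respects the window", {
  cfg <- tiny_config(n_cohorts = 1, n_samples_per_cohort = 5000,
                     n_cpgs = 40, frac_cpg_causal = 0.1,
                     frac_crp_responsive = 0, seed = 31)
  co <- simulate_cohort(cfg, 1)
  truth <- simulate_truth(cfg)
  res <- residualize_methylation(co$methylation, co$phenotypes)
  causal <- truth[truth$class == "cpg_causal", ][1, ]
  cand <- find_cis_instruments(causal$cpg, co$genotypes, res, co$snp_map,
                               co$annotation)
  expect_true(causal$cis_snp %in% cand$snp)
  best <- cand[1, ]
  expect_identical(best$snp, causal$cis_snp)
  expect_lt(best$p, 5e-8)
  expect_true(best$valid)

  # a SNP one bp beyond the 500 kb boundary is excluded
  ann <- data.frame(cpg = "cgX", chromosome = "1", position = 1e6)
  map <- data.frame(snp = c("in", "out"), chromosome = "1",
                    position = c(1e6 + 5e5, 1e6 + 5e5 + 1))
  g <- matrix(rbinom(200, 2, 0.3), 100, 2, dimnames = list(NULL, map$snp))
  rm <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "cgX"))
  cand2 <- find_cis_instruments("cgX", g, rm, map, ann)
  expect_identical(cand2$snp, "in")
  # empty window is a zero-row result, not an error
  map3 <- data.frame(snp = "far", chromosome = "2", position = 1)
  expect_equal(nrow(find_cis_instruments("cgX", g[, 1, drop = FALSE],
                                         rm, map3, ann)), 0)
})

test_that("direct-effect filter separates mediated from pleiotropic SNPs", {
  set.seed(32)
  n <- 5000
  g <- rbinom(n, 1, 0.4)
  # full mediation: SNP -> exposure -> outcome
  expo <- 0.5 * g + rnorm(n)
  out_med <- 0.8 * expo + rnorm(n)
  f1 <- direct_effect_filter(g, expo, out_med, threshold = 3.3e-5)
  expect_true(f1$pass)
  # planted direct (pleiotropic) path
  out_ple <- 0.8 * expo + 0.5 * g + rnorm(n)
  f2 <- direct_effect_filter(g, expo, out_ple, threshold = 3.3e-5)
  expect_false(f2$pass)
  expect_error(direct_effect_filter(g, NULL, out_med), "exposure")
  # the direction-specific default thresholds are Bonferroni arithmetic
  expect_equal(signif(bonferroni_threshold(1511), 2), 3.3e-5)
  expect_equal(signif(bonferroni_threshold(52 * 1511), 2), 6.4e-7)
})

test_that("PRS-CpG scan recovers the planted CRP-to-CpG chain", {
  cfg <- tiny_config(n_cohorts = 1, n_samples_per_cohort = 4000,
                     n_cpgs = 60, frac_crp_responsive = 0.2,
                     frac_cpg_causal = 0, effect_prs_on_lncrp = 0.6,
                     seed = 33)
  co <- simulate_cohort(cfg, 1)
  truth <- simulate_truth(cfg)
  res <- residualize_methylation(co$methylation, co$phenotypes)
  prs <- build_prs(co$genotypes, attr(truth, "prs_weights"))
  pa <- prs_cpg_association(prs, res)
  resp <- truth$class == "crp_responsive"
  # planted chain: responsive CpGs associate far more strongly than nulls
  expect_lt(median(pa$p[resp]), 1e-4)
  ks <- suppressWarnings(ks.test(pa$p[!resp], "punif"))
  expect_gt(ks$p.value, 0.01)
  # constant score: NA with warning
  expect_warning(pc <- prs_cpg_association(rep(1, nrow(res)), res),
                 "constant")
  expect_true(all(is.na(pc$p)))
})

test_that("triangulation reports rho and the exact binomial sign test", {
  # observed == predicted: rho 1
  set.seed(34)
  p1 <- rnorm(30); p2 <- rnorm(30)
  tri <- triangulate(p1, p2, p1 * p2)
  expect_equal(tri$rho, 1, tolerance = 1e-12)
  expect_equal(tri$sign_p, stats::binom.test(30, 30)$p.value)

  # 400 concordant of 709: the exact two-sided binomial
  expect_equal(stats::binom.test(400, 709)$p.value, 7e-4,
               tolerance = 0.05)

  expect_error(triangulate(1:2, 1:2, 1:2), "fewer than 3")
  expect_warning(triangulate(rnorm(5), rnorm(5), rnorm(5)),
                 "fewer than 10")
})

test_that("MR direction discrimination on planted worlds", {
  # world A: only CpG -> CRP loci; the Wald ratios are significant and the
  # reverse triangulation is null
  cfgA <- tiny_config(n_cohorts = 1, n_samples_per_cohort = 5000,
                      n_cpgs = 50, frac_cpg_causal = 0.2,
                      frac_crp_responsive = 0, seed = 35)
  coA <- simulate_cohort(cfgA, 1)
  trA <- simulate_truth(cfgA)
  resA <- residualize_methylation(coA$methylation, coA$phenotypes)
  causal <- trA$cpg[trA$class == "cpg_causal"]
  mr <- mr_cpg_to_crp(causal, coA$genotypes, resA, coA$snp_map,
                      coA$annotation, coA$phenotypes$lncrp)
  expect_gt(nrow(mr), 0)
  expect_gt(sum(mr$bonferroni), 0)
  # planted delta has the sign of the Wald ratio
  sgn <- sign(trA$delta[match(mr$cpg, trA$cpg)])
  expect_true(all(sign(mr$mr_estimate) == sgn))

  # world B: only CRP -> CpG loci; triangulation of the PRS arm correlates,
  # i.e. predicted (PRS->CRP x CRP->CpG) tracks observed (PRS->CpG)
  cfgB <- tiny_config(n_cohorts = 1, n_samples_per_cohort = 4000,
                      n_cpgs = 80, frac_crp_responsive = 0.35,
                      frac_cpg_causal = 0, effect_prs_on_lncrp = 0.6,
                      seed = 36)
  coB <- simulate_cohort(cfgB, 1)
  trB <- simulate_truth(cfgB)
  resB <- residualize_methylation(coB$methylation, coB$phenotypes)
  prs <- build_prs(coB$genotypes, attr(trB, "prs_weights"))
  obs <- prs_cpg_association(prs, resB)      # PRS -> CpG
  resp <- trB$class == "crp_responsive"
  prs_crp <- coef(lm(coB$phenotypes$lncrp ~ prs))[2]       # PRS -> CRP
  crp_cpg <- apply(resB[, resp], 2, function(y)
    coef(lm(y ~ coB$phenotypes$lncrp))[2])                 # CRP -> CpG
  tri <- triangulate(rep(prs_crp, sum(resp)), crp_cpg, obs$effect[resp])
  expect_gt(tri$rho, 0.5)
  expect_lt(tri$rho_p, 1e-4)
  expect_lt(tri$sign_p, 0.05)
})

test_that("score SNPs with direct CpG effects are excluded before scoring", {
  set.seed(37)
  n <- 3000
  g <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  colnames(g) <- paste0("rs", 1:4)
  lncrp <- rnorm(n)
  meth <- matrix(rnorm(n * 5, 0, 0.05), n,
                 dimnames = list(NULL, paste0("cg", 1:5)))
  # rs2 has a direct (CRP-independent) effect on cg3
  meth[, "cg3"] <- meth[, "cg3"] + 0.05 * g[, "rs2"]
  w <- c(rs1 = 0.2, rs2 = -0.1, rs3 = 0.3, rs4 = 0.05)
  kept <- filter_prs_snps(w, g, meth, lncrp, threshold = 6.4e-7)
  expect_identical(attr(kept, "excluded"), "rs2")
  expect_identical(sort(names(kept)), c("rs1", "rs3", "rs4"))
  # excluding SNPs never increases the score's SNP count
  expect_lte(length(kept), length(w))
  # a clean score keeps everything
  kept2 <- filter_prs_snps(w[c("rs1", "rs4")], g, meth, lncrp,
                           threshold = 6.4e-7)
  expect_length(attr(kept2, "excluded"), 0)
})
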