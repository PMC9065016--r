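test_that("BMI outlier rule is mean +/- 4 SD with inclusive bounds", {
  # construct mean 27, SD 4.5 exactly, then add a 45.5 sample:
  # bound 27 + 18 = 45, so 45.5 is excluded
  base <- c(27 - 4.5, 27 + 4.5)
  ph <- data.frame(sample_id = c("a", "b", "x"), bmi = c(base, 45.5))
  m <- mean(ph$bmi); s <- sd(ph$bmi)
  out <- exclude_bmi_outliers(ph)
  expect_identical(attr(out, "excluded"),
                   ph$sample_id[ph$bmi > m + 4 * s | ph$bmi < m - 4 * s])

  # exactly at mean + 4 SD is retained (inclusive)
  x <- c(rnorm(50, 27, 1))
  edge <- mean(x) + 4 * sd(x) * (50 / 51) # will shift; test on fixed vector
  ph2 <- data.frame(sample_id = seq_along(x), bmi = x)
  m2 <- mean(x); s2 <- sd(x)
  ph2$bmi[1] <- m2 + 4 * s2   # near the bound of the updated stats
  out2 <- exclude_bmi_outliers(ph2)
  # the bound uses the post-replacement distribution; recompute directly
  m3 <- mean(ph2$bmi); s3 <- sd(ph2$bmi)
  expect_identical(nrow(out2), sum(ph2$bmi >= m3 - 4 * s3 &
                                     ph2$bmi <= m3 + 4 * s3))

  ph3 <- data.frame(sample_id = 1:5, bmi = rep(25, 5))
  expect_equal(nrow(exclude_bmi_outliers(ph3)), 5)
})

test_that("Baron-Kenny paths match lm() and satisfy a*b = c - c'", {
  set.seed(40)
  n <- 300
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  expo <- rnorm(n, 27, 4) + 0.3 * covs$age
  med <- 0.1 * expo + rnorm(n)
  y1 <- 0.5 * med + 0.2 * expo + rnorm(n)
  y2 <- rnorm(n)
  Y <- cbind(cg1 = y1, cg2 = y2)
  bk <- baron_kenny_paths(expo, med, Y, pheno = covs,
                          covariates = c("age", "sex"))

  fa <- summary(lm(med ~ expo + age + sex, covs))$coefficients["expo", ]
  expect_equal(bk$a[1], unname(fa[1]), tolerance = 1e-10)
  expect_equal(bk$se_a[1], unname(fa[2]), tolerance = 1e-10)
  expect_equal(bk$p_a[1], unname(fa[4]), tolerance = 1e-10)

  fb <- summary(lm(y1 ~ expo + med + age + sex, covs))$coefficients
  expect_equal(bk$b[1], unname(fb["med", 1]), tolerance = 1e-10)
  expect_equal(bk$se_b[1], unname(fb["med", 2]), tolerance = 1e-10)
  expect_equal(bk$cprime[1], unname(fb["expo", 1]), tolerance = 1e-10)
  expect_equal(bk$p_cprime[1], unname(fb["expo", 4]), tolerance = 1e-10)

  fc <- summary(lm(y1 ~ expo + age + sex, covs))$coefficients["expo", ]
  expect_equal(bk$c[1], unname(fc[1]), tolerance = 1e-10)

  # the OLS algebraic identity, both CpGs
  expect_equal(bk$indirect_ab, bk$indirect_diff, tolerance = 1e-8)
})

test_that("Aroian-Sobel matches the hand example and its symmetries", {
  s <- aroian_sobel(0.5, 0.1, 0.4, 0.1)
  expect_equal(s$z, 0.2 / sqrt(0.0016 + 0.0025 + 0.0001), tolerance = 1e-12)
  expect_equal(round(s$z, 3), 3.086)
  expect_equal(s$p, 2 * pnorm(-s$z), tolerance = 1e-12)

  z0 <- aroian_sobel(0, 0.1, 0.4, 0.1)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  # symmetric under swapping (a, SE_a) with (b, SE_b)
  expect_equal(aroian_sobel(0.5, 0.1, 0.4, 0.2)$z,
               aroian_sobel(0.4, 0.2, 0.5, 0.1)$z, tolerance = 1e-12)

  # the as-printed variant differs (SE product outside the root)
  sp <- aroian_sobel(0.5, 0.1, 0.4, 0.1, variant = "as_printed")
  expect_equal(sp$z, 0.2 / sqrt(0.0016 + 0.0025) + 0.01, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sp$z, s$z)))
  expect_error(aroian_sobel(0.5, 0, 0.4, 0.1), "positive")
})

test_that("the gate enforces c-path, a-path and attenuation", {
  rec <- data.frame(cpg = c("c_fail", "a_fail", "suppress", "ok"),
                    a = c(0.5, 0.01, 0.5, 0.5), se_a = 0.1,
                    p_a = c(0.001, 0.6, 0.001, 0.001),
                    b = 0.4, se_b = 0.1, p_b = 0.001,
                    c = c(0.3, 0.3, 0.3, 0.3), se_c = 0.1,
                    p_c = c(0.2, 0.001, 0.001, 0.001),
                    cprime = c(0.1, 0.1, 0.5, 0.1), se_cprime = 0.1,
                    p_cprime = 0.5)
  g <- mediation_gate(rec)
  expect_identical(g$gate_status,
                   c("fail_c_path", "fail_a_path", "positive_indirect",
                     "eligible"))
  # Sobel only on eligible records
  expect_true(is.na(g$sobel_p[1]) && is.na(g$sobel_p[3]))
  expect_false(is.na(g$sobel_p[4]))
  # full mediation past zero still attenuates; larger-magnitude flips do not
  rec2 <- rec[4, ]; rec2$cprime <- -0.1
  expect_identical(mediation_gate(rec2)$gate_status, "eligible")
  rec3 <- rec[4, ]; rec3$cprime <- -0.4
  expect_identical(mediation_gate(rec3)$gate_status, "positive_indirect")
})

test_that("a planted BMI->CRP->CpG chain is eligible and significant", {
  set.seed(41)
  n <- 3000
  bmi <- rnorm(n, 27, 4.5)
  crp <- 0.08 * (bmi - 27) + rnorm(n, 0.3, 0.8)
  cpg_full <- 0.02 * crp + rnorm(n, 0, 0.05)          # full mediation
  cpg_null <- rnorm(n, 0, 0.05)
  bk <- baron_kenny_paths(bmi, crp, cbind(med = cpg_full, null = cpg_null))
  g <- mediation_gate(bk)
  expect_identical(g$gate_status[1], "eligible")
  expect_lt(g$sobel_p[1], bonferroni_threshold(1511))
  expect_identical(g$gate_status[2], "fail_c_path")
  # full mediation: c' near zero, c ~ a*b
  expect_lt(abs(g$cprime[1]), abs(g$c[1]))
  expect_equal(g$c[1], g$a[1] * g$b[1] + g$cprime[1], tolerance = 1e-8)
})

test_that("six-model selection keeps the planted orderings only", {
  set.seed(42)
  n <- 2500
  bmi <- rnorm(n, 27, 4.5)
  smoke <- sample(0:2, n, TRUE, prob = c(.5, .3, .2))
  crp <- 0.08 * (bmi - 27) + 0.2 * smoke + rnorm(n, 0, 0.8)
  cpg <- -0.03 * crp + rnorm(n, 0, 0.06)   # CpG responds to CRP only
  gate_of <- function(e, m, y) mediation_gate(baron_kenny_paths(e, m, y))
  records <- list(
    model1 = gate_of(bmi, crp, cpg),     # BMI -> CRP -> CpG
    model2 = gate_of(crp, bmi, cpg),     # CRP -> BMI -> CpG (a-path null)
    model3 = gate_of(smoke, crp, cpg),   # smoking -> CRP -> CpG
    model4 = gate_of(bmi, cpg, crp),     # BMI -> CpG -> CRP
    model5 = gate_of(crp, cpg, bmi),     # CRP -> CpG -> BMI
    model6 = gate_of(smoke, cpg, crp))   # smoking -> CpG -> CRP
  sel <- select_model(records)
  # the two planted orderings pass every Baron-Kenny precondition
  expect_true(all(sel$admissible[sel$model %in% c("model1", "model3")]))
  expect_equal(nrow(sel), 6)
  # all-null world admits nothing and names the violated precondition
  null_rec <- gate_of(rnorm(n), rnorm(n), matrix(rnorm(n), ncol = 1))
  nsel <- select_model(list(m = null_rec))
  expect_false(nsel$admissible)
  expect_true(nsel$dominant_violation %in%
                c("fail_a_path", "fail_c_path", "positive_indirect"))
  # empty input reports no_results, mirroring a model that produced nothing
  esel <- select_model(list(model6 = NULL))
  expect_identical(esel$dominant_violation, "no_results")
  expect_false(esel$admissible)
})

test_that("meta-mediation pools paths and sharpens the Sobel Z", {
  set.seed(43)
  n <- 800
  bmi <- rnorm(n, 27, 4.5)
  crp <- 0.08 * (bmi - 27) + rnorm(n, 0, 0.8)
  cpg <- 0.03 * crp + rnorm(n, 0, 0.05)
  rec <- mediation_gate(baron_kenny_paths(bmi, crp,
                                          matrix(cpg, ncol = 1,
                                                 dimnames = list(NULL,
                                                                 "cg"))))
  # one cohort: identical to the single-cohort record
  m1 <- meta_mediation(list(rec))
  expect_equal(m1$a, rec$a, tolerance = 1e-10)
  expect_equal(m1$sobel_z, rec$sobel_z, tolerance = 1e-10)

  # duplicated cohort: same estimates, SEs / sqrt(2), |Z| increases
  m2 <- meta_mediation(list(rec, rec))
  expect_equal(m2$a, rec$a, tolerance = 1e-10)
  expect_equal(m2$se_a, rec$se_a / sqrt(2), tolerance = 1e-10)
  expect_equal(m2$se_b, rec$se_b / sqrt(2), tolerance = 1e-10)
  expect_gt(abs(m2$sobel_z), abs(rec$sobel_z))
})

test_that("the Sobel test is conservative under the no-mediation null", {
  # simulate path estimates directly under a = 0 (no exposure-mediator
  # link); 10,000 nulls, rejection at alpha = 0.05 must stay below 6%
  set.seed(44)
  nsim <- 10000
  n <- 100
  se_a <- 1 / sqrt(n); se_b <- 1 / sqrt(n)
  a <- rnorm(nsim, 0, se_a)
  b <- rnorm(nsim, 0.3, se_b)
  s <- aroian_sobel(a, se_a, b, se_b)
  expect_lte(mean(s$p < 0.05), 0.06)
})
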