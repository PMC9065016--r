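test_that("pairwise correlations recover trivial structure", {
  set.seed(20)
  n <- 1000
  base <- rnorm(n)
  m <- cbind(a = base, b = base, c = -base + rnorm(n, 0, 1e-6),
             d = rnorm(n))
  pc <- pairwise_correlations(m)
  expect_equal(pc$r[pc$probe_a == "a" & pc$probe_b == "b"], 1)
  expect_lt(pc$r[pc$probe_a == "a" & pc$probe_b == "c"], -0.999)
  # zero-variance probe flags NA pairs
  m2 <- cbind(m, e = rep(0.5, n))
  pc2 <- pairwise_correlations(m2)
  expect_true(all(is.na(pc2$r[pc2$probe_b == "e"])))
  expect_error(pairwise_correlations(m[1:2, ]), ">= 3")
})

test_that("mean |r| of independent CpGs follows the sqrt(2/(pi n)) law", {
  set.seed(21)
  n <- 1000
  m <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("cg", 1:30)))
  pc <- pairwise_correlations(m)
  expect_equal(mean(abs(pc$r)), sqrt(2 / (pi * n)), tolerance = 0.1)
})

test_that("Fisher-z pooling matches hand values and the metafor oracle", {
  x <- data.frame(probe_a = "a", probe_b = "b", r = c(0.8, 0),
                  n = c(103, 103), cohort = c("c1", "c2"))
  mc <- meta_correlation(x)
  expect_equal(mc$r, tanh((atanh(0.8) * 100 + 0) / 200), tolerance = 1e-12)
  expect_equal(mc$r, 0.5, tolerance = 1e-4)
  expect_equal(mc$n, 206)

  # single cohort reduces to the input r
  one <- meta_correlation(data.frame(probe_a = "a", probe_b = "b", r = 0.3,
                                     n = 50, cohort = "c1"))
  expect_equal(one$r, 0.3, tolerance = 1e-12)

  # equal-n identical r pools to itself; |r| = 1 clamps with warning
  eq <- meta_correlation(data.frame(probe_a = "a", probe_b = "b",
                                    r = c(0.5, 0.5), n = c(40, 40)))
  expect_equal(eq$r, 0.5, tolerance = 1e-12)
  expect_warning(meta_correlation(data.frame(probe_a = "a", probe_b = "b",
                                             r = c(1, 0.5), n = c(40, 40))),
                 "clamped")

  skip_if_not_installed("metafor")
  set.seed(22)
  r <- runif(3, -0.8, 0.8); nn <- c(50, 80, 120)
  mine <- meta_correlation(data.frame(probe_a = "a", probe_b = "b", r = r,
                                      n = nn, cohort = 1:3))
  es <- metafor::escalc(measure = "ZCOR", ri = r, ni = nn)
  ref <- metafor::rma(yi = es$yi, vi = es$vi, method = "FE")
  expect_equal(mine$r, tanh(as.numeric(ref$beta)), tolerance = 1e-10)
})

test_that("pooled r is monotone in each cohort r", {
  base <- data.frame(probe_a = "a", probe_b = "b", r = c(0.2, 0.4),
                     n = c(60, 60))
  up <- base; up$r[2] <- 0.6
  expect_gt(meta_correlation(up)$r, meta_correlation(base)$r)
})

test_that("distance bins reproduce the 13-bin layout with right-closed edges", {
  ann <- data.frame(cpg = c("p0", paste0("p", 1:6)),
                    chromosome = c(rep("1", 6), "2"),
                    position = c(1000, 4500, 6000, 6001, 451001, 800000,
                                 5000))
  cm <- data.frame(probe_a = "p0",
                   probe_b = paste0("p", 1:6),
                   r = 0.5, n = 100, k = 1)
  bb <- bin_by_distance(cm, ann)
  expect_identical(bb$table$bin,
                   c("<=4kb",    # 3,500 bp
                     "<=5kb",    # exactly 5,000 bp stays in the 5 kb bin
                     "<=10kb",   # 5,001 bp crosses the edge
                     ">450kb",   # 450,001 bp
                     ">450kb",
                     "trans"))   # cross-chromosome pair: never a kb bin
  expect_equal(nrow(bb$summary), 14)  # 13 kb bins + trans bucket
  expect_identical(bb$summary$bin[1:5],
                   c("<=1kb", "<=2kb", "<=3kb", "<=4kb", "<=5kb"))
})

test_that("5 kb pruning is greedy by P, inclusive, and idempotent", {
  h <- data.frame(cpg = c("a", "b", "c"), chromosome = "1",
                  position = c(1000, 4000, 20000),
                  p = c(1e-10, 1e-8, 1e-9))
  ls <- prune_5kb(h)
  expect_identical(ls$retained, c("a", "c"))
  expect_identical(ls$dropped$cpg, "b")
  expect_identical(ls$dropped$retainer, "a")

  # all far apart: all retained
  far <- data.frame(cpg = letters[1:4], chromosome = "1",
                    position = c(0, 1, 2, 3) * 1e5, p = runif(4))
  expect_length(prune_5kb(far)$retained, 4)

  # exactly 5,000 bp apart collapses (inclusive rule)
  pair <- data.frame(cpg = c("a", "b"), chromosome = "1",
                     position = c(1000, 6000), p = c(0.5, 0.1))
  expect_identical(prune_5kb(pair)$retained, "b")

  # idempotence
  h2 <- h[h$cpg %in% ls$retained, ]
  expect_identical(prune_5kb(h2)$retained, ls$retained)

  # same position on different chromosomes does not collapse
  tw <- data.frame(cpg = c("a", "b"), chromosome = c("1", "2"),
                   position = 1000, p = c(0.1, 0.2))
  expect_length(prune_5kb(tw)$retained, 2)

  expect_warning(pr <- prune_5kb(data.frame(cpg = c("a", "b"),
                                            chromosome = "1",
                                            position = c(100, NA),
                                            p = c(0.1, 0.2))),
                 "without position")
  expect_identical(pr$retained, "a")
})

test_that("greedy pruning matches exhaustive search on small instances", {
  # the greedy retained set is the unique fixed point: among all subsets
  # satisfying the 5 kb spacing constraint, it is reproduced by picking
  # lowest-P first; verify against brute-force enumeration of maximal
  # admissible subsets built in P order
  brute <- function(h, window = 5000) {
    h <- h[order(h$p, h$cpg), ]
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      ok <- TRUE
      for (j in which(keep))
        if (h$chromosome[i] == h$chromosome[j] &&
            abs(h$position[i] - h$position[j]) <= window) ok <- FALSE
      keep[i] <- ok
    }
    sort(h$cpg[keep])
  }
  set.seed(23)
  for (rep in 1:25) {
    k <- sample(4:12, 1)
    h <- data.frame(cpg = sprintf("cg%02d", 1:k),
                    chromosome = sample(c("1", "2"), k, TRUE),
                    position = sample.int(30000, k),
                    p = signif(runif(k), 3))
    mine <- prune_5kb(h)
    expect_identical(sort(mine$retained), brute(h))
    # spacing invariant on the retained set
    r <- h[h$cpg %in% mine$retained, ]
    for (chr in unique(r$chromosome)) {
      pos <- sort(r$position[r$chromosome == chr])
      if (length(pos) > 1) expect_true(all(diff(pos) > 5000))
    }
  }
})

test_that("SNN density clustering recovers planted correlation blocks", {
  set.seed(24)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, k) sapply(1:k, function(i) sqrt(0.6) * f +
                                   sqrt(0.4) * rnorm(n))
  m <- cbind(block(f1, 100), block(f2, 100))
  colnames(m) <- paste0("cg", 1:200)
  cm <- cor(m)
  lab <- cluster_correlations(cm, k = 35, min_pts = 35, eps = 7, seed = 1)
  expect_length(lab, 200)
  found <- lab[lab > 0]
  expect_equal(length(unique(found[1:min(200, length(found))])), 2)
  # purity by best partition matching (labels compared as a partition)
  truth <- rep(1:2, each = 100)
  tab <- table(truth[lab > 0], lab[lab > 0])
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)

  # identical rows (perfectly correlated loci) land in one cluster
  same <- matrix(1, 40, 40)
  rownames(same) <- colnames(same) <- paste0("p", 1:40)
  lab2 <- cluster_correlations(same, k = 10, min_pts = 10, eps = 3, seed = 1)
  expect_equal(length(unique(lab2)), 1)

  expect_error(cluster_correlations(cm[1:20, 1:20], k = 35, min_pts = 35),
               "min_pts|lower k")
})

test_that("block-correlated CpGs decay with distance in the profile", {
  # generator blocks share a latent factor within < 5 kb: nearby pairs
  # correlate strongly, distant pairs are near zero
  cfg <- tiny_config(n_cohorts = 2, n_samples_per_cohort = 400,
                     n_cpgs = 200, frac_crp_responsive = 0,
                     frac_cpg_causal = 0, block_prob = 0.5, seed = 25)
  st <- simulate_study(cfg)
  ann <- attr(st$truth, "annotation")
  corr <- do.call(rbind, lapply(st$cohorts, function(co) {
    res <- residualize_methylation(co$methylation, co$phenotypes)
    pairwise_correlations(res, cohort = co$cohort)
  }))
  mc <- meta_correlation(corr)
  prof <- bin_by_distance(mc, ann)$summary
  near <- prof$mean_r[prof$bin %in% c("<=1kb", "<=2kb")]
  far <- prof$mean_r[prof$bin == ">450kb"]
  expect_gt(min(near, na.rm = TRUE), 0.2)
  expect_lt(abs(far), 0.1)
  # trans pairs exist and also hover near zero
  trans <- prof$mean_r[prof$bin == "trans"]
  expect_lt(abs(trans), 0.1)
})
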