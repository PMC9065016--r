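# Correlation structure of the CRP-associated CpGs: per-cohort Pearson
# correlations, Fisher-z meta-analysis, distance profiling, 5 kb locus
# pruning and shared-nearest-neighbor density clustering.

#' Per-cohort pairwise CpG correlations
#'
#' Pearson correlations between all CpG pairs of a probe subset, computed on
#' residualized methylation. Returned in long format (upper triangle only);
#' zero-variance CpGs yield `NA` pairs.
#'
#' @param resid_meth samples x CpGs residual matrix.
#' @param probes optional probe subset.
#' @param cohort identifier stamped on the rows.
#' @return Data frame `probe_a`, `probe_b`, `r`, `n`, `cohort`.
#' @export
pairwise_correlations <- function(resid_meth, probes = NULL,
                                  cohort = "cohort") {
  if (!is.null(probes))
    resid_meth <- resid_meth[, intersect(probes, colnames(resid_meth)),
                             drop = FALSE]
  if (nrow(resid_meth) < 3) stop("need >= 3 samples for correlations")
  v <- apply(resid_meth, 2, stats::var)
  cm <- suppressWarnings(stats::cor(resid_meth))
  cm[v == 0, ] <- NA
  cm[, v == 0] <- NA
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(probe_a = colnames(cm)[ut[, 1]], probe_b = colnames(cm)[ut[, 2]],
             r = cm[ut], n = nrow(resid_meth), cohort = cohort,
             stringsAsFactors = FALSE)
}

#' Sample-size-weighted meta-analysis of correlations
#'
#' Fixed-effect pooling on the Fisher-z scale: `z_i = atanh(r_i)` weighted by
#' `n_i - 3`, back-transformed with `tanh`. Correlations at `|r| = 1` are
#' clamped to `1 - 1e-12` with a warning (infinite z otherwise).
#'
#' @param corr_long long-format table from [pairwise_correlations()], rows
#'   from all cohorts stacked.
#' @return Data frame `probe_a`, `probe_b`, `r` (pooled), `n` (combined),
#'   `k` cohorts.
#' @export
#' @examples
#' x <- data.frame(probe_a = "a", probe_b = "b", r = c(0.8, 0),
#'                 n = c(103, 103), cohort = c("c1", "c2"))
#' meta_correlation(x)$r  # 0.5
meta_correlation <- function(corr_long) {
  if (any(corr_long$n < 4, na.rm = TRUE))
    stop("each cohort needs n >= 4 for Fisher-z weights")
  r <- corr_long$r
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlations at |r| = 1 clamped for the Fisher transform")
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  z <- atanh(r)
  w <- corr_long$n - 3
  w[!is.finite(z)] <- NA
  key <- paste(corr_long$probe_a, corr_long$probe_b, sep = "\r")
  sw <- tapply(w * !is.na(z), key, sum, na.rm = TRUE)
  sz <- tapply(w * z, key, sum, na.rm = TRUE)
  n <- tapply(corr_long$n * !is.na(z), key, sum, na.rm = TRUE)
  k <- tapply(!is.na(z), key, sum)
  ab <- do.call(rbind, strsplit(names(sw), "\r", fixed = TRUE))
  out <- data.frame(probe_a = ab[, 1], probe_b = ab[, 2],
                    r = tanh(as.numeric(sz) / as.numeric(sw)),
                    n = as.numeric(n), k = as.integer(k),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$probe_a, out$probe_b), , drop = FALSE]
}

# The 13 distance bins (upper edges in kb; right-closed).
distance_bin_edges_kb <- c(1, 2, 3, 4, 5, 10, 20, 50, 100, 150, 300, 450, Inf)

distance_bin_labels <- function() {
  e <- distance_bin_edges_kb
  c(paste0("<=", e[-length(e)], "kb"), ">450kb")
}

#' Bin CpG-pair correlations by genomic distance
#'
#' Same-chromosome pairs are assigned to the first right-closed bin whose
#' upper edge (1, 2, 3, 4, 5, 10, 20, 50, 100, 150, 300, 450 kb, then
#' `>450 kb`) is at least the pair distance `|pos_a - pos_b|`.
#' Cross-chromosome pairs go to a separate `"trans"` bucket, never a kb bin.
#'
#' @param corr_meta pooled correlation table ([meta_correlation()] output).
#' @param annotation CpG annotation with `cpg`, `chromosome`, `position`.
#' @return List with the per-pair `table` (added `distance`, `bin` columns)
#'   and a per-bin `summary` (n, mean r, SE of the mean).
#' @export
bin_by_distance <- function(corr_meta, annotation) {
  ia <- match(corr_meta$probe_a, annotation$cpg)
  ib <- match(corr_meta$probe_b, annotation$cpg)
  if (anyNA(ia) || anyNA(ib)) stop("probes missing from annotation")
  same <- annotation$chromosome[ia] == annotation$chromosome[ib]
  dist <- abs(annotation$position[ia] - annotation$position[ib])
  edges <- distance_bin_edges_kb * 1000
  labs <- distance_bin_labels()
  bin_idx <- findInterval(dist - 1, c(0, edges[-length(edges)])) # right-closed
  bin_idx <- pmax(bin_idx, 1L)                       # distance 0 -> first bin
  bin <- ifelse(same, labs[bin_idx], "trans")
  tab <- cbind(corr_meta, distance = ifelse(same, dist, NA_integer_),
               bin = bin)
  lev <- c(labs, "trans")
  grp <- factor(tab$bin, levels = lev)
  summ <- data.frame(
    bin = lev,
    n = as.integer(table(grp)),
    mean_r = as.numeric(tapply(tab$r, grp, mean, na.rm = TRUE)),
    se_r = as.numeric(tapply(tab$r, grp, function(x)
      stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))),
    stringsAsFactors = FALSE)
  list(table = tab, summary = summ)
}

#' Prune correlated hits to independent loci with a 5 kb window
#'
#' Greedy pruning: repeatedly retain the unclaimed probe with the globally
#' lowest association p-value and drop every unclaimed probe on the same
#' chromosome within the window (inclusive, i.e. a pair exactly `window` bp
#' apart is collapsed). Ties on p are broken lexicographically by probe id.
#' The result is idempotent and no two retained probes on one chromosome lie
#' within the window.
#'
#' @param hits data frame with `cpg`, `chromosome`, `position`, `p`.
#' @param window window size in bp (default 5000).
#' @return A `locus_set` list: `retained` probe ids, and `dropped` (data
#'   frame mapping each dropped probe to the retainer that absorbed it).
#' @export
#' @examples
#' h <- data.frame(cpg = c("a", "b", "c"), chromosome = "1",
#'                 position = c(1000, 4000, 20000), p = c(1e-10, 1e-8, 1e-9))
#' prune_5kb(h)$retained  # "a" and "c"
prune_5kb <- function(hits, window = 5000) {
  need <- c("cpg", "chromosome", "position", "p")
  stopifnot(all(need %in% names(hits)))
  nopos <- !is.finite(hits$position)
  if (any(nopos)) {
    warning(sum(nopos), " probe(s) without position excluded from pruning")
    hits <- hits[!nopos, , drop = FALSE]
  }
  hits <- hits[order(hits$p, hits$cpg), , drop = FALSE]
  retained <- character(0)
  dropped_id <- dropped_by <- character(0)
  claimed <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    retained <- c(retained, hits$cpg[i])
    near <- !claimed & hits$chromosome == hits$chromosome[i] &
      abs(hits$position - hits$position[i]) <= window
    if (any(near)) {
      dropped_id <- c(dropped_id, hits$cpg[near])
      dropped_by <- c(dropped_by, rep(hits$cpg[i], sum(near)))
      claimed[near] <- TRUE
    }
  }
  structure(list(retained = retained,
                 dropped = data.frame(cpg = dropped_id, retainer = dropped_by,
                                      stringsAsFactors = FALSE)),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d retained, %d dropped into retainers\n",
              length(x$retained), nrow(x$dropped)))
  invisible(x)
}

# k nearest neighbors (excluding self) from a coordinate matrix; points
# tied with the k-th neighbor distance are all included, so coincident
# points get symmetric neighborhoods.
knn_indices <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  lapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    kth <- sort(row, partial = k)[k]
    which(row <= kth)
  })
}

#' Density clustering of the pruned correlation matrix
#'
#' Embeds the rows of the meta-analyzed correlation matrix into two
#' dimensions, builds a shared-nearest-neighbor (SNN) graph with
#' neighborhood size `k`, and density-clusters it DBSCAN-style: two points
#' are SNN-reachable when each lies in the other's k-neighborhood and they
#' share at least `eps` of their k nearest neighbors; core points have at
#' least `min_pts` reachable points (self included); clusters grow from core
#' points, and unreachable points are labelled noise (`0`).
#'
#' The default embedding is classical metric MDS of the correlation rows
#' (`stats::cmdscale`); any function returning an n x 2 coordinate matrix
#' can be plugged in via `embed_fun` (e.g. a UMAP wrapper).
#'
#' @param cormat square correlation matrix of the pruned loci (rows used as
#'   feature vectors).
#' @param k neighborhood size.
#' @param min_pts minimum points for a core point.
#' @param eps minimum number of shared neighbors for an SNN edge.
#' @param seed RNG seed forwarded to the embedding.
#' @param embed_fun `function(cormat, seed)` returning an n x 2 matrix.
#' @return Integer cluster labels (0 = noise) named by the matrix rownames,
#'   with the embedding in attribute `"embedding"`.
#' @export
cluster_correlations <- function(cormat, k = 35, min_pts = 35, eps = 7,
                                 seed = 1, embed_fun = NULL) {
  n <- nrow(cormat)
  if (n < min_pts) stop("fewer loci than min_pts")
  if (n <= k) stop("fewer loci than the neighborhood size k; lower k")
  if (is.null(embed_fun))
    embed_fun <- function(m, seed) {
      m[!is.finite(m)] <- 0
      e <- suppressWarnings(stats::cmdscale(stats::dist(m), k = 2))
      if (!is.matrix(e) || ncol(e) < 2) {   # degenerate geometry: pad axes
        full <- matrix(0, nrow(m), 2)
        if (length(e)) full[, seq_len(ncol(e))] <- e
        e <- full
      }
      e
    }
  emb <- with_seed(seed, embed_fun(cormat, seed))
  nnsets <- knn_indices(emb, k)
  # SNN reachability within mutual k-neighborhoods
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- nnsets[[i]]
    mutual <- cand[vapply(cand, function(j) i %in% nnsets[[j]], TRUE)]
    shared <- vapply(mutual, function(j)
      length(intersect(nnsets[[i]], nnsets[[j]])), 0L)
    neighbors[[i]] <- mutual[shared >= eps]
  }
  core <- vapply(neighbors, length, 0L) + 1L >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (nb in neighbors[[j]]) {
        if (labels[nb] == 0L) {
          labels[nb] <- cl
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  names(labels) <- rownames(cormat)
  attr(labels, "embedding") <- emb
  labels
}
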