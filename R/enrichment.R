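# Overrepresentation of a CpG set in genomic feature tracks, with a
# permutation null matched on the CpGs' standard-error distribution.

# CpG manifest positions are 1-based; BED intervals are 0-based half-open.
# The conversion lives here and nowhere else.
cpg_granges <- function(cpgs, annotation, dialect = "plain") {
  idx <- match(cpgs, annotation$cpg)
  if (anyNA(idx)) stop("CpGs missing from annotation: ",
                       paste(utils::head(cpgs[is.na(idx)]), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = normalize_chr(annotation$chromosome[idx], dialect),
    ranges = IRanges::IRanges(start = annotation$position[idx], width = 1))
}

#' Count CpG overlaps with a feature track
#'
#' A CpG overlaps when its (1-based) position falls inside any interval of
#' the track; each CpG counts at most once however many intervals cover it
#' (union semantics). Chromosome names of track and manifest are normalized
#' to a common dialect before comparison.
#'
#' @param cpgs probe ids.
#' @param annotation CpG annotation with 1-based `position`.
#' @param track a `GRanges` feature track (see [read_bed()]).
#' @return Integer overlap count.
#' @export
overlap_count <- function(cpgs, annotation, track) {
  gr <- cpg_granges(cpgs, annotation)
  GenomeInfoDb::seqlevels(track) <-
    normalize_chr(GenomeInfoDb::seqlevels(track))
  sum(IRanges::overlapsAny(gr, track))
}

# Logical overlap indicator for every probe of a universe (precomputed once
# so permutation nulls are a matter of indexing).
overlap_indicator <- function(universe_cpgs, annotation, track) {
  gr <- cpg_granges(universe_cpgs, annotation)
  GenomeInfoDb::seqlevels(track) <-
    normalize_chr(GenomeInfoDb::seqlevels(track))
  IRanges::overlapsAny(gr, track)
}

#' Standard-error-matched permutation null sampler
#'
#' Bins the universe's per-CpG standard errors into fixed-width intervals
#' `[k w, (k+1) w)` with `w = bin_width`, and draws `n_perm` null sets that
#' reproduce the target set's per-bin counts exactly, sampling without
#' replacement within each draw. Target CpGs remain eligible for the null
#' draws (set `exclude_target = TRUE` to remove them). Deterministic given
#' `seed`.
#'
#' @param universe data frame `cpg`, `se` for every tested CpG.
#' @param target character vector of target CpG ids (subset of universe).
#' @param n_perm number of permuted sets.
#' @param bin_width SE bin width.
#' @param seed RNG seed.
#' @param exclude_target drop target CpGs from the sampling pool.
#' @return A `matched_null` list: `sets` (n_perm x set-size matrix of
#'   universe row indices), `bin` (per-universe-CpG bin index), and
#'   `target_counts` (required per-bin counts).
#' @export
sd_matched_null <- function(universe, target, n_perm = 10000,
                            bin_width = 0.005, seed = 1,
                            exclude_target = FALSE) {
  stopifnot(all(c("cpg", "se") %in% names(universe)))
  tidx <- match(target, universe$cpg)
  if (anyNA(tidx)) stop("target CpGs missing from the universe")
  bin <- floor(universe$se / bin_width)
  pool_ok <- rep(TRUE, nrow(universe))
  if (exclude_target) pool_ok[tidx] <- FALSE
  need <- table(bin[tidx])
  have <- table(bin[pool_ok])
  short <- names(need)[need > ifelse(is.na(have[names(need)]), 0,
                                     have[names(need)])]
  if (length(short))
    stop("under-populated SE bin(s) [", paste(short, collapse = ", "),
         "]: universe cannot supply the target's per-bin counts")
  pools <- split(which(pool_ok), bin[pool_ok])[names(need)]
  sets <- with_seed(seed, {
    draws <- matrix(0L, n_perm, length(tidx))
    for (i in seq_len(n_perm)) {
      picked <- unlist(lapply(seq_along(pools), function(bi) {
        pool <- pools[[bi]]
        if (length(pool) == 1L) pool else sample(pool, need[[bi]])
      }), use.names = FALSE)
      draws[i, ] <- picked
    }
    draws
  })
  structure(list(sets = sets, bin = bin, target_counts = need,
                 universe = universe$cpg, target_idx = tidx,
                 n_perm = n_perm, bin_width = bin_width, seed = seed),
            class = "matched_null")
}

#' Empirical enrichment p-values from a permutation null
#'
#' Add-one empirical p-values in both directions:
#' `P_high = (#\{null >= observed\} + 1) / (n_perm + 1)` and the analogous
#' `P_low` with `<=`, so neither can be zero. A Fisher exact p-value is also
#' computed from the 2x2 table of the observed overlap against the rounded
#' null mean (one defensible reading of a "Fisher P from the H0 mean";
#' labelled as such).
#'
#' @param observed observed overlap count of the target set.
#' @param null_counts vector of null overlap counts.
#' @param set_size size of the target set.
#' @param track name stamped on the result.
#' @return An `enrichment_result` data frame row: observed, null mean/SD,
#'   `empirical_p_high`, `empirical_p_low`, `fisher_p`, `n_permutations`.
#' @export
empirical_enrichment <- function(observed, null_counts, set_size,
                                 track = "track") {
  n <- length(null_counts)
  if (n < 100) warning("fewer than 100 permutations; p-values are coarse")
  p_high <- (sum(null_counts >= observed) + 1) / (n + 1)
  p_low <- (sum(null_counts <= observed) + 1) / (n + 1)
  m <- min(max(round(mean(null_counts)), 0L), set_size)
  fisher_p <- stats::fisher.test(
    rbind(c(observed, set_size - observed), c(m, set_size - m)))$p.value
  structure(data.frame(track = track, observed = observed,
                       null_mean = mean(null_counts),
                       null_sd = stats::sd(null_counts),
                       empirical_p_high = p_high, empirical_p_low = p_low,
                       fisher_p = fisher_p, n_permutations = n,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Permutation enrichment of a CpG set in a feature track
#'
#' Full test: observed overlap of the target set, null overlap distribution
#' over SE-matched permuted sets, and the empirical/Fisher p-values.
#'
#' @param universe data frame `cpg`, `se`.
#' @param target target CpG ids.
#' @param annotation CpG annotation (1-based positions).
#' @param track `GRanges` feature track.
#' @param n_perm,bin_width,seed,exclude_target forwarded to
#'   [sd_matched_null()].
#' @param track_name label for the result row.
#' @return An `enrichment_result` with the null counts in attribute
#'   `"null_counts"`.
#' @export
enrichment_test <- function(universe, target, annotation, track,
                            n_perm = 10000, bin_width = 0.005, seed = 1,
                            exclude_target = FALSE, track_name = "track") {
  ind <- overlap_indicator(universe$cpg, annotation, track)
  sampler <- sd_matched_null(universe, target, n_perm = n_perm,
                             bin_width = bin_width, seed = seed,
                             exclude_target = exclude_target)
  observed <- sum(ind[sampler$target_idx])
  null_counts <- null_overlap_counts(sampler, ind)
  res <- empirical_enrichment(observed, null_counts, length(target),
                              track = track_name)
  attr(res, "null_counts") <- null_counts
  res
}

# Null overlap counts by indexing the precomputed indicator.
null_overlap_counts <- function(sampler, indicator) {
  m <- matrix(indicator[sampler$sets], nrow = nrow(sampler$sets))
  as.integer(rowSums(m))
}
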