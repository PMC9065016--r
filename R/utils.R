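# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library code never disturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Stop unless all conditions hold; conditions given as named logicals.
stop_unless <- function(...) {
  conds <- c(...)
  bad <- names(conds)[!conds]
  if (length(bad)) stop(paste(bad, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

#' Normalize chromosome names to a dialect
#'
#' Genomic inputs mix the "chr1" (UCSC) and "1" (Ensembl) dialects; all
#' comparisons inside the package go through this normalizer.
#'
#' @param x character vector of chromosome names.
#' @param dialect `"plain"` (strip a leading "chr") or `"chr"` (ensure the
#'   prefix).
#' @return character vector in the requested dialect.
#' @export
#' @examples
#' normalize_chr(c("chr1", "2", "chrX"))
normalize_chr <- function(x, dialect = c("plain", "chr")) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  bare <- sub("^chr", "", x, ignore.case = TRUE)
  if (dialect == "plain") bare else paste0("chr", bare)
}

# logit / inverse logit on the methylation scale
logit <- function(p) log(p / (1 - p))

# Two-sided normal p-value from a z statistic.
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# Format a threshold the way study reports print them (two significant figures).
format_threshold <- function(x) signif(x, 2)
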