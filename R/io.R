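# Readers and writers for the exchange formats: METAL-compatible summary
# TSVs and BED feature tracks.

summary_aliases <- list(
  cpg = c("cpg", "MarkerName", "marker", "probe"),
  effect = c("effect", "Effect", "beta", "BETA"),
  se = c("se", "StdErr", "SE", "stderr"),
  p = c("p", "P", "P-value", "Pvalue", "P.value"),
  n = c("n", "N", "Weight"),
  meth_sd = c("meth_sd", "EffectSD", "sd"))

#' Read a cohort summary TSV
#'
#' Accepts both the package's native column names and METAL-style aliases
#' (`MarkerName`, `Effect`, `StdErr`, `P-value`, `Weight`, `EffectSD`).
#' Standard errors must be positive and p-values in (0, 1].
#'
#' @param path TSV file path.
#' @param cohort,model identifiers stamped on the rows (defaults: file
#'   columns if present, else the file name).
#' @return A `cohort_summary` data frame.
#' @export
read_summary_tsv <- function(path, cohort = NULL, model = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (field in names(summary_aliases)) {
    hit <- intersect(summary_aliases[[field]], names(df))
    if (length(hit)) out[[field]] <- df[[hit[1]]]
    else if (field %in% c("cpg", "effect", "se"))
      stop("required column missing from ", path, ": ", field,
           " (accepted names: ", paste(summary_aliases[[field]],
                                       collapse = ", "), ")")
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (any(out$se <= 0 | !is.finite(out$se)))
    stop("malformed standard errors (must be finite and > 0) in ", path)
  if (!is.null(out$p) && any(out$p <= 0 | out$p > 1, na.rm = TRUE))
    stop("malformed p-values in ", path)
  out$cohort <- cohort %||% df$cohort[1] %||%
    sub("[.]tsv$", "", basename(path))
  out$model <- model %||% df$model[1] %||% "base"
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Write a cohort summary as a METAL-compatible TSV
#'
#' Columns `MarkerName`, `Effect`, `StdErr`, `P`, `N`, `EffectSD`,
#' `cohort`, `model`; round-trips through [read_summary_tsv()].
#'
#' @param summary a `cohort_summary` data frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(summary, path) {
  out <- data.frame(MarkerName = summary$cpg, Effect = summary$effect,
                    StdErr = summary$se, P = summary$p, N = summary$n,
                    EffectSD = summary$meth_sd %||% NA_real_,
                    cohort = summary$cohort %||% "cohort",
                    model = summary$model %||% "base",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED feature track
#'
#' BED3+ via rtracklayer (gzip input accepted): 0-based half-open intervals
#' become the 1-based closed `GRanges` convention, so a BED line
#' `chr1 99 100` covers exactly the 1-based position 100. Records with
#' `start >= end` are rejected.
#'
#' @param path BED file path (optionally gzipped).
#' @param name track name (defaults to the file name).
#' @return A `GRanges` with metadata `track_name`.
#' @export
read_bed <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED intervals with start >= end in ", path)
  S4Vectors::metadata(gr)$track_name <-
    name %||% sub("[.]bed([.]gz)?$", "", basename(path))
  gr
}
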