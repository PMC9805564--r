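#' ssGSEA parameters
#'
#' @param alpha Rank-weighting exponent (default 0.25). Within each sample,
#'   genes are ordered by decreasing value and the gene at position i gets
#'   rank weight `(N - i + 1)^alpha` (so the top gene weighs `N^alpha`);
#'   `alpha = 0` makes all weights 1.
#' @param normalize Divide the score matrix by its global range
#'   (max - min) across all sets and samples (default TRUE).
#' @param min_set_size,max_set_size Matched-size bounds as in
#'   [enrichment_params()].
#' @return An object of class `SsgseaParams`.
#' @export
ssgsea_params <- function(alpha = 0.25, normalize = TRUE,
                          min_set_size = 15L, max_set_size = 500L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            alpha >= 0)
  min_set_size <- as.integer(min_set_size)
  max_set_size <- as.integer(max_set_size)
  if (min_set_size > max_set_size)
    stop("min_set_size must be <= max_set_size")
  structure(list(alpha = as.numeric(alpha), normalize = isTRUE(normalize),
                 min_set_size = min_set_size, max_set_size = max_set_size),
            class = "SsgseaParams")
}

# integrated in/out ECDF difference for one sample given the member index
# vector; `ord` and rank weights are precomputed by the caller
.ssgsea_es_ordered <- function(hit_sorted, rw, n) {
  nh <- sum(hit_sorted)
  p_in <- cumsum(rw * hit_sorted) / sum(rw[hit_sorted])
  p_out <- cumsum(!hit_sorted) / (n - nh)
  sum(p_in - p_out)
}

#' Single-sample enrichment score
#'
#' Ranks one sample's genes by decreasing value (ties broken by ascending
#' gene symbol), weights member genes by their descending rank index raised
#' to `alpha`, and returns the integrated (summed, not supremum) difference
#' between the cumulative normalized member-weight distribution and the
#' cumulative non-member fraction. Depends on the values only through their
#' ranks, so any strictly increasing transform of the sample leaves the
#' score unchanged.
#'
#' @param values Named numeric vector: one sample's gene values.
#' @param members Character vector of member gene symbols
#'   (case-insensitive).
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return The raw ssGSEA enrichment score (a single number).
#' @export
ssgsea_sample <- function(values, members, alpha = 0.25) {
  if (is.null(names(values))) stop("values must be named by gene")
  n <- length(values)
  if (n < 2L) stop("need >= 2 genes")
  genes <- toupper(names(values))
  if (anyDuplicated(genes)) stop("duplicate gene names in sample")
  hit <- genes %in% toupper(members)
  nh <- sum(hit)
  if (nh == 0L) stop("set not represented in the sample")
  if (nh == n) stop("set covers all genes; out-of-set fraction undefined")
  ord <- order(-values, genes, method = "radix")
  rw <- (n - seq_len(n) + 1)^alpha   # descending rank index N, N-1, ..., 1
  .ssgsea_es_ordered(hit[ord], rw, n)
}

#' ssGSEA over an expression matrix
#'
#' One enrichment score per (gene set, sample); sets are size-filtered as in
#' [run_prerank()]. When `normalize = TRUE` the whole score matrix is
#' divided by its global range (max - min); a zero range skips
#' normalization with a warning.
#'
#' @param dataset An [expression_dataset()] (phenotypes not required).
#' @param library A [gene_set_library()].
#' @param params An [ssgsea_params()].
#' @return An object of class `SsgseaResult`: list with `scores` (sets x
#'   samples matrix of raw ES), `normalized` (same shape, or NULL),
#'   `skipped` (data frame), and `params`.
#' @export
ssgsea_matrix <- function(dataset, library, params = ssgsea_params()) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(params, "SsgseaParams"))
  values <- dataset$values
  genes <- rownames(values)
  n <- length(genes)
  fparams <- list(min_set_size = params$min_set_size,
                  max_set_size = params$max_set_size)
  matched <- .match_library(library, genes, fparams)
  rw <- (n - seq_len(n) + 1)^params$alpha
  hit_all <- lapply(matched$kept, function(idx) {
    h <- logical(n); h[idx] <- TRUE; h
  })
  scores <- matrix(NA_real_, length(matched$kept), ncol(values),
                   dimnames = list(names(matched$kept), colnames(values)))
  for (j in seq_len(ncol(values))) {
    ord <- order(-values[, j], genes, method = "radix")
    for (nm in names(hit_all))
      scores[nm, j] <- .ssgsea_es_ordered(hit_all[[nm]][ord], rw, n)
  }
  normalized <- NULL
  if (params$normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) {
      warning("global score range is zero; normalization skipped")
    } else {
      normalized <- scores / rng
    }
  }
  structure(list(scores = scores, normalized = normalized,
                 skipped = matched$skipped, params = params),
            class = "SsgseaResult")
}

#' @export
print.SsgseaResult <- function(x, ...) {
  cat("SsgseaResult:", nrow(x$scores), "sets x", ncol(x$scores),
      "samples (alpha =", x$params$alpha, ")\n")
  invisible(x)
}

#' Write ssGSEA score matrices as TSV
#'
#' Rows are gene sets, columns are samples. Writes the raw ES matrix to
#' `es_path` and, when present, the normalized matrix to `nes_path`.
#'
#' @param result An `SsgseaResult`.
#' @param es_path Output path for raw scores.
#' @param nes_path Optional output path for normalized scores.
#' @return `es_path`, invisibly.
#' @export
write_ssgsea_tsv <- function(result, es_path, nes_path = NULL) {
  stopifnot(inherits(result, "SsgseaResult"))
  .write_mat <- function(m, path) {
    df <- data.frame(Term = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  .write_mat(result$scores, es_path)
  if (!is.null(nes_path)) {
    if (is.null(result$normalized))
      stop("result has no normalized scores")
    .write_mat(result$normalized, nes_path)
  }
  invisible(es_path)
}
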