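#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values across the terms of one library, clipped to
#' <= 1 and monotone with respect to the p-value ordering. Thin wrapper over
#' `stats::p.adjust(method = "BH")` kept as the module surface.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichr-style combined score
#'
#' `c = -ln(p) * z`. Here `z` is the standardized deviation of the observed
#' overlap from its hypergeometric expectation (a local surrogate for
#' Enrichr's server-side rank-deviation z, which requires precomputed
#' background ranks).
#'
#' @param p_fisher Fisher exact p-value in (0, 1].
#' @param z Overlap z-score.
#' @return The combined score.
#' @export
combined_score <- function(p_fisher, z) {
  if (any(p_fisher <= 0 | p_fisher > 1))
    stop("p_fisher must lie in (0, 1]")
  -log(p_fisher) * z
}

#' One-sided over-representation p-value
#'
#' Hypergeometric upper-tail probability `P[X >= k]` of observing at least
#' `k` query genes inside a set of size `K`, for a query of size `n` drawn
#' from a universe of size `N`. This is the Fisher exact enrichment p-value
#' used by [fisher_enrich()]. All arguments are vectorized.
#'
#' @param k Observed overlap count(s).
#' @param set_size Set size(s) `K` within the universe.
#' @param query_size Query size(s) `n`.
#' @param universe_size Universe size(s) `N`.
#' @return Numeric vector of p-values; `k = 0` gives exactly 1.
#' @export
overlap_pvalue <- function(k, set_size, query_size, universe_size) {
  stats::phyper(k - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Over-representation analysis of a query gene list
#'
#' For every library set, forms the 2x2 table of query/set membership over
#' the background universe and tests over-representation with the one-sided
#' Fisher exact test (hypergeometric upper tail, `P[X >= k]`). Reports the
#' BH-adjusted p-value, the table odds ratio (Haldane 0.5 correction only
#' when a zero cell makes it undefined), the combined score
#' (`-ln(p) * z` with the hypergeometric overlap z-score), and the percent
#' of query genes in the set.
#'
#' Sets are intersected with the universe before counting. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query Character vector of query gene symbols (case-insensitive).
#' @param library A [gene_set_library()].
#' @param universe Optional character vector of background genes; defaults
#'   to the union of all library genes.
#' @return A data frame of class `OraResult`, one row per set, sorted by
#'   p-value: columns `term`, `overlap_k`, `set_size_K`, `query_size_n`,
#'   `universe_N`, `p_fisher`, `p_adjusted`, `odds_ratio`,
#'   `combined_score`, `pct_query_in_set`, `overlap_genes` (comma-joined).
#' @export
fisher_enrich <- function(query, library, universe = NULL) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  if (!length(library$sets)) stop("gene set library is empty")
  query <- unique(toupper(query))
  if (is.null(universe)) {
    universe <- unique(unlist(library$sets, use.names = FALSE))
  } else {
    universe <- unique(toupper(universe))
  }
  if (!length(universe)) stop("universe is empty")
  drop <- setdiff(query, universe)
  if (length(drop)) {
    warning(length(drop), " query gene(s) not in the universe were dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty after universe filtering")
  n <- length(query)
  nn <- length(universe)
  if (nn < n) stop("universe smaller than query")
  rows <- lapply(names(library$sets), function(nm) {
    members <- intersect(library$sets[[nm]], universe)
    kk <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- overlap_pvalue(k, kk, n, nn)
    # 2x2 table: (k, n-k, K-k, N-K-n+k)
    a <- k; b <- n - k; cc <- kk - k; d <- nn - kk - n + k
    if (b == 0 || cc == 0) {  # zero denominator cell -> Haldane correction
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (b * cc)
    }
    expct <- n * kk / nn
    sd_hyp <- sqrt(n * (kk / nn) * (1 - kk / nn) * (nn - n) / (nn - 1))
    z <- if (sd_hyp == 0) 0 else (k - expct) / sd_hyp
    data.frame(term = nm, overlap_k = k, set_size_K = kk,
               query_size_n = n, universe_N = nn, p_fisher = p,
               odds_ratio = or,
               combined_score = combined_score(p, z),
               pct_query_in_set = 100 * k / n,
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_fisher)
  out <- out[, c("term", "overlap_k", "set_size_K", "query_size_n",
                 "universe_N", "p_fisher", "p_adjusted", "odds_ratio",
                 "combined_score", "pct_query_in_set", "overlap_genes")]
  out <- out[order(out$p_fisher, -out$combined_score, out$term,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("OraResult", "data.frame")
  out
}

#' Write an over-representation report as TSV
#'
#' Columns follow the Enrichr report convention: Term, Overlap (`k/K`),
#' P-value, Adjusted P-value, Odds Ratio, Combined Score, Genes.
#'
#' @param result An `OraResult` from [fisher_enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ora_tsv <- function(result, path) {
  stopifnot(inherits(result, "OraResult"))
  out <- data.frame(
    Term = result$term,
    Overlap = paste(result$overlap_k, result$set_size_K, sep = "/"),
    `P-value` = result$p_fisher,
    `Adjusted P-value` = result$p_adjusted,
    `Odds Ratio` = result$odds_ratio,
    `Combined Score` = result$combined_score,
    `% Query in Set` = result$pct_query_in_set,
    Genes = result$overlap_genes,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
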