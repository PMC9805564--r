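#' Enrichment analysis parameters
#'
#' @param weight_exponent Exponent applied to |ranking score| when weighting
#'   the running sum (default 1; 0 gives the classic unweighted
#'   Kolmogorov-Smirnov statistic).
#' @param n_permutations Number of permutations for the null distribution
#'   (default 1000).
#' @param permutation_type `"gene_set"` (random same-size gene subsets
#'   against the fixed ranking) or `"phenotype"` (sample-label shuffles with
#'   the ranking metric recomputed each time).
#' @param min_set_size,max_set_size Matched-size bounds; sets outside
#'   \[min, max\] are skipped (defaults 15 and 500).
#' @param seed Integer root seed. Gene-set permutation streams per set are
#'   derived from it by a stable hash of the set name, so set order never
#'   changes results.
#' @return An object of class `EnrichmentParams`.
#' @export
enrichment_params <- function(weight_exponent = 1,
                              n_permutations = 1000L,
                              permutation_type = c("gene_set", "phenotype"),
                              min_set_size = 15L,
                              max_set_size = 500L,
                              seed = 42L) {
  permutation_type <- match.arg(permutation_type)
  stopifnot(is.numeric(weight_exponent), weight_exponent >= 0,
            is.finite(weight_exponent))
  n_permutations <- as.integer(n_permutations)
  min_set_size <- as.integer(min_set_size)
  max_set_size <- as.integer(max_set_size)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be >= 1")
  if (min_set_size > max_set_size)
    stop("min_set_size must be <= max_set_size")
  structure(list(weight_exponent = as.numeric(weight_exponent),
                 n_permutations = n_permutations,
                 permutation_type = permutation_type,
                 min_set_size = min_set_size,
                 max_set_size = max_set_size,
                 seed = as.integer(seed)),
            class = "EnrichmentParams")
}

# stable 31-bit string hash, used to derive per-set RNG streams
.hash_string <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

.derive_seed <- function(seed, name) {
  as.integer((as.numeric(seed) + .hash_string(name)) %% 2147483647)
}

# run expr with the global RNG state restored afterwards
.preserve_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Running-sum enrichment score
#'
#' Walks the ranked list from top to bottom; at each member ("hit") the sum
#' increments by that gene's weight `|score|^weight_exponent` normalized by
#' the total hit weight, at each non-member it decrements by `1/(N - Nh)`.
#' The enrichment score (ES) is the curve value of maximal absolute
#' deviation from zero. With `weight_exponent = 0` every gene (including
#' score 0) gets weight 1 and ES reduces to the signed two-sample
#' Kolmogorov-Smirnov supremum.
#'
#' @param ranked A [ranked_list()].
#' @param members Character vector of gene symbols (case-insensitive). Must
#'   intersect the ranked genes and be a strict subset of them.
#' @param weight_exponent Non-negative weighting exponent (default 1).
#' @return An object of class `RunningSum`: list with `curve` (length-N
#'   numeric, final value 0), `hit_positions` (ascending 1-based positions
#'   of members), `es`, and `peak_position` (first position where |curve| is
#'   maximal).
#' @export
running_enrichment <- function(ranked, members, weight_exponent = 1) {
  stopifnot(inherits(ranked, "RankedList"))
  hit <- ranked$gene %in% toupper(members)
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop("set not represented in the ranked list")
  if (nh == n) stop("set covers the entire ranked list; decrement undefined")
  w <- if (weight_exponent == 0) rep(1, n) else abs(ranked$score)^weight_exponent
  wh <- w * hit
  sumw <- sum(wh)
  if (sumw == 0) {
    warning("all in-set ranking scores are zero; using unweighted increments")
    wh <- as.numeric(hit)
    sumw <- nh
  }
  # cumulative-count formulation: each curve value is a ratio of cumulative
  # sums, so the weight-0 case is exactly a difference of empirical CDFs
  curve <- cumsum(wh) / sumw - cumsum(!hit) / (n - nh)
  peak <- which.max(abs(curve))
  structure(list(curve = curve,
                 hit_positions = which(hit),
                 es = curve[peak],
                 peak_position = peak),
            class = "RunningSum")
}

# ES from sorted hit positions only (the curve is piecewise linear between
# hits, so its extremes sit just after or just before a hit). `pos` is an
# ascending integer vector or an m x nperm matrix of ascending columns;
# `w_all` is |score|^exponent over the full ranked list. Exact ties between
# the positive and negative extreme resolve to the positive one.
.es_from_positions <- function(pos, w_all, n) {
  if (is.matrix(pos)) {
    m <- nrow(pos); np <- ncol(pos)
    d <- 1 / (n - m)
    w <- matrix(w_all[pos], m, np)
    sw <- .colSums(w, m, np)
    zero <- sw == 0
    if (any(zero)) { w[, zero] <- 1; sw[zero] <- m }
    cw <- apply(w, 2L, cumsum)
    if (m == 1L) cw <- matrix(cw, 1L, np)
    swr <- rep(sw, each = m)
    a <- cw / swr - (pos - seq_len(m)) * d
    b <- a - w / swr
    es_pos <- pmax(apply(a, 2L, max), 0)
    es_neg <- pmin(apply(b, 2L, min), 0)
    ifelse(es_pos >= -es_neg, es_pos, es_neg)
  } else {
    m <- length(pos)
    d <- 1 / (n - m)
    w <- w_all[pos]
    sw <- sum(w)
    if (sw == 0) { w <- rep(1, m); sw <- m }
    a <- cumsum(w) / sw - (pos - seq_len(m)) * d
    b <- a - w / sw
    es_pos <- max(max(a), 0)
    es_neg <- min(min(b), 0)
    if (es_pos >= -es_neg) es_pos else es_neg
  }
}

# matched member indices per set after size filtering; returns list(kept =
# named list of index vectors, skipped = data.frame)
.match_library <- function(library, genes, params) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  if (!length(library$sets)) stop("gene set library is empty")
  kept <- list()
  skipped <- data.frame(term = character(), set_size = integer(),
                        matched_size = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  for (nm in names(library$sets)) {
    idx <- which(genes %in% library$sets[[nm]])
    ms <- length(idx)
    if (ms < params$min_set_size || ms > params$max_set_size ||
        ms == length(genes)) {
      reason <- if (ms < params$min_set_size) "below min_set_size"
                else if (ms > params$max_set_size) "above max_set_size"
                else "covers entire ranked list"
      skipped <- rbind(skipped,
                       data.frame(term = nm,
                                  set_size = length(library$sets[[nm]]),
                                  matched_size = ms, reason = reason,
                                  stringsAsFactors = FALSE))
    } else {
      kept[[nm]] <- idx
    }
  }
  if (!length(kept))
    stop("all gene sets were filtered out; adjust min_set_size/max_set_size ",
         "(current bounds ", params$min_set_size, "-", params$max_set_size,
         ")")
  list(kept = kept, skipped = skipped)
}

#' Permutation null distribution of enrichment scores
#'
#' `gene_set` mode reassigns each set's membership to a uniform random gene
#' subset of the same matched size against the fixed ranking; each set uses
#' an RNG stream derived from the root seed and a stable hash of its name,
#' so results do not depend on set order. `phenotype` mode shuffles sample
#' class labels (preserving class sizes), recomputes the ranking metric, and
#' rescores every set against the permuted ranking; one shared stream of
#' label permutations is drawn from the root seed before any set is scored.
#'
#' @param input A `RankedList` (gene_set mode) or an `ExpressionDataset`
#'   with two-class phenotypes (phenotype mode).
#' @param library A `GeneSetLibrary`.
#' @param params An [enrichment_params()].
#' @param spec A [metric_spec()], used in phenotype mode only.
#' @return An object of class `NullDistribution`: list with `per_set_es`
#'   (named list of length-`n_permutations` numeric vectors),
#'   `permutation_type`, and `seed`.
#' @export
build_null <- function(input, library, params = enrichment_params(),
                       spec = metric_spec()) {
  stopifnot(inherits(params, "EnrichmentParams"))
  .preserve_rng({
    if (params$permutation_type == "gene_set") {
      if (!inherits(input, "RankedList"))
        stop("gene_set permutation requires a RankedList input")
      genes <- input$gene
      n <- length(genes)
      w_all <- if (params$weight_exponent == 0) rep(1, n)
               else abs(input$score)^params$weight_exponent
      matched <- .match_library(library, genes, params)
      per_set <- lapply(names(matched$kept), function(nm) {
        m <- length(matched$kept[[nm]])
        set.seed(.derive_seed(params$seed, nm))
        pos <- vapply(seq_len(params$n_permutations),
                      function(j) sort.int(sample.int(n, m)),
                      integer(m))
        if (m == 1L) pos <- matrix(pos, 1L)
        .es_from_positions(pos, w_all, n)
      })
      names(per_set) <- names(matched$kept)
    } else {
      if (!inherits(input, "ExpressionDataset") ||
          is.null(input$phenotypes))
        stop("phenotype permutation requires an ExpressionDataset with ",
             "phenotypes")
      values <- input$values
      genes <- rownames(values)
      n <- length(genes)
      ph <- as.integer(input$phenotypes)
      matched <- .match_library(library, genes, params)
      set_names <- names(matched$kept)
      per_set <- lapply(set_names,
                        function(nm) numeric(params$n_permutations))
      names(per_set) <- set_names
      set.seed(params$seed)
      p <- params$weight_exponent
      for (j in seq_len(params$n_permutations)) {
        lab <- sample(ph)          # preserves the class-size multiset
        s <- .metric_scores(values, which(lab == 1L), which(lab == 2L), spec)
        ord <- order(-s, genes, method = "radix")
        pos_of <- integer(n)
        pos_of[ord] <- seq_len(n)
        w_sorted <- if (p == 0) rep(1, n) else abs(s[ord])^p
        for (nm in set_names) {
          pos <- sort.int(pos_of[matched$kept[[nm]]])
          per_set[[nm]][j] <- .es_from_positions(pos, w_sorted, n)
        }
      }
    }
    structure(list(per_set_es = per_set,
                   permutation_type = params$permutation_type,
                   seed = params$seed,
                   n_permutations = params$n_permutations),
              class = "NullDistribution")
  })
}

#' Empirical permutation p-value
#'
#' Compares an observed ES with the same-sign tail of its permutation null:
#' with `S` the null values sharing the sign of `es`,
#' `p = (1 + #\{x in S : |x| >= |es|\}) / (1 + |S|)` (add-one smoothing, so
#' p = 0 is never reported). `es = 0` returns 1 by convention, and an empty
#' same-sign null also yields 1 (with a warning).
#'
#' @param es Observed enrichment score.
#' @param null_vector Numeric vector of permutation null ES values.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(es, null_vector) {
  if (!length(null_vector)) stop("null_vector is empty")
  if (es == 0) return(1)
  s <- null_vector[sign(null_vector) == sign(es)]
  if (!length(s)) {
    warning("no same-sign null values (undefined-sign null); p = 1")
    return(1)
  }
  (1 + sum(abs(s) >= abs(es))) / (1 + length(s))
}

#' Normalized enrichment score
#'
#' `nes = es / mean(|x| : x in null, sign(x) == sign(es))`. Returns 0 for
#' `es = 0` and `NA` (with a warning) when no same-sign null values exist.
#'
#' @param es Observed enrichment score.
#' @param null_vector Numeric vector of permutation null ES values.
#' @return The NES (same sign as `es`), or `NA`.
#' @export
normalize_es <- function(es, null_vector) {
  if (!length(null_vector)) stop("null_vector is empty")
  if (es == 0) return(0)
  s <- null_vector[sign(null_vector) == sign(es)]
  if (!length(s)) {
    warning("no same-sign null values; NES undefined")
    return(NA_real_)
  }
  es / mean(abs(s))
}

# normalize a set's null ES values by that set's own same-sign null means
.normalize_null <- function(null_vector) {
  posm <- mean(null_vector[null_vector > 0])
  negm <- mean(abs(null_vector[null_vector < 0]))
  out <- numeric(length(null_vector))
  pos <- null_vector > 0
  neg <- null_vector < 0
  out[pos] <- null_vector[pos] / posm
  out[neg] <- null_vector[neg] / negm
  out
}

#' GSEA-style FDR q-values
#'
#' For a set with `NES* >= 0`,
#' `q = [fraction of pooled null NES >= NES*] / [fraction of observed NES >=
#' NES*]`, with both fractions taken within the same-sign (non-negative)
#' pools; negative NES use `<=` within the negative pools. Raw ratios are
#' clipped to \[0, 1\] and monotonicity is then enforced within each sign:
#' each set's q becomes the minimum raw q over itself and all less extreme
#' sets, so q never decreases as |NES| decreases.
#'
#' @param observed_nes Numeric vector of per-set NES (may contain NA).
#' @param null_nes Numeric vector of pooled normalized null ES values.
#' @return Numeric vector of q-values parallel to `observed_nes`.
#' @export
fdr_qvalues <- function(observed_nes, null_nes) {
  if (!length(observed_nes) || !length(null_nes))
    stop("observed and null NES vectors must be non-empty")
  q <- rep(NA_real_, length(observed_nes))
  ok <- !is.na(observed_nes)
  null_pos <- null_nes[null_nes >= 0]
  null_neg <- null_nes[null_nes < 0]
  obs <- observed_nes[ok]
  raw <- vapply(obs, function(x) {
    if (x >= 0) {
      num <- if (length(null_pos)) mean(null_pos >= x) else NA_real_
      den <- mean(obs[obs >= 0] >= x)  # includes x itself, so > 0
    } else {
      num <- if (length(null_neg)) mean(null_neg <= x) else NA_real_
      den <- mean(obs[obs < 0] <= x)
    }
    num / den
  }, numeric(1))
  raw <- pmin(pmax(raw, 0), 1)
  # monotone enforcement per sign: cummin walking inward from the least
  # extreme set toward the most extreme
  for (sgn in c(1, -1)) {
    grp <- if (sgn > 0) which(obs >= 0) else which(obs < 0)
    if (!length(grp)) next
    ord <- grp[order(sgn * obs[grp], decreasing = TRUE)]  # most extreme first
    tmp <- raw[ord]
    safe <- ifelse(is.na(tmp), Inf, tmp)  # NA q must not poison neighbours
    mono <- rev(cummin(rev(safe)))
    raw[ord] <- ifelse(is.na(tmp), NA_real_, pmin(tmp, mono))
  }
  q[ok] <- raw
  q
}

#' Leading-edge genes
#'
#' The member genes that appear in the ranked list at or before the peak of
#' the running sum when ES >= 0; for negative ES, at or after the peak (the
#' mirror convention).
#'
#' @param running A `RunningSum` from [running_enrichment()].
#' @param ranked The [ranked_list()] it was computed on.
#' @return Character vector of gene symbols in rank order.
#' @export
leading_edge <- function(running, ranked) {
  stopifnot(inherits(running, "RunningSum"), inherits(ranked, "RankedList"))
  hp <- running$hit_positions
  keep <- if (running$es >= 0) hp[hp <= running$peak_position]
          else hp[hp >= running$peak_position]
  ranked$gene[keep]
}

# shared tail of run_gsea / run_prerank: observed stats + null -> records
.finalize_records <- function(ranked, library, matched, null, params) {
  set_names <- names(matched$kept)
  running <- lapply(set_names, function(nm)
    running_enrichment(ranked, library$sets[[nm]], params$weight_exponent))
  names(running) <- set_names
  es <- vapply(running, `[[`, numeric(1), "es")
  nes <- vapply(set_names, function(nm)
    suppressWarnings(normalize_es(es[[nm]], null$per_set_es[[nm]])),
    numeric(1))
  pval <- vapply(set_names, function(nm)
    suppressWarnings(empirical_pvalue(es[[nm]], null$per_set_es[[nm]])),
    numeric(1))
  pooled <- unlist(lapply(null$per_set_es, .normalize_null),
                   use.names = FALSE)
  fdr <- fdr_qvalues(nes, pooled)
  le <- lapply(set_names, function(nm) leading_edge(running[[nm]], ranked))
  names(le) <- set_names
  res <- data.frame(
    term = set_names,
    es = unname(es),
    nes = unname(nes),
    pval = unname(pval),
    fdr = unname(fdr),
    matched_size = unname(lengths(matched$kept)),
    set_size = unname(lengths(library$sets[set_names])),
    leading_edge = vapply(le, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  ord <- order(res$pval, -abs(res$nes), res$term, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res,
                 skipped = matched$skipped,
                 running = running,
                 leading_edge_genes = le,
                 null = null,
                 params = params),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult:", nrow(x$results), "sets scored,",
      nrow(x$skipped), "skipped;", x$params$n_permutations,
      x$params$permutation_type, "permutations\n")
  print(utils::head(x$results[, c("term", "es", "nes", "pval", "fdr",
                                  "matched_size")], 10L))
  invisible(x)
}

#' Pre-ranked GSEA
#'
#' Runs the running-sum statistic for every library set against a
#' pre-ranked gene list, builds a gene-permutation null, and reports ES,
#' NES, empirical p-values, GSEA-style FDR q-values and leading-edge genes.
#' Sets whose matched size falls outside \[min_set_size, max_set_size\] are
#' excluded and listed in the `skipped` element. Identical seeds give
#' identical output.
#'
#' @param ranked A [ranked_list()].
#' @param library A [gene_set_library()].
#' @param params An [enrichment_params()]; `permutation_type` is forced to
#'   `"gene_set"`.
#' @return An `EnrichmentResult` (see [build_null()] and
#'   [fdr_qvalues()] for the component statistics).
#' @export
run_prerank <- function(ranked, library, params = enrichment_params()) {
  stopifnot(inherits(ranked, "RankedList"))
  params$permutation_type <- "gene_set"
  matched <- .match_library(library, ranked$gene, params)
  null <- build_null(ranked, library, params)
  .finalize_records(ranked, library, matched, null, params)
}

#' Two-class GSEA with phenotype or gene-set permutation
#'
#' Ranks the genes of a two-class expression dataset with the chosen
#' differential metric, scores every library set, and calibrates against a
#' permutation null. With `permutation_type = "phenotype"` (the default
#' here) sample labels are shuffled and the ranking metric is recomputed in
#' every permutation; with `"gene_set"` the observed ranking is kept fixed
#' and random gene subsets are scored.
#'
#' @param dataset An [expression_dataset()]; must carry two-class
#'   phenotypes (or supply `phenotypes`).
#' @param library A [gene_set_library()].
#' @param params An [enrichment_params()].
#' @param spec A [metric_spec()] selecting the ranking metric.
#' @param phenotypes Optional phenotype vector/factor overriding the one in
#'   `dataset`.
#' @return An `EnrichmentResult`.
#' @export
run_gsea <- function(dataset, library,
                     params = enrichment_params(permutation_type = "phenotype"),
                     spec = metric_spec(), phenotypes = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!is.null(phenotypes))
    dataset <- expression_dataset(dataset$values, phenotypes)
  if (is.null(dataset$phenotypes))
    stop("run_gsea requires two-class phenotypes")
  ranked <- score_genes(dataset, spec)
  matched <- .match_library(library, ranked$gene, params)
  null <- if (params$permutation_type == "phenotype")
    build_null(dataset, library, params, spec)
  else
    build_null(ranked, library, params)
  .finalize_records(ranked, library, matched, null, params)
}

#' Write an enrichment report as TSV
#'
#' Columns: Term, ES, NES, p-val, FDR q-val, matched_size, set_size,
#' leading_edge (comma-joined).
#'
#' @param result An `EnrichmentResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(result, path) {
  stopifnot(inherits(result, "EnrichmentResult"))
  out <- result$results
  names(out) <- c("Term", "ES", "NES", "p-val", "FDR q-val", "matched_size",
                  "set_size", "leading_edge")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a running-sum curve as TSV
#'
#' One row per ranked-list position with columns `position`, `gene`,
#' `score`, `hit`, `curve`, for external plotting of the enrichment curve.
#'
#' @param result An `EnrichmentResult`.
#' @param term Name of the gene set whose curve to export.
#' @param ranked The [ranked_list()] the result was computed on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(result, term, ranked, path) {
  stopifnot(inherits(result, "EnrichmentResult"))
  rs <- result$running[[term]]
  if (is.null(rs)) stop("no running sum stored for term: ", term)
  out <- data.frame(position = seq_along(rs$curve),
                    gene = ranked$gene,
                    score = ranked$score,
                    hit = as.integer(seq_along(rs$curve) %in%
                                       rs$hit_positions),
                    curve = rs$curve)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
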