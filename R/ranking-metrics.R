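#' Differential ranking metric specification
#'
#' Chooses the per-gene class-separation metric used to rank genes before the
#' running-sum statistic (and inside every phenotype permutation).
#'
#' Formulas (class A = first phenotype level, class B = second):
#' * `signal_to_noise`: (meanA - meanB) / (sdA + sdB), each sd floored at
#'   `sd_floor_fraction * |class mean|` and at an absolute floor of 1e-8.
#' * `t_test`: (meanA - meanB) / sqrt(sdA^2/nA + sdB^2/nB), sds floored at
#'   1e-8 only.
#' * `log2_ratio_of_classes`: log2(meanA / meanB); both class means must be
#'   strictly positive.
#' * `difference_of_classes`: meanA - meanB.
#'
#' @param name One of `"signal_to_noise"` (default), `"t_test"`,
#'   `"log2_ratio_of_classes"`, `"difference_of_classes"`.
#' @param sd_floor_fraction Relative sd floor for `signal_to_noise`
#'   (default 0.2).
#' @return An object of class `MetricSpec`.
#' @export
metric_spec <- function(name = c("signal_to_noise", "t_test",
                                 "log2_ratio_of_classes",
                                 "difference_of_classes"),
                        sd_floor_fraction = 0.2) {
  name <- match.arg(name)
  stopifnot(is.numeric(sd_floor_fraction), length(sd_floor_fraction) == 1L,
            is.finite(sd_floor_fraction), sd_floor_fraction >= 0)
  structure(list(name = name, sd_floor_fraction = sd_floor_fraction),
            class = "MetricSpec")
}

# row means and sample sds of a matrix restricted to given columns
.row_stats <- function(m, cols) {
  x <- m[, cols, drop = FALSE]
  n <- ncol(x)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (n - 1))
  list(mean = mu, sd = sd, n = n)
}

# metric scores for an explicit column split; used directly by the
# phenotype-permutation null so no RankedList objects are built per permutation
.metric_scores <- function(values, cols_a, cols_b, spec) {
  a <- .row_stats(values, cols_a)
  b <- .row_stats(values, cols_b)
  switch(spec$name,
    signal_to_noise = {
      sda <- pmax(a$sd, spec$sd_floor_fraction * abs(a$mean), 1e-8)
      sdb <- pmax(b$sd, spec$sd_floor_fraction * abs(b$mean), 1e-8)
      (a$mean - b$mean) / (sda + sdb)
    },
    t_test = {
      sda <- pmax(a$sd, 1e-8)
      sdb <- pmax(b$sd, 1e-8)
      (a$mean - b$mean) / sqrt(sda^2 / a$n + sdb^2 / b$n)
    },
    log2_ratio_of_classes = {
      if (any(a$mean <= 0) || any(b$mean <= 0))
        stop("log2_ratio_of_classes requires strictly positive class means")
      log2(a$mean / b$mean)
    },
    difference_of_classes = a$mean - b$mean
  )
}

#' Rank genes of a two-class expression dataset
#'
#' Computes one differential score per gene (see [metric_spec()] for the
#' formulas) and returns the genes sorted descending by score, ties broken by
#' ascending gene symbol. Class A is the first phenotype level (the
#' first-named class of a CLS header).
#'
#' @param dataset An [expression_dataset()] with phenotypes.
#' @param spec A [metric_spec()]; default signal-to-noise.
#' @return A [ranked_list()].
#' @export
score_genes <- function(dataset, spec = metric_spec()) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(spec, "MetricSpec"))
  if (is.null(dataset$phenotypes))
    stop("score_genes requires a dataset with phenotypes")
  ph <- dataset$phenotypes
  cols_a <- which(ph == levels(ph)[1L])
  cols_b <- which(ph == levels(ph)[2L])
  need <- if (spec$name == "t_test") 3L else 2L
  if (length(cols_a) < need || length(cols_b) < need)
    stop("metric '", spec$name, "' needs >= ", need, " samples per class")
  s <- .metric_scores(dataset$values, cols_a, cols_b, spec)
  ranked_list(rownames(dataset$values), s)
}
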