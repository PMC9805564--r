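#' Specification for planted-signal synthetic data
#'
#' Describes a gene universe, a random gene set library, and the planted
#' differential signal used by [make_library()], [make_expression()] and
#' [make_ranked()]. All generators are pure functions of the spec and its
#' seed.
#'
#' @param universe_size Number of genes in the universe (default 5000).
#' @param n_sets Number of gene sets in the library (default 50).
#' @param set_size_range Length-2 integer vector `(lo, hi)`: set sizes are
#'   drawn uniformly in this range (default `c(15, 50)`).
#' @param planted_sets Names of the sets carrying planted signal (default
#'   the first set, `"SET001"`); must exist in the generated library.
#' @param effect_size Mean shift of planted genes, in units of `noise_sd`
#'   (default 1).
#' @param n_samples_per_class Samples per phenotype class for
#'   [make_expression()] (default 10).
#' @param noise_sd Standard deviation of the background noise (default 1).
#' @param seed Integer root seed (default 42).
#' @return An object of class `PlantSpec`.
#' @export
plant_spec <- function(universe_size = 5000L, n_sets = 50L,
                       set_size_range = c(15L, 50L),
                       planted_sets = "SET001",
                       effect_size = 1, n_samples_per_class = 10L,
                       noise_sd = 1, seed = 42L) {
  universe_size <- as.integer(universe_size)
  n_sets <- as.integer(n_sets)
  set_size_range <- as.integer(set_size_range)
  stopifnot(universe_size >= 1L, n_sets >= 0L,
            length(set_size_range) == 2L,
            set_size_range[1L] <= set_size_range[2L],
            effect_size >= 0, noise_sd > 0,
            n_samples_per_class >= 2L)
  if (set_size_range[1L] < 1L || set_size_range[2L] > universe_size)
    stop("set_size_range must lie within [1, universe_size]")
  structure(list(universe_size = universe_size, n_sets = n_sets,
                 set_size_range = set_size_range,
                 planted_sets = as.character(planted_sets),
                 effect_size = as.numeric(effect_size),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "PlantSpec")
}

.universe_genes <- function(spec) {
  sprintf("G%05d", seq_len(spec$universe_size))
}

.set_names <- function(spec) {
  sprintf("SET%03d", seq_len(spec$n_sets))
}

#' Generate a random gene set library
#'
#' `n_sets` sets, each a without-replacement sample from the universe with
#' size drawn uniformly in `set_size_range`. Deterministic under the spec
#' seed. Planted and non-planted sets may overlap by chance, as in real
#' libraries.
#'
#' @param spec A [plant_spec()].
#' @return A [gene_set_library()] (empty when `n_sets = 0`).
#' @export
make_library <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  genes <- .universe_genes(spec)
  if (spec$n_sets == 0L)
    return(structure(list(sets = list(),
                          descriptions = character()),
                     class = "GeneSetLibrary"))
  .preserve_rng({
    set.seed(spec$seed)
    lo <- spec$set_size_range[1L]
    hi <- spec$set_size_range[2L]
    sizes <- lo + sample.int(hi - lo + 1L, spec$n_sets, replace = TRUE) - 1L
    sets <- lapply(sizes, function(m) sort(sample(genes, m)))
    names(sets) <- .set_names(spec)
    gene_set_library(sets)
  })
}

#' Generate a two-class expression matrix with planted enriched sets
#'
#' Background values are i.i.d. Normal(0, `noise_sd`^2); genes belonging to
#' any planted set are shifted by `+effect_size * noise_sd` in class A
#' samples only. Two classes (`A`, `B`) of `n_samples_per_class` each.
#'
#' @param spec A [plant_spec()].
#' @param library The [make_library()] output for the same spec (supplies
#'   the planted gene memberships).
#' @return An [expression_dataset()] with phenotypes attached.
#' @export
make_expression <- function(spec, library) {
  stopifnot(inherits(spec, "PlantSpec"), inherits(library, "GeneSetLibrary"))
  miss <- setdiff(spec$planted_sets, names(library$sets))
  if (length(miss))
    stop("planted set(s) not in library: ", paste(miss, collapse = ", "))
  genes <- .universe_genes(spec)
  ns <- 2L * spec$n_samples_per_class
  samples <- sprintf("S%03d", seq_len(ns))
  planted_genes <- unique(unlist(library$sets[spec$planted_sets],
                                 use.names = FALSE))
  .preserve_rng({
    set.seed(spec$seed + 1L)
    m <- matrix(stats::rnorm(length(genes) * ns, sd = spec$noise_sd),
                length(genes), ns, dimnames = list(genes, samples))
    cls_a <- seq_len(spec$n_samples_per_class)
    m[planted_genes, cls_a] <- m[planted_genes, cls_a] +
      spec$effect_size * spec$noise_sd
    ph <- rep(c("A", "B"), each = spec$n_samples_per_class)
    expression_dataset(m, ph)
  })
}

#' Generate a pre-ranked list with planted signal
#'
#' Scores are i.i.d. standard normal with genes of the planted sets shifted
#' by `+effect_size`; the result is sorted descending as every
#' [ranked_list()].
#'
#' @param spec A [plant_spec()].
#' @param library The [make_library()] output for the same spec.
#' @return A [ranked_list()] over the whole universe.
#' @export
make_ranked <- function(spec, library) {
  stopifnot(inherits(spec, "PlantSpec"), inherits(library, "GeneSetLibrary"))
  miss <- setdiff(spec$planted_sets, names(library$sets))
  if (length(miss))
    stop("planted set(s) not in library: ", paste(miss, collapse = ", "))
  genes <- .universe_genes(spec)
  planted_genes <- unique(unlist(library$sets[spec$planted_sets],
                                 use.names = FALSE))
  .preserve_rng({
    set.seed(spec$seed + 2L)
    s <- stats::rnorm(length(genes))
    names(s) <- genes
    s[planted_genes] <- s[planted_genes] + spec$effect_size
    ranked_list(genes, s)
  })
}

#' Write a full synthetic fixture to disk
#'
#' Emits a GMT library, a GCT expression matrix, a CLS phenotype file and a
#' RNK ranked list for the given spec, so command-line round trips are
#' testable end to end.
#'
#' @param spec A [plant_spec()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_synthetic_fixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lib <- make_library(spec)
  expr <- make_expression(spec, lib)
  rnk <- make_ranked(spec, lib)
  paths <- c(gmt = file.path(dir, "library.gmt"),
             gct = file.path(dir, "expression.gct"),
             cls = file.path(dir, "phenotypes.cls"),
             rnk = file.path(dir, "ranked.rnk"))
  write_gmt(lib, paths[["gmt"]])
  write_gct(expr, paths[["gct"]])
  write_cls(expr$phenotypes, paths[["cls"]])
  write_rnk(rnk, paths[["rnk"]])
  invisible(paths)
}
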