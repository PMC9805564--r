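#' Gene set library
#'
#' A named, ordered collection of gene sets, the container produced by
#' [read_gmt()] and by [make_library()]. Gene symbols are upper-cased on
#' construction so that matching against ranked lists and expression matrices
#' is case-insensitive (Enrichr-style libraries are upper-case).
#'
#' @param sets Named list of character vectors (members per set). Names must
#'   be unique; each member vector is de-duplicated keeping first occurrence.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; missing entries default to `"na"` (the common GMT
#'   convention for an empty description).
#' @return An object of class `GeneSetLibrary`: a list with elements `sets`
#'   (named list of upper-cased, unique gene symbols) and `descriptions`
#'   (named character, parallel to `sets`).
#' @export
gene_set_library <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L)
    return(structure(list(sets = structure(list(), names = character()),
                          descriptions = character()),
                     class = "GeneSetLibrary"))
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L])
  sets <- lapply(sets, function(g) {
    g <- toupper(as.character(g))
    g[!duplicated(g)]
  })
  if (any(lengths(sets) == 0L))
    stop("gene sets must be non-empty")
  desc <- rep("na", length(sets))
  names(desc) <- names(sets)
  if (!is.null(descriptions)) {
    hit <- intersect(names(descriptions), names(sets))
    desc[hit] <- ifelse(is.na(descriptions[hit]) | descriptions[hit] == "",
                        "na", descriptions[hit])
  }
  structure(list(sets = sets, descriptions = desc), class = "GeneSetLibrary")
}

#' @export
print.GeneSetLibrary <- function(x, ...) {
  cat("GeneSetLibrary with", length(x$sets), "sets\n")
  n <- min(5L, length(x$sets))
  for (i in seq_len(n))
    cat("  ", names(x$sets)[i], ": ", length(x$sets[[i]]), " genes\n", sep = "")
  if (length(x$sets) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.GeneSetLibrary <- function(x) length(x$sets)

#' Ranked gene list
#'
#' An ordered list of unique gene symbols with real-valued ranking scores,
#' sorted in non-increasing score order. Ties are broken by ascending
#' lexicographic gene symbol so the order is unique for any input.
#'
#' @param genes Character vector of gene symbols (upper-cased on
#'   construction; duplicates are an error).
#' @param scores Numeric vector of finite ranking scores, parallel to
#'   `genes`.
#' @return A data frame of class `RankedList` with columns `gene` and
#'   `score`, sorted descending by score.
#' @export
ranked_list <- function(genes, scores) {
  genes <- toupper(as.character(genes))
  scores <- as.numeric(scores)
  if (length(genes) != length(scores))
    stop("genes and scores must have equal length")
  if (anyDuplicated(genes))
    stop("duplicate gene symbol in ranked list: ",
         genes[duplicated(genes)][1L])
  if (any(!is.finite(scores)))
    stop("ranking scores must be finite")
  ord <- order(-scores, genes, method = "radix")
  structure(data.frame(gene = genes[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedList", "data.frame"))
}

#' Expression dataset
#'
#' A genes-by-samples real matrix with optional two-class sample phenotypes.
#'
#' @param values Numeric matrix, rows = genes (rownames required, unique
#'   after upper-casing), columns = samples (colnames required, unique).
#' @param phenotypes Optional character/factor vector of class labels, either
#'   named by sample id or parallel to the columns of `values`. Exactly two
#'   distinct classes, each with at least two samples. Class order follows
#'   first appearance (class A = first-seen label, as in a CLS header).
#' @return An object of class `ExpressionDataset`: list with elements
#'   `values` (matrix) and `phenotypes` (factor or NULL, levels in
#'   first-appearance order).
#' @export
expression_dataset <- function(values, phenotypes = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (!is.numeric(values) || anyNA(values))
    stop("expression values must be numeric with no missing values")
  ph <- NULL
  if (!is.null(phenotypes)) {
    lab <- as.character(phenotypes)
    if (!is.null(names(phenotypes))) {
      miss <- setdiff(colnames(values), names(phenotypes))
      if (length(miss))
        stop("phenotype missing for sample(s): ", paste(miss, collapse = ", "))
      lab <- as.character(phenotypes[colnames(values)])
    } else if (length(lab) != ncol(values)) {
      stop("phenotypes must be named by sample or match the sample count")
    }
    # honour an explicit factor level order (e.g. the CLS header order);
    # otherwise classes are taken in first-appearance order
    cls <- if (is.factor(phenotypes)) intersect(levels(phenotypes), lab)
           else unique(lab)
    if (length(cls) != 2L)
      stop("exactly 2 phenotype classes required, found ", length(cls))
    if (any(table(lab) < 2L))
      stop("each phenotype class needs >= 2 samples")
    ph <- factor(lab, levels = cls)
    names(ph) <- colnames(values)
  }
  structure(list(values = values, phenotypes = ph),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$phenotypes)) {
    tab <- table(x$phenotypes)
    cat("  phenotypes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

# split text into lines accepting Unix and Windows newlines
.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gsub("\r$", "", readLines(path, warn = FALSE))
}

#' Read a GMT gene set library
#'
#' Each non-blank line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' File order of sets and members is preserved; duplicate genes within a
#' line are dropped keeping the first occurrence; duplicate set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_library()] object.
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[!(seq_along(f) > 2L & f == "")]  # drop trailing empty gene fields
    if (length(f) < 3L)
      stop("malformed GMT line ", lineno[i], ": fewer than 3 fields")
    if (f[1L] %in% names(sets))
      stop("duplicate set name in GMT: ", f[1L])
    sets[[f[1L]]] <- f[-(1:2)]
    desc[f[1L]] <- f[2L]
  }
  gene_set_library(sets, desc)
}

#' Write a GMT gene set library
#'
#' Empty descriptions are written as `"na"`. `read_gmt(write_gmt(x))` is the
#' identity on any valid library, preserving set and member order.
#'
#' @param library A `GeneSetLibrary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  desc <- library$descriptions
  desc[is.na(desc) | desc == ""] <- "na"
  lines <- vapply(names(library$sets), function(nm) {
    paste(c(nm, desc[[nm]], library$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a RNK pre-ranked gene list
#'
#' Two tab-separated columns `gene<TAB>score`. The result is sorted
#' descending by score regardless of file order; duplicate genes and
#' unparseable scores are errors.
#'
#' @param path Path to a RNK file.
#' @return A [ranked_list()].
#' @export
read_rnk <- function(path) {
  lines <- .read_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("RNK file has no data lines: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed RNK line ", lineno[bad[1L]], ": expected gene<TAB>score")
  genes <- vapply(parts, `[`, character(1), 1L)
  raw <- vapply(parts, `[`, character(1), 2L)
  scores <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(scores))
  if (length(bad))
    stop("unparseable score on RNK line ", lineno[bad[1L]], ": '",
         raw[bad[1L]], "'")
  ranked_list(genes, scores)
}

#' Write a RNK file
#' @param ranked A `RankedList`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "RankedList"))
  writeLines(paste(ranked$gene,
                   format(ranked$score, trim = TRUE, digits = 15,
                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a two-class CLS phenotype file
#'
#' Three-line dialect: line 1 `N 2 1`; line 2 `# nameA nameB`; line 3 the N
#' space-separated labels. Labels may be the class names themselves or
#' `0`/`1` tokens, which are mapped to the line-2 names by first-appearance
#' order. Exactly two classes with at least two samples each are required.
#'
#' @param path Path to a CLS file.
#' @return A factor of length N with levels in header order (class A =
#'   first-named class of line 2).
#' @export
read_cls <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file must have 3 lines")
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(hdr) < 2L) stop("malformed CLS header line")
  n <- as.integer(hdr[1L]); ncls <- as.integer(hdr[2L])
  if (is.na(n) || is.na(ncls)) stop("malformed CLS header line")
  if (ncls != 2L) stop("CLS must declare exactly 2 classes, found ", ncls)
  l2 <- strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]
  if (l2[1L] != "#") stop("CLS line 2 must start with '#'")
  cls_names <- l2[-1L]
  if (length(cls_names) != 2L)
    stop("CLS line 2 must name exactly 2 classes")
  lab <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
  if (length(lab) != n)
    stop("CLS declares ", n, " samples but line 3 has ", length(lab))
  uniq <- unique(lab)
  if (all(uniq %in% c("0", "1"))) {
    # numeric tokens: map to class names by first-appearance order
    lab <- cls_names[match(lab, uniq)]
  }
  if (!all(lab %in% cls_names))
    stop("CLS label(s) not among declared classes: ",
         paste(setdiff(unique(lab), cls_names), collapse = ", "))
  found <- unique(lab)
  if (length(found) != 2L)
    stop("CLS must contain exactly 2 classes, found ", length(found))
  if (any(table(lab) < 2L))
    stop("each CLS class needs >= 2 samples")
  # class A is the first-named class of the header line
  factor(lab, levels = cls_names)
}

#' Write a two-class CLS phenotype file
#' @param phenotypes Factor or character vector of class labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(phenotypes, path) {
  lab <- as.character(phenotypes)
  cls <- unique(lab)
  if (length(cls) != 2L) stop("CLS output requires exactly 2 classes")
  writeLines(c(paste(length(lab), 2, 1),
               paste("#", cls[1L], cls[2L]),
               paste(lab, collapse = " ")), path)
  invisible(path)
}

#' Read an expression matrix (GCT v1.2 or plain TSV)
#'
#' GCT dialect: line 1 `#1.2`, line 2 `n_genes n_samples`, then a header row
#' `Name<TAB>Description<TAB>samples...` and one row per gene. TSV dialect: a
#' header row of sample ids and gene ids in the first column. Duplicate gene
#' rows are collapsed by keeping the row with the highest mean value (the
#' GSEA-desktop convention, deterministic). Missing-value tokens (``""``,
#' `NA`, `NaN`) are rejected unless `drop_na_genes = TRUE`, which drops any
#' gene row containing one.
#'
#' @param path Path to the file.
#' @param format `"gct"`, `"tsv"`, or `"auto"` (by extension, default).
#' @param phenotypes Optional phenotypes passed to [expression_dataset()].
#' @param drop_na_genes Drop gene rows containing NA tokens instead of
#'   erroring. Default FALSE.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv"),
                            phenotypes = NULL, drop_na_genes = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  lines <- .read_lines(path)
  if (format == "gct") {
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
      stop("not a GCT v1.2 file (missing '#1.2' header): ", path)
    dims <- as.integer(strsplit(trimws(lines[2L]), "[ \t]+")[[1L]])
    if (length(dims) < 2L || anyNA(dims))
      stop("malformed GCT dimension line")
    body <- lines[-(1:2)]
    header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-(1:2)]
    rows <- body[-1L]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) != dims[1L])
      stop("GCT declares ", dims[1L], " genes but body has ", length(rows),
           " rows")
    if (length(samples) != dims[2L])
      stop("GCT declares ", dims[2L], " samples but header has ",
           length(samples))
    parts <- strsplit(rows, "\t", fixed = TRUE)
    genes <- vapply(parts, `[`, character(1), 1L)
    cells <- lapply(parts, function(p) p[-(1:2)])
  } else {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("expression TSV needs a header and data")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-1L]
    # tolerate a header that also labels the gene-id column
    if (length(samples) == 0L) stop("expression TSV header has no samples")
    parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
    genes <- vapply(parts, `[`, character(1), 1L)
    cells <- lapply(parts, function(p) p[-1L])
  }
  bad <- which(lengths(cells) != length(samples))
  if (length(bad))
    stop("expression row ", bad[1L], " has ", lengths(cells)[bad[1L]],
         " values, expected ", length(samples))
  flat <- unlist(cells, use.names = FALSE)
  na_tok <- flat %in% c("", "NA", "NaN", "na", "nan")
  vals <- suppressWarnings(as.numeric(flat))
  if (any(is.na(vals) & !na_tok))
    stop("non-numeric expression cell: '", flat[is.na(vals) & !na_tok][1L],
         "'")
  mat <- matrix(vals, nrow = length(genes), byrow = TRUE,
                dimnames = list(toupper(genes), samples))
  if (anyNA(mat)) {
    if (!drop_na_genes)
      stop("missing values in expression input (use drop_na_genes = TRUE ",
           "to drop affected genes)")
    keep <- rowSums(is.na(mat)) == 0L
    mat <- mat[keep, , drop = FALSE]
    if (!nrow(mat)) stop("all gene rows dropped by NA policy")
  }
  if (anyDuplicated(rownames(mat))) {
    # keep the duplicate row with the highest mean
    means <- rowMeans(mat)
    ord <- order(-means)
    mat <- mat[ord, , drop = FALSE][!duplicated(rownames(mat)[ord]), ,
                                    drop = FALSE]
    mat <- mat[order(match(rownames(mat), toupper(genes))), , drop = FALSE]
  }
  expression_dataset(mat, phenotypes)
}

#' Write an expression dataset as GCT v1.2
#' @param dataset An `ExpressionDataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  m <- dataset$values
  header <- paste(c("Name", "Description", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], "na",
            format(m[i, ], trim = TRUE, digits = 15, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c("#1.2", paste(nrow(m), ncol(m)), header, rows), path)
  invisible(path)
}

#' Read a plain-text query gene list (one symbol per line)
#' @param path Path to the file.
#' @return Character vector of upper-cased, unique gene symbols.
#' @export
read_gene_list <- function(path) {
  g <- trimws(.read_lines(path))
  g <- toupper(g[nzchar(g) & !startsWith(g, "#")])
  if (!length(g)) stop("gene list file is empty: ", path)
  unique(g)
}
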