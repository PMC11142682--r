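# Abundance tables are stored as leaves x samples matrices aligned to the
# tree's leaf order, with every column normalized to sum to one (each
# sample a probability mass function on the leaves).

#' Align an abundance table to a phylogeny and normalize it
#'
#' Features are matched to tree leaves by name; the result is a
#' leaves-by-samples matrix in the tree's leaf order with compositional
#' columns. Tables supplied as samples-by-features are transposed
#' automatically when their column names (but not their row names) match
#' the tip labels.
#'
#' @param x a numeric matrix or data frame of non-negative abundances with
#'   feature identifiers as row (or column) names.
#' @param tree a `haar_phylo` object.
#' @param drop_unmatched drop features absent from the tree (with a
#'   warning) instead of raising an error.
#' @param normalize divide each column by its sum (default). Columns
#'   summing to zero are rejected.
#' @return a numeric matrix with `tree$n_tip` rows (tree leaves absent from
#'   the table get abundance 0) and one column per sample.
#' @export
align_abundance <- function(x, tree, drop_unmatched = FALSE, normalize = TRUE) {
  stopifnot(inherits(tree, "haar_phylo"))
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("abundance table must be numeric")
  tips <- tree$tip_label
  rn <- rownames(x)
  cn <- colnames(x)
  row_hits <- if (is.null(rn)) 0L else sum(rn %in% tips)
  col_hits <- if (is.null(cn)) 0L else sum(cn %in% tips)
  if (row_hits == 0L && col_hits == 0L) {
    if (nrow(x) == tree$n_tip && is.null(rn)) {
      rownames(x) <- tips  # assume tree leaf order
    } else {
      stop("no feature identifiers match the tree's tip labels")
    }
  } else if (col_hits > row_hits) {
    x <- t(x)
  }
  if (any(x < 0)) stop("abundances must be non-negative")
  unmatched <- setdiff(rownames(x), tips)
  if (length(unmatched) > 0L) {
    if (!drop_unmatched)
      stop(length(unmatched), " feature(s) absent from the tree ",
           "(set drop_unmatched = TRUE to drop them): ",
           paste(utils::head(unmatched, 5L), collapse = ", "))
    warning("dropping ", length(unmatched), " feature(s) absent from the tree")
    x <- x[rownames(x) %in% tips, , drop = FALSE]
  }
  out <- matrix(0, tree$n_tip, ncol(x),
                dimnames = list(tips, colnames(x)))
  out[rownames(x), ] <- x
  if (normalize) {
    cs <- colSums(out)
    if (any(cs <= 0))
      stop("sample(s) with zero total abundance: ",
           paste(utils::head(which(cs <= 0), 5L), collapse = ", "))
    out <- sweep(out, 2L, cs, "/")
  }
  out
}

#' Read an abundance table from TSV or BIOM
#'
#' TSV tables may be features-by-samples or samples-by-features (detected
#' by matching identifiers against the tree when one is given). BIOM files
#' are read through the biomformat package.
#'
#' @param path path to a `.tsv`/`.txt` table (first column = identifiers)
#'   or a `.biom` file.
#' @param tree optional `haar_phylo`; when given the table is passed
#'   through [align_abundance()].
#' @param ... forwarded to [align_abundance()].
#' @return a numeric matrix; leaves-by-samples and compositional when
#'   `tree` is given.
#' @export
read_abundance <- function(path, tree = NULL, ...) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    x <- as(biomformat::biom_data(biomformat::read_biom(path)), "matrix")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1L, check.names = FALSE,
                            comment.char = "")
    x <- as.matrix(df)
  }
  if (is.null(tree)) return(x)
  align_abundance(x, tree, ...)
}
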