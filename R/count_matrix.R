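#' Cells-by-features count matrix
#'
#' Lightweight container for one feature class of a CITE-seq style experiment:
#' antibody-derived tags (`"ADT"`), targeted transcripts (`"RNA"`) or sample
#' tags (`"TAG"`). Rows are cells, columns are features; counts are
#' non-negative integers stored as a sparse `dgCMatrix`.
#'
#' @param counts a matrix or Matrix of non-negative integer counts, cells in
#'   rows, with both dimnames set.
#' @param feature_class one of `"ADT"`, `"RNA"`, `"TAG"`.
#' @return a `count_matrix`: a list with elements `counts` (dgCMatrix) and
#'   `feature_class`.
#' @export
count_matrix <- function(counts, feature_class = c("ADT", "RNA", "TAG")) {
  feature_class <- match.arg(feature_class)
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty count matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs cell ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids")
  if (length(m@x)) {
    if (anyNA(m@x)) stop("counts contain NA")
    if (any(m@x < 0)) {
      bad <- arrayInd(which(as.matrix(m) < 0)[1L], dim(m))
      stop(sprintf("negative count at cell '%s', feature '%s'",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    if (any(m@x != round(m@x))) {
      bad <- arrayInd(which(as.matrix(m) != round(as.matrix(m)))[1L], dim(m))
      stop(sprintf("non-integer count at cell '%s', feature '%s'",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
  }
  structure(list(counts = m, feature_class = feature_class),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %s> %d cells x %d features, %.1f%% nonzero\n",
              x$feature_class, nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Cell ids of a count matrix
#' @param x a `count_matrix`.
#' @return character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Feature ids of a count matrix
#' @param x a `count_matrix`.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(x) colnames(x$counts)

#' Subset a count matrix to a set of cells
#' @param x a `count_matrix`.
#' @param cells cell ids (or logical/integer row index).
#' @return a `count_matrix` over the selected cells.
#' @export
subset_cells <- function(x, cells) {
  x$counts <- x$counts[cells, , drop = FALSE]
  x
}
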