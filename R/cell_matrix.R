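#' Cells-by-genes expression container
#'
#' A light container tying an expression matrix (cells in rows, genes in
#' columns; sparse `Matrix` or base matrix) to per-cell metadata. Counts and
#' normalized values share the class; `normalized` records which one is held.
#'
#' @param x Numeric matrix, cells x genes, with row and column names.
#' @param cells Data frame of per-cell metadata with a `cell_id` column
#'   matching `rownames(x)`; defaults to the bare ids.
#' @param normalized Logical flag: values are depth-normalized log1p rather
#'   than raw counts.
#' @return An object of class `cell_matrix` with elements `x`, `cells`,
#'   `genes`, `normalized`.
#' @export
cell_matrix <- function(x, cells = NULL, normalized = FALSE) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("'x' must have cell rownames and gene colnames", call. = FALSE)
  if (is.null(cells))
    cells <- data.frame(cell_id = rownames(x), stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cells) ||
      !identical(as.character(cells$cell_id), rownames(x)))
    stop("'cells$cell_id' must match rownames(x) in order", call. = FALSE)
  structure(list(x = x, cells = cells, genes = colnames(x),
                 normalized = isTRUE(normalized)),
            class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$x)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes (%s)\n",
              nrow(x$x), ncol(x$x),
              if (x$normalized) "normalized log1p" else "counts"))
  invisible(x)
}

# Dense numeric matrix view (cells x genes).
dense_values <- function(cm) {
  stopifnot(inherits(cm, "cell_matrix"))
  as.matrix(cm$x)
}
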