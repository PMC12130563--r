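#' Write a single-cell dataset as an MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells, the 10x convention), `barcodes.tsv`,
#' `features.tsv`, and `cells.csv` (per-cell metadata) into `dir`.
#'
#' @param cm A [cell_matrix()] of counts.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_sc_dataset <- function(cm, dir) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(cm$x), sparse = TRUE)     # genes x cells on disk
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$x), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cm$x), file.path(dir, "features.tsv"))
  utils::write.csv(cm$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                             "cells.csv")))
}

#' Read a single-cell dataset from an MTX triplet
#'
#' Expects the layout written by [write_sc_dataset()]: a genes x cells
#' MatrixMarket file plus barcode and feature line files, optionally
#' `cells.csv` metadata. The matrix is transposed to the internal cells x
#' genes orientation.
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, and optionally `cells.csv`.
#' @return A [cell_matrix()] of counts.
#' @export
read_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    if (file.size(p) == 0) stop("empty file: ", p, call. = FALSE)
  }
  m <- tryCatch(Matrix::readMM(paths[1]), error = function(e)
    stop("cannot parse ", paths[1], ": ", conditionMessage(e),
         call. = FALSE))
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
         length(barcodes), " barcodes", call. = FALSE)
  if (nrow(m) != length(features))
    stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
         length(features), " features", call. = FALSE)
  x <- t(as.matrix(m))
  dimnames(x) <- list(barcodes, features)
  meta_path <- file.path(dir, "cells.csv")
  cells <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  else NULL
  cell_matrix(x, cells = cells)
}

#' Read a numeric matrix from CSV
#'
#' First column is taken as row names; remaining columns must be numeric.
#'
#' @param path CSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_csv_matrix <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric values in ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write the two bulk cohorts as one CSV
#'
#' Columns: `sample_id`, `cohort`, `label`, then one column per gene.
#'
#' @param bulk A [simulate_bulk()] result (or a list with `cohort1`,
#'   `cohort2` in the same shape).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_bulk_dataset <- function(bulk, path) {
  rows <- lapply(1:2, function(i) {
    co <- bulk[[paste0("cohort", i)]]
    data.frame(sample_id = co$sample_id, cohort = i, label = co$labels,
               as.data.frame(co$x, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a two-cohort bulk CSV written by [write_bulk_dataset()]
#'
#' @param path CSV path.
#' @return List with `cohort1` and `cohort2`, each `list(x, labels,
#'   sample_id)`.
#' @export
read_bulk_dataset <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cohort", "label")
  if (!all(need %in% names(df)))
    stop("bulk CSV must have columns sample_id, cohort, label: ", path,
         call. = FALSE)
  out <- lapply(1:2, function(i) {
    sub <- df[df$cohort == i, , drop = FALSE]
    x <- as.matrix(sub[, setdiff(names(df), need), drop = FALSE])
    rownames(x) <- sub$sample_id
    list(x = x, labels = as.integer(sub$label), sample_id = sub$sample_id)
  })
  names(out) <- c("cohort1", "cohort2")
  out
}

#' Write named artifacts and a checksummed manifest
#'
#' Data frames are written as CSV, character vectors as line files, other
#' lists as JSON. `manifest.json` lists every file with its md5 checksum.
#'
#' @param dir Output directory.
#' @param artifacts Named list.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(dir, artifacts) {
  stopifnot(is.list(artifacts), !is.null(names(artifacts)),
            all(nzchar(names(artifacts))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    if (is.data.frame(a)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(a, f, row.names = FALSE)
    } else if (is.character(a) && is.null(dim(a))) {
      f <- file.path(dir, paste0(nm, ".txt"))
      writeLines(a, f)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(a, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(files = lapply(files, function(f)
    list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
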