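#' Median-binarize one column of scores
#'
#' The consensus rule of the classifier: the median is taken over all scored
#' cells; for the up-signature (signature1), a score strictly above the
#' median is assigned 1, otherwise 0; for the down-signature (signature2)
#' the coding is reversed — strictly above the median is 0, otherwise 1.
#' Ties at the median always fall to the "otherwise" branch.
#'
#' @param scores Finite numeric scores, one per cell (>= 2 cells).
#' @param direction `"signature1"` or `"signature2"`.
#' @return Integer 0/1 vector, one bit per cell.
#' @export
binarize_scores <- function(scores, direction = c("signature1",
                                                  "signature2")) {
  direction <- match.arg(direction)
  if (length(scores) < 2)
    stop("at least 2 cells are required", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  med <- stats::median(scores)
  above <- scores > med
  if (!any(above))
    if (length(unique(scores)) == 1)
      warning("all scores identical; every cell takes the 'otherwise' value")
  if (direction == "signature1") as.integer(above)
  else as.integer(!above)
}

#' Consensus classification of cells from a score tensor
#'
#' Binarizes every (scorer, signature) score column at its median with
#' [binarize_scores()] and sums the 2k bits per cell. A cell unanimous in
#' the high-risk direction (total 2k) is labelled `high`, a cell unanimous
#' in the low-risk direction (total 0) is labelled `low`, and every cell
#' with an intermediate total is `filtered`. Filtered cells are retained in
#' the result so downstream proportions keep their denominators.
#'
#' @param tensor A [score_all()] `score_tensor`.
#' @return Data frame of class `consensus_result` with columns `cell`,
#'   `total`, `label`; the full bit matrix (cells x 2k) is in
#'   `attr(, "bits")` and k in `attr(, "k")`.
#' @export
classify_cells <- function(tensor) {
  stopifnot(inherits(tensor, "score_tensor") ||
              (is.list(tensor) && !is.null(tensor$values)))
  k <- length(tensor$scorers)
  if (k == 0) stop("the registry is empty (k = 0)", call. = FALSE)
  n <- length(tensor$cells)
  bits <- matrix(NA_integer_, nrow = n, ncol = 2L * k,
                 dimnames = list(tensor$cells,
                                 c(paste0(tensor$scorers, ".sig1"),
                                   paste0(tensor$scorers, ".sig2"))))
  for (j in seq_len(k)) {
    bits[, j] <- binarize_scores(tensor$values[, j, 1], "signature1")
    bits[, k + j] <- binarize_scores(tensor$values[, j, 2], "signature2")
  }
  total <- as.integer(rowSums(bits))
  label <- ifelse(total == 2L * k, "high",
                  ifelse(total == 0L, "low", "filtered"))
  res <- data.frame(cell = tensor$cells, total = total, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("consensus_result", "data.frame")
  attr(res, "bits") <- bits
  attr(res, "k") <- k
  res
}

#' Per-group proportions of high-, low- and filtered cells
#'
#' @param results A [classify_cells()] result.
#' @param group_labels One group label per cell (e.g. condition); must be
#'   complete, and every group must contain at least one cell.
#' @return Data frame with columns `group`, `high`, `low`, `filtered`,
#'   `n_cells`; the three fractions sum to 1 within each group.
#' @export
risk_proportions <- function(results, group_labels) {
  stopifnot(inherits(results, "consensus_result"))
  if (length(group_labels) != nrow(results) || anyNA(group_labels))
    stop("every cell needs a non-missing group label", call. = FALSE)
  if (!all(results$label %in% c("high", "low", "filtered")))
    stop("unknown consensus label in results", call. = FALSE)
  if (is.factor(group_labels) &&
      any(table(group_labels) == 0))
    stop("empty group: ",
         paste(names(which(table(group_labels) == 0)), collapse = ", "),
         call. = FALSE)
  groups <- unique(as.character(group_labels))
  out <- do.call(rbind, lapply(groups, function(gr) {
    sel <- results$label[group_labels == gr]
    data.frame(group = gr,
               high = mean(sel == "high"),
               low = mean(sel == "low"),
               filtered = mean(sel == "filtered"),
               n_cells = length(sel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
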