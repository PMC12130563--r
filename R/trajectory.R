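#' Deterministic pseudotime along the low-to-high-risk axis
#'
#' Orders cells on the first principal axis of the normalized expression
#' matrix, oriented so that the mean pseudotime of consensus-`high` cells
#' exceeds the mean of consensus-`low` cells, and min-max rescaled to
#' [0, 1]. The orientation rule makes the axis identifiable: the result is
#' invariant to a global sign flip of the expression values and to cell
#' order.
#'
#' @param cm A normalized [cell_matrix()] (or plain cells x genes matrix).
#' @param consensus A [classify_cells()] result for the same cells; both
#'   `high` and `low` labels must be present to orient the axis.
#' @return Data frame with columns `cell` and `t` (pseudotime in [0, 1]).
#' @export
pseudotime <- function(cm, consensus) {
  x <- if (inherits(cm, "cell_matrix")) dense_values(cm) else as.matrix(cm)
  stopifnot(inherits(consensus, "consensus_result"),
            nrow(consensus) == nrow(x))
  if (sum(consensus$label != "filtered") < 2)
    stop("at least 2 non-filtered cells are required", call. = FALSE)
  if (!any(consensus$label == "high") || !any(consensus$label == "low"))
    stop("cannot orient pseudotime: need at least one 'high' and one ",
         "'low' consensus cell", call. = FALSE)
  pc1 <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
  if (mean(pc1[consensus$label == "high"]) <
        mean(pc1[consensus$label == "low"]))
    pc1 <- -pc1
  rng <- range(pc1)
  t <- if (rng[1] == rng[2]) rep(0, length(pc1))
       else (pc1 - rng[1]) / (rng[2] - rng[1])
  data.frame(cell = consensus$cell, t = t, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-gene Pearson correlation with pseudotime
#'
#' @param cm A normalized [cell_matrix()] (or matrix, cells x genes).
#' @param t Pseudotime per cell (finite; >= 3 cells), either a numeric
#'   vector or a [pseudotime()] data frame.
#' @return Data frame with columns `gene`, `r`, `p`. Constant genes are
#'   reported with `r = NA` (and `p = NA`); they are never selected
#'   downstream. Two-sided p from the t-distribution with n - 2 df.
#' @export
correlate_pseudotime <- function(cm, t) {
  x <- if (inherits(cm, "cell_matrix")) dense_values(cm) else as.matrix(cm)
  if (is.data.frame(t)) t <- t$t
  if (length(t) != nrow(x))
    stop("'t' must have one value per cell", call. = FALSE)
  if (!all(is.finite(t))) stop("'t' must be finite", call. = FALSE)
  n <- nrow(x)
  if (n < 3) stop("at least 3 cells are required", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  r <- rep(NA_real_, ncol(x))
  ok <- sds > 0 & stats::sd(t) > 0
  if (any(ok))
    r[ok] <- suppressWarnings(as.numeric(stats::cor(x[, ok, drop = FALSE],
                                                    t)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene = colnames(x), r = r, p = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Intersect pseudotime-correlated genes with bulk DEGs
#'
#' The feature-selection rule of the prediction framework: genes passing the
#' correlation filter (r strictly above `r_thresh`, p strictly below
#' `alpha`) in both single-cell datasets, intersected with the differential
#' genes of both bulk cohorts. The threshold applies to signed r by
#' default, so strongly negatively correlated genes are not selected unless
#' `use_abs = TRUE`.
#'
#' @param corr_human,corr_mouse [correlate_pseudotime()] tables from the two
#'   single-cell datasets (a shared gene id space is assumed).
#' @param degs_cohort1,degs_cohort2 Character vectors of bulk DEGs.
#' @param r_thresh Correlation threshold (default 0.6).
#' @param alpha P-value threshold (default 0.05).
#' @param use_abs Apply the threshold to |r| instead of signed r.
#' @return Alphabetically ordered character vector of selected genes.
#' @export
select_features <- function(corr_human, corr_mouse, degs_cohort1,
                            degs_cohort2, r_thresh = 0.6, alpha = 0.05,
                            use_abs = FALSE) {
  pass <- function(corr) {
    stat <- if (use_abs) abs(corr$r) else corr$r
    corr$gene[!is.na(corr$r) & stat > r_thresh & corr$p < alpha]
  }
  out <- Reduce(intersect, list(pass(corr_human), pass(corr_mouse),
                                as.character(degs_cohort1),
                                as.character(degs_cohort2)))
  if (length(out) == 0)
    stop("empty feature set: no gene passes the pseudotime-correlation ",
         "filter in both single-cell datasets and the DEG lists of both ",
         "cohorts", call. = FALSE)
  sort(out)
}
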