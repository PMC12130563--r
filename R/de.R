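#' Depth-normalize and log-transform a count matrix
#'
#' Scales each cell to a fixed total count (`target_sum`), then applies
#' log1p — the standard droplet-data preprocessing convention. Cells with
#' zero total counts cannot be scaled and are rejected.
#'
#' @param cm A [cell_matrix()] of raw counts.
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A [cell_matrix()] with `normalized = TRUE`.
#' @export
normalize_cells <- function(cm, target_sum = 1e4) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (cm$normalized)
    stop("matrix is already normalized", call. = FALSE)
  totals <- Matrix::rowSums(cm$x)
  if (any(totals == 0)) {
    bad <- rownames(cm$x)[totals == 0]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  scaled <- cm$x * (target_sum / totals)
  out <- cm
  out$x <- log1p(scaled)
  out$normalized <- TRUE
  out
}

# Wilcoxon rank-sum statistic for one gene: normal approximation with tie
# correction (no continuity correction), matching the convention of
# single-cell marker tests. Returns the two-sided p.
rank_sum_p <- function(values, is_a) {
  n_a <- sum(is_a)
  n_b <- sum(!is_a)
  n <- n_a + n_b
  r <- rank(values)
  u <- sum(r[is_a]) - n_a * (n_a + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n_a * n_b / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)               # constant gene
  z <- (u - n_a * n_b / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-gene two-group Wilcoxon rank-sum differential expression
#'
#' Tests every gene between two groups of cells (or samples) with the
#' two-sided Wilcoxon rank-sum test, normal approximation with tie
#' correction. For tiny groups (3 observations or fewer) an exact test is
#' used instead, with a warning. Log2 fold changes are computed on group means of the
#' de-logged (expm1) values when `delog = TRUE` (single-cell convention for
#' log1p-normalized input) or on the values as given (bulk abundance scale),
#' with a pseudocount in numerator and denominator. P-values are BH-adjusted
#' across tested genes.
#'
#' Genes detected (value > 0) in fewer than `min_cells` members of either
#' group are skipped, reported in the `skipped` attribute, and not tested.
#'
#' @param x Numeric matrix, observations x genes, or a [cell_matrix()].
#' @param group_labels Two-level factor/character vector over rows; the
#'   first level (or `case`) is group A, whose enrichment gives positive
#'   log2fc.
#' @param case Label treated as group A. Default: first unique label.
#' @param pseudocount Added to both means before the log ratio (default 1).
#' @param delog Apply expm1 before averaging (use for log1p-normalized
#'   single-cell matrices).
#' @param min_cells Minimum detected observations per group (default 3).
#' @return A data frame with columns `gene`, `log2fc`, `p`, `p_adj`,
#'   `mean_a`, `mean_b`, ordered as in the input; skipped genes in
#'   `attr(, "skipped")`.
#' @export
rank_sum_de <- function(x, group_labels, case = NULL, pseudocount = 1,
                        delog = inherits(x, "cell_matrix") && x$normalized,
                        min_cells = 3) {
  force(delog)                     # default depends on the class of 'x'
  if (inherits(x, "cell_matrix")) x <- dense_values(x) else x <- as.matrix(x)
  group_labels <- as.character(group_labels)
  if (length(group_labels) != nrow(x))
    stop("'group_labels' must have one entry per row of 'x'", call. = FALSE)
  lv <- unique(group_labels)
  if (length(lv) != 2)
    stop("exactly two groups are required, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (is.null(case)) case <- lv[1]
  if (!case %in% lv) stop("'case' label not present", call. = FALSE)
  is_a <- group_labels == case
  n_a <- sum(is_a); n_b <- sum(!is_a)
  if (n_a == 0 || n_b == 0)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- FALSE
  if (min(n_a, n_b) <= 3) {
    warning("tiny group (<= 3 observations); using the exact rank-sum test")
    exact <- TRUE
  }

  vals_a <- x[is_a, , drop = FALSE]
  vals_b <- x[!is_a, , drop = FALSE]
  det_a <- colSums(vals_a > 0)
  det_b <- colSums(vals_b > 0)
  keep <- det_a >= min_cells & det_b >= min_cells
  skipped <- colnames(x)[!keep]
  if (!any(keep))
    stop("no genes detected in at least ", min_cells,
         " observations per group", call. = FALSE)

  expr_a <- vals_a[, keep, drop = FALSE]
  expr_b <- vals_b[, keep, drop = FALSE]
  if (delog) {
    mean_a <- colMeans(expm1(expr_a))
    mean_b <- colMeans(expm1(expr_b))
  } else {
    mean_a <- colMeans(expr_a)
    mean_b <- colMeans(expr_b)
  }
  ratio <- (mean_a + pseudocount) / (mean_b + pseudocount)
  log2fc <- ifelse(ratio > 0, log2(ratio), NA_real_)

  xk <- x[, keep, drop = FALSE]
  p <- vapply(seq_len(ncol(xk)), function(j) {
    v <- xk[, j]
    if (exact) {
      suppressWarnings(
        stats::wilcox.test(v[is_a], v[!is_a], exact = TRUE)$p.value)
    } else {
      rank_sum_p(v, is_a)
    }
  }, numeric(1))
  p[is.na(p)] <- 1

  res <- data.frame(gene = colnames(xk), log2fc = log2fc, p = p,
                    p_adj = bh_adjust(p), mean_a = mean_a, mean_b = mean_b,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "skipped") <- skipped
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment over a family of p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Extract up/down signatures from single-cell DE results
#'
#' Splits a DE table into signature1 (up in case: log2fc strictly above the
#' threshold) and signature2 (down: strictly below the negated threshold),
#' both at adjusted p strictly below `alpha`. Comparisons are strict on both
#' sides, so a gene exactly at a threshold is excluded.
#'
#' @param records Data frame from [rank_sum_de()].
#' @param lfc_thresh Log2 fold-change threshold (default 0.25).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A list of class `signature_pair` with `signature1` and
#'   `signature2` gene vectors.
#' @export
extract_signatures <- function(records, lfc_thresh = 0.25, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("gene", "log2fc", "p_adj") %in% names(records)))
  ok <- !is.na(records$log2fc) & records$p_adj < alpha
  sig1 <- records$gene[ok & records$log2fc > lfc_thresh]
  sig2 <- records$gene[ok & records$log2fc < -lfc_thresh]
  if (length(sig1) == 0 || length(sig2) == 0)
    stop("empty signature",
         if (length(sig1) == 0) "1" else "2",
         ": no genes pass |log2fc| > ", lfc_thresh,
         " and adjusted p < ", alpha,
         "; consensus scoring is undefined", call. = FALSE)
  structure(list(signature1 = sig1, signature2 = sig2),
            class = "signature_pair")
}

#' Bulk differential expression with the cohort thresholds
#'
#' Runs the rank-sum test on a bulk samples x genes matrix (abundance
#' scale, no de-logging) and returns the genes passing |log2fc| strictly
#' above `lfc_thresh` at adjusted p strictly below `alpha`.
#'
#' @param x Samples x genes numeric matrix.
#' @param labels Binary outcome per sample (1 = case).
#' @param lfc_thresh Log2 fold-change cut-off (default 1).
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @param min_cells Minimum detected samples per group (default 3).
#' @return Character vector of DEG ids (both directions), alphabetical.
#' @export
bulk_de <- function(x, labels, lfc_thresh = 1.0, alpha = 0.05,
                    min_cells = 3) {
  res <- rank_sum_de(x, ifelse(as.integer(labels) == 1L, "case", "control"),
                     case = "case", delog = FALSE, min_cells = min_cells)
  hit <- !is.na(res$log2fc) & abs(res$log2fc) > lfc_thresh &
    res$p_adj < alpha
  sort(res$gene[hit])
}
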