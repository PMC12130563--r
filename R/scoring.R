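#' @name scoring
#' @title Per-cell gene-set scoring statistics
#'
#' @description
#' The consensus classifier needs many independent per-cell scores of the
#' same signature. The registry provides eight core statistics spanning the
#' main families used for single-cell signature scoring, plus documented
#' parameter variants to reach an arbitrary registry size k (default 19):
#'
#' 1. `zmean` — mean of per-gene z-scores over the signature.
#' 2. `aucell05` — rank-AUC: area under the recovery curve of signature
#'    genes within the top 5% of the cell's expression ranking, normalized
#'    so a cell whose signature occupies the top ranks scores 1.
#' 3. `ucell` — normalized Mann-Whitney U of signature genes vs the rest of
#'    the genes within the cell (1 = signature genes are the top genes).
#' 4. `meanrank` — centered mean within-cell rank of the signature genes.
#' 5. `ssgsea025` — weighted running-sum enrichment with exponent 0.25.
#' 6. `plage` — projection on the first right singular vector of the
#'    z-scored signature submatrix, oriented along the signature mean.
#' 7. `mscore24` — signature mean minus the mean of expression-bin-matched
#'    control genes (24 bins).
#' 8. `droprank` — dropout-adjusted mean rank of signature genes among the
#'    genes expressed in the cell (undetected signature genes score 0).
#'
#' Variants: `aucell10`/`aucell25`/`aucell50` (top 10/25/50%), `ssgsea0`/
#' `ssgsea05`/`ssgsea1` (exponent 0/0.5/1), `ztrim10` (10% trimmed mean of
#' z-scores), `zmedian` (median z-score), `gmean` (plain mean normalized
#' expression), `mscore10` (10 bins), `medrank` (centered median rank).
#' All scorers increase with signature expression.
NULL

# Shared, lazily cached per-matrix quantities reused by all scorers.
scoring_context <- function(cm) {
  x <- if (inherits(cm, "cell_matrix")) dense_values(cm) else as.matrix(cm)
  env <- new.env(parent = emptyenv())
  env$x <- x
  env$n <- nrow(x)
  env$g <- ncol(x)
  delayedAssign("ranks", t(apply(x, 1, rank)), assign.env = env)
  delayedAssign("z", {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1                      # constant gene -> z = 0
    sweep(sweep(x, 2, mu), 2, sd, "/")
  }, assign.env = env)
  delayedAssign("gene_means", colMeans(x), assign.env = env)
  delayedAssign("n_zero", rowSums(x == 0), assign.env = env)
  env$bin_means <- list()
  env
}

score_zmean <- function(ctx, sig, trim = 0, median_stat = FALSE) {
  zs <- ctx$z[, sig, drop = FALSE]
  if (median_stat) return(apply(zs, 1, stats::median))
  if (trim > 0) return(apply(zs, 1, mean, trim = trim))
  rowMeans(zs)
}

score_gmean <- function(ctx, sig) rowMeans(ctx$x[, sig, drop = FALSE])

score_aucell <- function(ctx, sig, top_frac) {
  g <- ctx$g
  m <- max(2, ceiling(top_frac * g))
  r_top <- g + 1 - ctx$ranks[, sig, drop = FALSE]  # 1 = highest expression
  raw <- rowSums(pmax(m - r_top, 0))   # first arg keeps the matrix shape
  s_eff <- min(length(sig), m - 1)
  max_raw <- s_eff * m - s_eff * (s_eff + 1) / 2
  if (max_raw <= 0) return(rep(0, ctx$n))
  raw / max_raw
}

score_ucell <- function(ctx, sig) {
  g <- ctx$g
  s <- length(sig)
  if (s >= g) return(rep(0.5, ctx$n))
  rs <- rowSums(ctx$ranks[, sig, drop = FALSE])
  u <- rs - s * (s + 1) / 2
  u / (s * (g - s))
}

score_meanrank <- function(ctx, sig, median_stat = FALSE) {
  r <- ctx$ranks[, sig, drop = FALSE]
  center <- if (median_stat) apply(r, 1, stats::median) else rowMeans(r)
  (center - (ctx$g + 1) / 2) / ctx$g
}

score_ssgsea <- function(ctx, sig, alpha) {
  g <- ctx$g
  in_sig <- logical(g)
  in_sig[sig] <- TRUE
  n_miss <- g - length(sig)
  vapply(seq_len(ctx$n), function(i) {
    v <- ctx$x[i, ]
    ord <- order(v, decreasing = TRUE)
    hit <- in_sig[ord]
    w <- if (alpha == 0) as.numeric(hit) else abs(v[ord])^alpha * hit
    tot <- sum(w)
    if (tot == 0) { w <- as.numeric(hit); tot <- sum(w) }
    p_hit <- cumsum(w) / tot
    p_miss <- cumsum(!hit) / n_miss
    sum(p_hit - p_miss) / g
  }, numeric(1))
}

score_plage <- function(ctx, sig) {
  zs <- ctx$z[, sig, drop = FALSE]
  if (ncol(zs) == 1) return(zs[, 1])
  sv <- svd(zs, nu = 0, nv = 1)
  sc <- drop(zs %*% sv$v[, 1])
  ref <- rowMeans(zs)
  if (sum(sc * ref) < 0) sc <- -sc        # orient along the signature mean
  sc
}

score_modulescore <- function(ctx, sig, nbin) {
  key <- as.character(nbin)
  if (is.null(ctx$bin_means[[key]])) {
    bin <- ceiling(rank(ctx$gene_means, ties.method = "first") *
                     nbin / ctx$g)
    bm <- vapply(seq_len(nbin), function(b) {
      idx <- which(bin == b)
      if (length(idx) == 0) rep(0, ctx$n)
      else rowMeans(ctx$x[, idx, drop = FALSE])
    }, numeric(ctx$n))
    ctx$bin_means[[key]] <- list(bin = bin, bm = bm)
  }
  cache <- ctx$bin_means[[key]]
  ctrl <- rowMeans(cache$bm[, cache$bin[sig], drop = FALSE])
  rowMeans(ctx$x[, sig, drop = FALSE]) - ctrl
}

score_droprank <- function(ctx, sig) {
  n_expr <- ctx$g - ctx$n_zero
  n_expr[n_expr == 0] <- 1
  xs <- ctx$x[, sig, drop = FALSE]
  rel <- (ctx$ranks[, sig, drop = FALSE] - ctx$n_zero) / n_expr
  rel[xs <= 0] <- 0                       # dropped-out signature genes
  rowSums(rel) / length(sig)
}

# name, function factory args, ordered: 8 core statistics then variants.
scorer_table <- function() {
  list(
    list(name = "zmean",     fun = function(ctx, sig) score_zmean(ctx, sig)),
    list(name = "aucell05",  fun = function(ctx, sig) score_aucell(ctx, sig, 0.05)),
    list(name = "ucell",     fun = score_ucell),
    list(name = "meanrank",  fun = function(ctx, sig) score_meanrank(ctx, sig)),
    list(name = "ssgsea025", fun = function(ctx, sig) score_ssgsea(ctx, sig, 0.25)),
    list(name = "plage",     fun = score_plage),
    list(name = "mscore24",  fun = function(ctx, sig) score_modulescore(ctx, sig, 24)),
    list(name = "droprank",  fun = score_droprank),
    list(name = "aucell10",  fun = function(ctx, sig) score_aucell(ctx, sig, 0.10)),
    list(name = "aucell25",  fun = function(ctx, sig) score_aucell(ctx, sig, 0.25)),
    list(name = "aucell50",  fun = function(ctx, sig) score_aucell(ctx, sig, 0.50)),
    list(name = "ssgsea0",   fun = function(ctx, sig) score_ssgsea(ctx, sig, 0)),
    list(name = "ssgsea05",  fun = function(ctx, sig) score_ssgsea(ctx, sig, 0.5)),
    list(name = "ssgsea1",   fun = function(ctx, sig) score_ssgsea(ctx, sig, 1)),
    list(name = "ztrim10",   fun = function(ctx, sig) score_zmean(ctx, sig, trim = 0.1)),
    list(name = "zmedian",   fun = function(ctx, sig) score_zmean(ctx, sig, median_stat = TRUE)),
    list(name = "gmean",     fun = score_gmean),
    list(name = "mscore10",  fun = function(ctx, sig) score_modulescore(ctx, sig, 10)),
    list(name = "medrank",   fun = function(ctx, sig) score_meanrank(ctx, sig, median_stat = TRUE))
  )
}

#' Build the scoring-algorithm registry
#'
#' Returns the first `k` scorers of the documented registry order: the 8
#' core statistics first, then parameter variants (see [scoring]).
#'
#' @param k Number of scorers (default 19, the registry maximum).
#' @return A list of class `scorer_registry`; each element has `name`,
#'   `fun`, and `direction_sensitive`.
#' @export
build_registry <- function(k = 19) {
  tab <- scorer_table()
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (k > length(tab))
    stop("'k' exceeds the number of available scorers (maximum ",
         length(tab), ")", call. = FALSE)
  reg <- lapply(tab[seq_len(k)], function(s) {
    s$direction_sensitive <- TRUE
    s
  })
  structure(reg, class = "scorer_registry")
}

#' @export
print.scorer_registry <- function(x, ...) {
  cat(sprintf("<scorer_registry> %d scorers: %s\n", length(x),
              paste(vapply(x, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

# Map signature genes to column indices; drop absent genes with a warning,
# error when none remain.
resolve_signature <- function(genes, universe, label = "signature") {
  genes <- unique(genes)
  idx <- match(genes, universe)
  if (anyNA(idx)) {
    missing <- genes[is.na(idx)]
    if (all(is.na(idx)))
      stop("no ", label, " genes present in the matrix", call. = FALSE)
    warning(length(missing), " ", label,
            " gene(s) absent from the matrix were dropped")
    idx <- idx[!is.na(idx)]
  }
  idx
}

#' Score every cell for one gene set with one scorer
#'
#' @param cm A normalized [cell_matrix()] (or plain matrix, cells x genes).
#' @param genes Signature gene ids; duplicates are deduplicated, genes
#'   absent from the matrix are dropped with a warning.
#' @param scorer One element of [build_registry()], or a scorer name.
#' @return Numeric vector, one finite score per cell.
#' @export
score_cells <- function(cm, genes, scorer = "zmean") {
  if (is.character(scorer)) {
    tab <- scorer_table()
    hit <- which(vapply(tab, `[[`, "", "name") == scorer)
    if (length(hit) == 0)
      stop("unknown scorer '", scorer, "'", call. = FALSE)
    scorer <- tab[[hit]]
  }
  ctx <- scoring_context(cm)
  universe <- if (inherits(cm, "cell_matrix")) cm$genes else colnames(cm)
  idx <- resolve_signature(genes, universe)
  scorer$fun(ctx, idx)
}

#' Score all cells with every registry scorer for both signatures
#'
#' Produces the score tensor of the consensus framework: one score per cell,
#' per scorer, per signature (k scorers give 2k scores per cell).
#'
#' @param cm A normalized [cell_matrix()].
#' @param sig A [extract_signatures()] `signature_pair` (or a list with
#'   `signature1`, `signature2`).
#' @param registry A [build_registry()] result.
#' @return A `score_tensor`: list with `cells`, `scorers`, and `values`, a
#'   cells x scorers x 2 array (slice 1 = signature1, slice 2 = signature2).
#' @export
score_all <- function(cm, sig, registry = build_registry()) {
  stopifnot(is.list(sig), !is.null(sig$signature1), !is.null(sig$signature2))
  if (length(sig$signature1) == 0 || length(sig$signature2) == 0)
    stop("both signatures must be non-empty", call. = FALSE)
  if (anyDuplicated(sig$signature1) || anyDuplicated(sig$signature2))
    warning("duplicate genes in signature list(s) were deduplicated")
  ctx <- scoring_context(cm)
  universe <- if (inherits(cm, "cell_matrix")) cm$genes else colnames(cm)
  idx1 <- resolve_signature(sig$signature1, universe, "signature1")
  idx2 <- resolve_signature(sig$signature2, universe, "signature2")
  k <- length(registry)
  names <- vapply(registry, `[[`, "", "name")
  cell_ids <- if (inherits(cm, "cell_matrix")) cm$cells$cell_id
              else rownames(cm)
  values <- array(NA_real_, dim = c(ctx$n, k, 2),
                  dimnames = list(cell_ids, names,
                                  c("signature1", "signature2")))
  for (j in seq_len(k)) {
    sc <- registry[[j]]
    v1 <- tryCatch(sc$fun(ctx, idx1), error = function(e)
      stop("scorer '", sc$name, "' failed on signature1: ",
           conditionMessage(e), call. = FALSE))
    v2 <- tryCatch(sc$fun(ctx, idx2), error = function(e)
      stop("scorer '", sc$name, "' failed on signature2: ",
           conditionMessage(e), call. = FALSE))
    if (!all(is.finite(v1)) || !all(is.finite(v2)))
      stop("scorer '", sc$name, "' produced non-finite scores",
           call. = FALSE)
    values[, j, 1] <- v1
    values[, j, 2] <- v2
  }
  structure(list(cells = cell_ids, scorers = names, values = values),
            class = "score_tensor")
}

#' @export
print.score_tensor <- function(x, ...) {
  cat(sprintf("<score_tensor> %d cells x %d scorers x 2 signatures\n",
              length(x$cells), length(x$scorers)))
  invisible(x)
}
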