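#' Simulation parameters for synthetic single-cell data
#'
#' Builds and validates the parameter set for [simulate_sc()]. The simulator
#' emulates a two-condition peripheral-blood neutrophil experiment: a control
#' condition (hypertension only, "HBP") and a case condition (microbleed,
#' "MB") that contains a planted subpopulation of high-risk cells. High-risk
#' cells over-express a planted up-signature and under-express a planted
#' down-signature; a disjoint set of trajectory genes varies smoothly with a
#' latent differentiation coordinate shared by all cells.
#'
#' @param n_cells_per_condition Cells simulated in each of the two conditions.
#' @param n_genes Total genes in the matrix.
#' @param n_sig_up,n_sig_down Sizes of the planted up- and down-regulated
#'   signatures (disjoint gene sets).
#' @param n_monotone Number of trajectory genes whose mean is linear in the
#'   latent coordinate (disjoint from both signatures); half are induced
#'   along the latent and half repressed, so the program is library-size
#'   neutral.
#' @param effect_log2fc Planted effect: in high-risk cells the up-signature
#'   means are multiplied by `2^effect_log2fc` and the down-signature means
#'   divided by it.
#' @param monotone_fold Fold-change in mean of a trajectory gene between the
#'   ends of the latent coordinate (latent 0 vs 1). The default is chosen so
#'   trajectory genes behave like the strongly pseudotime-correlated genes
#'   the feature-selection step is meant to find.
#' @param nb_dispersion Negative-binomial dispersion shared by all genes
#'   (variance = mu + dispersion * mu^2); counts are gamma-Poisson draws.
#' @param libsize_lognormal_sigma Log-normal sigma of per-cell library-size
#'   factors (0 disables depth variation).
#' @param frac_high_risk_in_case Fraction of case-condition cells flagged
#'   high-risk; control cells are never high-risk.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_cells_per_condition = 1000,
                          n_genes = 1000,
                          n_sig_up = 50,
                          n_sig_down = 50,
                          n_monotone = 50,
                          effect_log2fc = 1,
                          monotone_fold = 16,
                          nb_dispersion = 0.2,
                          libsize_lognormal_sigma = 0.3,
                          frac_high_risk_in_case = 0.5,
                          seed = 1L) {
  p <- list(n_cells_per_condition = as.integer(n_cells_per_condition),
            n_genes = as.integer(n_genes),
            n_sig_up = as.integer(n_sig_up),
            n_sig_down = as.integer(n_sig_down),
            n_monotone = as.integer(n_monotone),
            effect_log2fc = as.numeric(effect_log2fc),
            monotone_fold = as.numeric(monotone_fold),
            nb_dispersion = as.numeric(nb_dispersion),
            libsize_lognormal_sigma = as.numeric(libsize_lognormal_sigma),
            frac_high_risk_in_case = as.numeric(frac_high_risk_in_case),
            seed = as.integer(seed))
  check_positive_int <- function(field) {
    if (!is.finite(p[[field]]) || p[[field]] < 1L)
      stop("invalid parameter '", field, "': must be a positive integer",
           call. = FALSE)
  }
  for (f in c("n_cells_per_condition", "n_genes")) check_positive_int(f)
  for (f in c("n_sig_up", "n_sig_down", "n_monotone")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0L)
      stop("invalid parameter '", f, "': must be a non-negative integer",
           call. = FALSE)
  }
  if (p$n_sig_up + p$n_sig_down + p$n_monotone > p$n_genes)
    stop("invalid parameter 'n_genes': planted gene sets ",
         "(n_sig_up + n_sig_down + n_monotone) exceed n_genes", call. = FALSE)
  if (!is.finite(p$nb_dispersion) || p$nb_dispersion <= 0)
    stop("invalid parameter 'nb_dispersion': must be > 0", call. = FALSE)
  if (!is.finite(p$libsize_lognormal_sigma) || p$libsize_lognormal_sigma < 0)
    stop("invalid parameter 'libsize_lognormal_sigma': must be >= 0",
         call. = FALSE)
  if (!is.finite(p$frac_high_risk_in_case) ||
      p$frac_high_risk_in_case < 0 || p$frac_high_risk_in_case > 1)
    stop("invalid parameter 'frac_high_risk_in_case': must be in [0, 1]",
         call. = FALSE)
  if (!is.finite(p$monotone_fold) || p$monotone_fold <= 0)
    stop("invalid parameter 'monotone_fold': must be > 0", call. = FALSE)
  if (is.na(p$seed))
    stop("invalid parameter 'seed': must be an integer", call. = FALSE)
  structure(p, class = "sc_sim_params")
}

#' Simulation parameters for synthetic two-cohort bulk data
#'
#' Parameters for [simulate_bulk()], which emulates two bulk transcriptomic
#' cohorts of hypertensive patients with a binary hemorrhage outcome. A
#' planted set of informative genes is additively shifted in cases; cohort 2
#' carries a constant batch offset on every feature.
#'
#' @param n_samples_per_cohort Samples per cohort (two cohorts are produced).
#' @param n_features Number of gene features.
#' @param n_informative Number of planted outcome-discriminative genes.
#' @param informative_effect Additive shift of informative genes in cases, in
#'   units of the feature scale. The default is large relative to `noise_sd`
#'   so planted genes behave like bulk DEGs passing a |log2 fold change| > 1
#'   filter on abundance-scale values.
#' @param batch_offset Constant added to every feature of cohort 2.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param case_fraction Fraction of samples per cohort labelled case (1).
#' @param seed Integer seed.
#' @return An object of class `bulk_sim_params`.
#' @export
bulk_sim_params <- function(n_samples_per_cohort = 65,
                            n_features = 64,
                            n_informative = 10,
                            informative_effect = 6,
                            batch_offset = 1,
                            noise_sd = 1,
                            case_fraction = 0.5,
                            seed = 1L) {
  p <- list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
            n_features = as.integer(n_features),
            n_informative = as.integer(n_informative),
            informative_effect = as.numeric(informative_effect),
            batch_offset = as.numeric(batch_offset),
            noise_sd = as.numeric(noise_sd),
            case_fraction = as.numeric(case_fraction),
            seed = as.integer(seed))
  if (!is.finite(p$n_samples_per_cohort) || p$n_samples_per_cohort < 2L)
    stop("invalid parameter 'n_samples_per_cohort': must be >= 2",
         call. = FALSE)
  if (!is.finite(p$n_features) || p$n_features < 1L)
    stop("invalid parameter 'n_features': must be >= 1", call. = FALSE)
  if (!is.finite(p$n_informative) || p$n_informative < 0L ||
      p$n_informative > p$n_features)
    stop("invalid parameter 'n_informative': must be in [0, n_features]",
         call. = FALSE)
  if (!is.finite(p$noise_sd) || p$noise_sd <= 0)
    stop("invalid parameter 'noise_sd': must be > 0", call. = FALSE)
  if (!is.finite(p$case_fraction) || p$case_fraction <= 0 ||
      p$case_fraction >= 1)
    stop("invalid parameter 'case_fraction': must be in (0, 1)",
         call. = FALSE)
  if (!is.finite(p$informative_effect))
    stop("invalid parameter 'informative_effect': must be finite",
         call. = FALSE)
  if (!is.finite(p$batch_offset))
    stop("invalid parameter 'batch_offset': must be finite", call. = FALSE)
  if (is.na(p$seed))
    stop("invalid parameter 'seed': must be an integer", call. = FALSE)
  structure(p, class = "bulk_sim_params")
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a two-condition single-cell count matrix with planted truth
#'
#' Draws negative-binomial counts (gamma-Poisson mixture, shared dispersion)
#' for `2 * n_cells_per_condition` cells over `n_genes` genes. Baseline gene
#' means are log-normal; planted signature and trajectory genes get
#' moderately expressed baselines so the planted structure is detectable at
#' realistic depth. Every cell carries a latent differentiation coordinate in
#' [0, 1]; high-risk cells (a seeded fraction of case cells) sit in the upper
#' half of the coordinate and apply the planted signature effect.
#'
#' @param params An [sc_sim_params()] object.
#' @return A list with components `cells` (a [cell_matrix()] of counts with
#'   per-cell metadata: `condition` in HBP/MB, `high_risk`, `latent`) and
#'   `truth` (a `planted_truth` list: `sig_up_genes`, `sig_down_genes`,
#'   `monotone_pseudotime_genes` with its `monotone_up_genes` /
#'   `monotone_down_genes` halves, `high_risk_cell_ids`, plus the latent
#'   coordinate per cell).
#' @export
simulate_sc <- function(params) {
  if (!inherits(params, "sc_sim_params"))
    stop("'params' must be built with sc_sim_params()", call. = FALSE)
  with_seed(params$seed, {
    n_cond <- params$n_cells_per_condition
    n_cells <- 2L * n_cond
    g <- params$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    condition <- rep(c("HBP", "MB"), each = n_cond)

    planted <- seq_len(params$n_sig_up + params$n_sig_down +
                         params$n_monotone)
    idx_up <- seq_len(params$n_sig_up)
    idx_down <- params$n_sig_up + seq_len(params$n_sig_down)
    idx_mono <- params$n_sig_up + params$n_sig_down +
      seq_len(params$n_monotone)

    # Baselines: background genes span the usual low-expression bulk of a
    # droplet experiment; planted genes are moderately expressed so their
    # structure survives sampling noise at a few thousand counts per cell.
    base_mu <- exp(stats::rnorm(g, mean = log(0.5), sd = 1.2))
    base_mu[planted] <- stats::runif(length(planted), 2, 5)

    # High-risk flags: a fixed fraction of case cells, none in control.
    n_hr <- round(params$frac_high_risk_in_case * n_cond)
    hr <- logical(n_cells)
    if (n_hr > 0)
      hr[n_cond + sample.int(n_cond, n_hr)] <- TRUE

    # Latent differentiation coordinate: high-risk cells occupy the upper
    # half, all other cells the lower half, so the low-to-high-risk axis is
    # monotone in the latent by construction.
    latent <- stats::runif(n_cells, 0, 0.5)
    latent[hr] <- stats::runif(sum(hr), 0.5, 1)

    # Per-cell, per-gene means.
    mu <- matrix(base_mu, nrow = n_cells, ncol = g, byrow = TRUE)
    # Trajectory program: half the monotone genes are induced along the
    # latent, half repressed (mirror profile), so the program does not
    # inflate total library size at one end of the axis.
    n_mono_up <- ceiling(length(idx_mono) / 2)
    idx_mono_up <- idx_mono[seq_len(n_mono_up)]
    idx_mono_down <- setdiff(idx_mono, idx_mono_up)
    slope <- params$monotone_fold - 1
    if (length(idx_mono_up) > 0)
      mu[, idx_mono_up] <- mu[, idx_mono_up] * (1 + slope * latent)
    if (length(idx_mono_down) > 0)
      mu[, idx_mono_down] <- mu[, idx_mono_down] *
        (1 + slope * (1 - latent))
    eff <- 2^params$effect_log2fc
    if (any(hr)) {
      if (length(idx_up) > 0)
        mu[hr, idx_up] <- mu[hr, idx_up] * eff
      if (length(idx_down) > 0)
        mu[hr, idx_down] <- mu[hr, idx_down] / eff
    }
    sf <- exp(stats::rnorm(n_cells, 0, params$libsize_lognormal_sigma))
    mu <- mu * sf

    # Gamma-Poisson: shape 1/dispersion, so var = mu + dispersion * mu^2.
    shape <- 1 / params$nb_dispersion
    lambda <- matrix(stats::rgamma(n_cells * g, shape = shape,
                                   rate = shape / pmax(mu, 1e-12)),
                     nrow = n_cells)
    counts <- matrix(stats::rpois(n_cells * g, lambda), nrow = n_cells,
                     dimnames = list(cell_ids, gene_ids))

    cm <- cell_matrix(counts,
                      cells = data.frame(cell_id = cell_ids,
                                         condition = condition,
                                         cell_type = "neutrophil",
                                         sample = ifelse(condition == "HBP",
                                                         "HBP1", "MB1"),
                                         high_risk = hr,
                                         latent = latent,
                                         stringsAsFactors = FALSE))
    truth <- structure(list(
      sig_up_genes = gene_ids[idx_up],
      sig_down_genes = gene_ids[idx_down],
      monotone_pseudotime_genes = gene_ids[idx_mono],
      monotone_up_genes = gene_ids[idx_mono_up],
      monotone_down_genes = gene_ids[idx_mono_down],
      high_risk_cell_ids = cell_ids[hr],
      latent = stats::setNames(latent, cell_ids)),
      class = "planted_truth")
    list(cells = cm, truth = truth)
  })
}

#' Simulate two bulk cohorts with a planted outcome signal
#'
#' Features are Gaussian on an abundance-like scale: per-gene baseline means
#' are drawn uniformly on [2, 4] and noise is `noise_sd`. Informative genes
#' are shifted by `informative_effect` in cases, in both cohorts; every
#' feature of cohort 2 additionally receives the constant `batch_offset`.
#'
#' @param params A [bulk_sim_params()] object.
#' @param feature_ids Optional character vector of feature names of length
#'   `n_features`; defaults to `b0001...`. Passing single-cell gene ids here
#'   places the two modalities in one id space.
#' @param informative_pool Optional character vector (subset of
#'   `feature_ids`) from which informative genes are drawn; used to plant the
#'   bulk signal inside the single-cell trajectory gene set. Default: the
#'   first `n_informative` features.
#' @return A list with `cohort1`, `cohort2` (each a list with `x`, a samples
#'   x features matrix; `labels`, 0/1 integer; `sample_id`) and `truth`
#'   (`informative_genes`).
#' @export
simulate_bulk <- function(params, feature_ids = NULL,
                          informative_pool = NULL) {
  if (!inherits(params, "bulk_sim_params"))
    stop("'params' must be built with bulk_sim_params()", call. = FALSE)
  n <- params$n_samples_per_cohort
  g <- params$n_features
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("b%04d", seq_len(g))
  } else if (length(feature_ids) != g || anyDuplicated(feature_ids)) {
    stop("'feature_ids' must be ", g, " unique names", call. = FALSE)
  }
  if (is.null(informative_pool)) {
    informative <- feature_ids[seq_len(params$n_informative)]
  } else {
    if (!all(informative_pool %in% feature_ids))
      stop("'informative_pool' must be a subset of 'feature_ids'",
           call. = FALSE)
    if (length(informative_pool) < params$n_informative)
      stop("'informative_pool' smaller than n_informative", call. = FALSE)
    informative <- informative_pool[seq_len(params$n_informative)]
  }
  with_seed(params$seed, {
    base_mu <- stats::runif(g, 2, 4)
    inf_idx <- match(informative, feature_ids)
    one_cohort <- function(cohort_idx) {
      n_case <- round(params$case_fraction * n)
      labels <- c(rep(1L, n_case), rep(0L, n - n_case))
      x <- matrix(stats::rnorm(n * g, sd = params$noise_sd), nrow = n) +
        matrix(base_mu, nrow = n, ncol = g, byrow = TRUE)
      if (length(inf_idx) > 0 && n_case > 0)
        x[labels == 1L, inf_idx] <- x[labels == 1L, inf_idx, drop = FALSE] +
          params$informative_effect
      if (cohort_idx == 2L) x <- x + params$batch_offset
      sample_id <- sprintf("c%d_s%03d", cohort_idx, seq_len(n))
      dimnames(x) <- list(sample_id, feature_ids)
      list(x = x, labels = labels, sample_id = sample_id)
    }
    cohort1 <- one_cohort(1L)
    cohort2 <- one_cohort(2L)
    truth <- structure(list(informative_genes = informative),
                       class = "planted_truth")
    list(cohort1 = cohort1, cohort2 = cohort2, truth = truth)
  })
}
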