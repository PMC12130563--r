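# Small simulated datasets shared across test files; cached so each is
# built once per test run.
.fixtures <- new.env(parent = emptyenv())

small_sc <- function() {
  if (is.null(.fixtures$sc)) {
    p <- sc_sim_params(n_cells_per_condition = 300, n_genes = 400,
                       n_sig_up = 30, n_sig_down = 30, n_monotone = 30,
                       seed = 7)
    .fixtures$sc <- simulate_sc(p)
  }
  .fixtures$sc
}

small_sc_norm <- function() {
  if (is.null(.fixtures$sc_norm))
    .fixtures$sc_norm <- normalize_cells(small_sc()$cells)
  .fixtures$sc_norm
}

small_signatures <- function() {
  if (is.null(.fixtures$sig)) {
    nm <- small_sc_norm()
    de <- rank_sum_de(nm, nm$cells$condition, case = "MB")
    .fixtures$sig <- extract_signatures(de)
  }
  .fixtures$sig
}

small_bulk <- function() {
  if (is.null(.fixtures$bulk))
    .fixtures$bulk <- simulate_bulk(bulk_sim_params(seed = 11))
  .fixtures$bulk
}

# The canonical full run at default scale, shared by the acceptance tests.
default_run_dir <- function() {
  if (is.null(.fixtures$run_dir)) {
    dir <- file.path(tempdir(), "cccf-default-run")
    run_pipeline(dir, run_config(seed = 1))
    .fixtures$run_dir <- dir
  }
  .fixtures$run_dir
}

# A random expression matrix with named dims.
rand_mat <- function(n, g, seed = 1) {
  set.seed(seed)
  matrix(rpois(n * g, 5), n, g,
         dimnames = list(sprintf("c%03d", seq_len(n)),
                         sprintf("g%03d", seq_len(g))))
}
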