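# Shared fixtures, built once per test session.

quick_mcmc <- function(seed = 1L, burn_in = 200L, n_iter = 800L) {
  mcmc_settings(burn_in = burn_in, n_iter = n_iter, seed = seed)
}

tiny_synthetic <- function(seed = 1L, villages_per_district = 20L, ...) {
  synthetic_config(n_states = 2L, districts_per_state = 2L,
                   villages_per_district = villages_per_district,
                   seed = seed, ...)
}

# 4-level binomial count data at known parameters
sim_counts <- function(seed, S = 10L, D = 4L, Jc = 8L, nch = 25L,
                       beta = -0.5, s2u = 0.6, s2v = 0.1, s2f = 0.3) {
  withr::with_seed(seed, {
    st <- rep(seq_len(S), each = D * Jc)
    di <- rep(seq_len(S * D), each = Jc)
    f <- rnorm(S, 0, sqrt(s2f))
    v <- rnorm(S * D, 0, sqrt(s2v))
    u <- rnorm(S * D * Jc, 0, sqrt(s2u))
    eta <- beta + u + v[di] + f[st]
    list(y = rbinom(length(eta), nch, plogis(eta)),
         n = rep(nch, length(eta)),
         cluster_id = sprintf("c%05d", seq_along(eta)),
         district_id = sprintf("d%03d", di),
         state_id = sprintf("s%02d", st))
  })
}

# small end-to-end pipeline, memoised across test files
.fixture_env <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    cfg <- pipeline_config(
      synthetic = tiny_synthetic(seed = 7L, villages_per_district = 40L),
      mcmc = quick_mcmc(seed = 7L, burn_in = 150L, n_iter = 500L),
      n_repeats = 3L)
    .fixture_env$pipe <- suppressWarnings(suppressMessages(
      run_pipeline(cfg, quiet = TRUE)))
  }
  .fixture_env$pipe
}

# hand-rolled proximity graph from an explicit weight matrix
graph_from_weights <- function(W) {
  W <- Matrix::Matrix(W, sparse = TRUE)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))$membership
  structure(list(W = W, n = nrow(W), k = NA_integer_, bandwidth = NA_real_,
                 center = NULL, scale = NULL, kept_columns = NULL,
                 components = as.integer(comp)),
            class = "proximity_graph")
}
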