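# Shared fixtures: small meshes and cached simulations keep the suite fast.

small_params <- function(n_cells = 25L) wound_params(n_cells = n_cells)

# untreated trajectory on a coarse mesh, with derivatives, cached per session
untreated_traj <- local({
  cache <- new.env(parent = emptyenv())
  function(n_cells = 25L, dt_record = 0.01) {
    key <- paste0(n_cells, "_", dt_record)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_wound(horizon = 20,
                                     p = small_params(n_cells),
                                     dt_record = dt_record,
                                     record_deriv = TRUE)
    cache[[key]]
  }
})

random_mapper <- function(dx = 10L, du = 2L, hidden = c(6L, 5L), seed = 1L) {
  set.seed(seed)
  woundloop:::mapper_init(dx, du, hidden = hidden)
}

random_batch <- function(dx = 10L, du = 2L, n = 7L, seed = 2L) {
  set.seed(seed)
  structure(list(X = matrix(stats::runif(n * dx), n),
                 Xd = matrix(stats::rnorm(n * dx), n),
                 U = matrix(stats::runif(n * du), n),
                 scales = rep(1, 5L)),
            class = "mapper_dataset")
}
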