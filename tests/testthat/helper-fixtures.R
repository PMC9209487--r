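# Small shared fixtures, built once per test run.

# Deterministic extended-chain template (capped Q15-like, 140 atoms).
fix_template <- function() {
  make_chain_template(15, caps = TRUE, phi = -140, psi = 135)
}

# Tiny multi-basin run for fast end-to-end tests.
fix_small_run <- function(n_frames = 1200, seed = 42) {
  make_run(fixture_spec(n_res = 6, n_frames = n_frames, n_basins = 2,
                        within_basin_sd = 0.8, switch_probability = 0.05,
                        seed = seed))
}

# Random perturbed conformations of a template (frame-major matrix).
fix_random_frames <- function(k, template = fix_template(), sd = 1) {
  xyz <- template$xyz[rep(1, k), , drop = FALSE]
  xyz + matrix(rnorm(length(xyz), sd = sd), nrow = k)
}

# A quickly trained small autoencoder plus its data, cached for reuse.
fix_trained_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    run <- fix_small_run()
    parts <- split_trajectory(run, split_spec(0, 0.25))
    train <- align_frames(parts$train)
    scaling <- fit_scaling(train)
    scaled <- scale_coords(scaling, train$xyz)
    model <- train_autoencoder(
      scaled, network_spec(ncol(scaled), latent_dim_rule(8)),
      training_config(epochs = 40, seed = 7))
    cache <<- list(model = model, scaling = scaling, train = train,
                   test = align_to(parts$test, frame_coords(train, 1L)),
                   scaled = scaled, atoms = run$atoms)
    cache
  }
})
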