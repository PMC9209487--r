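#' End-to-end pipeline configuration
#'
#' Controls the full protocol: split each run (burn-in, training
#' fraction, dilution), align and scale on the training data, train the
#' autoencoder, fit the multivariate Gaussian to the training latent
#' vectors, sample and decode a generated set, and evaluate best-match
#' coverage on a further-diluted test set.
#'
#' @param burn_in_frames initial frames discarded per run.
#' @param train_fraction fraction of post-burn-in frames used for
#'   training.
#' @param train_dilution,test_dilution per-portion frame dilution
#'   applied at the split.
#' @param latent_dim latent dimension; `NULL` applies
#'   [latent_dim_rule()] to the residue count of the input (capping
#'   groups counted).
#' @param epochs,batch_size,loss,learning_rate training controls, see
#'   [training_config()].
#' @param generated_multiple size of the generated set as a multiple of
#'   the (post-split) test-set size; 1 by default.
#' @param eval_dilution dilution of the test set used for best-match
#'   evaluation (evaluation cost grows with test x generated size).
#' @param seed master seed; training and sampling seeds derive from it.
#' @param out_dir directory for artifacts (models, generated ensemble,
#'   reports); `NULL` keeps everything in memory only.
#' @return A `PipelineConfig`.
#' @export
pipeline_config <- function(burn_in_frames = 0L, train_fraction = 0.1,
                            train_dilution = 1L, test_dilution = 1L,
                            latent_dim = NULL, epochs = 100L,
                            batch_size = 40L,
                            loss = "binary_cross_entropy",
                            learning_rate = 1e-3,
                            generated_multiple = 1,
                            eval_dilution = 100L, seed = 1L,
                            out_dir = NULL) {
  stopifnot(generated_multiple > 0)
  structure(list(burn_in_frames = as.integer(burn_in_frames),
                 train_fraction = train_fraction,
                 train_dilution = as.integer(train_dilution),
                 test_dilution = as.integer(test_dilution),
                 latent_dim = latent_dim, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 learning_rate = learning_rate,
                 generated_multiple = generated_multiple,
                 eval_dilution = as.integer(eval_dilution),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

#' Sample the latent Gaussian and decode new conformations
#'
#' Draws `m` latent vectors from the fitted Gaussian, decodes them, and
#' maps the decoder outputs back to real coordinates with the training
#' scaling transform (the same scale factor and shift, inverted).
#' Deterministic given the seed, and prefix-nested: with the same seed,
#' the first rows of a larger generated set equal a smaller one, so
#' expanded generated sets are supersets of smaller ones.
#'
#' @param model an `AutoencoderModel`.
#' @param gaussian a [fit_gaussian()] model on the same latent space.
#' @param scaling the training [fit_scaling()] transform.
#' @param m number of conformations to generate.
#' @param seed integer sampling seed.
#' @param atoms atom table for the resulting ensemble.
#' @return A [conformation_ensemble()] labelled `"generated"`.
#' @export
generate_ensemble <- function(model, gaussian, scaling, m, seed = 1L,
                              atoms) {
  stopifnot(inherits(model, "AutoencoderModel"),
            inherits(gaussian, "GaussianLatentModel"))
  if (model$spec$latent_dim != gaussian$dim)
    stop("model and Gaussian latent dimensions differ")
  z <- sample_gaussian(gaussian, m, seed)
  xyz <- unscale_coords(scaling, decode(model, z))
  conformation_ensemble(xyz, atoms, "generated")
}

# Shared trailing stages: align/scale train, train autoencoder, fit the
# Gaussian, generate, evaluate. `train`/`test` are raw (unaligned) split
# ensembles.
.fit_generate_evaluate <- function(train, test, config) {
  n_res <- length(unique(train$atoms$resno))
  latent_dim <- if (is.null(config$latent_dim)) latent_dim_rule(n_res)
    else as.integer(config$latent_dim)

  train_al <- align_frames(train, 1L)
  ref <- frame_coords(train_al, 1L)
  test <- align_to(test, ref)  # one coordinate frame for all datasets
  scaling <- fit_scaling(train_al)
  spec <- network_spec(3L * n_atoms(train), latent_dim)
  tc <- training_config(config$epochs, config$batch_size, config$loss,
                        config$learning_rate, seed = config$seed)
  model <- train_autoencoder(scale_coords(scaling, train_al$xyz), spec, tc)

  latent_train <- encode(model, scale_coords(scaling, train_al$xyz))
  gaussian <- fit_gaussian(latent_train)

  n_gen <- max(1L, round(config$generated_multiple * n_frames(test)))
  generated <- generate_ensemble(model, gaussian, scaling, n_gen,
                                 seed = config$seed + 1L,
                                 atoms = train$atoms)

  test_eval <- dilute(test, config$eval_dilution)
  report <- best_match_rmsd(test_eval, generated)
  report$metadata <- c(report$metadata, list(
    n_train = n_frames(train), n_test_full = n_frames(test),
    n_generated = n_gen, eval_dilution = config$eval_dilution,
    generated_multiple = config$generated_multiple,
    latent_dim = latent_dim, seed = config$seed))
  report$mean_reconstruction_rmsd <-
    mean_reconstruction_rmsd(model, test_eval, scaling, dilution = 1L)
  report$test_vs_train_best_match <-
    best_match_rmsd(test_eval, train)$best_match_mean

  list(model = model, gaussian = gaussian, scaling = scaling,
       train = train_al, test = test, test_eval = test_eval,
       generated = generated, latent_train = latent_train,
       report = report)
}

.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(result$model, file.path(out_dir, "autoencoder"))
  write_gaussian(result$gaussian, file.path(out_dir, "gaussian.json"))
  write_scaling(result$scaling, file.path(out_dir, "scaling.json"))
  write_ensemble(result$generated, file.path(out_dir, "generated.pdb"),
                 "pdb")
  rep <- result$report
  jsonlite::write_json(list(best_match_mean = rep$best_match_mean,
                            mean_reconstruction_rmsd =
                              rep$mean_reconstruction_rmsd,
                            test_vs_train_best_match =
                              rep$test_vs_train_best_match,
                            metadata = rep$metadata),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(rep$per_conformation,
                     file.path(out_dir, "best_match.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  geo <- geometry_check(subset_frames(result$generated, 1L))
  jsonlite::write_json(list(n_bond_violations = geo$n_bond_violations,
                            n_angle_violations = geo$n_angle_violations,
                            thresholds = geo$thresholds),
                       file.path(out_dir, "geometry_first_generated.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the single-trajectory pipeline
#'
#' Splits one run into training and test portions, trains an
#' autoencoder on the (aligned, scaled) training portion, models its
#' latent vectors with a multivariate Gaussian, generates
#' `generated_multiple` times the test-set size of new conformations,
#' and evaluates the mean best-match RMSD of the diluted test set
#' against the generated set. Also records the reconstruction RMSD and
#' the test-vs-training best-match benchmark.
#'
#' @param run a [conformation_ensemble()] (or path to a PDB/table file).
#' @param config a [pipeline_config()].
#' @return A list with `model`, `gaussian`, `scaling`, `train`, `test`,
#'   `generated` and `report` (an `EvaluationReport`). Artifacts are
#'   written under `config$out_dir` when set.
#' @export
run_single <- function(run, config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(run)) run <- load_ensemble(run)
  run <- select_heavy_atoms(run)
  sp <- split_spec(config$burn_in_frames, config$train_fraction,
                   config$train_dilution, config$test_dilution)
  parts <- split_trajectory(run, sp)
  result <- .fit_generate_evaluate(parts$train, parts$test, config)
  if (!is.null(config$out_dir)) .write_artifacts(result, config$out_dir)
  result
}

#' Run the combined-replicates pipeline
#'
#' Splits each replicate run separately, concatenates the training
#' portions (in input order) and dilutes the combination by
#' `train_dilution`; one autoencoder and one Gaussian are trained on the
#' combined training set. The test portions are concatenated and
#' evaluated after `eval_dilution`. Combining replicates that mined
#' partially overlapping regions of conformational space broadens what
#' the generative model covers.
#'
#' @param runs list of >= 2 [conformation_ensemble()]s with identical
#'   atom tables.
#' @param config a [pipeline_config()]; here `train_dilution` applies to
#'   the combined training set (not within each run).
#' @return As [run_single()].
#' @export
run_combined <- function(runs, config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"), length(runs) >= 2L)
  runs <- lapply(runs, function(r) {
    if (is.character(r)) r <- load_ensemble(r)
    select_heavy_atoms(r)
  })
  at0 <- runs[[1L]]$atoms
  for (r in runs[-1L])
    if (!identical(r$atoms, at0))
      stop("replicate runs have heterogeneous atom tables")
  sp <- split_spec(config$burn_in_frames, config$train_fraction, 1L,
                   config$test_dilution)
  parts <- lapply(runs, split_trajectory, spec = sp)
  train <- dilute(.concat_ensembles(lapply(parts, `[[`, "train"),
                                    "combined_train"),
                  config$train_dilution)
  test <- .concat_ensembles(lapply(parts, `[[`, "test"), "combined_test")
  result <- .fit_generate_evaluate(train, test, config)
  if (!is.null(config$out_dir)) .write_artifacts(result, config$out_dir)
  result
}

.concat_ensembles <- function(sets, label) {
  at0 <- sets[[1L]]$atoms
  for (s in sets[-1L])
    if (!identical(s$atoms, at0)) stop("atom tables differ; cannot pool")
  out <- conformation_ensemble(do.call(rbind, lapply(sets, `[[`, "xyz")),
                               at0, label)
  attr(out, "sources") <- rep(vapply(sets, `[[`, "", "label"),
                              vapply(sets, n_frames, 1L))
  out
}

#' Pool generated (or other) ensembles
#'
#' Concatenates ensembles with identical atom tables, preserving each
#' frame's source label in the `"sources"` attribute. Used e.g. to pool
#' the generated sets of several per-run autoencoders into one larger
#' reference set.
#'
#' @param sets list of [conformation_ensemble()]s.
#' @param label label of the pooled ensemble.
#' @return A [conformation_ensemble()].
#' @export
pool_generated <- function(sets, label = "pooled") {
  stopifnot(length(sets) >= 1L)
  if (length(sets) == 1L) return(sets[[1L]])
  .concat_ensembles(sets, label)
}
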