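#' Latent-space dimension rule
#'
#' The latent dimension is set to 0.75 times the residue count (capping
#' groups counted as residues), rounded to the nearest integer with
#' half-values rounded up: 17 residues give 13, 40 give 30, 64 give 48.
#'
#' @param n_res number of residues (>= 2).
#' @return Integer latent dimension.
#' @export
latent_dim_rule <- function(n_res) {
  stopifnot(n_res >= 2)
  as.integer(floor(0.75 * n_res + 0.5))
}

#' Mirrored dense autoencoder architecture
#'
#' Encoder 3N -> 300 -> 50 -> n and decoder n -> 50 -> 300 -> 3N are
#' mirror images. Every layer uses a rectified-linear activation except
#' the final output layer, which is sigmoidal so outputs live in (0, 1)
#' like the scaled input coordinates. The rectified-linear latent layer
#' means latent vectors are nonnegative and some latent dimensions can
#' die (stay at zero for every input).
#'
#' @param input_dim 3N, the number of input coordinates (divisible by 3).
#' @param latent_dim latent dimension n (default via [latent_dim_rule()]
#'   must be supplied by the caller).
#' @param hidden_dims sizes of the two hidden layers.
#' @return A `NetworkSpec`.
#' @export
network_spec <- function(input_dim, latent_dim, hidden_dims = c(300L, 50L)) {
  stopifnot(input_dim %% 3 == 0, latent_dim >= 1, length(hidden_dims) >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim)),
            class = "NetworkSpec")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 100 epochs, batch size 40,
#' Adam optimisation (step size 1e-3, moment decays 0.9/0.999), binary
#' cross-entropy loss on the scaled coordinates. Mean squared error is
#' available as an alternative loss. Training order is reshuffled every
#' epoch with the seeded generator and the final partial batch is kept.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param loss `"binary_cross_entropy"` or `"mean_squared_error"`.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling weight initialisation and
#'   shuffling; identical seeds and data reproduce training exactly.
#' @return A `TrainingConfig`.
#' @export
training_config <- function(epochs = 100L, batch_size = 40L,
                            loss = c("binary_cross_entropy",
                                     "mean_squared_error"),
                            learning_rate = 1e-3, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Binary cross-entropy reconstruction loss
#'
#' H = (1/3N) sum_i [ -y_i ln y'_i - (1 - y_i) ln(1 - y'_i) ], the mean
#' element-wise cross-entropy between scaled input coordinates y in
#' `[0, 1]` and network outputs y'. Outputs are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param y numeric vector or matrix of targets in `[0, 1]`.
#' @param y_prime numeric vector or matrix of outputs, same shape.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(y, y_prime) {
  if (length(y) != length(y_prime)) stop("dimension mismatch")
  yp <- pmin(pmax(y_prime, 1e-7), 1 - 1e-7)
  mean(-y * log(yp) - (1 - y) * log(1 - yp))
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform Glorot-style fan-based initialisation.
.init_layer <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

.layer_dims <- function(spec) {
  enc <- c(spec$input_dim, spec$hidden_dims, spec$latent_dim)
  dec <- rev(enc)
  list(encoder = enc, decoder = dec)
}

# Forward pass through one stack of dense layers. `final` names the
# activation of the last layer ("relu" for the encoder so the latent
# vector is nonnegative, "sigmoid" for the decoder output).
.forward <- function(layers, X, final) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (j in seq_along(layers)) {
    Z <- sweep(acts[[j]] %*% layers[[j]]$W, 2L, layers[[j]]$b, "+")
    last <- j == length(layers)
    acts[[j + 1L]] <- if (last && final == "sigmoid") .sigmoid(Z)
      else .relu(Z)
  }
  acts
}

#' Train the autoencoder
#'
#' Full-batch data must already be scaled into `[0, 1]` (see
#' [fit_scaling()]). Runs seeded minibatch Adam for the configured number
#' of epochs and records the mean training loss per epoch.
#'
#' @param train_data numeric matrix `[K x 3N]` of scaled coordinates.
#' @param spec a [network_spec()].
#' @param config a [training_config()].
#' @return An `AutoencoderModel` with fields `spec`, `encoder`, `decoder`
#'   (lists of `W`/`b` per layer), `config` and `history` (per-epoch
#'   training loss).
#' @export
train_autoencoder <- function(train_data, spec, config = training_config()) {
  stopifnot(inherits(spec, "NetworkSpec"), inherits(config, "TrainingConfig"))
  train_data <- as.matrix(train_data)
  if (ncol(train_data) != spec$input_dim)
    stop("training data has ", ncol(train_data),
         " columns; spec expects ", spec$input_dim)
  if (min(train_data) < -1e-9 || max(train_data) > 1 + 1e-9)
    stop("training values must lie in [0, 1]; scale them first")

  dims <- .layer_dims(spec)
  K <- nrow(train_data)
  use_bce <- config$loss == "binary_cross_entropy"

  withr::with_seed(config$seed, {
    enc <- lapply(seq_len(length(dims$encoder) - 1L), function(j)
      .init_layer(dims$encoder[j], dims$encoder[j + 1L]))
    dec <- lapply(seq_len(length(dims$decoder) - 1L), function(j)
      .init_layer(dims$decoder[j], dims$decoder[j + 1L]))
    layers <- c(enc, dec)
    n_enc <- length(enc)
    L <- length(layers)

    # Adam state per parameter tensor
    mW <- lapply(layers, function(l) l$W * 0)
    vW <- mW
    mb <- lapply(layers, function(l) l$b * 0)
    vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    t <- 0L

    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(K)
      starts <- seq.int(1L, K, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, K)]
        Y <- train_data[rows, , drop = FALSE]
        B <- nrow(Y)

        acts <- .forward(layers, Y, final = "sigmoid")
        out <- acts[[L + 1L]]
        loss <- if (use_bce) bce_loss(Y, out) else mean((out - Y)^2)
        if (!is.finite(loss))
          stop("loss became non-finite at epoch ", epoch, "; aborting")
        ep_loss <- ep_loss + loss * B

        # Backward pass. For sigmoid + BCE the output-layer gradient
        # collapses to (out - Y); for MSE it is 2(out - Y) times the
        # sigmoid derivative.
        delta <- if (use_bce) (out - Y) / length(Y)
          else 2 * (out - Y) * out * (1 - out) / length(Y)
        for (j in rev(seq_len(L))) {
          gW <- crossprod(acts[[j]], delta)
          gb <- colSums(delta)
          if (j > 1L) {
            delta <- delta %*% t(layers[[j]]$W)
            delta[acts[[j]] <= 0] <- 0  # ReLU gate
          }
          mW[[j]] <- b1 * mW[[j]] + (1 - b1) * gW
          vW[[j]] <- b2 * vW[[j]] + (1 - b2) * gW^2
          mb[[j]] <- b1 * mb[[j]] + (1 - b1) * gb
          vb[[j]] <- b2 * vb[[j]] + (1 - b2) * gb^2
        }
        t <- t + 1L
        corr1 <- 1 - b1^t
        corr2 <- 1 - b2^t
        for (j in seq_len(L)) {
          layers[[j]]$W <- layers[[j]]$W -
            lr * (mW[[j]] / corr1) / (sqrt(vW[[j]] / corr2) + eps)
          layers[[j]]$b <- layers[[j]]$b -
            lr * (mb[[j]] / corr1) / (sqrt(vb[[j]] / corr2) + eps)
        }
      }
      history[epoch] <- ep_loss / K
    }

    structure(list(spec = spec, encoder = layers[seq_len(n_enc)],
                   decoder = layers[(n_enc + 1L):L], config = config,
                   history = history),
              class = "AutoencoderModel")
  })
}

#' Encode scaled coordinates to latent vectors
#'
#' Deterministic forward pass through the encoder. The rectified-linear
#' latent layer guarantees nonnegative entries.
#'
#' @param model an `AutoencoderModel`.
#' @param scaled_coords numeric matrix `[K x 3N]` (or a single vector).
#' @return Numeric matrix `[K x n]` of latent vectors.
#' @export
encode <- function(model, scaled_coords) {
  X <- .as_batch(scaled_coords, model$spec$input_dim, "input")
  acts <- .forward(model$encoder, X, final = "relu")
  acts[[length(acts)]]
}

#' Decode latent vectors to scaled coordinates
#'
#' Deterministic forward pass through the decoder; outputs are in (0, 1)
#' (sigmoid output layer) and must be passed through [unscale_coords()]
#' to obtain real Angstrom coordinates.
#'
#' @param model an `AutoencoderModel`.
#' @param latent_vectors numeric matrix `[K x n]` (or a single vector).
#' @return Numeric matrix `[K x 3N]` of scaled coordinates.
#' @export
decode <- function(model, latent_vectors) {
  Z <- .as_batch(latent_vectors, model$spec$latent_dim, "latent")
  acts <- .forward(model$decoder, Z, final = "sigmoid")
  acts[[length(acts)]]
}

.as_batch <- function(x, dim_needed, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != dim_needed)
    stop(what, " dimension mismatch: got ", ncol(x),
         ", expected ", dim_needed)
  x
}

#' Save / load an autoencoder
#'
#' Writes two self-describing JSON files, `<stem>_encoder.json` and
#' `<stem>_decoder.json` (layer dimensions plus full-precision weights),
#' and a manifest `<stem>_manifest.json` with the architecture, training
#' configuration and loss history. A round trip reproduces encoder and
#' decoder outputs to within 1e-6.
#'
#' @param model an `AutoencoderModel`.
#' @param stem path prefix for the three files.
#' @return For `save_model`, `stem` invisibly; for `load_model`, the
#'   restored `AutoencoderModel`.
#' @export
save_model <- function(model, stem) {
  ser <- function(layers) lapply(layers, function(l)
    list(dim = dim(l$W), W = as.numeric(l$W), b = l$b))
  jsonlite::write_json(ser(model$encoder),
                       paste0(stem, "_encoder.json"), digits = NA)
  jsonlite::write_json(ser(model$decoder),
                       paste0(stem, "_decoder.json"), digits = NA)
  manifest <- list(spec = unclass(model$spec),
                   config = unclass(model$config),
                   history = model$history)
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname save_model
#' @export
load_model <- function(stem) {
  des <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(raw, function(l) {
      d <- as.integer(unlist(l$dim))
      list(W = matrix(as.numeric(unlist(l$W)), d[1L], d[2L]),
           b = as.numeric(unlist(l$b)))
    })
  }
  man <- jsonlite::read_json(paste0(stem, "_manifest.json"),
                             simplifyVector = TRUE)
  spec <- network_spec(man$spec$input_dim, man$spec$latent_dim,
                       man$spec$hidden_dims)
  config <- training_config(man$config$epochs, man$config$batch_size,
                            man$config$loss, man$config$learning_rate,
                            man$config$seed)
  enc <- des(paste0(stem, "_encoder.json"))
  dec <- des(paste0(stem, "_decoder.json"))
  dims <- .layer_dims(spec)
  for (j in seq_along(enc))
    if (!all(dim(enc[[j]]$W) == dims$encoder[c(j, j + 1L)]))
      stop("encoder file does not match the declared architecture")
  for (j in seq_along(dec))
    if (!all(dim(dec[[j]]$W) == dims$decoder[c(j, j + 1L)]))
      stop("decoder file does not match the declared architecture")
  structure(list(spec = spec, encoder = enc, decoder = dec,
                 config = config, history = man$history),
            class = "AutoencoderModel")
}

#' @export
print.AutoencoderModel <- function(x, ...) {
  d <- .layer_dims(x$spec)
  cat("AutoencoderModel: ", paste(d$encoder, collapse = " -> "),
      " -> ", paste(d$decoder[-1L], collapse = " -> "), "\n", sep = "")
  if (length(x$history))
    cat("final training loss: ", format(x$history[length(x$history)]),
        " after ", length(x$history), " epochs\n", sep = "")
  invisible(x)
}
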