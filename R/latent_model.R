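#' Fit a multivariate Gaussian to latent vectors
#'
#' The mean is the plain average of the training latent vectors and the
#' covariance the plain (population, 1/K) average of outer products of
#' deviations. Dead rectified-linear dimensions (constant at zero)
#' produce zero rows/columns; the covariance is symmetrised and kept as
#' is, with degeneracy handled at sampling time.
#'
#' @param latent numeric matrix `[K x n]` of latent vectors, K >= 2.
#' @return A `GaussianLatentModel` with fields `mean`, `covariance`,
#'   `dim` and `n_obs`.
#' @export
fit_gaussian <- function(latent) {
  latent <- as.matrix(latent)
  K <- nrow(latent)
  if (K < 2L) stop("need at least two latent vectors")
  mu <- colMeans(latent)
  dev <- sweep(latent, 2L, mu)
  sigma <- crossprod(dev) / K
  sigma <- (sigma + t(sigma)) / 2
  structure(list(mean = mu, covariance = sigma, dim = ncol(latent),
                 n_obs = K),
            class = "GaussianLatentModel")
}

#' @export
print.GaussianLatentModel <- function(x, ...) {
  cat("GaussianLatentModel: dim ", x$dim, ", fitted on ", x$n_obs,
      " vectors\n", sep = "")
  invisible(x)
}

# Eigendecomposition with small negative eigenvalues clipped to zero;
# errors if an eigenvalue is materially negative (not a covariance).
.cov_eigen <- function(sigma, neg_tol = 1e-8) {
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  scale_ref <- max(abs(e$values), 1)
  if (min(e$values) < -neg_tol * scale_ref)
    stop("covariance has a substantially negative eigenvalue")
  e$values[e$values < 0] <- 0
  e
}

#' Sample latent vectors from a fitted Gaussian
#'
#' Sampling goes through the eigendecomposition of the covariance with
#' negative eigenvalues clipped to zero, so a degenerate Gaussian (dead
#' latent dimensions) is sampled exactly at its mean along the dead
#' directions. Draws are generated row by row from one seeded stream, so
#' for a fixed seed the first m rows of a larger sample equal the
#' smaller sample (prefix-nested sampling, up to floating-point
#' round-off from batched linear algebra).
#'
#' @param model a [fit_gaussian()] result.
#' @param m number of vectors to draw.
#' @param seed integer seed.
#' @return Numeric matrix `[m x n]`.
#' @export
sample_gaussian <- function(model, m, seed = 1L) {
  stopifnot(inherits(model, "GaussianLatentModel"), m >= 1)
  e <- .cov_eigen(model$covariance)
  A <- e$vectors %*% diag(sqrt(e$values), model$dim)
  withr::with_seed(as.integer(seed), {
    Z <- matrix(stats::rnorm(m * model$dim), m, model$dim, byrow = TRUE)
  })
  sweep(Z %*% t(A), 2L, model$mean, "+")
}

#' Indices of active latent dimensions
#'
#' A rectified-linear latent layer leaves some output neurons at (or
#' numerically near) zero for every conformation; these dead dimensions
#' carry no information. A dimension is active when the largest absolute
#' value observed across the set exceeds `tol`.
#'
#' @param latent numeric matrix `[K x n]`.
#' @param tol activity threshold in latent units.
#' @return Integer vector of active dimension indices (possibly empty).
#' @export
active_dimensions <- function(latent, tol = 1e-3) {
  latent <- as.matrix(latent)
  which(apply(abs(latent), 2L, max) > tol)
}

#' Multivariate Gaussian density
#'
#' Standard multivariate normal density with exponent
#' -(1/2) (z - mu)^T sigma^{-1} (z - mu) and normaliser
#' ((2 pi)^n det sigma)^{-1/2}. With `subspace = TRUE` a singular
#' covariance is handled on its positive-eigenvalue subspace
#' (pseudo-inverse and pseudo-determinant); the density is zero for
#' points off the support. Without it, a singular covariance is an
#' error.
#'
#' @param model a [fit_gaussian()] result.
#' @param z numeric n-vector.
#' @param subspace evaluate degenerate models on their active subspace.
#' @return Nonnegative density value.
#' @export
gaussian_density <- function(model, z, subspace = FALSE) {
  stopifnot(inherits(model, "GaussianLatentModel"),
            length(z) == model$dim)
  e <- .cov_eigen(model$covariance)
  pos <- e$values > 1e-12 * max(e$values, 1)
  d <- z - model$mean
  if (!all(pos)) {
    if (!subspace)
      stop("singular covariance; set subspace = TRUE to evaluate on ",
           "the active subspace")
    resid <- e$vectors[, !pos, drop = FALSE]
    if (any(abs(crossprod(resid, d)) > 1e-8)) return(0)
  }
  w <- crossprod(e$vectors[, pos, drop = FALSE], d)
  expo <- -0.5 * sum(w^2 / e$values[pos])
  lognorm <- -0.5 * (sum(pos) * log(2 * pi) + sum(log(e$values[pos])))
  exp(lognorm + expo)
}

#' Two-dimensional latent histogram
#'
#' Counts latent vectors on a uniform `bins x bins` grid over one pair
#' of latent dimensions. When two sets are to be compared (e.g. training
#' vs generated), pass the same `range` to both calls — see
#' [shared_range()] — because KL divergence requires identical grids.
#'
#' @param latent numeric matrix `[K x n]`.
#' @param pair length-2 integer vector of distinct latent dimensions.
#' @param bins number of bins per axis.
#' @param range optional `list(x = c(lo, hi), y = c(lo, hi))`; default is
#'   the data range per axis padded by 1%.
#' @return A `Histogram2D` with fields `dims`, `xedges`, `yedges`,
#'   `counts` (integer matrix) and `normalized` (sums to 1).
#' @export
histogram2d <- function(latent, pair, bins = 50L, range = NULL) {
  latent <- as.matrix(latent)
  if (nrow(latent) < 1L) stop("empty latent set")
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L],
            all(pair >= 1L), all(pair <= ncol(latent)))
  x <- latent[, pair[1L]]
  y <- latent[, pair[2L]]
  if (is.null(range)) range <- list(x = .padded_range(x),
                                    y = .padded_range(y))
  xe <- seq(range$x[1L], range$x[2L], length.out = bins + 1L)
  ye <- seq(range$y[1L], range$y[2L], length.out = bins + 1L)
  ix <- .bin_index(x, xe)
  iy <- .bin_index(y, ye)
  counts <- matrix(0L, bins, bins)
  ok <- !is.na(ix) & !is.na(iy)
  for (k in which(ok)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  total <- sum(counts)
  if (total == 0L) stop("no points fall inside the histogram range")
  structure(list(dims = as.integer(pair), xedges = xe, yedges = ye,
                 counts = counts, normalized = counts / total),
            class = "Histogram2D")
}

.padded_range <- function(v) {
  r <- range(v)
  pad <- max(diff(r), 1e-12) * 0.01
  c(r[1L] - pad, r[2L] + pad)
}

# Uniform-grid bin index; points exactly on the top edge land in the
# last bin, points outside the range are NA (dropped).
.bin_index <- function(v, edges) {
  nb <- length(edges) - 1L
  i <- floor((v - edges[1L]) / (edges[nb + 1L] - edges[1L]) * nb) + 1L
  i[v == edges[nb + 1L]] <- nb
  i[i < 1L | i > nb] <- NA_integer_
  as.integer(i)
}

#' Shared histogram range for comparing two latent sets
#'
#' Union of the per-axis ranges of both sets, padded by 1%, for use as
#' the `range` argument of [histogram2d()] on each set.
#'
#' @param a,b numeric latent matrices.
#' @param pair length-2 dimension pair.
#' @return `list(x = , y = )` of ranges.
#' @export
shared_range <- function(a, b, pair) {
  a <- as.matrix(a); b <- as.matrix(b)
  list(x = .padded_range(c(a[, pair[1L]], b[, pair[1L]])),
       y = .padded_range(c(a[, pair[2L]], b[, pair[2L]])))
}

#' Kullback-Leibler divergence between two 2-D histograms
#'
#' Both histograms are normalised to probabilities and the divergence is
#' the grid sum of p ln(p/q). Any grid cell where either p or q is zero
#' contributes nothing (the zero rule), so the result can underestimate
#' the divergence of distributions with poorly overlapping support —
#' two disjoint histograms give 0. Report KL values together with the
#' bin count used.
#'
#' @param p,q `Histogram2D` objects on identical grids.
#' @return Scalar divergence (0 when p = q).
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "Histogram2D"), inherits(q, "Histogram2D"))
  if (!isTRUE(all.equal(p$xedges, q$xedges)) ||
      !isTRUE(all.equal(p$yedges, q$yedges)))
    stop("histograms are on different grids")
  pp <- p$normalized
  qq <- q$normalized
  keep <- pp > 0 & qq > 0
  sum(pp[keep] * log(pp[keep] / qq[keep]))
}

#' Write a 2-D histogram as a TSV grid
#' @param hist a [histogram2d()] result.
#' @param path output file.
#' @param what `"counts"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, what = c("counts", "normalized")) {
  what <- match.arg(what)
  utils::write.table(hist[[what]], path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Save / load a Gaussian latent model as JSON
#' @param model a `GaussianLatentModel`.
#' @param path JSON file path.
#' @return The model (for `read_gaussian`), or `path` invisibly.
#' @export
write_gaussian <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean,
                            covariance = as.numeric(model$covariance),
                            dim = model$dim, n_obs = model$n_obs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaussian
#' @export
read_gaussian <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean,
                 covariance = matrix(x$covariance, x$dim, x$dim),
                 dim = as.integer(x$dim), n_obs = as.integer(x$n_obs)),
            class = "GaussianLatentModel")
}

# Log-density for mixture EM, with a small ridge for numerical safety.
.mvn_logdens <- function(latent, mu, sigma, ridge = 1e-8) {
  n <- length(mu)
  e <- .cov_eigen(sigma + diag(ridge, n))
  dev <- sweep(latent, 2L, mu)
  w <- dev %*% e$vectors
  -0.5 * (n * log(2 * pi) + sum(log(e$values))) -
    0.5 * rowSums(sweep(w^2, 2L, e$values, "/"))
}

#' Fit a mixture of Gaussians to latent vectors
#'
#' Expectation-maximisation with seeded k-means initialisation, at most
#' `max_iter` iterations and a relative log-likelihood tolerance of
#' `tol`. With `k = 1` the fit reduces exactly to [fit_gaussian()]. A
#' multi-peaked latent distribution (e.g. several conformational basins)
#' may be modelled better by a mixture than by one Gaussian.
#'
#' @param latent numeric matrix `[K x n]`, K >= k.
#' @param k number of components.
#' @param seed integer seed for the initialisation.
#' @param max_iter,tol EM stopping controls.
#' @return A `GaussianMixtureModel`: `weights` (sum to 1), `components`
#'   (list of `GaussianLatentModel`), `loglik`, `converged`.
#' @export
fit_gaussian_mixture <- function(latent, k, seed = 1L, max_iter = 200L,
                                 tol = 1e-6) {
  latent <- as.matrix(latent)
  K <- nrow(latent)
  stopifnot(k >= 1L, K >= k)
  if (k == 1L) {
    g <- fit_gaussian(latent)
    ll <- sum(.mvn_logdens(latent, g$mean, g$covariance))
    return(structure(list(weights = 1, components = list(g), loglik = ll,
                          converged = TRUE),
                     class = "GaussianMixtureModel"))
  }
  n <- ncol(latent)
  withr::with_seed(as.integer(seed), {
    km <- stats::kmeans(latent, centers = k, nstart = 5L)
  })
  resp <- matrix(0, K, k)
  resp[cbind(seq_len(K), km$cluster)] <- 1

  loglik_old <- -Inf
  converged <- FALSE
  weights <- rep(1 / k, k)
  mus <- vector("list", k)
  sigmas <- vector("list", k)
  for (iter in seq_len(max_iter)) {
    # M step (population-weighted moments)
    nk <- colSums(resp)
    weights <- nk / K
    for (j in seq_len(k)) {
      r <- resp[, j]
      mus[[j]] <- colSums(latent * r) / nk[j]
      dev <- sweep(latent, 2L, mus[[j]])
      sigmas[[j]] <- crossprod(dev * r, dev) / nk[j]
      sigmas[[j]] <- (sigmas[[j]] + t(sigmas[[j]])) / 2
    }
    # E step
    logd <- vapply(seq_len(k), function(j)
      log(weights[j]) + .mvn_logdens(latent, mus[[j]], sigmas[[j]]),
      numeric(K))
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    resp <- exp(logd - lse)
    loglik <- sum(lse)
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) <= tol * (abs(loglik_old) + 1e-12)) {
      converged <- TRUE
      loglik_old <- loglik
      break
    }
    loglik_old <- loglik
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations; returning the best fit so far")
  comps <- lapply(seq_len(k), function(j)
    structure(list(mean = mus[[j]], covariance = sigmas[[j]], dim = n,
                   n_obs = K),
              class = "GaussianLatentModel"))
  structure(list(weights = weights, components = comps,
                 loglik = loglik_old, converged = converged),
            class = "GaussianMixtureModel")
}
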