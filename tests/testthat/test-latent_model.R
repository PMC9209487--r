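test_that("Gaussian fitting uses plain population moments", {
  g <- fit_gaussian(rbind(c(0, 0), c(2, 2)))
  expect_equal(g$mean, c(1, 1))
  expect_equal(g$covariance, matrix(1, 2, 2))

  same <- fit_gaussian(matrix(3, 5, 2))
  expect_equal(same$covariance, matrix(0, 2, 2))
  expect_error(fit_gaussian(matrix(1, 1, 2)), "two")

  # closure: refitting a large sample of a model's own draws recovers it
  mu <- c(1, -2, 0.5)
  A <- matrix(c(1, 0.3, 0, 0.3, 2, -0.4, 0, -0.4, 1.5), 3)
  sig <- crossprod(A)
  model <- structure(list(mean = mu, covariance = sig, dim = 3L,
                          n_obs = 0L), class = "GaussianLatentModel")
  z <- sample_gaussian(model, 50000, seed = 21)
  refit <- fit_gaussian(z)
  se <- sqrt(diag(sig) / 50000)
  expect_true(all(abs(refit$mean - mu) < 4 * se))
  expect_lt(max(abs(refit$covariance - sig) / max(abs(sig))), 0.05)
})

test_that("Gaussian sampling is seeded, degenerate-safe, prefix-nested", {
  flat <- structure(list(mean = c(2, 3), covariance = matrix(0, 2, 2),
                         dim = 2L, n_obs = 0L),
                    class = "GaussianLatentModel")
  z <- sample_gaussian(flat, 5, seed = 1)
  expect_true(all(z[, 1] == 2 & z[, 2] == 3))

  g <- fit_gaussian(matrix(rnorm(400), 100, 4))
  expect_identical(sample_gaussian(g, 50, seed = 3),
                   sample_gaussian(g, 50, seed = 3))
  big <- sample_gaussian(g, 80, seed = 3)
  expect_equal(big[1:50, ], sample_gaussian(g, 50, seed = 3),
               tolerance = 1e-12)

  bad <- g
  bad$covariance[1, 1] <- -1
  expect_error(sample_gaussian(bad, 5), "negative eigenvalue")
})

test_that("active dimensions are those exceeding the tolerance", {
  z <- cbind(rep(0, 10), rnorm(10), rep(1e-5, 10))
  expect_equal(active_dimensions(z), 2L)
  expect_length(active_dimensions(matrix(0, 4, 3)), 0)
  expect_equal(active_dimensions(z, tol = 1e-6), c(2L, 3L))
})

test_that("Gaussian density matches the closed form and integrates to 1", {
  iso <- structure(list(mean = c(0, 0), covariance = diag(2), dim = 2L,
                        n_obs = 0L), class = "GaussianLatentModel")
  expect_equal(gaussian_density(iso, c(0, 0)), 1 / (2 * pi),
               tolerance = 1e-12)

  g <- structure(list(mean = c(1, -1),
                      covariance = matrix(c(1, 0.5, 0.5, 2), 2),
                      dim = 2L, n_obs = 0L),
                 class = "GaussianLatentModel")
  # quadrature over a wide grid
  s <- seq(-9, 9, length.out = 301)
  h <- s[2] - s[1]
  total <- sum(outer(s, s, Vectorize(function(x, y)
    gaussian_density(g, c(x, y))))) * h^2
  expect_equal(total, 1, tolerance = 1e-3)

  # mode at the mean
  set.seed(6)
  dens_mode <- gaussian_density(g, g$mean)
  for (i in 1:20)
    expect_gte(dens_mode, gaussian_density(g, g$mean + rnorm(2)))

  # singular covariance needs the subspace flag
  sing <- structure(list(mean = c(0, 0),
                         covariance = diag(c(1, 0)), dim = 2L,
                         n_obs = 0L), class = "GaussianLatentModel")
  expect_error(gaussian_density(sing, c(0, 0)), "singular")
  on_support <- gaussian_density(sing, c(0.5, 0), subspace = TRUE)
  expect_equal(on_support, exp(-0.125) / sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(gaussian_density(sing, c(0, 1), subspace = TRUE), 0)
})

test_that("2-D histograms bin on a shared uniform grid", {
  z <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  h <- histogram2d(z, c(1, 2), bins = 2,
                   range = list(x = c(-2, 2), y = c(-2, 2)))
  expect_true(all(h$counts == 1))
  expect_equal(sum(h$counts), 4)
  expect_equal(sum(h$normalized), 1, tolerance = 1e-12)

  set.seed(7)
  z2 <- matrix(rnorm(2e5), ncol = 2)
  h2 <- histogram2d(z2, c(1, 2), bins = 50)
  # the mode bin sits at the origin up to binning noise
  peak <- which(h2$counts == max(h2$counts), arr.ind = TRUE)[1, ]
  wx <- diff(h2$xedges[1:2])
  wy <- diff(h2$yedges[1:2])
  expect_lt(abs(mean(h2$xedges[peak[1] + 0:1])), 3 * wx)
  expect_lt(abs(mean(h2$yedges[peak[2] + 0:1])), 3 * wy)
  expect_equal(sum(h2$counts), 1e5)

  expect_error(histogram2d(z, c(2, 2), 2), "pair")
})

test_that("KL divergence obeys the zero-bin rule and vanishes at p = q", {
  set.seed(8)
  a <- matrix(rnorm(4000), ncol = 2)
  ha <- histogram2d(a, c(1, 2), bins = 20)
  expect_identical(kl_divergence(ha, ha), 0)

  # disjoint supports: every term is dropped by the zero rule
  b <- matrix(rnorm(4000, mean = 100), ncol = 2)
  rg <- shared_range(a, b, c(1, 2))
  ha2 <- histogram2d(a, c(1, 2), bins = 20, range = rg)
  hb2 <- histogram2d(b, c(1, 2), bins = 20, range = rg)
  expect_identical(kl_divergence(ha2, hb2), 0)

  # mismatched grids are refused
  hb3 <- histogram2d(b, c(1, 2), bins = 20)
  expect_error(kl_divergence(ha, hb3), "grids")

  # asymmetry is tolerated: both directions are finite and nonnegative
  c2 <- matrix(rnorm(4000, mean = 0.5), ncol = 2)
  rg2 <- shared_range(a, c2, c(1, 2))
  hc <- histogram2d(c2, c(1, 2), bins = 20, range = rg2)
  ha3 <- histogram2d(a, c(1, 2), bins = 20, range = rg2)
  expect_gte(kl_divergence(ha3, hc), 0)
  expect_gte(kl_divergence(hc, ha3), 0)
})

test_that("mixture EM reduces to one Gaussian and separates clusters", {
  set.seed(9)
  z <- matrix(rnorm(300), ncol = 3)
  m1 <- fit_gaussian_mixture(z, k = 1)
  g <- fit_gaussian(z)
  expect_equal(m1$components[[1]]$mean, g$mean, tolerance = 1e-8)
  expect_equal(m1$components[[1]]$covariance, g$covariance,
               tolerance = 1e-8)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-12)

  mu_a <- c(0, 0)
  mu_b <- c(8, 8)
  z2 <- rbind(sweep(matrix(rnorm(800, sd = 0.7), ncol = 2), 2, mu_a, "+"),
              sweep(matrix(rnorm(600, sd = 0.7), ncol = 2), 2, mu_b, "+"))
  m2 <- fit_gaussian_mixture(z2, k = 2, seed = 5)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-12)
  means <- t(vapply(m2$components, `[[`, numeric(2), "mean"))
  ord <- order(means[, 1])
  expect_lt(max(abs(means[ord[1], ] - mu_a)), 0.1)
  expect_lt(max(abs(means[ord[2], ] - mu_b)), 0.1)
})

test_that("latent vectors of a trained model behave as expected", {
  fx <- fix_trained_model()
  z <- encode(fx$model, fx$scaled)
  act <- active_dimensions(z)
  expect_gt(length(act), 0)
  # test-set latents fall inside the training Gaussian's support region
  g <- fit_gaussian(z[, act, drop = FALSE])
  zt <- encode(fx$model, scale_coords(fx$scaling, fx$test$xyz))
  zt <- zt[, act, drop = FALSE]
  e <- eigen(g$covariance, symmetric = TRUE)
  keep <- e$values > 1e-10
  w <- sweep(zt, 2, g$mean) %*% e$vectors[, keep, drop = FALSE]
  d2 <- rowSums(sweep(w^2, 2, e$values[keep], "/"))
  thresh <- qchisq(0.999, df = sum(keep))
  expect_gt(mean(d2 < thresh), 0.5)
})
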