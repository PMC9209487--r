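test_that("pairwise RMSD agrees with the quaternion oracle", {
  set.seed(10)
  tpl <- fix_template()
  a <- frame_coords(tpl)
  expect_equal(rmsd(a, a), 0)

  # rigid motion is removed exactly
  b <- a %*% random_rotation()
  b <- sweep(b, 2, c(5, -3, 2), "+")
  expect_lt(rmsd(a, b), 1e-9)

  # random pairs match Horn's method
  for (i in 1:25) {
    n <- sample(4:30, 1)
    x <- matrix(rnorm(3 * n), n)
    y <- matrix(rnorm(3 * n), n)
    expect_lt(abs(rmsd(x, y) - oracle_rmsd(x, y)), 1e-9)
  }

  # symmetry and the frame-major vector interface
  x <- matrix(rnorm(30), 10)
  y <- matrix(rnorm(30), 10)
  expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-12)
  expect_equal(rmsd(as.vector(t(x)), as.vector(t(y))), rmsd(x, y))
  expect_error(rmsd(x[1:2, ], y[1:2, ]), "three")
  expect_error(rmsd(x, y[1:5, ]), "differ")
})

test_that("best-match RMSD is the exhaustive minimum with stable ties", {
  set.seed(11)
  tpl <- fix_template()
  test <- conformation_ensemble(fix_random_frames(8, tpl), tpl$atoms)
  ref <- conformation_ensemble(fix_random_frames(20, tpl), tpl$atoms)

  rep1 <- best_match_rmsd(test, ref)
  # brute-force double loop with the independent oracle
  for (i in 1:8) {
    per <- sapply(1:20, function(j)
      oracle_rmsd(frame_coords(test, i), frame_coords(ref, j)))
    expect_lt(abs(rep1$per_conformation$rmsd[i] - min(per)), 1e-9)
    expect_equal(rep1$per_conformation$match_index[i], which.min(per))
  }
  expect_equal(rep1$best_match_mean, mean(rep1$per_conformation$rmsd))

  # a reference containing the test set matches at zero
  sup <- pool_generated(list(ref, test))
  expect_lt(best_match_rmsd(test, sup)$best_match_mean, 1e-9)

  # enlarging the reference never hurts any per-conformation minimum
  small <- subset_frames(ref, 1:10)
  r_small <- best_match_rmsd(test, small)$per_conformation$rmsd
  expect_true(all(rep1$per_conformation$rmsd <= r_small + 1e-12))

  expect_error(best_match_rmsd(test, subset_frames(ref, 1)$xyz[, 1:9]))
})

test_that("diversity and within-set benchmarks match exhaustive loops", {
  set.seed(12)
  tpl <- fix_template()
  xyz <- fix_random_frames(10, tpl)
  set <- conformation_ensemble(xyz, tpl$atoms)

  m <- matrix(0, 10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    m[i, j] <- oracle_rmsd(frame_coords(set, i), frame_coords(set, j))
  m <- m + t(m)
  expect_lt(abs(pairwise_diversity(set) - mean(m[upper.tri(m)])), 1e-9)
  diag(m) <- Inf
  expect_lt(abs(within_set_best_match(set) - mean(apply(m, 1, min))),
            1e-9)
  expect_lte(within_set_best_match(set), pairwise_diversity(set))

  same <- conformation_ensemble(xyz[c(1, 1, 1), ], tpl$atoms)
  expect_lt(pairwise_diversity(same), 1e-12)
  two <- subset_frames(set, 1:2)
  expect_equal(pairwise_diversity(two),
               rmsd(frame_coords(two, 1), frame_coords(two, 2)))
  dup <- conformation_ensemble(xyz[rep(1:5, each = 2), ], tpl$atoms)
  expect_lt(within_set_best_match(dup), 1e-12)
  expect_error(pairwise_diversity(subset_frames(set, 1)), "two")
})

test_that("reconstruction RMSD is translation-invariant and subsample-stable", {
  fx <- fix_trained_model()
  r1 <- mean_reconstruction_rmsd(fx$model, fx$test, fx$scaling, 30)
  shifted <- conformation_ensemble(fx$test$xyz + 2, fx$test$atoms)
  r2 <- mean_reconstruction_rmsd(fx$model, shifted, fx$scaling, 30)
  expect_equal(r1, r2, tolerance = 1e-6)
  # dilution only subsamples: means agree within sampling noise
  r_all <- mean_reconstruction_rmsd(fx$model, fx$test, fx$scaling, 1)
  expect_lt(abs(r1 - r_all) / r_all, 0.10)
})

test_that("series error metrics match their definitions", {
  e <- c(1, 2, 4, 8)
  expect_equal(mape(e, e), 0)
  expect_equal(mape(1.1 * e, e), 10, tolerance = 1e-12)
  expect_equal(rmse(e, e), 0)
  expect_equal(rmse(e + 3, e), 3)
  set.seed(13)
  o <- rnorm(50)
  x <- rnorm(50, mean = 5)
  expect_equal(mape(o, x), mean(abs(o - x) / abs(x)) * 100,
               tolerance = 1e-12)
  expect_equal(rmse(o, x), sqrt(mean((o - x)^2)), tolerance = 1e-12)
  expect_error(mape(o, c(x[-1], 0)), "nonzero")
  expect_error(rmse(o, x[-1]), "mismatch")
})

test_that("geometry audit flags exactly the injected violations", {
  tpl <- fix_template()
  clean <- geometry_check(tpl)
  expect_equal(clean$n_bond_violations, 0)
  expect_equal(clean$n_angle_violations, 0)

  # stretch one CA-C bond to twice its ideal length
  at <- tpl$atoms
  conf <- frame_coords(tpl)
  i_ca <- which(at$resno == 5 & at$elety == "CA")
  i_c <- which(at$resno == 5 & at$elety == "C")
  v <- conf[i_c, ] - conf[i_ca, ]
  # translate C, its carbonyl O and every later residue by one extra
  # bond vector: only the CA-C bond stretches (to 2x ideal); all other
  # bonds and all audited angles are preserved
  move <- c(i_c, which(at$resno == 5 & at$elety == "O"),
            which(at$resno > 5))
  conf2 <- conf
  conf2[move, ] <- sweep(conf[move, , drop = FALSE], 2, v, "+")
  rep2 <- geometry_check(conf2, at)
  expect_equal(rep2$n_angle_violations, 0)
  expect_equal(rep2$n_bond_violations, 1)
  expect_equal(rep2$bonds$atom_a, "5/CA")
  expect_equal(rep2$bonds$atom_b, "5/C")

  # random perturbations: bond-violation count equals the oracle scan
  set.seed(14)
  for (i in 1:5) {
    pert <- conf + matrix(rnorm(length(conf), sd = 0.25), ncol = 3)
    got <- geometry_check(pert, at)$n_bond_violations
    expect_equal(got, oracle_bond_violations(pert, at))
  }

  # unknown residues are skipped with a warning
  at2 <- at
  at2$resid[at2$resno == 3] <- "XYZ"
  expect_warning(geometry_check(conf, at2), "template")
})
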