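test_that("PDB and table round trips preserve frames, atoms, coordinates", {
  set.seed(1)
  tpl <- fix_template()
  xyz <- fix_random_frames(3, tpl, sd = 0.5)
  ens <- conformation_ensemble(xyz, tpl$atoms, "toy")

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb, "pdb")
  back <- load_ensemble(pdb, "pdb")
  expect_equal(n_frames(back), 3)
  expect_equal(n_atoms(back), n_atoms(ens))
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-12)

  tab <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble(ens, tab, "table")
  back2 <- load_ensemble(tab, "table")
  expect_equal(back2$xyz, ens$xyz, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(back2$atoms$resno, ens$atoms$resno)

  # single frame still writes a well-formed model
  one <- subset_frames(ens, 1)
  write_ensemble(one, pdb, "pdb")
  expect_equal(n_frames(load_ensemble(pdb)), 1)
})

test_that("malformed inputs are rejected", {
  tpl <- fix_template()
  expect_error(conformation_ensemble(tpl$xyz, tpl$atoms[-1, ]), "atoms")
  expect_error(conformation_ensemble(tpl$xyz * NA, tpl$atoms), "finite")
  # PDB whose second model has fewer atoms
  lines <- c("MODEL        1",
             sprintf("ATOM  %5d  %-3s GLN A   1    %8.3f%8.3f%8.3f  1.00  0.00",
                     1:4, c("N", "CA", "C", "O"), 1:4, 1:4, 1:4),
             "ENDMDL", "MODEL        2",
             sprintf("ATOM  %5d  %-3s GLN A   1    %8.3f%8.3f%8.3f  1.00  0.00",
                     1:3, c("N", "CA", "C"), 1:3, 1:3, 1:3),
             "ENDMDL", "END")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(suppressWarnings(load_ensemble(bad, "pdb")))
})

test_that("heavy-atom selection keeps backbone, caps, and CB/CG/CD/OE1/NE2", {
  tpl <- fix_template()
  expect_equal(n_atoms(select_heavy_atoms(tpl)), 140)

  # full-atom glutamine-like residue: hydrogens and distal atoms dropped
  at <- data.frame(resno = 1,
                   resid = "GLU",
                   elety = c("N", "CA", "C", "O", "CB", "CG", "CD",
                             "OE1", "OE2", "HA", "1HB", "HE21"))
  ens <- conformation_ensemble(matrix(rnorm(36), 1), at)
  kept <- select_heavy_atoms(ens)
  expect_equal(kept$atoms$elety,
               c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1"))

  # uncapped 5-residue polyglycine keeps backbone only: 4 x 5 atoms
  gly <- data.frame(resno = rep(1:5, each = 4), resid = "GLY",
                    elety = rep(c("N", "CA", "C", "O"), 5))
  ens2 <- conformation_ensemble(matrix(rnorm(60), 1), gly)
  expect_equal(n_atoms(select_heavy_atoms(ens2)), 20)

  # order preserved
  expect_equal(select_heavy_atoms(tpl)$atoms$elety, tpl$atoms$elety)
})

test_that("alignment superposes frames onto the reference", {
  set.seed(2)
  tpl <- fix_template()
  base <- frame_coords(tpl)

  # identical frames stay identical
  same <- conformation_ensemble(tpl$xyz[rep(1, 3), ], tpl$atoms)
  expect_equal(align_frames(same)$xyz, same$xyz, tolerance = 1e-9)

  # a rigidly moved copy aligns back exactly
  R <- random_rotation()
  moved <- matrix(t(base %*% R + 3), nrow = 1)
  ens <- conformation_ensemble(rbind(tpl$xyz, moved), tpl$atoms)
  al <- align_frames(ens)
  expect_lt(rmsd_matrix(al, al)[1, 2], 1e-6)
  expect_lt(max(abs(frame_coords(al, 2) - base)), 1e-6)

  # random frames: per-frame distance-to-reference after alignment
  # equals the oracle's minimal RMSD
  xyz <- fix_random_frames(10, tpl, sd = 2)
  ens2 <- conformation_ensemble(xyz, tpl$atoms)
  al2 <- align_frames(ens2)
  for (i in 2:10) {
    plain <- sqrt(mean(rowSums((frame_coords(al2, i) -
                                  frame_coords(al2, 1))^2)))
    expect_lt(abs(plain - oracle_rmsd(frame_coords(ens2, i),
                                      frame_coords(ens2, 1))), 1e-6)
  }

  # degenerate collinear coordinates fall back without error
  lin <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  at <- data.frame(resno = 1:3, resid = "GLY", elety = c("N", "CA", "C"))
  deg <- conformation_ensemble(rbind(as.vector(t(lin)),
                                     as.vector(t(lin + 1))), at)
  expect_no_error(align_frames(deg))
})

test_that("external-reference alignment matches within-ensemble alignment", {
  set.seed(3)
  tpl <- fix_template()
  xyz <- fix_random_frames(4, tpl, sd = 1)
  ens <- conformation_ensemble(xyz, tpl$atoms)
  al <- align_frames(ens, 1)
  ext <- align_to(subset_frames(ens, 2:4), frame_coords(ens, 1))
  expect_equal(ext$xyz, al$xyz[2:4, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("scaling maps the training box into [0,1] and inverts exactly", {
  at <- data.frame(resno = 1, resid = "GLY", elety = c("N", "CA", "C"))
  xyz <- matrix(c(-3, 0, 7, 2, -1, 5, 0, 4, 6), 1)
  ens <- conformation_ensemble(xyz, at)
  tr <- fit_scaling(ens)
  expect_equal(tr$shift, 3)
  expect_equal(tr$scale, 10)
  sc <- scale_coords(tr, ens$xyz)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 1)
  expect_lt(max(abs(unscale_coords(tr, sc) - ens$xyz)), 1e-9)

  # values beyond the training maximum scale above 1 (allowed)
  expect_gt(scale_coords(tr, 12), 1)
  # degenerate range errors
  flat <- conformation_ensemble(matrix(2, 1, 9), at)
  expect_error(fit_scaling(flat), "range")
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_scaling(tr, f)
  expect_equal(read_scaling(f), tr)
})

test_that("split and dilution bookkeeping matches trajectory arithmetic", {
  # published-scale arithmetic on indices
  s <- split_spec(0, 0.1)
  idx <- idpae:::.split_indices(95000, s)
  expect_equal(length(idx$train), 9500)
  expect_equal(length(idx$test), 85500)
  idx2 <- idpae:::.split_indices(140000, split_spec(0, 0.2))
  expect_equal(length(idx2$train), 28000)
  expect_equal(length(idx2$test), 112000)
  expect_equal(length(idpae:::.dilute_indices(1218000, 1000)), 1218)
  expect_equal(length(idpae:::.dilute_indices(1218000, 100)), 12180)
  # combined-training bookkeeping: 12 runs x 30% of 145,000, diluted 10x
  per_run_train <- length(idpae:::.split_indices(145000,
                                                 split_spec(0, 0.3))$train)
  expect_equal(length(idpae:::.dilute_indices(12 * per_run_train, 10)),
               52200)

  # conservation for random cases
  set.seed(4)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    burn <- sample(0:10, 1)
    frac <- runif(1, 0.1, 0.9)
    sp <- split_spec(burn, frac)
    ix <- idpae:::.split_indices(n, sp)
    expect_equal(burn + length(ix$train) + length(ix$test), n)
  }

  # on an ensemble, with dilution composition
  run <- fix_small_run(n_frames = 100)
  parts <- split_trajectory(run, split_spec(0, 0.5))
  expect_equal(n_frames(parts$train), 50)
  expect_equal(n_frames(parts$test), 50)
  expect_equal(dilute(dilute(run, 2), 3)$xyz, dilute(run, 6)$xyz)
  expect_equal(dilute(run, 1)$xyz, run$xyz)
  expect_error(dilute(run, 0), "factor")
  expect_error(split_trajectory(run, split_spec(99, 0.5)))
})
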