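#' Minimal RMSD between two conformations
#'
#' Root-mean-square deviation after optimal rigid superposition (Kabsch
#' closed form with reflection correction). Every pairwise RMSD in this
#' package re-superposes the pair; a global ensemble alignment is never
#' reused, so "best match (lowest RMSD)" is the true minimum.
#'
#' @param conf_a,conf_b numeric `N x 3` coordinate matrices (or
#'   frame-major vectors of length 3N) with matched atom ordering,
#'   N >= 3.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(conf_a, conf_b) {
  a <- .as_coords(conf_a)
  b <- .as_coords(conf_b)
  if (nrow(a) != nrow(b)) stop("atom counts differ")
  if (nrow(a) < 3L) stop("need at least three atoms for superposition")
  cpp_rmsd_pair(a, b)
}

.as_coords <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  if (is.null(dim(x))) {
    if (length(x) %% 3 != 0) stop("coordinate vector length not 3N")
    return(matrix(x, ncol = 3L, byrow = TRUE))
  }
  stop("coordinates must be an N x 3 matrix or a length-3N vector")
}

.frame_matrix <- function(x) {
  if (inherits(x, "ConformationEnsemble")) return(x$xyz)
  as.matrix(x)
}

#' All pairwise minimal RMSDs between two ensembles
#'
#' @param a,b ensembles (or frame-major coordinate matrices) with
#'   matched atoms.
#' @return Numeric matrix `[n_frames(a) x n_frames(b)]` in Angstrom.
#' @export
rmsd_matrix <- function(a, b) {
  A <- .frame_matrix(a)
  B <- .frame_matrix(b)
  if (ncol(A) != ncol(B)) stop("atom counts differ between sets")
  cpp_rmsd_matrix(A, B)
}

#' Best-match RMSD of a test set against a reference set
#'
#' For each test conformation, the minimum RMSD over all reference
#' (e.g. generated) conformations; the mean of these best-match RMSDs
#' measures how well the reference set covers the test set. Ties are
#' broken by the lowest reference index. Enlarging the reference set can
#' only decrease each per-conformation minimum.
#'
#' @param test,reference ensembles with matched atoms.
#' @return An `EvaluationReport` list: `best_match_mean` (Angstrom),
#'   `per_conformation` data frame (`test_index`, `match_index`,
#'   `rmsd`), and `metadata` with the set sizes.
#' @export
best_match_rmsd <- function(test, reference) {
  A <- .frame_matrix(test)
  B <- .frame_matrix(reference)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("both sets must be nonempty")
  if (ncol(A) != ncol(B)) stop("atom counts differ between sets")
  bm <- cpp_best_match(A, B)
  per <- data.frame(test_index = seq_len(nrow(A)),
                    match_index = as.integer(bm$index),
                    rmsd = as.numeric(bm$rmsd))
  structure(list(best_match_mean = mean(per$rmsd), per_conformation = per,
                 metadata = list(n_test = nrow(A), n_reference = nrow(B))),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport: mean best-match RMSD ",
      format(x$best_match_mean, digits = 4), " A over ",
      x$metadata$n_test, " test vs ", x$metadata$n_reference,
      " reference conformations\n", sep = "")
  invisible(x)
}

#' Mean reconstruction RMSD over a diluted test set
#'
#' Each (diluted) test conformation is superposed onto the training
#' reference stored in the scaling transform, scaled, passed through
#' encoder and decoder, unscaled, and compared to the original by
#' minimal RMSD, so the value is invariant to rigid motions of the test
#' set. The mean over the diluted test set is the
#' reconstruction accuracy of the autoencoder.
#'
#' @param model an `AutoencoderModel`.
#' @param test a test [conformation_ensemble()] in real coordinates.
#' @param scaling the training [fit_scaling()] transform.
#' @param dilution keep every k-th test frame before evaluating.
#' @return Mean reconstruction RMSD in Angstrom.
#' @export
mean_reconstruction_rmsd <- function(model, test, scaling, dilution = 1L) {
  test <- dilute(test, dilution)
  if (n_frames(test) < 1L) stop("diluted test set is empty")
  if (!is.null(scaling$reference))
    test <- align_to(test, scaling$reference)
  scaled <- scale_coords(scaling, test$xyz)
  recon <- unscale_coords(scaling, decode(model, encode(model, scaled)))
  mean(diag(cpp_rmsd_matrix(test$xyz, recon)))
}

#' Mean pairwise RMSD within a set (ensemble diversity)
#'
#' The average of all K(K-1)/2 pairwise minimal RMSDs; large values mean
#' a broad (diverse) ensemble.
#'
#' @param set an ensemble with at least two frames.
#' @return Mean pairwise RMSD in Angstrom.
#' @export
pairwise_diversity <- function(set) {
  X <- .frame_matrix(set)
  if (nrow(X) < 2L) stop("need at least two frames")
  m <- cpp_rmsd_matrix(X, X)
  mean(m[upper.tri(m)])
}

#' Mean nearest-neighbour RMSD within a set
#'
#' For each conformation, the minimum RMSD to any *other* member of the
#' set; the mean is a benchmark for best-match coverage: a generated set
#' that "fully covers" a test set should match its conformations at
#' least as closely as the test set's own nearest neighbours do. Always
#' less than or equal to [pairwise_diversity()].
#'
#' @param set an ensemble with at least two frames.
#' @return Mean nearest-neighbour RMSD in Angstrom.
#' @export
within_set_best_match <- function(set) {
  X <- .frame_matrix(set)
  if (nrow(X) < 2L) stop("need at least two frames")
  m <- cpp_rmsd_matrix(X, X)
  diag(m) <- Inf
  mean(apply(m, 1L, min))
}

#' Mean absolute percentage error
#'
#' `mean(|observed - expected| / expected) * 100`, e.g. for comparing a
#' computed SAXS profile against experiment.
#'
#' @param observed,expected numeric series of equal length; `expected`
#'   must be nonzero everywhere.
#' @return MAPE in percent.
#' @export
mape <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(expected == 0)) stop("expected values must be nonzero")
  mean(abs(observed - expected) / abs(expected)) * 100
}

#' Root-mean-square error
#'
#' `sqrt(mean((observed - expected)^2))`, e.g. for secondary chemical
#' shifts in ppm.
#'
#' @param observed,expected numeric series of equal length.
#' @return RMSE in the units of the series.
#' @export
rmse <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  sqrt(mean((observed - expected)^2))
}

# Ideal bond lengths (Angstrom) and angles (degrees) for the residue
# types this package builds and audits. Inter-residue entries use the
# "-C" prefix for the preceding residue's carbonyl carbon.
.geometry_templates <- function() {
  gln_bonds <- list(c("N", "CA", 1.458), c("CA", "C", 1.525),
                    c("C", "O", 1.231), c("CA", "CB", 1.530),
                    c("CB", "CG", 1.530), c("CG", "CD", 1.516),
                    c("CD", "OE1", 1.231), c("CD", "NE2", 1.328))
  gln_angles <- list(c("N", "CA", "C", 111.2), c("CA", "C", "O", 120.8),
                     c("N", "CA", "CB", 110.5), c("CA", "CB", "CG", 114.1),
                     c("CB", "CG", "CD", 111.3), c("CG", "CD", "OE1", 121.5),
                     c("CG", "CD", "NE2", 116.6),
                     c("OE1", "CD", "NE2", 121.9))
  list(
    GLN = list(bonds = gln_bonds, angles = gln_angles),
    GLY = list(bonds = list(c("N", "CA", 1.458), c("CA", "C", 1.525),
                            c("C", "O", 1.231)),
               angles = list(c("N", "CA", "C", 111.2),
                             c("CA", "C", "O", 120.8))),
    ACE = list(bonds = list(c("CH3", "C", 1.508), c("C", "O", 1.231)),
               angles = list(c("CH3", "C", "O", 120.8))),
    NME = list(bonds = list(c("N", "CH3", 1.449)), angles = list()),
    # inter-residue peptide geometry (previous C to current N)
    peptide = list(bond = 1.329,
                   angles = list(CA_C_N = 116.2, O_C_N = 123.0,
                                 C_N_CA = 121.7, C_N_CH3 = 121.7))
  )
}

#' Audit bond lengths and bond angles of a conformation
#'
#' Decoded conformations are produced coordinate-wise and can violate
#' covalent geometry. This reporter scans a conformation against ideal
#' residue templates (e.g. N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom)
#' and flags bonds deviating by more than a fractional tolerance and
#' angles deviating by more than a degree tolerance. It only reports;
#' no refinement is attempted. Residues without a template are skipped
#' with a warning.
#'
#' @param conf numeric `N x 3` matrix (or one-frame ensemble).
#' @param atoms atom table (ignored when `conf` is an ensemble).
#' @param bond_tol allowed fractional deviation of a bond length.
#' @param angle_tol allowed absolute deviation of an angle, degrees.
#' @return A `GeometryReport`: counts plus data frames `bonds`
#'   (`atom_a`, `atom_b`, `length`, `ideal`) and `angles`.
#' @export
geometry_check <- function(conf, atoms = NULL, bond_tol = 0.15,
                           angle_tol = 15) {
  if (inherits(conf, "ConformationEnsemble")) {
    atoms <- conf$atoms
    conf <- frame_coords(conf, 1L)
  }
  stopifnot(!is.null(atoms), nrow(atoms) * 3L == length(conf))
  tmpl <- .geometry_templates()
  key <- paste0(atoms$resno, "/", toupper(trimws(atoms$elety)))
  lookup <- stats::setNames(seq_len(nrow(atoms)), key)
  get_idx <- function(resno, name) {
    i <- lookup[paste0(resno, "/", name)]
    if (is.na(i)) NA_integer_ else unname(i)
  }
  blen <- function(i, j) sqrt(sum((conf[i, ] - conf[j, ])^2))
  bang <- function(i, j, k) {
    u <- conf[i, ] - conf[j, ]
    v <- conf[k, ] - conf[j, ]
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
      180 / pi
  }

  bonds_bad <- list()
  angles_bad <- list()
  check_bond <- function(i, j, ideal, tag_a, tag_b) {
    if (is.na(i) || is.na(j)) return()
    l <- blen(i, j)
    if (abs(l - ideal) > bond_tol * ideal)
      bonds_bad[[length(bonds_bad) + 1L]] <<-
        data.frame(atom_a = tag_a, atom_b = tag_b, length = l,
                   ideal = ideal)
  }
  check_angle <- function(i, j, k, ideal, tag) {
    if (is.na(i) || is.na(j) || is.na(k)) return()
    a <- bang(i, j, k)
    if (abs(a - ideal) > angle_tol)
      angles_bad[[length(angles_bad) + 1L]] <<-
        data.frame(angle = tag, value = a, ideal = ideal)
  }

  resnos <- unique(atoms$resno)
  for (rn in resnos) {
    resid <- toupper(trimws(atoms$resid[match(rn, atoms$resno)]))
    t <- tmpl[[resid]]
    if (is.null(t)) {
      warning("no geometry template for residue ", resid, "; skipped")
      next
    }
    for (b in t$bonds)
      check_bond(get_idx(rn, b[1L]), get_idx(rn, b[2L]),
                 as.numeric(b[3L]), paste0(rn, "/", b[1L]),
                 paste0(rn, "/", b[2L]))
    for (a in t$angles)
      check_angle(get_idx(rn, a[1L]), get_idx(rn, a[2L]),
                  get_idx(rn, a[3L]), as.numeric(a[4L]),
                  paste0(rn, "/", a[1L], "-", a[2L], "-", a[3L]))
  }
  # peptide links between consecutive residues
  pep <- tmpl$peptide
  for (p in seq_len(length(resnos) - 1L)) {
    rn <- resnos[p]; rn2 <- resnos[p + 1L]
    ci <- get_idx(rn, "C")
    ni <- get_idx(rn2, "N")
    if (is.na(ni)) ni <- get_idx(rn2, "CH3")  # NME handled via N
    check_bond(ci, ni, pep$bond, paste0(rn, "/C"), paste0(rn2, "/N"))
    check_angle(get_idx(rn, "CA"), ci, ni, pep$angles$CA_C_N,
                paste0(rn, "/CA-C-", rn2, "/N"))
    check_angle(ci, ni, get_idx(rn2, "CA"), pep$angles$C_N_CA,
                paste0(rn, "/C-", rn2, "/N-CA"))
    if (is.na(get_idx(rn2, "CA")))
      check_angle(ci, ni, get_idx(rn2, "CH3"), pep$angles$C_N_CH3,
                  paste0(rn, "/C-", rn2, "/N-CH3"))
    if (is.na(get_idx(rn, "CA")))  # ACE: CH3 plays the CA role
      check_angle(get_idx(rn, "CH3"), ci, ni, pep$angles$CA_C_N,
                  paste0(rn, "/CH3-C-", rn2, "/N"))
  }

  bonds <- if (length(bonds_bad)) do.call(rbind, bonds_bad) else
    data.frame(atom_a = character(), atom_b = character(),
               length = numeric(), ideal = numeric())
  angles <- if (length(angles_bad)) do.call(rbind, angles_bad) else
    data.frame(angle = character(), value = numeric(), ideal = numeric())
  structure(list(n_bond_violations = nrow(bonds),
                 n_angle_violations = nrow(angles), bonds = bonds,
                 angles = angles,
                 thresholds = list(bond_tol = bond_tol,
                                   angle_tol = angle_tol)),
            class = "GeometryReport")
}

#' @export
print.GeometryReport <- function(x, ...) {
  cat("GeometryReport: ", x$n_bond_violations, " bond and ",
      x$n_angle_violations, " angle violation(s)\n", sep = "")
  invisible(x)
}
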