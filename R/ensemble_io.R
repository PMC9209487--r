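#' Conformational ensemble container
#'
#' A `ConformationEnsemble` holds a set of conformations (frames) of one
#' molecule: a frame-major coordinate matrix (one row per frame, columns
#' ordered x1, y1, z1, x2, ...) in Angstrom, plus a per-atom metadata
#' table shared by every frame.
#'
#' @param xyz numeric matrix `[n_frames x 3*n_atoms]` of coordinates in
#'   Angstrom, frame-major order.
#' @param atoms data frame with one row per atom and columns `resno`
#'   (1-based residue index), `resid` (residue name) and `elety`
#'   (atom name, PDB conventions).
#' @param label run identifier carried through splits and pooling.
#' @return An object of class `ConformationEnsemble`.
#' @export
conformation_ensemble <- function(xyz, atoms, label = "run") {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || nrow(xyz) < 1L)
    stop("xyz must be a numeric matrix with at least one frame")
  if (!all(is.finite(xyz))) stop("coordinates must all be finite")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("resno", "resid", "elety")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns resno, resid, elety")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but atoms describes ",
         nrow(atoms), " atoms (need 3 columns per atom)")
  structure(list(xyz = xyz, atoms = atoms[, need],
                 label = as.character(label)),
            class = "ConformationEnsemble")
}

#' @export
print.ConformationEnsemble <- function(x, ...) {
  cat("ConformationEnsemble '", x$label, "': ", n_frames(x), " frame(s), ",
      n_atoms(x), " atoms, ", length(unique(x$atoms$resno)),
      " residues\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a [conformation_ensemble()].
#' @return Integer count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) nrow(ensemble$atoms)

#' Keep a subset of frames
#' @param ensemble a [conformation_ensemble()].
#' @param i integer frame indices.
#' @return The subsetted ensemble.
#' @export
subset_frames <- function(ensemble, i) {
  if (length(i) < 1L) stop("frame subset must be nonempty")
  conformation_ensemble(ensemble$xyz[i, , drop = FALSE], ensemble$atoms,
                        ensemble$label)
}

#' Coordinates of one frame as an N x 3 matrix
#' @param ensemble a [conformation_ensemble()].
#' @param i frame index (1-based).
#' @return Numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ensemble, i = 1L) {
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Read a conformational ensemble from disk
#'
#' Supports multi-model PDB files (one MODEL per frame) and a plain
#' frame-major table (one row per frame, 3N columns, header columns named
#' `<resno>.<resid>.<elety>.<x|y|z>`).
#'
#' @param path file to read.
#' @param format `"pdb"` or `"table"`.
#' @param label run identifier attached to the result.
#' @return A [conformation_ensemble()].
#' @export
load_ensemble <- function(path, format = c("pdb", "table"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("PDB parse error: ",
                                             conditionMessage(e)))
    xyz <- unclass(pdb$xyz)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    atoms <- data.frame(resno = pdb$atom$resno, resid = pdb$atom$resid,
                        elety = pdb$atom$elety, stringsAsFactors = FALSE)
    if (ncol(xyz) != 3L * nrow(atoms))
      stop("inconsistent atom counts across PDB models")
    conformation_ensemble(xyz, atoms, label)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (nrow(tab) < 1L) stop("table has no frames")
    atoms <- .atoms_from_header(names(tab))
    conformation_ensemble(as.matrix(tab), atoms, label)
  }
}

.atoms_from_header <- function(cols) {
  parts <- strsplit(cols, ".", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad))
    stop("table header must use <resno>.<resid>.<elety>.<axis> columns")
  m <- do.call(rbind, parts)
  keep <- m[, 4L] == "x"
  data.frame(resno = as.integer(m[keep, 1L]), resid = m[keep, 2L],
             elety = m[keep, 3L], stringsAsFactors = FALSE)
}

#' Write a conformational ensemble to disk
#'
#' The PDB writer emits a standard multi-MODEL file (occupancy 1.00,
#' B-factor 0.00); coordinates survive a round trip to PDB precision
#' (1e-3 Angstrom). The table writer is lossless.
#'
#' @inheritParams load_ensemble
#' @param ensemble a [conformation_ensemble()].
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("pdb", "table")) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "ConformationEnsemble"))
  if (format == "pdb") {
    at <- ensemble$atoms
    n <- nrow(at)
    bio3d::write.pdb(file = path, xyz = ensemble$xyz, resno = at$resno,
                     resid = at$resid, elety = at$elety,
                     chain = rep("A", n), o = rep(1, n), b = rep(0, n))
  } else {
    at <- ensemble$atoms
    nm <- paste(rep(at$resno, each = 3L), rep(at$resid, each = 3L),
                rep(at$elety, each = 3L), rep(c("x", "y", "z"), nrow(at)),
                sep = ".")
    tab <- as.data.frame(ensemble$xyz)
    names(tab) <- nm
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

# Atom names whose first letter (after stripping leading digits) is H are
# hydrogens under PDB conventions (HB2, 1HG1, ...).
.is_hydrogen <- function(elety) {
  grepl("^[0-9]*H", toupper(trimws(elety)))
}

#' Select the modelled heavy atoms
#'
#' Keeps every backbone heavy atom (N, CA, C, O, and OXT when present),
#' all heavy atoms of acetyl/N-methylamide capping groups (ACE, NME/NMA),
#' and side-chain heavy atoms named CB, CG, CD, OE1 or NE2. Longer side
#' chains are thereby truncated; hydrogens are always dropped. Atom order
#' is preserved. For a capped 15-residue polyglutamine this leaves 140
#' atoms.
#'
#' @param ensemble a [conformation_ensemble()].
#' @return The ensemble restricted to the selected atoms.
#' @export
select_heavy_atoms <- function(ensemble) {
  at <- ensemble$atoms
  elety <- toupper(trimws(at$elety))
  resid <- toupper(trimws(at$resid))
  keep <- !.is_hydrogen(elety) &
    (elety %in% c("N", "CA", "C", "O", "OXT") |
       resid %in% c("ACE", "NME", "NMA") |
       elety %in% c("CB", "CG", "CD", "OE1", "NE2"))
  if (!any(keep)) stop("heavy-atom selection is empty")
  cols <- rep((which(keep) - 1L) * 3L, each = 3L) + 1:3
  conformation_ensemble(ensemble$xyz[, cols, drop = FALSE],
                        at[keep, , drop = FALSE], ensemble$label)
}

#' Superpose all frames onto a reference frame
#'
#' Each frame is rotated and translated to minimise its RMSD to the
#' reference frame (Kabsch superposition over all retained atoms). The
#' reference frame itself is returned unchanged. If a frame's coordinates
#' are degenerate (e.g. all collinear) the rotation is ill-conditioned
#' and a pure translation is applied instead.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param reference_index 1-based frame used as the alignment reference.
#' @return The aligned ensemble.
#' @export
align_frames <- function(ensemble, reference_index = 1L) {
  k <- n_frames(ensemble)
  if (reference_index < 1L || reference_index > k)
    stop("reference index out of range")
  xyz <- cpp_align_frames(ensemble$xyz, as.integer(reference_index))
  conformation_ensemble(xyz, ensemble$atoms, ensemble$label)
}

#' Superpose all frames of an ensemble onto an external reference
#'
#' Like [align_frames()], but the reference conformation comes from
#' outside the ensemble (e.g. aligning test or generated frames onto the
#' training reference), so several datasets can share one coordinate
#' frame.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param reference an `N x 3` coordinate matrix or a one-frame
#'   ensemble with matching atoms.
#' @return The aligned ensemble.
#' @export
align_to <- function(ensemble, reference) {
  if (inherits(reference, "ConformationEnsemble"))
    reference <- frame_coords(reference, 1L)
  ref_row <- matrix(t(reference), nrow = 1L)
  if (ncol(ref_row) != ncol(ensemble$xyz))
    stop("reference atom count does not match the ensemble")
  xyz <- cpp_align_frames(rbind(ref_row, ensemble$xyz), 1L)
  conformation_ensemble(xyz[-1L, , drop = FALSE], ensemble$atoms,
                        ensemble$label)
}

#' Fit the shift-and-scale transform mapping coordinates into [0, 1]
#'
#' After alignment, training coordinates are shifted by a single global
#' offset so the minimum value is zero, then divided by one global scale
#' (the maximum shifted value). The transform is fit on the training set
#' only and reused verbatim for test and generated data; values outside
#' the training range simply map outside `[0, 1]`.
#'
#' @param ensemble the (aligned) training ensemble.
#' @param reference_index frame that served as alignment reference; its
#'   coordinates are stored so that other datasets (test, generated) can
#'   be superposed into the same frame before scaling.
#' @return A `ScalingTransform` with fields `shift` (Angstrom, added
#'   before scaling), `scale` (Angstrom) and `reference` (the reference
#'   conformation, `N x 3`).
#' @export
fit_scaling <- function(ensemble, reference_index = 1L) {
  lo <- min(ensemble$xyz)
  shift <- -lo
  scale <- max(ensemble$xyz + shift)
  if (scale <= 0) stop("zero coordinate range; cannot scale")
  structure(list(reference_frame_index = as.integer(reference_index),
                 shift = shift, scale = scale,
                 reference = frame_coords(ensemble, reference_index)),
            class = "ScalingTransform")
}

#' Apply or invert a scaling transform
#' @param transform a [fit_scaling()] result.
#' @param xyz numeric matrix (or vector) of real coordinates in Angstrom.
#' @return Scaled coordinates in (approximately) `[0, 1]`, or for
#'   `unscale_coords()` real coordinates in Angstrom.
#' @export
scale_coords <- function(transform, xyz) {
  stopifnot(inherits(transform, "ScalingTransform"))
  (xyz + transform$shift) / transform$scale
}

#' @rdname scale_coords
#' @export
unscale_coords <- function(transform, xyz) {
  stopifnot(inherits(transform, "ScalingTransform"))
  xyz * transform$scale - transform$shift
}

#' Save / load a scaling transform as JSON
#' @param transform a `ScalingTransform`.
#' @param path JSON file path.
#' @return The transform (for `read_scaling`), or `path` invisibly.
#' @export
write_scaling <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- if (!is.null(x$reference)) as.matrix(x$reference) else NULL
  if (!is.null(ref)) dimnames(ref) <- NULL
  structure(list(reference_frame_index = as.integer(x$reference_frame_index),
                 shift = x$shift, scale = x$scale, reference = ref),
            class = "ScalingTransform")
}

#' Train/test split specification
#'
#' @param burn_in_frames frames discarded from the start of the run.
#' @param train_fraction fraction (0, 1) of the remaining frames taken,
#'   from the front, as training data; the rest is the test set.
#' @param train_dilution,test_dilution keep every k-th frame of the
#'   respective portion (1 = keep all).
#' @return A `SplitSpec`.
#' @export
split_spec <- function(burn_in_frames = 0L, train_fraction = 0.1,
                       train_dilution = 1L, test_dilution = 1L) {
  stopifnot(burn_in_frames >= 0L, train_fraction > 0, train_fraction < 1,
            train_dilution >= 1L, test_dilution >= 1L)
  structure(list(burn_in_frames = as.integer(burn_in_frames),
                 train_fraction = train_fraction,
                 train_dilution = as.integer(train_dilution),
                 test_dilution = as.integer(test_dilution)),
            class = "SplitSpec")
}

# Index bookkeeping for splits, shared by split_trajectory() and the
# arithmetic tests: returns 1-based frame indices before dilution.
.split_indices <- function(n, spec) {
  if (spec$burn_in_frames + 1L >= n)
    stop("burn-in leaves fewer than two frames")
  remaining <- n - spec$burn_in_frames
  n_train <- floor(spec$train_fraction * remaining)
  if (n_train < 1L || n_train >= remaining)
    stop("train fraction produces an empty train or test set")
  list(train = spec$burn_in_frames + seq_len(n_train),
       test = (spec$burn_in_frames + n_train + 1L):n)
}

.dilute_indices <- function(n, factor) {
  if (factor < 1L) stop("dilution factor must be >= 1")
  seq.int(1L, n, by = as.integer(factor))
}

#' Split a trajectory into training and test portions
#'
#' Burn-in frames are discarded; the first `train_fraction` of the
#' remaining frames (rounded down) becomes the training set and the rest
#' the test set, exploiting the temporal ordering of the trajectory.
#' Dilution (keep every k-th frame, starting at the first) is applied to
#' each portion afterwards. E.g. 95,000 frames at 10% give a 9,500-frame
#' training and an 85,500-frame test set.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param spec a [split_spec()].
#' @return `list(train = , test = )` of ensembles.
#' @export
split_trajectory <- function(ensemble, spec) {
  stopifnot(inherits(spec, "SplitSpec"))
  idx <- .split_indices(n_frames(ensemble), spec)
  train <- subset_frames(ensemble, idx$train)
  test <- subset_frames(ensemble, idx$test)
  list(train = dilute(train, spec$train_dilution),
       test = dilute(test, spec$test_dilution))
}

#' Dilute an ensemble by keeping every k-th frame
#'
#' Keeps frames 1, 1+factor, 1+2*factor, ... Reduces the temporal
#' redundancy of trajectory frames (adjacent frames are structurally
#' similar); e.g. 1,218,000 frames at factor 1000 leave 1,218.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param factor integer >= 1.
#' @return The diluted ensemble.
#' @export
dilute <- function(ensemble, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(ensemble)
  subset_frames(ensemble, .dilute_indices(n_frames(ensemble), factor))
}
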