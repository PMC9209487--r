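# Synthetic conformational trajectories with the statistical structure
# the generative pipeline assumes: several conformational basins,
# temporal autocorrelation (so "initial portion as training" is
# meaningful), and replicate runs whose basins only partially overlap.
# Chains are glutamine-like polymers built from ideal internal
# coordinates, so the heavy-atom selection rule and the geometry auditor
# both apply to them.

# Place atom D bonded to C with |CD| = bond, angle(B, C, D) = angle and
# dihedral(A, B, C, D) = torsion (degrees). Standard internal-coordinate
# (NeRF) construction.
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Backbone/side-chain ideal values shared with the geometry templates.
.fix <- list(b_NCA = 1.458, b_CAC = 1.525, b_CO = 1.231, b_CN = 1.329,
             b_CACB = 1.530, b_CBCG = 1.530, b_CGCD = 1.516,
             b_CDOE1 = 1.231, b_CDNE2 = 1.328, b_ACE = 1.508,
             b_NME = 1.449,
             a_NCAC = 111.2, a_CACO = 120.8, a_CACN = 116.2,
             a_CNCA = 121.7, a_NCACB = 110.5, a_CACBCG = 114.1,
             a_CBCGCD = 111.3, a_CGCDOE1 = 121.5, a_CGCDNE2 = 116.6)

# Canonical backbone dihedral combinations (beta strand, alpha helix,
# polyproline II) used to diversify basin centres.
.phi_psi_menu <- matrix(c(-140, 135, -60, -45, -75, 145), ncol = 2,
                        byrow = TRUE)

#' Build an ideal-geometry polymer chain template
#'
#' Constructs a single conformation of a glutamine-like chain (backbone
#' N, CA, C, O plus side chain CB, CG, CD, OE1, NE2 per residue) from
#' ideal bond lengths and angles, optionally capped with acetyl (ACE:
#' CH3, C, O) and N-methylamide (NME: N, CH3) groups. A capped
#' 15-residue chain has 140 heavy atoms. Backbone dihedrals default to
#' an extended strand; random per-residue dihedrals (drawn from
#' beta/alpha/polyproline-II combinations) produce diverse,
#' clash-checked conformations. [geometry_check()] reports zero
#' violations on any template.
#'
#' @param n_res number of (non-cap) residues, >= 2.
#' @param caps add ACE/NME capping groups (counted as residues in the
#'   atom table).
#' @param phi,psi backbone dihedrals in degrees, recycled over residues;
#'   `NULL` draws them per residue from the canonical menu (requires a
#'   live RNG, e.g. inside `withr::with_seed()`).
#' @param chi side-chain dihedrals (chi1, chi2, chi3) in degrees.
#' @param max_retries clash-resolution attempts when drawing random
#'   dihedrals (two atoms from non-adjacent residues closer than 1.8
#'   Angstrom count as a clash).
#' @return A one-frame [conformation_ensemble()].
#' @export
make_chain_template <- function(n_res, caps = TRUE, phi = NULL, psi = NULL,
                                chi = c(-60, 180, 90), max_retries = 50L) {
  stopifnot(n_res >= 2)
  random <- is.null(phi) || is.null(psi)
  for (attempt in seq_len(max_retries)) {
    if (random) {
      pick <- sample.int(nrow(.phi_psi_menu), n_res, replace = TRUE)
      phi_use <- .phi_psi_menu[pick, 1L]
      psi_use <- .phi_psi_menu[pick, 2L]
      chi_use <- matrix(sample(c(-60, 60, 180), 3L * n_res,
                               replace = TRUE), n_res, 3L)
      chi_use[, 3L] <- 90  # amide plane orientation
    } else {
      phi_use <- rep_len(phi, n_res)
      psi_use <- rep_len(psi, n_res)
      chi_use <- matrix(rep_len(chi, 3L), n_res, 3L, byrow = TRUE)
    }
    ens <- .build_chain(n_res, caps, phi_use, psi_use, chi_use)
    if (!.has_clash(ens)) return(ens)
    if (!random)
      stop("fixed dihedrals produce a clashing chain")
  }
  stop("could not build a clash-free chain after ", max_retries,
       " attempts")
}

.build_chain <- function(n_res, caps, phi, psi, chi) {
  f <- .fix
  coords <- list()
  meta <- list()
  add <- function(xyz, resno, resid, elety) {
    coords[[length(coords) + 1L]] <<- xyz
    meta[[length(meta) + 1L]] <<- data.frame(resno = resno, resid = resid,
                                             elety = elety)
  }
  idx <- function(k) coords[[length(coords) + k]]  # k <= 0, from end

  res0 <- 0L
  if (caps) {
    ch3 <- c(0, 0, 0)
    cc <- c(f$b_ACE, 0, 0)
    # planar placement in the xy-plane: angle(CH3, C, O) = a_CACO
    oo <- c(cc[1] - f$b_CO * cos(f$a_CACO * pi / 180),
            f$b_CO * sin(f$a_CACO * pi / 180), 0)
    add(ch3, 1L, "ACE", "CH3")
    add(cc, 1L, "ACE", "C")
    add(oo, 1L, "ACE", "O")
    res0 <- 1L
    prevA <- oo; prevB <- ch3; prevC <- cc  # for placing the next N
  } else {
    # start the backbone directly: N, then CA along x
    nn <- c(0, 0, 0)
    ca <- c(f$b_NCA, 0, 0)
    add(nn, 1L, "GLN", "N")
    add(ca, 1L, "GLN", "CA")
  }

  atoms_of <- function(resno, name) {
    for (k in seq_along(meta))
      if (meta[[k]]$resno == resno && meta[[k]]$elety == name)
        return(coords[[k]])
    NULL
  }

  for (r in seq_len(n_res)) {
    rn <- res0 + r
    if (caps || r > 1L) {
      # amide N from the previous carbonyl (omega = 180)
      prevC_at <- atoms_of(rn - 1L, "C")
      prevCA_at <- if (caps && r == 1L) atoms_of(1L, "CH3") else
        atoms_of(rn - 1L, "CA")
      prevO_at <- atoms_of(rn - 1L, "O")
      # dihedral O-CA-C-N = 180 keeps the amide planar
      nn <- .place_atom(prevO_at, prevCA_at, prevC_at, f$b_CN, f$a_CACN,
                        180)
      add(nn, rn, "GLN", "N")
      ca <- .place_atom(prevCA_at, prevC_at, nn, f$b_NCA, f$a_CNCA, 180)
      add(ca, rn, "GLN", "CA")
    } else {
      nn <- atoms_of(1L, "N")
      ca <- atoms_of(1L, "CA")
    }
    anchor <- if (caps || r > 1L) atoms_of(rn - 1L, "C") else
      nn + c(0, 1, 0)  # arbitrary phi reference for an uncapped start
    cb_anchor <- anchor
    cc <- .place_atom(anchor, nn, ca, f$b_CAC, f$a_NCAC, phi[r])
    add(cc, rn, "GLN", "C")
    oo <- .place_atom(nn, ca, cc, f$b_CO, f$a_CACO, psi[r] + 180)
    add(oo, rn, "GLN", "O")
    # side chain
    cb <- .place_atom(cb_anchor, nn, ca, f$b_CACB, f$a_NCACB,
                      phi[r] + 122)
    add(cb, rn, "GLN", "CB")
    cg <- .place_atom(nn, ca, cb, f$b_CBCG, f$a_CACBCG, chi[r, 1L])
    add(cg, rn, "GLN", "CG")
    cd <- .place_atom(ca, cb, cg, f$b_CGCD, f$a_CBCGCD, chi[r, 2L])
    add(cd, rn, "GLN", "CD")
    oe1 <- .place_atom(cb, cg, cd, f$b_CDOE1, f$a_CGCDOE1, chi[r, 3L])
    add(oe1, rn, "GLN", "OE1")
    ne2 <- .place_atom(cb, cg, cd, f$b_CDNE2, f$a_CGCDNE2,
                       chi[r, 3L] + 180)
    add(ne2, rn, "GLN", "NE2")
  }

  if (caps) {
    rn <- res0 + n_res + 1L
    last <- res0 + n_res
    nn <- .place_atom(atoms_of(last, "O"), atoms_of(last, "CA"),
                      atoms_of(last, "C"), f$b_CN, f$a_CACN, 180)
    add(nn, rn, "NME", "N")
    ch3 <- .place_atom(atoms_of(last, "CA"), atoms_of(last, "C"), nn,
                       f$b_NME, f$a_CNCA, 180)
    add(ch3, rn, "NME", "CH3")
  }

  atoms <- do.call(rbind, meta)
  xyz <- matrix(unlist(coords), nrow = 1L)
  conformation_ensemble(xyz, atoms, "template")
}

# Clash test: any two atoms from non-adjacent residues closer than
# 1.8 Angstrom.
.has_clash <- function(ens, cutoff = 1.8) {
  x <- frame_coords(ens, 1L)
  resno <- ens$atoms$resno
  d <- as.matrix(stats::dist(x))
  sep <- abs(outer(resno, resno, "-")) >= 2L
  any(d[sep] < cutoff)
}

#' Fixture trajectory specification
#'
#' Describes a synthetic replicate "run": a Markov chain over
#' `n_basins` conformational basins (distinct ideal-geometry chain
#' conformations) with per-frame switch probability
#' `switch_probability`, and within-basin first-order autoregressive
#' Gaussian displacements of stationary standard deviation
#' `within_basin_sd` per coordinate (autoregression coefficient
#' `ar1_rho`), giving trajectories that are temporally autocorrelated
#' within and between basins.
#'
#' @param n_res residues per chain (excluding caps).
#' @param caps add ACE/NME capping groups.
#' @param n_frames frames per run.
#' @param n_basins number of conformational basins.
#' @param basin_occupancy basin probabilities (default uniform).
#' @param within_basin_sd per-coordinate displacement SD, Angstrom.
#' @param switch_probability per-frame probability of redrawing the
#'   basin (controls how long the chain dwells in one basin).
#' @param ar1_rho frame-to-frame autocorrelation of the displacement.
#' @param run_overlap fraction of basins shared between replicate runs
#'   (used by [make_replicates()]).
#' @param seed master seed.
#' @return A `FixtureSpec`.
#' @export
fixture_spec <- function(n_res = 15L, caps = TRUE, n_frames = 5000L,
                         n_basins = 3L, basin_occupancy = NULL,
                         within_basin_sd = 1.0, switch_probability = 0.02,
                         ar1_rho = 0.95, run_overlap = 0.5, seed = 1L) {
  if (is.null(basin_occupancy))
    basin_occupancy <- rep(1 / n_basins, n_basins)
  stopifnot(n_basins >= 1L, length(basin_occupancy) == n_basins,
            abs(sum(basin_occupancy) - 1) < 1e-9,
            switch_probability >= 0, switch_probability <= 1,
            within_basin_sd > 0, ar1_rho >= 0, ar1_rho < 1,
            run_overlap >= 0, run_overlap <= 1)
  structure(list(n_res = as.integer(n_res), caps = caps,
                 n_frames = as.integer(n_frames),
                 n_basins = as.integer(n_basins),
                 basin_occupancy = basin_occupancy,
                 within_basin_sd = within_basin_sd,
                 switch_probability = switch_probability,
                 ar1_rho = ar1_rho, run_overlap = run_overlap,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

# Draw n distinct basin centre conformations (consumes the live RNG).
.draw_centers <- function(spec, n) {
  lapply(seq_len(n), function(b)
    make_chain_template(spec$n_res, spec$caps))
}

#' Simulate one synthetic trajectory
#'
#' Runs the Markov-plus-autoregression model of [fixture_spec()]:
#' each frame is its current basin's centre conformation plus a
#' temporally correlated Gaussian displacement. Successive frames within
#' a basin are therefore much closer (in RMSD) than frames from
#' different basins, mimicking the redundancy of molecular dynamics
#' trajectories.
#'
#' @param spec a [fixture_spec()].
#' @param centers optional pre-built list of basin centre ensembles
#'   (e.g. from [make_replicates()]); drawn from `spec` when `NULL`.
#' @param label run identifier.
#' @return A [conformation_ensemble()] with `n_frames` frames. The
#'   basin path is attached as attribute `"basins"`.
#' @export
make_run <- function(spec, centers = NULL, label = "run1") {
  stopifnot(inherits(spec, "FixtureSpec"))
  withr::with_seed(spec$seed, {
    if (is.null(centers)) centers <- .draw_centers(spec, spec$n_basins)
    stopifnot(length(centers) == spec$n_basins)
    cmat <- do.call(rbind, lapply(centers, function(e) e$xyz))
    atoms <- centers[[1L]]$atoms
    p <- ncol(cmat)
    sdv <- spec$within_basin_sd
    rho <- spec$ar1_rho
    innov <- sqrt(1 - rho^2) * sdv

    xyz <- matrix(0, spec$n_frames, p)
    basins <- integer(spec$n_frames)
    state <- sample.int(spec$n_basins, 1L, prob = spec$basin_occupancy)
    D <- stats::rnorm(p, sd = sdv)
    for (t in seq_len(spec$n_frames)) {
      if (t > 1L) {
        if (stats::runif(1L) < spec$switch_probability) {
          new_state <- sample.int(spec$n_basins, 1L,
                                  prob = spec$basin_occupancy)
          if (new_state != state) D <- stats::rnorm(p, sd = sdv)
          state <- new_state
        }
        D <- rho * D + stats::rnorm(p, sd = innov)
      }
      basins[t] <- state
      xyz[t, ] <- cmat[state, ] + D
    }
    out <- conformation_ensemble(xyz, atoms, label)
    attr(out, "basins") <- basins
    out
  })
}

#' Simulate replicate runs with partially overlapping basins
#'
#' A fraction `run_overlap` of each run's basins (rounded) is shared by
#' all replicates; the rest are private to each run. Replicates of a
#' real system explore partially overlapping regions of conformational
#' space, which is what makes combining runs for training useful. Per-run
#' seeds are derived deterministically from the master seed.
#'
#' @param spec a [fixture_spec()].
#' @param n_runs number of replicate runs, >= 2.
#' @param run_overlap overrides `spec$run_overlap` when given.
#' @return List of [conformation_ensemble()]s labelled `run1`, `run2`, ...
#' @export
make_replicates <- function(spec, n_runs, run_overlap = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"), n_runs >= 2L)
  if (is.null(run_overlap)) run_overlap <- spec$run_overlap
  n_shared <- round(run_overlap * spec$n_basins)
  n_private <- spec$n_basins - n_shared
  shared <- if (n_shared > 0L)
    withr::with_seed(spec$seed, .draw_centers(spec, n_shared)) else list()
  lapply(seq_len(n_runs), function(r) {
    seed_r <- spec$seed + 7919L * r
    private <- if (n_private > 0L)
      withr::with_seed(seed_r, .draw_centers(spec, n_private)) else list()
    spec_r <- spec
    spec_r$seed <- seed_r + 1L
    make_run(spec_r, centers = c(shared, private),
             label = paste0("run", r))
  })
}

#' Save / load a fixture specification as JSON
#' @param spec a `FixtureSpec`.
#' @param path JSON file path.
#' @return The spec (for `read_fixture_spec`), or `path` invisibly.
#' @export
write_fixture_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixture_spec
#' @export
read_fixture_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_spec(x$n_res, x$caps, x$n_frames, x$n_basins,
               x$basin_occupancy, x$within_basin_sd,
               x$switch_probability, x$ar1_rho, x$run_overlap, x$seed)
}
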