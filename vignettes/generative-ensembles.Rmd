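---
title: "Generative autoencoder sampling of disordered protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative autoencoder sampling of disordered protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(idpae)
```

## The problem and the model

Intrinsically disordered proteins (IDPs) populate broad conformational
ensembles. Molecular dynamics (MD) can sample them, but multi-microsecond
trajectories are costly and single runs mine limited regions of
conformational space. `idpae` treats ensemble generation as a learning
problem: compress heavy-atom Cartesian conformations into a
low-dimensional latent space with an autoencoder trained on the *initial*
portion of a trajectory, describe the training latent vectors by a
multivariate Gaussian, and decode samples from that Gaussian into new
conformations. The later portion of the trajectory, never seen in
training, serves as the test of whether the generated ensemble covers
conformational space that the model was not shown.

The pipeline (`run_single()`, `run_combined()`) is:

1. **Atom selection.** All backbone heavy atoms, heavy atoms of
   acetyl/N-methylamide caps, and side-chain atoms named CB, CG, CD, OE1
   or NE2 (`select_heavy_atoms()`); longer side chains are truncated.
   This keeps the input dimension manageable while retaining shape
   information; a capped polyglutamine 15-mer keeps N = 140 atoms.
2. **Preprocessing.** Frames are superposed onto the first training
   frame (Kabsch superposition, `align_frames()`), then shifted by one
   global offset so all coordinates are positive and divided by one
   global scale (the maximum shifted value), mapping the training data
   into [0, 1] (`fit_scaling()`). The transform is fit on training data
   only and reused verbatim for test and generated data; test
   coordinates may map slightly outside [0, 1], which is harmless.
3. **Autoencoder.** Mirrored dense stacks 3N → 300 → 50 → n and
   n → 50 → 300 → 3N. Every layer is rectified-linear except the
   sigmoidal output layer (so outputs live in (0, 1) like the scaled
   inputs). The loss is the mean element-wise binary cross-entropy; mean
   squared error is available and performs comparably on fixtures.
   Training runs 100 epochs with batch size 40 under Adam.
4. **Latent Gaussian.** `fit_gaussian()` uses plain (population, 1/K)
   moment estimates. `sample_gaussian()` draws by eigen-decomposition
   with negative eigenvalues clipped to zero.
5. **Evaluation.** `best_match_rmsd()` scores coverage: for each
   conformation of a diluted test set, the minimum pairwise-superposed
   RMSD to any generated conformation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| latent width `n` | `round(0.75 * N_res)`, halves up | capping groups count as residues (a capped 15-mer has N_res = 17, n = 13) |
| hidden widths | 300, 50 | mirrored in the decoder |
| epochs / batch | 100 / 40 | final partial batch is kept |
| Adam step size | 1e-3 | moment decays 0.9 / 0.999 |
| `train_fraction` | 0.1 | initial fraction of post-burn-in frames used for training |
| `eval_dilution` | 100 | test-set dilution for evaluation (adjacent MD frames are redundant) |
| `generated_multiple` | 1 | generated-set size as a multiple of the test size |
| histogram bins | 50 × 50 | KL values are only comparable at a stated bin count |
| active-dimension tolerance | 1e-3 | a latent dimension is dead if no value exceeds this |

## Numerical and design choices

* **Latent activation.** The latent layer is rectified-linear like the
  other non-output layers. This makes latent vectors nonnegative and
  typically leaves about half the dimensions dead (constantly zero) — an
  automatic, data-driven reduction of the effective dimension.
  `active_dimensions()` reports the live ones.
* **Degenerate Gaussians.** Dead latent dimensions give a singular
  covariance. Sampling clips negative eigenvalues to zero, so dead
  dimensions are sampled exactly at their (zero) mean, which reproduces
  the decoder's behaviour for inactive neurons. `gaussian_density()`
  evaluates the standard multivariate normal (exponent
  −½ (z−μ)ᵀ σ̃⁻¹ (z−μ), normaliser ((2π)ⁿ det σ̃)^(−1/2)), restricted to
  the positive-eigenvalue subspace on request.
* **Scaling convention.** One scalar shift (−minimum over all training
  coordinates) and one scalar scale (maximum shifted value), not
  per-axis quantities: dividing by "the" maximum coordinate value is
  only well-defined for a single scalar. Generated coordinates are both
  unscaled and unshifted; RMSD-based evaluation is invariant to the
  choice of whether the shift is inverted.
* **Alignment reference.** Frame 1 of the training portion, fixed for
  determinism; the reference choice does not meaningfully affect
  accuracy. The scaling transform stores the reference conformation so
  test and external data can be superposed into the same frame
  (`align_to()`) before encoding.
* **Cross-entropy clamping.** Sigmoid outputs are clamped to
  [1e-7, 1 − 1e-7] before the logarithm.
* **Initialisation and shuffling.** Uniform Glorot-style fan-based
  weight initialisation and per-epoch reshuffling, both driven by one
  stated seed; identical seeds and data reproduce training exactly.
* **Every pairwise RMSD re-superposes the pair** (compiled Kabsch kernel
  with reflection correction, `src/rmsd.cpp`). The optimal rotation is
  applied and the residual evaluated explicitly because the trace
  shortcut loses half its significant digits to cancellation near zero
  RMSD. Best-match ties break to the lowest reference index; best-match
  search is exhaustive (no approximate nearest-neighbour shortcuts).
* **Nested generated sets.** Latent samples are drawn row by row from
  one seeded stream, so a 4× generated set extends the 1× set
  (up to floating-point round-off from batched linear algebra) and
  best-match coverage is non-increasing in the set size by the superset
  property.
* **KL zero rule.** Grid cells where either histogram is empty
  contribute nothing. This makes KL(p, q) = 0 for disjoint supports, so
  KL values here are only meaningful for substantially overlapping
  distributions and must be reported with the grid used.
* **Mixture option.** `fit_gaussian_mixture()` (EM, seeded k-means
  initialisation, 200 iterations, 1e-6 relative log-likelihood
  tolerance) reduces exactly to the single Gaussian at k = 1; it exists
  because multi-basin latent distributions are visibly multi-modal.

## The fixture simulator

Real MD inputs for this protocol are multi-microsecond trajectories;
development and validation instead use `make_run()`: a glutamine-like
polymer built from ideal internal coordinates (bond lengths and angles
from standard amino-acid values; per-residue backbone dihedrals drawn
from beta/alpha/polyproline-II combinations, clash-checked), with

* several **basins** (distinct chain conformations),
* a per-frame basin **switch probability** (0.02 by default), and
* within-basin displacements following a first-order autoregressive
  process (coefficient 0.95, stationary SD 1 Å per coordinate),

so trajectories are temporally autocorrelated and an "initial portion"
training split is meaningful. `make_replicates()` gives runs whose basin
sets only partially overlap (`run_overlap`), emulating replicate MD runs
that mine different regions. The default validation conditions are a
capped 15-residue chain, 5,000 frames, 3 basins; the combined-replicates
checks use four 2,400-frame runs at 30% training size with overlap 0.5.
These sizes keep a full single-run pipeline around 20 s on one CPU while
leaving the comparisons far from their decision boundaries.

What the fixtures do **not** emulate: real force-field energetics,
secondary-structure statistics, solvent effects, and the slow, partial
convergence of real IDP simulations. Passing the suite demonstrates that
the implementation is correct and that the protocol behaves as designed
on data with the assumed structure — not that any particular real IDP
will be covered at a given RMSD.

```{r pipeline, eval = FALSE}
run <- make_run(fixture_spec())
res <- run_single(run, pipeline_config())
res$report
```

## Degenerate inputs and failure modes

* Collinear coordinates make the superposition rotation ill-conditioned;
  alignment falls back to a pure translation.
* A zero coordinate range cannot be scaled and errors immediately.
* A non-finite training loss aborts with a diagnostic rather than
  continuing.
* Dilution keeps frames 1, 1+k, 1+2k, …; it never empties a nonempty
  ensemble.
* Decoded conformations are produced coordinate-wise and generally
  violate covalent geometry; `geometry_check()` audits bonds (±15% of
  ideal) and angles (±15°) against residue templates. Refinement
  (energy minimisation) is out of scope — generated ensembles are
  written unrefined with the audit alongside.

## Known limitations

* Training-set coverage bounds generative coverage: a single run that
  never visits a basin cannot generate it. Combining replicate runs
  (`run_combined()`) is the remedy and measurably improves coverage on
  partially overlapping fixtures.
* The single multivariate Gaussian oversmooths strongly multi-modal
  latent distributions; samples between basins decode to blended
  conformations (visible in the geometry audit).
* Best-match evaluation is O(test × reference) pairwise
  superpositions; dilute the test set accordingly.
* The latent-width rule `0.75 × N_res` is an empirical operating point,
  not an optimum; widening the latent space does not necessarily help.
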