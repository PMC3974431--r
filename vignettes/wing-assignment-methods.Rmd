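---
title: "Landmark shape analysis and taxonomic assignment with wingshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark shape analysis and taxonomic assignment with wingshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wingshape` places unknown insect-wing specimens — typically fossils known
only from their venation — among labeled reference groups using
landmark-based geometric morphometrics. This vignette explains the model
behind each stage, the parameters that matter, the numerical conventions,
and what the synthetic data generator does and does not emulate.

## Data model

A specimen is a configuration of *k* homologous planar landmarks (vein
intersections), stored in long form: one row per landmark with
`specimen_id`, `group`, `side`, `landmark`, `x`, `y`. Landmark order *is*
the homology correspondence and is never re-sorted. TPS files are the
exchange format (`read_tps()` / `write_tps()`); group labels travel in a
sidecar CSV because TPS has no grouping field.

Two ingest conventions deserve note:

* **Scale.** A `SCALE=` factor is multiplied into the coordinates at read
  time (the tpsDig convention); `write_tps()` divides it back out, so
  read → write → read is the identity. Since superimposition removes size,
  this choice cannot affect any shape statistic.
* **Missing landmarks.** The analysis requires complete configurations.
  `read_tps()` rejects non-finite coordinates and the conventional
  `-1 -1` missing-data sentinel. Generic negative coordinates are accepted:
  centered or translated configurations are legitimate TPS content, and a
  blanket ban on negative values would break the read/write round trip.
* **Handedness.** Reflections are never fitted during superimposition. Left
  wings are made comparable with right wings explicitly, by
  `reflect_configuration()` (negate x about the centroid, flip the `side`
  flag). Whether a digitizing protocol requires landmark re-indexing after
  reflection depends on the landmark scheme; the function leaves order
  unchanged and exposes a `relabel` permutation hook for protocols that
  need it.

## Superimposition

`gpa()` implements generalized least-squares Procrustes superimposition
under the *partial* Procrustes convention: every configuration is centered
and fixed at unit centroid size, with no residual per-specimen scale
fitting during iterations — the common default of landmark-morphometrics
software. The algorithm initializes the consensus from the first specimen,
alternates optimal proper rotation of all preshapes onto the consensus with
consensus re-estimation (mean, rescaled to unit size), and stops when the
consensus moves less than `tol = 1e-8` in partial Procrustes distance
(`max_iter = 100`; non-convergence returns a flagged result with a
warning). The summed squared deviation from the consensus is recorded per
iteration and is non-increasing.

For planar shapes the optimal rotation has a closed form: with
cross-products a = Σ xᵢ·yᵢ and b = Σ (xᵢ × yᵢ), the optimal inner product
is √(a² + b²). The public `optimal_rotation()` uses the SVD of the 2×2
cross-product matrix with a determinant correction so reflections are
impossible; the two routes agree and are cross-checked against each other
and against a dense angular grid search in the tests.

Two gauge freedoms are fixed for reproducibility: the final aligned set is
rotated so the consensus's major principal axis is horizontal, and flipped
180° if needed so the first consensus landmark lies in the right
half-plane. Output files are therefore byte-identical across runs and
input orderings.

## Tangent projection and its adequacy

Aligned preshapes lie on a sphere (unit centroid size); statistics are done
in the tangent space at the consensus **c** (a unit vector after
vectorization). Each vectorized aligned shape **x** is projected as
**x′** = **x** − (**x**·**c** − 1)**c** and expressed as the deviation
**x′** − **c**. The resulting n × 2k score matrix has rank at most 2k − 4
(two translations, one scale, one rotation are gone).

The linearization is only valid if tangent distances faithfully represent
shape-space distances. `tangent_adequacy()` computes all pairwise
Procrustes ρ distances (arc length on the preshape sphere) and all pairwise
Euclidean distances among tangent scores, and reports the
**through-origin** regression slope of Euclidean on ρ and their uncentered
correlation — through the origin because the claim under test is
proportionality; an intercept would mask a failure at small distances.
Both values reach ≥ 0.999 at 1% landmark noise (the regime of real
digitization error) and degrade as variance grows. Samples with no shape
variation (maximum ρ below 1e−7, the numerical floor that √/acos near 1
impose on double precision) are rejected rather than regressed.

## Discrimination and cross-validation

Raw tangent coordinates make the pooled within-group covariance singular
(36 variables, rank ≤ 32 for k = 18), so `lda_fit()` always discriminates
in a retained-principal-component space. The `"auto"` rule keeps
components with eigenvalue > 1e−10 × the largest, capped at
min(p, n − G − 1) so the pooled covariance stays invertible with room to
spare; the retained dimension is recorded in every downstream report and
can be overridden with an integer `n_components`. Group means and the
pooled within-group covariance are estimated in that space; canonical axes
come from the symmetrized generalized eigenproblem of between- versus
within-group scatter (at most G − 1 axes).

Priors default to group-size proportional (`"equal"` and explicit vectors
are available) and are recorded in the fitted model. Posteriors follow the
shared-covariance Gaussian model, PP_g ∝ π_g exp(−MD_g²/2), normalized
with a log-sum-exp guard so extreme distances cannot underflow to 0/0.
With equal priors, maximum posterior and minimum Mahalanobis distance give
identical assignments; exact posterior ties are broken toward the first
group in label order and flagged. The hand-built discriminant is verified
in the tests against an independent reference implementation
(`MASS::lda`) on random low-dimensional instances.

`loo_crossvalidate()` refits everything that is estimated from data —
including the PC reduction — inside each fold, then tallies held-out
predictions into a confusion matrix. Per-group hit ratios are displayed
rounded to integers and the overall ratio to two decimals (the field's
reporting convention); full precision is kept in the returned columns. The
Procrustes superimposition is *not* re-run per fold: cross-validation
operates "in LDA space", treating superimposition as upstream. This is a
documented limitation — the consensus sees every specimen once — but its
leakage is negligible for n in the hundreds and matches standard practice.

## Assigning unknowns

`assign_unknowns()` mirrors the two-step reference/unknown protocol: in the
default `joint` mode the reference and unknowns are superimposed together
(n_ref + n_unk configurations), but the PCA/LDA maps are estimated from
the reference rows only, and unknowns are passed through those fixed maps
a posteriori. The alternative `opa` mode aligns each unknown one-by-one
onto the reference-only consensus, guaranteeing unknowns cannot influence
the consensus; the two modes agree for well-separated cases and the choice
is logged in the report. Mahalanobis distances are computed in the full
retained-PC space (not a discriminant-axis subset), and the dimension used
is recorded, since reported distances are only comparable at a stated
dimension.

Replicate digitizations of one physical specimen stay independent rows and
are additionally summarized by modal vote (`modal_agreement`, consensus
group); coordinates are never averaged by default. The procedure always
assigns to *some* group — there is no novelty model — so a warning flags
any unknown whose smallest MD exceeds the 99th percentile of the
reference's own within-group distances, the pragmatic "none of the above"
signal.

## The synthetic generator

`wing_sim_spec()` describes the data-generating process the analysis
assumes, and is the package's test bed:

* **Template**: k landmarks on a flattened convex arc with seeded jitter,
  unit centroid size — a stand-in for a real wing's landmark scheme.
* **Group mean shapes**: template + a seeded Gaussian displacement field
  scaled to `effect_size` and projected orthogonal to the template's
  similarity directions (translations, scale, rotation), so the nominal
  effect is pure shape signal that superimposition cannot remove.
* **Specimens**: group mean + isotropic N(0, `noise_sd`²) per landmark
  per axis, then a random similarity transform (rotation uniform on
  (−π, π), log-scale uniform on (−0.7, 0.7), translation uniform on
  (−2, 2)) — the nuisance the pipeline must be invariant to.
* **Replicates**: one true specimen drawn from the group model, then
  `n_replicates` observations with independent `digitization_sd` noise and
  nuisance transforms, emulating the same wing digitized by several
  experimenters.

Defaults are k = 18 landmarks and the 15-group/360-specimen composition of
the bee-forewing reference collection shipped in `inst/extdata`, with
`effect_size = 0.05`, `noise_sd = 0.01` (1% of centroid size, a typical
digitization error), `digitization_sd = 0.005`. At these values the
synthetic design reproduces the empirical regime: adequacy slope ≈ 0.9997
and leave-one-out hit ratio ≈ 99%, comparable to the 98.61% that the
reference collection's published confusion table yields. Every draw is
deterministic given the seed, with independent sub-streams per group so
adding a group never perturbs earlier groups' data.

What the generator does **not** emulate: anatomically structured
(non-isotropic, spatially correlated) landmark covariance, allometry
(shape–size correlation), within-group phylogenetic structure (species
nested in subfamilies), measurement error that differs among landmarks,
and digitizer-specific bias. Passing tests therefore demonstrate the
correctness and invariances of the algorithms under the stated model, not
that any particular empirical dataset satisfies that model.

## Numerical choices and problem sizes

* Convergence: 1e−8 on consensus movement; invariance assertions at 1e−9
  where algebra permits, 1e−7 where √/acos near 1 amplify machine epsilon.
* Posterior normalization via log-sum-exp; pooled-covariance inversion via
  symmetric eigendecomposition with a 1e−12 relative floor, refusing to
  fit rather than silently regularizing.
* Ties: first group in label order, flagged.
* Test and acceptance runs use n up to 360 specimens (the reference
  design), 2000 specimens for the law-of-large-numbers noise-recovery
  check, 100 random pairs for the rotation-oracle comparison, and 100
  seeded trials for replicate-fossil recovery; each completes in seconds
  to a couple of minutes on one CPU.
* The chance-level check for a zero-effect design uses equal priors, where
  chance is exactly 100/G percent; with proportional priors and strongly
  unequal groups, "chance" depends on how much the classifier follows the
  prior and is not a well-defined benchmark.
* The fossil-recovery acceptance trials use `effect_size = 0.12` (rather
  than the default 0.05): that check asks whether the replicate workflow
  recovers a *clearly distinct* group with near-certain posteriors, so the
  design separation is set well above noise by construction.

## Limitations

Two-dimensional fixed landmarks only (no curves/semilandmarks, no 3-D);
complete configurations required; no novelty detection beyond the
distance-quantile warning; cross-validation does not refit the
superimposition per fold; assignment assumes the unknown's true group is
present in the reference — when it is not, posteriors can still be
confidently wrong, which is why the Mahalanobis distances themselves, and
the warning threshold, should always be inspected alongside the posterior
probabilities.
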