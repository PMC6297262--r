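---
title: "Longitudinal Jacobian-map morphometry with jacmorph: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal Jacobian-map morphometry with jacmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

`jacmorph` implements a longitudinal voxel-based (tensor-based) morphometry
pipeline for three-timepoint structural MRI of the rodent brain: a baseline
scan, a scan after an exposure (for the motivating design, four days of binge
ethanol), and a scan after a week of recovery. The question the pipeline
answers is *which brain regions expand or shrink over each interval, and
which of those changes reverse with recovery* — without tracing regions of
interest by hand.

The core quantity is the **log-Jacobian determinant map**. Non-rigid
registration of the earlier scan of an interval to the later one yields a
deformation $\varphi(x) = x + u(x)$; the determinant of its spatial gradient,
$\det \nabla\varphi(x)$, is the local volume ratio (later / earlier), and

$$ J(x) = \ln \det \nabla \varphi(x) $$

is positive where tissue or fluid expanded and negative where it shrank.
Because the earlier scan is the fixed image, interval-1 maps live on the
baseline grid and interval-2 maps on the post-exposure grid, which matches
the analysis plan: interval-1 statistics are carried out on a group-wise
template built from the baseline scans, interval-2 statistics on a separate
template built from the post-exposure scans. The two templates are never
mixed.

# Pipeline stages and their assumptions

1. **Preprocessing** (`denoise`, `correct_bias`, `skull_strip`,
   `rigid_align`, `match_intensity`). Non-local-means denoising (patch
   radius 1, search radius 2, bandwidth tied to a background noise
   estimate); multiplicative bias-field correction by order-3 polynomial
   regression of log-intensity inside the brain mask with Tukey-biweight
   reweighting (four passes) so distinct tissue classes do not leak into the
   smooth field; skull stripping by registering a template to the scan and
   carrying the template's brain mask through the deformation; 6-DOF rigid
   alignment by multi-resolution coordinate descent on normalised
   cross-correlation from four starting orientations. Bias correction runs
   twice — before and after stripping — since the background biases the
   first fit. Before each interval registration, the earlier scan's
   intensity profile is matched to the later scan's by exact monotone
   quantile mapping.

2. **Dense diffeomorphic registration** (`register_nonrigid`). A
   multi-resolution (3-level) demons scheme over a stationary velocity
   field: each iteration computes the Thirion intensity-difference force,
   smooths it (fluid-like regularisation), adds it to the velocity, smooths
   the velocity (diffusion-like regularisation), and exponentiates by
   scaling-and-squaring to obtain the transform. The exponential of a
   smooth velocity field is fold-free, and the discrete Jacobian is checked
   at every exit path; a field with non-positive determinant is never
   emitted.

3. **Group-wise template** (`build_groupwise_template`). All subjects are
   registered to an evolving mean image; each outer iteration subtracts the
   mean displacement field from every subject's field (unbiasing) before
   averaging the warped images, so the final fields have zero mean
   displacement by construction. Template averaging uses cubic (Keys)
   interpolation: with trilinear resampling the double interpolation cost
   exceeds the sharpness gained by aligning a mildly jittered cohort, and
   the classic "template sharper than the naive mean" property is lost to
   interpolation blur rather than misalignment.

4. **Jacobian handling** (`log_jacobian`, `to_template_space`,
   `bilateral_average`). Spacing-aware central differences (exact for
   affine transforms); scalar transport to template space by linear
   interpolation *without* Jacobian modulation, so template-space values
   remain interpretable as subject-space log volume ratios; bilateral
   averaging about the central sagittal index plane (each voxel averaged
   with its mirror), after which inference uses only the right hemisphere.
   No additional smoothing is applied to the maps (an optional Gaussian is
   deliberately absent; registration regularisation is the only smoothing).

5. **Inference** (`voxelwise_t`, `permutation_p`, `estimate_fwhm`,
   `mc_cluster_threshold`, `extract_clusters`). One-tailed voxel-wise
   t statistics (pooled two-sample for exposed vs control, one-sample
   against zero within group), with p-values from group-label permutations
   or sign flips — exhaustive whenever the number of arrangements is within
   the permutation budget, and equal to brute-force enumeration in that
   case. Both directions (expansion and shrinkage) are tested everywhere
   and retain their direction labels, since the reported tables carry
   expand and shrink columns per interval. Cluster-extent correction
   simulates null fields at the smoothness estimated from the standardised
   residuals (gradient estimator), thresholds at the voxel p, and takes the
   smallest cluster size whose exceedance probability is at most the
   family-wise $\alpha$; one threshold per comparison is shared by both
   directions. Contiguity defaults to 6-connectivity (faces); 18 and 26 are
   available.

6. **Atlas overlap and pattern labels** (`map_clusters_to_atlas`,
   `roi_overlap_table`, `overall_change`, `classify_pattern`). Surviving
   clusters are mirrored to both hemispheres (consistent with bilateral
   averaging and bilateral reporting), carried through the
   template-to-atlas registration with nearest-neighbour interpolation, and
   intersected with each atlas ROI. Percentages are $100 \cdot
   \text{overlap}/\text{ROI volume}$, rounded half-up to two decimals at
   report time only; the net Overall column is computed from raw voxel
   counts *before* rounding (a large expansion followed by an almost equal
   shrinkage must yield the small net value the unrounded arithmetic
   implies). The 10%-of-ROI relevance threshold drives the pattern
   taxonomy: reversible expansion (expand then shrink), reversible
   shrinkage (shrink then recover), enduring shrinkage (shrink without
   recovery), enduring tissue/fluid expansion (expansion with no opposing
   change; the fluid label for CSF-class ROIs), below-threshold, and mixed.

# A note on intensity matching under large volume change

`run_pipeline` matches the earlier scan's intensity profile to the later
scan before each interval registration (`histogram_match = TRUE`), the
appropriate default for acquired data whose global intensity profile
drifts between sessions. Whole-histogram quantile matching has a failure
mode worth knowing about, however: when a scan pair differs by a *large
focal* volume change, the two histograms genuinely differ (an enlarged
bright CSF compartment adds mass to the upper intensities), and forcing
them equal shifts tissue intensities everywhere — in a group-specific way
when only one group carries the change. In validation cohorts with an 87%
ventricular expansion this produced consistent, spurious "recovery"
clusters in remote tissue in the between-group interval-2 comparison.
Phantom scans share a common intensity profile by construction, so the
validation analyses disable the matching step (`histogram_match = FALSE`);
the registration's own foreground-median normalisation provides the
required scale invariance. For real data a middle ground (e.g. matching on
a tissue-only mask) may be preferable; the flag makes the choice explicit.

# The synthetic cohort generator

Real raw scans for this design are not publicly deposited, so the package
ships a first-class phantom module that generates cohorts with analytically
known deformations; every downstream stage is validated against it.

* **Anatomy.** A T2-like intensity volume on a 160x160x32 grid of
  0.2x0.2x1 mm voxels (the test-suite uses 64x64x32 at the same spacing for
  speed): an ellipsoidal brain envelope containing mirror-symmetric
  ellipsoidal compartments — prelimbic and infralimbic cortex, nucleus
  accumbens, lateral ventricles, central and VPL/VPM thalamus, anterior
  pretectal nuclei, superior and inferior colliculi, and a midline CSF pool
  above the frontal regions. CSF compartments are bright, tissue
  intermediate, background near zero. Intensities are slightly band-limited
  (Gaussian, 0.7 voxel in-plane), as acquired MRI is.
  The acquisition's through-plane geometry is internally inconsistent in
  the motivating description (isotropic 0.2 mm voxels vs 0.5 mm slices with
  a 0.5 mm gap), so through-plane spacing is exposed as a configuration
  knob; 1 mm (slice plus gap) is the default.

* **Known deformations.** Regional volume changes are applied as compactly
  supported radial warps: inside an inner ball the transform is a uniform
  scaling with local volume ratio exactly equal to the prescribed factor;
  a cubic Hermite radial profile blends C1-smoothly to the identity at the
  outer radius, and monotonicity of the profile is verified numerically on
  1024 samples before a field is emitted (fold-free by construction). The
  inner ball is sized to contain the ROI's *preimage* under the pullback —
  for an expansion, the ROI enlarged by the cube root of the volume ratio —
  so the prescribed ratio holds over the whole ROI.

* **Cohorts.** Each subject receives a smooth random jitter warp (max
  displacement 2 voxels, fixed across its three timepoints) emulating
  anatomical variability; group- and interval-specific effect warps are
  composed in base-anatomy coordinates; acquisition artifacts (unit-mean
  low-order polynomial bias field, additive Gaussian noise) are applied
  independently per scan. Rician noise is deliberately not modelled: the
  downstream stages are contrast-driven and additive Gaussian noise
  exercises them equally at far lower complexity. Ground-truth per-ROI
  volume ratios are *measured* from the composed transforms on a 2x2x4
  supersampled grid (plain voxel counting on 1 mm slices cannot resolve
  sub-slice boundary motion) and written alongside the scans.

# Numerical choices

* Demons force: Thirion normalisation with $K = \overline{\Delta x}^2$;
  per-iteration force capped at 0.8 voxel; the force is floored to zero
  where the intensity difference is below $10^{-4}$ of the normalised
  intensity scale, because the Thirion force is scale-free in the
  difference and would otherwise respond to numerically tiny residuals in
  flat regions with O(0.5 mm) pushes.
* Intensity normalisation for registration: each image is divided by its
  foreground median (tissue level). This makes the recovered field exactly
  invariant to a global intensity rescaling of either image, and — unlike
  a high-quantile scale — is insensitive to focal volume changes such as an
  enlarged CSF compartment.
* Regularisation sigmas are specified in millimetres (update 0.5 mm, total
  0.15 mm by default) but floored at 0.8 / 0.3 voxels per axis, so thick
  slices still receive through-plane regularisation; without the floor,
  slice-to-slice oscillation can make the *discrete* Jacobian negative even
  though the underlying exponential is fold-free. If the discrete check
  still fails at exit, the velocity is re-smoothed (up to three times)
  before the field is rejected.
* Field inversion is damped fixed-point iteration (factor 0.8) with a
  mean-residual stopping rule in voxel units.
* Permutation p-values use the $(b+1)/(m+1)$ estimator with the identity
  arrangement always included, so the smallest attainable p equals one over
  the number of arrangements and p is never zero.
* The smoothness estimator converts the lag-one autocorrelation
  $\rho = 1 - \mathrm{var}(\Delta r)/2$ of standardised residuals to a
  Gaussian-equivalent $\sigma = \sqrt{-1/(4\ln\rho)}$ per axis, floored at
  half a voxel.
* Percentages are rounded half-up (not banker's rounding) to match printed
  two-decimal tables; all classification happens on unrounded values.

# Study conditions used by the validation suite

The test suite and the acceptance analyses run at deliberately chosen,
fixed problem sizes:

* phantoms on the 64x64x32 test grid; cohorts of 6 exposed + 6 control
  subjects (the two-sample permutation test is then exhaustive with 924
  arrangements);
* the effect cohort carries ventricular expansion by 1.87 over interval 1
  reversing over interval 2, and 0.85 shrinkage of the superior and
  inferior colliculi without recovery — the reversible-expansion and
  enduring-shrinkage archetypes;
* group-wise templates use 2 outer iterations in the pipeline tests
  (5 is the function default), and Monte-Carlo cluster thresholds use
  300-500 null simulations;
* the family-wise error analysis uses a 48^3 grid at FWHM 2 voxels,
  500-1000 threshold simulations and 400 independent null datasets.

With 6 subjects per group, the within-group sign-flip test has 64
arrangements and a p-value floor of 1/64 > 0.01, so within-group tables are
empty at the default voxel threshold; within-group inference needs the
larger cohort sizes of the motivating design (13 and 12, with 8192 and 4096
arrangements). The between-group comparisons drive the pattern
classification in the validation cohorts.

# What the phantom does and does not show

Passing the phantom suite demonstrates that the machinery is correct: exact
Jacobian arithmetic, exhaustive-permutation equivalence, family-wise error
control on pure noise, and end-to-end recovery of prescribed
reversible/enduring patterns against measured ground truth. It does not
demonstrate robustness to everything real data adds: genuinely
non-Gaussian (Rician) noise at low SNR, susceptibility and motion
artifacts, partial-volume mixtures at fine anatomical boundaries,
atlas-to-subject anatomy mismatch, or inter-scanner intensity
non-stationarity. Registration accuracy on the phantom's high-contrast
compartments is an upper bound on accuracy for subtle tissue boundaries.

# Known limitations

* The demons metric is mean-squared intensity difference after histogram
  matching; there is no mutual-information option, so cross-modality
  registration is out of scope.
* Cluster thresholds depend on the simulated null smoothness; they are
  recomputed per comparison and never reused across geometries.
* The atlas-overlap stage uses a single atlas-space ROI volume per ROI for
  both intervals' percentages.
* The CLI covers the simulate / run / report verbs; stage-wise re-runs
  (statistics or overlap only) are done from R, where every stage is an
  exported function.
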