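# jacmorph

Longitudinal Jacobian-map (tensor-based) morphometry for small-animal
structural MRI, in R.

`jacmorph` is for researchers who scan the same animals repeatedly — a
baseline scan, a scan after an exposure, a scan after recovery — and want to
know *which brain regions expanded or shrank over each interval, and which
changes reversed*, without hand-tracing regions of interest. The motivating
design is a rodent binge-ethanol study: three T2-weighted scans per rat
(baseline, post-binge, post-recovery), an exposed and a control group, and a
digital label atlas for reporting.

## The model

For each animal and scan interval, the earlier scan is non-rigidly
registered to the later one, giving a diffeomorphic deformation
$\varphi(x) = x + u(x)$. The **log-Jacobian determinant map**

$$ J(x) \;=\; \ln \det \nabla\varphi(x) $$

is the local log volume ratio (later/earlier): $J > 0$ where tissue or
fluid expanded, $J < 0$ where it shrank. Per interval, all animals' maps
are carried into a group-wise unbiased template space, bilaterally averaged
about the mid-sagittal plane, and tested voxel-wise with one-tailed
permutation tests (group-label permutations between groups, sign flips
within group) at voxel $p < 0.01$. Multiple comparisons are controlled by
cluster extent: Monte-Carlo simulation of smooth null fields at the
residual smoothness yields the minimum cluster size with family-wise
$\alpha = 0.05$. Surviving clusters are mirrored to both hemispheres,
warped onto the atlas, and reported per ROI as expansion/shrinkage
percentages with a net "overall" column and a pattern label — reversible
expansion/shrinkage, enduring shrinkage, enduring tissue or fluid
expansion — using a 10%-of-ROI relevance threshold.

Because raw scans for such designs are rarely deposited, the package also
ships a first-class synthetic cohort generator: phantom brains with labeled
compartments, per-subject anatomical jitter, acquisition artifacts, and
analytically known regional volume changes (compactly supported radial
warps whose Jacobian inside the region equals the prescribed ratio
exactly). Every stage of the pipeline is validated against it.

## Worked example

Overlap arithmetic on printed-table counts — a 253-voxel ventricle ROI
overlapped by a 221-voxel expansion cluster in interval 1 and a 220-voxel
shrinkage cluster in interval 2:

```r
library(jacmorph)
r1 <- roi_overlap_row("Ventricles", 253, expand_vol = 221, interval = 1, tissue_class = "csf")
r2 <- roi_overlap_row("Ventricles", 253, shrink_vol = 220, interval = 2, tissue_class = "csf")
c(expand_pct = r1$expand_pct, shrink_pct = r2$shrink_pct,
  overall = overall_change(r1, r2))
#> expand_pct shrink_pct    overall
#>      87.35      86.96       0.40
classify_pattern(r1, r2)
#> [1] "reversible_expansion"
```

The expansion and shrinkage nearly cancel: the overall column is computed
from raw voxel counts before rounding, which is why it is 0.40% rather
than the 0.39% that subtracting the rounded percentages would give.

An analytic deformation with exactly known Jacobian, recovered by the
finite-difference log-Jacobian map:

```r
geom <- list(dim = c(40L, 40L, 40L), spacing = c(0.2, 0.2, 0.2), origin = c(0, 0, 0))
spec <- analytic_warp_spec(center = c(4, 4, 4), inner_radius = 2,
                           outer_radius = 3.2, volume_ratio = 1.8735)
lj <- log_jacobian(make_analytic_warp(spec, geom))
exp(mean(lj$values[as.vector(
  outer(outer((1:40 - 1) * 0.2 - 4, (1:40 - 1) * 0.2 - 4,
        function(a, b) a^2 + b^2), ((1:40 - 1) * 0.2 - 4)^2, `+`)) < 1.75^2]))
#> [1] 1.8735
```

End to end on a simulated cohort (6 exposed + 6 control subjects,
64 x 64 x 32 phantoms; ventricular expansion by 1.87 reversing after
recovery, 15% collicular shrinkage without recovery; ~5 minutes on one
core):

```r
g   <- phantom_geometry(c(64, 64, 32))
eff <- rbind(effect_spec("ventricles", 1, "EtOH", 1.87),
             effect_spec("ventricles", 2, "EtOH", 1 / 1.87),
             effect_spec("superior_colliculus", 1, "EtOH", 0.85),
             effect_spec("inferior_colliculus", 1, "EtOH", 0.85))
man <- simulate_cohort(list(n_etoh = 6, n_con = 6, geometry = g), eff,
                       list(noise_sigma = 4, bias_amplitude = 0.1),
                       seed = 101, outdir = "sim")
cfg <- run_config(manifest = man$manifest, template = man$template,
                  template_mask = man$template_mask,
                  atlas_labels = man$atlas_labels, atlas_lut = man$atlas_lut,
                  atlas_tissue = man$atlas_tissue, outdir = "out", seed = 7,
                  reg = reg_params(iterations = c(30, 20, 12)),
                  strip_reg = reg_params(iterations = c(15, 8, 4)),
                  n_outer_groupwise = 2, n_sim = 250,
                  histogram_match = FALSE)  # phantom scans share one intensity profile
res <- run_pipeline(cfg)
res$tables$between[c(5, 9, 10), c("roi", "expand_pct_1", "shrink_pct_1",
                                  "expand_pct_2", "shrink_pct_2", "pattern")]
#>                    roi expand_pct_1 shrink_pct_1 expand_pct_2 shrink_pct_2              pattern
#> 5           ventricles        93.75         2.21         1.10        94.49 reversible_expansion
#> 9  superior_colliculus         0.00        59.84         0.00         0.00   enduring_shrinkage
#> 10 inferior_colliculus         0.00        14.64         0.00         0.00   enduring_shrinkage
```

The ventricles are flagged as almost entirely covered by an expansion
cluster in interval 1 and a shrinkage cluster in interval 2 — the
reversible-expansion archetype — while both colliculi show interval-1
shrinkage with no recovery. On a null cohort (no effects) all tables come
back empty (`below_threshold` everywhere). Full reports — per-comparison
overlap CSVs, cluster-size thresholds, a pattern summary, the run log and
an output checksum manifest — are written under `outdir`.

A thin command-line front end with `simulate`, `run`, and `report` verbs
is installed at `inst/cli/jacmorph.R`; stage-wise re-runs are done from R,
where every stage is an exported function.

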