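# acroplan

Geometric planning of two parallel fixation screws for fractures of the
anatomic acromion (Ogawa type I), computed from a 3D bone surface model.

Clinically, these fractures are fixed with two screws driven along the
long axis of the distal acromion — a thin, curved plate of bone where a
screw that is too wide, too long, or badly aimed breaches cortex. Given a
watertight scapular surface mesh (or a binary CT segmentation) plus three
anatomical landmarks, `acroplan` computes, per subject:

- the **viewing axis** that maximizes the intraosseous corridor — the
  projected region through which a straight path crosses one continuous
  segment of bone (the oval seen when rendering the bone semi-transparent
  down the acromion axis);
- the **maximal diameter and bicortical length** of a medial and a
  lateral screw, by splitting the corridor evenly and inscribing the
  largest circle in each half, with full 3D cylinder-containment
  verification;
- the **entry-point distances** L1–L4 to the acromioclavicular facet and
  the anterior edge, and the **angles** α (downdip against the superior
  reference plane A) and β (medial/lateral inclination against the
  perpendicular plane B).

A pixel of the corridor map is *safe* iff its ray has exactly one in-bone
interval with chord ≥ `min_chord`; the direction search maximizes the
area above a chord threshold frozen at a fraction of the longest chord in
the search cone, which is maximal exactly when the view aligns with the
corridor. The statistics layer reproduces cohort summary tables
(mean ± SD rows by sex, pooled two-sample *t*, p-values), including *t*
statistics recomputed directly from printed group summaries:

```
t = (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2)),   sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2)
```

Because no patient imaging is distributed with the reference study, the
package includes a parametric generator of acromion-like solids (curved,
tapering elliptical rod with an oblique posterior cut, a flattened
superior strip, and smooth surface bumps) that returns exact ground truth
— including an analytic inside/outside predicate used as an independent
oracle by the test-suite.

## Worked example

```r
library(acroplan)

subject <- generate_acromion(acromion_params(seed = 42))   # one synthetic subject
res <- run_subject(subject = subject, subject_id = "demo", sex = "M")
res$screws$medial
#> screw_plan [medial]: diameter 4.02 mm, length 49.1 mm
#>   entry (-0.9, 0.1, 0.0), direction (-0.083, -0.056, 0.995)
round(res$measurement[, 3:12], 2)
#>  ms_length ms_diameter ls_length ls_diameter   L1   L2    L3   L4 alpha beta
#>      49.07        4.02      45.9        4.25 9.94 2.94 13.76 4.54  8.25 2.24
```

The medial screw is 49.1 mm long and 4.0 mm wide: its axis enters the
anterior cortex, exits flush with the posterior cortex, and the whole
shaft (checked 0.05 mm inside its radius) stays in bone. It is longer
than the lateral screw because the medial acromion runs on into the
scapular spine. `alpha = 8.25` says the screw course dips 8.25° below the
superior surface plane of the distal acromion.

The statistics layer works from raw measurements or from printed
summaries (`c(mean, sd, n)`):

```r
t_from_summary(c(50.79, 4.33, 50), c(41.87, 4.19, 50))  # medial length, M vs F
#> t = 10.468, df = 98.0, p = 0.000 (pooled)
pooled_mean_sd(c(43.26, 4.64, 50), c(35.20, 4.28, 50))  # combined cohort row
#> 39.23 ± 6.01 (n = 100)
```

File-based inputs work the same way: `load_mesh()` (STL/PLY),
`load_volume()` + `mesh_from_volume()` (NIfTI segmentations), and
`read_landmarks()` (JSON with `ac_facet`, `anterior_edge`,
`superior_patch`), then `run_subject(mesh = ..., landmarks = ...)`.

## Analysis scripts

The study itself lives in `analysis/`, thin drivers over the package:

- `analysis/01_reference_statistics.R` — recomputes the combined-cohort
  rows and pooled *t* statistics of the published screw tables from their
  printed sex-stratified summaries, flagging the printed cells that are
  internally inconsistent; writes `results/reference_statistics.csv`.
- `analysis/02_single_subject.R` — plans one synthetic subject end to
  end; writes the corridor map (PGM + JSON frame sidecar), screw plans
  (JSON), measurement row (CSV), and the mesh (STL).
- `analysis/03_cohort_study.R` — the 50 + 50 synthetic cohort with the
  three sex-comparison tables; writes `results/cohort/`.

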