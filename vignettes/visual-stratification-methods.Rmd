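---
title: "Automated tau PET visual stratification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tau PET visual stratification: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauvisread)
```

## The problem

Flortaucipir PET measures aggregated tau neurofibrillary pathology in the
living brain. Quantitation pipelines summarize a scan as a single
AD-signature weighted SUVr (standardized uptake value ratio) and call a
patient *high tau* when that SUVr exceeds 1.46 -- but they require
specialized software and processing. The visual stratification read is a
two-step procedure a trained physician can perform with ordinary display
software: anchor a threshold on the cerebellum, look at a fixed set of
cortical regions, and classify the scan. `tauvisread` implements that
procedure as a deterministic image classifier, plus the statistics a
multi-reader validation study of such a read uses, plus a synthetic
phantom generator so the whole pipeline can be exercised end-to-end with
known ground truth.

## The stratification model

All thresholds are anchored on the **mean cerebellar count (MCC)**, the
mean tracer intensity over a cerebellar reference region. Because every
threshold is a *multiple* of the MCC, the classifier is invariant to
global intensity scaling -- units (raw counts vs. SUVr) never matter.
This invariance is asserted by tests on every synthetic cohort scan.

* **Step 1 (tier read).** Voxels strictly above `1.65 x MCC` are
  suprathreshold. Twelve cortical region-sides (lateral anterior
  temporal, lateral posterior temporal, occipital, parietal, precuneus,
  frontal; left and right) are scored positive/negative, and an ordered
  decision table maps the 12 scores to a tier:
  - `tau_ad_negative`: no posterior AD pattern (none of lateral
    posterior temporal, occipital, parietal, precuneus positive on
    either side);
  - `tau_ad_plusplus` (advanced): an AD pattern with parietal,
    precuneus, or frontal involvement;
  - `tau_ad_plus` (moderate): an AD pattern without those regions.

* **Step 2 (high-tau read).** Only scans consistent with AD continue.
  The threshold is raised to `2.80 x MCC` and four regions are scored
  bilaterally (temporal, occipital, parietal, frontal). The scan is
  **high tau** iff either frontal side is positive at this raised
  threshold. Non-frontal step-2 scores are recorded but unused, matching
  the validated protocol.

The frontal lobe carries the decision because tau accumulates there late
in the typical AD cascade: highly elevated frontal signal is a proxy for
advanced global tau burden.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `step1_multiplier` | 1.65 | x MCC | tier-read visual threshold |
| `step2_multiplier` | 2.80 | x MCC | high-tau visual threshold |
| `min_cluster_voxels` | 5 | voxels | smallest 26-connected cluster that counts as regional positivity |
| `mcc_method` | `mask3d` | -- | `slice2d` mimics a manually drawn 2-D ROI |
| `step2_scheme` | `step2` | -- | coarse 4-region bilateral scoring; `step1` re-uses the 12 atomic sides |

Both thresholds use strict `>`, exactly as the protocol words them. The
protocol says a region is positive "regardless of the signal intensity or
extent"; read literally, a single suprathreshold voxel suffices. Human
readers in practice ignore single-voxel speckle, so the default demands a
26-connected cluster of at least 5 voxels; setting
`min_cluster_voxels = 1` realizes the literal reading. Components are
labeled on the whole suprathreshold map and then intersected with the
region mask, so a cluster straddling a region boundary still counts with
its in-region extent.

The exact supplemental rule text of the original 3-tier read is not
reproduced in the source describing this method, so the decision table is
a named, swappable object (`decision_table()`); the default encodes the
narrative rules above and is verified *total* by exhaustive enumeration
of all 2^12 score patterns at construction. Step 2 names four bilateral
regions while step 1 names six: by default step-2 "temporal" is the union
of the two lateral temporal sides and step-2 "parietal" the union of
parietal and precuneus, preserving 8 step-2 scores. Only the frontal
scores feed the high-tau decision, so this granularity choice cannot
change the stratum; the `step1` scheme is provided for invariant checks
(threshold nesting needs shared region definitions).

The MCC default is `mask3d` (mean over the full 3-D cerebellar mask)
because it is reproducible and uses all reference voxels; `slice2d`
(densest axial slice only) mimics the label-protocol 2-D ROI and is
provided for sensitivity analyses. With a nonpositive MCC the scan is
rejected as corrupt rather than silently producing thresholds.

## Quantitation module

The simplified SUVr is `sum(w * intensity) / mean(reference)` with `w` a
voxel weight map normalized to sum 1. Two deliberate simplifications,
both recorded in every result object:

* the published AD-signature target's voxel-level weights are not
  public, so the default map weights posterior cortical region-sides 2:1
  over frontal (honoring the heavier posterior weighting) and is
  user-replaceable by any nonnegative weight volume;
* the reference statistic is the arithmetic mean of the named reference
  region (default cerebellum), not the histogram-mode white-matter
  estimate used by the published pipeline, which is a separate algorithm
  outside this package's scope.

Cuts are strict as printed: eligibility requires SUVr >= 1.10 (an
advanced-pattern scan is eligible regardless -- the override affects
eligibility only, never high-tau status), and high tau requires
SUVr > 1.46. Consequently the phantom SUVr values are comparable to the
method's thresholds only qualitatively; the designed cohort truth is the
authoritative label for synthetic scans.

## The phantom generator

`build_synthetic_atlas()` parcellates a grid (default 48^3 voxels at
2 mm) into an inferior central cerebellar block and 12 cortical boxes
mirrored across the mid-sagittal plane, each at least 50 voxels.
`generate_phantom()` realizes designed uptake: region voxels get
`multiplier x cerebellar_mean`, cerebellum gets `cerebellar_mean`,
background gets half the cerebellar mean (so the 1.65x threshold never
fires on background, mirroring real sub-cerebellar contrast); then
Gaussian smoothing of the stated FWHM; then seeded i.i.d. Gaussian
noise. Single-scan defaults are `noise_sd = 0.05` cerebellar-mean units
and 4 mm FWHM -- mild, scanner-like values; invariant tests that require
exact designed truth pass `0` for both explicitly.

`generate_cohort()` draws per-scan multipliers from documented ranges
chosen so the designed truth stays unambiguous after smoothing:

* high-tau scans: frontal in (2.9, 3.6), posterior AD regions
  (lateral posterior temporal, occipital, parietal, precuneus) in
  (1.8, 3.0), anterior temporal in (1.2, 2.6);
* non-high AD scans: frontal in (1.1, 2.6), same posterior ranges;
* moderate-pattern (tau_ad_plus) scans: only lateral posterior
  temporal/occipital elevated in (1.8, 3.0); parietal, precuneus and
  anterior temporal in (0.9, 1.3), frontal in (1.1, 1.5);
* negative scans: all multipliers in (0.9, 1.3).

The default mix is 70 high-tau, 70 non-high AD, 20 negative scans with
~5% of AD-pattern scans carrying the moderate pattern -- the validated
study's composition. A high-tau design forces frontal signal above
1.65 x MCC and hence an advanced tier, so moderate patterns are
allocated from the non-high pool (as a count,
`round(fraction * n_AD_pattern)`); a moderate high-tau scan is
geometrically impossible under the decision rules. All draws flow from
one seed through one generator; identical specs give identical cohorts.

What the phantoms do *not* emulate: anatomy (regions are boxes),
scanner physics beyond Gaussian blur (no scatter, no motion, no
attenuation artifacts), off-target binding, and the intensity
*distributions* of real patients (no public mapping from SUVr to the
visual scale exists, so multipliers are an abstraction). Passing the
recovery tests therefore demonstrates that the decision logic is
implemented correctly and is robust to additive noise -- not that the
classifier would reproduce human reads on clinical scans.

## Agreement statistics

Endpoints compare reader calls against the quantitation standard:
`PPA = 100 * TP / (TP + FN)`, `NPA = 100 * TN / (TN + FP)`, overall
agreement `100 * (TP + TN) / n`, each with a Wilson score interval
(inverting the score test; the interval always contains the point
estimate, and its bounds solve the score equation -- tested against a
root-finding oracle). Scans without truth labels (e.g. quantitation
failures) are excluded from endpoint denominators but retained for
kappa.

Inter-reader reliability is a two-category Fleiss kappa: observed
agreement is the mean per-scan pairwise agreement; expected agreement
uses category marginals pooled across readers. The standard error is the
Fleiss--Nee--Landis large-sample formula. `fleiss_kappa_from_summary()`
computes the identical statistic from the summary a report prints
(per-scan split counts plus per-reader positive totals); the matrix path
delegates to it through a canonical tabulation, so the two agree
bit-exactly -- a tested equivalence. The published validation study's
printed CI differs from the Fleiss--Nee--Landis interval in the fourth
decimal (0.8356 vs. 0.8359 at the lower bound); the CI method used there
is not stated, so reproduction of the CI is asserted to +-0.001 while
the point estimate 0.8882 reproduces to all four printed decimals.

Intra-reader (test-retest) reliability is Cohen kappa with per-rater
marginals and the asymptotic Fleiss--Cohen--Everitt variance; identical
constant vectors define kappa = 1 with zero SE, and reported CI upper
bounds are capped at 1.000.

The report's pooled row computes endpoints of the *summed* per-reader
contingencies. The validation study labels its overall row a median, but
its printed values (83.4%, 88.9%, 86.1%) equal the pooled-count
estimates and its CIs equal Wilson intervals on pooled counts -- the
median of the five printed per-reader PPAs would be 84.3%. The report
therefore carries both the pooled row (matching the published table) and
the per-reader medians, clearly labeled.

`reader_study_matrix()` deserves a note: the validation study published
only marginals, so the package reconstructs one 140 x 5 matrix that
jointly realizes *all* of them (agreement splits 124/9/7, per-reader
positive totals, every per-reader TP/TN, and the majority-read counts
60/10/62/8). The construction was derived by solving the count
equations by hand; tests assert every marginal. Statistics that depend
only on these marginals are exactly those of the study; scan-level
quantities beyond them are not identified and are never reported.

Success criteria follow the protocol with inclusive comparisons: PPA and
NPA CI lower bounds >= 50% for at least 3 of 5 readers, and Fleiss
kappa >= 0.64 with CI lower bound >= 0.55.

## Numerical choices

* 26-connectivity for clusters; labeling is iterative minimum-label
  propagation restricted to the foreground bounding box, with one step
  equal to a separable 3x3x3 minimum filter. The fixed point equals
  flood-fill labeling, verified against a brute-force BFS oracle on 8^3
  grids.
* Gaussian smoothing is separable with kernels truncated at 3 sigma and
  renormalized; edges replicate. FWHM converts to sigma via
  `FWHM / (2 sqrt(2 ln 2))` per axis in voxel units.
* Wilson bounds are exact 0/1 at 0 or n successes (special-cased to
  avoid floating-point dust).
* Ties in the `slice2d` MCC slice choice resolve to the lowest slice
  index. Majority reads require an odd panel or an explicit tie rule.
* Atlas/scan grids must match exactly in shape and to 1e-4 in the
  affine; there is no resampling.
* Volumes are written as float64 (int32 for atlases), so NIfTI
  round-trips are value-identical.

## Problem sizes used in the test suite

Most tests run on a 24^3 atlas, where a stratification takes well under
a second. The end-to-end recovery check uses the full study-size mix
(70/70/20) at the default 48^3 resolution -- about 160 stratifications
in under a minute -- and recovers the designed tier and high-tau label
for every scan in the noiseless configuration. Noise-robustness checks
run 102-scan cohorts at noise SD 0, 0.05, 0.1, 0.2, requiring agreement
with designed truth to be non-increasing in noise (2-percentage-point
Monte-Carlo slack). Reader-panel recovery uses 50 replicates of a
140-scan, 5-reader panel at sensitivity 0.85 / specificity 0.90,
comparing pooled endpoints and Fleiss kappa to their analytic values
within 3 Monte-Carlo standard errors.

## Known limitations

* The default decision table approximates the original 3-tier rules
  from their published narrative; if the exact supplemental rule text is
  available, encode it with `decision_table()` and pass it through
  `stratify_config()`.
* The geometric atlas supports no spatial normalization: real scans
  must arrive co-registered with their label map.
* Phantom multipliers are not calibrated to any clinical dataset;
  absolute SUVr values from `compute_suvr()` on phantoms are
  internally consistent but not clinically interpretable.
* Intra-reader test-retest and quantitation-failure reliability
  statistics from the validation study cannot be reproduced (their raw
  matrices were never published); `cohen_kappa()` is validated against
  hand-computed 2x2 oracles instead.

## A worked example

```{r}
atlas <- build_synthetic_atlas(c(24L, 24L, 24L), c(2, 2, 2))
scan <- generate_phantom(atlas, phantom_spec(
  list(frontal_L = 3.1, parietal_L = 2.2, parietal_R = 2.1,
       lateral_posterior_temporal_L = 2.3),
  noise_sd = 0.05, smoothing_fwhm_mm = 4, seed = 11L))
stratify_scan(scan, atlas)
```

```{r}
s <- reader_study_summary()
fleiss_kappa_from_summary(s$splits, s$positive_totals, s$n_scans)
agreement_report(reader_study_matrix())
```
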