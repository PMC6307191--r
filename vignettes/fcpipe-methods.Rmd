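---
title: "Methods: motion-censored functional connectivity with synthetic BOLD cohorts"
author: "fcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-censored functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the pipeline computes

`fcpipe` implements a resting-state / naturalistic-viewing functional
connectivity analysis for comparing three developmental cohorts — a
low-verbal-and-cognitive-performance autism group (LVCP), a
higher-performance autism group (HVCP), and neurotypical controls (NT) —
together with a synthetic BOLD generator that reproduces the statistical
structure the analysis assumes, so every stage can be validated by parameter
recovery.

The processing chain, per subject and per run:

1. **Framewise displacement (FD).** From the six rigid-body motion
   parameters, $FD(t) = \sum_i |\Delta d_i(t)| + r \sum_j |\Delta
   \theta_j(t)|$ with translations in mm, rotations in radians converted at
   head radius $r = 50$ mm. $FD(1) = 0$: FD is a transition quantity.
2. **Censoring.** Every transition with $FD > 0.2$ mm marks both adjacent
   frames (the frame before and the frame after the motion event) for
   removal. A subject is usable when the kept frames summed over runs reach
   200 volumes.
3. **Confounds.** Six motion parameters; mean time series over the
   one-voxel-eroded white-matter and CSF masks (erosion keeps voxels whose
   full 6-neighborhood lies inside the mask); mean over the face soft-tissue
   mask; optionally the mean over all in-brain voxels (global signal
   regression, GSR). Both streams — with and without GSR — are first-class.
4. **Nuisance regression with simultaneous bandpass.** Per voxel, one OLS fit
   removes the intercept, the confounds, and a discrete-cosine basis spanning
   all frequencies outside 0.001–0.1 Hz. Implementing the bandpass inside the
   GLM avoids re-introducing regressed noise through sequential filtering.
   Residuals are exactly orthogonal to every regressor; the projection is
   realized sequentially (DCT block first, then the DCT-residualized
   confounds), which is algebraically identical to the simultaneous fit and
   lets the QR of the large shared DCT block be cached per run geometry.
   With runs of minutes, the 0.001 Hz lower edge lies below the frequency
   resolution, so near-DC trends are handled by the intercept and lowest
   cosine columns; runs are filtered separately, then concatenated.
5. **Extraction and connectivity.** Censored frames are dropped at
   extraction; per-ROI means are centered per run before concatenation (so
   run offsets cannot inflate correlations across the seam). Connectivity is
   the Pearson correlation of ROI time series, Fisher transformed
   ($z = \operatorname{atanh} r$); the matrix diagonal is stored as NaN and
   never averaged.
6. **Summaries.** Within-network mean (mean of $z$ over distinct ROI pairs
   inside each of eight networks), between-network synchrony (Fisher $z$ of
   the correlation between network *mean* time series, for all 28 pairs),
   homotopic connectivity (each ROI paired with the contralateral ROI whose
   centroid is nearest to the mirror image of its own centroid; ties to the
   lower id; the pairing is directional nearest-neighbor with non-mutual
   pairs flagged), and a network-to-ROI map (Fisher $z$ between one network's
   mean series and every ROI, members flagged).
7. **Group statistics.** Within-network values enter a three-group ANCOVA
   (group F by model comparison, 2 numerator df) with age, sex, and
   motion-free volumes as covariates; pairwise contrasts are unprotected t
   statistics from the same fit (the analyses report pairwise directions
   alongside the omnibus F, so no Tukey protection is applied). Between-network
   and homotopic values use pooled-variance two-sample t tests (LVCP vs NT,
   LVCP vs HVCP) plus the covariate GLM as a check. Each analysis family is
   corrected separately by Benjamini–Hochberg FDR over exactly its own tests
   (8 networks; 28 pairs; all ROIs; all homotopic pairs per contrast) — never
   pooled across analyses. Flags use $q \le 0.05$: the step-up rule rejects
   at equality, which the boundary case $p_{(i)} = \alpha i/m$ requires.
8. **Dimensional IQ analysis.** Within a group (LVCP by default), the Pearson
   correlation across subjects between composite IQ and every ROI pair's $z$,
   plus scalar summaries (e.g. within-default mean vs IQ).
9. **GSR contrast.** Median pairwise connection per group per stream,
   sign agreement of group-difference t maps between streams, and the shift
   in the median LVCP−HVCP difference.

# The synthetic cohort generator

The generator is not a fixture: it is the experimental apparatus for
validating the pipeline, and its defaults encode the emulated study
conditions.

**Geometry.** An even-x voxel grid (2 mm isotropic) whose affine places
$x = 0$ exactly between the two middle slices, so mirroring voxel indices
negates world x exactly. ROIs are cubic blocks placed in the left hemisphere
and mirrored, each carrying one of eight networks (auditory, salience,
frontoparietal, default, dorsal attention, ventral attention, sensorimotor,
visual); optionally a fraction of ROIs carry no network label ("none"),
mimicking the unassigned parcels of a Gordon-style 333-parcel scheme (47 of
333), and are excluded from network analyses while remaining in ROI-level
and homotopic analyses. WM/CSF/face masks are disjoint blocks at least three
voxels thick, so erosion leaves a non-empty core by construction.

**Signal model.** ROI signals are zero-mean multivariate normal draws with a
target correlation matrix assembled from Fisher-z parameters: `within_z`
(default 0.25) on within-network cells, `between_z` (0.10) on between-network
cells, base + `homotopic_z` (0.15) on mirror pairs, `none_z` (0.10) on cells
involving unassigned ROIs; the diagonal is 1 and non-positive-definite
assemblies are repaired by the nearest-PD correlation projection with the
repair magnitude reported. Units are z-scaled with no physiologic
calibration — only correlations matter downstream. All latent series are
temporally colored by an AR(1) kernel with $\phi = 0.35$. A strictly
band-limited process below 0.1 Hz would cap the effective sample size of an
8.5-minute run near $2BT \approx 100$, making single-subject Fisher-z
estimates so noisy that planted group effects of realistic size could not be
recovered at the study's group sizes; moderate coloring concentrates power
at low frequencies while keeping subject-level estimates informative, and we
treat this trade-off as a deliberate design choice of the generator.

A shared global series (amplitude 0.4) is added to all in-brain voxels;
WM/CSF/face blocks carry their own series which leak into gray matter at
amplitude 0.1; voxel noise is white with SD 1 (ROI blocks of 8 voxels give
ROI-level noise SD $1/\sqrt 8$). Tissue series also carry the global
component — physiologically realistic, with the consequence that tissue
regression already removes part of a pure global-amplitude difference even
without GSR; generalized group differences are therefore planted at the
coupling level in stream-contrast experiments.

**Between-subject variability.** Subject-level jitter with SD 0.05 is applied
at the network-parameter level (per-network within, per-pair between,
homotopic). The emulated study does not report within-group connectivity
variances, so this default is a choice, set low enough that scaled-down
recovery benchmarks are informative; empirical pediatric cohorts are often
more variable, which passing tests do not speak to.

**Phenotypes and planted effects.** Group sizes 17/20/19; ages 7–17 and
composite IQ drawn from the emulated groups' means and SDs (LVCP
54 ± 17.5 truncated to [25, 79]; HVCP 106.9 ± 13.6 and NT 111.8 ± 13.1 at or
above 80). Planted defaults: LVCP within-network z reduced by 0.15 in
default, salience, auditory and frontoparietal; LVCP default↔dorsal-attention
between-network z raised by 0.15; LVCP coupling decreasing in IQ at
−0.002 z per IQ point (group-centered), reproducing the direction
"lower IQ, higher connectivity".

**Motion.** Six-parameter traces are a low-amplitude random-walk drift plus
Poisson-placed sustained head-position steps of 0.6 mm FD. Each subject's
retained fraction is drawn from a truncated normal matched to the emulated
cohort's motion-free volume means (fractions 0.508/0.689/0.713 of 1240 for
LVCP/HVCP/NT), with the latent mean adjusted so the truncated mean hits the
target; the per-transition spike probability is then $1 - \sqrt{f}$, since
the censor rule keeps a frame only when neither adjacent transition spiked.
Per-subject heterogeneity matters: with a fixed rate per group, motion-free
volumes become a near-perfect group code and the motion covariate absorbs
genuine group effects in the ANCOVA — exactly the failure mode the emulated
design avoids by having wide within-group motion spread. The usability
truncation compresses the realized SDs below the emulated cohort's
(~230 vs ~340 volumes for LVCP).

**Exact ROI-level fast path.** Because the nuisance-regression residual
operator is linear and identical across voxels, the ROI mean of voxel
residuals equals the residual of the ROI mean. `simulate_subject(voxel =
FALSE)` therefore simulates the same latent signals plus ROI-mean noise
directly, carrying measured confound series (eroded-core WM/CSF means, face
mean, in-brain mean reconstructed from voxel counts) alongside. With
`noise_sd = 0` the two paths agree to machine precision (tested); replicate
studies use the fast path, voxel-level tests exercise the full path.

# Numerical and design choices

- **FD convention**: Power-style sum of absolute parameter differences,
  rotations at 50 mm radius; first frame 0; "before and after" censoring
  drops frames $t-1$ and $t$ for a violating transition $t$. A brute-force
  oracle encodes the same single convention in the tests.
- **Erosion** is the exact face-adjacency interior; volume boundaries count
  as outside.
- **Constant confound columns** (e.g. a motionless scan's motion parameters)
  are dropped with a record, since they carry nothing beyond the intercept;
  genuinely collinear designs raise an error naming the columns.
- **Degenerate correlations** (zero-variance ROI, $|r| = 1$ duplicated
  series) raise errors rather than propagating infinities; `atanh(1)` never
  enters a mean.
- **Covariance repair** uses Higham's nearest-PD correlation projection
  (`Matrix::nearPD`), reporting the max absolute cell change.
- **Seed fan-out** is counter-based (subject i, run r, purpose salt), so any
  subject can be regenerated independently of cohort order, and results are
  bit-reproducible for a fixed seed, including file checksums in the run
  manifest.
- An optional zero-phase Butterworth bandpass is deliberately *not* the
  default; the DCT-in-GLM route is the reference implementation and the one
  the contracts test.

# Validation studies and problem sizes

The test suite runs every oracle comparison (censoring, erosion, BH step-up,
homotopic pairing) exhaustively on randomized cases, and three simulation
studies at sizes chosen to keep the full suite in the minutes range:

- **Recovery benchmark** (`recovery_benchmark_spec()`,
  `planted_effect_recovery()`): 32 ROIs (two per network per hemisphere), one
  600-frame run, groups of 17/20/19, equal low motion and no IQ slope so only
  the two planted effects separate groups; 50 replicate cohorts through the
  full non-GSR pipeline. All planted effects are FDR-flagged in ≥ 90% of
  replicates (0.96 observed), with unplanted within-network cells flagging at
  the nominal rate. Equalizing motion here is a controlled-experiment choice:
  recovery failures then indicate estimator problems rather than
  censoring imbalance; motion effects are validated separately.
- **Null calibration** (`null_pipeline_calibration()`): 50 null cohorts
  (10/10/10, 300 frames, 16 ROIs) through the full pipeline; uncorrected
  rejection at $\alpha = 0.05$ falls in [0.03, 0.07]; plus 1000 scalar-level
  ANCOVA nulls and 1000 global-null BH families of size 333.
- **GSR median property**: on a Gordon-proportioned atlas (92 ROIs, 13%
  unassigned) with the full default cohort, the post-GSR median pairwise z
  per group lies within ±0.02 of zero. Two structural terms keep it slightly
  negative — the regression sum constraint (≈ $-1/(n_{ROI}-1)$) and the
  within-network excess removed with the mean — both of which shrink with
  atlas size and with the unassigned-parcel fraction; at 32 ROIs the
  property genuinely does not hold (≈ −0.03), which is why the scaled atlas
  for this check mirrors the real parcellation's proportions.

# What passing tests do and do not show

The generator draws stationary Gaussian signals on a block-structured
covariance. Real BOLD data have non-Gaussian artifacts, spatially structured
noise, distance-dependent motion artifacts, physiological rhythms, and
between-site heterogeneity, none of which are simulated; no scanner physics,
susceptibility distortion, or stimulus response is modeled, and inputs are
assumed already realigned in a common space. Recovery of planted effects
therefore validates the estimator chain and its statistical calibration, not
robustness to artifact classes the generator does not produce. Sample sizes,
run lengths and atlas sizes in the validation studies are scaled-down
choices of this package, stated above.
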