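---
title: "Quantitative ratiometric redox imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ratiometric redox imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
library(dplyr)
```

## The measurement problem

Redox-sensitive GFP (roGFP) carries an engineered disulfide whose oxidation
state shifts the balance between its two excitation bands. Under two-photon
excitation, alternating 740 nm and 910 nm illumination yields an image pair
(F740, F910) whose pixelwise ratio R = F740/F910 rises with oxidation and is
invariant to sensor expression level and optical path length — the basis of
excitation-ratiometric quantification. `redoxmap` implements the complete
analysis chain from such image pairs to group statistics, together with a
synthetic-data generator that renders photon-limited image pairs from known
ground truth so that every stage can be verified without a microscope.

## The two-state sensor model and its calibration

Each sensor molecule is modelled as oxidized or reduced, with linear emission
in both channels (`fluorophore_model()`). With emission coefficients
$a_{ox}, a_{red}$ (F740) and $b_{ox}, b_{red}$ (F910), the expected ratio at a
degree of oxidation $OxD \in [0,1]$ is

$$R(OxD) = \frac{a_{ox}\,OxD + a_{red}(1 - OxD)}{b_{ox}\,OxD + b_{red}(1 - OxD)},$$

a strictly increasing function. Its three identifiable constants are the
calibration triple: the fully oxidized ratio $R_{ox} = a_{ox}/b_{ox}$, the
fully reduced ratio $R_{red} = a_{red}/b_{red}$, and the instrument factor
$IF = b_{ox}/b_{red}$ (the ratio of F910 intensities between the two states, a
property of the optics and wavelength settings, not of the tissue). Inverting
$R(OxD)$ gives the conversion applied to every measured cell
(`oxd_from_ratio()`):

$$OxD = \frac{R - R_{red}}{IF\,(R_{ox} - R) + (R - R_{red})}.$$

This algebraic inverse relationship is the package's central internal oracle:
for any valid model and any $OxD$, converting the forward ratio back recovers
$OxD$ to machine precision, and the test suite asserts this over a thousand
random models. Two closed forms give additional exact anchors: $OxD(R_{red}) =
0$, $OxD(R_{ox}) = 1$, and at the arithmetic midpoint of the endpoints
$OxD = 1/(1+IF)$.

The triple is estimated from endpoint recordings (`estimate_calibration()`):
the same field imaged after a strong oxidant (H2O2) and, after wash-out, a
strong reductant (DTT). Ratios average per endpoint; for the instrument
factor, per-cell F910 quotients between the two states are preferred because
they cancel each cell's expression level, which varies by tens of percent.
When the two recordings carry coordinates, cells are paired by mutual nearest
neighbour rather than by ROI label — automatically generated labels are
positional and may collide across recordings without denoting the same cell,
and label-based pairing would inflate the quotient by the expression-level
variance (for lognormal brightness with log-SD $\sigma$, by about
$e^{\sigma^2}$). The unmatched fallback divides group-mean F910 intensities.
A default calibration of $R_{ox} = 0.916$, $R_{red} = 0.408$, $IF = 0.497$ —
typical for cytosolic roGFP in acute slices — parameterizes the generator.

Conversion is deliberately not clamped: ratios outside $[R_{red}, R_{ox}]$
produce OxD outside $[0,1]$ and are removed later by the intactness filter,
not silently clipped. Uncertainty in the triple can be propagated by Monte
Carlo (`propagate_calibration_uncertainty()`), treating the three constants
as independent normals (no covariance information is available) and rejecting
unphysical draws.

## From images to per-neuron ratios

`compute_ratio_image()` divides the channels pixelwise wherever F910 exceeds
a validity floor; pixels below it carry essentially no sensor signal and are
excluded from all downstream averages. The default floor is background mean
plus three background SDs, estimated from the dimmest half of the F910 pixels.
`detect_somata()` replaces manual ROI placement for reproducibility (an
externally supplied ROI table is accepted to preserve the manual workflow):
Gaussian smoothing, Otsu thresholding, a distance-map watershed to split
touching somata, connected-component labelling, and reduction to circular
ROIs within a radius range. `measure_rois()` averages the pixelwise ratio
over the valid pixels of each ROI — the primary statistic, since ratio images
are computed first and then averaged — at 0.7 of the nominal radius, so that
point-spread-blurred soma-edge pixels (partly mixed with background) do not
bias the average. The ratio of channel means is carried as a QC cross-check
and flagged when it disagrees by more than 5%; further flags mark low valid
fractions and near-saturation intensities. For display, the unitless ratio is
scaled by 1000 onto the 12-bit (4096-level) pseudocolor palette
(`render_ratio_display()`); this path is visualization-only and never feeds
back into quantification, which the tests assert bit-exactly.

## Screening and inference

Per-neuron OxD tables pass through, in order: the intactness filter
(`filter_intact()`, closed interval 5–95% OxD — values outside the
calibrated response range indicate damaged or mis-measured cells), then a
ROUT outlier screen (`rout_outliers()`, Q = 1%) applied within each
(region, genotype, age) column, the grouping in which values are plotted and
compared. The range filter runs first so the outlier model operates on
plausible biology; the order is switchable. The column reduction of ROUT
fits the constant model robustly (median centre; scale = 68.27th percentile
of absolute residuals with the small-sample factor $n/(n-1)$, which matches
the SD on clean normal data), converts residuals to t-tail probabilities with
$n-1$ df, and flags by the step-up false-discovery rule from the most extreme
residual inward. It is validated behaviourally: a gross planted outlier in a
clean column is always caught, and the false-flag rate on clean normal
columns of 20–1000 values stays at or below 2%.

Aggregation (`aggregate_redox()`) is reported at two levels: per neuron, and
slice-first (neurons averaged within each slice, then slices averaged), which
weights slices equally and differs from the cell-level mean whenever slice
sizes are unequal — a constructed counterexample in the tests keeps this
distinction honest. Group inference (`compare_redox()`) fits, per region, a
2×2 genotype-by-age ANOVA with marginal (Type III) sums of squares under
sum-to-zero coding — the convention of the widefield statistics packages for
unbalanced designs — and compares all six group pairs with t statistics on
the pooled residual variance. The six raw p-values form one Holm–Šídák family
per region ($\tilde p_{(i)} = 1-(1-p_{(i)})^{k-i+1}$, made monotone); no
correction is applied across regions. Markers follow the plotting convention:
asterisks for age contrasts, hatches for genotype contrasts, at 0.05/0.01.
Welch's t (`welch_t()`) with Satterthwaite df is computed explicitly and
cross-checked against `stats::t.test()` in the tests.

## Correlative microscopy

To relate redox state to MeCP2 expression in X-inactivation mosaics, the same
field is imaged live (ratiometric) and again after fixation and
immunostaining (nuclear stain, MeCP2 immunolabel, structural green). The
square laser bleach marks burned next to the imaged region anchor
re-identification: `register_by_fiducials()` binarizes both structural
channels into dark masks and finds the integer translation maximizing their
FFT cross-correlation, exact to one pixel on synthetic pairs; a peak below a
confidence threshold raises a registration-failed error rather than returning
a guess. `classify_mecp2()` scores each detected nucleus by mean immunolabel
intensity and splits log intensities with a two-component Gaussian mixture
(k-means fallback); a BIC difference below 6 between the two- and
one-component fits — weak evidence for bimodality on the conventional scale —
triggers a warning while still returning the split. `match_cells()` pairs
somata to nuclei greedily one-to-one after applying the offset.

Because the post-fixation optics differ from the calibrated live recordings,
this stage compares raw ratios, not OxD. `normalize_and_compare()` divides
every cell's ratio by the mean ratio of the MeCP2-positive cells of its own
slice, which removes between-slice gain and redox-baseline differences. With
the default inclusive denominator the within-slice positive mean is exactly
1; a leave-one-out denominator is provided because pooled positive means
slightly below 1 in real data hint at some such convention, though which one
was used there is not recorded. Slices with fewer than 5 positive cells are
excluded — their denominator would be too unstable. Matching is
translation-only: fixation shrinkage and rotation are not modelled, and the
default matching radius is one soma radius.

## What the generator emulates — and what it does not

`sim_scenario()` fixes the study conditions: fields of non-overlapping
disk somata (radius 7 px on 192 px fields, 12 per field) whose ground-truth
OxD is drawn per (region, genotype, age) from a normal truncated to
[0.02, 0.98] — just inside the 5–95% analysis range, keeping the conversion
well-conditioned; the generating distribution is an assumption, as only
means and SDs of real populations are known. The default group table uses
the measured slice-level means of ten brain regions in WT and Mecp2
heterozygous females at p50 and >p100, with measured cell-level dispersions
where available (CA1 and dentate gyrus at p50 in WT) and a typical
cell-level SD of 0.15 elsewhere. Rendering follows a standard photon-limited
two-photon detection model: expected per-cell channel amplitudes from the
two-state model (so the amplitude ratio is exactly the model ratio), scaled
by a per-cell lognormal expression factor (log-SD 0.3, mean 1 — needed so
ratios are brightness-invariant but single-channel intensities are not),
Poisson shot noise on expected counts (photon scale 2000 counts for a
unit-brightness reduced cell in F910), additive Gaussian read noise (SD 3),
a uniform tissue background (20 counts) against which bleach marks appear
dark, and a logistic soft edge (scale 0.7 px) as the PSF proxy. Channels are
generated pre-registered; misregistration is injected only where registration
is under test. A single master seed expands into named substreams
(placement, OxD draws, expression, mosaic, noise) so toggling one source
leaves the others bit-identical.

Mosaic expression is clonal: `simulate_mosaic_labels()` scatters a small
number of progenitor-clone seed points (default 40), assigns each cell to its
nearest clone, and makes each clone MeCP2-positive with the mosaic fraction
(default 0.45, the fraction observed in CA1). With many clones this
degenerates to independent Bernoulli labels; the spatial granularity of real
mosaic patches is not quantified anywhere, so the clone count is an explicit
knob. The correlative generator sets raw ratios directly — positive cells
spread around the slice base ratio (relative SD 0.311), each deficient cell
at the slice's positive mean times 1.101 with spread 0.348, the measured
per-class dispersions of normalized values — because the printed spreads can
place true ratios outside $[R_{red}, R_{ox}]$, which an OxD-parameterized
two-state renderer cannot represent, and because this stage is analysed on
raw ratios anyway. An `mcat_effect` multiplier scales the genotype OxD shift
(1 = full shift, 0 = abolished), standing in for mitochondrial catalase
rescue as a pure effect-size switch.

Deliberately not modelled: optics beyond the Gaussian/logistic blur, tissue
scattering and depth attenuation, z-stacks and best-plane selection,
photobleaching, neurites and subcellular structure, dynamic oxidant/reductant
time courses (endpoints only), and antibody chemistry beyond a two-class
lognormal intensity model. Passing tests therefore demonstrate correctness of
the analysis chain under a faithful but idealized image-formation model —
they do not certify performance on tissue with depth-dependent scattering,
strong autofluorescence gradients, or deformation between live and fixed
imaging.

## Numerical choices and degenerate inputs

Truncated-normal draws use inverse-CDF sampling, so a fixed seed yields fixed
values regardless of rejection paths. Soma packing is rejection sampling with
an explicit failure (never silent truncation) when the requested count cannot
be placed. Division is guarded only by the F910 floor; valid ratio pixels are
guaranteed finite. Eq.-1 denominators can only vanish when $IF > 1$ and the
ratio lies far above $R_{ox}$; such cells get an `NA` OxD with an exclusion
reason, not an exception. ROIs with zero valid pixels return a flagged `NA`
measurement. A slice-level group with a single slice reports `NA` SD with
n = 1. Registration requires a minimum dark-mask footprint (a detectable mark
is tens of pixels across) and a minimum normalized correlation of 0.3.
Detection ties are broken deterministically (brightest-first overlap
suppression; row-major ordering), so repeated runs on the same image are
identical.

## Verification scale

The shipped tests and the acceptance script run the pipeline at desk scale,
chosen as the package's own verification budget: recovery simulations use
10 seeds (20 for calibration recovery and the correlative significance
check), fields of 192–512 px, and the printed group sizes (110 and 142
neurons for the cell-level recoveries, 9 slices of ~30 neurons at slice
level, ~300 matched neurons in the correlative recovery, 76 + 78 cells for
calibration endpoints). At these sizes the recovered quantities sit within
about ±0.02 of the generating truth; the dominant residual bias (~+0.01–0.02
OxD) stems from tissue background entering soma-edge pixels, which the
analysis — like the published workflow it follows — does not
background-subtract.

One power note for interpreting the correlative comparison: at the measured
group sizes (193 vs 110), per-class SDs (0.348/0.311) and effect
(1.101 vs ~1), the Welch noncentrality is ≈2.6 against a two-sided 1%
critical value of ≈2.6 — a study observing p ≈ 0.006 under exactly these
population parameters replicates p < 0.01 only about half the time. The
simulation reproduces this: the effect size is recovered accurately, while
the dichotomous significance verdict is intrinsically unstable at this
sample size.

## A worked example

```{r example, eval = FALSE}
library(redoxmap)

cal <- calibration_params(0.916, 0.408, 0.497)
sc <- sim_scenario(seed = 1)

design <- tibble::tribble(
  ~region, ~genotype,  ~age_group, ~n_cells,
  "DG",    "WT",       "p50",      48,
  "DG",    "WT",       "gt_p100",  48,
  "DG",    "Mecp2+/-", "p50",      48,
  "DG",    "Mecp2+/-", "gt_p100",  48
)
res <- run_redox_pipeline(design, sc, calib = cal)
res$log            # n at every filtering step
res$summary_slices # slice-first means +/- SD with n
tidy(res$comparison)[, c("contrast", "p", "p_adj", "marker")]
autoplot(res$summary_cells)
```
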