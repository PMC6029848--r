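---
title: "Models and methods behind spatcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatcell)
```

spatcell analyses open-arena spatial-cell recordings: place, grid,
head-direction (HD) and speed-modulated cells recorded while a rodent
forages in a square or cylindrical arena, in the real world (R) or in
virtual reality (VR). This vignette explains the models the package
implements, the tunable parameters that matter, the synthetic-data
generator used to validate every stage, and the numerical choices made
where the standard methods leave details open.

## Session model and conventions

A session couples a trajectory (50 Hz samples of position, head direction,
running speed and running direction), a list of per-cell spike trains, and
a single LFP channel, under a configuration giving arena shape and width,
condition (R or VR), trial duration, and binning parameters. Conventions:

* coordinates in cm; origin at the arena corner (square) or centre
  (cylinder);
* angles in degrees, counter-clockwise, 0 = +x; angular differences wrap
  to (-180, 180];
* head direction (`hd`, from the tracked head) and running direction
  (`run_dir`, from displacement) are kept distinct. Directional tuning
  uses `hd`; behavioural direction statistics use `run_dir`. In VR the
  head is restrained to horizontal rotation while translation comes from
  the ball, so the two can dissociate.

Sessions are stored as a directory of plain-text files
(`write_session()` / `read_session()`), with numerics printed at 17
significant digits so round-trips are bit exact. Native acquisition
formats are out of scope; an adapter only needs to produce the positions,
spikes and LFP tables.

## Preprocessing

Tracking gaps up to 0.5 s are filled by linear interpolation per
coordinate (angles along the shorter arc); longer gaps stay masked and are
excluded everywhere downstream. Positions are then smoothed with a 0.4 s
boxcar. The window is implemented symmetrically (21 samples at 50 Hz)
rather than as an asymmetric 20-sample window: an even-length boxcar would
shift every position by half a sample, which biases all
displacement-derived quantities, whereas the extra 20 ms of window width
is negligible. Speed and running direction are per-sample displacements
times the sampling rate; behavioural direction statistics use a 2.5 Hz
downsampled trajectory (every 20th sample), the standard sampling for
running-direction summaries.

## Firing-rate maps and directional tuning

Rate maps bin positions into 1.5 cm square bins, smooth the spike-count
and dwell-time maps separately with a 5 x 5 boxcar, and divide. The boxcar
is truncated at arena borders and renormalised in mass-conserving form:
each bin's mass is spread uniformly over the in-arena part of its window.
This conserves total spike count and total dwell exactly, cancels in the
spikes/dwell ratio, and avoids the rate bias at walls where rodents
over-sample. Bins never visited are NaN. Cylindrical arenas use the square
bounding grid with out-of-arena bins masked.

Directional tuning curves use 6-degree bins smoothed with a 5-bin circular
boxcar applied to spike counts and occupancy separately; the bin width and
smoothing are configurable because they are conventions rather than
published constants.

Field detection serves two purposes. The *field-size* measure is the
fraction of arena bins above 50% of the map peak. The *per-field
segmentation* grows connected components around local maxima in
descending peak order, each component being the bins above 50% of its own
peak; components adjacent to an already-grown field are treated as
shoulders, not fields. Two robustness choices matter here: the 50%
threshold is taken relative to the mean of the 3 x 3 neighbourhood of the
peak bin (a single max bin is upward-biased by selection noise, which
systematically shrinks fields), and each field also carries its
rate-weighted centroid, a sub-bin centre estimate used as the origin for
traversal analyses.

For comparing field sizes *between conditions* (the VR/R expansion), the
half-max bin count is a poor estimator: its numerator and denominator both
inherit the peak-threshold noise, and expanded fields near walls get
truncated. `field_sigma()` instead fits an isotropic Gaussian to the
smoothed map around the field centroid by least squares and subtracts the
boxcar smoothing variance (w^2/12 per axis) from the fitted variance; the
resulting sigma is threshold- and truncation-independent, and ratios of
sigmas recover generative expansion factors within a few percent where
area-count ratios scatter by 5-10%. The expansion recovery also runs in
the 90 cm arenas so the expanded fields stay clear of the walls.

Behavioural summaries include a wall-following proxy: the fraction of
samples whose running direction lies within 15 degrees of a wall axis
(chance 1/3), since the exact wall-parallel statistic used for this
behaviour is not standardised.

## Scalar metrics

*Skaggs information* (bits/spike): `sum p_i (r_i/R) log2(r_i/R)` with
`p_i` the smoothed dwell (or directional occupancy) fraction and `R` the
dwell-weighted mean rate. *Rayleigh vector length*: resultant of the
rate-weighted bin-centre unit vectors. *Tuning width*: angular width of
the region around the peak above baseline + (peak - baseline)/2, with
interpolated crossings; the baseline subtraction handles background
firing. *Map similarity*: Pearson correlation over bins finite in both
maps, optionally after 180-degree point reflection — the statistic of the
cue-rotation probe.

### Gridness and grid scale

The spatial autocorrelogram is the Pearson correlation of the rate map
with itself at every integer-bin offset, over the overlapping finite bins
(at least 20). A compiled kernel computes it; a plain-R implementation is
cross-checked against it in the tests.

Gridness correlates an annulus of the correlogram with copies rotated by
30, 60, 90, 120 and 150 degrees: `min(r60, r120) - max(r30, r90, r150)`.
The inner radius is the first integer ring whose azimuthal mean drops
below 0.2 (bounding the central peak); the outer radius then expands over
all admissible values and the maximum annulus gridness is returned. This
deterministic expanding-annulus rule is applied *identically* to observed
and shuffled maps. That matters: a rule that adapts the annulus to the
observed map's peaks (as some toolboxes do) breaks the exchangeability
between observed and null scores and mis-calibrates the shuffle
classifier. Grid scale is the median distance from the correlogram centre
to the six (at least three) nearest local maxima outside the central peak.

## The pxd model

Apparent directional tuning can arise from inhomogeneous sampling of
directions inside a locational field. The pxd model fits
`rate(x, theta) = p(x) * d(theta)` by maximum likelihood to the joint
histogram of spike counts over (spatial bin, direction bin) with joint
dwell as Poisson exposure, using alternating closed-form multiplicative
updates (iterative proportional fitting); each update is the ratio of
observed to expected spikes marginalised over the other factor, and the
likelihood increases monotonically. The gauge freedom (scale `p` by c,
`d` by 1/c) is fixed by renormalising `d` to occupancy-weighted mean 1
each iteration. Spatial bins are coarsened to 7.5 cm so the joint
occupancy stays dense; unvisited joint bins contribute no likelihood
terms; convergence is a relative log-likelihood change below 1e-6
(at most 500 iterations, deterministic flat initialisation). The
pxd directional information applies the Skaggs formula to `d` scaled by
the overall mean rate, after smoothing `d` and the occupancy with the same
5-bin circular boxcar as the binned tuning curves — without this the two
measures would have different noise floors and the comparison in the
de-confounding analysis would be biased.

## Shuffle classification

The null for all spatial statistics is the rigid time shift: all spike
times are offset by one uniform draw from [4 s, T - 4 s] and wrapped
modulo the trial duration, preserving the spike count and the ISI
structure while destroying the spike-position relationship. A cell is a
place cell if its spatial information exceeds the 99th percentile
(linearly interpolated order statistics, strict inequality) of 1000
shuffled scores and its smoothed-map peak exceeds 2 Hz; grid cells use
gridness with the same peak criterion; HD cells use the Rayleigh vector
length against a *population* null by default — all cells' shuffled values
pooled into one distribution whose 99th percentile is a common threshold —
with a per-cell mode available; speed cells use the Pearson correlation
between running speed and the instantaneous rate (spikes per 20 ms sample
/ 0.02 s) across samples.

Cells with fewer than 100 spikes are flagged rather than classified. For
shuffled nulls at scale the package batches the work: shuffled spike maps
are smoothed by one sparse-matrix product, gridness nulls run through the
compiled correlogram kernel, and the speed classifier evaluates the
correlation at *every* circular shift at once via FFT cross-correlations
and then samples the admissible shifts. Classifier calibration is checked
in the test suite: on 500 homogeneous Poisson cells (10-minute trials,
1000 shuffles each) each classifier's pass rate must lie in the 99%
binomial band around 1%. The grid classifier computes its correlograms
from the smoothed rate over all bins with smoothed dwell (rather than the
NaN-masked display map) so that all 1000 maps share one support, which is
what makes the compiled fast path valid.

## Theta analyses

The LFP is band-passed at 6-12 Hz (zero-phase Butterworth, order 3 —
the band is a convention, so it is a parameter) and the analytic signal
taken by FFT. Phase is 0 degrees at the theta peak and increases through
the cycle; precession slopes flip sign under the opposite convention, so
this is fixed and documented. Instantaneous frequency is the wrapped phase
derivative over 2 pi, median-filtered over ~0.25 s, masked where it
leaves the band. Speed profiles average instantaneous theta frequency (or
instantaneous firing rate) in 2.5 cm/s speed bins from 2.5 to 30 cm/s and
fit a count-weighted line through the bin means.

Theta rhythmicity of a spike train models the lag distribution (all spike
pairs within 0.5 s) as `(1 + a cos(2 pi f lag)) exp(-lag/tau)`, fitted by
maximum likelihood (multi-start L-BFGS-B over modulation depth a,
frequency f in 4-14 Hz, decay tau). `a` is the theta index, `f` the
intrinsic frequency. Significance compares `a` to the 95th percentile of
indices from surrogate trains with permuted inter-spike intervals. A
rigid-shift null is useless here — the lag distribution is invariant
under rigid shifts — whereas ISI permutation preserves the ISI marginal
while destroying the rhythmic phase alignment across spikes.

## Two-dimensional phase precession

Each detected field's traversals are normalised onto the unit disc: the
field centroid maps to the origin and the half-max contour to radius 1,
preserving proportional peak-to-edge distance along each ray, and each
pass is rotated so its average running direction is 0 degrees. The edge
contour is located with sub-bin precision by marching rays of the smoothed
map from the centroid to the half-max crossing; the crossing estimate
averages the first down-crossing with the last above-threshold radius
(first passage alone is inward-biased under map noise), interpolates
across isolated unvisited bins, and is circularly smoothed across 5-degree
sectors. pdcd — the distance travelled through the field — is the
normalised position projected on the instantaneous running direction, in
[-1, 1] up to a small overhang where in-field bins exceed the smoothed
contour.

The phase-pdcd relationship is fitted by circular-linear regression:
the slope maximises the resultant length of the phase residuals over a
bounded range (±720 deg per pdcd unit; grid search plus local
refinement), the offset is the circular mean residual, and the
correlation between phase and |slope|·pdcd is reported with a permutation
p-value and a bootstrap 95% CI on the slope. Slopes are reported in
degrees per pdcd unit.

These geometric estimators were audited against ground truth: with the
centroid origin, robust peak and symmetrised edge crossing, the recovered
slope for a generative 360-degree sweep is unbiased on average, with a
remaining per-session scatter of a few percent that traces to the
estimated field geometry (visible because the bootstrap CI, which
conditions on the estimated field, is narrower than the across-session
spread). Recovery is therefore asserted on the across-cell confidence
interval of the mean slope.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analyses assume, not any biophysical mechanism.

*Trajectories* are a mean-reverting random walk: speed relaxes towards a
target (default 12 cm/s, the reported running speed in these arenas, with
empirical means required within 10%) under Gaussian perturbations of scale
`smoothness` (cm/s^2, default 15), heading diffuses with matching
intensity, and walls reflect specularly. `smoothness = 0` gives
constant-speed billiard motion. `wall_follow_bias` steers headings
wall-parallel near walls, reproducing the wall-following of head-fixed
VR. A separate loop generator produces ring-running with one dominant
rotational sense — the direction-biased sampling that makes a pure place
cell look directional and that the pxd model must undo. No quantitative
trajectory model is published for these sessions, so these dynamics are
chosen to match the summary behaviour (speeds, tortuosity) only.

*Spikes* are inhomogeneous Poisson: place fields are Gaussians; grids are
the rectified sum of three plane waves at 60-degree offsets, normalised to
the peak rate; HD tuning is von Mises; speed cells are linear in speed;
any spatial cell can carry a multiplicative directional gain
`1 + m cos(theta - mu)`. Thinning is piecewise-constant per sample with
uniform placement; the test suite applies a time-rescaling (Ogata) check
that the realised trains match the generative intensity.

*LFP* is a phase-continuous oscillation with instantaneous frequency
`base + slope * v(t)` (defaults 8 Hz and 0.05 Hz/(cm/s)) plus Gaussian
noise; the generative phase is stored for recovery tests.

*Precession* gates the intensity on the fine LFP grid with a unit-mean von
Mises factor (kappa = 3, circular SD about 40 degrees) on theta phase,
whose preferred phase sweeps linearly from 180 + range/2 to 180 - range/2
(default range 360 degrees) as the traversal coordinate — displacement
from the field centre projected on the running direction, in units of the
smoothed half-max radius — goes from -1 to 1, continuing at the same rate
slightly beyond the edge. Gating the intensity (rather than moving spike
times after the fact) keeps the phase-position relationship exact at
emission time; time-shifting schemes decorrelate the phase from the
recorded heading within tens of milliseconds and attenuate recovered
slopes.

*VR manipulations* scale place-field sigma by 1.44 and grid spacing by
1.42 — the reported VR/R expansion factors, used as generator defaults
and recovered by the analyses within 5% — add directional modulation to
place cells, multiply the LFP speed slope by a factor (0.5 in the
recovery tests), and rotate all spatial and directional tuning by 180
degrees for the cue-rotation probe.

## Problem sizes and limitations

The validation suite uses 10-minute trials for classifier calibration
(500 cells, 1000 shuffles), 20-minute R and 40-minute VR trials for the
expansion recovery (the standard trial lengths for these conditions), and
40-minute sessions for precession. The classification correlogram window
in the calibration is 20 bins (30 cm), which covers grid spacings up to
the arena half-width.

What passing tests do *not* show: the generator has no spike sorting
noise, no electrode drift, no overdispersion relative to Poisson, no
theta-cycle skipping, and trajectories are statistically stationary.
Results on real recordings inherit none of these guarantees. The paired
VR/R recovery demonstrates that the estimators read out the generative
contrasts, not that any particular real dataset shows them. Conjunctive
grid-by-direction taxonomy beyond flagging cells that pass both criteria,
border/speed-score variants, and ellipticity correction of grids are out
of scope.
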