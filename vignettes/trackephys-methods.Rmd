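---
title: "Models and methods behind trackephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trackephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackephys)
```

# The setting

trackephys analyzes extracellular recordings (sorted single units plus the
local field potential) made while a rodent runs a self-paced reward-seeking
task on a 50 cm linear track joining two platforms. A trial starts when the
animal leaves the reward zone, crosses the track to the trigger zone
("traversal to trigger"), turns, runs back ("traversal to reward"), and
collects a liquid reward that is delivered on 85% of correct trials. The
task is deliberately asymmetric -- running toward reward is faster than
running toward the trigger -- which makes the traversal direction (the "run
phase") a behaviorally meaningful variable alongside track position, trial
outcome, and the moment-to-moment kinematics.

Because recordings of this kind are not publicly archived, the package
ships a first-class synthetic-session generator whose ground truth
(tuning weights, oscillation parameters, optotagging parameters) is stored
alongside the data it generates. Every analysis stage is validated by
recovery: the generator plants a known effect and the analysis must find
it, at calibrated error rates.

# The encoding model

The central statistical object is a Poisson encoding model of single-neuron
activity. Spike trains are binned at the video frame rate (50 ms bins) and
smoothed with a Gaussian kernel of SD 100 ms; behavioral regressors are
sampled at the bin centers. The log rate of neuron $i$ is modelled as

$$\log \lambda_i(t) = \beta_0 + \sum_v \beta_v^\top x_v(t),$$

with one-hot blocks for linear position (10 bins: bin 1 the reward zone,
bins 2--9 the track, bin 10 the trigger zone), run phase, and trial
outcome, and z-scored continuous regressors for speed, acceleration, and
turning (head angular velocity, ipsiversive-positive). Goodness of fit is
the cross-validated $cvR^2$: the squared Pearson correlation between the
predicted rate and held-out activity, averaged over five *contiguous*,
non-overlapping folds. Contiguity matters -- smoothed spike counts are
autocorrelated, and interleaved folds would leak information between train
and test.

Two complementary quantities bracket a variable's explanatory power:

* the single-variable $cvR^2$, an upper bound that absorbs everything
  correlated with the variable, and
* the unique contribution $\Delta r^2$: the drop in full-model $cvR^2$
  when the variable's design columns are circularly shifted in time and
  the model refit. Shifting preserves the regressor's autocorrelation but
  destroys its alignment with the spike train, so whatever the shifted
  model still explains is credited to the other variables.

A neuron significantly encodes a variable when its full-model $cvR^2$
exceeds the 99th percentile of the $cvR^2$ values of 1000 reduced
(shifted) models. Shift offsets are drawn uniformly at least `min_lag_bins`
(default 100 bins = 5 s) away from zero lag in either direction, so no
shift is close to the identity.

Numerical choices. The Poisson fits use plain maximum likelihood via
iteratively reweighted least squares in compiled code, with a $10^{-8}$
diagonal ridge purely for numerical stability (a real ridge penalty is
available as an escape hatch for separable designs). The permutation
refits are warm-started from the unshifted per-fold solutions; two Newton
steps then reproduce the fully converged null distribution to four
decimals, which is what makes $1000$-shift runs per neuron and variable
tractable on one CPU. The linear predictor is capped at $\pm 30$
($e^{30}$ Hz) to guard overflow; degenerate CV folds (constant prediction
or response) contribute 0 to $cvR^2$. We additionally record the signed
per-fold correlation, since squaring would silently reward anti-correlated
predictions.

The candidate set screened by population-level stepwise inclusion contains
nine variables: the six above plus trial time (slow/fast split at 3 raw
MADs above the median duration), trial history (previous trial rewarded),
and trial type (current trial will be rewarded). Variables are added in
descending order of population-mean single-variable $cvR^2$ and kept when
a one-sided paired Wilcoxon test across neurons shows improvement at
$\alpha = 0.05$. One modelling choice deserves a note: the trial-outcome
regressor is only active from the moment the animal reaches the reward
port (when the outcome is revealed), whereas trial type spans the whole
trial; without this distinction the two would be structurally collinear.

A separate context model, restricted to running bins, contains a
position-with-direction conjunction (10 bins x 2 directions = 20
predictors) together with speed and acceleration, and asks -- per cell
type -- whether spatial context or movement explains the unique variance.

# Spatial statistics and decoding

Activity vectors are per-direction, trial-averaged firing-rate profiles
over the 10 position bins, built from traversals no longer than 10 s in
sessions with at least 10 traversals per direction. Traversal epochs are
extended symmetrically by 0.25 s so that the two zone bins are sampled at
both ends of the run regardless of direction; without this, zone-bin
missingness alone identifies the direction and would contaminate every
downstream comparison.

The direction modulation index is
$\mathrm{MI} = (r_{reward} - r_{trigger}) / (r_{reward} + r_{trigger})$,
on the means of the two activity vectors; it is $\pm 1$ when the neuron
fires in one direction only, 0 when balanced, and undefined for a silent
neuron. Its significance comes from a Wilcoxon rank-sum test on
per-traversal mean rates. Per-bin direction differences are tested against
1000 shuffles of the traversal direction labels (two-sided, 2.5%/97.5%),
after flipping the to-trigger vector so both directions share a
start-to-end frame. Spatial consistency correlates odd- and even-trial
activity vectors, with a null from 1000 circular shifts of the neuron's
binned activity against behavior. Spatial information over the track bins
(2--9) is $\sum_i p_i (f_i/f) \log_2 (f_i/f)$ bits/spike with occupancy
$p_i$ taken from time spent per bin during qualifying traversals;
zero-rate bins contribute zero, and the measure is invariant to rate
rescaling.

Decoding uses linear support-vector machines (cost 1) on single-traversal
10-bin rate vectors. Self mode: 20 random stratified 80/20 splits per
neuron, with label-shuffled controls. Cross mode: for each test neuron,
SVMs are trained on 15 + 15 z-scored activity vectors from 1--10 randomly
drawn same-class neurons and evaluated on all of the test neuron's
vectors; populations with a shared tuning template support cross-neuron
generalization, heterogeneous ones do not.

# LFP analyses

The LFP is processed at 1 kHz. Epoch spectra use a Hann-windowed averaged
periodogram (Welch, 0.5 s segments, 50% overlap); time-resolved power uses
complex Morlet convolution (7 cycles). The estimator is a configuration
choice and every reported quantity is relative, so the conclusions do not
hinge on it. Optogenetic resonance compares relative power (band power
over total 2--100 Hz power) between 1 s light trains and the preceding
1 s baselines, in the bands 6--14, 16--24 and 36--44 Hz, and reports the
power ratio $P_{light}/P_{baseline}$ within $\pm 4$ Hz of each drive
frequency. Rhythmic drive produces harmonics at integer multiples, which
is why cross-band comparisons across different drive frequencies are not
attempted.

Track-traversal spectra are restricted to temporally homogeneous
traversals (0.5--1.5 s across bins 2--9); each traversal's spectrum is
normalized by its total 1--100 Hz power and averaged per direction.
Gamma bursts are detected on the 30--50 Hz Morlet power averaged across
the band: the threshold is the 75th percentile of that power over all
qualifying traversal samples of the session (per site), and peaks above
it separated by at least one gamma cycle (25 ms) are counted. Because the
threshold is a percentile of the signal itself, detection is invariant to
rescaling the LFP. Speed-resolved power normalizes the spectrogram per
traversal by its peak and averages within 1 cm/s speed bins over the range
covered by both directions (15--75 cm/s).

Spike-gamma phase coupling extracts the instantaneous 30--50 Hz phase
from a zero-phase 4th-order Butterworth band-pass followed by the analytic
signal (cosine convention: phase 0 at the oscillation peak; no result
depends on the absolute reference). For each direction, neurons with at
least 50 spikes inside traversal epochs get a pairwise phase consistency
(PPC, computed through the algebraic identity
$(|\sum e^{i\theta}|^2 - n)/(n(n-1))$ and validated against the explicit
pairwise mean), a mean resultant length, and a Rayleigh test with the
standard finite-sample correction. PPC is unbiased in the spike count
under uniformity while MRL is positively biased (roughly
$\sqrt{\pi/4n}$), which is why both are reported. The two per-direction
Rayleigh flags partition neurons into four coupling groups.

# Unit classification and optotagging

Units are classified from two waveform features -- spike width
(peak-to-trough time) and peak-to-valley ratio, taken from the tetrode
with the largest amplitude -- by a two-component Gaussian mixture on
standardized features with full covariances. The narrower-mean-width
component is the narrow-spiking (NS) one; posterior NS probability above
0.95 labels NS, below 0.30 labels WS, anything between stays
unclassified. Identifying the NS component by width rather than mixing
weight keeps the rule robust to class imbalance.

Directly light-activated units are found with a stimulus-associated spike
latency test: first-spike latency histograms (1 ms bins over a 10 ms
window) after each light pulse are compared -- via Jensen--Shannon
divergence -- against histograms from ten 10 ms baseline windows preceding
each pulse. The observed statistic is the median test-vs-baseline
divergence and the null is the set of baseline-vs-baseline divergences;
the window, bin size and number of baseline epochs are configuration keys
following the cited method's convention, since this study does not restate
them. A unit is promoted to FS-PV only if it was NS, the latency test
gives p < 0.05, and the mean light-evoked waveform correlates with the
spontaneous one at r > 0.95 (a guard against sorting artefacts during
light application).

# What the generator emulates -- and what it does not

The behavioral simulator produces alternating platform-dwell and
track-traversal segments with trapezoidal speed profiles (to reward
faster: 60 vs 45 cm/s plateaus) and a smooth sinusoidal within-run speed
modulation (+/- 25%) so that the speed distributions of the two directions
overlap, as real running does; 180 degree turns take 0.5--1.5 s with random
chirality; tracking observations get Gaussian noise (SD 0.5 cm) and a
small fraction of dropped frames. Spike trains are inhomogeneous Poisson
draws from the same log-linear model the analysis fits, with spikes of
phase-locked units placed at von Mises-distributed phases of a continuous
gamma reference oscillation embedded in the LFP. The LFP adds $1/f^{1.5}$
background noise and Gaussian-enveloped gamma bursts (75--150 ms,
center frequency uniform in 30--50 Hz) as a Poisson process at 5.9 and 4.8
bursts/s in the two directions. Optotagging appends light trains (1 s at
10/20/40 Hz, 2 ms pulses) after the behavioral epoch; tagged units emit
evoked spikes with configurable latency, jitter and reliability, and the
LFP receives a pulse-locked alpha-function response whose gain grows with
drive frequency, mirroring the resonance the analyses should find.

The generator does not emulate: non-Poisson spiking statistics (bursting,
refractory structure beyond a 1 ms collision rule), waveform shape beyond
the two-feature clusters, electrode drift, theta-band structure, movement
artefacts in the LFP, or cross-neuron correlations beyond shared tuning
templates. Passing the recovery tests therefore shows that the estimators
are correct and calibrated under the generative model, not that real
recordings satisfy that model.

Two generator defaults deserve flagging. Inter-burst refractoriness
defaults to zero so that burst rates stay exactly at their configured
values; detector validation fixtures set a 150 ms separation because
recall/precision against ground truth is only well defined when the
ground-truth events are individually resolvable. And the
direction-preference weight used in the decoding-regime fixture
($\pm 0.25$ log-rate units) was calibrated once against the observed
single-neuron decoding range (60--70%) and then frozen.

# Validation fixtures and problem sizes

The test suite and the package's standard fixtures use sessions of 20--30
trials (roughly 2 to 4 minutes), populations of up to 200 synthetic
neurons, 100--200 circular shifts for per-neuron significance, and 400--1000
replicates for calibration checks; the full-inference default of 1000
shifts is used when final tables are produced. At these sizes the
permutation criterion's type-I error is measured at its nominal 1% level,
variable-recovery sensitivity exceeds 0.9 at false-positive rates below
3%, and the burst detector exceeds 90% recall and precision at
signal-to-noise 3. Determinism is enforced end to end: identical
configurations and seeds produce byte-identical sessions on disk and
byte-identical result tables.

# Known limitations

* All models are linear in their regressors; nonlinear encodings and
  interactions (beyond the explicit position-with-direction conjunction)
  are out of scope.
* The squared-correlation $cvR^2$ rewards any monotone association and,
  squared, hides sign pathologies; the signed fold correlations are kept
  for diagnosis.
* The smoothing kernel (100 ms) sets a floor on recoverable spatial
  detail: place fields much narrower than the distance covered in ~100 ms
  are flattened, and spatial information saturates accordingly.
* The circular-shift null preserves autocorrelation but not slow
  nonstationarities; a drifting neuron can defeat it.
* With one recording site there is no accounting for volume conduction or
  reference effects in the LFP analyses.
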