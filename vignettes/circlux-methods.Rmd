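---
title: "Methods: single-cell circadian oscillator ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell circadian oscillator ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlux)
```

# Overview

`circlux` analyzes multiday single-cell bioluminescence recordings of
circadian clock-protein reporters (PER or TIM luciferase fusions) in
cultured *Drosophila* brains, alongside matched locomotor/sleep data
from live flies. The pipeline runs: light-schedule construction →
(optionally) raw frame processing → wavelet detrending → per-cell
rhythm metrics → ensemble synchrony with randomization inference →
sleep statistics. A first-class synthetic-data generator emulates the
oscillator ensembles and fly activity under programmable light
schedules so that every stage can be tested against known ground truth
without any recorded data.

# Light schedules

Time is continuous hours from experiment start; day *d* spans
$[24d, 24(d+1))$ and intervals are half-open $[start, end)$, which
makes binning and segment boundaries unambiguous. The strobed-LD
protocol places one short light pulse (default 15 min) at the top of
each of the 12 daytime hours followed by darkness, then a 12-h night;
it entrains flies indistinguishably from standard 12/12 LD while
leaving 45 min of darkness per hour for photon counting. Skeleton
photoperiods cap the 12-h day with a dawn pulse starting at lights-on
and a dusk pulse ending at the dark transition. Constant light
continues the hourly pulse cycle through the night; constant darkness
has no pulses.

The weekend light shift (WLS) applies a 3-h phase delay beginning at
the dusk transition of the third recorded day ("Friday evening") — the
night is lengthened at its start and every subsequent pulse moves 3 h
later — and restores the original phase on the morning of the sixth
day ("Monday"), shortening that night. The source protocol does not
give minute-level mechanics for the Friday evening transition; because
the strobe day ends at hour 12, no Friday pulses themselves move, and
any consistent convention that delays subsequent lights-on by 3 h is
equivalent. Analysis segments are always bounded by the *control*
schedule's lights-on times, including for the shifted arm; in constant
darkness the boundaries extrapolate the last lit day's phase at 24-h
spacing.

# Synthetic oscillator ensembles

Each cell is a damped phase–amplitude (Poincaré-style) oscillator:

$$\frac{d\phi_i}{dt} = \frac{2\pi}{\tau_i}
  + k_i L(t)\,\sin(\phi_{target}(t) - \phi_i)
  + g\,\sin(\Phi(t) - \phi_i),$$

integrated with a fixed-step explicit scheme at 0.05 h. $L(t)$ is the
schedule's light state, $\phi_{target}$ is locked to the current day's
(possibly shifted) lights-on, and $\Phi$ is the mean phase of the
cell's brain (six brains per arm by default; network coupling acts
within a brain). Light coupling acts continuously while $L(t)=1$, so a
15-min pulse delivers a quarter of the phase pull of a lit hour —
strobe-vs-standard-LD equivalence is emergent, not assumed. The
emitted signal is $y = b(t) + A_i(t)\,(1+\cos\phi_i)/2 + \varepsilon$
sampled every 0.75 h (45-min bins), with shot-like noise (SD
proportional to the square root of the mean signal), additive Gaussian
noise, a slow baseline drift, and an elevated baseline transient
decaying over the first ~12 h of culture to emulate post-dissection
instability (this is what the standard 12-h trim removes). The TIM
reporter option advances the emitted phase by 3 h and scales amplitude
to 60%, matching the reported PER/TIM relationship.

Four mechanisms beyond the minimal oscillator are part of the stated
world because the analysis exists to detect their consequences:

* **Heterogeneous shift speed.** Per-cell light coupling $k_i$ spans a
  log-uniform range (about 0.06–0.54 /h for the lateral ventral
  neurons). Under a stable schedule all cells lock with small lags, but
  after a phase shift fast cells re-entrain within a day while slow
  cells take several days — heterogeneous shift speed, not the shift
  itself, is what desynchronizes a subgroup.
* **Amplitude suppression by mistimed light.** Light arriving at a
  conflicting circadian phase suppresses amplitude at rate
  $k_{amp}(1-\cos\Delta)/2$ per lit hour. Cells that stay misaligned
  through the weekend collapse to a small fraction of their amplitude;
  recovery (relaxation toward $A_0$ at 0.02/h) takes days, so the
  deficit outlasts the shift.
* **Low-amplitude phase instability.** Phase diffusion scales as
  $A_0/A$: a nearly flat oscillator has a poorly defined phase that
  wanders, so amplitude-collapsed cells scatter over the cycle and
  re-entrain from random phases. This combination reproduces the
  "first out, last back in" lateral-ventral phenotype.
* **Resonant network drive of light-blind DN3s.** DN3 cells carry no
  cell-autonomous photoreception ($k=0$); their oscillation is
  sustained by network input whose efficacy falls off steeply with the
  cell's phase lag to the network mean (modelled as
  $A_{target} = A_0 \max(0.1, \cos(\Phi-\phi))^3$). With a long
  intrinsic period (24.9 ± 0.1 h) they trail the 24-h entrained
  network with substantial, heterogeneous lags, giving the most
  variable amplitudes of any subgroup under control conditions. During
  the weekend delay the network transiently runs at a longer period —
  closer to the DN3s' own — so their lags compress and their
  amplitudes rise and homogenize: the counterintuitive *increase* in
  DN3 synchrony under WLS is an emergent resonance effect here.

Per-cell periods and couplings are quantile-stratified within each
subgroup (the assignment order is still randomized): an 18-cell
subgroup then represents its stated heterogeneity by construction
rather than by luck of the draw, which keeps arm-to-arm differences
reflecting dynamics rather than sampling noise. Amplitudes, baselines,
initial phases, and all emission noise remain independently random.

No quantitative coupling or damping constants are available for the
real circuit; all defaults are synthetic calibrations chosen once to
reproduce qualitative orderings (LNvs most light-labile, DN1 highest
amplitude, DN3 network-following and weekend-tightening) and are
clearly labelled as such. A green test against this generator
establishes that the *analysis* behaves correctly on data with this
structure, not that the constants describe real neurons. In a typical
run the lateral-ventral difference is strongly significant on multiple
weekend/post-weekend days, while the DN3 weekend effect is a small
positive shift against residual arm-to-arm noise: its window mean is
positive in most, not all, seeds.

# Fly activity and sleep generator

Per-minute beam-crossing counts are inhomogeneous Poisson draws. The
rate carries a day/night plateau contrast, two crepuscular Gaussian
bumps phase-locked to each day's (possibly shifted) lights-on, and a
per-fly random-walk drift of daily timing (step SD 0.75 h) emulating
day-to-day onset variability. Consolidated sleep bouts — intervals
where the rate is forced to zero — alternate with wake bouts; bout
lengths are Poisson-distributed with night sleep (mean 35 min) longer
than day sleep (mean 12 min), so hourly sleep varies across flies
without saturating at 0 or 60 min (degenerate bins would otherwise
make rank tests uninformative). An optional death time zeroes all later
counts, which the automated dead-fly rule (terminal silence ≥ 24 h)
removes.

# Imaging chain

The raw-frame chain mirrors the acquisition pipeline: (1) cosmic-ray
rejection — per frame, S = sum of pixel values exceeding 800, rejected
when S exceeds the mean by more than 3 SD over the trailing 30
*accepted* frames (using accepted frames only prevents one hit from
masking the next; the first window is a warm-up, and both readings of
the ambiguous statistic are available behind a flag); (2) 45-min
pixelwise binning, with empty bins carried as explicit missing frames,
never zeros; (3) running minimum over sequential frame pairs, which
removes any single-frame transient such as residual cosmic rays and
hot pixels; (4) ROI extraction as cell-ROI mean minus the *same
frame's* background-ROI mean — values may be negative and are not
clipped; (5) conversion to photons per minute. No TIFF reader exists
in this R stack, so stacks are held as plain arrays with a documented
CSV text serialization; all operations are format-independent.

# Rhythm metrics

**Detrending.** A translation-invariant (maximal-overlap) discrete
wavelet transform with the LA(8) least-asymmetric filter and
reflection boundary handling decomposes each trace; no wavelet package
exists in the target R stack, so the transform is implemented in the
package and cross-checked against an FFT band-pass oracle. At 0.75-h
sampling, detail level *j* spans periods of roughly
$[2^j \cdot 0.75, 2^{j+1} \cdot 0.75]$ h: the circadian signal is
levels 4–5 (12–48 h), and the noise floor $\sigma_{noise}$ is the SD
of the finest level (1.5–3 h, entirely below 4 h; the 3–6-h level
straddles 4 h and is excluded). $\sigma_{noise}$ is computed once per
record — a single baseline noise value — not per window. The detail
filters are soft-edged: on white noise $\sigma_{noise}$ sits ~15%
below an ideal <4-h band-pass, and re-detrending attenuates the
in-band signal by another 1–2% RMS (the band selection is not an exact
projection). Gaps are linearly interpolated with a logged mask; the
detrended series is centered.

**Sine fits.** In 2-d sliding windows (6-h step; the reporting
convention is window midpoints), $x(t) \approx \hat A\cos(2\pi(t -
\hat\phi)/\hat\tau)$ is fitted by least squares: $\hat\tau$ on a
16–32 h grid (0.1-h step, ties toward 24 h, refined by local
optimization), $\hat A$ and $\hat\phi$ in closed form per candidate.
$\hat\phi$ is the peak time relative to the window start, in
$[0,\hat\tau)$, reported in hours and radians. The goodness of sine
fit is the Pearson correlation between fit and data (the source
threshold 0.82 is quoted without a functional form; correlation is our
documented reading, with $R^2$ behind a flag). Windows with more than
25% missing samples are skipped; flat windows report zero amplitude
and zero gof with a flag.

**Reliably rhythmic.** A window passes when period ∈ [16, 32] h
(inclusive), amplitude strictly exceeds $\sigma_{noise}$, and gof ≥
0.82. These calls gate only *phase reporting* (circular summaries);
the order parameter never discards cells.

**Lomb–Scargle.** The variance-normalized periodogram over 16–32 h on
consecutive 4-d segments, with false-alarm probability
$1-(1-e^{-z})^M$, where $M$ is the number of independent frequencies
the band spans ($M = T\,\Delta f \approx 3$ for 4 days). A cell is
called rhythmic when at least half its segments are; the per-segment
false-positive rate is what calibrates to $\alpha$.

**Delay embedding.** The trace is embedded as
$(x(t), x(t-6\,\mathrm{h}))$ — a quarter period — centered by a 24-h
running mean; phase is the unwrapped polar angle (zero at the waveform
peak) and amplitude the radius smoothed over 3 h, flagged invalid
below the noise floor. Embedded phases validate the sine-fit phases
(circular MAD < 0.5 h on clean oscillators) without assuming
sinusoidal shape.

# Synchrony

The order parameter on each 24-h control-lights-on-bounded segment is
the variance ratio

$$R = \frac{\mathrm{Var}_t\left(\frac1N\sum_i \tilde
x_i(t)\right)}{\frac1N\sum_i \mathrm{Var}_t(\tilde x_i(t))},$$

computed from the entire detrended waveforms rather than phase
estimates: identical traces give exactly 1, two equal-amplitude
antiphase cosines give exactly 0, and $N$ independent noise traces
give $\approx 1/N$. It is invariant to common multiplicative scaling,
and sensitive to phase, period, waveform *and* amplitude-proportion
differences (a subgroup whose cells' amplitudes diverge loses R even
at identical phases, as $\bar a^2 / \overline{a^2} < 1$). The exact
normalization in the originating work is not reprinted; this
variance-ratio form is adopted and documented, with an
amplitude-prenormalized variant available by rescaling inputs. Cells
with zero segment variance are dropped from that segment's denominator
with a warning; segments with fewer than two usable cells are missing.

Group differences use the source randomization design: cells from both
arms are pooled, two *disjoint* subsets of the smallest cluster size
are drawn uniformly (a symmetric null for a difference statistic),
their per-day R difference computed, and 5000 replicates (1000 in the
scaled-down acceptance runs) give empirical 95% and 99% percentile
bands under the null of no group difference; the observed
$R_{WLS}-R_{CTRL}$ outside a band marks that day significant. The seed
is recorded in the output.

Circular phase statistics use only reliably rhythmic windows: phases
are standardized so that ZT0 equals the overall mean phase of all
control cells on day 3 (when entrainment is most stable), reduced to
the circular mean, resultant length $\rho$, the Rayleigh test
$p = e^{-z}\left(1+\frac{2z-z^2}{4n}-\frac{24z-132z^2+76z^3-9z^4}{288
n^2}\right)$ with $z=n\rho^2$, and the $\alpha$-threshold radius
$\sqrt{-\ln\alpha/n}$ for plotting. Windows with no qualifying cell
are omitted, never reported as zero. The phase-ensemble export writes
relative phase angle and normalized radius per cell per time — the
table behind disk-style ensemble animations — without rendering.

# Locomotor activity and sleep

The Sokolove–Bushell chi-square periodogram runs on 15-min binned
counts over periods 16–32 h (integer bins per period):
$Q_p = \sum_h n_h (M_h-\bar M)^2 / s^2$ with $K-1$ degrees of freedom,
significance line at the 0.95 chi-square quantile. "Power" is peak
$Q_p$ minus the line at the peak (the published criterion power ≥ 40
only makes sense relative to a baseline) and "width" is the contiguous
super-threshold span around the peak — both our documented
conventions, configurable, since the original software's exact
definitions are not printed. With this width reading the ≥ 4 h
criterion is comfortably met on 4–6-day records (the design the
original behavioral quantification used) and becomes knife-edged at 8+
days, because the peak narrows as the record lengthens; rhythmicity
tests therefore use 5-day windows.

Sleep is any maximal run of zero activity lasting ≥ 5 min, every
minute counting (including the first five, the standard reading of a
rule the source states ambiguously); minutes are summed per 60-min bin
with boundary-spanning runs split pro rata, conserving sleep + wake =
60 per bin. Flies whose record ends in ≥ 24 h of silence are removed
as dead (an automated stand-in for manual curation). Group comparisons
are per-bin and per-day Wilcoxon rank-sum tests at α = 0.01 (sleep is
floor/ceiling-bounded and non-normal); bins where every fly in both
arms ties exactly are degenerate and get `p = NA` rather than a
significance call.

# Orchestration and reproducibility

`run_experiment()` executes both arms end to end and writes trace,
fit, R-series, band, circular, and sleep tables plus a JSON summary.
The master seed expands into fixed per-stage child seeds (control
cells, WLS cells, randomization, two activity arms), so any stage can
be rerun in isolation and identical configuration yields byte-identical
summaries. The package is a library rather than a shell tool: the
exported functions, `scripts/acceptance.R`, and this vignette are its
interface.

# Known limitations

* The oscillator model is phenomenological: phase, amplitude, and
  their couplings are the state — no molecular clock variables, no
  anatomy, no temperature or feeding zeitgebers; the cry-mutant
  condition is representable only as zero light coupling with free
  parameters.
* Simulated arms share no brains; arm-to-arm baseline differences in R
  (a few hundredths) persist after stratification, so small effects —
  notably the DN3 weekend tightening — are near the noise floor of a
  ~100-cell experiment.
* MODWT edge effects extend roughly one filter width into the record;
  sine-fit windows touching the record boundary inherit small period
  and amplitude biases, which is why recovery tests read interior
  windows.
* The DAM dialect is fixed at 42 tab-separated columns (32 channels);
  ROI tracking/segmentation is out of scope — ROIs are inputs.
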