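---
title: "Methods: stepwise nucleosome translocation from smFRET traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stepwise nucleosome translocation from smFRET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepfret)
```

# The measurement and its model

A surface-tethered mononucleosome carries a FRET donor (Cy3) on the histone
octamer and an acceptor (Cy5) on the DNA. As a remodeling enzyme
translocates DNA past the octamer, the donor–acceptor distance changes and
the FRET efficiency tracks the position of the labeled DNA site. The
analysis rests on four modeling assumptions:

1. **FRET as proximity ratio.** We use the uncorrected ratio
   $E = I_A/(I_A + I_D)$ on background-corrected intensities, with no gamma
   or crosstalk correction. The observed FRET ranges in this assay are well
   separated (initial ~0.45, entry-side peak ~0.85, entry product ~0.17,
   exit product ~0), so the uncorrected ratio preserves all the structure
   the analysis needs; corrections would rescale, not reorder, the levels.
2. **Linear FRET–linker calibration.** Over the measured range, mean FRET
   is approximately linear in linker DNA length, with slope magnitudes near
   0.05 per bp depending on the labeling scheme. This line is the ruler
   that converts FRET step sizes to bp, and its span defines where step
   detection is trusted — plateaus outside the linear range are discarded.
3. **Memoryless stepping.** Pauses between translocation steps are
   exponentially distributed; pauses shorter than the 5-frame detection
   threshold are unobservable, which both censors the pause-lifetime sample
   and merges consecutive steps into apparent multi-step events.
4. **Piecewise-constant trajectories.** Between steps the FRET level is
   constant up to additive Gaussian camera noise; step detection is a
   change-point problem in the mean.

# Trace processing and selection

Single molecules are selected by **one-step photobleaching**: the total
(donor + acceptor) intensity is step-fitted and a trace is accepted only if
it shows exactly one discrete drop to the final baseline. The drop
threshold is 3x the noise SD of the final segment. The post-bleach mean of
each channel is the background subtracted from that channel. In our
emission model an acceptor-only bleach leaves the total unchanged (the
donor recovers the transferred energy), so such traces show no drop and
are excluded by the same rule — consistent with how the selection behaves
on real data, where only a terminal bleach to background provides a usable
background estimate.

"Initial FRET" is the mean of the first 10 valid frames and "final FRET"
the mean of the last 10 valid frames before the bleach; the window is
configurable, and 10 frames at 1 Hz averages enough noise without reaching
into the remodeling transient.

# Entry/exit classification

A trace is classified after 3-pt median filtering. If 3 consecutive points
exceed the initial FRET by a threshold (0.1 by default; 0.07 for the
backbone,−15 labeling geometry whose FRET excursions are smaller) *before
the trace first reaches its final plateau*, the trace contains a FRET rise;
otherwise it is monotone. For end-labeled constructs a rise means
entry-side movement; for the backbone,−15 construct the geometry inverts
the mapping. Two operational choices make the rule automatic:

- "Reaching the final FRET value" means the first frame at which the
  filtered trace enters within ±0.05 of the final plateau level and stays
  there. The ±0.05 band is about 1.5x the filtered noise SD, wide enough
  not to trigger on noise, narrow enough not to swallow real plateaus.
- Traces whose total FRET change is below 0.15 are flagged unclassified
  rather than forced into a class. This replaces manual curation of
  "traces exhibiting remodeling" with a reproducible gate; 0.15 is
  comfortably above the ~0.1 photophysical donor-enhancement artifact and
  below the smallest genuine remodeling excursion (~0.3).

The small apparent FRET dip that precedes entry-side movement — a donor
brightness increase upon enzyme binding, not a distance change — is
invisible to the classifier because the rule only tests upward excursions.

# Step detection

Two independent idealization algorithms are implemented, and their
agreement is itself a result (a shared histogram peak supports the step
sizes being real rather than algorithm artifacts).

**Chi-square minimization.** A greedy best-first search: at each round the
single change point that maximally reduces the residual sum of squares over
all current segments is inserted. Each insertion must reduce the RSS by
more than a mean-shift significance penalty $\hat\sigma^2 \cdot 2\log n$,
with $\hat\sigma$ estimated robustly from the median absolute first
difference — this screens noise-level splits that the counter-fit ratio
alone discriminates poorly. Placements are then refined by coordinate
descent (each change point re-optimized within the segment bounded by its
neighbors), which makes the placements jointly optimal; on two-step traces
the refined greedy result coincides with exhaustive enumeration over all
placements. The retained step count maximizes the **counter-fit quality
ratio** $S_k = RSS_{counter}/RSS_{fit}$, where the counter fit places its
change points at the midpoints of the fitted plateaus; $S_k$ peaks at the
supported step count and a trace whose maximal $S_k$ falls below 1.3 is
declared step-free. The 1.3 default balances false splits against missed
steps at the signal-to-noise of this assay (step 0.1 ΔFRET, noise SD
~0.03); it is configurable. Plateau levels are segment means, matching the
chi-square objective. Step detection runs on unfiltered FRET values — the
fitters model the noise explicitly, and median filtering would correlate
it.

**Hidden Markov model.** Gaussian-emission HMMs with state-specific means
and a shared emission SD are fitted by Baum–Welch EM for 1..10 states, with
5 random restarts per state count (initial means spread over the data
quantiles with jitter). The state count is selected by BIC; the complexity
term counts one mean per state, the shared SD, and one escape probability
per state ("sticky" transitions), which is the effective parameterization
of stepping data — counting a full transition matrix over-penalizes larger
state counts and merges genuine plateaus. The state-count scan stops after
the BIC worsens twice in a row. The most probable state path (Viterbi) is
decoded and consecutive identical states merged into plateaus whose levels
are the state means. The forward–backward and Viterbi recursions are
compiled (Rcpp) for speed.

**Step acceptance.** Both idealizations pass the same filters: flanking
pauses of at least 5 frames (the detection threshold that defines the
missed-step probability), flanking plateau FRET inside the calibration
range, and exclusion of backward steps (sign opposite the expected
translocation direction — monotone-down for exit-side traces; for
entry-side traces "forward" is FRET-increasing before the maximal plateau
and decreasing after). Backward steps are tallied as a fraction of
filter-surviving steps, and are rare (<5%) in both the synthetic and the
original data.

# Step-size statistics

Accepted step magnitudes are binned at 0.02 ΔFRET (the scale of the
figures; the exact width is configurable) and fitted by unweighted
nonlinear least squares to the missed-step mixture

$$y(x) = \sum_{n=1}^{6} A\, f^{\,n-1} \exp\!\left(-\frac{(x - n c)^2}{2 s^2}\right)$$

with the width $s$ shared globally across histograms of the same movement
type and $(A, f, c)$ per histogram; with a single histogram the joint fit
degenerates to an independent one. The fit is multi-started over a grid of
`c` values around the modal bin (0.5x–1.5x) and the best-residual start
wins; parameter standard errors come from the covariance at the optimum.
Fits on the model's own noiseless curve recover the generating parameters
to machine precision, and fits on 1000 sampled steps recover `c` within
±0.005 and `f` within ±0.05.

Dividing `c` (and its SE) by the calibration slope magnitude (and its SE,
combined in quadrature) gives the step size in bp. The enzyme-free
calibration slopes are the default ruler — they reproduce the reported bp
values (e.g. 0.104/0.053 → 2.0 bp) — and enzyme-bound slopes can be passed
explicitly. Slope signs are treated as magnitudes; the direction
information lives in the classification, not the calibration.

Pause lifetimes from the idealizations are left-truncated at the 5-frame
threshold: with exponential dwell times the memoryless property gives
$\hat\tau = \overline{d} - t_{thr}$, and the expected missed-event fraction
is $1 - e^{-t_{thr}/\tau}$ (0.221 at $\tau = 20$ frames). Interior pauses
only are used — the first and last plateaus are censored by the observation
window.

# The synthetic-data generator

The generator emulates the study conditions: 1 Hz imaging, exponential
pauses (mean 20 frames), a 1-bp fundamental translocation unit emitted as
1–2 bp observable steps (defaults 30%/70%, giving the observed ~2 bp
histogram peak with the default calibration), plateau FRET levels moving
along the calibration line, a 1.10x donor brightness enhancement from the
enzyme-binding frame onward (photophysical only: the acceptor channel is
untouched, so the apparent FRET dips without a distance change), additive
Gaussian channel noise (SD 35 on a total intensity of 1000, i.e. raw FRET
noise ~0.05), and memoryless single-event photobleaching per dye (default
0.0015 per frame per dye). Entry-side trajectories rise to the top of the
calibration range and then fall to the ~0.17 product level; exit-side
trajectories fall monotonically. Gap constructs force the movement class,
mirroring the ssDNA-gap controls.

What the generator does **not** emulate: photon-counting (Poisson/EM gain)
noise, spot drift or overlap, multi-dye labeling artifacts, baseline drift,
blinking, enzyme rebinding after completed remodeling, and any
ATP-dependence of the pause rate (the generator exposes the mean pause
directly, since the kinetic scheme linking ATP concentration to stepping
rate is not part of the model). Tests passing on synthetic data therefore
validate the algorithms under the stated statistical model; they cannot
certify behavior under instrument pathologies outside it.

# Numerical choices and degenerate inputs

- Segment RSS values are computed from cumulative sums; the "zero RSS"
  tolerance scales with the series' power (1e-10 x sum of squares) so
  noiseless staircases are recognized as exact fits at any intensity scale.
- Median filtering shrinks its window at the edges; the median of an
  even-sized window is the mean of the two central values.
- Even at `f` fitted against its bounds (0 or 1) the mixture fit returns,
  with the `f_pinned` flag raised.
- Degenerate inputs reject loudly: zero-variance Gaussian fits, flat
  ensemble curves, FRET of exactly 0 or 1 in the Förster conversion,
  calibration with fewer than 3 linker lengths, pause samples containing
  sub-threshold durations.
- All stochastic functions take explicit seeds; identical seeds give
  bit-identical outputs.

# Problem sizes

The shipped tests and the acceptance script use 200 simulated staircases
(5 steps each) for step-finder validation, 400 traces for classification,
1000 sampled steps for mixture recovery, 10^4 draws for pause-lifetime
recovery, and 200-trace datasets for the end-to-end pipeline — sizes
comparable to the per-construct molecule counts of the original study
(>100–200 nucleosomes per condition) and large enough that the binomial
error on every rate estimate is a few percent.

# Known limitations

- The proximity ratio is uncorrected; absolute distances from the Förster
  conversion inherit the usual κ²≈2/3 point-dye assumptions and are
  interpretive, not metrological.
- The chi-square stop rule's threshold (1.3) and the HMM's BIC complexity
  count are calibrated to this assay's SNR regime; very different
  noise-to-step ratios may need retuning.
- The pipeline classifies traces independently; it does not model enzyme
  rebinding, multi-enzyme events, or composite traces.
- Backward steps are excluded from histograms (as in the original
  analysis); a mechanistic treatment of back-stepping would need them.
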