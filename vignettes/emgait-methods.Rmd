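---
title: "Methods: EMG-based evaluation of gait rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-based evaluation of gait rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgait)
```

## Scope and rationale

`emgait` evaluates how closely a walking patient's lower-limb muscle
activation resembles normative activation, from eight channels of surface
EMG (bilateral tibialis anterior TA, soleus SOL, rectus femoris RF,
semitendinosus ST, sampled at 1 kHz) plus an optional binary footswitch.
It produces three families of outcomes:

1. **Pattern similarity indices** per muscle and muscle couple: the Gait
   Metric (GM, amplitude and timing agreement with a normative gait-cycle
   profile) and the Burst Duration Similarity Index (BDSI, percent of the
   cycle in the same on/off state as the normative burst pattern).
2. **Agonist–antagonist intermuscular coherence** in three bands — alpha
   5–10 Hz (spinal drive), beta 15–30 Hz and gamma 30–45 Hz (cortical
   drive) — with band areas and a multi-trial 95% confidence limit.
   In healthy gait antagonist coherence is present in alpha and absent in
   beta/gamma; after stroke this reverses, so clinical improvement is
   *gaining* alpha significance and *losing* beta/gamma significance.
3. **A composite Capacity Score** summarizing six clinical scales
   against healthy references, with minimum-detectable-change (MDC)
   flags on T1−T0 changes.

Because no raw recordings from any clinical study ship with the package,
a synthetic gait-EMG generator with full ground truth (step boundaries,
activation windows, injected common drive) is a first-class module: every
pipeline stage is validated by parameter recovery on generated data. The
package is a library plus this vignette rather than a shell tool; all
entry points are plain R functions that read and write the TSV/JSON
formats described in the function documentation.

## Pre-processing and the linear envelope

Each channel passes through a 3rd-order Butterworth high-pass at 20 Hz,
full-wave rectification, and a 3rd-order Butterworth low-pass at 4 Hz
(`compute_envelope()`). Two numerical choices deserve mention:

* **Zero-phase filtering.** Both filters are applied forward–backward.
  The downstream indices are *timing* indices (burst on/off phases, epoch
  placement for coherence), and causal filtering would delay bursts by a
  muscle-dependent group delay. The price is that the effective
  attenuation is that of a 6th-order filter; amplitude effects are
  irrelevant because every profile is later normalized to its own peak.
* **Edge handling.** One settling length (three time constants of the
  cutoff) is reflect-padded at each end before filtering, suppressing
  onset transients on short walks.

Sanity anchor: a unit 50 Hz sinusoid settles at the analytic rectified
mean 2/π ≈ 0.637 (within 2%, the residual being twice-applied passband
attenuation at 2.5× the cutoff), and DC maps to ~0.

```{r envelope}
env <- compute_envelope(sin(2 * pi * 50 * (0:4999) / 1000), 1000)
mean(env$values[1000:4000])
```

## Step segmentation from SOL deactivation

SOL is the only recorded muscle with a monophasic burst per gait cycle,
so each transition of its envelope from active to inactive marks exactly
one step. `detect_deactivations()` uses a trailing moving-window adaptive
threshold: at sample *t* the threshold is *k* × mean envelope over the
previous `window` seconds. Defaults — `window = 2` s, `k = 0.5`,
`min_off = 100` ms, `refractory = 300` ms — were chosen once as follows:
2 s always spans at least one full cycle at walking cadence, so the
trailing mean tracks roughly half the burst duty amplitude and `k = 0.5`
puts the threshold well above the inter-burst floor and well below the
burst plateau; 100 ms is much shorter than the shortest physiological
inter-burst gap (~500 ms) but long enough to ignore ripple; 300 ms merges
double-crossings within one burst tail. All four are exposed.

Conventions that matter downstream:

* A *deactivation event* requires the below-threshold run to be preceded
  by an above-threshold run — the initial rest before the first burst is
  not a deactivation. K bursts therefore give exactly K events.
* The **detected step count is the number of deactivation events**; the
  K−1 intervals between consecutive events are the cycles that profiles
  average over. Count-based accuracy against the footswitch is
  `100 × (1 − |detected − true|/true)`, floored at 0.
* Patients are segmented from the **non-paretic** SOL (the monophasic
  burst stays reliable on the unaffected side); healthy subjects from the
  right SOL by convention.
* A cycle that starts at SOL deactivation is rotated relative to the
  conventional heel-strike cycle. The segmentation carries
  `anchor_offset_pct` (default 50: SOL deactivates around toe-off, half
  way through the heel-strike cycle with the default templates) so that
  phase windows stated in the heel-strike frame — such as the coherence
  epochs below — can be mapped into segmented profiles. With this anchor
  the terminal-swing-through-loading co-activation region becomes a
  *contiguous* mid-cycle span, which is also why the segmentation anchor
  is analytically convenient.

## Gait-cycle profiles, masks and normative patterns

Each step's envelope is linearly resampled to a fixed grid of
G = 1000 points (0.1% resolution — finer than the native sample count of
a ~1 s step at 1 kHz, so no information is lost and 200 ms windows are
not aliased), averaged pointwise across steps, and normalized to its own
maximum. Linear interpolation suffices because the envelope is 4 Hz
band-limited. The activation mask is `value > 0.40 × peak` with a strict
inequality (ties off — deterministic and measure-zero on real data). The
normative profile is the pointwise mean of healthy subjects' profiles,
re-normalized, with its own 40% mask; the healthy cohort's mean step
duration is stored as the time-normalization target for patients.

## Pattern similarity: GM and BDSI

The Gait Metric rewards EMG activity where the normative pattern is
active and penalizes it where the normative pattern is silent. The
closed form used here is

* magnitude M = A_in / (A_in + A_out), the fraction of the patient's
  envelope area falling inside the normative "on" region (M := 0 when
  the envelope is identically zero);
* timing T = fraction of the grid where the patient's mask equals the
  normative mask (rewarding both co-activation and co-silence);
* GM = (M + T)/2.

The composition is configurable (`mean`, `product`, `geometric`) because
the historical definition defers to an external reference; the arithmetic
mean is the default as the only choice that keeps a silent-but-correct
half-credit structure and a [0, 1] range compatible with published
normative values. GM is invariant to amplitude scaling of the patient
envelope by construction.

BDSI is the percentage of the cycle in the same binary state:
(Σ ON_timing + Σ OFF_timing)/N × 100, where ON_timing marks joint
activation and OFF_timing joint silence. The implementation is verified
against a direct-counting oracle exhaustively over all mask pairs on
small grids. Muscle-couple values (proximal RF–ST, distal TA–SOL,
agonist RF–SOL, antagonist ST–TA) pool the two muscles by unweighted
mean, the only symmetric choice absent a stated weighting.

## Intermuscular coherence

For each couple the pipeline takes, per step, the earliest 200 ms span
that lies inside the couple's gait-phase window with *both* activation
masks on throughout, and extracts it from the **high-pass-filtered,
rectified** signal — not the 4 Hz envelope, which would annihilate the
beta and gamma bands. Rectification before coherence follows the
standard intermuscular-coherence methodology (it demodulates common
amplitude modulation to the drive frequency). Steps without a qualifying
span are skipped; fewer than `min_steps = 5` qualifying steps raises
`NoCommonSlot` (below 5 epochs the confidence limit exceeds 0.53 and the
estimate is vacuous) — mirroring participants excluded from coherence
analysis in practice.

Default phase windows, heel-strike anchored: 10–30% (initial mid-stance)
for TA–SOL; 85–110% (terminal swing wrapping through loading response)
for RF–ST. The RF–ST window extends past heel strike because a 200 ms
epoch cannot fit inside 15% of a ~1.1 s cycle; terminal-swing antagonist
co-activation physiologically continues into weight acceptance. Both
windows are configurable.

The estimator is the multi-trial (one disjoint segment per step) scheme:
per-segment mean removal, a Hann taper, cross- and auto-spectra averaged
over the L segments, coherence = |S_xy|²/(S_xx·S_yy), 5 Hz resolution.
Significance uses the independence limit 1 − 0.05^(1/(L−1)), exceeded by
a single bin with probability 0.05 under independence — the estimator is
calibrated against this limit in the test suite (empirical exceedance
0.05 ± 0.02). To compare T0 and T1 within a subject, both inputs are
truncated to the smaller epoch count so the confidence limits coincide.

**The 30 Hz bin.** At 5 Hz resolution the 30 Hz bin is the upper edge of
beta (15–30 Hz) and the lower edge of gamma (30–45 Hz). Band *areas*
integrate the full closed interval, so the bin contributes to both
areas. Band *significance*, however, excludes bins shared by two bands
(configurable via `boundary = "include"`): a band-level claim should not
hinge on a bin that belongs equally to its neighbour, and restricting
each band to its unambiguous bins (two for alpha, three for beta and
gamma) keeps the per-band family-wise false-alarm rate near
1 − 0.95³ ≈ 0.14 rather than 0.19.

## The synthetic generator

Each simulated channel is

> burst envelope × broadband carrier × (1 + common modulation) + noise

* **Burst envelopes** are plateau bursts with raised-cosine (Tukey)
  edges (taper fraction 0.25) rendered from per-muscle templates in the
  heel-strike frame, plus a tonic floor. Plateaus (rather than pure
  raised cosines) make the 40% mask essentially coincide with the
  declared window, which is what guarantees ≥ 200 ms co-activation slots.
  Windows may wrap past heel strike (`end > 100`), rendered continuously
  across the cycle boundary.
* **Default templates** (percent of cycle): TA 60→112 (swing through
  loading), SOL 10–50 (monophasic, the segmentation anchor), RF 55–70
  and 82→115, ST 85→110. These place TA–SOL co-activation in early
  stance and RF–ST co-activation around heel strike, the two slots the
  coherence analysis exploits.
* **Carrier**: Gaussian white noise band-passed 20–450 Hz at
  fs = 1000 Hz, so energy survives the 20 Hz high-pass in all three
  coherence bands.
* **Common drive** is injected as shared amplitude modulation: one
  narrow-band unit-variance noise process per couple and limb multiplies
  both muscles' carriers inside the drive's phase window, with
  modulation index = coupling/2 (clipped at zero; at coupling 0.8 the
  clipping probability is < 1%, keeping harmonic leakage into
  neighbouring bands negligible). Additive injection would not work:
  rectification moves an additive narrow-band component to DC and twice
  its frequency, whereas common amplitude modulation — the physiological
  picture of a shared oscillatory drive modulating motor-unit activity —
  surfaces in rectified EMG at the drive frequency itself.
* **Jitter**: per-step duration multiplier lognormal(0, σ), keeping
  durations positive; σ = 0.05 by default (~5% step-to-step
  variability, typical of steady treadmill-free walking).
* **Defaults**: 20 steps of 1.1 s at 1 kHz, additive noise SD 5% of the
  burst peak, stance = 60% of the cycle for the footswitch.
* **Stroke-like perturbations** (`stroke_perturbation()`): `TONIC_ST`
  raises the ST tonic floor toward 1 (the post-stroke hamstring that
  stays contracted through stance and swing), `SHIFTED_TIMING` rotates
  burst windows by up to 25% of the cycle, `REDUCED_MODULATION`
  compresses the floor-to-peak range of every muscle. Severity 0 is the
  identity everywhere. Severities are free parameters, not calibrated to
  any cohort.

What the generator does *not* emulate: motor-unit potentials and their
interference statistics, electrode artifacts, crosstalk between
channels, kinematics, and any quantitative feature of real patients'
EMG. Passing parameter-recovery tests on this generator therefore shows
the pipeline is *internally correct* (it recovers what was injected
under its own assumptions), not that it is robust to everything real
recordings contain.

## Capacity Score

Six scales enter: 5-item Barthel Index (0–55), Motricity Index (0–100),
10 m walk speed (m/s), 6 min walk distance (m), Functional Ambulation
Category (0–5), Trunk Control Test (0–100). Healthy references are the
scale maxima for the four bounded scales and literature values for the
walk tests (1.40 m/s, 500 m — registry defaults, overridable). MDCs:
7.84, 12.92, 0.11 m/s, 60.98 m, and 1 (the minimum score step) for FAC
and TCT. The default aggregation is RATIO_TO_HEALTHY — each scale
contributes value/reference, equally weighted, so the healthy reference
scores exactly 6 — with an alternative MDC_UNITS mode (value/MDC, capped
at reference/MDC) for expressing capacity in detectable steps. The exact
aggregation used with any particular published cohort is not derivable
from summary tables, which is why both modes are explicit and neither
claims to reproduce published composite medians. T1−T0 changes carry a
per-scale flag for |Δ| ≥ MDC.

## Cohort statistics

`wilcoxon_paired()` drops zero differences (Wilcoxon's rule; Pratt
exposed), is exact via the signed-rank distribution for ≤ 25 untied
pairs, exact by sign-flip enumeration for ≤ 20 pairs with tied ranks,
and falls back to a tie-corrected normal approximation with continuity
correction. `chi_squared_proportions()` is the Pearson 2×2 test without
continuity correction by default (exposed), and
`improvement_proportion()` is the percentage of improved subjects.
Coherence-based improvement is classified per band: alpha improves by
gaining significance, beta/gamma by losing it.

## Problem sizes used in the validation suite

The test suite and acceptance script validate on deliberately small
instances chosen to estimate each property tightly: cohorts of 5–7
healthy subjects at 14 steps for normative profiles; 26-step walks
truncated to L = 20 epochs for coherence power (100 seeds per drive
configuration, 200 for the null false-positive rate, whose target bound
sits close to the family-wise exceedance of three 5%-level bins); 100
seeds of 10–30 steps for segmentation recovery; 200 replicates for the
confidence-limit calibration; exhaustive mask-pair enumeration up to
N = 7 plus sampled pairs and identity/complement sweeps to N = 12 for
BDSI.

## Known limitations

* GM's exact historical formula (and its phase-shift computation) lives
  in an external reference; the closed form here satisfies the
  documented reward/penalty structure but published per-muscle values
  are not expected to be numerically reproduced.
* The TA–SOL couple has no qualifying co-activation slot under the
  *default healthy* templates (TA is silent through most of stance), so
  TA–SOL coherence on default synthetic data raises `NoCommonSlot` —
  as it did for some real participants; supply templates with an
  extended TA burst to study that couple synthetically.
* Tied-rank Wilcoxon beyond 20 pairs uses the normal approximation.
* The TSV dialect is the only on-disk format; no vendor binary formats.
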