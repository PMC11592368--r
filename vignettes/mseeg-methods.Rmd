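---
title: "EEG complexity with multiscale entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG complexity with multiscale entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mseeg` quantifies the temporal complexity of multichannel EEG with
multiscale entropy (MSE) and carries that quantity through a complete group
analysis: preprocessing, per-electrode entropy curves, spectral band power as
the traditional comparison measure, behavioral scoring and grouping for
metacontrol/creativity designs, aggregation over scalp functional networks,
and a split-plot inferential battery. Because studies of this kind rarely
ship raw subject data, the package also contains a first-class synthetic
cohort generator whose statistical structure matches what the analysis
assumes, so every stage is testable end to end. This vignette documents the
model, the conventions, and the design decisions — including the ones that
were genuinely open.

## Multiscale entropy

**Coarse-graining.** For a series $x_1,\dots,x_N$ and scale $\tau$, the
coarse-grained series is the mean of consecutive non-overlapping windows,

$$y_j^{(\tau)} = \frac{1}{\tau} \sum_{i=(j-1)\tau+1}^{j\tau} x_i,
\qquad 1 \le j \le \lfloor N/\tau \rfloor,$$

with trailing samples that do not fill a window discarded. At $\tau = 1$ the
coarse series equals the original — an identity the tests assert exactly.

**Sample entropy.** SampEn$(m, r)$ is $-\ln(A/B)$ where $B$ counts pairs of
$m$-point templates within Chebyshev distance $r$ of each other (self-matches
excluded, tolerance tested with $\le$), and $A$ counts the pairs still within
$r$ at the next point. The production kernel is a compiled $O(N^2 m)$ pair
counter; a brute-force oracle that materializes the full distance matrices
must agree with it count for count, which the suite checks on hundreds of
random series. When $A$ or $B$ is zero the statistic is undefined and
propagates as missing — it is never imputed.

**Conventions.** Defaults are $m = 2$ and $r = 0.2\,\mathrm{SD}$, the common
choices for EEG sample entropy; both are configurable via `mse_params()`. The
absolute tolerance is computed once from the SD of the original (scale-1)
series and held fixed across scales. This is the convention that makes the
canonical benchmark behavior visible: white-noise MSE declines monotonically
with scale (coarse-graining averages away independent variance while $r$
stays put), while $1/f$ noise stays approximately flat and exceeds white
noise at coarse scales. Both behaviors, plus the i.i.d. Gaussian closed form
$-\ln(2\Phi(r/\sigma\sqrt 2) - 1) \approx 2.19$ at $r = 0.2\sigma$, are
acceptance-tested. The scale grid defaults to $1..20$; coarse series shorter
than `min_coarse_length` (default 50) are flagged invalid rather than
estimated. Short stimulus-locked epochs are analyzed per epoch and the curves
averaged (2.5 s epochs cannot meaningfully be concatenated at $\tau = 20$);
the long divergent-thinking epochs are analyzed singly.

## Preprocessing

Continuous recordings are re-referenced to the averaged mastoids (TP9/TP10
by default), band-pass filtered 0.1–40 Hz, notch filtered at 50 Hz, epoched
around stimulus markers and baseline corrected on the 500 ms pre-stimulus
interval. The band-pass is a 4th-order Butterworth applied
forward–backward (zero phase); the notch is a biquad with quality factor 30.
Epochs follow a half-open sample convention, $[\mathrm{start},
\mathrm{end})$ in milliseconds, so a $(-500, 2000)$ window at 1000 Hz holds
exactly 2500 samples — stated explicitly so sample counts are testable.
Markers whose window exceeds the record are dropped with a counted warning.
Independent-component artifact removal is deliberately not implemented: the
synthetic data is artifact-free, and the preprocessing surface accepts
externally cleaned data. Supported on-disk format is the BrainVision triplet
(`.vhdr/.vmrk/.eeg`, float32, multiplexed) via a minimal reader/writer.

## Spectral band power

The comparison analysis integrates the one-sided rectangular-window FFT
periodogram over five bands — δ (2–4), θ (4–8), α (8–13), β (13–30),
γ~low~ (30–40 Hz). *Total power is defined as the sum of the five band
powers*, so relative powers form a simplex (sum to 1 exactly); whether
out-of-band energy should enter the denominator is not decidable from the
analysis description this package follows, and the simplex definition is the
one that makes the invariant testable. Bin assignment is half-open on the
left with only the final band's upper edge closed, so shared edges are
counted exactly once. The nominal analysis segment is the first 10 s after
the stimulus; epochs shorter than that (the 2.5 s metacontrol epochs) fall
back to the full post-stimulus span with a logged deviation warning.

## Behavioral scoring

The performance ratio is accuracy divided by mean correct-trial reaction
time, and the adaptive (metacontrol) score is the easy-minus-difficult
difference of ratios. The RT unit entering the ratio is a configurable
constant (`rt_scale`); with RT in seconds and `rt_scale = 10` the ratio reads
as accuracy per 100 ms, which places cohort means in the conventional
0.1–0.2 range. Only the ordering matters for the median split, but the unit
is exposed because the absolute score scale is meaningless without it.

Median splits assign subjects strictly above/below the median; exact ties
alternate starting with "low", a deterministic rule that preserves the
balanced split. Rater consistency of originality scores uses ICC(2,k), the
two-way random-effects reliability of a k-rater mean,
$(MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)$, with raters treated as a random
sample (the rater variance component stays in the denominator). Incomplete
rating designs are rejected, never imputed.

## Functional networks

Electrodes are assigned to eight canonical systems (DMN, DAN, FPN, VAN, VN,
SMN, LN, SN) by maximum probability from an electrode-by-network table;
exact ties break alphabetically and are logged. The bundled table
(`network_map_synthetic.tsv`) is a **synthetic topographic approximation**
built from the usual scalp correspondence of those systems — it is package
data for testing and demonstration, and real analyses should supply a
published projection via `network_probability_map(path =)`. The network
summary statistic is the per-electrode sum of SampEn over scales 10–15
averaged across the network's electrodes; sum-then-average equals
average-then-sum by linearity, and the choice is recorded here because either
reading is defensible. Missing (invalid/undefined) scale values are excluded
pairwise with counts reported.

## Statistics

The omnibus test is the orthodox subject-nested split-plot ANOVA: group as
the between-subjects factor, electrode and time scale as within-subject
factors, each within effect tested against its own subject-by-effect error
stratum (`aov` with `Error(subject/(electrode*scale))`). Published analyses
of this design sometimes report observation-level error degrees of freedom in
the tens of thousands; that corresponds to ignoring the subject stratum, and
the package deliberately implements the subject-nested partition instead.
Sphericity is assessed per within effect with Mauchly's test on the pooled
covariance of the orthonormal-contrast projection; the Greenhouse–Geisser
$\varepsilon = \mathrm{tr}(S)^2 / (d\,\mathrm{tr}(S^2))$ deflates the degrees
of freedom whenever Mauchly rejects at 0.05 — or whenever the covariance is
rank-deficient (fewer error df than contrast dimensions, the usual case with
dozens of electrode-by-scale cells), where sphericity cannot be tested and
the correction is applied conservatively. Partial $\eta^2$ is
$SS_\mathrm{eff}/(SS_\mathrm{eff} + SS_\mathrm{err})$ within the stratum.

Post-hoc families keep their own corrections: Bonferroni for pairwise cell
contrasts, a fixed two-tailed $\alpha = 0.01$ for the per-electrode-by-scale
unpaired t-map, and Benjamini–Hochberg for the electrode family of Pearson
correlations between behavioral scores and coarse-scale entropy. All tests
are two-sided by default. Degenerate cells follow documented conventions
(zero variance with equal means gives $p = 1$; with unequal means, $p = 0$
flagged degenerate).

## The synthetic cohort

`cohort_spec()`/`gen_cohort()` emulate the study conditions the analysis
assumes: 58 subjects in two latent profiles, a 64-channel 10–20 montage at
1000 Hz, 2.5 s metacontrol epochs and one 20.5 s divergent-thinking epoch,
trial-level behavior, and a 4-rater originality panel.

* **EEG model.** Each channel is an amplitude mixture
  $(1-w)\cdot\text{white} + w\cdot\text{pink}$ of unit-variance noises; the
  pink weight $w$ is the latent complexity dial. Defaults: high profile
  $w \sim N(0.75, 0.05)$, low profile $N(0.60, 0.05)$. The 0.15 gap at a
  0.05 between-subject SD makes the latent separation unambiguous (three
  subject SDs) while SampEn estimation noise on single epochs keeps observed
  network-level effects in the large-but-realistic range; the per-subject SD
  encodes that complexity is a stable individual trait with real dispersion.
  Pink noise is produced by FFT spectral shaping ($1/\sqrt f$ amplitude), so
  its $1/f$ power law is exact by construction and checkable by periodogram
  regression.
* **Behavior.** Per-subject target performance ratios are normal around
  0.176 (easy) and 0.138 (difficult) with the profile gap (default 0.046)
  injected on the easy task only — the difficult task is profile-blind, so
  the group difference appears where the design expects it. Accuracies are
  truncated-normal in $(0, 1]$ (0.92/0.88, SD 0.04); trial RTs are lognormal
  (CV ≈ 0.2) around the subject's implied mean. Nothing in the published
  record constrains single-trial distributions, so these are conventions
  chosen for positivity and realistic skew, not empirical claims.
* **Ratings.** Item truth = subject mean (2.86 ± half a 0.24 profile gap,
  subject SD 0.10, item SD 0.50) plus rater bias (SD 0.10) plus residual
  noise, then rounded to the 1–5 Likert grid. The residual variance is solved
  analytically from the target ICC(2,k) (default 0.844) with a $1/12$
  allowance for rounding, so the rounded scores recover the target within
  the tested ±0.05.
* **Seeding.** One master seed spawns a named table of 31-bit sub-seeds (one
  per stage and per subject/task), so any component can be regenerated in
  isolation and the whole cohort is byte-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: no event-related potential morphology, no
ocular/muscle artifacts, no volume conduction or spatial correlation between
channels (channels are independent realizations), no topographic structure
in the complexity effect (the injected gap is spatially uniform), and no
trial-order or learning effects.

## The filter–tolerance interaction, and how the calibration runs handle it

One empirical property of the mixture model matters for interpretation.
Because the match tolerance is fixed at $0.2\,\mathrm{SD}$ of the analyzed
series, band-pass filtering changes what SampEn sees: the pink component
concentrates variance below 2 Hz, which survives the 0.1–40 Hz filter and
inflates the SD — raising $r$ relative to mid-band fluctuations and almost
exactly cancelling the mixture contrast at every scale. On *unfiltered*
epochs the generator shows its designed signature: a small reversed
difference at fine scales (pink noise is more regular than white at scale 1)
and a clear positive high-complexity advantage from medium scales upward.
The statistical calibration checks (type-I rate of the t-map on null
cohorts; recovery of the injected gap at 29+29) therefore epoch the
synthetic EEG without the filtering stage — synthetic data carries no drift,
line noise, or artifacts for the filter to remove — while real-data runs
keep the full preprocessing chain. This is a documented divergence between
the synthetic model and real EEG, where broadband and band-limited
complexity cannot be separated this cleanly.

## Problem sizes and numerical choices

Test and acceptance runs use scaled designs chosen as the package's own
validation sizes: noise benchmarks at $N = 2\times10^4$ with 20 replicate
series; type-I calibration on 100 null cohorts of 10+10 subjects, 8
electrodes (one per network) and 4 scales; effect recovery on 50 cohorts at
the full 29+29 with four 2.5 s epochs per subject (per-epoch MSE averaged, a
scaled-down stand-in for the study's multi-trial design) and scales 1–15;
behavioral
and rater calibrations at the full 58. Greenhouse–Geisser corrections are
applied automatically whenever sphericity is rejected or untestable; filter
probes measure attenuation on interior samples to avoid forward–backward
edge transients; the BrainVision container stores float32, so round-trips
are exact to single precision.

## Known limitations

Assignment of scalp electrodes to cortical systems is topographic by
construction and inherits EEG's limited spatial resolution; the bundled map
is synthetic (see above). The ANOVA requires balanced complete designs — no
Type-III fallback for unbalanced data. No refined or composite multiscale
entropy variants are provided, and no cluster-based permutation correction;
the battery mirrors a classical ANOVA + t-map + correlation workflow.
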