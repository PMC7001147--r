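---
title: "Methods: envelope-shaped neurostimulation and the multiperiodic analysis of speech reception thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-shaped neurostimulation and the multiperiodic analysis of speech reception thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtacs)
```

# The scientific problem

Cortical activity tracks the slow (< ~15 Hz) amplitude envelope of speech at
latencies of roughly 100 ms and 250 ms. Transcranial alternating current
stimulation (tACS) shaped as the speech envelope can modulate how well a
listener understands speech in babble noise, and two parameters of that
stimulation matter: the *latency* of the current relative to the audio, and
its *phase*. Because natural speech envelopes are broadband, a phase shift is
not a time shift: the two can be varied independently, which is the core
experimental idea this package supports.

The observable is the sentence reception threshold (SRT): the
signal-to-noise ratio, in dB, at which a listener repeats half the key words
of a sentence correctly. The pipeline covers four stages:

1. **Stimulation construction** — from a speech (or synthetic) envelope to a
   safe, phase- and latency-shifted current.
2. **Adaptive psychophysics** — a closed-loop up-down staircase estimating
   the SRT against a (here: simulated) listener.
3. **Circular statistics** — Moore-Rayleigh tests of SRT versus stimulation
   phase at the periods resolvable on the phase grid.
4. **Multiperiodic modelling** — a discrete-cosine decomposition of the
   phase profile with LASSO/LARS selection, covariance-test inference, and a
   linear-response criterion separating linear from nonlinear modulation.

A synthetic-data generator with known ground truth stands in for the human
cohort, so every stage is testable end to end.

# Stimulation waveforms

## Phase shifting through the analytic signal

An envelope $y(t)$ is complexified as $z(t) = y(t) + i\,H[y(t)]$ with $H$
the Hilbert transform; a phase shift by $\varphi$ is
$y_\varphi(t) = \mathrm{Re}\,[e^{i\varphi} z(t)]$. Every spectral component
is rotated by the same angle while its magnitude is preserved, and
$\varphi = 180^\circ$ is exactly the negated envelope.

Two numerical choices matter here:

* **The mean is removed before the rotation.** Rotating a nonnegative
  envelope would mix its large DC offset into the shifted signal and
  $180^\circ$ would no longer be an inversion; `phase_shift_envelope()`
  therefore operates on the zero-mean envelope. This is the only reading
  consistent with inversion at $180^\circ$.
* **The transform is the plain circular FFT operator, without padding.**
  With the unpadded operator the algebraic identities hold to machine
  precision at every sample: shifting by $\varphi_1$ then $\varphi_2$ equals
  shifting by $\varphi_1 + \varphi_2$; $360^\circ$ is the identity; the
  magnitude spectrum is bit-preserved (band-limited signals have an empty
  Nyquist bin, the one bin the real-part projection can attenuate).
  Reflect-padding would buy slightly cleaner edges at the cost of breaking
  those identities at the $10^{-3}$ level; we keep padding where it belongs,
  namely around the Hilbert *magnitude* inside `extract_envelope()`, whose
  output is not subject to algebraic identities but to ringing.

## Envelope extraction and conditioning

`extract_envelope()` takes the magnitude of the analytic signal and applies
a linear-phase Hamming-windowed FIR low-pass (cut-off 12 Hz by default, the
upper edge of syllabic modulation), with an even order of about
$6 \cdot \mathrm{rate}/\mathrm{cutoff}$ so the group delay is an integer
number of samples and can be compensated exactly. At audio rates the filter
transition band is a few hundredths of a Hz; at the low rates used for
synthetic work it is several Hz, which the tests account for.

`condition_current()` enforces the safety conventions of envelope tACS:
mean subtraction (the current alternates around zero), half-sine onset and
offset ramps (default 250 ms) so the current starts and ends at exactly
0 mA, and rescaling so the peak magnitude equals the device limit
`max_abs_mA`. The taper is one unresolved ambiguity of the protocol — a
"sine centred at zero" admits several readings — and the half-sine ramp of
configurable length is our choice; its exact shape does not enter any
statistic downstream. The sham control is a 500 ms tapered burst of the
conditioned envelope (100 ms ramps) followed by silence; the burst's exact
shape is likewise a choice, since only its brevity matters (it mimics the
skin sensation of stimulation onset without sustained current). The
16-condition battery (`stim_conditions()`) is sham, DC anodal, DC cathodal,
an unrelated-sentence envelope, and six phases
($0^\circ$–$300^\circ$ in $60^\circ$ steps) crossed with two latencies
(100, 250 ms).

## Stimulus characterization

`amplitude_spectrum()` is a Welch-style estimator (4 s Hann segments, 50 %
overlap, per-segment demeaning, amplitude not power — amplitudes are what
the stimulation hardware sees). `phase_time_correlation_map()` correlates
the envelope shifted by $\varphi$ against the envelope delayed by $\tau$.
Lags are applied **circularly**: for a sinusoid at frequency $f$ over an
integer number of periods the map is then *exactly*
$\cos(2\pi f \tau + \varphi)$ — the closed form that demonstrates the
phase/lag equivalence for periodic signals — while for a long aperiodic
envelope the wrap-around bias is $O(\mathrm{lag}/\mathrm{duration})$
(≲ 1 % at the grids used here). Trimming the lag-induced gap instead would
leave $O(1/\#\mathrm{periods})$ partial-period errors that drown the
closed form.

`autocorrelation()` reports the normalized circular autocorrelation with a
significance band for the claim that matters scientifically: *the envelope
carries no correlation beyond a short range* (i.e. no dominant
periodicity, in particular none at the 500 ms period of the 2 Hz spectral
peak). Phase-randomized surrogates — the standard tool for the correlation
map — are provably useless for this statistic, because phase randomization
preserves the periodogram and hence the circular autocorrelation of every
surrogate equals the data's exactly. The band is instead built from
Gaussian-process surrogates whose autocovariance equals the sample
autocovariance tapered to zero beyond `null_span_ms` (default 100 ms,
fading to zero by twice that): the null keeps the short-range structure,
destroys everything beyond it, and the band is the $(1-\alpha)$ quantile of
the surrogates' maximum $|r|$ over the tested lags.

# Adaptive psychophysics

The staircase follows the standard speech-audiometry protocol: initial SNR
10 dB; a sentence passes when at least half of its five key words are
correct; a pass lowers the SNR, a fail raises it; steps are 3 dB up to and
including the fourth reversal and 1 dB from the fifth on; about 25
sentences per condition; the SRT is the mean presented SNR of the last 10
sentences. Two protocol ambiguities and our readings:

* The literature name for this family is the *weighted* up-down method, in
  which asymmetric steps target arbitrary percent points; the protocol as
  described is symmetric (equal up/down steps, 50 % target), and that is
  what `run_staircase()` implements. The symmetric rule converges to the
  SNR where the sentence pass probability is $1/2$; for a five-keyword
  binomial listener that is exactly the per-keyword 50 % point, which the
  tests verify against a brute-force root-find.
* "The last 10 sentence presentations" is read as the plain last 10 trials,
  not the last 10 reversals.

The virtual listener (`psychometric_listener()`) reports each key word
correctly with probability
$(1-\mathrm{lapse}) \cdot \mathrm{logistic}((\mathrm{snr} -
\mathrm{srt})/\mathrm{slope})$; `slope_db = 0` degenerates to a step
listener used for deterministic convergence checks. Over 1000 seeded
25-trial runs with a 1 dB slope the mean estimate stays within 0.5 dB of
the true threshold (the bound the test suite asserts).

# Circular statistics

With six equally spaced phases, variation is resolvable at exactly three
periods — $360^\circ$, $180^\circ$, $120^\circ$
(`representable_periods(6)`). A test at period $P$ folds the phases by
$\varphi \mapsto (360/P)\,\varphi \bmod 360$ and asks whether the folded
weighted vectors concentrate.

The **Moore-Rayleigh test** replaces each observation's weight by its rank
(mid-ranks on ties) and uses
$R^* = \bigl|\sum_j r_j e^{i\theta_j}\bigr| / n^{3/2}$. Weights are SRTs
with the minimal overall SRT subtracted, pooled over subjects and phases —
one weighted vector per (subject, phase). P-values are Monte Carlo rather
than interpolated from Moore's asymptotic tables: the default null redraws
the angles uniformly on the circle with the ranks fixed (Moore's original
null, and the only one under which a degenerate all-same-angle
configuration is correctly flagged as maximally concentrated); a
permutation null (ranks shuffled against observed angles) is available as
an option for strictly conditional inference on grid designs. The add-one
correction keeps the test valid at any `n_mc`. Under the uniform null the
empirical level at $n = 102$ is within $[0.04, 0.06]$ at $\alpha = 0.05$
(checked over 2000 replicates with $10^4$ draws each).

The **latency-difference test** forms, per subject and phase, the SRT
difference between the long and short latency, shifts by the minimum, and
runs the Moore-Rayleigh machinery at the three periods with
Benjamini-Hochberg adjustment across them. Multiplicity corrections are
`stats::p.adjust` (BH within the three periods; the
Benjamini-Hochberg-Yekutieli variant for the fifteen paired
against-sham comparisons, valid under arbitrary dependence). The Rayleigh
test for best-phase uniformity uses the standard finite-sample corrected
p-value, which is well calibrated at the cohort size of 17.

# The multiperiodic model

## DCT decomposition

On the six-phase grid the SRT profile decomposes as

$$\mathrm{SRT}(\varphi) = A_0 + A_1\cos(\varphi - \psi_1) +
A_2\cos(2\varphi - \psi_2) + A_3\cos(3\varphi - \psi_3),$$

a real (cosine) reparametrization of the discrete Fourier transform of six
points. Orthogonality on the grid gives
$\sum_j \cos^2(k\varphi_j) = 3$ for $k = 1, 2$ but $= 6$ for $k = 3$, so
the alias-limit coefficient is $c_3 = \tfrac16 \sum_j y_j \cos 3\varphi_j$
with $A_3 = |c_3|$ — and since $\sin(3\varphi_j) \equiv 0$ on the grid,
$\psi_3$ is only identified up to sign and is restricted to
$\{0^\circ, 180^\circ\}$. With these conventions `dct_fit()` followed by
`reconstruct()` is the identity at the six phases to machine precision, and
the sample variance satisfies the Parseval split
$(A_1^2 + A_2^2)/2 + A_3^2$ (both are asserted property-style in the
tests). Extrema of a fitted curve are located by $1^\circ$ grid search,
matching the whole-degree reporting convention of the field.

## LASSO/LARS selection and post-selection inference

`lasso_select()` stacks all subjects' observations at one latency and
regresses them on the five-column trigonometric design
$\{\cos\varphi, \sin\varphi, \cos 2\varphi, \sin 2\varphi, \cos
3\varphi\}$ ($\sin 3\varphi$ is identically zero and excluded). Reading
"the amplitudes subjected to LASSO" as a LASSO on this basis — rather than
on three precomputed per-subject amplitudes — keeps the model linear,
preserves the phase offsets, and lets the penalty act on the cosine/sine
pairs that constitute each amplitude; it is the reading under which
cross-validation over stacked raw observations is well defined. Subject
intercepts are unpenalized and projected out (within-subject centering),
which both reflects the paired design and keeps the error variance
estimate honest when every condition shares a subject's sham reference.
The LARS path is computed from the closed-form piecewise-linear solution
(with the lasso drop modification, and rank guards for the aligned
five-phase design where the trigonometric columns are collinear with the
intercepts); the package's path agrees with `glmnet` at matched penalties
to $10^{-14}$, and `glmnet` serves as an independent cross-check in the
test suite, never as the implementation. The penalty is chosen by 10-fold
cross-validation with folds stratified by subject, so no subject leaks
across folds.

Each variable's entry along the path is scored with the covariance-test
statistic
$T_k = \bigl(\langle y, X\beta(\lambda_{k+1})\rangle - \langle y,
X_{A}\tilde\beta_{A}(\lambda_{k+1})\rangle\bigr)/\hat\sigma^2$. For its
null distribution the package defaults to a finite-sample Monte-Carlo
calibration rather than the asymptotic exponential: under a simulated
global null on the same design, the statistic of the $r$-th entry is
tabulated, and an observed entry at step $k$ is compared against rank
$r = k - s$, where $s$ counts earlier entries already declared
significant. The discounting reflects the renewal behaviour of the path:
after $s$ strong signals the remaining path restarts as a smaller null
problem, so the first noise entry is compared against a *first*-entry
null — the property that makes the classical Exp(1) reference sound — while
under the global null every entry is compared against its own rank and the
per-step p-values are uniform by construction. An amplitude's p-value is
the smaller of its cosine/sine pair's entry p-values with a Šidák
correction for the pair size. The combination is calibrated: under a
global null each amplitude is falsely declared significant at close to the
nominal 5 %, and under a strong pure-$A_1$ truth the false-significance
of the higher harmonics stays near nominal as well. The classical
Exp(1)-everywhere reference (conservative at later steps) remains
available as `null = "exp1"`. The error variance comes from the full
least-squares fit with subject intercepts, rank-aware degrees of freedom,
and a relative floor of $10^{-12}$ so that noise-free synthetic profiles
do not divide by zero.

The reported fit ("only the significant terms") is a least-squares refit
on the columns of the significant amplitudes, from which amplitudes,
offsets and extrema are taken.

## Linear response and the nonlinearity criterion

If the threshold depends linearly on the stimulation current, it is a
linear functional of the phase-shifted envelope,
$\mathrm{SRT}(\varphi) = \int \chi(t - t')\, y_\varphi(t')\, dt'$ with a
susceptibility kernel $\chi$. Since
$y_\varphi = \cos\varphi \cdot y_0 - \sin\varphi \cdot H[y_0]$, *any* such
functional is exactly $A_1 \cos(\varphi - \psi_1)$: a pure
$360^\circ$ sinusoid. Higher harmonics ($A_2$, $A_3$) are therefore a
signature of nonlinearity, and `classify_linearity()` maps a selection
result to `nonlinear` (any of $A_2, A_3$ significant), `linear` (only
$A_1$), or `no_modulation`. `linear_response_srt()` implements the
discrete functional, and `gen_linear_listener()` wraps a random kernel
into a ground truth whose phase curve is sinusoidal by construction — the
package's own falsification device: over seeded batteries of random
kernels the fitted $A_2/A_1$ and $A_3/A_1$ stay below $10^{-9}$.

## Best-phase alignment

`best_phase_align()` finds each subject's best (lowest-SRT) phase, tests
the best phases for uniformity (Rayleigh), relabels phases so the best
phase is $0^\circ$, drops the $0^\circ$ observation — it is minimal by
construction, and keeping it would bias any subsequent fit — and reruns the
selection on the remaining five points per subject. On that grid the six
trigonometric functions are linearly dependent given the intercepts, which
is why the selection machinery is rank-aware throughout.

# The synthetic-data generator

`gen_speech_like_envelope()` draws random-phase Gaussian processes on a
fixed smooth spectral profile (a sum of raised-cosine bumps, support
limited to 12 Hz) designed for three statistical targets of natural
speech envelopes: a broadband 1–12 Hz amplitude spectrum, a spectral peak
near the ~2 Hz word/phrase rhythm, and autocorrelation that is
indistinguishable from zero beyond ±150 ms (speech is aperiodic: the 2 Hz
peak must not induce a 500 ms correlation). The last two targets pull in
opposite directions — a prominent narrow peak necessarily rings in the
autocorrelation — and the shipped profile is a smooth compromise computed
once by constrained optimization and frozen as a design constant: its
implied autocorrelation stays below 0.07 beyond 150 ms while the 2 Hz bin
exceeds every bin outside 1.5–2.5 Hz by 20 %. Because draws differ only in
their spectral phases, every realization has exactly the designed
spectrum. The series is shifted by its minimum to nonnegativity, which
alters only the DC component.

What the generator does *not* emulate: the spiky, bursty marginal
distribution of real syllable envelopes (ours is shifted Gaussian), any
dependence of intelligibility on envelope content, session or order
effects, and listener lapses under fatigue. Passing tests therefore
demonstrate that the *pipeline* recovers what it assumes, not that real
cortices behave this way.

`gen_dataset()` produces the 16-condition SRT table: subject baseline
offsets $\sim N(0, \mathrm{subject\_sd}^2)$ around a −6 dB babble-scale
baseline (cosmetic — it cancels under sham normalization), the programmed
multiperiodic phase effect per latency, a +2 dB penalty for the
unrelated-envelope condition and no DC effect (the two control findings
the analysis should reproduce), and either direct Gaussian residuals
(default SD 0.5 dB, a typical test-retest spread for adaptive SRTs) or a
full closed-loop staircase per record. Default truth amplitudes
(1.0/0.8/0.4 dB at 100 ms with offsets 26°/90°/0°; 1.0/0.8/0.6 dB at
250 ms with 346°/120°/180°) are generator choices loosely scaled to
plausible modulation depths of a couple of dB — no published amplitude
estimates exist to copy. Each (subject, condition) record draws from its
own seed-derived stream, so enlarging the cohort never perturbs existing
records.

# Analysis pipeline and problem sizes

`analyze()` runs the full plan on any 16-condition dataset: per-subject
sham normalization (sham becomes exactly 0 dB), Moore-Rayleigh tests per
latency and period with BH adjustment, the latency-difference test, the
DCT + LASSO fit with linearity classification and extrema per latency,
best-phase alignment with its Rayleigh test and aligned refit, and the
fifteen BHY-adjusted paired comparisons against sham. The report is a pure
function of `(data, config)` and serializes to JSON.

The test suite exercises the pipeline at the study's own scale — 17
subjects, 6 phases, 2 latencies — with Monte-Carlo suite sizes chosen to
keep the whole run in the tens of minutes on one core: 500 replicates for
recovery and false-selection calibration (Monte-Carlo SE ≈ 1 % on a 5 %
rate), 2000 replicates at $10^4$ draws for the circular-test levels, 1000
staircase runs for bias, 100 random kernels for the linear-response
battery, and 60 s envelopes at 100 Hz for stimulus characterization.

# Known limitations

* The Moore-Rayleigh null is a choice (uniform angles vs. permutation);
  on grid designs the uniform null is only approximately the conditional
  null, mirroring standard practice with Moore's tables.
* Covariance-test calibration relies on a simulated global-null table per
  design; with weak (neither clearly null nor clearly strong) signals the
  rank discounting is intermediate and mildly conservative.
* The aligned five-phase refit is rank-deficient by construction; the
  sparse path resolves it, but individual aligned amplitudes are not
  separately identifiable in a full model.
* Envelope operators are circular; edge-sensitive use at very short
  durations should evaluate interior samples.
* No mixed-effects or Bayesian alternatives are offered; the pipeline
  deliberately reproduces the original analysis plan.
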