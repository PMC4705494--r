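---
title: "Predicting the orthostatic blood-pressure drop from short-term HRV: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the orthostatic blood-pressure drop from short-term HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hrvdrop)
```

## The problem

Standing up pools blood in the lower body; if the autonomic nervous system
does not compensate quickly, arterial pressure falls. A large enough systolic
drop (standing hypotension) causes dizziness and is a leading mechanism of
indoor falls in older adults. Because the autonomic state *before* standing is
readable from heart rate variability (HRV) — the beat-to-beat fluctuation of
RR intervals — the drop should be predictable from a short ECG recorded while
the subject is still lying down.

`hrvdrop` implements that idea end to end: it extracts a standard battery of
22 HRV measures from the 5 minutes of RR intervals preceding the stand, and
fits the linear model

$$\Delta BP = c_0 + c_1 f'_1 + \dots + c_n f'_n + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_\varepsilon^2)$$

where $f'$ is a subset of at most five HRV measures, selected by exhaustive
search under leave-one-subject-out (LOSO) cross-validation, and the fit is a
robust (Tukey bisquare) regression. The outcome is
$\Delta BP = BP_7 - \overline{BP_{2:5}}$: the systolic reading in the second
minute after standing minus the mean of the four lying readings (negative =
drop). Its measurement error, propagated from the cuff's nominal
$NE = 3$ mmHg through one standing reading and a 4-reading mean, is
$NE + NE/\sqrt{n} = 4.5$ mmHg; predictions inside that band are
indistinguishable from a perfect prediction.

## The measurement protocol the synthetic cohort emulates

Real per-subject recordings for this design are not publicly deposited, so
the package ships a first-class generator. Per subject it produces the
three-phase session: one sitting baseline (2-min RR, 1 BP reading), then
`n_reps` (default 4) repetitions of lying (5-min RR, 4 BP readings) and
standing (5-min RR, 4 BP readings). At the reference scale of 10 subjects and
4 repetitions this yields 9 instances, 33 BP readings and 42 minutes of RR
per subject, and a 40-row predictive dataset — the arithmetic the acceptance
suite checks.

RR series follow a two-tone sinusoid plus white noise,

$$RR_i = \mu + a_{LF}\sin(2\pi f_{LF} t_i) + a_{HF}\sin(2\pi f_{HF} t_i)
  + \sigma_{RR} w_i,$$

with the modulation evaluated at the cumulative beat time $t_i$ (irregular
sampling, the way real autonomic modulation acts). This is the simplest
process with independently controllable mean rate, LF/HF spectral balance and
SDNN; it is *not* a baroreflex simulation. Defaults (mean RR 750–950 ms,
amplitudes 10–20 ms, noise 5–12 ms, systolic baseline 105–135 mmHg, cuff
noise 3 mmHg) were chosen once for plausibility, with one coherence
constraint: artefact-free synthetic series should mostly stay below the 5%
artefact-filter deviation, otherwise the pipeline would "correct" clean beats
wholesale. At these defaults the filter touches about 2% of beats.

The standing systolic readings are generated as
`mean(lying BPs) + delta + N(0, sigma_bp)` where
`delta = c0 + sum(c_j * f_j(lying RR)) + N(0, eps_sd)` is computed from the
subject's *actual* artefact-corrected lying-phase features. The realised
drops are stored in a ground-truth sidecar, so parameter recovery can be
asserted exactly: with `eps_sd = sigma_bp = 0` the full pipeline returns the
planted coefficients to machine precision. Seeds are split per
(subject, phase, repetition) with a deterministic counter, so enlarging a
cohort never reshuffles existing subjects. The generator reproduces the
protocol's schedule and a truly linear HRV–drop link; it does not reproduce
nonstationarity, ectopy, respiration–heart-rate coupling or any nonlinear
dependence of the drop on autonomic state — so green tests certify the
machinery, not physiological realism.

## Artefact filter

Beat $i$ is flagged when its RR deviates from the median of its 5 nearest
unflagged neighbours by more than 5% (one left-to-right pass); flagged beats
are replaced by a cubic spline through the unflagged beats and the beat times
rebuilt. Two details are deliberate:

* Interpolation runs over the **beat index**, not the beat time: a spurious
  2000 ms interval shifts every later beat time, so the time axis is itself
  corrupted by the artefact the filter is removing; the index is the only
  ordinate left intact. On smooth trends the two agree to well under 1 ms.
* `preprocess_rr()` iterates detection and correction to a fixpoint. A cubic
  spline can overshoot and regenerate a value the median detector keeps
  rejecting; beats still flagged after two spline passes are therefore
  snapped to the detector's own local-median reference, which guarantees
  termination and makes re-running the filter a no-op (a property the test
  suite asserts).

Flagging more than 5% of beats raises a warning (this filter is meant for
sparse artefacts); more than 20% is an error. The threshold is read as a
per-beat relative deviation, and the 5% ceiling as the filter's intended
operating range — both interpretations of the "5%" are honoured.

## The 22 measures

Time domain: MeanRR, STDNN (sample SD), RMSSD, NN50, pNN50 (denominator
$N-1$, the number of successive pairs — the dominant guideline convention).
Geometric: HRVtri ($N$ / modal bin height, bin width 1/128 s) and TINN, the
base width of the least-squares triangular fit to the RR histogram, found by
exhaustive search over integer bin-edge pairs with ties broken towards the
smallest width. Frequency domain: the tachogram is mean-centred,
cubic-spline resampled at 4 Hz and fitted with a Burg autoregressive model of
order 16; LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) powers are trapezoid
integrals of the one-sided AR spectrum, in ms²; LF/HF is reported missing
when HF is zero, never infinite. Poincaré: SD1 $= SDSD/\sqrt2$,
SD2 $=\sqrt{2\,STDNN^2 - SD1^2}$ (both identities are asserted to $10^{-9}$
in the tests). Entropies: ApEn (self-matches included) and SampEn
(self-matches excluded), $m = 2$, $r = 0.2\,STDNN$, Chebyshev distance.
Correlation dimension D2: Grassberger–Procaccia with embedding dimension 10,
delay 1; the scaling region is selected deterministically as the radii where
$C(r) \in [0.01, 0.3]$ — enough pairs below the saturation shoulder — and D2
is the log–log slope there (missing when no such region exists). DFA:
$\alpha_1$ over boxes 4–16, $\alpha_2$ over 16–64, linear detrend per
non-overlapping box. Note that $\alpha_1$ measured this way on white noise is
$\approx 0.59$, not exactly 0.5 — the well-known small-box detrending bias —
which is why the reference-exponent tests allow $\pm 0.1$. RQA: embedding
dimension 10, delay 1, radius $\sqrt{m}\,STDNN$, Euclidean distance, minimum
diagonal line 2; REC excludes the main diagonal, DET is the fraction of
recurrent points on diagonals of length $\ge 2$, and the Shannon entropy of
the line-length distribution uses natural logs.

All of these parameters live in `feature_config()` and are overridable; the
defaults follow the conventions of the standard HRV analysis software in this
field. A measure that cannot be computed (series too short, degenerate
histogram, no scaling region) is reported as `NA` with a reason, never as a
silent zero; the subset search then excludes that feature from the candidate
pool with a message.

## Robust fit and model selection

`fit_robust()` is iteratively reweighted least squares with the Tukey
bisquare weight $(1-u^2)^2$ for $|u|<1$, $u = r_i^{adj}/(4.685\,s)$.
Residuals are leverage-adjusted ($r/\sqrt{1-h_i}$) and the scale $s$ is the
median of the largest $n-p+1$ absolute adjusted residuals divided by 0.6745.
The iteration starts at ordinary least squares and stops when the largest
coefficient change falls below $10^{-8}$ or after 50 iterations (both
configurable). On zero-residual data the scale collapses and the OLS solution
is returned unchanged, which is what makes the noiseless recovery tests
exact. The compiled fitter is pinned against an R-native reimplementation to
$10^{-8}$ and against an independent M-estimator within a few percent (the
two use different scale estimators, so exact agreement is not expected).

`exhaustive_search()` scores every subset of size 1–5 (35,442 subsets for 22
candidates) by LOSO cross-validation: one fold per subject, the model refitted
without that subject, and $\sigma_{est} = \sqrt{\sum(Y-Y')^2/(N-2)}$ computed
on the held-out instances with the fold's own $N$ (guarded as
$\max(N-2,1)$ for folds of $\le 2$ instances); the unweighted mean across
folds is the subset's score. A pooled-residual variant is available
(`mode = "pooled"`), since either reading of "average error across folds" is
defensible; per-fold is the default. Ties are broken towards the smaller
subset, then lexicographic feature order, so results are independent of
evaluation order (the search is also compared against a brute-force
re-enumeration on a reduced problem). The winner is refitted on all
instances. The inner loop is compiled (RcppArmadillo): scoring 35,442 subsets
over 10 folds takes roughly half a minute, which is what makes the seeded
replication suites practical.

Evaluation mirrors the protocol's conventions: %CP is the percentage of
predictions with absolute error *strictly* below the 4.5 mmHg drop
measurement error (an error exactly at the threshold counts as incorrect);
false negatives are predictions more than 5 mmHg below the measured drop
(missed severity, the clinically dangerous direction) and false positives
more than 5 mmHg above. The 4.5 and 5 mmHg constants are kept distinct and
configurable on purpose. %CP, FP/FN and the residual histogram (symmetric
2 mmHg bins centred on 0, nearest-centre assignment) are computed from the
final whole-dataset model, matching how such reports are usually produced
after refitting on all subjects; LOSO out-of-fold predictions are retained on
the fit object for honest generalisation checks.

## Validation design and problem sizes

The test suite works at three levels. Hand-computable examples pin each
operation (e.g. RMSSD of a 4-interval series, the −5 mmHg drop example, the
4.5 mmHg error bound). Property suites assert invariants across seeds:
Poincaré identities, scale invariance, oracle equivalence of
ApEn/SampEn/RQA against dumb double-loop counters on 50 random series of
length ≤ 200, DFA reference exponents, permutation invariance of the robust
fit. Study-scale suites run the full pipeline: protocol arithmetic at
10 × 4, exact noiseless recovery, a 200-replicate unbiasedness check of the
robust fit under 3 mmHg Gaussian noise on a fixed realistic design, and a
20-seed planted-subset experiment (10 subjects × 4 repetitions, planted
model `MeanRR` 0.1 and `LF` −0.15 with 0.5 mmHg model noise and no cuff
noise) requiring the planted features inside the winning subset in at least
90% of seeds. The planted effects are deliberately strong relative to the
noise: the experiment certifies the search machinery, not marginal
detectability. With only ten subjects the generator's handful of latent
parameters make the 22 measures heavily collinear, so at higher noise
definitionally correlated measures (the LF/HF ratio for LF) legitimately
substitute and the notion of "the" correct subset dissolves; for the same
reason the planted set avoids measure pairs that are near-duplicates by
construction (RMSSD vs SD1).

## Known limitations

Subset selection and error estimation share the same LOSO loop, so the
reported test error is optimistically biased after selection (no nested CV —
deliberately out of scope). The generator's linear HRV–drop link makes
recovery testable but says nothing about real physiological predictability.
Diastolic drops are computed and stored but not modelled by default; a
diastolic planted model can be supplied. The symptom score is stored, never
modelled. The 35,442-subset search is exhaustive, not greedy — with far more
candidate features it would need pruning.
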