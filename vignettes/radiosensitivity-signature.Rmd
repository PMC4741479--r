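---
title: "Deriving a radiosensitivity miRNA signature: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a radiosensitivity miRNA signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomir)
```

## The problem

Tumor response to radiotherapy varies widely, and microRNAs regulated
through the ATM kinase arm of the DNA damage response are candidate
biomarkers for that variation. The workflow this package implements has
two halves. In vitro, a dual-channel miRNA microarray compares
ATM-proficient and ATM-deficient lymphoblastoid cells before and after a
6 Gy dose, yielding per-miRNA fold changes; miRNAs whose change exceeds a
two-standard-deviation band are screen hits. Clinically, those hits are
checked against a three-arm patient cohort — irradiated patients with a
complete response (radiosensitive), irradiated patients with tumor
progression (radioresistant), and untreated patients — and a miRNA whose
expression moves in opposite directions in responders and progressors, in
the direction the in vitro screen predicts, joins the signature. An ATM
protein (RPPA) comparison between the response groups accompanies the
signature.

Because the raw array sheets and the clinical cohort behind the original
screen are not redistributable, the package pairs every analysis stage
with a synthetic generator that produces inputs of the same shape with
known ground truth. All claims the test suite makes about recovery are
claims about those generators, not about any particular clinical dataset.

## Array model and normalization

Each gene is spotted in triplicate; `aggregate_replicates()` summarizes
the spots by arithmetic mean and *sample* SD (n − 1 denominator — the
triplicates are a sample of spot-level variation; the SD is 0 for a
single spot). Detection is mechanical: a gene is detected when its mean
exceeds `max(detection_floor, background)`, where the background is the
mean of the negative-control means (`qc_negative_controls()`). The floor
defaults to 0 a.u. so that, absent controls, only identically-zero signal
is undetected; the background term is what generates the `0/0` rows seen
in screen tables.

Normalization is the positive-control ratio: a gene's value is its mean
intensity over the mean of the housekeeping-control means, computed per
array. No cross-array normalization is applied, because the fold change —
the ratio of normalized values, IR over mock — already cancels any global
per-array scale. Both fluorescence channels are stored and one is
analysed (`channel`, default F635); the assay dye is read at either
635 nm or 532 nm and nothing downstream depends on which is chosen as
long as it is consistent.

The fold-change SD is first-order (delta-method) propagation of the
replicate SDs, `sd_fc = fc * sqrt((sd_t/mean_t)^2 + (sd_c/mean_c)^2)`.
Replicate-level fold-change SDs (pairing spots across arrays) would be an
equally defensible reading of a "± SD" column; propagation was chosen
because it needs no spot pairing across arrays and is exact in the
small-noise limit. This is a genuine free choice and is the package's
default interpretation.

## Threshold analysis

The screen's detection behavior is summarized per condition by a
threshold on fluorescence. Genes whose fold-change test returned zero are
failures; the admissible thresholds under the rule "success iff X > θ"
form exactly the interval

> (max fluorescence among failures, min fluorescence among successes)

which `estimate_threshold()` reports at full input precision, flagging
separation when the interval is non-empty. The data determine θ only up
to this interval; `apply_threshold()` needs one operative value and uses
the midpoint — symmetric, deterministic, and strictly inside the interval
so both training classes are reproduced. The motivating observation that
a logistic regression on these data has a perfect predictor is treated as
motivation only; no logistic model is fitted. With boundary values tied
(a failure and a success at the same fluorescence) the interval is empty
and classification is refused rather than broken arbitrarily.

## Hit calling

"± 2 standard deviations" is formalized on the linear fold-change scale:
up when `fc − 1 ≥ k·sd` and `fc > 1`, down when `1 − fc ≥ k·sd` and
`fc < 1`, with `k = sd_multiplier = 2`. Ties with the band edge count as
significant (the rule is ≥, not >). Rows with `fc = 0` **and** `sd = 0`
are undetected and excluded from the up/down tally — a zero there denotes
absent signal, not measured repression; their `effect` is reported as
`NA` for the same reason. A row with `fc = 0` but `sd > 0` is *not*
undetected and falls to the down branch. A zero SD with a nonzero effect
is significant: any effect exceeds a zero-width noise band.

Applied to the packaged 28-miRNA screen table, this rule yields, for the
ATM-deficient line, 9 up / 5 down / 7 undetected / 7 unchanged
(14 altered). Published summaries of comparable screens quote different
tallies (16 altered, 12 up, 4 down) that we could not reproduce under any
simple reading of the stated rule, including alternative zero-handling;
the package therefore reports its own deterministic counts, frozen as a
byte-level regression fixture in the test suite, rather than tuning the
rule toward a printed summary. An alternative formalization — a single
population SD across all miRNAs' fold changes — was rejected because it
yields far fewer hits on the same table.

## Cohort concordance

`group_ratios()` computes, per miRNA, the arithmetic group means and the
responder and progressor ratios to the untreated mean; a pseudocount
(default 0.5, a conventional half-count offset for normalized-count
data) is added to numerator and denominator means so ratios stay defined
at zero expression, and it vanishes smoothly: as `pseudo → 0` with
positive data the ratios converge to the plain mean ratios.

The responder–progressor contrast uses a two-sided Welch t-test on
`log2(x + pseudo)` by default. The t-test family is fixed by the method;
within it, Welch was preferred over the pooled-variance form for
robustness on skewed expression (an `var_equal` switch restores the
classical test), and the log scale because expression noise is
multiplicative. Only responder vs progressor is tested — that is the
contrast the signature definition needs — while both ratios versus
untreated are always reported.

`concordance_screen()` assigns directions from the log2 ratio with a
dead band `epsilon` (default 0.25, ≈ 1.19-fold — not part of the original
method; it suppresses flat-direction noise and is exposed in the
configuration) and requires three clauses at once: opposite non-flat
directions in the two irradiated groups, responder direction equal to the
in vitro reference direction, and `p ≤ alpha` (default 0.05, raw p-values
— no multiple-testing correction by default, mirroring screens of this
type; Bonferroni and BH are available). The in vitro reference is a
parameter because the two genotypes' fold changes disagree in direction
for some signature members: it can be a genotype (directions then come
from that genotype's hit calls) or an explicit direction table. The
packaged table (`signature_directions()`) encodes the established
five-miRNA pattern — miR-016, miR-029b, miR-150, miR-1254 up and let-7e
down in responders; miRNAs absent from an explicit table have no
reference direction and can never be concordant, which confines the
signature search to the table's members.

## Sample-size formula

`sample_size()` implements the correlation-based formula
`n = z_sum_sq / atanh(r)^2 + 3`, where `atanh(r) = ½ ln((1+r)/(1−r))` is
the Fisher z-transform. The printed form this is taken from is
typographically garbled — it reads `n=(8.52{12(ln[1+R(y,x)])−ln[1−R(y,x)])}2)+3`
— and is interpreted as the Fisher-z expression because `8.52 ≈ 2.92²`
matches a `(z_α + z_β)²` constant and the `+3` matches the standard
correlation sample-size formula; the underlying α and β are not stated
and remain free through `z_sum_sq`. Rounding defaults to `ceil`
(conservative for a sample size); with `rounding = "nearest"`,
`r = 0.80` gives `n = 10`, consistent with the validation cohort's groups
of 10 patients — a consistency note, not a claim that `r = 0.80` was the
design value.

## Synthetic generators

`simulate_array()` emulates the four-condition experiment (two cell
lines × mock/6 Gy): true gene abundance is lognormal
(`baseline_log_mean = log(800)`, `baseline_log_sd = 0.6` — bright,
plausibly dispersed probes), spot noise is multiplicative lognormal with
unit mean and CV `spot_cv = 0.08` (tight triplicates, as hybridization
replicates on one array are), positive controls sit at 1500 a.u. and
negative controls at 40 a.u., and irradiation multiplies chosen miRNAs by
a planted effect per genotype (0 encodes irradiation-induced dropout).
`simulate_cohort()` emulates the three-arm cohort: per-miRNA lognormal
baselines (`baseline_log2_mean = 8`, `baseline_log2_sd = 2`, a
normalized-count scale), patient-level lognormal noise with
`noise_cv = 0.3` (typical biological CV for miRNA abundance between
patients), multiplicative planted group effects, and a Gaussian RPPA-style
ATM level (baseline 0, progressor shift +0.5, noise SD 0.2 — RPPA scores
are normalized and may be negative, hence Gaussian rather than
lognormal). `n_per_group` defaults to 10, the validation cohort's group
size. `signature_pattern_config()` plants the five-miRNA pattern at
two-fold effects with the inverse pattern in progressors and null effects
for the other 23 screen miRNAs.

Both generators return the ground truth as a first-class table, so tests
never re-derive it from a configuration, and both run under a local RNG
stream: the same seed gives byte-identical output and the caller's
`.Random.seed` is untouched.

What the generators do *not* model: batch or array-position effects, dye
bias between channels, count-based (miRNA-Seq) sampling noise,
missing-data mechanisms beyond dropout, and correlation between miRNAs.
A recovery result on these generators therefore shows the pipeline's
statistical machinery is sound under its stated noise model — it does not
show the signature would survive the messier covariance structure of real
cohorts.

## Numerical choices and degenerate inputs

* Tables are serialized at full double precision (`%.17g`), so
  write/read round trips are bit-identical; this is load-bearing for the
  byte-stable regression fixture.
* `fold_change()` refuses asymmetric gene universes by name rather than
  intersecting silently.
* Zero-variance groups in a t-test (a degenerate but constructible case)
  return p = 1 when the means agree and p = 0 otherwise instead of
  erroring.
* Single-class threshold data (no failures, or no successes) is an
  error — "threshold undefined" — and the pipeline records an
  `NA` interval row for such conditions rather than aborting the screen.
* Pipeline outputs are staged in a temporary directory and renamed into
  place, so a failed run leaves no partial output tree.

## Problem sizes in the test suite

The suite exercises the threshold oracle on 1000 random small instances,
signature recovery on 100 seeds at the default cohort size, the null
false-positive bound on 200 seeds, ATM-shift power on 100 seeds, and
Welch parity on 100 random samples; these sizes give stable pass/fail
behavior at the 95%-of-seeds recovery bar while keeping the whole suite
under half a minute.

## Known limitations

* The concordance screen takes group structure as given; it does not
  model follow-up time, censoring, or treatment covariates.
* With an explicit direction table the signature can only ever contain
  the table's members; discovering new signature members requires the
  genotype-derived reference.
* The fold-change SD interpretation (propagation vs replicate-level) is
  a free choice; tables produced under the other convention will carry
  somewhat different SDs and hence different borderline hit calls.
* The two-SD rule has no error-rate calibration — it is a screening
  heuristic, and the package deliberately applies no multiple-testing
  correction to it.
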