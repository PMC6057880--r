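---
title: "PDX trial analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PDX trial analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxtrial)
```

`pdxtrial` implements the analysis chain of a 1x1x1 patient-derived
xenograft (PDX) drug trial: one treated and one vehicle mouse per
patient model, caliper follow-up for 18 days, and downstream molecular
profiling of the cohort. This vignette explains the statistical models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where the methodology left room.

## Response scoring

Tumor volume is the standard two-diameter ellipsoid approximation,

$$V = \frac{\text{shorter}^2 \times \text{longer}}{2} \quad [\text{mm}^3],$$

and a model's response is the treated-over-control score

$$T/C\,(\%) = 100\,\frac{T_i - T_0}{C_i - C_0},$$

where subscript $0$ is the volume at treatment start and $i$ at the end
of treatment. Because the score compares growth *increments* between
matched arms, it credits a drug for holding a fast-growing tumor still —
a case a RECIST-style size criterion would file under stable disease.
Models are classified as **progression** when $T/C > 50$,
**suppression** when $0 \le T/C \le 50$ (both boundaries belong to
suppression), and **regression** when $T/C < 0$. The three classes
partition the real line; `classify_response()` is exact at the
boundaries and `response_summary()` reports integer percentages rounded
half away from zero (8/13/10 of 31 models read 26/42/32%).

Three conventions needed fixing where thrice-weekly calipers make the
endpoints ambiguous:

* $T_0$/$C_0$ is the measurement whose day is closest to day 0, ties
  resolved toward the earlier day;
* $T_i$/$C_i$ is each arm's own last measurement at or before the
  horizon (default 18 days) — no extrapolation when arms end on
  different days;
* a vehicle tumor that fails to grow ($C_i - C_0 \le 0$) makes the
  ratio's sign meaningless, so the model is flagged invalid and dropped
  from the waterfall with a warning rather than scored.

Growth speed (`growth_speed()`) is the secant slope of the volume curve
over the observation window, the simplest reading of "average growth
speed"; an OLS regression slope is available behind a flag but is not
the default. Group summaries report mean ± SEM per arm and
`compare_group_speeds()` runs a two-sided Student's t-test (equal
variances, matching the field's convention) on per-model speeds.

## Doubling-time survival

Progression-free survival is anchored on tumor doubling: the event is
the first *measured* day on which volume reaches at least twice the
treatment-start baseline; curves that never double by the horizon are
censored there. The criterion referenced by the trial design is not
spelled out anywhere we could follow, so this definition — measured day,
not an interpolated crossing; baseline as in the T/C computation — is
this package's documented choice, made for consistency with
thrice-weekly sampling (an interpolated crossing would manufacture
precision the calipers do not have).

`km_fit()` and `logrank_test()` wrap `survival::survfit()` and
`survival::survdiff()`; ties between events and censoring at the same
day follow the standard convention that events precede censoring. The
test suite checks both against independent brute-force implementations
(an explicit product-limit walk over all small record multisets, and a
hand-coded observed-minus-expected log-rank with hypergeometric
variance), and checks that log-rank p-values are uniform under label
permutation.

One caution a user should know: the product-limit estimator is not
invariant to administrative censoring. Adding a record censored at the
horizon enlarges every earlier risk set, so $S(t)$ shifts (weakly
upward) even for $t$ before the horizon. The tests assert this true
behaviour — unchanged event times, risk sets grown by one, survival
weakly increased — rather than the tempting but false claim that early
survival is untouched.

## Graft/host read disambiguation

RNA-seq of xenografts carries mouse stroma. After alignment to a
combined human+mouse reference (the aligner itself is outside this
package), each read reduces to three flags: does it map to human, to
mouse, and is its primary alignment on the human reference. The verdict
rule is total on the six valid flag combinations: human-only reads are
kept, mouse-only reads dropped, and dual mappers kept exactly when the
primary alignment is human. The rule is deliberately conservative —
its purpose is to keep mouse reads out of the variant caller, where
they masquerade as subclonal human variants. `read_sam_assignments()`
adapts SAM text to the flag table using configurable reference-name
prefixes and the standard flag bits; multi-mapping within one species
collapses to a single flag because the rule only inspects species and
primacy.

## Variant calling and the retention cascade

`call_pileup()` is a threshold consensus caller in the VarScan dialect,
with defaults chosen for maximum sensitivity on a small gene panel
(min-coverage 2, min-reads2 2, min-var-freq 0.01, min-avg-qual 15, all
inclusive). Observations below the quality floor are excluded from
support but still count toward depth, so the VAF denominator is the
full column. Sensitivity is then repaired by specificity filters
downstream, not by the caller. Calling runs once per sample and once on
the pooled cohort; `merge_callsets()` unions the two on
(sample, chrom, pos, ref, alt), keeping the record with more supporting
reads on collision (ties keep the per-sample record).

The retention cascade (`filter_cascade()`) encodes the annotation-driven
specificity rules in a fixed order, and each record's verdict names the
first rule it fails:

1. drop non-exonic/non-splicing regions,
2. drop synonymous changes,
3. drop variants present in the non-flagged (germline) subset of dbSNP,
4. oncogene variants must sit at known COSMIC sites,
5. tumor-suppressor variants outside COSMIC must be absent from
   ESP6500 and 1000 Genomes (suppressors earn novel loss-of-function
   calls; oncogenes do not),
6. genes that are neither role are not reported,
7. surviving novel variants adjacent to homopolymer runs, or supported
   only at read ends, are artifacts.

The cascade is a pure per-record function — the tests shuffle record
order and require identical verdicts — and rule order is observable only
in the verdict labels, never in the retained set. One ambiguity was
resolved in favour of the literal rule order: a COSMIC hotspot that also
has a non-flagged dbSNP entry is discarded by rule 3 before the COSMIC
exception is consulted. `homopolymer_adjacent()` uses run length ≥ 5
within 1 bp of the variant, counting a variant inside the run as
adjacent (at least as suspect as one beside it). A manual-rescue
whitelist reproduces inspection-driven additions: whitelisted records
bypass the cascade but are always flagged low confidence, as are any
calls with ≤ 2 supporting reads; the oncoprint draws low-confidence
cells transparent.

## Expression normalization, binning and the DE substitute

`size_factors()` is the median-of-ratios estimator: each sample's factor
is the median, over genes expressed in every sample, of its count
divided by the gene's geometric mean across samples. Note a subtlety
the tests also respect: scaling one column by 2 shifts the
geometric-mean reference by $2^{1/J}$, so what is exactly true is that
the *relative* factor of the scaled column doubles and its normalized
profile stays proportional — not that other factors are untouched.
Unexpressed genes (zero total) are removed before normalization.

Efflux-pump expression (the ABCB1 resistance biomarker) is binned on
normalized counts: low 0–99, mid 100–1000 inclusive, high strictly
above 1000. The original analysis derived its display values from a
variance-stabilizing transform; here the bins are applied to
median-of-ratios normalized counts and documented as such — the
generator plants its high subgroup far above the 1000 boundary, so the
distinction does not affect any conclusion drawn from synthetic data.

`de_test()` deliberately does not re-implement a negative-binomial GLM.
It computes batch-adjusted log2 fold changes (per-gene, per-batch mean
centering of $\log_2(\text{normalized}+1)$, a removeBatchEffect-style
adjustment) and calibrates them with a permutation test of group labels
*stratified by batch*, so a group/batch confound can never masquerade as
signal; a batch wholly inside one group is rejected as untestable. When
the stratified label assignments number at most `n_perm` (default
10,000) they are enumerated exhaustively and p-values are exact;
otherwise assignments are sampled and the add-one estimate
$(1+\#\text{extreme})/(1+B)$ is used. Multiplicity is controlled with
Benjamini–Hochberg. This substitute is the right tool for the
structural question the package targets — is one gene dramatically high
in a subset of one response group — and is validated against exhaustive
enumeration, a planted 8-fold signal, and null uniformity; it is not a
general replacement for shrinkage-based NB inference at small fold
changes.

## The synthetic cohort generator

`gen_growth_cohort()` emulates the statistical structure of the
31-model trial, not its biology:

* **Growth model.** Exponential volume growth $V(t) = V_0 e^{g t}$ per
  mouse — the simplest model with a well-defined doubling time, matching
  the doubling-time survival framing. Model-level rates are log-normal
  (median 0.09/day, sdlog 0.3; vehicle doubling in roughly 5–14 days,
  typical of serially passaged melanoma xenografts), with 10% log-normal
  per-mouse jitter.
* **Inclusion and arms.** Three mice per model grow from seeded
  engraftment volumes (20–45 mm³) on a 2-day pre-treatment caliper
  grid; the first to enter the 50–100 mm³ window becomes the treated
  arm, the second the vehicle arm, the third is excluded. Ties go to
  the lower mouse index, making arm assignment deterministic.
* **Treatment effect.** A three-component mixture targeting the
  response classes. Components are parameterised by outcome: a target
  analytic T/C drawn uniformly on (70, 140) for progression and
  (15, 35) for suppression, and a treated end/start volume ratio on
  (0.25, 0.55) for regression. The treated growth rate is solved from
  the target given the drawn baseline volumes and vehicle rate, and the
  implied additive effect on $g$ is stored as ground truth. This
  parameterisation makes the intended class consistent with the
  noiseless curves *by construction* for every seed — the calibrated
  alternative (drawing effects on $g$ directly and tuning until classes
  recover) reproduces labels only for individually tuned seeds.
  Components are allocated by largest remainder, so the default weights
  10/31, 13/31, 8/31 produce exactly 10/13/8 models.
* **Measurement noise.** Multiplicative log-normal noise with 2% CV on
  each diameter (caliper repeatability; about 4.5% CV on volumes).
  Target ranges keep analytic scores several noise standard deviations
  away from the 0 and 50 boundaries, so classifying the noisy cohort
  recovers every intended label in better than 99% of seeds; the rare
  exception is a slow-growing vehicle whose small denominator lets one
  suppression model drift past 50.
* **Diameters.** Volumes invert to calipers at a fixed aspect ratio
  $r = 1.5$ via $s = (2V/r)^{1/3}$, $l = r\,s$; with zero noise the
  round trip is exact to floating point, which the tests assert at
  $10^{-9}$ mm³.

What the generator does *not* emulate — and what passing tests therefore
do not show about animal data: growth-rate changes over time
(Gompertzian deceleration, regrowth after response), measurement-day
irregularity, mouse dropout, within-tumor heterogeneity, or any
correlation between growth rate and treatment effect. Conclusions about
the pipeline's correctness transfer; conclusions about melanoma biology
do not.

The companion generators follow the same contract (deterministic given
a seed, ground truth sufficient to score the downstream stage):
`gen_reads()` emits species-labelled reads with ambiguous dual-mappers
whose primary lands on human with probability 1/2; `gen_variants()`
builds one record per cascade rule, each failing exactly that rule, plus
records for each retention path; `gen_counts()` draws negative-binomial
counts (dispersion 0.1) with log-normal sequencing depths (sd 0.25), a
gene-by-batch log-normal offset (sd 0.2), and a designated resistance
gene planted high in two progression samples and low elsewhere. The
planted means (6000 and 20 normalized reads) sit far enough from the
100/1000 bin boundaries that negative-binomial sampling noise crosses
them with probability below 1e-4, so the binned call set equals the
planted set by construction rather than merely in expectation.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 31 models,
$10^4$ simulated reads, 50-record variant fixtures, 2000-gene count
matrices, exhaustive Kaplan–Meier checks over all record multisets of
size ≤ 6 on a 3-point time grid, and 1000 label permutations for
log-rank uniformity — sizes chosen so every property is exercised at
full strength while the whole suite completes in a few minutes on a
laptop. Threshold comparisons in the caller are inclusive; percentages
round half away from zero; permutation p-values from sampling use the
add-one estimator so they are never zero; random draws inside the
package always flow through an internal seeded-RNG scope that restores
the caller's RNG state.

## Known limitations

* The doubling criterion and the exact endpoint-day conventions are
  documented substitutes for under-specified trial conventions; real
  datasets using different conventions will shift T/C values near class
  boundaries.
* The DE substitute has limited power for small fold changes and
  reports discrete p-values at small sample sizes; use it for
  structural screens, not for full transcriptome inference.
* The variant caller handles SNVs on pileup columns; indel realignment
  and left-normalization of complex alleles are out of scope.
* Expression bins are fixed at 100/1000 normalized reads and are only
  as comparable across datasets as the normalization feeding them.
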