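---
title: "Scoring and confirming hits in plate-based RNAi reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and confirming hits in plate-based RNAi reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

## The measurement model

A reporter screen measures one luminescence value per well. We model
the raw signal of well $w$ on plate $p$ in replicate screen $r$ as

$$y_{prw} = 2^{\,\mu_{pr} + \delta_{g(w)} + e(w) + \varepsilon_{prw}},
  \qquad \varepsilon \sim N(0, \sigma^2),$$

i.e. log-normal well noise around a plate- and replicate-specific
baseline $\mu_{pr}$, a reagent effect $\delta$ in log2 units, and an
optional positional edge term $e(w)$. Nothing in the analysis depends
on this model being exactly right — the scoring pipeline is built from
medians and MADs precisely so that heavy tails and a minority of large
true effects do not distort the scale — but it is the model the
synthetic generator draws from, and it motivates each step:

1. **log2 transform** makes the multiplicative biology additive.
2. **Per-plate normalization** to the median of designated reference
   wells removes $\mu_{pr}$: mock (transfection-reagent-only) wells
   for the reporter channel, nontargeting-siRNA wells for the
   viability channel. Reference wells have median normalized value
   exactly 0 on their plate by construction.
3. **Robust Z-scoring** divides the centred value by
   $1.4826 \cdot \mathrm{MAD}$ of the *library wells only*, per
   replicate screen. Controls are scored against that library
   distribution but never contribute to it, so a strong control
   cannot shrink the ruler it is measured with. Within each
   replicate, library-well Z then has median 0 and scaled MAD 1 to
   numerical precision (the test suite checks $<10^{-9}$).

### Scoring scope

Normalization is always per plate, but the Z-score location and scale
can be estimated per replicate screen (the default) or per plate
(`scope = "per_plate"`). Screen-wide scoring is the default because
hit thresholds and control anchors are quoted per screen, and because
per-plate MADs from a few hundred wells are noticeably noisier; the
per-plate option remains the right choice when plates differ
materially in spread. This default is an assumption, not something the
scoring convention forces — both scopes satisfy the same invariants on
their own scale.

### Why the control anchor is not effect/σ

A control with true effect $\delta = \pm 2$ log2 and well noise
$\sigma = 0.5$ does *not* score at $Z = \pm 4$: the per-plate
reference median is itself estimated from $n_{\mathrm{mock}}$ noisy
wells, adding variance $\approx \sigma^2 \pi / (2 n_{\mathrm{mock}})$
to every normalized value. The expected anchor is

$$E[Z_{\mathrm{ctrl}}] \approx
  \frac{\delta}{\sigma \sqrt{1 + \pi / (2 n_{\mathrm{mock}})}},$$

about $\pm 3.66$ at the defaults ($n_{\mathrm{mock}} = 8$). The
control-recovery tests assert this refined expectation within a
simulation tolerance of $\pm 0.4$.

## Hit rules

* **Fixed threshold**: inhibitor hit iff $Z_r > z_{\min}$ in *every*
  replicate; enhancer iff $Z_r < -z_{\min}$ in every replicate.
  Strict inequalities, matching the usual "$Z > 3$" phrasing; a gene
  with any missing replicate is flagged unevaluable rather than
  dropped. Raising $z_{\min}$ can only remove hits, and no gene can be
  both directions — both properties are tested on randomized tables.
* **Control-anchored**: inclusive comparisons ("at least as extreme as
  the control"), either on the mean Z across replicates or per
  replicate against that replicate's own summarized control score.
  Control wells replicated within a screen are summarized by their
  median Z (robustness; any summary could be configured). The
  per-replicate mode is our executable reading of requiring a gene to
  be at least as strong as the control in all screens; a rank-based
  "empirical probability" reading would be a different statistic and
  is deliberately not conflated with this one.

## Viability stratification

A reporter-down well can mean reduced reporter activity or dead cells.
Down-direction hits are therefore classed against the viability
counterscreen: `enhancer_candidate` when viability Z exceeds the
toxicity cut, `toxicity_confounded` otherwise, `unevaluable` when no
viability score exists. The cut defaults to $-2$ viability robust-Z
units. That number is an explicit assumption — qualitative
stratifications of this kind in the literature do not state one — and
it is a tunable argument; the classes always partition the input, and
lowering the cut can only grow the candidate set. Hit-set toxicity
enrichment against a neutral comparison set (genes with
$|\bar Z| < 0.5$, the conventional "scores around 0" band) uses the
two-sided Mann–Whitney test below.

## Confirmation rules

Fold induction is $F = 2^m$ relative to the mock median. "At least
twofold" is inclusive ($F \ge 2$) everywhere, taken literally. A pool
is confirmed on the arithmetic mean of its per-experiment folds
(geometric mean by flag — with 2–4 experiments per gene the choice
rarely matters, and published per-gene fold values do not state their
summary). In deconvolution, a single siRNA is *consistent* iff
$F \ge 2$ in every experiment in which it was measured, provided it
was measured in at least `min_experiments = 2`; with fewer it is
unevaluable and never counted, because "consistent" over one
observation is vacuous. A gene is confirmed when at least
`k_required = 2` of its (typically four) siRNAs are consistent.
Strict all-experiment consistency is used even for genes tested four
times; tolerating one sub-threshold replicate would be a different,
laxer rule and is not offered.

## qPCR quantification and concordance

Knockdown is $2^{-\Delta\Delta C_t}$ with replicate $C_t$ values
averaged *before* differencing (the simplest reading of the ΔΔCt
method; a per-replicate mode could be added but would change nothing
in the identities tested: treated = control gives exactly 1.0,
$\Delta\Delta C_t = 2$ gives exactly 0.25). Splice-variant abundance
uses $2^{-\Delta C_t}$ against a household gene within one sample, and
group comparisons use the classical two-sided Student's t-test
(pooled variance by default, Welch by flag; two identical constant
groups return $t = 0, p = 1$ by convention).

Knockdown–phenotype concordance classifies each siRNA: *effective*
iff residual expression $\le$ `kd_cut` (default 0.4, i.e. at least
60% knockdown); effective siRNAs are *concordant* iff fold induction
$\ge$ 2, else *discordant*; ineffective ones are *uninformative*. The
gene verdict is `insufficient_data` below `min_effective = 2`
effective siRNAs, `disqualified` when discordant ≥ concordant among
the effective ones (near-complete knockdown without the phenotype is
the signature of an off-target hit), else `qualified`. The published
narratives these rules formalize are qualitative; the defaults are
arguments, and the verdict is invariant to siRNA ordering.

## Rank and many-to-one tests

**Mann–Whitney.** $U_a$ counts pairs with $a_i > b_j$, ties counting
one half. Exact mode enumerates all $\binom{n_a+n_b}{n_a}$ splits of
the pooled multiset and computes the two-sided p as the fraction of
splits with $|U - n_a n_b/2|$ at least as large as observed — under
ties the permutation distribution need not be the classical one, and
this deviation form handles both cases uniformly (for tie-free data it
agrees with `wilcox.test`'s exact p, which the tests verify). Exact
enumeration is used automatically up to 10 per group; beyond that, the
normal approximation with tie-corrected variance and a continuity
correction of 1/2, which agrees with the exact p to better than 0.01
by $n = 15$.

**Subgroup shift scan.** Each subgroup's member scores are compared
against either all other scored genes ("genome" background) or the
rest of its parent set ("within_set", for nested questions such as
whether a mitosis-linked subset is further enriched within an
already-shifted pathway). p-values are Benjamini–Hochberg adjusted per
scan by default; the adjusted value never undercuts the raw one.
Scores enter as per-gene mean Z values, one observation per gene —
treating genes as the experimental unit is itself a modelling choice,
made explicit here because subgroup comparisons could also be built on
well-level replicates.

**Dunnett many-to-one.** Group-versus-control comparisons under the
pooled-variance one-way model, familywise-adjusted by the null
distribution of $\max_j |T_j|$. That null is evaluated by Monte Carlo
(default $10^5$ draws, deterministic given a seed): group and control
means as independent normals with variance $1/n_j$, the pooled
variance as $\chi^2_\nu/\nu$. Monte Carlo was chosen over the
equicorrelated multivariate-t quadrature because it is directly
verifiable by simulation; the trade-off is sampling noise of order
$\sqrt{p(1-p)/n_{\mathrm{mc}}}$ in each adjusted p. Two coherence
properties are enforced exactly: the adjusted p is clamped to be at
least the unadjusted two-sided t p, and it is monotone in $|t|$. With
$k = 1$ the adjusted p collapses to the ordinary two-sample t-test;
calibration at $k = 5$ holds the familywise error at
$0.05 \pm 2\,\mathrm{SE}$ over 1000 null simulations, and the
adjusted p agrees with `multcomp`'s multivariate-t computation to
within Monte-Carlo error.

## The synthetic screen generator

`sim_config()` defaults *are* the study conditions exercised
throughout the tests: 2000 library genes on 16×24 plates (controls in
the first two columns: 8 mock, 8 nontargeting, 4 + 4 positive
controls), 3 replicate screens, well noise $\sigma = 0.5$ log2, plate
offsets SD 0.3, positive controls at $\mp 2$ log2 (approximately
fourfold, the stated effect size of the canonical TP53/SYVN1
control pair), 1% true reporter-up hits at $+3$ log2, 0.5% true
reporter-down genes at $-3$ log2 of which half are
toxicity-confounded, and toxicity shifts of $-1.5 \pm 0.5$ log2 for
60% of true up-hits (silencing a p53 pathway inhibitor frequently
costs viability). Deconvolution data multiply the gene's pool effect
by per-siRNA attenuations $U(0.6, 1)$, with a 25% chance of a "dud"
duplex ($U(0, 0.25)$), reproducing 2-to-4-of-4 consistency patterns.
Identical configurations (including seed) give byte-identical tables,
and the generator restores the caller's RNG state.

What the generator does **not** emulate: spatial gradients beyond a
simple optional edge bump, transfection-efficiency variation,
signal-dependent (heteroscedastic) noise, cross-well contamination,
batch drift across replicates, and correlated off-target structure
among siRNAs. Passing recovery tests on this generator therefore
demonstrates that the scoring and calling rules are implemented
correctly and behave as designed under log-normal noise — not that
they are robust to every artifact of real plate data. The B-score /
median-polish family of spatial corrections is intentionally out of
scope.

## Numerical choices and degenerate inputs

* MAD scaling constant 1.4826 throughout (normal consistency).
* A constant scope (MAD = 0) is an error naming the scope, never a
  silent division — a noiseless simulated screen exercises this path.
* Missing measurements stay missing (`NA`), are excluded from every
  median/MAD, and flag genes unevaluable in all-replicate rules;
  nothing is imputed.
* Nonpositive raw signals are rejected at read time (log2 undefined).
* Threshold ties: strict for "Z > 3"-style rules, inclusive for
  "at least as" anchored and twofold rules — mirroring the wording
  each rule formalizes.
* All readers/writers round-trip exactly on valid CSV (comma default,
  tab by flag, UTF-8, stable column order); letter-form row indices
  ("A".."P") are normalized to integers on input.

## Problem sizes used in validation

The shipped test suite validates the robust-Z path against a
brute-force median/MAD oracle on 1000 random vectors (≤ 20 values, to
$10^{-12}$), exact Mann–Whitney against full enumeration on 500
random instances with group sizes ≤ 6 including ties, hit-recovery on
twenty 2000-gene triplicate screens (precision and recall ≥ 0.9 in ≥
90% of seeds; zero false positives expected, and bounded at the
binomial 99.9% envelope of a $10^{-4}$ rate, with the hit fraction set
to zero), Dunnett familywise error over 1000 null simulations at
$k = 5$, and the full pipeline end to end at 150 genes. These sizes
were chosen so the entire suite runs in well under a minute per
module while leaving each statistical check adequately powered.

## Known limitations

* No amplification-efficiency (Pfaffl) correction in the qPCR module;
  ΔΔCt assumes near-100% efficiency for both transcripts.
* No redundant-siRNA activity (RSA) or FDR-style hit calling; the
  implemented rules are the threshold and anchor rules they formalize.
* The subgroup scan tests location shift only; it will not flag a
  variance-only difference.
* Monte-Carlo Dunnett p-values below about $10/n_{\mathrm{mc}}$ are
  reported as small but are not precise; raise `n_mc` when exact tail
  values matter.
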