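---
title: "Quantifying mutational hotspot potency in replicated evolution experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutational hotspot potency in replicated evolution experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem

In replicated evolution experiments with *Pseudomonas fluorescens*, dozens of
independent lines are founded from a non-motile ancestor and scored daily for
the re-emergence of motility over a six-week (42-day) horizon. Each line that
evolves does so through one adaptive mutation, and the striking observation is
how *unevenly* those mutations are distributed: in the ancestral genomic
context, upwards of 95% of lines fix the very same transversion SNP — `A289C`
in the nitrogen-regulation gene *ntrB* — a mutational hotspot. Moving the
locus around the chromosome, flipping its strand, editing the local sequence,
or knocking out mismatch repair (MMR, via *mutS*) all reshape that spectrum.

`hotspotr` packages the statistics such an experiment needs:

1. **classification** of the mutations found in evolved lines (transition vs
   transversion vs indel);
2. **spectrum construction and comparison** across strain backgrounds
   (Pearson chi-square, asymptotic and Monte-Carlo);
3. the **transition-omission/enrichment test** against the combinatorial
   1/3 null, as a bootstrap resampler with its exact binomial oracle;
4. **rank-based time-to-emergence comparisons** (Kruskal–Wallis, Dunn
   pairwise, Wilcoxon rank-sum), implemented from the rank formulas;
5. a **synthetic experiment generator** under a first-arrival model, so the
   entire pipeline can be exercised, and parameter recovery verified, without
   any external data.

## Mutation labels and the 1/3 null

Labels follow the printed dialect of the motivating study: substitutions as
`<REF><POS><ALT>` with 1-based positions in the gene's coding sequence
(`A289C`), deletions as `Δ<start>–<end>` with any delta/dash typography
(`Δ410–421`, `del410-421`, `410-421` all parse identically). Unparseable
labels become an explicit `unknown` kind rather than an error, because
line-level tables in the wild contain entries like "unidentified". Positions
are only checked for positivity — the coding-sequence length is deliberately
not modelled, so no upper bound is enforced.

Each base has one transition partner (purine↔purine or
pyrimidine↔pyrimidine) and two transversion partners, so 4 of the 12 ordered
substitutions are transitions. Under equal fixation probability per mutation
type this gives the null `P(transition) = 1/3` — implemented as exactly 1/3,
not 0.33, since the combinatorial argument is exact:

```{r}
classify_mutation(c("A289C", "T326C", "Δ410–421"))
titv_exact(1, 21, p_transition = 1/3, tail = "lower")
```

The lower tail asks whether transitions are *under*-represented (as expected
where MMR is intact and a transversion hotspot dominates); the upper tail
asks for enrichment. The tail is an explicit argument because the two
hypotheses are scientifically distinct. The bootstrap version redraws the
classification of all `n_total` substitutions per resample and uses the
add-one estimator `(1 + #extreme)/(B + 1)`, which can never return 0; the
exact version is the binomial tail the resampler converges to, and the two
are cross-checked in the test suite over a grid of inputs. Indels and
unknown-kind mutations never enter `n_total`: the 1/3 null is a statement
about point substitutions.

## Spectra, potency and the categorization policy

A spectrum is a conditions × categories count matrix built from the evolved
lines under a `categorization_policy()`. The two levels — per-mutation
(`"gene:label"`) and per-gene — answer different questions (is the *same
change* recurring? is the *same target* recurring?), and both appear in
practice. Unidentified lines are kept as their own category by default
because they are a genuine slice of the spectrum (25% of the mutator lines
here); a flag drops them for analyses restricted to identified mutations.
Pooling of rare categories (`pool_below`) is off by default and conserves
totals when enabled.

```{r}
fx <- study_fixtures()
sp <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
sp
hotspot_fraction(sp, "AR2", "ntrB:A289C")$percent
hotspot_fraction(sp, "mutS", "ntrB:A289C")$percent
```

Hotspot potency is simply the hotspot category's share of a condition's
evolved lines, rendered to one decimal place (the convention spectrum shares
are reported in; evolved percentages use two).

`compare_spectra()` computes the Pearson statistic on the two conditions'
rows restricted to their jointly non-zero categories, with `df = k - 1`.
Because these tables are sparse almost by construction (20–35 lines spread
over up to ten categories), the asymptotic chi-square p-value is unreliable,
and the result flags `mc_recommended` whenever any expected count falls below
5. The Monte-Carlo p-value resamples tables with **both margins fixed**
(random reassignment of category labels to lines, Patefield's algorithm via
`r2dtable`), again with the add-one estimator. No continuity correction is
applied at either route.

```{r}
compare_spectra(sp, "AR2", "mutS", method = "both",
                n_resamples = 20000, seed = 1)
```

Two numerical notes, verified in the test suite. First, the Monte-Carlo
estimate converges to the *fixed-margin permutation* p-value (checked by
exhaustive enumeration on small 2×2 tables), which is the exact reference
here. Second, that permutation p-value differs from the asymptotic one by the
residual discreteness of the table even when all expected counts exceed 5
(about 0.01 at 100 lines), so perfect agreement between the two routes should
not be expected at any resample count — they estimate subtly different
reference distributions (conditional vs unconditional).

The published analysis this package generalizes did not state its exact
categorization (which categories, whether unidentified lines were included,
whether the p-values were simulated). The printed chi-square p-values are
therefore treated as a *significance pattern* to match under the documented
default policy (mutation level, no pooling, unidentified included), not as
digits to reproduce: ancestral vs mutator spectra differ at α = 0.01, the
two leading-strand variants do not differ at the locus level at α = 0.05.
The acceptance suite checks exactly that pattern.

## Time to emergence

Emergence days are compared with rank statistics implemented from the
formulas, with mid-ranks for ties and the standard tie corrections:

* Kruskal–Wallis: `H / (1 − Σ(t³−t)/(N³−N))`, p from chi-square with
  `k − 1` df;
* Dunn pairwise z on ranks pooled across *all* groups, with the pooled tie
  term `Σ(t³−t)/(12(N−1))`; antisymmetric in the pair, two-sided normal p.
  Multiple-comparison adjustment is a flag (`"none"` default, Bonferroni and
  Benjamini–Hochberg available): the motivating study reported unadjusted-looking
  Dunn p-values while describing values near 0.035 as nonsignificant, so the
  adjustment convention is ambiguous and is left to the user;
* Wilcoxon rank-sum for two conditions (the between-strain "Wilcoxon test"
  is the two-sample rank-sum, not the signed-rank); exact enumeration of all
  `choose(N, n_a)` assignments when `N ≤ 12` (ties handled exactly),
  tie-corrected normal approximation without continuity correction otherwise.

Censored lines — those that never evolve within the horizon — are excluded
from rank tests and summarized separately by `evolved_percentage()`:
day-of-emergence is undefined for them, and the per-line day plots the tests
mirror include evolved lines only. No survival-model machinery
(Kaplan–Meier, log-rank) is attempted; with censoring this light and
spectra as the primary endpoint, rank tests on the evolved subset match the
original analysis. All procedures are invariant under strictly monotone
transforms of the day scale, which the suite checks.

Numerical behaviour worth knowing: with six lines per group the rank-sum
normal approximation tracks the exact p-value to within 0.02 in the
significance region (exact p ≲ 0.1) but can deviate by up to ~0.07 around
p ≈ 0.5, purely because a 12-observation rank distribution is coarse. The
exact mode exists for precisely these sizes. At 15 lines per group the
nominal 0.05 level is attained to three decimals (exact rejection rate
0.0502), which is what the type-I-error simulation in the tests verifies.

## The synthetic generator

`simulate_experiment()` implements the smallest model with the right
observable structure: a first-arrival (origin–fixation) race. Each line draws
an exponential waiting time with rate `Λ = Σ r_j` over the competing targets'
effective supply rates, and the winning target is categorical with
probability `r_j / Λ`. Effective rates decompose as

```
r_j = base_rate_j × (m if j is the hotspot) × (c if MMR intact and j is a transition)
```

so the hotspot multiplier `m ≥ 1` and the MMR transition-retention factor
`c ∈ (0, 1]` are the two biological dials the experiment manipulates. Lines
whose waiting time plus a fixed detection lag (default 2 days, cosmetic: it
puts simulated days on the scale motility assays report) exceed the 42-day
horizon are censored. Closed forms used for verification:
`P(censored) = exp(−Λ(horizon − lag))` and hotspot share `r_h / Λ`.

What this emulates: independent replicate lines, one adaptive mutation each,
endpoint spectra, emergence days, censoring. What it does not: within-line
population dynamics, clonal interference, double mutants, day-resolution
scoring, or any mechanistic model of hairpin-mediated replisome stalling —
the hypothesized *mechanism* of the hotspot is outside the package's scope.
Passing tests on simulated data therefore validate the statistical pipeline,
not any mechanistic claim about real genomes.

`recover_hotspot_multiplier()` inverts the categorical law,
`m̂ = f/(1−f) · Σr_{−h}/r_h`, with a Clopper–Pearson interval on the observed
hotspot fraction pushed through that strictly increasing map; coverage is
inherited from the binomial interval and verified at ≥ 95% over 1000
seeded 21-line replicates in the acceptance suite. `f = 1` (every line hits
the hotspot, as a 21/21 experiment can easily produce) gives an infinite
point estimate and upper bound with a finite lower bound — the honest answer.

Scenario presets named after the strain backgrounds (`AR2`, `Lag`, `sm-Lag`,
`Lead`, `sm-Lead`, `mutS`) carry rate vectors calibrated so expected spectrum
shares match each background's reported endpoint spectrum, with total rates
set so expected evolved fractions at 42 days resemble the reported ones
(e.g. `Λ = 0.40`/day for the ancestor, where every line evolves, down to
`0.045` for the slowest background, where ~63% do). They are calibrated
illustrations for testing and teaching, not inferred mutation rates; the
`sm-Lag` preset in particular invents plausible target identities since only
its hotspot share (zero) is reported.

## Fixtures and reconstruction status

`study_fixtures()` ships the endpoint tables. Two are verbatim per-line
lists: the ancestral table (20× *ntrB* A289C, 1× *ntrB* T326C) and the
mutator table (7× A289C; *ntrB* T323C, T407C, A608G ×2, A683G; *glnK* T11C,
A131G, A263G; 5 unidentified lines). The evolved/total counts per condition
(21/21, 22/23, 22/34, 26/35, 22/35) are likewise printed values. The `Lag`,
`Lead` and `sm-Lead` mutation tables are *reconstructions*: integer counts
chosen to reproduce the printed spectrum percentages exactly (e.g. 22.2%,
66.7%, 7.4%, 3.7% is exactly 6/18/2/1 over 27), with placeholder
`"unspecified"` labels where individual mutation identities were not printed.
Reconstructed tables are used only for spectrum-level analyses; they never
feed transition/transversion counts.

Per-line emergence days are not printed anywhere (the raw data live in the
study's public archive), so fixture `day` values are `NA` and
`run_pipeline()` skips the rank-test stage on them with a logged notice. The
printed medians and Dunn/Wilcoxon p-values are consequently not reproduction
targets; the rank machinery is validated against enumeration oracles and
null simulations instead.

## The pipeline

```{r}
report <- run_pipeline(c("AR2", "mutS"), n_resamples = 20000, seed = 1)
report
```

Everything stochastic in the report carries its seed and resample count, and
re-running with identical inputs and seed reproduces the report (and its JSON
serialization via `write_report_json()`) byte for byte.

## Problem sizes and defaults

Default resample counts are 10^4 in `run_pipeline()` (exploratory scale;
the headline bootstrap result is quoted at 10^6, which takes well under a
second) and the test suite uses 2 × 10^4 – 6 × 10^4 where it compares
resampling estimates to exact oracles, 2000–3000 datasets for type-I-error
checks, 1000 replicates for CI coverage, and 5000–10^4 lines where simulator
closed forms are checked against 99% binomial intervals. These sizes put
Monte-Carlo noise well below every tolerance asserted while keeping the whole
suite around a minute.

## Known limitations

* Chi-square comparisons are two-condition; omnibus comparisons across all
  backgrounds at once are not implemented (the motivating analyses were
  pairwise).
* No multiple-testing correction is applied across the five strain
  comparisons, matching the original reporting; `dunn_pairwise()` exposes
  adjustment for its own family only.
* The generator's exponential-race model has no within-population dynamics;
  emergence-day *distributions* from presets are schematic even where
  spectrum shares are calibrated.
* Reconstructed fixture tables inherit rounding ambiguity from printed
  percentages (the leading-strand background prints 26 evolved lines but its
  percentages imply 27 mutations — evidently one line carried two; the
  reconstruction keeps 27 records).
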