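---
title: "Methods: disorder-centric classification of missense mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder-centric classification of missense mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrmut)
```

## The model

`idrmut` treats intrinsic disorder as a per-residue property predicted
from sequence composition. The built-in predictor averages the TOP-IDP
disorder propensity scale over a centred sliding window and maps the
windowed mean through a logistic:

$$ps_i = \mathrm{logistic}\bigl(k\,(\bar{x}_i - m)\bigr),$$

with $\bar{x}_i$ the window mean at residue $i$, $m$ the mean of the 20
scale values (the scale midpoint) and $k$ the steepness. Scores live in
$[0,1]$; a residue is called *disordered* iff $ps \ge 0.5$ and *ordered*
otherwise. The threshold is deliberately part of the score convention,
not a tunable: every classification, rate and enrichment in the package
uses this one rule, and the pipeline log echoes it
(`ps >= 0.5 => disordered`) so the boundary convention is auditable.

A point mutation is scored by rescoring the **full-length** mutant
sequence — never by patching the wild-type profile — and the transition
class is a function of the mutated residue's scores only:

| wild type | mutant | class |
|-----------|--------|-------|
| $ps \ge 0.5$ | $ps < 0.5$ | D→O |
| $ps < 0.5$ | $ps \ge 0.5$ | O→D |
| $ps \ge 0.5$ | $ps \ge 0.5$ | D→D |
| $ps < 0.5$ | $ps < 0.5$ | O→O |

Score changes at neighbouring residues (the "ripple" within half a
window of the site) are observable in the full mutant profile but never
affect the class; this keeps the classification definition local and
exactly reproducible from the two scores stored with every call.

### Assumptions

The predictor assumes disorder is driven by local composition on the
scale of tens of residues, which is what a propensity scale can capture.
It does not model long-range contacts, binding-induced folding or
context beyond the window, and it makes **no claim of numerical
equivalence** with neural-network or energy-based disorder predictors;
those can be consumed instead via external per-residue score tracks
(`read_score_track()`), in which case mutant tracks must be supplied per
mutation because the package cannot rescore a mutant it did not score.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window` | 21 | residues | smooths the single-residue scale to region-level signal, comparable to long-disorder predictors; must be odd so the window is centred |
| `steepness` | 8 | per propensity unit | calibrated so the extreme homopolymers separate cleanly: mean $ps$(poly-P) $\ge 0.5 >$ mean $ps$(poly-W), the calibration property asserted in the test suite |
| `scale` | TOP-IDP | — | the published ordering from order-promoting (W) to disorder-promoting (P); any user scale with one finite value per residue is accepted |

Edge handling uses mirror padding (the first/last window halves reflect
the sequence, excluding the edge residue itself). This keeps the profile
exactly sequence-length, makes homopolymer profiles constant, and makes
the predictor exactly mirror-symmetric: reversing the sequence reverses
the profile. Sequences too short to mirror ($L < \lfloor w/2\rfloor+1$)
fall back to the full-sequence mean at every position. Non-canonical
residues are rejected under the default `strict` policy; under `mask`
they are scored at the scale midpoint, a deliberately neutral choice.

## MoRF detection

Stage 1 scans the profile for maximal ordered runs of length 5–25
flanked on both sides by at least 10 consecutive disordered residues —
the "short order-prone stretch inside long disorder" signature of an
α-MoRF. Runs touching a terminus have no flank there and are rejected.
These three thresholds are exposed because the original two-stage
predictor's exact settings are not public; the defaults follow the
α-MoRF literature's notion of a short binding element inside a long
disordered region, and the published MoRF gain/loss fold values are
therefore **not** reproduction targets of this package.

Stage 2 is a quadratic discriminant over six candidate features (mean
stretch score, mean flank score, stretch length, both flank lengths,
mean propensity of stretch residues): Gaussian class densities with
class-specific covariances and empirical priors, score = log posterior
odds, accepted iff positive. A numerically singular class covariance is
ridge-regularized by adding $10^{-6}\,\mathrm{tr}(S)/d$ to the diagonal,
with a warning. The model ships untrained; `gen_morf_training()` builds
a labelled training set from synthetic sequences with planted strong
(W/F/Y/I) versus weak (M/I/L/Y/V/T) order-prone stretches.

Per-mutation impact compares accepted MoRFs overlapping the mutated
position — the ordered stretch only, flanks excluded — in wild type and
mutant: `lost`, `gained`, `present_no_change`, or `absent`; `absent`
mutations are excluded from enrichment denominators. Mutations are
placed into IDR/OR strata using the wild-type score.

## Curation

Pairwise identity comes from a Gotoh affine-gap global alignment over
BLOSUM85 (shipped as a text file) with gap open −11 and extension −1
(the gap cost is $\mathrm{open} + (L-1)\,\mathrm{ext}$ for a gap of
length $L$). Tie-breaking in the traceback is fixed (match state over
gap-in-b over gap-in-a, extension over re-opening), so alignments are
deterministic; the optimal score itself is tie-independent and is
checked against brute-force enumeration in the tests. Identity is
computed over alignment columns by default; a shorter-sequence
denominator is available by argument since conventions differ.

Redundancy clustering joins proteins at ≥ 40% pairwise identity and
takes single-linkage connected components, so near-identity is allowed
to chain. The partition is seed-independent; only the uniformly drawn
cluster representative uses the seed. Outlier proteins can be flagged by
top-k mutation burden or by a count threshold; their mutations are
removed downstream and the removed fraction reported.

NES extraction walks aligned human/ortholog pairs at ≥ 95% identity and
emits one pseudo-mutation per mismatching column (both residues
canonical, neither gapped; columns where the human sequence is gapped
have no human coordinate and are skipped). Records identical to an
annotated disease mutation are filtered out. Duplicates across orthologs
collapse by default — the alternative (`keep_multiplicity = TRUE`)
retains one record per ortholog; both are offered because either
convention is defensible and the package does not assert which one any
published dataset used.

## Statistics

* **Fisher's exact test** (two-sided) uses the point-probability
  convention: the p-value sums hypergeometric probabilities of all
  same-margin tables whose point probability is at most the observed
  one, within $10^{-7}$ relative slack against floating-point ties. The
  test suite checks this against an independent exhaustive enumeration
  for every 2×2 table with total ≤ 40.
* **Bonferroni** multiplies by the family size and caps at 1; the family
  is all tests within one analysis (e.g. all features tested in one
  enrichment run).
* **Fold differences** are ratios of event proportions with a
  delta-method standard error on the log ratio,
  $\mathrm{fold}\cdot\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)}$. A zero
  proportion makes the fold undefined (flagged `NA`, with a warning),
  never infinite.
* **Composition profiles** report $(f_s - f_b)/f_b$ per residue with a
  seeded multinomial bootstrap SE (default 10,000 replicates);
  a residue absent from the sample scores exactly −1.
* **Excess kurtosis** of the Δps distribution uses the unbiased sample
  estimator; tail fractions default to $|\Delta ps| \ge 0.2$.
* **Feature normalization** drops `Potential`/`Probable`/`By similarity`
  qualifiers, strips leading qualifier prefixes ("Required for",
  "Involved in", …) longest-first and case-insensitively, collapses
  whitespace, removes disease-named keywords, and removes features
  observed fewer than 5 times in the reference dataset.

## The synthetic generator

`gen_proteins()` builds sequences from alternating ordered/disordered
blocks with geometric lengths (memoryless and easy to reason about;
first block type random). Residues are drawn with probability
$\propto \exp(\pm\beta z)$, $z$ the standardized propensity, sign by
block type, so disordered blocks are genuinely enriched in
disorder-promoting residues; $\beta = 0$ recovers unbiased composition.
Long disordered blocks may carry an embedded MoRF-like stretch.

`gen_mutations()` plants transitions: with probability `p_do` a mutation
is placed at a residue currently called disordered and its residue
replaced by a more order-promoting one **verified to flip the call**
(rejection sampling over sites and candidates with bounded retries).
Planted flips therefore materialize exactly; failures fall back to
background mutations and are counted per dataset, which scales both
case and control effective rates by the same factor and preserves the
planted fold. Background mutations can flip calls accidentally; this
baseline is *measured* (run with `p_do = p_od = 0`), never suppressed.

Defaults are fixed study conditions: 60 proteins, lengths uniform on
80–400, mean block length 40/40 (≈ 50% disorder content, giving both
region types comparable power), $\beta = 2$, planted $p_{D\to O}$ =
0.2 (DM-like) versus 0.1 (both controls) — a planted enrichment fold of
2 — $p_{O\to D} = 0.05$ everywhere, and 150 annotations placed on
disordered blocks at 3:1 odds.

**What passing tests do and do not show.** The generator emulates the
*statistical structure* the analysis assumes — block architecture,
composition bias, planted transition probabilities, planted annotation
odds — so parameter recovery demonstrates that the pipeline measures
what it claims without bias at realistic sample sizes. It does not
emulate real proteome length/composition distributions, genetic-code
constraints on reachable substitutions, CpG-driven mutability, or
correlated domain architectures; agreement on synthetic data is
therefore evidence of pipeline correctness, not of any biological claim
about real mutation sets. Two estimator caveats are worth noting: the
annotation-odds recovery uses the fold of per-mutation feature overlap
between true disordered and ordered strata, which is mildly attenuated
when feature intervals overlap each other (union saturation), and the
observed transition fold includes the small accidental-flip baseline in
both numerator and denominator.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; profiles, alignments
and scans are deterministic. The test suite validates parameter
recovery at 5,000 mutations over 60 proteins (chosen so binomial
standard errors are small relative to the planted effects while the
suite stays fast), sweeps all 135,750 Fisher tables with total ≤ 40
exhaustively, and checks alignment scores against exponential
enumeration for sequence pairs up to length 6.

## Known limitations

* The built-in predictor is a propensity smoother: adequate for
  threshold-crossing logic and fully controllable, but not a
  state-of-the-art disorder predictor; its Δps dynamic range is its own
  and no attempt is made to match any published predictor's range.
* Secondary-structure transition analysis consumes external state
  tracks; the reliability filter applies at the mutated residue only.
* The stage-2 MoRF discriminant is only as good as its training set;
  with the synthetic trainer it separates planted strong/weak stretches
  but has not been trained on curated MoRF annotations.
* NES construction requires precomputed ortholog alignments (or pairs
  alignable by `global_align`); ortholog detection and multiple
  alignment at scale are out of scope.
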