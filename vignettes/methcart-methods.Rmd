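---
title: "Methods: methylation calling, bias correction and tree classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation calling, bias correction and tree classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcart)
```

`methcart` analyses targeted bisulfite amplicon sequencing of single
hematopoietic colony-forming-cell (CFC) clones at the MLH1 promoter:
from barcoded reads to per-clone per-CpG methylation frequencies, and
from those frequencies to a decision-tree classifier of the clone's
binary MLH1 expression status. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The assay model

The assay sequences the bisulfite-converted *minus* strand of two PCR
amplicons (Fragment 1: −938..−483, 38 CpG sites; Fragment 2: −596..−337,
16 sites; coordinates relative to the transcription start site at 0,
upstream negative; 7 sites fall in both windows and are kept as separate
per-fragment estimates throughout, since the two amplicons are
calibrated separately). In plus-sense reads a minus-strand cytosine
appears at a plus-strand G position, so:

* a methylated CpG reads `CG`, an unmethylated CpG reads `CA`;
* every non-CpG minus-strand C is expected fully converted and reads
  `A`; a residual `G` there is a bisulfite conversion failure.

`build_theoretical_reference()` converts the reference window assuming
100% methylation and classifies each column as `cpg_g` (informative G/A
position of a CpG site), `conversion` (non-CpG minus-strand C), or
`fixed`. Reads are compared to this reference; `score_reads()` maps
`CG` to 1 and `CA` to 0 at each site, with anything else (a gap, a
non-C at the C position, an unexpected base) unscorable (`NA`, excluded
from both numerator and denominator of the site frequency — no
imputation). The pooled fraction of `A` at conversion columns is the
run's conversion efficiency, which bounds the false-positive
methylation call rate.

On fragment windows the stated coordinates imply a 602-bp region
(−938..−337 inclusive) and a 456-column Fragment 1 read frame; the
window coordinates are taken as authoritative wherever derived lengths
disagree with them by one or a few bases.

The packaged reference (`mlh1_promoter()`) is a synthetic 602-bp
sequence carrying CG dinucleotides exactly at the assay's CpG
coordinates and nowhere else, so no genome download is needed; a user
can substitute the true GRCh37 window via `load_promoter_reference()`
without touching the rest of the pipeline.

## Read processing

**Demultiplexing** is an exact match of the first 9 bases against the
sample sheet's barcodes. No mismatch tolerance is offered: the
published barcode set is mutually distant, and with 454-style noise an
unassigned read is cheaper than a misassigned one.

**Trimming** locates the fragment's forward primer (exact fixed-string
search first, then a 2-mismatch search for the reads that miss),
reverse-complements reverse-orientation reads into the plus-sense frame,
and strips everything outside the primer pair.

**Alignment** projects each insert onto the reference frame. The scoring
scheme is global with free end gaps on the read: match +1, mismatch −1,
gap open −2, gap extend −1 — parameters chosen for the short-indel error
profile of pyrosequencing; no aligner or parameters are prescribed by
the assay, so these are package choices and are exposed in the
documentation. Inserts whose length equals the reference length are
projected by direct column comparison, which is exact when the read has
no indels; only length-shifted inserts go through the dynamic program.
The rare read whose insertions and deletions cancel in length is
mis-projected by the direct path, drops below the identity threshold,
and is discarded like any other failed read. **Identity** is defined as
matching columns over all reference columns, with gaps and uncovered
ends counting as mismatches; this makes the assay's "> 70% identity"
filter well-defined (the inequality is strict). Note that identity is
measured against the fully-methylated theoretical reference, so a fully
unmethylated Fragment 1 read scores (456 − 38)/456 ≈ 0.917 — well above
the threshold by design.

## Molecule classification and the methylation matrix

`build_matrix()` aggregates per-read calls into per-clone per-site
counts and frequencies, plus clone-level "molecules methylated /
unmethylated" summaries whose ratio mirrors the published per-clone
tables. How a whole molecule was called methylated in those tables is
not documented, so the package makes the rule explicit and
configurable: the default calls a molecule methylated if at least one
CpG call is 1 (sensitive, matching the idea that any methylation marks
the molecule); a majority-of-scorable-calls rule is available via
`rule = "majority"`. The ratio itself — n_meth / n_unmeth, which is what
the published tables print — is independent of this choice only in the
trivial cases, so both the counts and the rule used are carried in the
output. A zero unmethylated count raises an explicit infinite-ratio
error unless the caller opts into `Inf`.

## Hyperbolic amplification-bias correction

PCR favours unmethylated (less CpG-dense after conversion) template.
With two competing templates at amplification-efficiency ratio `b`
(unmethylated : methylated), a true methylated fraction `m` is observed
as

    o = m / (m + b (1 − m)).

The assay's own description says only that a "hyperbolic solution" was
calibrated from enzymatically methylated:unmethylated control DNA at
1:0, 1:1 and 0:1; the two-template hyperbola above is adopted as the
canonical such model because it passes both endpoint controls by
construction, has a single parameter identified by the midpoint control
(`o_half = 1/(1+b)`, so `b = (1 − o_half)/o_half`), and inverts in
closed form:

    m = o b / (1 − o + o b),

clamped to [0, 1] — the clamp implements the stated normalization of
corrected frequencies. Endpoint controls are used as diagnostics: more
than 0.05 off their ideals triggers a warning. Calibration is per
fragment by default (one midpoint estimate per amplicon); per-site
calibration is available when per-site control tallies are supplied.
The correction is exactly self-inverse (`correct_frequency(forward_bias
(m, b), b) = m`), strictly increasing in `o`, and leaves counts
untouched for audit.

## Classical statistics

Per-site comparisons between expressing and non-expressing clones use
the two-tailed *pooled-variance* Student t-test (the default of the
commercial package used for the original analysis); Welch's form is a
flag. Degenerate inputs are explicit: fewer than two observations per
group gives `NA`; zero variance in both groups gives p = 1 at equal
means and p = 0 otherwise. The headline per-site p-values are
unadjusted, as in the original screen over 38 sites; Benjamini-Hochberg
q-values are emitted alongside. The aggregate comparison collapses each
site to its group mean (one value per site per group) before testing,
and per-site univariate logistic regressions (`stats::glm`, Wald slope
p) report non-convergence and complete separation as flags rather than
silent estimates. Whether the original logistic analysis was univariate
per site is not stated; univariate is implemented as the literal
reading.

## The classification tree

The tree is written from scratch (no `rpart`/`tree` dependency — those
remain available to a user as independent cross-checks). For two
classes k ∈ {Exp, Non-Exp} with counts n_k at a node (n total), the
node deviance is the multinomial −2 log-likelihood

    D_i = −2 Σ_k n_k ln(n_k / n),      0·ln 0 ≡ 0,

zero for a pure node and maximal per case at a 50/50 mix. The −2 ln
scale (rather than the bare entropy form) is fixed by the AIC pruning
below: `D(T) + 2·size(T)` is AIC only on this scale.

*Growth*: exhaustive search over every site and every midpoint between
consecutive sorted unique frequency values, choosing the split that
minimizes the sum of child deviances (cases strictly below the
threshold go left). A node is terminal when it has fewer than 10 cases
(strict inequality), when its own deviance falls below 1% of the root
deviance (the homogeneity reading of the stopping rule; the alternative
"improvement < 1%" reading is not used), or when no split reduces the
deviance. Ties among equal-deviance splits resolve to the earlier site
column, then the smaller threshold, making the fit deterministic.

*Pruning*: the pruned tree is the subtree minimizing the
cost-complexity `D_k(T) = D(T) + k·size(T)` with `k = 2` (AIC), where
`D(T)` sums leaf deviances and `size(T)` counts leaves. Because the
objective is additive over leaves, the optimum over all pruned subtrees
is computed exactly by bottom-up dynamic programming
(`cost(node) = min(D_node + k, cost(left) + cost(right))`), with ties
collapsing to the smaller tree. The test suite verifies this DP against
brute-force enumeration of all subtrees.

*Labels and prediction*: each node is labelled P (majority expressing)
or A (majority non-expressing); leaf ties go to A, the cohort's larger
class, for determinism. Prediction descends the threshold
inequalities; a missing site value is an error naming the site.
Resubstitution misclassification (minority count per leaf) is the
reported success measure — no cross-validation, matching the original
report. Trees serialize to JSON losslessly (thresholds at 17
significant digits, so serialize → deserialize → serialize is
byte-identical).

## The synthetic data generator

`simulate_clone_reads()` emulates the structure the analysis assumes:
reads are `barcode + forward primer + converted insert +
revcomp(reverse primer)` in either orientation, with three independent
noise processes — bisulfite conversion failures (default 10⁻⁴,
matching the assay's reported 99.99% conversion), per-base substitutions
(default 10⁻³) and per-base indels (default 10⁻³, a uniform
approximation of pyrosequencing homopolymer errors; no flow-space
simulation). Two mixture modes exist because the bias model presumes
competing templates:

* **pattern** — per-site independent Bernoulli draws from the clone's
  site probabilities: the right generator for frequency-matrix tests;
* **two_template** — each molecule is entirely methylated or entirely
  unmethylated, and unmethylated molecules are sampled with relative
  weight `b`, so the observed methylated fraction has expectation
  `m/(m + b(1 − m))` exactly: the right generator for calibration and
  correction tests (`simulate_controls()` uses it at m = 1, ½, 0).

`simulate_cohort()` draws expressing clones' site probabilities from
Beta(2, 10) (mean ≈ 0.17) and non-expressing from Beta(4, 6) (mean
≈ 0.4), scaled by a clone-level Unif(0.5, 1.5) factor to mimic the wide
clone-to-clone spread of the published per-clone ratios (0.065–0.98 on
Fragment 1); per-clone depth is drawn log-uniformly from [600, 3000] by
default — within the published depth range, whose upper extreme adds
precision but no structure. `simulate_frequency_cohort()` skips reads
and draws observed frequencies binomially at a given depth; with a
`planted_site`, all other sites become class-independent Beta(2, 2)
noise so that recovery of the single informative site is measurable.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: 454 flowgram/homopolymer error structure,
chimeric molecules, per-site variation in amplification bias within an
amplicon, spatial correlation of methylation along a molecule (sites
are independent given the clone in pattern mode, perfectly correlated
in two-template mode; real molecules sit between), and the unexplained
clone-to-clone depth variation of the real run.

## Problem sizes and numerical choices

The packaged tests and the acceptance script use: 50,000-read control
sets for bias calibration (recovering `b` within 5% for b ∈ [0.25, 4]);
4,000-read sets for conversion-efficiency recovery (≈ 250,000 non-CpG
tallies, enough to resolve a 10⁻⁴ failure rate within 3 binomial SEs);
200 replicate 30-clone cohorts for planted-split recovery and for
resubstitution under 10% label noise; 2,000 null replicates for t-test
type-I calibration; and full-pipeline cohorts of 30 clones at depths of
600–1500 reads per clone per fragment — sizes chosen so each check's
sampling error is small against its tolerance. Floating-point
specifics: deviances normalize −0 to 0; a split must reduce deviance by
more than 10⁻⁹ to be accepted (guarding against float noise creating
spurious splits); thresholds are midpoints, so scoring is invariant to
which side of the data gap a test value falls in; the bias inverse is
analytic, so the round trip is exact to machine precision.

## Known limitations

The molecule-level classification rule behind the published per-clone
counts is an assumption (documented above). The hyperbola is the
canonical but assumed form of the "hyperbolic solution"; data with a
different bias mechanism (e.g. length- or GC-driven) would need a
different calibration. The assay cannot distinguish 5-methylcytosine
from 5-hydroxymethylcytosine, and neither can anything downstream of
it. Dataset-specific published figures (the 46% significant-site
fraction, the exact tree splits and 83–90% success rates) depend on the
deposited sequencing data and are reproduced only as pipeline outputs
when a user supplies that data; the packaged tests assert the
corresponding *properties* (planted-split recovery, resubstitution
under label noise) on synthetic cohorts instead.
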