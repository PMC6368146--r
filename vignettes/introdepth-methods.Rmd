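---
title: "Methods: discordance, node-depth introgression tests, and LTR dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordance, node-depth introgression tests, and LTR dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`introdepth` addresses a recurring situation in comparative phylogenomics:
three lineages (call them A, B, C) split in rapid succession, individual
gene trees disagree about which two are sisters, and the analyst must decide
how much of the disagreement is incomplete lineage sorting (ILS) and how
much is post-speciation gene flow. The package implements the full chain of
computations for that decision — alignment quality masking, triplet
gene-tree classification with internode certainty, and a node-depth test —
plus insertion-age dating of LTR retrotransposons, and a coalescent
simulator that generates all required inputs with known ground truth.

```{r setup}
library(introdepth)
```

## The discordance model

For a rooted species tree `(((A,B),C),O)` with an internal branch of
length $t$ coalescent units (one unit = $2N$ generations), the
multispecies coalescent predicts that a fraction $e^{-t}$ of loci fail to
coalesce on the internal branch; those loci resolve the triplet uniformly,
so each *minority* topology (`AC|B`, `BC|A`) occurs with probability
$\frac{1}{3}e^{-t}$ and the concordant topology with
$1 - \frac{2}{3}e^{-t}$. Two consequences drive everything downstream:

* **Symmetry under ILS.** With no gene flow the two minority topologies are
  exchangeable — equally frequent and with identical node-depth
  distributions. Any significant asymmetry therefore points to
  introgression.
* **Depth reduction under introgression.** An introgressed locus carries a
  lineage that diverged at the time of gene flow, not at speciation, so its
  gene tree is shallower than a speciation-order tree of the same topology.

## Gene-tree classification and internode certainty

`classify_triplet()` reduces a gene tree to the four roles via a
user-supplied taxon map, roots it on the outgroup, and reports which pair
forms a cherry (or `UNRESOLVED` at a polytomy). `summarize_concordance()`
stratifies trees by mean internal-branch bootstrap support (default
cutoffs 50–90, strict `>`), because discordance patterns that persist in
the best-supported trees cannot be blamed on gene-tree estimation error.

Internode certainty for the focal branch is computed from the two most
prevalent conflicting bipartitions:
$\mathrm{IC} = 1 + p\log_2 p + q\log_2 q$ with $p = n_1/(n_1+n_2)$.
A 42:38 head-to-head split gives

```{r}
internode_certainty(42, 38)
```

i.e. zero at two decimals — the quantitative way of saying the branch is
genuinely contested rather than weakly sampled. The three-way entropy
variant is available via `method = "entropy3"`; whole-tree certainty
(averaging over all internodes) is out of scope.

## Node depths from sequence divergence

For a locus whose tree resolves cherry $(X,Y)$ with third taxon $Z$, the
depth estimator assumes a molecular clock and uses corrected pairwise
divergences:

$$T_1 = \tfrac{1}{2}\,d(X,Y), \qquad
  T_2 = \tfrac{1}{4}\left[d(X,Z) + d(Y,Z)\right],$$

in substitutions/site, with $d$ the one-parameter (equal-rates) corrected
divergence $-\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ (`correction = "raw"`
available). Two site sets play different roles, and this is a deliberate
design choice:

* **Distances are computed over all fully resolved columns** (no gap or
  mask character in any row). Restricting the distance itself to
  parsimony-informative columns is not viable: conditioned on a fully
  resolved quartet, cross-pair divergence on that subset approaches
  saturation (observed proportions near 0.9, beyond the 0.75 validity
  bound of the correction) while cherry-pair divergence collapses to
  homoplasy noise, destroying both estimates.
* **Biallelic informative sites gate the loci.** A locus is dated only if
  it carries at least `min_sites` (default 10) columns with exactly two
  states, each in at least two taxa — the columns that actually anchor the
  quartet's internal structure. Below that the per-locus depth variance
  dominates any between-class signal, so such loci are excluded and
  logged, not averaged in. The informative-only distance remains available
  as `site_set = "informative"` for sensitivity analysis.

An optional outgroup normalization (`normalize_by_outgroup = TRUE`)
divides both depths by the mean ingroup–outgroup divergence; it is off by
default because the simulator is clock-like and the raw scale keeps units
interpretable.

## The depth test and its verdict rule

`compare_depth_classes()` compares the two most prevalent conflicting
topology classes. Loci are resampled within class (`n_boot` nonparametric
bootstrap replicates, seeded); each replicate yields the differences of
mean $T_1$, mean $T_2$, and their average $(\Delta T_1 + \Delta T_2)/2$.
The verdict is **resolved** — the deeper class is declared the speciation
topology — only when the two point differences agree in sign *and* the
percentile interval of the combined difference excludes zero (default
95%). Otherwise it is **ambiguous**.

The combined statistic is the package's own choice among several
defensible rules. $T_1$ and $T_2$ are strongly positively correlated
within loci, and introgression shifts both in the same direction, so
pooling them preserves an exact nominal false-resolution rate of 5% under
the ILS null (where the two minority classes are exchangeable) while
gaining substantial power over requiring each depth to clear significance
separately — under realistic calibrations the $T_2$ contrast alone sits
near $z \approx 2.5$ and would fail sporadically even with a real pulse.
Per-depth intervals and two-sided rank-test p-values are reported alongside
(`tidy()` on the result) so the individual contrasts stay inspectable.

## The synthetic-data generator

`sim_config()` + `simulate_gene_trees()` implement a structured coalescent
on `(((A,B),C),O)` with one shared population size. Introgression is a
single instantaneous pulse: with probability `gamma` the recipient taxon's
lineage is relocated into the donor's population at time `t_gamma`
(backwards in time) — the simplest model that captures the verbal argument
the depth test rests on. Defaults, chosen once to emulate the empirical
situation the package targets:

| parameter | default | meaning |
|---|---|---|
| `tau1`, `tau2`, `tau_out` | 1.5, 1.95, 4 | split times, coalescent units |
| `t_gamma` | 0.1 | pulse time (recent gene flow) |
| `gamma` | 0 | pulse probability per locus (null) |
| `donor`, `recipient` | A, C | pulse direction (see below) |
| `theta` | 0.02 | subs/site per coalescent unit is `theta/2` |
| `seq_length` | 1000 | sites per locus, gap-free |

The internal branch $t = 0.45$ puts each minority topology near 21% under
the null; adding a pulse with `gamma = 0.3` yields the two leading classes
at roughly 40% each with the third near 18% — the near-tied conflict
pattern, stable across bootstrap strata, that motivates a depth test in
real data.

**Pulse direction matters more than is obvious.** Moving the *third*
taxon's lineage into the ingroup population (`donor = "A"`,
`recipient = "C"`; forwards in time, ingroup alleles entering C) lets the
introgressed pair coalesce below the deep split, so both $T_1$ and $T_2$
of the introgressed class shrink — the full double-depth signature. The
reverse relocation (ingroup lineage into population C) shortens only
$T_1$: the migrant lineage rejoins the others above the deep split, so
mean $T_2$ is essentially unchanged. Both directions inflate the same
minority topology and both shallow $T_1$, so topology counts cannot
distinguish them — but only the default direction reproduces a joint
$T_1$/$T_2$ reduction. The direction is exposed as a parameter because
real systems rarely announce it.

Sequences evolve site-independently under the equal-rates model with a
vectorized per-edge transition sampler (exact JC transition probabilities;
validated in the tests against the closed-form expected divergence given
each tree's path lengths). Seeding is two-level: every locus draws from a
stream derived deterministically from `(seed, locus index, stage)`, so a
subset of loci reproduces bit-identically regardless of how many other
loci are simulated. The generator makes no attempt at several features of
real data — no recombination within loci, no rate heterogeneity among
sites or lineages, no indels, no alignment error, one individual per
taxon — so passing tests demonstrate correctness of the inference chain
under the model, not robustness to alignment artefacts or rate variation.

## Alignment masking

`mask_alignment()` implements the sliding-window filter: any 15-column
window (step 1) containing more than six mismatching columns is masked in
all rows, gaps are rewritten to the mask character, and an alignment with
more than 20% of its columns window-masked is dropped. All thresholds are
strict inequalities and configurable. A "mismatch" is a column property —
at least two non-gap residues disagree — which is the natural reading of a
mismatch "among all" sequences; a per-pair tally is available as
`mismatch_mode = "pairwise"` for sensitivity. Gap-masked columns do not
count towards the drop fraction, only window-masked ones do. The
implementation is cross-checked in the test suite against an independent
brute-force per-window reimplementation on a thousand random alignments.

## LTR insertion-age dating

Terminal repeats are identical when an element inserts, so their corrected
divergence $K$ dates the insertion as $T = K/(2\mu)$, with
$\mu = 1.3\times10^{-8}$ substitutions/site/year by default (the
conventional plant LTR rate; always user-settable). Raw divergence is
mismatches over non-gap aligned columns; the equal-rates correction is the
default (declared in the output metadata) with `"raw"` selectable, since
annotation pipelines differ on this point. Pairs are aligned globally via
`Biostrings::pairwiseAlignment()`; for annotators that emit already
aligned repeat regions (and for the indel-free simulator) `method =
"as_is"` skips the quadratic-time alignment. Elements with fewer than 100
aligned columns or with raw divergence at or beyond 0.75 are flagged
(`overlap_too_short`, `divergence_saturated`) rather than dropped
silently. `age_histogram()` bins ages into half-open `[lo, hi)` intervals
(default 0.5 Myr width) per superfamily, with empty labels grouped as
`"unknown"`.

```{r}
pairs <- simulate_ltr_pairs(100, true_age_years = 1e6, length = 2000, seed = 7)
est <- estimate_insertion_age(pairs, method = "as_is")
mean(est$t_years)
```

## Pipeline, determinism, and problem sizes

`run_introgression_analysis()` chains mask → drop → classify →
concordance → depth test from one validated config, writes every table as
TSV plus a JSON verdict, an exclusion log (one row per skipped locus with
a reason code), and a manifest with a config hash and per-stage locus
counts. No output contains a timestamp, so identical config and seed give
byte-identical files — the property the determinism test asserts with
checksums. `validate_config()` reports all violations at once instead of
failing at the first.

The test and acceptance experiments use problem sizes chosen to make the
Monte-Carlo error small relative to the tolerance being asserted: 30,000
loci for null topology frequencies (MC SE ≈ 0.002 against a 3-SE band),
100 replicate datasets of 500 loci for the recovery rate, cohorts of 500
repeat pairs of 5 kb for the dating round trip (< 5% bias band), and
1,000 random alignments for the masking oracle.

## Known limitations

* The depth estimator assumes a clock; strong lineage-specific rate
  variation would bias class comparisons (the outgroup normalization
  option mitigates, not removes, this).
* The conversion of the verbal "node depths from biallelic informative
  sites" procedure into explicit formulas is an interpretation; the
  gate-plus-resolved-distance design above is documented precisely so it
  can be revisited.
* With four taxa, one sequence per taxon and a single pulse, the model
  cannot represent bidirectional or multi-episode gene flow; direction and
  strength enter only through topology excess and depth shifts.
* IC is computed for the focal internode only, from the triplet classes
  themselves, not from all bipartitions of larger trees.
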