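---
title: "Calling enhancer activity from mosaic reporter assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling enhancer activity from mosaic reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonhancer)
```

## The measurement problem

Transient Tol2 reporter transgenesis in zebrafish is mosaic: a construct
with real enhancer activity in, say, the notochord will light up the
notochord in only a subset of injected embryos, and the minimal-promoter
control itself produces background expression in every anatomy (in the
shipped control data, between 7% and 34% of embryos per region). Deciding
whether a construct is an enhancer for an anatomy is therefore a
two-sample proportion problem over hundreds of embryos, not an
image-by-image judgement. The scoring pipeline dictates, per embryo, the
subset of ten anatomical regions showing GFP at 22–30 hpf; the package
parses those token streams into binary embryo × anatomy matrices
(`parse_transcript()`), keeps all-zero embryos (denominators are surviving
embryos), and merges injection rounds with their batch labels
(`merge_batches()`).

The ten regions are coded 1–10 in the conventional reporting order
(forebrain … tail region). The code-to-anatomy mapping and the embryo
delimiter token (`"new"`) are conventions of this package, configurable
through `anatomy_vocabulary()`/`read_vocabulary()`; duplicate anatomy
tokens within an embryo are idempotent because the representation is
presence/absence.

## The dual calling rule

An anatomy is called active for a construct only when two criteria each
reach $p \le \alpha$ (default 0.05):

* **Proportions criterion.** `proportions_test()` wraps the
  continuity-corrected chi-squared two-sample proportion test, one-sided
  (candidate greater). One-sidedness matters: a candidate whose fraction
  is far *below* control yields $p \approx 1$, which is the behaviour the
  published example table shows (e.g. a heart cell printed as 1.0000 where
  the candidate fraction is 0 against a control of 0.32).
* **Partition rank-sum criterion.** `partition_ranksum()` shuffles the
  candidate's embryos, splits them into `n_partitions = 5` near-equal
  groups (sizes differing by at most one), computes each group's
  expressing fraction, does the same for the control, and applies a
  one-sided Wilcoxon rank-sum test to the two sets of group fractions.
  The run is repeated `n_runs = 3` times and the arithmetic mean p-value
  is reported. Because a single dominant injection round inflates only
  some groups, this criterion penalises constructs whose apparent signal
  is concentrated in one round.

Design choices worth recording, since the procedure leaves them open:

* *Control partitioning.* The control is also shuffled into 5 groups,
  giving a symmetric 5-vs-5 comparison. The group count is configurable;
  5-vs-5 is the default for symmetry with the candidate side.
* *Ties and exactness.* Group fractions on 0/1 data tie constantly, and a
  5-vs-5 rank-sum is deeply discrete (252 relabellings). Rather than rely
  on the tie-corrected normal approximation in that regime, the package
  enumerates the conditional null exactly with midranks whenever both
  sides have at most 8 groups, and falls back to the corrected normal
  approximation above that. On tie-free data the enumeration equals the
  classical exact distribution (verified in the tests against
  `wilcox.test(exact = TRUE)`).
* *Seeding.* Every shuffle derives a substream seed deterministically
  from the pipeline seed and the (construct, anatomy, run) labels, so a
  study rerun is byte-identical while substreams stay decorrelated.
* *Conservatism.* The conjunction of two level-$\alpha$ tests is at most
  level $\alpha$; simulation at the study's sample sizes (candidate
  n = 120 vs control n = 161, control rates from the shipped table) puts
  the per-anatomy false-call rate near 0.02 — the rule is conservative,
  by construction, because discreteness makes the rank-sum criterion
  under-reject.

Construct classes follow the published scheme: *none* below a 5%
whole-embryo expressing fraction, *significant* with at least one dual-rule
anatomy, *weak* otherwise, and *specific* when 1–4 anatomies are called
(`classify_activity()`). The 5% and 4-anatomy thresholds are exposed as
parameters; the whole-embryo fraction is the fraction of embryos with at
least one active region, an objective stand-in for the visual
"clear GFP expression" judgement, which this package does not attempt to
replicate.

Fold ratios for significant anatomies are the plain ratio of expressing
fractions, rounded to one decimal for reporting; they are undefined when
the control fraction is zero. Published tables print proportions rather
than counts; `reconstruct_counts()` inverts them to the best integer
count and flags cells where no integer reproduces the printed value at
four-decimal precision — in the shipped table all 40 candidate-construct
cells invert exactly, while 9 of 10 control cells sit within one count but
not within 5e-5, i.e. the control column was printed at coarser effective
precision.

## Concurrency versus mosaicism

For an anatomy pair, `concurrency_z()` compares the count of
doubly-active embryos against a null of equal probability 1/4 for the
four joint patterns: $z = (N_{11} - 0.25N)/\sqrt{0.1875\,N}$, one-sided
upper tail. Two caveats are intentional properties, not bugs, and are
pinned by regression tests: the null is *four cases equally likely*, not
*independence of the margins*, so with high marginal rates the statistic
is large even without association (independent Bernoulli(0.9) margins at
N = 400 give z ≈ 25); and no multiple-testing correction is applied
across the 45 pairs by default (a Bonferroni option exists). This is why
reporting highlights only pairs with z > 3. Under its stated null the
flag rate at $p < 0.05$ is close to nominal (≈ 0.05 ± 0.01 at N = 400,
binomial discreteness accounts for the wobble).

## Matching activity to annotated gene expression

`gene_matches()` asks whether a construct's called anatomies overlap a
gene's curated expression records. Anatomy terms are expanded exactly one
ontology sub-level down (`expand_terms()`) — enough to absorb resolution
differences (telencephalon records match a forebrain call) without
walking the whole subtree — and records must intersect the stage window
(closed intervals on an explicit ordered stage list; the study window is
26+ somites through Prim-15, i.e. 22–30 hpf). Probe-quality and
end-stage filters are optional arguments because the original analyses
apply them only when building gene sets for the chromatin-mark
comparison, not in the expression-overlap comparison.

The chance level of host-gene overlap comes from a permutation null
(`random_gene_null()`): each of 100 iterations samples 20 distinct genes
without replacement from the annotation universe minus the
host/neighbor/miRNA exclusions, assigns one per construct, and counts
constructs with any matched anatomy. When matches are iid across genes
the count is Binomial(20, p); the generator is built so this closed form
holds exactly, which is how the null is validated. One modelling point:
the sampling universe is *genes in the expression file*, so the simulated
annotation table gives every gene at least one (background-term) record —
otherwise sampling would condition on "has an anatomy record" and bias
the null upward. Genes without any annotation data are excluded from
overlap denominators, mirroring the use of only constructs with available
in-situ data.

## Sequence conservation

`percent_identity()` scores gap-free columns only; columns with N in
either sequence are excluded from the denominator as well (ambiguity is
not penalised as divergence). `fourfold_sites()` extracts third positions
of codons where both species have a whole, gap-free, in-frame codon and
an *identical* dinucleotide prefix from a fourfold-degenerate family —
prefix identity is required because without it the third position is not
guaranteed synonymous in both species. `fourfold_p_distance()` reports
the conserved fraction over such sites (the conserved-site convention)
and is undefined below 5 qualifying codons. Whole-codon gap-freedom is
assumed for qualifying sites; frame offsets handle alignments that start
mid-codon. The candidate filter (`cce_candidate_filter()`) applies the
selection used for testable exons: identity strictly above 60%, length in
the closed interval [100, 1000] bp, no XhoI (CTCGAG) or BglII (AGATCT)
site (both palindromic, so a forward-strand scan suffices), and a
developmental-gene flag.

## Interval overlaps

All peak/exon analyses use BED conventions — 0-based half-open input,
strand-blind, 1-bp minimum overlap, abutting intervals disjoint — with
GenomicRanges doing the interval arithmetic behind the module's surface;
the tests hold every operation to an independent brute-force all-pairs
oracle. Specific rules: TFBS "full coverage" requires a *single* cluster
with score ≥ 500 to contain the exon (a union of smaller clusters does
not count); exon cleaning for the p300 analysis collapses exact duplicate
records to one copy but removes partially-overlapping distinct records
entirely, then drops exons outside 3 bp–16 kbp; EST adjacency counts
transcripts intersecting a ±1 kb window around a region without spanning
it; intronic controls are size-matched sub-intervals placed uniformly
within uniformly chosen sufficiently-long introns. Fractions carry the
plug-in binomial standard error $\sqrt{p(1-p)/n}$ (n, not n−1), with
half-even rounding for display.

## What the synthetic data does and does not emulate

`simulate_embryos()` draws independent per-anatomy Bernoulli bits,
applies batch effects on the odds scale (keeping probabilities in range),
and adds pairwise co-activity through a shared latent indicator OR'd into
both anatomies — chosen because the joint law stays closed-form, so
concurrency tests have analytic expectations. Presets taking rates from
the shipped example table (`example_sim_spec()`) define the calibration
and power conditions: null calibration at candidate n = 120 vs control
n = 161 with control rates; power at the published notochord effect
(0.60 vs 0.16, n = 53 vs 161), recovered in >99% of seeds.

What it does not model: embryo death and re-scoring, spatial correlation
of mosaicism within an embryo beyond a single shared latent cause,
scorer-specific dictation error structure (token noise is iid), realistic
codon usage or indel evolution, and clustered genomic feature placement.
Passing tests therefore demonstrate correctness of the statistics under
the stated laws and calibration at realistic rates — not robustness to
every artefact of real scoring sessions.

## Problem sizes and numerical choices

The validation experiments use 1000 null replicates and 200
planted-effect seeds for the calling rule, 2000 replicates at N = 400 for
concurrency calibration, 100 random interval fixtures (up to ~400 × 400
intervals) for the overlap oracle, 50 seeds × 200 codons for conservation
recovery, and a 1500-gene pool for the permutation-null closed form —
sizes at which Monte-Carlo error is a small fraction of each tolerance.
Other numerical conventions: one-sided p-values are clamped to [0, 1];
the exact rank-sum comparison uses a 1e-9 slack on the observed statistic
to absorb floating-point rank sums; partition group sizes differ by at
most one with the first `n mod g` groups taking the extra embryo; and all
simulation substreams derive from a single seed via a string-hash, kept
below 2^31.

## Known limitations

Printed p-values from the original software cannot be reproduced
bit-for-bit (RNG and option details are unknowable); the reproduction
surface is the decision pattern and fold ratios, which the dual rule
recovers exactly from the printed p-value pairs. The concurrency
statistic is not calibrated under independence with extreme margins (by
design, see above). The ontology expansion is exactly one level; deeper
hierarchies require pre-expanded anatomy maps. The partition rank-sum's
discreteness makes the dual rule conservative at small group counts —
that is the documented trade-off for round-robustness.
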