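---
title: "Measuring selection of somatic mutations with conservation scores and Simpson diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsel)
```

## The model

Somatic mutations that drive tumor growth are under positive selection in
tumor evolution; passengers are not. `mutsel` measures two complementary
footprints of that selection in a cohort's mutation table.

**Functional impact of a substitution.** A protein family's multiple
alignment is treated as a statistical ensemble: each column's residue
distribution reflects the constraints acting on that position, and columns
are treated independently of one another. The impact of substituting the
query's residue $\alpha$ by $\beta$ at the column mapped from protein
position $i$ is

$$\mathrm{FIS}_i(\alpha\!\to\!\beta) \;=\; -\frac{1}{2}\left[
\ln\frac{n_i(\beta)+1}{n_i(\alpha)} \;+\;
\ln\frac{n_{ip}(\beta)+1}{n_{ip}(\alpha)}\right],$$

with $n_i(\cdot)$ counting residue types over the whole family and
$n_{ip}(\cdot)$ within the query's subfamily $p$, over a 21-letter alphabet
(20 amino acids plus gap; nonstandard characters count as gaps). The two
terms are complementary views of conservation: a residue may be variable
across the family yet strictly conserved within the query's subfamily.
Conventions, exactly as implemented:

* natural logarithm; the $+1$ pseudocount applies to the $\beta$ counts
  only (so an unobserved alternate residue contributes $\ln 1 = 0$ in the
  numerator, not $-\infty$);
* $n_i(\alpha) \ge 1$ and $n_{ip}(\alpha) \ge 1$ are guaranteed because the
  query itself is in the alignment and carries $\alpha$ — the score is
  *refused* (an error, not a silent number) if the alignment's query
  residue disagrees with the stated reference residue, since that signals
  an annotation/alignment mismatch;
* substitutions to or from a gap are never scored; silent and truncating
  records are never scored;
* if the query's subfamily is a singleton, $n_{ip}(\alpha) = 1$ and the
  subfamily term degenerates to $-\tfrac12\ln(n_{ip}(\beta)+1)$; the score
  is computed as written;
* no redundancy weighting of sequences is applied before counting.

The score is zero exactly when the two count ratios cancel,
$(n_i(\beta)+1)(n_{ip}(\beta)+1) = n_i(\alpha)\,n_{ip}(\alpha)$; the
canonical instance is both $\beta$ counts being one short of their
$\alpha$ counts.

**Subfamily labels.** Externally computed labels are the first-class input
(`build_ensemble(..., subfamilies = )`). When absent, a deterministic
baseline is used: average-linkage hierarchical clustering on pairwise
sequence-identity distance, cut at `n_subfamilies` clusters (default 4,
capped at the sequence count). This is a plain, reproducible stand-in for
specificity-aware subfamily clustering methods; supplying labels from such
a tool is preferred.

**Non-uniformity of a mutation distribution.** For per-gene counts $N_i$
over $Q$ mutated genes, $M = \sum N_i$, and shares $p_i = N_i/M$:

$$\lambda = \sum_i p_i^2,\qquad \bar N = M\lambda,\qquad K = 1/\lambda,
\qquad \mu = \lambda Q = Q/K.$$

$\lambda$ is the Simpson diversity index and $K$ the effective number of
mutated genes — the number of equally mutated genes that would give the
same diversity. When mutations fall evenly, $p_i \approx 1/Q$ so $\mu
\approx 1$; when one gene dominates, $\lambda \to 1$, $K \to 1$ and $\mu
\to Q$. Selection is read off as $\mu$ increasing with the FIS threshold:
the higher-scoring the mutations, the fewer genes carry them. Both limits
are exercised as tests with exact expected values.

## The pipeline statistics

* `tally_mutations()` slices a mutation table by class (missense, silent,
  truncating), by a *cumulative* FIS lower bound (`FIS>x` includes
  everything above $x$; bins are not disjoint intervals), and by gene group
  (all, TS, OG, CG, nCG; genes absent from the annotation are non-cancer
  genes by definition). Unscored missense records are *excluded* from
  FIS-binned tallies rather than imputed at zero — imputation would deflate
  the high bins. Score bounds never gate truncating or silent records.
* `non_uniformity()` refuses empty tallies explicitly ($M = 0$ carries no
  information; a zero would masquerade as a statistic).
* `cancer_gene_fraction()` counts at mutation level (percentages of
  mutations), `truncating_concurrency()` at gene level (percentages of
  genes) — the two different units the two questions call for. Concurrency
  requires the missense and truncating hits to come from different tumor
  samples: two events in one tumor are one clonal story, not two
  independent selections.
* `cna_concurrency()` joins mutations to discretized copy-number states
  $\{-1, 0, 1, 2\}$ by (sample, gene) and compares each class's
  loss/gain fractions to the silent class — the no-selection control — with
  a two-sided Fisher exact test on the 2×2 in-state/out-of-state counts.
  The exact test is the conservative default for these small-count
  comparisons; the test suite checks it against an independent
  full-enumeration hypergeometric oracle.
* `length_null_non_uniformity()` reports the non-uniformity expected from
  gene length alone ($p_i \propto$ coding length). It is deliberately kept
  a separate null rather than folded into $\mu$: across large gene groups,
  length effects average out, and the cohort-level comparisons the package
  makes are between large groups.

## Driver nomination

`rank_gene_burden()` counts, per gene, high-functional mutations (missense
with FIS > 2.5 plus all truncating — truncating mutations are
loss-of-function regardless of any score) and low-functional mutations
(missense with FIS < 1). Scores inside the closed band $[1, 2.5]$ count in
neither tally: that is where the predicted impact is most uncertain, and
the closed interval keeps the boundary values out of both tallies. The
passenger flag is the literal rule `n_low >= n_high`; a gene with no
counted mutations at all (everything inside the band) is flagged by that
rule but ranks last and cannot enter any effective set.

`effective_gene_set()` computes $K$ over a mutation basis (all missense +
truncating, or FIS>2.5 missense + truncating), rounds it half-up with a
floor of one — a real-valued $K$ must become a set size somehow, and
half-up is the least surprising deterministic choice — and returns the
top-$K$ genes of the burden ranking. Ties at the boundary are resolved by
the ranking's deterministic tie-break (descending high-functional count,
then descending missense+truncating count, then gene symbol). The
rank-then-cut reading is one design choice among possible set
constructions; it makes the set a pure function of the ranking.

`long_gene_filter()` flags genes with coding length strictly above 15,000
nucleotides (long genes win high-functional counts by target size alone)
but excludes them only on request — the passenger rule, not removal, is
the preferred guard, because long genes are not uniformly non-drivers.

## The synthetic cohort generator

`gen_cohort()` draws every input the pipeline reads, with the statistical
structure the analysis assumes, plus ground truth:

* **Alignments** (`gen_alignment()`): columns are globally conserved
  (consensus carried by ≥ 90% of sequences, guaranteed by a noise cap),
  subfamily-specific (distinct consensus per subfamily), or variable
  (near-uniform draws from 15-residue pools, occasional gaps). The query
  is gap- and noise-free so protein positions map 1:1 to columns. Default
  templates are 80 sequences × 60 columns with 3 subfamilies — family
  sizes at which an unobserved substitution at a conserved column scores
  ≈ 3.4–3.8, giving the score its realistic dynamic range.
* **Drivers**: `n_driver_genes` genes receive extra missense and
  truncating mutations. Intensities follow a $1/\mathrm{rank}^{1.25}$
  power law interpolating from neutrality (mean multiplier =
  `selection_strength`; strength 1 is *exactly* the null), mirroring real
  cohorts where one or two genes dominate the driver burden. Each driver's
  probability of placing a missense mutation on a conserved column scales
  with its relative intensity, from 0.8 for the top driver down toward the
  passenger value 0.03: strongly selected genes owe most of their burden
  to functional mutations, weakly selected ones mostly to background. This
  coupling matters — if all driver mutations were thinned proportionally
  by the FIS threshold, binned and unbinned distributions over the driver
  set would have identical non-uniformity by construction, and the
  selection signal within that set would be an artifact of noise.
* **Truncating mutations** get an additional 8× multiplier in drivers on
  top of the missense multiplier (tumor suppressors are classically
  inactivated by truncation) and are pulled into (gene, sample) pairs in
  copy loss by `cna_loss_enrichment` (default 2, matching the modest
  enrichment real cohorts show).
* **Background**: silent, passenger missense and passenger truncating
  mutations land on genes in proportion to coding length (log-normal,
  median 1.5 kb, floored at 300 nt); passenger missense hit conserved
  columns with probability 0.03 (truly damaging passenger missense are
  rare). Copy-number states are i.i.d. categorical with loss mass 15%.
* **Annotations**: drivers are annotated TS; additional unselected TS
  (4% of genes), OG (1%) and CG (15% total, a superset of TS and OG)
  members emulate curated lists in which most entries are not under
  selection in any one cancer.
* **Scoring**: by default FIS values come from actually scoring the
  planted substitutions against the generated template alignments (5
  templates reused across genes), keeping the scoring function in the loop
  end to end. `fis_mode = "sample"` draws from a calibrated two-component
  mixture instead, for large property sweeps.

Defaults are a cohort of 100 samples × 50 mutations (1000 genes, 10
drivers, mean driver multiplier 20) — a mid-sized exome cohort at desk
scale.

**What the generator does not emulate**: trinucleotide mutation
signatures, hypermutator samples, gene-to-gene background rate variation
beyond length, correlated copy-number segments, and subclonal structure.
Mutation protein positions live on the 60-residue template query (the
per-gene protein model); coding lengths drive placement weights and the
length table only. Passing tests therefore show that the statistics detect
the selection structure they target when it is present and stay silent
under the null — not that the pipeline is robust to every artifact of real
sequencing data.

## Numerical choices

* The plug-in Simpson estimator is biased upward at finite $M$:
  $E[\hat\lambda] = \lambda + (1-\lambda)/M$, and the observed $Q$
  undershoots the gene count. Null-configuration tests therefore compare
  the seed-averaged $\mu$ against the finite-$M$ expectation
  $E[\hat\lambda]\cdot\sum_i\left(1-(1-p_i)^M\right)$ of the
  length-proportional null, within three standard errors, rather than
  against the infinite-$M$ analytic value.
* $K$ is rounded half-up with floor 1 when it becomes a set size; all
  orderings carry deterministic tie-breaks (input order for clustering,
  lexicographic gene symbol for rankings).
* Percentages are reported with full precision and rounded only for
  display; tests always compare counts, never rounded percentages.
* Degenerate inputs fail loudly: ragged alignments, unknown queries,
  empty tallies, all-zero bases, CNA states outside $\{-1,0,1,2\}$,
  conflicting gene lengths. Malformed protein changes degrade the record
  to class `other` with a warning instead of dropping the row.
* Every generator takes an explicit integer seed and restores the RNG
  state on exit; identical seeds give byte-identical outputs.

## Problem sizes used by the test suite

Property suites run on alignments up to 8 sequences × 6 columns
(exhaustive enumeration against a literal-recount oracle), 200 random
tables for the Simpson statistics, 100 null-configuration cohorts of 150
genes, and 50 default cohorts for the planted-signal checks — sizes chosen
so each suite pins its property with comfortable margins while the whole
suite stays fast enough to run habitually.

## Known limitations

* The baseline subfamily clustering is identity-based; it will not find
  specificity-determining positions the way dedicated subfamily methods
  do. Supplying external labels is the intended path.
* Gene symbols are matched case-insensitively but no alias resolution is
  attempted; inputs must agree on symbols.
* The MAF reader covers the columns the analysis needs, not the full MAF
  specification; column names and class mappings are configurable per
  dialect.
* Raw p-values are reported without multiple-testing correction, matching
  the reporting style of the concurrency tables this package produces.
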