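---
title: "The C-value model: scoring ncRNA participation in the transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The C-value model: scoring ncRNA participation in the transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnt)
```

## The model

Differential-expression screens rank non-coding RNAs by how much their own
abundance changed (|log2FC|) or how reliably it changed (p-value). Neither
index captures regulatory reach: an ncRNA matters biologically through the
genes it regulates, and in particular through how much of the
*differential* transcriptome its targets cover.

The Contribution value addresses this directly. Fix a category of gene sets
(one of the GO branches BP/CC/MF, or KEGG). Let pathway $k$
($k = 1, \dots, n$) range over the pathways significantly enriched in
differentially expressed genes (DEGs), with enrichment p-value $p_k$. For an
ncRNA with target-gene set $T$,

$$
C \;=\; \sum_{k=1}^{n} \mathrm{Proportion}_k \cdot \bigl(-\log_{10} p_k\bigr),
\qquad
\mathrm{Proportion}_k \;=\;
\frac{\lvert T \cap \mathrm{DEG} \cap P_k \rvert}{\lvert P_k \rvert},
$$

where $P_k$ is pathway $k$'s gene set restricted to the enrichment universe.
The four category scores are computed independently and the total C value is
their plain sum, `BP + CC + MF + KEGG`. The structure is a weighted coverage
score: each pathway contributes the fraction of it that the ncRNA's
differential targets cover, weighted by how convincingly that pathway is
dysregulated. Broad shallow coverage of many strongly enriched pathways and
deep coverage of a few both raise the score; targets that avoid enriched
pathways contribute nothing, and an ncRNA with no differential targets
scores exactly 0.

Assumptions worth keeping in mind: the score inherits all the biases of the
target map (a permissive target predictor inflates everyone's coverage), it
does not normalize for target-set size (a documented non-goal: the raw
participation degree is the quantity of interest), and the enrichment
p-values entering the weights are treated as fixed quantities, not
re-estimated per ncRNA.

## Pipeline stages and their parameters

**DEG screen.** A gene is differential iff $p < 0.05$ (strict) and
$|\mathrm{log2FC}| \ge 1$ (inclusive). Both thresholds are exposed
(`screen_degs`), and the boundary conventions are deliberate: a gene at
exactly $p = 0.05$ fails, a gene at exactly $|\mathrm{log2FC}| = 1$ passes.

**Enrichment.** Over-representation is tested with the hypergeometric upper
tail $P(X \ge \text{overlap})$ — identical to the one-sided Fisher exact
test — per pathway, with Benjamini–Hochberg correction across all tested
pathways of one collection; pathways with corrected $p < 0.05$ are retained.
The chi-square variant sometimes quoted alongside Fisher's test for ORA adds
no discriminating power at these counts and is not implemented. Correction
is applied per category because the four category scores are defined
independently. The default universe is the collection's annotation universe
(every gene in at least one pathway), the common default of enrichment
tools; a measured-gene universe can be supplied and is used as given.
Pathways overlapping fewer than `min_overlap = 1` DEGs are excluded before
testing; optional min/max pathway-size filters are off by default. A
`correct_length_bias` flag is reserved in the pipeline configuration but
rejects activation: no defined procedure exists for length-correcting an
ORA of an already-thresholded DEG list, and we prefer a loud refusal to a
silent no-op.

**Weights.** The weight uses the pathway's *raw* p-value by default, over
the pathways that passed the corrected-p filter; `weight_p = "adjusted"`
switches to BH-adjusted weights. Both readings of "the pathway's p-value"
are defensible; raw-p weighting preserves more resolution between pathways
that the correction would tie, which is why it is the default. P-values are
floored at 1e-300 before the log so a numerically-zero p cannot produce an
infinite weight.

**Proportion denominator.** "The proportion of the intersection in the
pathway" admits two denominators: the pathway's size in the universe
(default, matching the ratio-to-total-pathway-genes convention used in the
package's pathway-proportion comparisons) or the pathway's DEG overlap
(`denominator_mode = "deg_overlap"`, a strictly larger proportion). The
ambiguity is exposed as a mode rather than buried.

**lncRNA targets.** Direct all-pairs Pearson screening across samples:
a pair is kept iff $|r| \ge 0.90$, two-sided $p < 0.01$ (t-distribution,
$n-2$ df) and BH-FDR $< 0.01$, the FDR being computed over the full family
of pairs tested in the call — the widest, most conservative family. We use
plain correlation screening rather than weighted co-expression module
detection because the threshold triple is the operative, testable criterion
and module topology is never consumed downstream. A perfect $|r| = 1$
reports the smallest positive double instead of $p = 0$. All samples are
used; per-condition sub-setting is left to the caller.

**PPI partition.** Nodes are ranked by degree (distinct neighbours,
undirected, edge scores ignored) and split at the top 20 % (core) and
top 50 % (core + sub-core) using `ceiling` so a one-node network still has a
core. Ties at the boundaries break by ascending node id — the paper-silent
but determinism-critical choice; the same descending-value/ascending-id
rule is used everywhere a ranking is produced (C value, |log2FC|, p-value).

**Increase rates.** `increase_rate(a, b) = (a - b) / b` compares the
C-value group's statistic against a comparator group's. Per-dataset pathway
"efficiency" rates aggregate per-pathway proportions as a ratio of sums,
$(\sum_k c_k - \sum_k o_k) / \sum_k o_k$ — scale-free in the number of
pathways; a mean-based aggregation is equivalent for equal-length inputs
and available via `aggregate = "mean"`. Presentation rounding for 2-dp
report tables is half-away-from-zero on a 1e-9-snapped grid
(`round_half_away`): means of printed 2-dp entries such as 0.605 and 0.845
are exact decimals that binary floating point and round-half-even would
both misprint (0.60, 0.84 instead of 0.61, 0.85).

## The synthetic-data generator

`world_spec()` / `make_world()` produce a complete, seeded study: gene
universe `G0001…`, four pathway collections, an mRNA DE table with planted
DEGs, an ncRNA DE table, a target map, an expression matrix, and a PPI
network, all serializable to the exact formats the readers consume.

The generative design is a two-component mixture built around a **signal
block** of 80 genes (of 600). The planted (truly enriched) pathways — 3 of
20 per category, sizes uniform on 35–60 — are drawn from the signal block,
so they overlap heavily, like nested ontology terms. Signal-block genes are
differential with probability `5 × deg_fraction` (0.5 at the default 0.1);
background genes with `deg_fraction`. Differential genes receive
$p \sim U(10^{-6}, 0.05)$ and $|\mathrm{log2FC}| \sim U(1, 4)$ with random
sign; background genes receive $p \ge 0.05$ so they always fail the screen.
These sizes were chosen once to give the hypergeometric test clear power on
the planted pathways at the stated mixture (recovery of all three planted
pathways per category in ≈99 % of worlds) while a 200-replicate study runs
in well under a minute; they are stated here as the package's simulation
conditions.

The planted ncRNA draws `planted_coverage` (default 0.6) of its 40 targets
from the differential signal pool and the rest uniformly; the 20 decoys
draw uniformly from the whole universe. Decoy target density inside any
enriched pathway is therefore ≈ 40/600, versus ≈ 0.6·40 spread over the
≈ 40-gene differential signal pool for the planted ncRNA — roughly an
order-of-magnitude density advantage, which is what makes top-1 recovery
nearly deterministic at coverage 0.6 and degrades gracefully as coverage
falls (at coverage 0 the planted ncRNA is distributionally a decoy, which
the test suite checks). The ncRNA DE table draws p and fold change from the
same distribution for planted and decoy ncRNAs, so the expression-based
indexes carry *no information* about the planted ncRNA — rank-sum
comparisons against them measure exactly the information added by the
C value.

The expression matrix embeds the planted lncRNA–target pairs at
$r \approx 0.98$ (target = lncRNA profile + Gaussian noise with
$\sigma = \sqrt{1/0.98^2 - 1}$) over 10 samples; all other profiles are
independent standard normals. The PPI network is preferential-attachment
(2 edges per node) over the differential genes, giving the heavy-tailed
degree distribution that makes a degree partition meaningful.

Reproducibility: a single integer root seed; each sub-generator
(pathways, DEG assignment, tables, targets, expression, PPI) re-seeds at a
fixed offset from the root, so adding a new output never perturbs existing
ones. Identifiers are zero-padded, making lexicographic tie-breaks coincide
with numeric order.

What the generator does **not** emulate: the GO DAG (no term nesting beyond
the shared signal block), miRNA seed-match biology, count-level noise or
library-size effects, and correlated decoy target sets. Passing tests on
these worlds therefore demonstrate the pipeline's arithmetic, determinism
and statistical behaviour under the stated mixture — not performance on any
real tissue dataset, where target-map quality dominates.

## Numerical and degenerate-input choices

- All gene/ncRNA identifiers are upper-cased and whitespace-stripped at
  ingestion; matching is exact string equality afterwards. No alias or
  ortholog resolution is attempted.
- Duplicate (ncRNA, gene) target pairs collapse to one, keeping the maximum
  score when scores are present (a predictor may report several sites per
  gene).
- Undirected edges are canonicalized to lexicographic order; self-loops are
  dropped at parse time.
- Out-of-range p-values in input tables are an error, never clamped;
  rows with unparseable numerics are dropped with a counted warning.
- DE ncRNAs missing from the target map score 0 with a warning (an empty
  intersection is well-defined); a missing enrichment category contributes
  0 with a warning.
- Empty enrichment results are valid and give C = 0 for every ncRNA.
- Writers emit sorted, LF-terminated output so reruns are byte-identical.

## Problem sizes in the test suite

Unit and property tests run on worlds of 200 genes, 6 pathways per category
and 10 ncRNAs; the distributional checks use 200 replicates of the default
600-gene world for ncRNA recovery and rank-sum comparisons, 200 small
replicates for lncRNA-target recovery, an exhaustive sweep of every
hypergeometric parameter tuple with universe ≤ 25 against a
binomial-coefficient summation oracle, brute-force C-value recomputation on
random worlds of ≤ 30 genes and ≤ 5 pathways, and partition-size checks for
every network size from 1 to 1000. These sizes are the package's chosen
verification conditions: small enough to run routinely, large enough that
the stochastic bounds (≥ 95 % top-1 recovery, ≥ 90 % rank-sum wins, ≤ 1 %
null admission) are meaningfully exercised.

## Known limitations

- The C value has no significance measure of its own (no permutation null);
  it is a prioritization index, not a test statistic.
- Scores are not comparable across datasets with different enrichment
  depths: more enriched pathways mechanically allow larger sums.
- The proportion-denominator and weight-p ambiguities are resolved by
  defaults, not by evidence; both alternates are one argument away.
- Gene-length bias correction for the enrichment stage is deliberately
  unimplemented (see above).
- GSEA-style ranked tests, topology-aware pathway analysis, and
  ontology-graph propagation are out of scope; gene sets are taken as
  given.
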