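---
title: "Methods: phenotype-guided network and similarity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-guided network and similarity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idphenomics)
```

`idphenomics` implements the statistical chain used to interpret a
genome-scale *Drosophila* eye screen of intellectual-disability (ID) gene
orthologs: quantify behaviour, collapse per-RNAi-line observations into
per-gene phenotype profiles, and then ask three questions about genes that
share a phenotype — do their human orthologs concentrate in particular
tissues, are they unusually interconnected in protein-interaction
networks, and do they cause phenotypically similar human disorders? This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the underlying procedures are
conventionally left underspecified.

## Screen quantification

The phototaxis index of a fly population distributed over the six tubes
of a countercurrent apparatus is the count-weighted mean tube number,
`PI = (Σ i·N_i)/N`, bounded in [1, 6]. Replicate summaries use the sample
(n−1) standard deviation — the three test-day replicates are a sample,
not a population — and a quality-control flag fires above a replicate SD
of 1.2, the maximal accepted per-line spread. Hit calling is strictly
`mean PI < 4` (`pi_threshold`, configurable): the threshold sits several
control SDs below typical control behaviour (PI ≈ 5.2), so the strict
versus weak inequality only matters at an exact-4 boundary, which we
resolve to "not a hit".

Per-gene aggregation follows the *single-hit rule*: a gene receives every
category called in at least one of its lines. RNAi knockdown strength is
variable, and demanding concordance across lines would let one weak
construct veto an efficient one, inflating false negatives. The converse
cost — a single off-target line mislabels a gene — is mitigated upstream
by construct specificity (s19) filtering, which is off by default (inputs
are assumed pre-filtered) but available via `s19_min`; lines with missing
s19 are never filtered out. When a gene has several assayed lines it is a
phototaxis hit if *any* line is, consistent with the single-hit rule.

Major classes: EMD (any of the 13 morphology categories), ERG-defective,
lethal, and NED (no category at all). Only NED is exclusive; a gene can
be EMD and ERG-defective at once. The category vocabulary is closed and
validated at parse time, so typos in input files fail loudly rather than
silently creating new phenotype classes.

## Tissue assignment

EST libraries differ greatly in depth, so absolute abundances are not
comparable between tissues. We therefore rank genes within each tissue
(ascending, ties averaged) and assign each gene the tissue of its highest
rank. The assignment is invariant under any strictly monotone per-tissue
transform — which is also why the question of whether abundances were
first converted to transcripts-per-million is immaterial here. Rank ties
across tissues are broken by declared tissue order and flagged; genes
with all-zero expression have no defined argmax and are reported as
unassigned. Class compositions per tissue are compared by
`fold = (k_A/n_A)/(k_B/n_B)` with a two-sided Fisher exact p-value on the
2×2 table (a chi-squared option exists); the fold is reported as infinite
when the comparison class has zero assigned genes.

## Network enrichment

The interaction graph is undirected, simple, and multi-source: a gene
pair is one "unique connection" no matter how many sources (direct PPI,
interologs, co-purified complexes, genetic interactions) report it;
source tags are retained for provenance only. Self-loops are dropped at
load time.

Homotypic enrichment of a category compares the observed within-set
connection count with the mean of `n_perm` (default 10 000) equal-size
sets drawn uniformly without replacement from a declared universe — by
default the network-present members of that universe, since genes absent
from the interaction databases cannot contribute connections either way
(`restrict_to_network = FALSE` keeps them as degree-0 pool members). The
empirical p-value uses the add-one estimator `(1+#{null ≥ obs})/(n+1)`,
whose floor `1/(n_perm+1)` avoids literal zeros.

The PIE score replaces the uniform null with a degree-matched one:
network nodes are binned into equal-frequency degree quantiles (default
10 bins), and each member of the query set is substituted by a random
gene from its own bin (never by itself within a draw; bins left with a
single member are merged downward with a warning). This confronts the
ascertainment bias that intensively studied genes — disease genes in
particular — have more *reported* interactions: a uniform null would
credit them with enrichment that merely reflects study depth. With one
bin the PIE null reduces to uniform sampling, which the test suite
verifies, and query sets drawn by the matched sampler itself score
PIE ≈ 1.

Homotypic modules are the connected components (size ≥ 2) of the subgraph
induced on one category's genes; pairs count as modules. Because the
subgraph is induced per category, a neighbouring gene with a
non-overlapping phenotype can never join a module. Cross-category module
summaries report the connection count both deduplicated by pair and
once-per-category, since "number of homotypic connections" is ambiguous
when one edge is homotypic for two categories.

## Phenotype similarity

Human gene-to-phenotype annotations over a rooted DAG ontology become
weighted feature vectors in four steps:

1. **Prune** the ascertainment subtree (e.g. the intellectual-disability
   terms, when the gene list was selected on that feature) from all
   direct annotations — and again after augmentation, so excluded terms
   cannot re-enter as ancestors.
2. **Augment**: every ancestor of a direct term joins the vector at
   weight `decay^level`, with `level` the minimal parent-step distance
   and `decay = 0.5` per level by default. Contributions from several
   direct terms sum. Geometric decay encodes that a grandparent term
   ("abnormality of the eye") carries less specific information than the
   annotated term ("retinal dystrophy") but still supports similarity
   between genes annotated in the same region of the hierarchy.
3. **Weight by rarity**: `−ln(g_t/G)` with descendant-inclusive gene
   counts `g_t` (frequency clipped to `1/G`), so ubiquitous terms
   contribute little. The root, carried by every gene, is dropped
   outright — it would only inflate all correlations.
4. **Length-normalize**: direct-term weights are divided by the number of
   direct terms, preventing heavily annotated genes from dominating.

Pair similarity is the Pearson correlation over the union of the two
vectors' terms (absent terms = 0); Spearman is available. A pair with no
variance over its union (e.g. a single shared term) is undefined and
excluded from group means with a count. Group coherence is the mean over
all C(n,2) defined pair scores, tested against `n_samples` (default
1000) uniform equal-size draws from the annotated universe, reporting the
null interquartile range and the add-one empirical p.

Feature over-representation uses the exact hypergeometric upper tail on
descendant-inclusive term membership (a gene annotated to a term is
implicitly annotated to all its ancestors — the standard convention for
ontology enrichment), ranked by p with ties broken by higher fold;
Benjamini–Hochberg q-values are emitted alongside. Top-level category
composition maps each top feature to every root-child it descends from
(features under none land in an "unclassified" bucket) and compares
counts with the plain chi-squared statistic, continuity correction off by
default.

## Synthetic data: what it does and does not emulate

The generators produce inputs with the statistical structure the analysis
assumes, each deterministic under its seed and accompanied by a truth
record sufficient to score recovery exactly:

* **Ontology**: single-root DAG with up to `max_parents` parents per term
  and one marked, self-contained subtree (default 7 terms) for exclusion
  tests.
* **Screen**: planted category groups expressed per line with probability
  `line_efficacy`; PI replicates Normal(true PI, 0.4) truncated to
  [1, 6]. The 0.4 SD keeps control-like genes (true PI 5.2) essentially
  never below the 4.0 threshold while planted phototaxis-defective genes
  (true PI 2–3.5) are reliably called.
* **Network**: Erdős–Rényi background with planted dense modules —
  matching the assumption that phenotype groups carry an interaction
  excess over a sparse background.
* **Annotations**: group members draw a fraction `coherence` of their
  terms from a hidden group pool; at coherence 1 with a pool of
  `terms_per_gene` the group is annotated identically, at 0 it is
  indistinguishable from background.
* **Expression**: log-normal baselines (σ = 1, the heavy right tail
  typical of EST counts) with per-tissue scale factors spanning an order
  of magnitude, so the rank procedures are exercised under both skew and
  library-size imbalance; spiked (gene, tissue) entries are multiplied by
  `foldboost`.

What passing these tests shows is that the machinery is correct and
calibrated under its own assumptions. Real screens and databases add
structure the generators deliberately omit: correlated annotation noise,
degree distributions far heavier than Erdős–Rényi, shared-pathway edges
between categories, batch effects in EST libraries, and hand-curated
orthology. Results on real data therefore inherit the assumptions
discussed above, not the test outcomes.

A note on spike recovery: assigning each gene its top-ranked tissue
necessarily loses a spiked gene when several spiked genes share one
tissue (only one can hold the top rank, and runner-up ranks can be beaten
by chance elsewhere). The high-recovery property (≥ 95%) holds — and is
tested — in the strong-signal regime with at most one spike per tissue
and a clear boost; this reflects the statistic's resolution, not an
implementation artifact.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from `stats::phyper`, which sums the exact
  mass stably on genome-scale backgrounds.
* Fold of a permutation test with a zero null mean is +Inf when the
  observed count is positive, and 1 (flagged degenerate) when both are
  zero.
* Empirical p-values can never be 0 or exceed 1 by construction.
* Ontologies must have exactly one root; multiple roots are a hard error
  rather than patched with a synthetic super-root, because rarity and
  decay weighting are defined relative to a single hierarchy.
* Cycles in OBO input are reported with an offending edge; obsolete terms
  are skipped.
* Tie-breaks are deterministic everywhere (tissue order for rank ties,
  size-then-lexicographic for modules, p-then-fold-then-id for feature
  rankings), so equal seeds give byte-identical outputs.
* All randomness flows through explicit integer seeds; the pipeline
  derives per-stage seeds from one global seed by stage-name hashing, so
  stages can be rerun in isolation and still reproduce the full run. RNG
  state of the calling session is always restored.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances chosen to keep the full suite fast while leaving the
statistical assertions well-powered: networks of 100–300 genes,
ontologies of 30–80 terms, 45-tissue expression matrices of up to 2000
genes, 199–5000 permutations per enrichment in tests (999–10 000 in the
examples and acceptance runs), and 20 seeds for the planted-module
recovery study. All scale linearly in edges × permutations; the defaults
(`n_perm = 10000`, `n_similarity_samples = 1000`) mirror common practice
for production runs.

## Known limitations

* Gene identifiers are treated as exact, case-sensitive strings; no alias
  resolution is attempted, so inputs must use a consistent namespace.
* The degree-matched PIE null conditions on marginal degree only; it does
  not preserve higher-order structure (clustering, assortativity).
* Pearson correlation on sparse weighted vectors is sensitive to vector
  length normalization; the provided `length_norm` default is a
  reasonable convention, not an optimum, and Spearman is available for
  robustness checks.
* The expression model ignores EST library-size variance beyond a static
  per-tissue scale factor; rank assignment absorbs monotone distortions
  but not count noise at very low depth.
* `module_summary` reports both resolutions of the cross-category edge
  count; consumers must choose one explicitly.
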