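---
title: "pathoCNV: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathoCNV: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A diagnostic microarray run returns dozens of copy number variants (CNVs)
per patient, almost all benign. The analyst's question is not "which genes
cause disease X" but "which of *this patient's* CNVs plausibly explain
*this patient's* phenotypes". pathoCNV implements a two-layer classifier
for that question. The first layer scores each CNV-affected gene as
causative or not from its functional profile and the patient's phenotype
terms; the second layer classifies the CNV itself from three features: the
OR of its genes' causative calls, its length, and how often similar
regions appear in benign-variant catalogs.

# Layer 1: the gene classifier

## Semantic similarity over annotation taxonomies

Both the gene-function ontology and the phenotype ontology are DAGs of
terms under "is a" edges; terms annotate targets (genes, or disorders).
After propagating every annotation to all ancestor terms, the information
content of a term `t` is

    IC(t) = -ln( fraction of targets annotated by t )

so rare, specific terms are informative and the root carries none. The
similarity of two term sets is the asymmetric Resnik-style measure

    sim(X, Y) = avg over x in X of max over y in Y of IC(MICA(x, y))

with `MICA(x, y)` the common ancestor of maximal IC. The average runs over
the *first* argument; we keep that asymmetric form exactly (a
`symmetrize` flag exists but defaults off, and nothing in the package
turns it on). Numerical choices, all made once:

* logarithms are natural; the base only rescales a measure used
  comparatively (max/avg),
* a term annotating zero targets has undefined frequency; it gets an `NA`
  sentinel, is never a MICA candidate, and a pair whose only common
  ancestors are such terms contributes 0 ("no evidence"),
* IC ties in the MICA are broken by lexicographically smallest term
  identifier — the IC value, the only quantity consumed downstream, is
  identical either way,
* empty sets score 0, and cross-root pairs in a multi-rooted ontology
  (e.g. the three GO namespaces read from one OBO file) score 0.

## Network expansion of gene features

Gene annotations are first reduced to a slim vocabulary: each term maps to
its nearest slim ancestors by is-a path length, keeping *all* ancestors
tied at the minimal distance (dropping one arbitrarily would lose
information); terms with no slim ancestor contribute nothing.

A gene's feature vector is then widened with the functions of its
interaction neighborhood:

1. the composite interaction network is filtered to its strongest edges
   (default: top 5%, ties at the cutoff kept);
2. edge weights `w` become distances `d = max_w / w`, where `max_w` is the
   filtered network's maximum weight, so the strongest interaction has
   distance 1;
3. Dijkstra's algorithm selects the 30 closest genes around the query; the
   edges among them are kept, and a *sink* node is attached to every
   member that lost a connection in the cut, carrying the summed weight of
   that member's removed edges. The sink models leakage into the rest of
   the network: it is an ordinary bidirectional node for the walk, but is
   never ranked and never contributes features;
4. a random walk with restart at the query (restart probability
   `restart_alpha`, default 0.5; row-normalized transition weights
   including sink edges) gives each member a visiting probability; power
   iteration stops when the L1 change drops below 1e-9 and errors out —
   rather than silently approximating — after 10,000 iterations. Restart
   guarantees a unique query-centered distribution and keeps the sink from
   absorbing the walk. Non-query members are ranked 1, 2, ... by
   descending probability (ties by ascending Dijkstra distance, then gene
   identifier); the query's own rank is 0.

Two feature-weighting systems are implemented. *Network-Uniform* sets
weight 1 on every slim term annotating the query or any of its top-k
ranked neighbors. *Network-Weighted* sums, over the query (rank 0) and its
top-k neighbors, `10^-rank * 10^-tier` per surviving annotation, where the
evidence tier is 1 for experimentally supported annotation codes (EXP,
IDA, IPI, IMP, IGI, IEP, TAS, IC), 2 for computational/inferred ones (ISS,
ISO, ISA, ISM, IGC, IBA, RCA, IEA); no-support codes (ND, NAS, NR) are
dropped entirely. Codes outside these lists are treated as tier 2, the
conservative choice; a missing code (the two-column fixture dialect) is
tier 1 so undocumented fixtures are not damped. One best-tier contribution
is counted per (member, term), so redundant annotation rows never
double-count. The damping applies to the query's own annotations too —
that is what the summation formula says, and we follow it as written.

`k_neighbors` (default 10) bounds which ranked neighbors contribute under
*both* systems; it is the swept parameter of the published neighbor-count
experiment, which found 10 optimal.

## Phenotype-relevance training weights

Gene labels are inherited from their CNV (harmful CNVs do not identify
their causative gene), so most "harmful" gene rows are mislabeled
passengers. To focus training on plausible drivers, each gene `g` of a CNV
in a patient with phenotypes `P` gets a relevance score

    relevance(g, P) = max over catalog entries (g', P') of
                      sim(GO(g), GO(g')) * sim(P, P')

over a catalog of genes with known phenotype associations. If the direct
score is exactly zero, the gene borrows one hop from its subnetwork: the
maximum *direct* neighbor score scaled by `1/d(g, neighbor)`. The scale
factor is the normalized proximity in (0, 1] rather than the raw
`max_w/d` neighbor weight — the raw form could let a borrowed score exceed
the neighbor it came from, and the two differ only by the constant
`max_w`, which cancels inside any max. Fallback consults all subnetwork
members by default (`fallback_scope = "top_k"` restricts it to the ranked
top k); it does not recurse.

Relevance becomes integer copy counts: under *Phenotype-Weighted*
weighting, `ceiling(rel / sum(rel) * 1000)` copies per gene, so each CNV
is represented by just over 1000 training rows; a CNV whose genes all
score zero gets one copy per gene instead, keeping uninformative genes
from flooding the training set. *Phenotype-Uniform* assigns
`ceiling(1000 / n_genes)` copies each. Copies are materialized by row
replication — the instance-weighting mechanism of the original protocol.

The gene model is a Random Forest (100 trees, `sqrt(p)` features per
split, no depth cap, seeded per run — standard defaults of the era's
toolkits, exposed in the configuration) over the slim features plus a 0/1
indicator block covering the cohort's full phenotype vocabulary, with the
patient's terms set to 1.

# Layer 2: the CNV classifier

Each CNV contributes three features:

* `causative_gene` — the logical OR of its genes' Random-Forest calls; a
  gene-less CNV is FALSE;
* `length` — end minus start; coordinates are 0-based half-open (BED
  convention) throughout, so width and length coincide;
* `dgv_frequency` — benign-catalog support: per study, regions are merged
  (overlapping *or touching* intervals union; merging is idempotent and
  preserves covered bases), and every merged region overlapping at least
  50% of the CNV's length (ties included) adds `overlap / length` to the
  sum. Two studies fully covering the CNV give 2.0; a 40% overlap gives 0.

Genes are assigned to CNVs by any overlap of at least 1 bp, the
intersect default of standard BED tooling; the DUP/DEL type is carried
through but is deliberately *not* a classifier feature (the classifier is
defined on exactly the three features above), and benign-region overlap is
type-agnostic by default (`dgv_type_match` exists but defaults off — the
protocol does not state type matching).

The CNV model is Naive Bayes: Bernoulli for the causative flag (with
Laplace smoothing 1 so an unobserved flag value cannot zero a posterior),
Gaussian for `log10(length)` — harmful and benign lengths separate far
better on the log scale — and Gaussian for `dgv_frequency`. Any non-empty
subset of the three features can be selected for ablation comparisons.

# Evaluation protocol

Each run splits the labeled cohort three ways: 50% trains the gene
classifier, 25% tests it and trains the CNV classifier, 25% tests the CNV
classifier. The *balanced* regime stratifies by phenotype with matched
classes: phenotypes are visited in deterministic order, and while one
still has two unassigned cases and two controls, a round of 2+2 is drawn
at random and the whole round assigned to the next pool in a 2:1:1 cycle,
keeping every pool balanced 1:1; CNVs never reached by the sweep sit out
that run (a leftover-inclusion flag is deliberately not offered — the
protocol defines membership by the sweep). The *unbalanced* regime
assigns whole patients to pools in the same cycle, so no patient's CNVs
straddle pools and the cohort's benign excess carries into testing. The
six-column clinical table dialect has no patient identifier, so the
reader accepts an optional seventh `patient` column; the balanced regime
ignores it, the unbalanced regime requires it.

Precision, recall and F on the harmful class are computed per run and
averaged over 20 runs (run i uses seed i unless overridden); runs are
never pooled before computing metrics. Zero predicted positives report
precision 0 with an explicit flag rather than NaN.

# The synthetic cohort generator

`simulateCohort()` builds, as a pure function of its configuration, every
resource the pipeline reads: a rooted function ontology with a slim layer
and diamond multi-parent structure; a small phenotype ontology whose leaf
terms form the patient vocabulary; genes laid out on four toy chromosomes
and grouped into functional modules (one per slim term); evidence-coded
annotations; a complete-graph interaction network in which same-module
pairs carry strong weights and everything else weak background weight, so
the top-5% filter recovers the functional backbone; per-module known
genes linked to a module phenotype in the catalog; disorder annotations
giving phenotype terms their frequencies; benign study regions; and a
labeled CNV cohort.

The planted signal: a configurable number of modules (default 2) are
harmful-associated. A harmful CNV contains at least one planted-module
gene with probability `effect_strength`; benign CNVs avoid planted genes
up to a small contamination rate. Harmful CNVs draw longer log-normal
lengths (`harmful_meanlog = log(3e5)` vs `benign_meanlog = log(6e4)`,
`sdlog 0.5` — the qualitative published length-harm relationship, not
fitted values) and sweep in 1-4 extra positional passenger genes versus
0-1 for benign, reproducing the passenger-dilution problem the relevance
weighting addresses. Spurious annotations (rate `annotation_noise`, up to
two per gene) always carry tier-2 evidence codes: computationally
transferred noise is precisely what the evidence damping exists to
absorb, and a generator that planted noise under experimental codes would
misrepresent that mechanism. Benign CNVs are covered by each of three
benign studies with probability 0.8, harmful ones almost never. The
default benign:harmful ratio is 15, the clinical-regime imbalance;
evaluation fixtures use ratio 1 for the balanced protocol.

What the generator does *not* emulate: realistic genome coordinates or
gene density, breakpoint uncertainty, correlated phenotype comorbidity,
ontology depth (real ontologies are 10+ levels; toys are 3), or
annotation incompleteness that varies by gene popularity. Passing the
recovery tests therefore shows the machinery is wired correctly and can
exploit a function-to-harm association under noise — not that clinical
performance figures transfer.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run the full protocol on a
48-CNV, 48-gene, 24-patient cohort with a 37-term function ontology —
small enough that 20-run experiments finish in minutes on one CPU, large
enough that every stage (subnetworks with ranks, relevance fallback, both
weighting systems, both split regimes) is exercised. The reader and split
protocols are additionally exercised on a synthetic six-column table at
the published cohort scale (2,643 records, 162 harmful, 140 patients).
Oracle-equivalence checks run on over a hundred seeded random fixtures of
8-15 nodes/terms, where exhaustive brute force (Floyd-Warshall, dense
linear solves, quadratic interval scans, exhaustive ancestor
intersection) is feasible and independent of the implementation under
test.

# Known limitations

* Relevance scoring is quadratic in (genes x catalog entries) with cached
  pair similarities; cohort-scale use with a full OMIM-sized catalog
  would need a sparser candidate pre-filter.
* Instance weighting by literal row replication is faithful to the
  protocol but memory-hungry at 1000 copies per CNV; a weights-aware
  forest would be the natural optimization at scale.
* The OR combination of gene calls is known to overcall harmful CNVs;
  probabilistic combination is out of scope here.
* The walk, tie-break and fallback conventions fill gaps the protocol
  leaves open; all are configurable, and the defaults are documented
  above precisely because they are choices, not derivations.
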