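---
title: "Ranking-and-recovery inference of transcription factor regulons"
author: "rankrecover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking-and-recovery inference of transcription factor regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankrecover)
```

## The problem and the model

Given a set of co-expressed genes, which transcription factor (TF)
directly regulates them? `rankrecover` answers this with a
*ranking-and-recovery* strategy: instead of asking whether a motif is
over-represented in the input sequences, it pre-ranks the **whole gene
universe** once per motif (or ChIP track) by how strongly each gene's
regulatory search space supports that feature, and then measures how
early the input set is *recovered* along each ranking. A feature whose
ranking concentrates the input genes near the top is a candidate
regulator, and the genes above the leading edge of its recovery curve
are its predicted direct targets.

This inverts the usual gene-set-enrichment picture: one gene set is
tested against thousands of genomic rankings, rather than many gene
sets against one ranking.

## Stages

### 1. Regulatory search spaces

Each gene's search space is one of three TSS-anchored windows — 500 bp
upstream (`up500`), 10 kb centred on the TSS (`tss10kb`), or 20 kb
centred on the TSS (`tss20kb`, the default used for whole-genome
databases). Windows from alternative TSSs of the same gene are merged
when they overlap; every window is truncated where any other gene's
span intrudes; and coding exons of all genes are subtracted, because
coding conservation would otherwise leak into the motif-conservation
signal. A gene can therefore own several disjoint regions, or none.

Coordinates are 0-based half-open (BED convention) throughout. Two
choices here were genuinely open and are fixed as follows:

* truncation uses the neighbouring gene's full span on either strand —
  the simplest reading of "cut where the neighboring gene begins or
  ends";
* downstream halves of the symmetric windows are truncated by the same
  rule as upstream halves; and fragments shorter than 10 bp are
  dropped, since they cannot hold a binding site.

### 2. Homotypic cluster scoring

Functional binding sites in vertebrates tend to occur in *homotypic
clusters* — several sites of the same motif within a few tens of base
pairs. Each region is scored per motif with a two-state generative
model: background emits bases from a 0-order composition model; the
cluster state emits motif sites (either strand) separated by gaps whose
lengths are geometric with mean `gap_expectation` (default 35 bp). The
region score is the log2 likelihood ratio of the best-scoring cluster
against pure background:

score = Σ site log-odds + Σ gaps [log2 p + g·log2(1−p)] − (−log2 p),

with p = 1/(1 + gap_expectation); the final term is the cluster-opening
cost. The maximum over all clusters is found by dynamic programming
(Viterbi-style max rather than a forward sum over all clusters — a
deliberate simplification that keeps the score exactly checkable by
brute-force enumeration of site placements, which the test suite does
on toy sequences). The score is floored at 0, so every region scores
and no region is discarded by a cluster-score threshold.

Site log-odds use motif probabilities with a pseudocount of 0.375 per
count cell over the background model. The background is estimated from
each scanned sequence by default (local composition, add-one smoothed);
a fixed global composition can be supplied instead, and is what the
strand-symmetry and oracle tests use because local estimation makes the
score depend on the entire sequence, not just the sites. `N` bases are
emitted by both states with equal probability and hence contribute zero
log-odds.

### 3. Cross-species aggregation and ranking databases

Per species, each gene is ranked by its best region's cluster score
(ties get average ranks) and the rank becomes a ratio r = rank/G. The
per-species ratios of a gene are combined by rank order statistics:

Q = K!·V_K,  V_0 = 1,  V_k = Σ_{i=1..k} (−1)^{i−1} V_{k−i}
r_(K−k+1)^i / i!,

the probability of seeing K independent uniform ratios jointly at least
this extreme. Genes conserved near the top of every species' ranking
get very small Q. Species lacking a gene simply reduce that gene's K —
missing orthologs are not penalized with a worst-case ratio. Genes
scoring zero in every species are appended in seeded-random order
("randomly queued"), and q-value ties are broken by a seeded shuffle,
so a ranking database is a deterministic function of (inputs, seed) and
every column is a permutation of 1..G.

ChIP tracks are ranked the same way from a single "species": each gene
takes the maximum peak `signalValue` over peaks overlapping its
regions, genes without any overlapping peak are randomly queued.

The on-disk database is a TSV rank matrix plus a JSON sidecar carrying
the seed, build parameters and a hash of the gene universe; enrichment
refuses to mix databases whose universe hashes differ.

### 4. Recovery, AUC and NES

For an input set of s genes, the recovery curve of a feature counts
c(k), the members found at rank ≤ k. Enrichment is the area under this
curve restricted to the top fraction of the ranking (default 3%,
T = ⌈0.03·G⌉), normalized as AUC = Σ_{k≤T} c(k)/(T·s), so AUC ∈ [0, 1).
AUCs are z-scored **within each feature collection** (motifs and tracks
separately, sample standard deviation) into a normalized enrichment
score; features with NES ≥ 3 (the default threshold) are reported.

Note a structural consequence of z-scoring: with n features in a
collection the largest attainable NES is (n−1)/√n, so the NES ≥ 3
cutoff is only meaningful for collections of a dozen features or more.
The synthetic studies use 50.

### 5. Leading-edge target selection

The reported feature's recovery fraction c(k)/s is compared with a
collection background b(k) = mean over all features of the recovery
fraction plus twice its across-feature (population) standard deviation
— a descriptive envelope of what rankings of this collection do on this
input set. The leading edge k* is the smallest rank below the rank
threshold (default 5000) maximizing c(k)/s − b(k); input genes ranked
at or above k* are the predicted direct targets. If the signal never
exceeds the envelope, no targets are predicted. The rank-threshold
default is a conservative top-of-ranking bound recorded in metadata;
ties at the maximum resolve to the smallest k (the smaller, more
conservative target set).

### 6. Motif-to-TF mapping

Motif collections are much larger than the set of directly annotated
human motifs, so enriched motifs are mapped to candidate TFs over a
heterogeneous graph: motif–TF annotation edges (with the annotated TF's
species), TF–TF homology edges (percent identity) and motif–motif
similarity edges (p-value). A path may use at most one similarity edge
and at most one homology edge — the four admissible shapes are
annotation; annotation+homology; similarity+annotation;
similarity+annotation+homology — which prevents unbounded transitive
chaining through motif space. Edge filters (minimum identity, default
0%; maximum similarity p, default 0.001) apply before traversal.

Candidates are ranked by tier: direct annotations first, then TFs
encoded by a gene of the input set, then homology-derived, then
similarity-derived; within a tier the shortest path wins, then higher
identity, then lower similarity p, then lexicographic TF id (the last
an explicit tie-break the original description leaves unstated).
Tightening the edge thresholds can only remove candidates; in the
corner case of a TF with several similarity paths it can demote a
survivor to a longer path, so the guaranteed invariant is the subset
property plus order preservation among candidates whose best path
survives.

The built-in `motif_similarity()` metric — best mean per-column Pearson
correlation of probability columns over ungapped offsets in both
orientations (≥ 5 overlapping columns), with a column-shuffling
empirical p — exists so the pipeline is self-contained; importing a
precomputed similarity table from a dedicated motif-comparison tool is
the recommended production path.

### 7. Regulons and meta-regulons

Reported features are grouped by their best candidate TF; a TF's
regulon is the union of its features' leading-edge targets, each target
annotated with the number of supporting features. Features with no TF
candidate are kept as orphan regulons — an unannotated motif is still a
finding. Across a batch of gene sets (GMT input), a TF's meta-regulon
counts for each target the number of gene sets in which the TF was
enriched *and* the gene was in its optimal target subset; a target is
counted once per gene set regardless of how many motifs supported it.

For validating predicted targets against an external ranking (e.g.
genes ranked by ChIP peak score), `rank_set_enrichment_test()` maximizes
the unweighted running enrichment d(k) = c(k)/s − k/G and reports the
upper-tail hypergeometric probability of the overlap at the maximizing
rank. The unweighted form (rather than a weighted Kolmogorov–Smirnov
statistic) is the one consistent with a hypergeometric count at the
leading edge. Because k* is chosen to maximize the enrichment, this
p-value is *descriptive*, not calibrated: under a null of random sets
it is markedly anti-conservative, so it should be read as a ranking of
evidence strength, not as a frequentist error rate.

## The synthetic data generator

`simulate_dataset()` creates a complete, fully deterministic study from
a seed: a universe of G genes laid out on one chromosome with spacing
that keeps neighbour truncation out of the picture; one regulatory
region per gene (the annotation reproduces the regions under `up500`
delineation at the default 500 bp region length); a "true" motif with
one dominant base per column at the probability matching a target
per-column information content (default 1.3 bits, length 12); decoy
motifs, half column-shuffles of the true motif (hard negatives with
identical composition) and half Dirichlet-random; planted homotypic
clusters of Poisson(λ)+1 sites (λ = 2) in the regions of the target
genes, sites drawn from the motif distribution on random strands;
orthologous sequences for further species derived by per-base
substitution at 30% outside sites versus 5% inside (mimicking purifying
selection on functional sites — the signal the cross-species
aggregation exploits); a ChIP-like track with strong peaks over planted
regions plus Poisson background peaks; and input gene sets at noise
fractions 0–100%, where noise *replaces* positives at fixed set size so
AUC values stay comparable across noise levels.

Default study sizes (G = 1000 genes, 3 species, 1 true + 49 decoy
motifs, 20 target genes; 200 targets for the noise study, matching a
top-200-targets design) were chosen once as a desk-scale version of a
whole-genome analysis and are what the acceptance studies run.

What the generator deliberately does **not** emulate: indels and
rearrangements (orthology is the identity map, since lift-over is an
input in production use), phylogenetic tree structure (all species
diverge independently from the base), heterotypic clusters,
composition heterogeneity along the genome, and ChIP fragment-level
read noise. Passing the synthetic studies therefore demonstrates the
statistical machinery — ranking, aggregation, recovery, normalization,
target selection — not robustness to alignment error or complex
genome structure.

## Numerical and degenerate-input policy

* Q is clamped to (0, 1]; ratios must lie in (0, 1].
* A degenerate feature collection (all AUCs equal) yields all-zero NES
  with a warning rather than dividing by zero.
* Input genes absent from the universe are dropped with a warning; an
  empty effective set is an error.
* Sequences shorter than the motif score 0 with an empty cluster;
  non-IUPAC characters are rejected; motifs shorter than 4 positions
  are rejected for scoring.
* All stochastic steps (random queueing, tie shuffles, noise mixing,
  simulation) consume explicit seeds; identical seeds and inputs give
  byte-identical databases, result TSVs and manifests, which is also
  why manifests omit wall-clock timestamps by default.

## A short worked example

```{r example}
ds <- simulate_dataset(simulation_config(seed = 7, G = 300,
                                         n_target_genes = 12,
                                         n_decoy_pwms = 24,
                                         n_species = 2))
scores <- do.call(rbind, lapply(names(ds$sequences), function(sp)
  scan_regions(ds$sequences[[sp]], ds$pwms)))
cols <- lapply(unique(scores$motif_id), function(m)
  build_motif_ranking(scores[scores$motif_id == m, ],
                      ds$annotation$gene_id, seed = 7))
names(cols) <- unique(scores$motif_id)
db <- ranking_db_from_columns(cols, "motifs")
res <- run_enrichment(db, ds$gene_sets$noise_000)
res[, c("feature_id", "AUC", "NES", "leading_edge_rank", "n_targets")]
```

The planted motif should be the only feature over the NES threshold,
with most of the 12 planted targets above its leading edge.

## Known limitations

* The cluster score maximizes over site placements instead of summing
  over them, so it is a lower bound on a full forward-sum cluster
  likelihood; scores are comparable across regions but not numerically
  identical to a forward-sum implementation.
* NES depends on the composition of the feature collection; adding or
  removing features changes every NES. This is inherent to the method.
* The leading-edge hypergeometric p is anti-conservative under the
  null (see above) and is not multiplicity-corrected.
* The motif-similarity p-value is empirical (resolution 1/(1+shuffles))
  and column-shuffling preserves column composition only, not
  dinucleotide structure.
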