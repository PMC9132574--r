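---
title: "Methods: validating, classifying and characterizing gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating, classifying and characterizing gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A large fraction of the genes predicted from metagenomes and microbial
genomes cannot be assigned a function. `gcdark` operates on gene clusters
(GCs) — groups of homologous predicted proteins produced by an upstream
clustering tool — and provides the bespoke computational core needed to
(i) validate that each cluster is compositionally and functionally
homogeneous, (ii) partition the validated clusters into four categories
along the known–unknown axis, (iii) aggregate clusters into gene-cluster
communities (GCCs) by remote profile homology, and (iv) characterize their
environmental distribution and phylogenomic signal. External
search/alignment tools are consumed as tabular inputs, never executed.

The four categories are: **K** (Known: consensus domain architecture
contains at least one Pfam domain of known function), **KWP** (Known
without Pfam: no domain annotation but homology to characterized
proteins), **GU** (Genomic Unknown: DUF-only annotation or homologs of
unknown function), and **EU** (Environmental Unknown: no homologs in any
reference).

## Validation

Clusters with fewer than 10 genes are flagged and bypass validation — too
few sequences for reliable intra-cluster statistics. For the rest:

1. **SSN and representative.** A complete sequence-similarity network is
   built over the members (semi-global alignment similarity, BLOSUM62,
   scores clamped positive). The network is trimmed to the edges with
   weight at or above the largest threshold that keeps one connected
   component — equivalently the bottleneck weight of the maximum spanning
   tree, which the test suite verifies against an exhaustive-threshold
   oracle. The new representative is the node maximizing eigenvector
   centrality; ties go to the lexicographically smallest id so the result
   is permutation-invariant.
2. **MSA outlier screen.** Each member's distance to the representative is
   1 minus the fraction of identical aligned columns. Outliers must exceed
   both the Tukey fence (Q3 + 1.5 IQR) and a hard floor of 0.8. The floor
   is our choice (the distance of unrelated random proteins is ~0.95; true
   members in the stated synthetic world sit near the mutation rate, 0.1),
   and the fence alone is not trusted for fewer than 4 sequences, which
   return no outliers. The aligner is an injection point; the bundled
   naive aligner right-pads sequences and is only adequate for
   substitution-only families, which is exactly what the generator emits.
3. **Decision.** A cluster is discarded when its outlier fraction exceeds
   the broken-stick threshold computed over all clusters' outlier
   fractions, or when at least 30% of its members are shadow genes
   (shorter genes overlapping a longer one by ≥ 60 bp on opposite strands
   or ≥ 50% of their length on the same strand). Kept clusters lose their
   individual shadow, spurious and outlier genes.

The broken-stick threshold sorts value shares in decreasing order against
the null expectations $E_k = \frac{1}{N}\sum_{i=k}^{N} 1/i$ and returns
the smallest value whose share still strictly exceeds its expectation.
The deterministic closed form is the default; the resampling variant
(random 80% subsets, rounded mean cut rank) exists behind `n_iter` and
agrees with the closed form within one rank on fixtures.

A separate functional screen shingles each annotated gene's domain
architecture (k = 2), collapses domains to their Pfam clan and strips
N/C/M terminal-variant suffixes, and discards clusters whose median
pairwise Jaccard similarity is below 1. Unannotated genes are excluded
from the median (a cluster with fewer than two annotated genes passes),
and adjacent repeats of one canonical token are merged so that a split
domain is not counted as architecture.

## Classification

Annotated clusters get a consensus domain architecture: per-gene
architectures (consecutive repeats collapsed) are overlaid on a directed
graph with virtual source and sink; each complete gene adds weight 1 to
every transition it traverses, each incomplete gene 0.5 (the upstream
method states completeness is a positive weight without a number; 0.5 is
our choice, exposed as the `complete` argument). The consensus is the
maximum-weight source-to-sink path, ties resolved by complete-gene
support and then lexicographically. All-DUF consensus → GU, else K.

Unannotated clusters go through a nested homolog search: hits within 60%
of the log of the best e-value are retained ($|\log_{10} e| \ge 0.6\,
|\log_{10} e_{best}|$), and a quorum vote over the retained annotations
decides unknown (GU) versus known (KWP). Unknown requires a strict
majority; ties go to known, because unknown status should require
positive evidence — the conservative direction. Clusters with no hits in
either tier are EU. Two refinement screens then re-route: EU clusters
with profile hits at probability ≥ 0.90 are re-voted into KWP/GU; KWP
clusters with Pfam-profile hits at probability ≥ 0.90 and target coverage
> 0.60 move to K (known-function domain) or GU (DUF only). Refinement is
monotone toward "more known" by construction.

High-quality clusters have a complete representative and a complete-gene
fraction above both 1/3 and the broken-stick threshold of the
completeness distribution. The non-redundant architecture set collapses a
fragmented architecture into a larger one when it is a contiguous
sub-architecture, the 3-gram cosine distance of the token strings is
below 0.9, and the fragment's cluster has fewer than 75% complete genes.

## Communities

Profile hits with probability ≥ 0.5 and both coverages > 0.6 become edges
weighted by bitscore / aligned columns. Markov clustering iterates
expansion (matrix squaring) and inflation (entrywise power, column
renormalization) with pruning at 1e-5 until the maximum entrywise change
is below 1e-8 (cap 200 iterations); communities are read off the
attractors. Pruning, tolerance and the self-loop policy (loop weight =
maximum incident weight) are implementation choices exposed as arguments;
the tests pin the behavior to an independent naive dense-matrix oracle.

The inflation grid 1.2–3.0 (step 0.1) is scanned on the Known category
and scored by the unweighted mean of five metrics, each in [0, 1]:
single-architecture community fraction, multi-cluster community fraction,
zero-clan-entropy fraction, normalized intra-community edge weight, and
closeness of the community count to the non-redundant architecture count.
The unweighted mean is our choice — the method description maximizes "the
relationship" of the five properties without a formula. The best Known
inflation is reused for KWP, GU and EU. Orphans (clusters filtered out of
the graph) are rescued in three passes: best qualifying hit under relaxed
thresholds (probability ≥ 0.5, coverage ≥ 0.4, best = highest
probability then highest weight), one repeat pass against the updated
assignment, then singleton communities. Pass 2 uses the relaxed
thresholds as well (the method text does not say; relaxed is assumed).

## Ecology

Cluster abundance is the sum over member genes of per-base coverage
divided by gene length, total-sum scaled per sample. Samples with gene
counts below the first quartile are dropped (type-7 quantiles
throughout). For the distribution calls, samples are grouped by
Bray–Curtis dissimilarity with average linkage; the flat cut maximizes
the mean silhouette over candidate merge heights (singletons score 0) and
groups smaller than 3 are merged into their nearest group by centroid
dissimilarity — a deliberately simpler stand-in for the dynamic
hybrid tree cut, which is out of scope.

Each of `n_datasets` (default 10) random datasets picks one sample per
group; abundances are rescaled to integers (×10^6, rounded) and
randomized into `n_null` (default 100) matrices that preserve both margin
vectors exactly: a random margin-preserving fill (`r2dtable`) followed by
at least 10 × fill random 2×2 swap moves. Levins niche breadth
$B = 1/\sum p_i^2$ of the observed row is compared to the 2.5%/97.5%
null quantiles: Narrow below, Broad above, Nonsignificant otherwise, with
a plurality vote across datasets (ties → Nonsignificant). Clusters with
mean relative abundance below 1e-5 are excluded.

## Phylogenomics

For lineage specificity, every internal node of the genome tree is scored
with F1 = 2PR/(P+R), where recall is the fraction of clade genomes
carrying the cluster and precision the fraction of carrier genomes inside
the clade; the best node breaks ties toward deeper nodes, then larger
clades. A cluster is lineage-specific when best F1 > 0.95, it occurs in
at least 2 genomes, and in fewer than half of all genomes (all genomes,
not per-domain — configurable). The reported rank is the nearest
rank-labelled ancestor of the best node.

Phylogenetic conservation (consenTRAIT) finds the maximal non-nested
clades in which at least 90% of tips carry the cluster; each contributes
its mean root-to-tip depth from the clade root, isolated positive tips
contribute half their terminal branch, and tau_D is the mean
contribution. tau_D scales linearly with branch lengths. The
known-vs-unknown comparison uses the Wilcoxon signed-rank test — the
method description names a "paired rank-sum" test, which is internally
inconsistent; "paired" is taken at face value — pairing known and unknown
tau_D values by rank within each lineage-specificity stratum.

Genomes whose only support for a cluster lies in flagged prophage regions
are removed from that cluster's presence set before these analyses.

## The synthetic stated world

The generator emits every input with planted truth: families are random
root proteins (length 80–400) with iid substitutions at rate 0.1 — at the
high end of what survives 30%-identity clustering but comfortably below
the 0.8 outlier floor — with no indels, 70% complete genes, intruders
inserted at a configurable rate, categories drawn at weights
0.40/0.20/0.25/0.15 (K/KWP/GU/EU), communities of 1–4 families sharing an
architecture, and profile hits only within planted communities.

Narrow clusters place all abundance in one home group (assigned
round-robin so every group hosts some); broad clusters are spread exactly
evenly across samples. The exact evenness is deliberate: with columns
total-sum scaled, every dataset submatrix has equal column sums, so the
null model's rows are maximally even and only an exactly even observed
row can exceed the 97.5% null quantile. Real data reach Broad calls
through uneven sampling margins; a green Broad test here establishes the
quantile machinery, not robustness to margin noise. Similarly, the
generator has no indels, no chimeras and no fragmented-architecture
noise, so green validation tests establish the screening rules, not
performance on real alignments.

Lineage-specific clusters are present in exactly one planted clade (2
tips to just under half the genomes); cosmopolitan clusters occupy at
least 60% of genomes, which by construction exceeds the prevalence bound
— the false-positive check therefore guards the rule's implementation,
not borderline prevalence behavior.

## Numerical choices and degenerate inputs

E-values of 0 are clamped to 1e-308; probabilities above 1 are read as
percents. Eigenvector centrality ties use a 1e-8 band. MCL that fails to
converge in 200 iterations warns and returns the current interpretation.
A single validated cluster has no outlier-fraction distribution, so the
broken-stick discard rule cannot fire. All-zero abundance rows and empty
presence sets are errors, not silent zeros. Seeds: every stochastic
function takes an explicit seed and restores the caller's RNG state.

## Known limitations

The MSA screen substitutes one internal identity-based scheme for the two
external evaluation tools used at scale upstream; supply external
alignments through the `aligner` argument when families have indels. The
silhouette-based sample grouping is not the dynamic hybrid tree cut. The
quorum vote is unweighted by default (`weight_by_bitscore` exists). The
pipeline is designed for desk-scale data (thousands of clusters), not the
hundreds of millions of genes processed by the original workflow.
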