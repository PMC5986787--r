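---
title: "Methods and design of the rootapex pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the rootapex pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootapex)
```

# Scope

`rootapex` implements a complete analysis pipeline for de novo
transcriptomes of root apices sampled across developmental stages — the
setting in which some desert plants (notably many cacti) exhaust their
root apical meristem and switch to determinate primary-root growth. The
pipeline covers expression quantification, exact-test differential
expression, expression profiling (PCA, clustering, GO enrichment),
cross-species orthology, projection of a curated transcriptional
regulatory map, and the triage of candidate lineage-specific transcripts.
Read processing, de novo assembly and annotation services are upstream of
this package: it consumes transcript catalogs (FASTA), count matrices and
annotation tables, and a seeded generator supplies statistically
realistic stand-ins for every input so each stage is testable without
external data.

# Quantification

Counts are normalized as reads per kilobase of transcript per million
mapped reads,

$$\mathrm{RPKM}_{g,s} = \frac{10^9\, C_{g,s}}{N_s\, L_g},$$

with $C_{g,s}$ the read count of transcript $g$ in sample $s$, $L_g$ the
transcript length in nt and $N_s$ the sample's mapped-read total. When
the original mapping totals are unavailable the column sums of the count
matrix stand in for $N_s$; this surrogate is exact for the synthetic
data and standard practice otherwise. Per-stage summaries are arithmetic
means of unlogged RPKM; `log2(RPKM + 1)` is a separate, explicit
transform used only where stated (PCA input, network node attributes),
because the filter cascade below is defined on the raw RPKM scale.

Reference-gene candidates for RT-qPCR are ranked by the coefficient of
variation (sample standard deviation, $n-1$ denominator, over the mean)
of their per-stage mean RPKM, ascending, with a lexicographic
transcript-id tie-break.

# Differential expression

The test is the conditional exact negative-binomial test for two groups
with a single common dispersion $\varphi$ (variance $\mu + \varphi
\mu^2$). Because the conditional argument requires equal library sizes,
counts are first mapped to a common depth — the geometric mean of the
observed library sizes — by quantile matching: the NB$(\mu, \varphi)$
distribution is approximated by a gamma distribution with the same mean
and variance, and each observed count is carried to the count with the
same gamma quantile at the common depth. The common dispersion maximizes
the conditional log-likelihood (each group conditioned on its
pseudo-count total) summed over transcripts, alternating with
re-equalization until stable; under-dispersed data estimate
$\hat\varphi = 0$. On simulated data this estimator agrees with the
established quantile-adjusted conditional maximum likelihood
implementation to well under 1%, and the resulting p-values track it to
a fraction of a percent — that external implementation is used only as a
cross-check in the test suite, never called by the pipeline.

Given group pseudo-count sums $(s_a, s_b)$ with $n_a, n_b$ samples, the
test conditions on $t = s_a + s_b$: each split $k$ of $t$ has conditional
probability proportional to the product of the two group-sum NB
densities (a negative hypergeometric; binomial in the Poisson limit
$\varphi = 0$), and the two-sided p-value sums the probabilities of all
splits at most as likely as the one observed, ties included. Pseudo
counts are rounded to integers before enumeration since the conditional
distribution lives on integer splits; the bias is negligible at the
depths involved. The suite verifies exact agreement (relative error
$< 10^{-10}$) with an independent enumeration oracle for every split
with total $\le 30$ at $\varphi \in \{0, 0.5\}$.

A transcript is called differentially expressed when it passes all of:

* fold change $\ge 2$ in either direction, computed from per-stage mean
  RPKM with no pseudocount (a zero earlier-stage mean yields an infinite
  fold change, which is retained when the other criteria pass and
  flagged, rather than silently damped);
* Benjamini–Hochberg $q \le 0.005$ (the step-up procedure; the
  literature this pipeline follows specifies only "FDR-corrected", and
  BH is the default of the tooling in this field);
* an expression floor of RPKM 3 in the compared stages. Two floor modes
  exist because the field's descriptions of this filter differ between
  a stage-mean and an every-sample reading: `stage-mean` (default)
  requires both per-stage mean RPKM $> 3$; `all-samples` requires RPKM
  $\ge 3$ in every sample of both stages. The default is the more
  permissive reading; both are exposed and tested.

# Expression profiles

**PCA.** Samples are decomposed by SVD after standardizing each
transcript to zero mean and unit variance across samples — the
correlation-matrix convention — on `log2(RPKM + 1)` values (a raw-RPKM
mode is available). Variance fractions are $\sigma_i^2 / \sum
\sigma^2$. For cross-species co-projection the two matrices are
restricted to one-to-one orthologous rows (at least 50, or the
projection is refused as under-determined), each transcript is
standardized *within its species* — which removes species-level location
and scale and is the step that makes the joint decomposition meaningful —
and the concatenated samples are decomposed jointly. This is one
defensible joining procedure among several; a projection of one species
onto the other's components is a plausible alternative the package does
not implement.

**Clustering.** Profiles (per-stage mean expression) are z-scored per
transcript, seeded with k-means++ from a user seed, and refined by Lloyd
iterations (at most 300) to an assignment fixed point. The cluster count
is user-set: at the scale of a real study a few dozen clusters
(e.g. 27) are typical, while the bundled fixtures use $k = 3$ matching
the three planted archetypes (up at terminal, down at terminal, peak at
intermediate). No automatic $k$ selection is attempted.

**Enrichment.** GO over-representation uses the upper-tail
hypergeometric probability with BH adjustment across tested terms; terms
with zero overlap are skipped; the universe is all annotated transcripts
in the expression matrix. Terms are flat labels — no propagation to GO
ancestors — and only over-representation is tested.

# Orthology

The aligner is an affine-gap Smith–Waterman (gap of length $L$ costs
$\mathrm{open} + L \cdot \mathrm{ext}$) in compiled code, with BLAST-like
scoring: nucleotide match $+2$ / mismatch $-3$, gap 5/2, both query
strands searched; translated mode aligns a protein query against all six
frame translations of the target (BLOSUM62, gap 11/1). The best cell and
traceback are deterministic (maximum score, ties to the smallest end
coordinates; diagonal preferred). Raw scores convert to bits via
$b = (\lambda S - \ln K)/\ln 2$ with the standard gapped Karlin–Altschul
parameters for these schemes ($\lambda = 0.625, K = 0.41$ nucleotide;
$\lambda = 0.267, K = 0.041$ protein), and $E = mn\,2^{-b}$ with $n$ the
total database length — no finite-size edge correction, which is
inconsequential at the sequence scales involved and keeps the threshold
semantics transparent.

Orthologue calling is exhaustive all-vs-all (no heuristic seeding — the
catalogs this package targets are small enough that exactness is worth
the quadratic cost). Best hit per query is the maximum raw score, ties
broken by longer alignment then lexicographic id. A pair is
*bidirectional* when each sequence is the other's best hit and both
directions pass the gates: query coverage (aligned query span over query
length — coverage is deliberately defined on the query, the ambiguous
convention resolved explicitly) above 0.40, E-value below $10^{-10}$,
and a domain gate requiring the query's annotated domain set to be a
subset of the hit's (queries without domain annotation pass vacuously).
A passing best hit without reciprocity is reported *unidirectional*;
everything else is *unmapped*. Hits can be exported and re-imported in
the conventional 12-column tabular dialect (1-based inclusive
coordinates in files, 0-based half-open in memory), which also allows an
external search tool to stand in for the built-in aligner.

# Regulatory-map projection

From a curated directed regulator→target map, the subgraph of interest
is the seed genes plus all first neighbours (adjacent in either
direction) with the *induced* edge set — neighbour–neighbour
interactions are kept, which is the reading that preserves the most
curated interactions; a `seed_incident_only` flag provides the stricter
alternative. Projection replaces each source node by its orthologous
transcript; nodes without an orthologue are dropped together with their
incident edges, so the projected edge count can only reach the subgraph
edge count when every node maps. Multi-mapping is resolved by best
supporting bit score with alternates preserved in the output rather than
discarded. Node attributes record the orthology class (bidirectional or
unidirectional) and mean `log2(RPKM + 1)` over all samples (plus
per-stage values), matching how such networks are conventionally drawn
with node size proportional to expression. Weakly connected components
are labelled deterministically (sorted by smallest member id) and the
network exports to SIF, GraphML and a node-attribute TSV for Cytoscape.

# Lineage-specific transcripts

Candidates are the differentially expressed transcripts with *zero*
annotation records from any source — a hit annotated "uncharacterized"
or "hypothetical" still counts as annotated. Candidates are screened
against a second species' transcriptome in nucleotide mode (any hit with
$E < 10^{-10}$ flags conservation within the lineage), and their coding
potential is summarized by the longest open reading frame across all six
frames: ATG through the first in-frame stop, standard code, the stop
*required* — ORFs running off the contig end are not counted, the
conservative choice. Peptide lengths (Met included, stop excluded) fall
into half-open classes $[200,\infty)$, $[100,200)$, $[50,100)$,
$[1,50)$, none; half-open bins resolve the boundary ambiguity of the
conventional "50–100 / 100–200 / >200" reporting so every length maps to
exactly one class.

# The synthetic-data generator

The generator reproduces the statistical and sequence structure the
pipeline assumes, at desk scale:

* **Counts**: negative binomial, $C \sim \mathrm{NB}(L_s q_g, \varphi)$,
  three ordered stages × 2 replicates, library size $10^6 \pm 5\%$,
  log-normal baseline abundances (sdlog 1.5). A `de_fraction` of
  transcripts (default 10%) carries a planted fold change (default 4)
  between the earliest and terminal stage, split evenly between up- and
  down-regulation so library composition stays balanced; nothing is
  planted between the two earlier stages, mirroring how few transcripts
  separate adjacent early stages in real apices. Default dispersion is
  0.01 (biological CV 0.1): each replicate emulates a pool of hundreds
  of dissected apices, which averages away between-plant variation;
  runs that need other noise regimes set `dispersion` explicitly.
* **Catalog**: random ACGT transcripts with lengths uniform in
  [400, 4000] nt (the 400-nt floor mirrors minimum contig length in the
  target assemblies). Planted orthologues are point-substitution copies
  (no indels, so identity-recovery oracles stay exact); a fraction of
  them get a second near-identical reference copy emulating the allelic
  variants of a tetraploid, exercising best-hit tie-breaking; unrelated
  decoys are appended. Planted ORFs have known codon counts drawn to
  match the long/medium/short peptide proportions seen in de novo root
  transcriptomes (~6/28/66%). The GO table plants one enriched term on
  the same DE set the count generator uses.
* **Regulatory map**: seeds, first neighbours attached to seeds, a few
  neighbour–neighbour edges, and decoy components that must not survive
  extraction.

Each generator draws from its own RNG stream (fixed offsets from the
master seed) so adding one generator never shifts another's output.
What the generator does **not** emulate: positional read biases, indels
and chimeric contigs, fragmented or redundant assemblies, GO-term
correlation structure, unbalanced designs, and batch effects. Passing
tests therefore demonstrate correctness of the computations and recovery
of planted structure under the stated model — not robustness to
assembly artefacts.

# Numerical choices and problem sizes

Tolerances: exact-test oracle agreement at $10^{-10}$ relative; RPKM
count conservation at $10^{-9}$ relative; PCA reconstruction at
$10^{-8}$. Dispersion optimization is bounded to $\varphi \in [10^{-6},
4]$ on the log scale with boundary collapse to 0. Ties in exact-test
probabilities are included in the p-value with a $1 + 10^{-12}$ relative
tolerance; k-means++ duplicate centres are jittered by $10^{-6}$.

The bundled analyses use 2,000 transcripts for distributional checks
(calibration, power, dispersion recovery), 50 planted orthologue pairs
with decoys and paralogues for the all-vs-all BBH recovery, 100 random
1-kb sequences for the ORF oracle, and 210 three-stage profiles for
clustering recovery — sizes chosen so every property is measured with
comfortable margins while a full run of the suite stays interactive.

# Known limitations

Tagwise (per-transcript) dispersion, TMM normalization and GLM-based
testing are out of scope, as are read-level simulation, heuristic
alignment seeding for genome-scale searches, HMM/profile homology,
synteny-aware orthology, GO-graph propagation, and network layout. The
fold-change convention (ratio of per-stage mean RPKM) is one of two
plausible readings of how fold changes are computed in the workflows
this package mirrors; the other (normalized-count means) generally
differs by at most the length-normalization constant, which cancels
within a transcript.
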