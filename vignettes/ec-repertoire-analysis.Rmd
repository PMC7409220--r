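---
title: "Comparing the enzymatic repertoire of a culture collection with gut microbiomes"
author: "panEC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the enzymatic repertoire of a culture collection with gut microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panEC)
```

## The question

Bacterial culture collections built over decades of dairy research hold
hundreds of sequenced strains, mostly lactic acid bacteria. A natural
question is how much of the *functional* repertoire of a human gut
microbiome such a collection could, in principle, supply. panEC answers
this at the level of Enzyme Commission (EC) numbers: each strain and each
metagenome is reduced to its set of fully specified EC numbers (its "uEC"
repertoire), and the comparison becomes set algebra — unions
(pan-genomes), intersections (core-genomes), cross-coverages and
metabolic-pathway coverage — with resampling-based significance for
selection heuristics.

## The annotation-transfer model

EC profiles for strains are derived from homology hits of predicted coding
sequences (CDS) against a curated protein database, in four steps:

1. **Filter.** Hits with e-value $\ge 10^{-6}$ are discarded (strict
   inequality). This conventional cutoff keeps only alignments reliable
   enough for annotation transfer.
2. **Cluster.** The remaining hits of one CDS are clustered by DBSCAN on
   the two-dimensional points (percent identity, query coverage) with
   Euclidean distance. Homologs of the same protein family form tight
   blobs in this plane; density-based clustering separates them from
   distant paralog groups without fixing the number of groups in advance.
3. **Assign.** The GO terms of every subject in the cluster containing the
   *best* hit (minimum e-value; ties broken by maximum bit score, then
   lexicographically smallest subject id) are assigned to the CDS. If the
   best hit is a noise point, it is treated as a singleton cluster and
   only its own GO terms are used — a noise point is evidence about the
   best hit itself, not about any surrounding density. GO terms of Pfam
   domain hits passing the same e-value filter are unioned in.
4. **Map.** GO terms are translated to EC numbers through an ec2go-style
   mapping. Partial EC numbers (any field `-`) are dropped, so uEC counts
   are counts of fully specified enzymes; expanding a partial EC to all
   its children would inflate repertoires with enzymes never observed.

Two parameters matter and are exposed everywhere: `eps` (default 5 percent
units) and `min_points` (default 3). Near-identical homologs differ by a
few percent identity/coverage, so a 5-point radius groups them while
keeping well-separated families (tens of points apart) distinct. Identity
and coverage are used on their natural percent scales without rescaling,
since both axes span the same [0, 100] range. We treat the clustering
semantics as part of the method's contract: the implementation is checked
exactly against a brute-force region-query oracle in the test suite.

## Quality control and strain selection

Assemblies are filtered before analysis: flagged strains (legal
restrictions, mixtures, uncertain taxonomy) are removed, as are assemblies
with more than 500 scaffolds or below 90% BUSCO single-copy completeness.
Both thresholds are strict as stated, so a strain at exactly 500 scaffolds
and exactly 90% is retained. Re-sequenced duplicates are resolved in
favour of the better assembly, which we define operationally as fewest
scaffolds, then highest BUSCO, then smallest strain id — scaffold count is
the more direct proxy for assembly contiguity, completeness breaks ties.
A configurable species exclusion list is applied;
`defaultExcludedSpecies()` ships a documented seven-name default for
dairy-relevance filtering. Finally `selectBestPerSpecies()` implements the
stratified selection heuristic: one strain per species, the one with the
most uECs, ties resolved by strain id for determinism.

## Set algebra and pathway coverage

`panGenome()` and `coreGenome()` are plain union and intersection —
deliberately so, since EC sets ignore gene copy number.
`crossCoverage(source, target)` is $100\,|S \cap T|/|T|$ and
`gainIfAdded(addition, base)` is $100\,|A \setminus B|/|B|$; percentages
are reported to users rounded to the nearest integer (`meanPercentage()`,
x.5 rounding up) while raw values are retained internally.

Superpathway coverage of a profile is the fraction of the pathway's
reactions matched by at least one EC of the profile. A reaction annotated
with several ECs counts as matched if *any* is present, because alternate
ECs of one reaction describe the same chemical step. Reactions without EC
annotation remain in the denominator by default: they can never be
matched, so the attainable coverage of such pathways is capped below 1,
which faithfully reflects that EC-based annotation cannot see those steps.
The alternative reading — EC-annotated reactions only — is available via
`denominator = "annotated"`.

Heatmap axes are ordered by agglomerative hierarchical clustering. The
linkage and metric are genuinely free choices here; we use average linkage
on Euclidean distances between coverage vectors (configurable), a robust
default that avoids single-linkage chaining, and export dendrograms as
Newick with merge heights as branch lengths.

## Resampling null and significance

Whether a stratified selection of $k$ strains is *better* than chance is
judged against a null of random selections: each of `n_reps` (default
1000) replicates draws $k$ distinct strains uniformly without replacement,
ignoring species, and computes either the pan uEC count or the mean
superpathway coverage of the pan profile. Sampling without replacement
within a replicate matches the object under study — a *selection* of $k$
distinct strains — rather than a classical with-replacement bootstrap of
the strain list. The observed statistic is standardized by the replicate
mean and standard deviation (n−1 denominator) and assessed against the
standard normal; the default tail is one-sided upper, since the question
is whether a designed selection exceeds random ones, with two-sided and
lower-tail variants available. When every replicate is identical (k equals
the collection size) the null sd is zero and the z-score is refused rather
than fabricated.

Annotation-rate distributions between two groups of genomes are compared
with a Mann–Whitney U test implemented in the package: midrank ties, exact
p by full enumeration when both samples have at most 8 observations, and a
tie-corrected normal approximation with continuity correction otherwise.
The exact branch is validated against an independent enumeration oracle,
the approximate branch against the reference implementation in base R.

## What the synthetic generator emulates

All pipeline stages are exercised on synthetic data with the statistical
structure the analysis assumes:

- **Strains** are species-structured: strains of one species share a
  species core EC set (mean size 800) plus strain-specific accessory ECs
  (mean 150), giving uEC counts in the high hundreds to low thousands —
  the realistic range for sequenced dairy isolates.
- **Microbiomes** are larger EC sets (mean 1600, landing in roughly the
  1400–1800 band typical of annotated gut metagenomes), with a tunable
  fraction (`overlap_fraction`, default 0.89) drawn from the strain
  pan-genome and the rest from outside it.
- Strain ECs are drawn from a designated fraction of the universe
  (`strain_pool_fraction`, default 0.6). Without this, many strains
  jointly saturate the whole universe and no out-of-pan pool would remain
  for microbiomes, making low overlap targets unrealizable.
- **Pathways** draw reaction counts uniformly from 5–40, with 15% of
  reactions unannotated by default, so the coverage cap below 1 is
  exercised.
- **Hit tables** plant isotropic Gaussian blobs (sd 1 percent unit) at
  lattice centres at least 25 units apart — five times the default `eps`,
  so the blobs are provably separable by DBSCAN — truncated to
  $[0,100]^2$, plus uniform noise whose e-values fail the filter. The GO
  set of the blob holding the globally best passing hit is recorded as
  planted truth.
- **Metadata** is sampled so that a configurable fraction of strains
  (default 10%) violates each quality filter and a fraction is duplicated,
  guaranteeing the filter logic is tested non-vacuously.

EC strings themselves are syntactically valid random four-field codes with
no attempt at realistic EC class frequencies: only set identity matters
downstream. The generator does **not** emulate nucleotide sequences,
assembly artefacts, phylogenetic correlation between species, gene copy
numbers, or annotation-quality bias between well- and poorly-studied taxa.
Passing tests therefore demonstrate the correctness of the set algebra,
clustering, coverage and resampling machinery under the assumed structure
— not that real collections will show any particular coverage of real
microbiomes, which depends on the genomes and databases used.

## Problem sizes and numerical choices

The default study scale is 24 species × 5 strains, 4 microbiomes, 190
pathways, and 1000 bootstrap replicates; unit tests run reduced instances
(typically 3–10 profiles, tens of pathways, hundreds of replicates) chosen
so the full suite completes in well under a minute of compute per module.
Stochastic assertions use 3-standard-error bands around binomial or
enumeration-derived expectations, under fixed seeds. All generator
functions save and restore the caller's RNG state, so determinism per seed
never leaks into or out of user code. Floating-point comparisons of
coverage monotonicity allow a 1e-12 slack; set operations are exact.

## Known limitations

EC sets ignore copy number and expression; two strains with identical EC
sets are functionally identical to this analysis. GO terms are not
propagated up the ontology graph before EC mapping, so annotations
attached only to ancestors of a hit's terms are missed. Pathway coverage
ignores topology: a profile covering scattered, disconnected reactions
scores the same as one covering a contiguous chain. The normal
approximation for the selection p-value is a modelling convenience; with
1000 replicates its tail probabilities below about 1e-3 extrapolate beyond
the resampled support.
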