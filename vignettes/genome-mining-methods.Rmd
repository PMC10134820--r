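---
title: "Methods: genome mining analytics for BGC surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome mining analytics for BGC surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcmine)
```

# Scope

`bgcmine` implements the informatic core of a large-scale survey of natural
product biosynthetic gene clusters (BGCs) in a bacterial isolate
collection: MinHash-based genome dereplication and putative-species
delineation, cataloguing of antiSMASH-style BGC regions, region-to-reference
similarity scoring against MIBiG-like reference clusters, gene cluster
family (GCF) membership analytics over BiG-SLiCE-style distances, and
chemical-space-guided molecular-family (MF) networking. What it deliberately
does *not* do: read trimming, assembly, HMM-based BGC detection,
BiG-SLiCE's pHMM featurization (its distance `d` is consumed, never
computed), phylogenetic placement, or figure drawing. Every consumed input
can be simulated by the `generate_*` family with planted ground truth, so
the whole chain is testable offline.

The repository is organised as an analysis workflow: the numbered scripts
under `analysis/` narrate the pipeline over simulated inputs and write
their tables under `results/`, while every computation lives in the
package and is exercised by the test suite.

# Genome sketching and distance

A genome is reduced to a bottom-`s` MinHash sketch of its canonical k-mers
(lexicographic minimum of each k-mer and its reverse complement). Defaults
are `k = 21`, `s = 1000` — the defaults of the Mash tool this stage
mirrors; the survey did not state them, and they are exposed as
parameters. k-mers containing `N` are skipped rather than substituted, so
ambiguous assembly positions never create phantom k-mers.

Hashing is a seeded splitmix64-style 64-bit mixer over the 2-bit-packed
k-mer, with a fixed documented seed (42) and the result truncated to its
top 53 bits. The truncation keeps every hash exactly representable as an R
double (R has no native 64-bit integers); at 53 bits the collision
probability over even a 10-million-k-mer union is below 1e-2 per genome
pair and has no practical effect on Jaccard estimates. Because 2-bit
packing (A<C<G<T) preserves lexicographic order, canonicalization can be
done on packed values.

For two sketches the Jaccard index is estimated Mash-style: among the `s`
smallest hashes of the union, the fraction present in both sketches. When
the union holds fewer than `s` distinct hashes the estimate is exact, and
the test suite verifies exact agreement with a brute-force k-mer-set
oracle in that regime. The Mash distance is

    d = -(1/k) * ln(2j / (1 + j)),

capped at 1, with `j = 0` mapped to the cap; `1 - d` approximates average
nucleotide identity (ANI).

Dereplication clusters the all-pairs distance matrix with average linkage
and cuts at `d = 0.005` (members >= 99.5% ANI), keeping the
lexicographically smallest genome id of each cluster as representative.
Species delineation cuts the same tree at `d = 0.04`; the survey's "96%"
(results) and "4% identity" (methods) phrasings are read as the same
threshold, 96% ANI == distance 0.04. A merge at exactly the cutoff is
kept (`stats::cutree` cuts strictly above the given height), and
agglomeration ties are resolved by `stats::hclust`'s deterministic
smallest-index rule.

# The BGC catalogue

Regions use 0-based half-open coordinates everywhere; converters sit at
the I/O boundary. The region-JSON dialect is a flat array of records with
the fields of `bgc_region()` — a deliberate simplification of antiSMASH 5
output that keeps exactly what the downstream analysis uses
(`contig_edge`, `product`, gene coordinates); `read_antismash_regions()`
extracts the same fields from genuine antiSMASH 5 JSON. Each record also
carries its contig length because the survey's 5,000 bp rule is a *contig*
filter (antiSMASH only processed sequences larger than 5 kb), not a region
filter; `load_regions()` applies it on load and reports exclusions.

Chemical classes follow the packaged product-type table: single product
types map to NRP / Polyketide / RiPP / Terpene / Saccharide / Other; a
region with product types from two different classes is "hybrid", while
several types within one class keep that class. Unknown product types fall
back to Other with a warning rather than an error, since antiSMASH's
vocabulary grows between versions. Completeness equates "complete" with
`on_contig_edge = FALSE` — an assembly-level proxy, not a biological
guarantee.

# Region-to-reference similarity

For a query region and a reference cluster the score is

    score = (# distinct query genes with >= 1 hit to the reference) / denominator,

capped at 1. Distinct-gene counting (not hit counting) makes the score
invariant to duplicated HSPs and is the only reading under which 1 is a
guaranteed maximum. The survey states the denominator two ways: its
methods equation divides by the region's gene count, while its worked
example (4 query genes hitting 4 reference genes giving 4/4 = 1) divides
by the reference side. The package defaults to the methods reading
(`mode = "query-genes"`) and offers `mode = "reference-genes"`, where the
denominator is the count of distinct *hit* reference genes, matching the
worked example's wording; both modes score the worked example 1.0.
`best_reference()` maximizes over references with lexicographic
tie-breaking, and `link_table()` keeps regions whose best score reaches
the cutoff (default 0.2, inclusive — "a similarity cut-off of 0.2" is read
as >=).

# GCF membership

BiG-SLiCE assigns each BGC to its nearest GCF centroid with a distance
`d`; the package classifies `d <= 900` as core, `900 < d <= 1800` as
putative and `d > 1800` as orphan, with both thresholds as parameters
defaulting to the survey's values and boundary inclusivity following the
printed inequalities. Percentages in summaries are rounded half-up to two
decimals, matching the survey's printed style (26.83%, not banker's
rounding). Cross-dataset comparison computes the GCF sets per dataset,
all subset intersection sizes (the Venn counts), and each dataset's
unique-GCF fraction; prevalent GCFs are ranked by the number of distinct
genomes contributing a member BGC with lexicographic tie-breaking.

# Molecular families

Reference compounds are fingerprinted with a Morgan-style iterated
neighbourhood hash (radius 2; 2048 bits — the width is not stated in the
survey and 2048 is the common default, recorded in the output). No
cheminformatics toolkit exists in this R stack, so the package carries its
own small SMILES reader covering the organic subset, aromatic atoms,
brackets with charge/explicit H, branches, ring closures and fragments;
stereochemistry and isotopes are accepted and ignored. Implicit hydrogens
come from standard valences with aromatic bonds counted as 1.5 and the
bond-order sum rounded up; the test suite checks the resulting molecular
formulas of all 24 packaged scaffolds against RDKit as an independent
oracle. One consequence is worth stating plainly: bit values are *not*
interchangeable with RDKit/ECFP bits, so Tanimoto values are internally
consistent but not numerically identical to a toolkit's — all thresholds
in this package are applied to its own fingerprints, and the planted
chemistry of the synthetic library is verified with the same fingerprints
it is analysed with.

Chemical edges connect two references when the *maximum* Tanimoto over
their compound pairs reaches the threshold (default 0.5, inclusive). Max
is the only aggregation that yields one edge decision per reference pair
when entries carry several compounds. The MF network is the union of
genomic edges (query region to linked reference) and chemical edges
(reference to reference); an MF is a connected component containing at
least one query *and* one reference node — a family without a chemistry
anchor is not an MF, and unlinked queries are reported separately. Because
the survey's "288 MFs" figure is ambiguous about whether the size-6
display filter was applied first, `molecular_families()` reports the
component count both before and after `min_size` filtering; `min_size`
only prunes the reported list. `compare_grouping()` quantifies
MF-vs-GCF agreement as the intersection of the query (and reference) id
sets that each scheme co-groups with the other node type.

# The synthetic world

The generators state one fixed world; their defaults are the survey's
conditions where stated and field-plausible choices otherwise, and they
are not tuned against test outcomes:

* **Strain panels.** One root genome; species ancestors diverge from it at
  `between_rate` (default 0.08) and strains from their ancestor at
  `within_rate` (default 0.005), so expected pairwise divergence is about
  twice each rate — comfortably astride the 0.04 species cutoff.
  Genomes are i.i.d. sequences (default GC 0.6, actinomycete-like);
  there are no repeats, so Mash behaves slightly better than on real
  assemblies.
* **BGC collections.** Product types drawn from the packaged survey
  distribution; hybrids (two types) with probability 0.2 (survey: 1,731
  of 8,541 multi-type regions); contig-edge flags Bernoulli at 0.372
  (survey: 3,179/8,541); lengths uniform on 5-60 kb, giving a 32.5 kb
  mean near the survey's 31.9 kb; gene stubs every ~1.5 kb. Genes are
  coordinate+label stubs only — nothing downstream reads sequence.
* **Reference libraries.** Each planted family decorates one of 24
  packaged drug-like scaffolds with short substituents; the planted
  within-family Tanimoto >= 0.5 / between-family < 0.5 structure is
  verified at generation time and violating scaffolds are discarded
  (template exhaustion is an error, not a silent degradation).
* **Hit tables.** A planted link places hits on exactly
  `score x n_genes` distinct query genes, so scores must be realizable
  (`score x n_genes` integral) — unrealizable plants are an argument
  error. Noise links cover strictly less than 20% of a region's genes and
  therefore never cross the 0.2 link cutoff.
* **GCF tables.** Membership strata are a multinomial draw (default
  fractions 5,146/3,073/322 of 8,541) with `d` uniform within each
  stratum; the orphan stratum is capped at `d_max = 3000`, an arbitrary
  but harmless bound since every analysis only compares `d` to the two
  thresholds.

All generators draw from a single RNG seeded per call and restore the
caller's RNG state, so fixtures are reproducible and never leak global
state. A green test on this world establishes that the *analytics* are
correct at the stated parameter separations; it does not establish
robustness to real-data pathologies (repeats, fragmented assemblies,
mis-annotated products, tautomer/charge-state SMILES variants), nor does
it reproduce the survey's headline counts, which would require the
published assemblies, antiSMASH, the BiG-SLiCE model and MIBiG.

# Numerical and degenerate-input choices

* Hashes are 53-bit doubles (see above); sketch files store them as JSON
  numbers at full precision.
* `jaccard()` requires matching `k` and `s`; an all-`N` or too-short
  genome is an explicit empty-sketch error rather than an empty sketch.
* `mash_distance()` treats `j = 0` as the cap 1.0 (disjoint sketches are
  "maximally distant", not an error).
* Cluster ids are contiguous integers from 0 in order of first appearance,
  so outputs are stable across platforms.
* Tanimoto of two empty fingerprints is defined as 0 (references without
  parsable compounds form no edges anyway).
* Percentages round half-up; all printed-style comparisons in tests use
  that convention.
* A region with zero genes cannot be scored (argument error); a region
  absent from the hit table scores 0 with an empty accession.

# Known limitations

* The SMILES dialect omits stereochemistry; enantiomers collapse to one
  fingerprint. For family-level Tanimoto grouping this is immaterial, but
  the parser is not a general-purpose cheminformatics layer.
* Average-linkage clustering materializes the full distance matrix;
  fine up to a few thousand genomes, not for hundreds of thousands.
* `read_antismash_regions()` is a best-effort extractor for the fields
  this analysis uses; it is not a full antiSMASH JSON model.
* The membership stage trusts its input `d` values; no attempt is made to
  validate them against BiG-SLiCE's featurization.
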