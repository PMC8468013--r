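---
title: "Discovering species-specific marker genes and quantifying them by qPCR"
author: "panmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering species-specific marker genes and quantifying them by qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmarker)
```

## The problem

Closely related bacterial species — the *Lacticaseibacillus casei* group is
the motivating case — are hard to tell apart with 16S rRNA sequencing because
their marker loci are nearly identical. A comparative-genomics alternative is
to look at gene *content*: cluster every annotated gene from a cohort of
genomes into ortholog families, and search for a family that every genome of
the target species carries but no other genome does. Such a clade-unique gene
is a natural target for a species-specific PCR assay: design a primer pair
inside it, confirm in silico that the pair can only amplify the target clade,
and calibrate the resulting real-time PCR assay with a standard curve so it
also quantifies the organism.

`panmarker` implements that whole chain as testable R functions plus one
orchestrating pipeline: ingest → ortholog clustering → pan-genome partition →
phylogeny → clade-specificity screen → primer design and in-silico PCR →
standard-curve analysis. A synthetic-community generator with full ground
truth makes every stage verifiable without downloading genomes.

## Ortholog clustering

All genes from all genomes are pooled and clustered by a greedy centroid
(UCLUST-style) algorithm at a global-identity cutoff, by default 50% — the
conventional default for bacterial pan-genome construction. Genes are sorted
canonically (length descending, then genome and gene id, in C locale) so the
result does not depend on input file order. Each gene is compared to existing
cluster representatives in descending shared-8-mer order and joins the first
representative reached at `identity >= cutoff`; after `maxrejects` failed
alignments (default 8, the UCLUST convention) it founds a new cluster.
Candidates whose length ratio alone proves the cutoff unreachable
(`len_short/len_long < cutoff`, since matches cannot exceed the shorter
length and columns cannot undercut the longer) are skipped without cost.

Two consequences of this bounded search are worth knowing. First, the
guarantees that matter — every member is within the cutoff of its
representative, and representatives are mutually below the cutoff whenever
all of them were examined — hold by construction and are tested against a
brute-force all-pairs identity matrix. Second, in pathological inputs where a
gene is within the cutoff of several representatives, the k-mer ordering
(not founding order) decides which cluster it joins; for well-separated gene
families, as in real pan-genomes and in all our fixtures, the two orders
coincide.

### Alignment and identity

Identity is computed from a global (Needleman–Wunsch) alignment with affine
gaps and defined as match columns divided by all alignment columns, terminal
gaps included. The default scoring is match +1, mismatch −1, gap open −10,
gap extend −1 (a gap of length L costs `10 + L`). The stiff gap penalties are
deliberate: with weak ones (say open −2) a global aligner "gap-chases"
isolated matches, and unrelated random DNA then scores 0.45–0.50 identity —
at which point a 50% cutoff stops meaning anything. With the defaults,
unrelated sequences measure ≈0.30–0.40, two sequences independently diverged
at 0.45 substitutions/site measure ≤0.43, and a planted 36%-identity homolog
measures ≈0.36. All scoring parameters are exposed.

Among equal-score alignments the one with the most matches (then the most
paired columns) is reported, so identities are deterministic across
platforms. The aligner is validated against an independent full-matrix DP
oracle and against `Biostrings::pairwiseAlignment` scores.

A conservative k-mer prefilter (`kmer_prefilter()`) is provided
and provably never discards a pair that could reach the cutoff; note that at
permissive cutoffs (0.5) its bound is vacuous and it passes everything — it
only bites near identity 0.9 and above. That is why the clusterer's work
bound comes from `maxrejects`, not from the filter.

Clustering operates on nucleotide CDS by default so that everything
downstream (primer design, in-silico PCR) stays in nucleotide coordinates; a
`mode = "protein"` switch translates genes (standard code, frame 0) and
clusters amino-acid sequences instead, which mirrors how protein-level
pan-genome tools behave. Both modes are tested.

## Pan-genome partition and trees

The clusters × genomes count matrix (paralogs counted; presence = count ≥ 1)
is partitioned into **core** (present in every genome), **unique**
(singleton: confined to exactly one genome) and **accessory** (everything
else). Note the two senses of "unique" in this field: the singleton class
above, versus the *clade-specific* gene the screen looks for (confined to
all genomes of one species). The package keeps them strictly apart. With a
single genome every cluster would be both core and unique; it is reported as
core.

Genome relatedness is summarised two ways, matching the two customary
pan-genome figures: a gene-content tree (Jaccard or Hamming distance on
presence vectors) and a core-genome tree (p-distance over the concatenated
alignment of `n_clusters = 20` randomly sampled single-copy core clusters —
the sample seed is a required, recorded parameter, making the "random"
choice reproducible). Trees are built by classical Saitou–Nei neighbor
joining via `ape::nj` with canonical label order and negative branch
lengths clamped to zero (flagged by a warning). NJ is exact on additive
matrices, which the tests exploit as an oracle: random trees are converted
to distance matrices and must be recovered with Robinson–Foulds distance 0
and exact branch lengths. On low-noise synthetic communities every species
must come out monophyletic in both trees.

## The clade-specificity screen

The screen has two stages, mirroring how such markers are found in practice
(cluster-level presence/absence first, explicit homology search second):

1. **Shared-in-target**: clusters present in *all* target-species genomes,
   absent from *all* other genomes, with every target member at
   `within_identity_min` (default 0.94) or more to the representative —
   the lower edge of the 94–100% within-clade identity band a genuine
   species-wide gene shows.
2. **Cross-homology scan**: each surviving representative is aligned against
   every gene of every non-target genome. The best hit is reported; the scan
   prunes, exactly, pairs whose length bound proves they cannot beat the
   current best or reach `homology_report_floor` (default 0.30 — weaker hits
   are reported as "below floor"). Candidates whose best cross-identity
   reaches `cross_identity_max` (default 0.50, the clustering cutoff) are
   excluded. The published use case saw its marker's closest relative at 36%
   identity; that value is an observation, not a threshold, which is why the
   default exclusion bound is the cutoff and the floor merely truncates
   reporting.

Survivors are ranked for primer-design suitability:
`rank_score = w_gc * gc_penalty + w_len * len_penalty` with unit weights,
where `gc_penalty` is the distance of the representative's GC fraction from
[0.40, 0.60] and `len_penalty` the relative distance of its length from
[300, 2000] nt (zero inside the intervals; length distances are normalised
by the violated bound so the two penalties are on comparable scales). The
weighting is this package's own construction — the motivating study says
only that GC content and length informed the final choice — so both weights
and intervals are configuration.

## Primer design and in-silico PCR

`design_primers()` enumerates every window of the marker satisfying the
primer-level constraints — length 18–24 nt, GC in [0.40, 0.60], Wallace-rule
Tm (`2(A+T) + 4(G+C)`) in [55, 65] °C, no homopolymer run of 5+ — and every
pairing with product size in [80, 200] bp and |ΔTm| ≤ 3 °C. Pairs are ranked
by |ΔTm|, closeness of the product to 130 bp, then a soft preference for
G/C 3′ ends, with positional tie-breaks; the enumeration is verified against
an independent exhaustive oracle in the tests. Product size is the inclusive
span between the two primers' 5′ ends — two 20-mers flanking an 88 nt insert
give 20 + 88 + 20 = 128 bp.

`insilico_pcr()` scans every gene of every genome, on both strands, for
binding sites with at most 2 mismatches per primer and the 3′-terminal 3
bases exact (indels are not modelled — primer binding tolerates internal
wobble far better than 3′ mispairing, and the exact clamp encodes the fact
that polymerase extension fails from a mismatched 3′ end). Any
opposite-strand, inward-facing site pair on one sequence within 3000 bp is a
predicted amplicon. A pair is *specific* when all target genomes amplify and
no non-target genome does. The pipeline walks the ranked pairs and selects
the first specific one — the computational analogue of validating candidate
primers against a strain panel. Predicted product Tm uses the salt-adjusted
duplex formula `81.5 + 0.41·GC% − 675/N + 16.6·log10[Na+]` (default 0.05 M,
reported to 0.5 °C) and is descriptive only, never a pass/fail criterion.

## qPCR standard-curve model

`fit_standard_curve()` is ordinary least squares of Ct on log10
concentration, returned as a classed model object with the standard verbs
(`print`, `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`).
Amplification efficiency is `(10^(−1/slope) − 1)·100`%; a slope of −3.3219
is exactly 100% (perfect doubling). A curve qualifies as *high-efficiency*
when R² ≥ 0.98 and the slope lies in [−3.6, −3.1], bounds inclusive.
Unknowns are quantified by the inverse map `(ct − intercept)/slope`.
`simulate_ct()` generates Gaussian-noise readouts along a known line for
calibration studies; with noise 0.1 cycles over log10 concentrations 3–9 the
refitted slope lands within ±0.05 of truth in well over 95% of runs.

The fit demands ≥3 points and non-degenerate concentrations; a span under
2 log10 units only warns, since the fit is defined, merely weak. Display
rounds efficiency to one decimal; the unrounded value is kept.

## The synthetic community generator

`generate_community()` draws, per gene family, an ancestral sequence at the
target GC (default 0.47, typical of the motivating organisms), then a species
allele by per-site substitution at `between_species_divergence` and a genome
allele at `within_species_divergence` (substitution only by default; an
optional indel rate stresses the aligner). The default community is 9
species — 5 genomes of the target species and 20 non-target genomes — with
120 core families, 80 accessory families assigned to random proper species
subsets, 20 singleton genes, and one planted clade-unique marker
(1200 nt) present in every target genome, plus a homolog at ≈0.36 identity in
one non-target species. Gene lengths are uniform on 250–450 nt: deliberately
below the bacterial average so that desk-scale studies over 100 seeds finish
in minutes; the identity thresholds the pipeline tests are length-free, and
the 1200 nt marker is sized like a real glycosyltransferase gene so that
within-clade identity estimates are stable against binomial noise around the
0.94 threshold.

Two calibration choices need explaining:

* `within_species_divergence = 0.02`: under the per-site collision model
  (`expected_identity()`: `(1−d)² + d²/3`) two genomes of a species then
  measure ≈0.96 identity, i.e. the 94–100% band a species-wide gene family
  is expected to show.
* `between_species_divergence = 0.10` for *shared* families: cross-species
  identity ≈0.81, comfortably above the 0.50 cutoff, so core families stay
  single clusters — which is what makes them core. A per-lineage divergence
  of 0.45 (cross-species identity ≈0.37) describes the relation between a
  clade-unique marker and its nearest foreign homolog, not between shared
  core genes; the generator therefore expresses that regime through
  `marker_homolog_identity = 0.36` rather than through the backbone
  divergence. Had shared families been drawn at 0.45, every core family
  would shatter into per-species clusters, the pan-genome would have no
  core, and every fragment would masquerade as clade-specific — an
  internally inconsistent simulation.

Accessory species subsets never equal the target clade alone (a family
present in exactly the five target genomes would be a second, unintended
clade-specific gene and would make "the planted marker" ill-defined);
single-species subsets are drawn from the non-target species. A requested
homolog identity at or above the clustering cutoff is refused unless
explicitly enabled, because it would merge the homolog into the marker
cluster — that switch exists for tests of the screen's exclusion path.

What the generator does *not* emulate: real genome architecture (operons,
synteny, mobile elements), horizontal transfer, paralog expansions, rate
heterogeneity across sites, and annotation noise. Passing the planted-marker
study therefore shows the pipeline's logic is sound under its stated
assumptions — clade-unique presence with high within-clade identity and deep
cross-species divergence — not that any particular real cohort contains such
a marker.

## Numerical and design choices

* Internal coordinates are R's 1-based inclusive convention everywhere;
  GFF3 input is already 1-based inclusive, and minus-strand CDS are
  reverse-complemented at ingest. Sequences are upper-cased, `U → T`;
  ambiguity codes other than `N` are rejected; `N` matches nothing, not even
  itself, in alignment, k-mer counting or primer scans.
* Species labels are free strings matched exactly and case-sensitively:
  they come from one user-supplied table, and silent case-folding hides
  errors.
* Ties everywhere (clustering candidate order, ranking, primer ordering,
  NJ label order) are broken by explicit deterministic keys; two runs from
  one config are byte-identical, which the tests assert.
* Every random choice is seeded from the run config: the community seed,
  the core-gene sample seed, and the qPCR simulation seed.
* The marker-recovery studies use 100 seeds of the default community and the
  slope-recovery study 200 simulated assays — sizes chosen so the whole
  validation suite runs on a laptop in well under half an hour.

## Command-line entry point

`exec/panmarker` is a thin wrapper over the package: `panmarker all --config
run.yaml [--seed N] [--out DIR]` runs the full pipeline, `simulate` writes a
synthetic community, `qpcr --observations ct.tsv` fits a standard curve.
Exit codes are 0 (success), 1 (domain error), 2 (usage error). Per-stage
re-execution is deliberately left to the R functions (`greedy_cluster()`,
`build_pan_matrix()`, `screen_markers()`, …), each of which reads and writes
plain TSV/Newick/FASTA artifacts, so a shell layer per stage would add
nothing but indirection.

## Known limitations

* The in-silico PCR surrogate ignores primer–dimer and hairpin
  thermodynamics, degenerate bases, and amplification from unassembled or
  intergenic sequence (it scans annotated genes, which is also all the
  synthetic communities contain).
* The homology scan runs against the supplied genome set only; it replaces,
  and does not approximate, a search of comprehensive public protein
  databases. A marker that is "specific" within the cohort may still have
  relatives outside it.
* Greedy centroid clustering is order-canonical but not globally optimal;
  at extreme parameter settings (cutoff near the identity of unrelated
  sequences) cluster boundaries are scoring-dependent.
* The paper-scale pan-genome counts (tens of thousands of clusters from a
  hundred-plus assemblies) are reproducible in structure but not in number
  from synthetic communities; they depend on the real cohort and annotation
  pipeline.
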