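---
title: "Phasing, dosage and dating in complex polyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing, dosage and dating in complex polyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphase)
```

## The problem

Allopolyploid genomes are mosaics of chromosomes inherited from two or
more ancestral species.  An octoploid forage grass with 2n = 8x = 48
chromosomes and three ancestries (A, B, C) poses four linked questions
that this package answers at desk scale:

1. **How many chromosomes are there?**  If single-copy markers each
   align *m* times in an assembly, and the lineage's base chromosome
   number is *x*, the expected karyotype is *m·x* chromosomes
   (`count_marker_copies()`, `modal_copy_fraction()`,
   `estimate_chromosome_number()`).
2. **Which chromosome came from which ancestor?**  K-mers amplified by
   lineage-specific repeat variants mark each subgenome;
   `phase_subgenomes()` clusters chromosomes on these *differential
   k-mers* (`count_kmers()`, `find_differential_kmers()`).
3. **How do fragmented contigs become chromosomes?**  Synteny to a
   reference (or to a fused-karyotype surrogate built with
   `build_fused_reference()`) anchors contigs; only uniquely linked
   alignment chains are trusted (`chain_alignments()`,
   `filter_unique_links()`, `anchor_contigs()`, `apply_agp()`).
4. **What is the subgenome dosage of other accessions?**  Competitive
   ("top best") read assignment sorts reads into their subgenome of
   origin; integer chromosome counts are fitted to the read shares
   (`competitive_assign()`, `coverage_table()`, `infer_composition()`).

A fifth, orthogonal question -- **when did each repeat family
amplify?** -- is answered by LTR insertion dating: the two long terminal
repeats of a retrotransposon are identical at insertion and diverge
independently afterwards, so an element's age is `T = d / (2 mu)` with
`d` the corrected LTR-pair distance (`ltr_p_distance()`,
`jc_correct()`, `insertion_age()`, `subgenome_age_profile()`,
`family_enrichment()`).

Every stage is driven and verified by a synthetic polyploid generator
(`simulate_tully()` and friends) that emits full ground truth.

## The synthetic polyploid generator

The generator is first-class, tested code; its defaults define the
study conditions of the package's tests.

**Ancestries.**  `simulate_ancestral_genomes()` draws a random root
sequence per base chromosome (x = 6 of 100 kb each by default) and
derives one copy per lineage by i.i.d. substitutions along a star tree.
Branch proportions are solved in closed form: a single round of
substitution at proportion *p* per branch composes between two tips as
`u + v - (4/3)uv`, which becomes additive under
`g(p) = -(3/4) log(1 - 4p/3)` -- the same transform as the
Jukes-Cantor correction.  The default divergence map (A-B 3%, A-C and
B-C 12%) makes A and B recently diverged relative to a distant C, the
configuration in which subgenome phasing is interesting.  Divergences
at or above 75% are rejected as saturated.

**Repeats.**  `insert_repeats()` splices LTR retrotransposon copies
into the ancestral chromosomes.  Each family has one consensus, but the
copies inserted into a lineage derive from a *per-lineage variant* of
that consensus, drifted by the same branch divergences as the host
genome.  This is the decisive modelling choice: different base
chromosomes are unrelated random sequences, so single-copy regions
cannot carry ancestry-wide k-mer signal -- exactly as in real genomes,
where subgenome-diagnostic k-mers derive from repeats that amplified
after the lineages split.  It also makes phasing degrade honestly: as
the A-B divergence is dialled down to the haplotype level, the family
variants merge and the A/B partition becomes unrecoverable (a property
the test suite asserts).  Each copy's two LTRs start identical and are
independently mutated by `mu x age` substitutions per site, with the
age drawn per copy (defaults: young A/B families at 0.75-1 Myr, old
C-restricted families at 4-4.5 Myr; `mu = 1.3e-8`/site/year, a common
grass rate).

**Composition.**  `compose_polyploid()` emits one chromosome per
haplotype copy requested by a `polyploid_spec()`, named
`chr{base}{ancestry}{hap}`, each mutated by the haplotype divergence
(default 0.5%; the intra-subgenome allelic distance is a free parameter
of the model, chosen an order of magnitude below the closest
inter-subgenome distance).  `tully_spec()` encodes the octoploid
fixture: AABBBBCC for base chromosomes 1-4 and AAABBBCC for 5-6, i.e.
14A + 22B + 12C = 48.

**Substrates for the pipelines.**  `fragment_to_contigs()` partitions
chromosomes into contigs (exact truth AGP retained);
`simulate_reads()` samples error-prone paired reads uniformly per
chromosome so subgenome read shares mirror dosage;
`plant_markers()` overwrites one copy of each marker onto every
haplotype copy of its home base chromosome, so a marker's true copy
number equals the base chromosome's total dosage (8 on every base
chromosome of the octoploid fixture).

**What the generator does not emulate:** indels and structural
variation (substitution-only by default), recombination, sequencing
error profiles beyond uniform substitution, GC and mappability biases,
centromeres/telomeres, nested or truncated repeat insertions, and gene
content.  Passing tests therefore demonstrate the correctness of the
algorithms under clean, known conditions -- not robustness to every
artefact of real data.

## Differential k-mer phasing

`count_kmers()` builds a sparse chromosomes-by-k-mers matrix of
canonical (strand-folded) k-mer counts, normalised to occurrences per
Mb; `k = 15` by default (odd, so a k-mer never equals its own reverse
complement).  A k-mer is *differential* when its best cluster-mean
count is at least `fold_q = 2` times the second best and at least
`min_count = 2` per Mb.  The count floor is what removes
haplotype-private k-mers: a k-mer present in one chromosome of a
14-chromosome cluster dilutes to 10/14 < 2 per Mb on the fixture.

`phase_subgenomes()` iterates: initial centroid clustering on the
10,000 highest-variance k-mer columns (no homologous groups need to be
known a priori), then alternately recompute differential k-mers from
the clusters and re-cluster the chromosomes on the differential
submatrix (capped at the top 50,000 k-mers by enrichment) until the
partition stabilises.  k-means runs with 10 seeded restarts on the
distinct rows (duplicated chromosomes are assigned to their nearest
centre afterwards), so results are deterministic given `seed`.
Reported alongside the labels: per-chromosome silhouette widths, an
average-linkage dendrogram on the Jaccard distance of differential
k-mer presence/absence, and a 2-axis PCA ordination.  Non-convergence
within `max_iter` returns the last labels with a warning and
`converged = FALSE`.  Cluster letters are assigned by order of first
appearance along the input, and every partition-level result is
invariant to relabelling.

## Ploidy from marker multiplicity

`count_marker_copies()` is seed-and-extend: exact 15-mer seeds every
10 bp (both strands) located with a `PDict`, candidate loci opened
where at least 3 seeds co-project, then verified by local pairwise
alignment at `min_coverage = 0.9` of the marker length and
`min_identity = 0.9`.  Overlapping verified loci (≥ 50% of the shorter
interval) collapse to one.  These thresholds are module parameters,
deliberately permissive enough to count 0.5%-diverged haplotype copies
as the same marker while rejecting chance seed hits.  The histogram's
mode (ties broken towards the larger copy number, since collapsed
haplotypes are the common failure mode of assemblies) times the base
number x estimates the chromosome count: a modal multiplicity of 8
with x = 6 gives 48.

## Synteny scaffolding

Contig-to-reference alignment is delegated to minimap2 (`-x asm5`,
primary alignments only); everything after the PAF is this package.
Greedy colinear chaining per (contig, chromosome, strand) tolerates
gaps up to 100 kb and discards chains below 10 kb of aligned bases.
The unique-link rule is a two-pass automation of manual AGP curation:
drop every chain whose contig appears in more than one chain, then
drop every chain whose target window overlaps another's.  Retained
contigs are ordered by chain midpoint, oriented by chain strand, and
separated by 100 bp scaffold gaps (`U` records, evidence
`align_genus`) in an AGP v2.1 plan; coordinates are 0-based half-open
in memory (PAF convention) and 1-based inclusive on disk (AGP
convention).  Primary-only alignment matters: with secondary hits, a
contig from one haplotype also aligns to its 0.5%-diverged homologs
and every link would be discarded as ambiguous.
`build_fused_reference()` constructs karyotype surrogates (e.g. a
9-chromosome relative collapsed to x = 6 by fusing 1+7, 2+4, 5+6) with
an exact, bijective coordinate liftover.

## Competitive read assignment and composition

A read pair is scored against each chromosome by the number of shared
canonical 21-mers over both mates and assigned to the top-scoring
chromosome ("top best"), requiring at least `min_shared = 10` shared
k-mers.  Ties -- typically among near-identical haplotype copies -- are
resolved by an unbiased deterministic hash by default.  The
alternative strict rule (`ties = "unassign"`) discards tied pairs, but
this systematically deflates subgenomes with more haplotype copies
(the probability that a pair sees no discriminating site grows with
copy number), which visibly distorts dosage at 0.5% haplotype
divergence; the default mirrors the unbiased tie resolution of a
"top best" aligner, which is what makes read shares track chromosome
dosage.  `infer_composition()` converts shares into integer
chromosome counts summing to N by largest-remainder apportionment,
verified optimal by a +-1 local search on the L2 residual, and formats
the result as a genome formula (`AABBBB`) or aneuploid notation
(`14A 22B 12C`) with a dosage ratio string (`1A:2B`).  Percentages are
rounded half-up, the convention used for printed coverage tables.
RNA-seq pairs are accepted as plain reads; no splice awareness is
attempted, and expression imbalance between alleles is a documented
source of noise for RNA-based dosage.

## LTR insertion dating

`ltr_p_distance()` compares the two LTRs of an element (site-by-site
when equal length, after global alignment otherwise);
`jc_correct()` applies d = -(3/4) ln(1 - 4p/3), with saturation
(p >= 0.75) an error; `insertion_age()` returns T = d/(2 mu).  A
Kimura 2-parameter correction is available behind
`estimate_ltr_ages(model = "K2P")`.  Because the choice of mu is
external, absolute ages are only as good as the rate; the defensible
outputs are *relative* statements (e.g. the C subgenome's insertions
older than A's and B's), which is how the test suite uses them.  Note
that elements extracted from composed haplotypes
(`extract_ltr_elements()`) carry roughly 2 x the haplotype divergence
of extra LTR-pair distance on top of the age signal (about +0.2 Myr at
the defaults); the generator's insertion truth records the LTRs as
aged at insertion time, which is what accuracy checks use.
`family_enrichment()` tests each family x subgenome cell with the
hypergeometric tail probability under the null that family labels are
permuted among elements (so a singleton family's p-value is simply the
subgenome's element share), with Benjamini-Hochberg adjustment across
cells.

## Numerical and design choices

* Half-up decimal rounding (`round_half_up()`) everywhere percentages
  are printed; sums of rounded percentages are asserted to 100 ± 0.02.
* k-mer columns are exact 2-bit integer codes for k <= 25 (decode with
  `decode_kmers()`); k of 27-31 falls back to string columns.
* `infer_composition()` tie-breaks equal remainders towards the larger
  quota, and `modal_copy_fraction()` towards the larger copy number.
* Orientation of an anchored contig comes from its single retained
  chain, so orientation ties cannot arise after unique-link filtering.
* Apportionment, chaining, filtering and AGP application are pure
  functions of their inputs; the only RNG-dependent stages are the
  generator and k-means seeding, both governed by explicit seeds.

## Problem sizes used by the test suite

Most unit tests run on a 20 kb-base-chromosome version of the
octoploid fixture (48 chromosomes, ~1.4 Mb genome).  The heavier
end-to-end checks use the full default fixture (100 kb base
chromosomes, ~7 Mb with repeats) for phasing recovery and scaffold
round-trip, and twenty 20x-coverage replicates of a hexaploid AABBBB
accession on 20 kb base chromosomes for composition recovery.  These
sizes are the package's chosen desk-scale stand-in for a multi-Gb
genome: large enough that every statistical property under test is
well inside its tolerance, small enough to iterate on.

## Known limitations

* Phasing presumes repeat-derived subgenome signal; a polyploid whose
  subgenomes share all repeat families at equal abundance (or a
  repeat-poor genome) will not phase by differential k-mers, in this
  package or in general.
* The unique-link filter trades completeness for safety: repetitive or
  chimeric contigs are left unplaced rather than risk misjoins.
* Composition inference reports an L2 residual but no uncertainty
  interval; replicate-level variability is the test suite's proxy.
* Marker copy counting is not an orthology search: markers are taken
  as given sequences, and paralogous families would inflate counts.
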