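---
title: "Detecting RNase III-cleaved small dsRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNase III-cleaved small dsRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcscan)
```

## The biological setting

Bacterial genomes are pervasively transcribed on both strands. Where a
sense transcript and an overlapping antisense transcript (asRNA) coexist,
their overlap is fully complementary and can anneal into long
double-stranded RNA (dsRNA). RNase III, the bacterial dsRNA
endoribonuclease, digests such duplexes into short fragments, leaving the
enzyme family's signature geometry: a 2-nt 3' overhang at every cleavage
point. Exhaustive digestion yields ~14-bp products in Mg2+ conditions,
while Mn2+ conditions (and Dicer-family enzymes) yield ~21-bp products.
Ectopically expressed *Tombusvirus* p19 binds perfectly paired ~21-22 bp
duplexes with high affinity and thereby stabilizes RNase III decay
intermediates in vivo, so deep sequencing of p19-captured small RNA
converts a very labile class of molecule into a mappable signal.

`dcscan` implements the computational side of that experiment as a reusable
pipeline: read preprocessing and exact mapping, strand-specific coverage,
cluster calling, duplex (cleavage-site) detection, positional nucleotide
composition profiling, per-gene sense/antisense quantification, and
overlap/density statistics against external feature sets. A fully seeded
synthetic-data generator produces genomes, overlapping transcript pairs,
digestion products, captured duplexes and reads with complete ground
truth, so every stage is testable without external data.

## The duplex signature

The central object is the duplex site. After collapsing alignments to
unique placements with RPM (reads per million aligned reads) abundances,
`find_duplexes()` pairs a plus-strand read occupying `[a, a + L)` with a
minus-strand read occupying `[a - 2, a + L - 2)`, both of the same length
`L` in {21, 22} and both at >= 1 RPM. The 2-nt offset leaves a 2-nt 3'
overhang at both ends of the implied duplex - precisely the RNase III
signature - and the paired region is `[a, a + L - 2)`. Blunt, coincident
opposite-strand reads (offset 0) are never paired. Relevant choices:

* **Homotypic lengths.** Both strands must have the same `L`;
  21/22-mixed pairs cannot carry 2-nt overhangs at both ends. A
  `require_equal_length = FALSE` flag relaxes this by one base for
  exploration.
* **RPM boundary.** The threshold is inclusive (`>= 1` RPM), with a
  `strict` flag for `> 1`.
* **Chained products.** Consecutive cleavage products share a cut;
  every geometric pair is reported independently, with no de-chaining.

`collapse_unique()` + `find_duplexes()` run in near-linear time via a
keyed join on expected partner placements; the test suite holds them to
exact agreement with an exhaustive all-pairs scan on hundreds of random
instances, including instances of 2,000 unique reads.

## Cluster calling

A dsRNA cluster is a genomic region containing at least `min_reads` reads
(default 2,000; both strands pooled) whose 5' ends fall within some
200-bp window, windows taken at every base offset. Reads are localized by
their 5' end - the position anchored by the cleavage chemistry - and the
reported cluster interval is the *tight span* of the 5' ends assigned to
the run of qualifying windows, not the window union. This is why a
cluster can be far narrower than 200 bp: a hard threshold met by a pocket
of reads spanning 34 coordinates reports those 34 coordinates. Qualifying
windows whose intervals touch or overlap (gap <= `merge_gap`, default 0)
merge into one cluster. The threshold is strict: 1,999 reads in the best
window yield nothing. An RPM-based threshold (`min_rpm`) is converted
with the library size at call time. The sweep implementation (cumulative
sums over 5'-end counts) is tested for exact equality against explicit
enumeration of every window offset, and for the containment property that
raising the threshold only shrinks clusters into lower-threshold ones.

Clusters are ranked into deciles by total RPM (`rank_deciles()`, sizes
differing by at most one, coordinate tie-break) for abundance-stratified
comparisons with external data: interval overlap (`overlap_count()`,
`decile_overlap()`), TSS proximity within a +-50-nt flank
(`tss_proximity()`), and read-density contrasts (below).

## Positional composition and the region map

`positional_gc()` profiles %GC per position over reads of fixed length
`L` plus 10-nt genomic flanks, in the read's own 5'->3' orientation
(minus-strand records are reverse-complemented, so position semantics
match the cleavage geometry on the read's strand). Read positions are
1-based `1..L`; flanks are `-10..-1` and `L+1..L+10`. When the RNase III
double-cleavage geometry is modeled onto this coordinate system the
positions partition exactly into:

| region | positions (L = 22) | expectation |
|---|---|---|
| body | 4..17 | GC-enriched in p19-captured RNA |
| partner-strand overhang | -2, -1 | GC-rich |
| this-strand overhang | 21, 22 | GC-rich |
| cleavage flanks | -5..-3, 1..3, 18..20, 23..25 | AU-rich |
| background | remaining flank positions | genomic average |

For `L = 21` the body is 4..16. Half of each AU-rich flank lies outside
the read itself, which is what makes the pattern attributable to cleavage
preference rather than to cloning or sequencing bias. `region_summary()`
averages the profile per region; `compare_body_gc()` compares
per-sequence body GC between two read sets with a two-sided Mann-Whitney
U test (chosen because body GC fractions are bounded, granular and
non-normal; the original comparison of capture pools reports only a
p-value threshold, not a test statistic). Weighting is selectable:
`unique` (one vote per unique sequence) or `abundance` (weight = read
count); unique weighting is the default for cleavage-site work, abundance
weighting for library-level profiles.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth at every stage.

**Loci** (`plant_loci()`). Four overlap architectures are planted on a
random genome (default GC 0.508, the E. coli genome average): `divergent5`
(transcripts overlapping at their 5' ends), `convergent3` (3' ends),
`full_overlap` (asRNA contained in the sense transcript), and `novel_as`
(same geometry, but the asRNA is withheld from the annotation, emulating
an unannotated antisense unit). The overlap length is exact by
construction; non-overlapping extensions default to 100 nt.

**Digestion** (`digest_duplexes()`). The enzyme is modeled as sequential
5'->3' cutting along each duplex molecule. Inter-cut spacing is
`round(Normal(mean, sd))`, clamped to >= 6, with the mean set by the
divalent-cation mode: 14 (`mg`) or 21 (`mn`), sd 2. The realized cut is
drawn among candidates within +-3 of the sampled spacing with probability
proportional to `exp(beta_site * score)`, where the score rewards AU in
the two 3-nt windows flanking the scissile bonds and GC in the 2-nt
overhang - the empirically observed preference pattern (both enrichments
are ~60% in the real libraries). `beta_site` defaults to 2, which
produces clear hot spots and ~60% enrichments without collapsing cutting
onto single positions; it is a free shape parameter, not a fitted value.
Each cut severs the two strands offset by 2 nt, so every internal product
is a perfect duplex with 2-nt 3' overhangs; the two terminal fragments of
each molecule carry only one cut end, are flagged non-duplex, and are
never captured. An `overhang = 0` setting produces blunt products as a
negative control.

**Capture** (`p19_capture()`). Each internal product is retained with
probability proportional to `length_weight[L] * exp(beta_body * bodyGC)`.
The default length weights put all mass on 21-22 bp; `beta_body`
(default 1) encodes p19's mild preference for GC-rich duplex bodies. The
published data bound the effect (captured body GC ~53-56% vs ~48-49% in
the digestion pool) but not the coefficient, so `beta_body` is a free
parameter chosen to reproduce a shift of that order. Retention
probabilities are normalized by the maximum attainable weight; only
relative capture rates are identifiable.

**Read emission** (`emit_reads()`). Per captured placement with molecule
count `m`, strand read counts are `Poisson(m * b)` and `Poisson(m / b)`
with `log(b) ~ Normal(0, strand_bias_sd)` per unique sequence - the
per-sequence cloning strand bias that makes real sense/antisense counts
at a hot spot unequal. Reads are exact genomic substrings
(reverse-complemented on the minus strand) written as Q40 FASTQ;
sequencing errors are not simulated because the downstream mapper is
exact-match and error modeling is a non-goal. Background noise is
`noise_read_count` single-stranded reads of length 18-30 placed
uniformly - a structure-free stand-in for RNase III products of
stem-loop RNAs, which are not perfectly paired and are not captured by
p19.

**Determinism.** One config seed fans out to fixed per-stage seeds
(genome, digestion, capture, emission), so an identical configuration
reproduces byte-identical FASTQ and truth tables while stages remain
individually re-runnable.

### What the generator does and does not emulate

It reproduces overlap geometry, cleavage geometry and sequence
preference, length selection, body-GC capture bias, strand bias, and
uniform background. It does not model RNA secondary structure, imperfect
duplexes, rRNA precursors, transcription dynamics, adapter chemistry or
platform-specific base-composition bias (the real SOLiD/Illumina body-GC
discrepancy is out of scope). Tests passing on synthetic data therefore
validate the pipeline's statistical machinery and geometry handling, not
the biology of any particular locus in real libraries.

## Numerical and design choices

* **Coordinates.** 0-based half-open everywhere internally (BED/bedGraph
  convention); 1-based inclusive only in report tables and the cleavage
  TSV.
* **Mapping.** Exact, unique matching (both orientations considered
  jointly); multi-mapping and unmatched reads are dropped and counted.
  Synthetic reads are error-free, and duplex geometry requires exact
  placements; real data can enter as SAM from any aligner instead.
* **RPM denominator.** Genome-aligned reads, not raw reads; flagged as an
  interpretation since the original description does not specify it.
* **Gene counting.** A read is assigned to every gene containing its
  midpoint (`floor((start+end)/2)`); midpoint assignment is unambiguous
  for ~21-nt reads and avoids double counting at gene boundaries. An
  any-overlap mode is available behind a flag. Count correlations use
  `log10(x + 0.1)`; the pseudocount is configurable.
* **TSS windows.** "Within 50 nt of the cluster region" is read as a
  symmetric +-50-nt flank around the cluster interval.
* **Density contrasts.** `region_density_compare()` computes per-interval
  RPKM by 5'-end containment (consistent with the cluster caller), the
  arithmetic-mean fold change as the headline (geometric also reported),
  a Mann-Whitney p-value between groups, and an empirical p-value against
  length-matched random interval sets: each control set reproduces the
  experimental length multiset exactly and is placed uniformly, so the
  empirical p is bounded below by `1/(n_control_sets + 1)`.
* **Degenerate inputs.** Zero-variance profiles refuse to correlate;
  empty alignment sets yield empty cluster lists (not errors); a
  zero-density reference group yields an `Inf` fold change with an
  explicit finite-flag; fully tied body-GC comparisons return p = 1.

### The blunt-end negative control

One subtlety surfaced while validating the duplex finder. At saturating
read depth, independent blunt digestion products can land exactly 2 nt
apart - especially under sequence-biased cutting, which concentrates cuts
on a hotspot lattice - and such cross-molecule coincidences reproduce the
overhang geometry without any overhang existing. The claim "blunt
products yield no duplex calls" is therefore only exact when placements
cannot collide: the negative control digests one molecule per locus,
where successive cuts are >= 6 nt apart within a chain and loci are
hundreds of bases apart, making the 2-nt offset structurally impossible.
The paired positive control (same configuration with 2-nt overhangs)
confirms the detector fires on the same data when the geometry is real.
This is a general caveat for interpreting duplex calls in extremely deep
real libraries: a small fraction of calls at saturating depth can be
coincidental juxtapositions of independent products.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data
at desk scale, sizes chosen to make the statistical assertions
well-powered: 200 random duplex-finder instances (up to 2,000 unique
reads each) against the all-pairs oracle; 20 mixed-architecture loci for
recall/precision and cluster recovery; 5,000 planted sequences for
composition recovery (estimates within +-0.03 of planted values); ~1.5e5
cuts over 2.1 Mb of distinct duplex sequence for the product-size modes
(the +-3 candidate jitter flattens the length peak, so resolving the mode
needs sequence diversity, not digestion depth); ~5,000 products for the
capture-bias contrast; and 20+20 loci at a 30:1 planted abundance ratio
for the density fold change. The genome-wide numbers reported for the
original libraries (hundreds of clusters, thousands of duplexes, 87%/13.5%
gene fractions) depend on ~20 million deposited reads and a specific
aligner and are not reproducible at this scale; what the desk-scale
checks establish is that every estimator recovers planted truth under the
model's own assumptions.

## A worked example

```{r example, eval = FALSE}
plan <- data.frame(
  architecture = c("divergent5", "convergent3", "full_overlap", "novel_as"),
  overlap_length = c(300, 300, 225, 250),
  abundance = 100)
cfg <- sim_config(genome_length = 30000, locus_plan = plan,
                  noise_read_count = 100, cluster_min_reads = 50, seed = 7)
sim <- simulate_dataset(cfg, "sim_out")

reads <- read_reads("sim_out/reads.fastq")
alignments <- map_exact(reads, sim$genome)
lib <- sum(alignments$count)

clusters <- call_clusters(alignments, cluster_params(min_reads = 50), lib)
records <- collapse_unique(alignments, lib)
duplexes <- find_duplexes(records, min_rpm = 1)
profile <- positional_gc(records[records$length == 22, ], sim$genome,
                         composition_params(22))
region_summary(profile)
```

## Known limitations

Exact-match mapping cannot place reads containing sequencing errors; the
cluster definition is a plain threshold with no significance model (by
design); duplex detection requires both strands to be sequenced at
threshold abundance, so one-sided cloning dropout hides true sites; the
method inherently cannot see RNase III cleavage in single-stranded
structured RNA; and the simulator's digestion walk is a phenomenological
model - it reproduces the product signature (sizes, overhangs,
composition) rather than the enzyme's kinetics.
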