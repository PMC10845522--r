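---
title: "Methods behind vitiscan: read-depth CNV calling, repeatome profiling and satellite characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind vitiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitiscan)
library(dplyr)
```

`vitiscan` implements the computational core of a grapevine (*Vitis
vinifera*) resequencing analysis: detecting copy-number differences between
varieties from read depth, testing how structural variants distribute over
chromosomes, profiling the repetitive fraction of the genome directly from
unassembled reads, and characterizing satellite-DNA families down to their
monomer structure and chromosomal sites. Every stage can be exercised on
synthetic genomes with recorded ground truth, so the statistical behaviour
of the pipeline is testable end to end without any external download.

This vignette explains the models and algorithms, the parameters that
matter, and the design decisions taken where the underlying methodology
leaves room for choice. It states no empirical result that the package's
test suite and `scripts/acceptance.R` do not themselves compute.

## The synthetic-genome generator

`sim_reference()` builds a multi-chromosome reference of i.i.d. background
sequence at a configurable GC content (default 0.35, grapevine-like) and
implants two kinds of events:

* **Sequence features** — tandem satellite arrays (a random monomer of
  requested length and A/T content, concatenated `n_copies` times with
  per-copy substitution divergence) and dispersed repeat families (a random
  master element copied to non-overlapping positions, each copy diverged).
  These are written into the reference sequence itself.
* **Copy-number events** — per-sample duplications (true CN > 2) and
  deletions (true CN < 2). These never alter the sequence: depth is later
  simulated on reference coordinates with CN-weighted rates
  (`sim_read_starts()` draws the number of reads starting at position *p*
  from Poisson with mean `coverage / read_length × CN(p) / 2`). This
  reproduces exactly the signal that window-based read-depth callers
  exploit while avoiding any dependence on an aligner; the trade-off is
  that breakpoint-spanning reads and mapping artefacts are not modelled.

Dispersed copies are placed on a genome-wide grid of free slots (element
length + 1 kb spacer) sampled without replacement. The spacer prevents
copies of different families from sitting nearly adjacent, which would let
physically overlapping reads bridge unrelated repeat clusters — an artefact
of dense artificial genomes, not of the method. The repeat mask is placed
independently of events by default; `mask_satellites = TRUE` adds arrays to
the mask to mimic a repeat-masked reference.

Every generator output is a pure function of its arguments and the seed;
the test suite asserts byte-identical FASTA output across reruns, the
conservation identity (implanted CN-event bases equal the bases where the
sample's CN track departs from 2), and the depth-scaling law (mean depth in
a CN = 4 region converges on twice the diploid background, checked at 60×
within 5%).

Reads for the repeatome stage (`sim_reads()`) are drawn uniformly from the
(CN-weighted) genome, reverse-complemented with probability one half, with
i.i.d. substitution errors and flat Q30 qualities except for a configurable
fraction of reads carrying a short Q10 3' tail — just enough quality
structure to exercise the Q < 20 trimming rule. Indels, paired-end inserts
and position-dependent error profiles are deliberately out of scope, so
passing tests say nothing about alignment robustness on real reads.

## Windows, depth and absolute copy number

Read-depth CNV analysis uses windows containing a fixed number of
**unmasked** bases (1000 by default) rather than fixed genomic spans:
`define_windows()` scans each chromosome left to right and closes a window
when exactly `w` unmasked bases have accumulated, so masked blocks stretch
a window's genomic span without diluting its information content. The
terminal sub-window remainder of each chromosome is dropped. This is
asserted against an independent per-base oracle over randomized masks.

`window_depth()` assigns each simulated read to the left-most window whose
unmasked bases its span overlaps — one window per read, so no read is
counted twice — and reports depth as mean per-unmasked-base coverage,
`reads × read_length / w`.

Absolute copy number is calibrated by `calibrate_cn()` with iterative
3-sigma trimming: compute mean and sd over retained windows, drop windows
outside the band, repeat until stable. The surviving windows are the
diploid control set, their mean is the depth of CN 2, and every window gets
`cn = 2 × depth / control_mean`. The procedure fails loudly if trimming
discards more than 90% of windows (a profile with no diploid backbone
cannot be calibrated). CN is invariant under any positive rescaling of
depths, which the tests assert to numerical precision.

GC correction (`gc_correct()`) is available — windows are binned by GC
fraction, each depth scaled by the global-to-bin median ratio, sparse bins
inheriting the nearest populated bin's factor — but is **off by default**:
the generator produces GC-unbiased depth, and whether the original
depth-calibration tooling applied GC correction is not documented, so the
package does not guess.

## WSSD-style calling and digital CGH

`call_wssd()` labels a window duplicated when its CN exceeds 2.5 and
deleted below 1.5, and emits maximal runs of at least five consecutive
same-state windows. Two readings of the run rule are possible (thresholding
each window's own CN, or a five-window sliding mean); the per-window
reading is used because it is the only one consistent with the defining
example of the rule — `[2,2,3,3,3,3,3,2]` yields one duplication spanning
exactly the five CN = 3 windows — and with "at least five consecutive
windows with a CN > 2.5". No gap tolerance is applied: one sub-threshold
window splits a run. This is conservative; real callers sometimes bridge
single noisy windows, at the cost of fusing nearby events.

Digital CGH compares two profiles window by window:
`L2R = log2(CN_sample / CN_reference)`, with windows where either CN falls
below 0.1 flagged undefined and excluded (a near-zero denominator would
make the ratio numerically meaningless). `call_cgh()` emits maximal
same-sign runs with |L2R| > 0.25 whose genomic span exceeds 10 kb. The loss
threshold is the negated gain threshold — a symmetric band, since "below
+0.25" would classify every quiet window as lost. Undefined windows break
runs, and no merging of nearby regions is performed before the length
filter.

Two structural identities are enforced by tests: a profile compared against
itself yields zero regions, and swapping sample and reference negates every
defined L2R and exchanges gain and loss calls exactly.

`intersect_cnvrs()` defines a shared CNVR as a maximal interval covered by
a same-kind region in **every** sample (base-wise intersection, then
merged), checked exactly against a brute-force per-base boolean-AND oracle
on random region sets. A region is flagged sample-specific when it overlaps
no same-kind region of any other sample; with more than two samples this is
the weakest sensible reading of "no counterpart", and intermediate cases
(overlap with some but not all samples) are represented only through the
shared intervals. `annotate_regions()` attaches gene identifiers from GFF3
`gene` features overlapping each region by at least one base, and
`gene_fraction()` reports the fraction of regions containing a gene.

## Chromosome-level variant statistics

Under a random placement of variants, a chromosome's expected count is the
genome-wide rate per kbp times its length in kbp, so expectations sum to
the observed total by construction. `chisq_randomness()` computes
`X² = Σ (O − E)² / E` with `df = n − 1` (one degree lost because the
expectation is derived from the observed total), the upper-tail p value,
per-chromosome standardized residuals `(O − E)/√E` and descriptive one-df
components. Per-chromosome components are reported without multiplicity
correction — they are diagnostics, not tests. `flag_enriched()` marks
chromosomes with |residual| above 2, a simple scale-free enrichment flag.

`hypergeom_enrich()` provides term enrichment for gene sets in CNVRs:
upper-tail hypergeometric p per term, Benjamini–Hochberg q across terms.
Its null calibration is verified by simulation (p values of random study
sets are uniform, Kolmogorov–Smirnov at α = 0.01; the fixture sizes are
chosen large enough that the discreteness of the hypergeometric stays
below the KS band). No GO-graph propagation is performed: terms are flat
gene sets.

## Repeatome profiling from unassembled reads

The profiler follows the standard read-clustering recipe: sample one
million reads (seed 100 by default), trim 3' bases below Q20, drop reads
under 100 nt, cut survivors to exactly 100 nt, and subsample to 250,000
standardized reads per sample (`prepare_reads()`).

`cluster_reads()` builds a graph with reads as nodes and an edge whenever
two reads share at least 10 canonical 17-mers (strand-agnostic), and takes
connected components as repeat clusters; components below 0.01% of the
input dissolve to singletons, mirroring the reporting floor of read-based
repeat profilers. Exhaustive pairwise comparison is quadratic in cluster
size and infeasible at 250,000 reads, so the implementation (in C++)
generates candidate edges from k-mer occurrence buckets — all pairs in
small buckets, a chain over consecutive reads plus a star to the first read
in large ones — and verifies every candidate's exact shared-k-mer count by
sorted-set intersection, with union-find pruning of already-connected
pairs. Candidate generation is a connectivity heuristic: reads of an
abundant repeat co-occur in dozens of buckets and remain densely
interlinked, so the components it finds coincide with those of the full
graph in all tested regimes; the `≥ 10 shared k-mers` criterion itself is
always evaluated exactly per tested edge. This stands in for published
graph-based repeat clustering at desk scale; it preserves the contract
(clusters and genome proportions from unassembled reads) but not the
community-detection refinements of the published tool.

A cluster's **genome proportion** is its read share of the standardized
sample. `classify_clusters()` matches member reads to a labeled repeat
reference through shared canonical k-mers, estimating read-to-family
identity with the standard sketching estimator `identity ≈ C^(1/k)` (C the
k-mer containment); a literal "80% of k-mers shared" would reject honest
members of families at even 2% divergence, because 17-mer survival decays
as `(1 − d)^17`. The cluster takes the majority family when at least half
of its matched members agree; a 50/50 conflict or no matches leaves it
`unclassified`.

`compare_landscapes()` centers and unit-scales the sample-by-family
abundance matrix, summarizes it by PCA, partitions samples with K-means
(k = 2 by default, 25 restarts under a caller seed), and tests each family
between groups with a two-sided Wilcoxon rank-sum test at α = 0.05, exact
where the sample sizes allow. No multiple-testing correction is applied by
default, matching the conventional per-family p ≤ 0.05 usage in comparative
repeatome work; `correct = TRUE` switches the significance flags to
Benjamini–Hochberg q values. A matrix with no between-sample variance is
rejected with an explicit error rather than silently producing a degenerate
ordination.

The read subsampling depth follows the stated read-count convention
(250,000 reads of 100 nt) rather than the coverage figure sometimes quoted
with it; for a genome of several hundred Mbp those reads correspond to a
few hundredths of a fold, and it is the read count that drives the
clustering behaviour.

## Satellite characterization and in-silico FISH

`estimate_period()` scores every candidate period p between 10 and 2000 nt
by shifted identity — the fraction of positions i with
`base(i) = base(i + p)`, pooled across input sequences — and reports the
smallest p that is a local maximum above 0.8 and at least 0.05 over the
median score. Taking the smallest significant period avoids reporting
dimer or higher multimer harmonics, which score equally well at 2p, 3p, …
The thresholds are deliberately blunt: a tandem array at ≤ 5% divergence
scores ≈ 0.9 at the true period while off-period scores hover near the
random base-coincidence level, so the margin is wide.

`build_consensus()` cuts the sequences into period-phased frames and takes
the per-column majority base (ties to the lexicographically smallest base,
keeping the consensus IUPAC-free). For a tandem array every phase rotation
yields the same per-column agreement up to edge frames, so the consensus is
computed in the phase of the array start via residue-class counting;
consensus sequences should be compared up to rotation.

`find_palindrome()` scans the monomer circularly (a tandem monomer has no
privileged origin) for the longest substring equal to its own reverse
complement with at most 2 mismatching base pairs, expanding around every
center. The center base of an odd-length palindrome is an unpaired
hairpin-loop base and does not count as a mismatch — no DNA base is its own
complement, so the alternative convention would make any odd perfect-arm
palindrome unreportable at its exact length. Ties break to fewer
mismatches, then the smaller offset.

`map_monomer()` slides the monomer ungapped along both strands of an
assembly (C++ inner loop with early exit on the mismatch budget), keeps
local matches at ≥ 80% identity, and reduces them to non-overlapping hits,
best identity first. Ungapped alignment at a fixed identity floor is a
deliberate simplification: satellite variants within a species share high
identity, and gapped alignment buys little at this scale. `call_tandem_loci()`
chains hits whose gaps do not exceed twice the monomer length and keeps
chains of at least five monomer matches — the per-chromosome locus counts
are the in-silico analogue of FISH site counts. `compare_haplotypes()`
matches loci across two haplotype assemblies on homologous chromosomes
(explicit homology table, or identical names) at a reciprocal overlap of
0.1, flagging unmatched loci hemizygous; haplotype naming conventions
differ between published assemblies, which is why the table is explicit.

## Pipeline, configuration and reproducibility

`pipeline_config()` collects every stage parameter with the analysis
defaults (1-kb unmasked windows; ≥ 5 consecutive windows at CN > 2.5 /
< 1.5; |L2R| > 0.25 over > 10 kb; 1 M sampled reads at seed 100, Q20
trimming, 100-nt reads, 250,000 final reads; Wilcoxon α = 0.05; K-means
k = 2) and rejects unknown keys before anything runs. `run_pipeline()`
executes simulate → profile → call → intersect → chi-square → repeatome →
satellite in dependency order, writes every artefact under one run
directory, and records an append-only manifest of files with md5 checksums
plus a YAML echo of the effective configuration; an identical configuration
reproduces identical checksums. The package is R-native: these functions,
not shell subcommands, are the operational interface.

## Numerical choices and problem sizes

All coordinates are 0-based half-open (BED convention) in every tibble;
GFF3 input is converted on read. Randomness is always funnelled through an
explicit `seed` argument and `withr::local_seed()`, so no function disturbs
the caller's RNG state. The evaluation studies shipped under
`inst/studies/` (and driven by `scripts/acceptance.R` and the acceptance
tests) use: a 1-Mb genome at 30× over 20 seeds for duplication/deletion
recovery; 50 random region sets on a 100-kb toy genome against the
base-wise intersection oracle; 2,000 multinomial simulations for chi-square
type-I calibration; a 50-Mb ten-chromosome genome with families at 2, 5 and
10% sampled at 250,000 standardized reads for proportion recovery; 1,000
null simulations for the Wilcoxon flag rate; 40 arrays per monomer length
in {107, 187, 677, 964, 994} nt at 5% divergence for period recovery; and a
two-chromosome diploid pair for the shared/hemizygous locus count. These
sizes were chosen as the smallest at which the expected statistical
behaviour is unambiguous.

## Known limitations

* Depth is simulated, not aligned: mappability, multi-mapping reads and
  reference bias — all prominent in real repeat-rich regions — are outside
  the model, so recovery results bound what the statistics can do on clean
  signal, not what an aligner will deliver.
* The shared-k-mer clustering is a stand-in for published graph-based
  repeat clustering; genome proportions agree at desk scale, but cluster
  substructure (variant families, superfamily links) is not resolved.
* CGH regions are not merged across small gaps, and breakpoints are only
  window-resolution.
* Satellite higher-order repeat structure, centromere prediction and any
  wet-lab validation are out of scope.

## A worked example

```{r example, eval = FALSE}
library(vitiscan)
library(dplyr)

events <- bind_rows(
  tibble(sample_id = "AGL", chrom = "chr1", start = 300000L, end = 320000L,
         kind = "duplication", cn = 4),
  tibble(sample_id = "AGL", chrom = "chr1", start = 600000L, end = 615000L,
         kind = "deletion", cn = 1)
)
sim <- sim_reference(c(chr1 = 1e6), events = events, seed = 42)

windows <- define_windows(sim)
starts <- sim_read_starts(derive_sample(sim, "AGL"), coverage = 30, seed = 7)
profile <- calibrate_cn(window_depth(windows, starts), sample_id = "AGL")
call_wssd(profile)
autoplot(profile)
```
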