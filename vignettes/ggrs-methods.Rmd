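---
title: "GGRS: design, simulation and filtering of genome-reducing genotyping libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GGRS: design, simulation and filtering of genome-reducing genotyping libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggrs)
```

## The method

Genotyping by genome reducing and sequencing (GGRS) is a
reduced-representation genotyping protocol: genomic DNA is digested with a
methylation-sensitive restriction enzyme, a per-sample barcode adapter and a
common adapter are ligated onto the cut ends, fragments in a fixed size
window are amplified and sequenced as a multiplexed pool, and SNPs are
called from reads anchored at the restriction sites. Because every sample's
reads start at the same cut sites, the sequenced loci overlap strongly
across individuals, which is what makes shallow per-sample sequencing
usable for population genotyping.

This package implements the computational side of that design for any
reference genome and enzyme:

1. **In silico digestion** (`find_sites()`, `digest_genome()`): degenerate
   IUPAC motif scanning, fragments between consecutive cut positions, size
   selection.
2. **Multiplex planning** (`samples_per_lane()`, `run_capacity()`,
   `cost_per_sample()`): the lane-capacity arithmetic.
3. **Barcode design** (`generate_barcodes()`): variable-length prefix-free
   barcodes compatible with the cut-site remnant.
4. **Library simulation** (`simulate_reads()`): paired-end reads with the
   exact library structure plus truth tables.
5. **Demultiplexing** (`classify_reads()`, `demux_fastq()`): the four
   read-quality filters.
6. **SNP retention** (`filter_vcf()`): quality/call-rate/depth/MAF
   screening of a multi-sample VCF.
7. **Reports** (`density_table()`, `block_occupancy()`,
   `adjacent_distances()`, `platform_compare()`): per-chromosome density
   and platform-comparison arithmetic.

The default enzyme is AvaII, recognition `GGWCC` (W = A or T) cut after the
first G, so every ligated fragment end begins with the four-base remnant
`GWCC`. `GGWCC` is palindromic as a degenerate set, so a single-strand scan
finds all sites; this is asserted against a double-strand oracle in the
tests.

## Digestion conventions

All internal coordinates are 0-based, half-open (BED convention); the SAM
and VCF adapters convert at the boundary. Cut positions are
`site + cut_offset`. Only *internal* fragments — flanked by a cut at both
ends — are returned by default, because only those receive both adapters in
the ligation; `include_terminal = TRUE` restores the two chromosome-end
intervals. Fragment length is the inter-cut distance, so lengths tile the
span between the first and last cut exactly. The size window (default
200–400 bp) is inclusive at both bounds. A motif never matches across an
`N` base.

## Capacity arithmetic

A lane yielding $Y$ bases supports
$\left\lfloor Y / (G \cdot c \cdot d) \right\rfloor$ samples for genome
size $G$, captured fraction $c$ and target depth $d$. With the defaults
(35 Gbp lane, 1.05 Gbp genome, 2 % capture, 5× depth) this gives 333
samples; at the realized 2.2 % coverage it gives 303. The published GGRS
chicken protocol quotes 257 for the same inputs, a figure we cannot
reproduce from the stated formula; the formula is implemented as stated and
the protocol's realized choice (252-plex, chosen for base balance in the
barcode positions) is used wherever the 252-plex library is meant. Run
capacity is the plain product samples × channels × flow cells
(252 × 7 × 2 = 3528), and cost per sample is total cost / samples
($4500 / 252 ≈ $18).

Marker spacing is set by the extent of linkage disequilibrium: 10 kb here,
giving `target_marker_count()` ≈ 100,000 locations on a ~1 Gbp genome.

## Barcode design

Barcodes are read as the R1 prefix directly against the remnant, which
imposes structural constraints beyond ordinary index design:

* no occurrence of the recognition motif inside the barcode (it would be
  cut);
* the barcode must not recreate the motif across the junction with the
  remnant — for AvaII this reduces to *never ending in G*, since
  `G` + `GWCC` = `GGWCC`;
* `barcode + first remnant base` strings must be prefix-free, so
  longest-prefix demultiplexing of variable-length codes is unambiguous
  (the remnant always starts with `G`, so a code extending another code
  through `G` is the only ambiguous case);
* pairwise Hamming distance ≥ 3 computed over the shared prefix length, so
  a single sequencing error cannot move a read between samples.

`generate_barcodes()` is a seeded randomized greedy search. The
shared-prefix distance makes short codes expensive — a 4-mer must differ in
3 of its 4 positions from the 4-prefix of *every* other code — so realized
lengths concentrate at 5–8 nt; this matches the behaviour of public GBS
barcode generators. When the requested set provably cannot exist (small,
fully enumerable length ranges) or the candidate budget is exhausted, a
capacity error is raised rather than a short set returned.

`adapter_dimer_check()` reports the longest reverse-complementary run
between two adapter strands by brute-force diagonal scan — a screening
heuristic only; no thermodynamic (ΔG) duplex model is attempted — and flags
products near the ~128 bp adapter-dimer band seen on electropherograms.

## What the simulator emulates — and what it does not

`simulate_reads()` reproduces the *structure* of a GGRS library:

* R1 = barcode + remnant + fragment 5′ sequence; the remnant's `W` is the
  actual genomic base, never redrawn, so simulated reads re-match the
  reference. R2 reads the opposite end, beginning with that end's remnant.
  Each molecule's barcode end is chosen uniformly.
* Per-sample expected read counts are lognormal with CV 0.69, the evenness
  observed for the 252-plex chicken library. Note the reported convention:
  the published CV is computed *after* dropping the 5 largest and 2
  smallest samples, which biases the statistic downward (a lognormal with
  parameter CV 0.69 yields ≈ 0.60 after exclusion); `cv_of_counts()`
  implements exactly that exclusion rule, fully parameterized.
* `depth` is reads per fragment per sample (default 5). With 2 × 100 bp
  reads on 200–400 bp inserts, a mate covers a given interior base with
  probability well below 1, so the realized per-locus call depth is about
  0.5–0.7 × `depth`, and the centre of inserts longer than ~190 bp plus
  barcode is never sequenced at all. This is faithful to the real geometry:
  at the default sizes roughly a quarter of uniformly placed loci are
  structurally uncallable, and recovery statistics should be read against
  the callable set.
* Planted variants are biallelic, uniform over fragment interiors with the
  in-fragment motif bases excluded — a variant inside the recognition site
  would abolish the cut site itself (allele dropout), which we deliberately
  do not model — with allele frequency uniform on `maf_range` and
  Hardy–Weinberg genotypes. Heterozygotes transmit either allele with
  probability 1/2 per read.
* Noise: independent per-base substitution errors (default 0.001,
  consistent with the >Q30 average quality of the real run); per-read N
  contamination (default 0.005, 1–3 `N` bases at uniform positions —
  modelled per read rather than per base so rejection counts are directly
  binomial); and a configurable adapter-dimer read fraction (default 0.01:
  dimers are rare in a well-built library but not absent). Base qualities
  are constant Q35 and carry no information; quality-score training, PCR
  duplicates and GC bias are out of scope.

Consequently, passing tests demonstrate the pipeline's bookkeeping and
statistics on structurally faithful data; they do not certify performance
on real sequencer error profiles, enzyme-efficiency variation or DNA
quality effects, which dominate real-library unevenness.

## Demultiplexing filters

The four filters are applied to R1 in order, and the first failure is the
reported reason: (1) exact barcode match (no error-tolerant rescue — the
protocol demands exact matches); (2) remnant `GWCC` immediately after the
barcode; (3) no adapter dimer, realized as an exact ≥ 8-base common-adapter
prefix immediately after barcode + remnant — the signature of an
empty-insert molecule; (4) no `N` anywhere in the read, the read length
taken from the data. R2 inherits R1's verdict, so pairs are kept or
rejected together. Filter order affects only the attributed reason, never
the good-read set, since the four predicates are independent of one
another.

A *unique read* is a distinct (chromosome, 5′ position, strand) key covered
by at least one good read; strand is part of the key by default
(`ignore_strand` collapses it). The MAPQ screen before variant calling
keeps alignments with quality strictly greater than 20 (`strict = FALSE`
relaxes to ≥).

## SNP retention

A sample's genotype counts as called only when its genotype quality exceeds
`min_quality` (20 ⇒ 99 % call accuracy). A site is retained when, over
called samples, all of the following hold strictly (`inclusive = TRUE`
relaxes every rule to ≥): called fraction > 0.25 (more than 63 of 252),
mean depth > 5, and folded minor allele frequency > 0.05. Missing
genotypes never enter the MAF denominator. Mean depth is averaged over
genotyped samples (the `depth_over_all` flag averages over the cohort
instead). Multiallelic records are rejected outright — the method targets
biallelic SNPs; split them upstream if needed. Missing-genotype imputation
is intentionally out of scope: the filter reports missingness so an
external imputer can be slotted in after it.

## Density reporting conventions

`density_table()` computes per-chromosome densities as count / size (per
Mbp, printed to 2 decimals). Two different summary conventions exist in
published per-chromosome tables and both are emitted, clearly labelled: the
summary-row density as the *arithmetic mean of per-chromosome densities*
(`mean_density`; this reproduces the published 154.4/Mbp GGRS figure and
the 37.5/Mbp gene figure), and the pooled density *total count / total
size* (`overall_per_mbp`, also expressed per 10 kb: 0.91 for GGRS, 0.55–0.56
for the 60K chip depending on whether the rounded 1001 Mbp genome total is
used). Macrochromosome percentages (GGA1–5) are computed against each
platform's full marker total including unplaced markers, which is the
convention that reproduces the published 58 / 46 / 52 % triplet.
`block_occupancy()` tiles chromosomes into half-open 10-kb blocks from
coordinate 0; `adjacent_distances()` never crosses chromosome boundaries.

The bundled `chicken_marker_table()` carries the published
Gallus_gallus-4.0 per-chromosome sizes, gene counts and marker counts for
GGRS and the 60K/600K chips. Its printed 600K column is internally
inconsistent in two ways we preserve rather than repair: the printed
per-chromosome counts sum to 575,716 while the printed total is 577,187,
and its printed summary density follows the total/total convention while
the other columns follow mean-of-densities. The published claim that GGRS
SNP density is "six-fold" the gene density is not reproducible under
either convention (mean-density ratio 4.1, count ratio 4.8);
`platform_compare()` emits both ratios without asserting a multiplier.

## Problem sizes and numerical choices

The test-suite and the acceptance script run on synthetic genomes of
60–350 kb with 2–252 samples and a few thousand to ~60,000 read pairs —
sizes chosen so the full pipeline (including the 252-barcode design and the
252-sample evenness check) completes in seconds while leaving every
statistical check well-powered at 3σ. Whole-genome digestion of a real
~1 Gbp reference uses the same code path and needs only the FASTA.

Determinism: every stochastic stage requires an explicit seed, restores the
caller's RNG state, and records the seed in the run manifest
(`write_manifest()`); the same seed reproduces byte-identical FASTQ.
Degenerate inputs are defined rather than accidental: fewer than two cut
sites digest to no fragments; empty FASTQ demultiplexes to zero counts; a
site with no called genotypes has undefined MAF and fails retention;
`cv_of_counts()` refuses fewer than two values after exclusion; fragments
shorter than the remnant are skipped with a warning.

## Known limitations

* Methylation sensitivity of the enzyme is not modelled; in vivo digestion
  of a methylated site simply does not happen, shifting the realized
  fragment set.
* Restriction-site polymorphism (allele dropout) is excluded from the
  simulator by construction.
* The aligner and genotype-likelihood caller are external interfaces; the
  synthetic `genotype_calls()` stage stands where they would sit and its
  GQ model (`min(99, 12 × DP)`) is a convenience, not a likelihood.
* Barcode demultiplexing is exact-match by design; reads with an error in
  the barcode are lost, as in the real protocol.
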