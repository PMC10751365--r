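---
title: "Detecting somatic SVA insertions and de novo numts in a two-sample design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic SVA insertions and de novo numts in a two-sample design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senomob)
```

## The problem

Senescent cells accumulate structural genomic changes beyond epigenetic
drift. Two classes of somatic insertion events are of particular interest
in a proliferating-versus-senescent comparison of a cell line:

* **De novo SVA retrotransposition.** SVA elements are non-autonomous
  hominoid retrotransposons carrying a 5' (CCCTCT)n hexamer repeat; they
  are mobilized in trans by the LINE-1 machinery. Their upstream genomic
  flanks can be enriched by representational difference analysis (RDA): a
  subtractive, kinetic PCR in which driver DNA from proliferating cells is
  supplied in large excess, suppressing flanks shared by both samples, so
  that tester-specific (senescence-acquired) flanks amplify
  exponentially. Deep-sequenced amplicons then carry three landmarks:
  RDA adaptor, nuclear flank, hexamer run.

* **De novo numts.** Fragments of mitochondrial DNA integrate into
  nuclear chromosomes, typically as NHEJ filler at double-strand breaks,
  leaving junctions with short microhomologies. In 150 nt single-end
  reads, a fresh numt shows up as a chimera: a perfect mtDNA segment next
  to a perfect nuclear flank inside one continuous read.

`senomob` implements both readouts as tested pipelines, together with a
synthetic spike-in study (toy genomes, planted events, read simulators,
truth tables) that validates every stage end to end.

## The numt filter chain

For each read the scanner finds every *maximal 100%-identity mtDNA
segment* of at least `min_mt_len` nt (default 30), on both strands, with
the circular origin handled transparently. The filter chain then applies,
in order:

1. **Segment cap** — any per-read mtDNA alignment *exceeding* 130 nt is
   discarded (a 130 nt segment passes; 131 nt does not). Long perfect
   mtDNA stretches in a 150 nt read leave no informative flank.
2. **Flank floor** — the mtDNA segment is subtracted from the read; the
   remainder must contain a flank of at least 20 nt (inclusive).
3. **Placement** — the flank is aligned to the nuclear reference and must
   be gapless, cover at least 95% of the flank, and have a *unique* best
   pslScore (any tie rejects the flank). Flanks still containing a
   perfect mtDNA segment of `min_mt_len` nt or more are rejected.
4. **Two-sample subtraction** — senescent placements overlapping (by one
   base or more) any proliferating-sample placement, any known-numt
   interval, or an optional extra exclusion set, are removed.
5. **Merging** — surviving placements whose junction coordinates lie
   within `merge_window` (default 100 nt) and whose mtDNA intervals
   overlap are collapsed into one call with summed read support.
   Junction reads start at many offsets; without this, one event would be
   multi-counted. Calls from long insertions can legitimately split into
   a left-junction and right-junction call when their mtDNA sub-segments
   do not overlap.

Both threshold readings are deliberately inclusive: a segment is
discarded only when strictly longer than 130 nt, and a flank of exactly
20 nt is kept. `min_mt_len = 30` is a choice: much shorter
perfect matches to a 16.6 kb mitochondrial genome arise by chance in
large nuclear backgrounds; it is config-exposed.

"Uniquely mapped" is operationalized as a unique best pslScore with no
tie. No online re-check against public sequence databases is performed;
the known-numt BED plus an optional extra exclusion BED (for externally
verified hits) fills that role.

## The SVA/RDA readout

Amplicon reads are parsed by locating the adaptor (exact match, either
orientation) and the first run of at least three exact CCCTCT units; the
intervening flank (minimum 20 nt) is placed under the same uniqueness
contract as numt flanks. The insertion point is the flank end adjacent to
the hexamer. Placements within `exclusion_window` (default 100 nt) of an
annotated SVA are discarded as germline-derived; surviving points within
20 nt collapse into one call with summed support.

Summaries follow the total/unique contrast: *total* is read-level support
summed over calls, *unique* is the number of distinct collapsed
coordinates. Replicate overlap clusters coordinates within 20 nt across
call sets (single linkage); each cluster is counted once for its exact
replicate subset, so the Venn counts satisfy inclusion-exclusion by
construction. Whether the original de-duplication used exact coordinates
or a window is not stated anywhere we could follow; the 20 nt window is a
documented decision mirroring the collapse tolerance, since RDA
fragmentation shifts read starts.

## Target-site annotation

Each call site receives exactly one feature label under a fixed
precedence: Promoter > 3UTR > Exon > TTS > SINE > LINE > LTR > Satellite
> DNA > Intron > Intergenic, using the feature containing the site
midpoint (an any-overlap mode is available). Promoter windows are TSS
-1000..+100 and TTS windows end -100..+1000. Repeat classes outrank
Intron because repeat and intron fractions are reported side by side as
disjoint categories. The usual peak-annotation tooling is re-implemented
rather than wrapped; its exact tie-breaking is not documented, so the
precedence above is this package's own, stated rule.

De novo motif discovery is out of scope; in its place a deterministic
consensus scan reports the fraction of insertion points whose +/-10 nt
window contains the L1 endonuclease consensus TTTT/AA (at most one
mismatch inside the T-tract, AA exact, either strand).

## Abundance profiles

The mitochondrial genome (16,559 nt) is tiled into 1,000 nt windows (17
tiles, the last of 559 nt). A read counts toward a tile when it has an
ungapped alignment at the chosen identity with the shorter sequence fully
contained in the longer; each read counts at most once per tile. RPM is
count / (total reads / 1e6) and fold changes are always reported as
log2((RPM_test / rate_test) / (RPM_ref / rate_ref)), where the rates are
each sample's overall alignment rate (default 1). The worked-example RPM
pairs in the acceptance script (277/103 and 596/222) give log2 values of
about 1.43 and 1.42, inside a 1.3-1.46 fold-change band, which fixes the
log2 (not linear) reading of "FC" here. A zero reference RPM yields NA,
never infinity.
SVA subfamily abundance uses the first 200 nt of each subfamily 5'
region as query (the informative, non-repetitive part); a read matching
two subfamilies counts toward each. Because the containment rule drops
reads straddling tile borders, per-tile counts are proportional to tile
length only across equal-length tiles; the edge loss is uniform and
cancels in fold changes.

## The synthetic study design

The generator is first-class, tested code; its defaults are the study
conditions the acceptance suite runs under.

* **Toy genomes**: 2 chromosomes x 50 kb of random sequence at GC 0.41,
  plus a circular 16,559 nt mtDNA carrying a human-like feature map
  (D-Loop, 13 protein-coding genes, 2 rRNAs, tRNA blocks, scaled to
  length). Germline features are planted by overwriting background:
  annotated SVAs (hexamer run of 30-50 units plus subfamily consensus),
  germline numts (exact mtDNA substrings, 100-600 nt, possibly
  origin-spanning), and repeats — Alu-like SINEs with exact 25 nt primer
  ends and 2% body divergence per copy, LINEs, LTRs, satellites. Gene
  models are annotation-only and may overlap repeats (the two layers are
  independent in real annotation).
* **Consensus stand-ins**: SVA subfamily and repeat consensus sequences
  are bundled synthetic sequences generated once under a fixed internal
  seed (distinct 5' 200-mers per SVA subfamily); real consensus FASTA can
  be substituted. No download is needed and no third-party database
  content ships with the package.
* **De novo events** exist only in the senescent genome. Numts insert an
  exact mtDNA substring (default 40-400 nt, so the truth contains both
  detectable and undetectable events relative to the 130 nt per-read
  cap) at a site whose left-adjacent reference bases equal the segment's
  first h bases (h sampled 0-5), which realizes genuine junction
  microhomology without editing either sequence. SVAs insert a hexamer
  run of 30-50 units plus a possibly 5'-truncated consensus, with a
  4-20 nt target site duplication. Insertion sites keep 150 nt clearance
  from annotated features: placements abutting annotated elements are
  excluded by the callers' own annotation filters, so planting there
  would make events undetectable by construction rather than exercise the
  method. `repeat_target_bias` optionally directs SVA insertions into
  annotated repeats to study the non-unique-flank failure mode.
* **Reads** are single-end 150 nt and error-free by default (both
  scanners demand 100% identity; an error-rate switch exists to measure
  sensitivity loss). Single-end suffices because the detection logic
  operates on one continuous read; pairing adds nothing. WGS reads are
  uniform; mtDNA is drawn at `mt_copy_number`-fold relative depth. RDA is
  modeled as per-locus Bernoulli suppression (default efficiency 0.99
  for driver-shared loci) plus multiplicative amplification — the
  enrichment chemistry is treated as a black box because only its readout
  is analyzed. AluScan emits amplicons between convergent Alu primer
  sites up to 5 kb apart, tiled into reads. The RDA adaptor is a
  synthetic 24-mer default and a config parameter, as is the primer
  geometry.
* **Truth tables** record every event with reference insertion point,
  senescent-genome interval, inserted sequence and per-kind parameters,
  and serialize as tagged BED.

What passing these tests shows — and does not show. Error-free reads and
a clean random background isolate the filter-chain logic: recovery
failures would indicate algorithmic defects, not noise sensitivity. Real
data adds sequencing errors, polymorphism, PCR chimeras and a repeat-rich
genome, which the toy background only sketches; the simulator's
`error_rate` and `repeat_target_bias` switches probe those directions but
the acceptance conditions do not claim performance on real libraries.

## Numerical and design choices

* Intervals live in `GRanges` (1-based closed) internally — the idiomatic
  container in this ecosystem — with BED written and read 0-based
  half-open and PSL fields kept in their native 0-based dialect.
* The internal aligner is deterministic with fully defined orderings:
  exact matching is k-mer seeding plus diagonal-run merging (every
  maximal exact match of length >= min_len is found, provably, because
  each window of a longer match is itself a seed hit); near-exact
  matching is full-query and ungapped, with pigeonhole seeds and Hamming
  verification. 'N' never matches; reads over 10% N are dropped and
  counted. Circular targets are searched on a doubled linearization with
  results deduplicated modulo L; an origin-spanning hit is reported once,
  with end > L. The 100%- and 95%-identity screens the pipelines need
  never require gapped hits; externally produced gapped alignments can be
  supplied as PSL and flow through the same filters.
* Uniqueness fast path: a full-length exact placement always attains the
  best possible pslScore, so uniqueness is decided among full-length hits
  when one exists; only flanks without a full-length hit fall back to the
  maximal-match search for partial (>= 95%) placements. Batched
  multi-pattern passes (mtDNA k-mers over concatenated reads; nuclear
  k-mers over concatenated flanks) make the 20-seed acceptance sweeps
  tractable in pure R; batch and per-read paths are tested for
  agreement.
* Ties: call coordinates are the rounded median of member junctions;
  clusters are formed by single linkage on sorted positions, which makes
  call sets invariant to read order.
* Degenerate inputs: empty call sets, zero planted events, and empty
  subtrahends are all defined and tested; `fold_change` with a zero
  reference is NA.

## Problem sizes used by the test suite

The acceptance sweeps run 20 seeds of a 2 x 50 kb genome: the numt sweep
plants 10 de novo numts (segments 50-130 nt) over 5 germline numts at
50x coverage, the SVA sweep plants 10 de novo SVAs over 50 germline SVAs
with perfect subtraction. WGS simulations use a relative mtDNA copy
number of 3: mitochondrial depth only adds pure-mtDNA reads, which the
segment cap discards regardless, so the figure is chosen for turnaround
rather than realism (fibroblast-like cells carry hundreds of copies; the
copy-number dial matters only for the tile-abundance profile, which is
exercised separately). The annotation law-of-large-numbers check uses
10,000 sites.

## Known limitations

* The aligner is a functional stand-in for BLAT/blastn at toy scale, not
  a replica (tile size, minScore and the exact uniqueness heuristics of
  the original tools are not public in the form used); gapped or spliced
  alignment and genome-scale indexing are out of scope.
* Assembly of a sample-specific D-Loop from WGS data is out of scope: the
  synthetic mtDNA already contains its D-Loop.
* Subfamily assignment of the inserted element from RDA amplicons is not
  attempted (the amplified 5' head is too short), and the approach is
  unsuitable for LINE-1 (5' truncations remove the primer targets) and
  Alu (copy number and internal similarity defeat both the hybridization
  and the bioinformatic discrimination).
* numt allele fractions and assembly of insertions longer than one read
  are not quantified.
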