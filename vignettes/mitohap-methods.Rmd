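---
title: "Extracting mitogenome haplotypes from shotgun WGS reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting mitogenome haplotypes from shotgun WGS reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun whole-genome sequencing (WGS) libraries contain a small fraction of
reads — typically a few hundredths of a percent of mapped reads — derived
from the 16,569-bp circular mitochondrial genome.  Those reads are a free
by-product from which a complete mitogenome haplotype can be reconstructed.
Two obstacles stand between the raw alignment and a haplotype one would
trust in a population, medical or forensic study:

1. **NUMTs.**  Nuclear mitochondrial DNA segments are ancient insertions of
   mtDNA into the nuclear genome.  Their reads co-align to the
   mitochondrial reference and, wherever the insertion's sequence differs
   from the sample's authentic mtDNA, they surface as low-frequency mixed
   positions that mimic heteroplasmy.  Because nuclear DNA outnumbers mtDNA
   when mitochondrial copy number is low, NUMT interference grows as
   mitochondrial read depth shrinks.
2. **Sequencing artifacts.**  Homopolymer stretches — particularly the
   HVS1/HVS2 C-stretches of the control region — produce alignment
   ambiguity, length-heteroplasmy calls, and an elevated miscall rate
   immediately 3' of the run on patterned-flowcell chemistry, which
   manifests as spurious heteroplasmy in the A-stretches preceding the
   C-stretches (the recurrent A302M-type signal).

`mitohap` implements an end-to-end, deterministic pipeline for this
setting: consensus mapping on the circular reference, quality-filtered
low-frequency variant detection, forensic-nomenclature haplotype emission,
and a rule engine that classifies each mixed position as a probable point
heteroplasmy (PHP) or a NUMT variant.  A paired-end simulator with truth
labels generates the validation data for every stage.

## Consensus mapping

Reads are mapped three times:

1. **Permissive pass** against the circular reference (doubled sequence,
   start coordinates reduced modulo 16,569 so origin-spanning reads map
   unsplit), acceptance at 0.5 length fraction and 0.8 similarity fraction.
2. **Majority consensus** is built from the first pass (per-position
   majority base; zero-coverage positions and exact ties fall back to the
   reference base, which keeps the consensus deterministic and
   reference-stable).  All reads are then remapped to this consensus with
   **stringent** 0.95/0.95 acceptance.  A read dissimilar to the sample's
   own haplotype — a NUMT read carrying many insertion-specific variants, a
   contaminant from a distant haplogroup — fails here.
3. **Realignment** of the surviving reads to the reference, again at
   0.5/0.8, yields the final, reference-anchored mapping used for variant
   calling.

The acceptance contract is explicit: *length fraction* is aligned read
bases over read length; *similarity fraction* is matching columns over
aligned columns excluding read-insert columns.  Both are recomputable from
the CIGAR by a column walk, and the test suite does exactly that as an
independent oracle.  The aligner itself is a seed-and-extend (15-mer
seeds) banded local aligner with affine gaps (match +1, mismatch −1, gap
open 2, extend 1, band ±8).  Only the acceptance contract matters to the
pipeline's semantics; any correct local aligner honouring the fraction
definitions is interchangeable.  Reads with two equally scoring loci on
the circle are discarded as ambiguous rather than placed randomly — random
placement would inject seed-dependence into minor-allele frequencies.
Mates are aligned independently; pairing is used downstream for phasing,
not for placement rescue.

A deliberate consequence of the 0.95 similarity cutoff: a NUMT read
carrying, say, 3–6 diffs across 150 bp (similarity 0.96–0.98) *survives*
the stringent remap.  Consensus mapping removes grossly dissimilar reads;
close NUMT signatures reach the variant caller and must be handled by
classification.  This mirrors the behaviour observed with production
mappers in this field and motivates the rule engine below.

## Variant detection

Per-position profiles count a base only when its own quality is ≥ 30 *and*
the mean quality of the ±5-bp window on the read is ≥ 30 (windows truncate
at read ends; the two-sided reading of "central/neighbourhood quality" is
this package's concrete interpretation of the filter).  Deletions are
tallied at the deleted positions and included in the qualified depth, so
minor-allele frequencies always have the qualified depth as denominator.

At every position with ≥ 100X qualified depth the major base is called; a
second base at ≥ the detection threshold (2%, 5% or 10%; 5% is the
reporting default, 2% the review band) becomes a mixed position coded with
its IUPAC symbol.  Three alleles above threshold route the position to QC
as multi-allelic mixture evidence instead of force-coding a two-base
symbol.  Positions below 100X are flagged, not called; a sample with ≤ 4
such positions ("nearly complete") may auto-confirm them when depth ≥ 20X
and major frequency ≥ 90% — an automated stand-in for the manual review
such positions receive in practice.

Homopolymer handling: indels are shifted to the 3'-most equivalent
position within their run (insertions take decimal suffixes at the run's
last position, e.g. `315.1C`; deletions report the run end, `315del`).
Length heteroplasmy in the configured C-stretch regions (nps 303–315 and
16,184–16,193, standard forensic bounds — the regions are conventionally
named but their coordinates are a design choice here) is resolved by a
read-count vote over reads fully spanning the run; only the major-length
molecule is reported, a 50/50 tie reporting the shorter (more
reference-like) molecule.  Point substitutions inside the runs (e.g.
T16189C) are unaffected.  Mixed positions inside the A-stretch artifact
zones (nps 300–302 and 16,180–16,183) are removed as post-homopolymer
sequencing artifacts before any classification.

## Classifying mixed positions

The two-stage review replaces analyst judgement with an explicit, ordered
rule set, so the classification is reproducible bit-for-bit.  The
classification universe is the 2%-threshold call set; reported mixed
positions are those at or above the reporting threshold, and per-threshold
views are obtained purely by filtering minor frequency, which makes the
2%/5%/10% call sets nest exactly.

**Stage 0 — strand balance.**  A minor allele whose observations fall
almost entirely on one strand (rarer-strand share < 10%, configurable) is
tagged `artifact`.  No published figure exists for this cutoff; it is a
package choice.

**Stage 1 — initial review.**  A position is provisionally NUMT when

* (a) it lies in one of the two documented NUMT signature regions
  (nps 12,612–13,105 and 16,390–16,527) and is in-phase with another
  universe member of the same region;
* (b) it is in-phase with a catalog NUMT variant; or
* (c) it belongs to a positional cluster (members ≤ 500 bp apart,
  circularly) in which at least half the members are catalog or
  signature-region members — restricted to candidates that themselves have
  catalog/region support and are not known PHP hotspots, so purely
  positional coincidence cannot overrule the phasing rules.

Phasing uses read pairs as the unit: fragments covering both positions
vote, `in_phase` requiring ≥ 90% of minor-bearing fragments to carry both
minors, with < 5 covering fragments deemed unassessable (150-bp reads and
~350-bp inserts make many pairs unassessable by construction, as in real
short-read data).

**Stage 2 — secondary review.**  Only positions with minor frequency
< 10% in samples with average depth ≤ 1500X enter the review — mixed
positions above either bound default to PHP, reflecting the empirical
envelope of NUMT interference.  Within the gate, known PHP hotspots
(nps 146, 152, 204, 16,093, 16,192 by default) are vetoed to PHP, and a
position is NUMT when at least two of the following concur: catalog
membership; the same variant provisionally NUMT-labeled in ≥ 3 other
samples; an in-phase 2–5%-band partner; not being a PHP hotspot.  The
"≥ 2 votes" structure is this package's explicit stand-in for a holistic
review and is configurable (`votes_required`), as are all gate values.
Everything else is a probable PHP.

Position 16,093 deserves note: it is both the most active heteroplasmy
hotspot and NUMT-susceptible, and short reads generally cannot phase it
against HVS1 NUMT variants.  The default keeps it classifiable (the
hotspot veto protects it); `ignore_16093 = TRUE` drops the position from
all interpretation, the conservative alternative.

## The simulator

The generator emulates the statistical structure the pipeline must
survive, with truth labels for every read pair:

* authentic mtDNA fragments drawn uniformly from the circular molecule
  (inserts Gaussian 350 ± 50 bp, 150+150 paired ends, constant Q35,
  per-base miscall 0.001 — desk-scale figures matching the patterned
  flowcell chemistry this workflow targets);
* point heteroplasmies realised per molecule at a stated minor fraction,
  independently across PHPs (so distinct PHPs live on distinct molecule
  subsets and phase discordantly, as authentic heteroplasmy does);
* NUMT donor reads from a donor haplotype over its homology span.  Two
  built-ins carry the documented signature clusters: `ND5_sig`
  (A13062G, T13095C, A13105G over nps 13,060–13,110) and `HVS1_sig`
  (G16390A, A16399G, C16444T, G16496A, T16519C, C16527T over
  nps 16,380–16,535).  Donor fragments are drawn from the span extended by
  one insert length of reference-identical flank on each side — real
  insertions carry homologous flanks, and without them no 150-bp read
  could cover a 51-bp signature.  A donor's `copy_fraction` is the target
  minor read fraction *at its own region* (donor depth over total depth
  there), which is the quantity the variant caller observes; a global
  read-fraction reading would concentrate reads on a small window and
  produce unrealistic local frequencies;
* optional exogenous contaminant molecules at a stated fraction of reads;
* a post-homopolymer error model: bases within 3 bp 3' of a run ≥ 4 bp
  (in read orientation) miscall at `error_rate × 20` by default, biased
  3:1 toward the run's base.  This is the simplest mechanism that
  reproduces the A-stretch artifact; no quantitative published rate
  exists, so the boost is a free knob, not a measured value.

A single RNG stream is seeded from the spec, and the generator
saves/restores the caller's RNG state, so identical seeds give
byte-identical output without side effects.

What the simulator does **not** model: PCR duplicates, indel sequencing
errors, GC bias, quality-score decay along the read, mega-NUMT
tandem-repeat structure, and damage patterns.  Passing tests therefore
demonstrate correctness of the pipeline's logic under the modelled error
structure, not robustness to every artifact of real instruments.

## Numerical and degenerate-input choices

* Consensus ties and zero-coverage positions → reference base.
* LHP length ties → shorter molecule.
* Mixed-position 50/50 ties keep the reference base as major when it is
  involved.
* Empty read sets map to an empty mapping with a warning; an empty
  first-pass mapping aborts the consensus workflow with a stage-named
  error; an empty classification yields an all-zero threshold report.
* Haplotype strings order insertions by decimal suffix between their
  anchor and the next position.
* All percentages in reports round to one decimal.

## The bundled reference

The packaged FASTA (`inst/extdata/rCRS_synthetic.fa`) is **synthetic**: a
16,569-bp sequence with human-mtDNA base composition carrying the
canonical control-region landmark motifs (A-stretches, C-stretches with
their T interruptions, hotspot and signature reference bases) at their
true rCRS coordinates, generated deterministically by
`data-raw/make_reference.R`.  Every coordinate-anchored rule behaves
exactly as on the real reference, and the whole package operates on any
user-supplied single-sequence FASTA — for real data, use the genuine rCRS
(NC_012920.1).  The synthetic sequence simply makes the package and its
tests self-contained.

## Problem sizes

The test suite validates most behaviour on 150–300X simulations (a few
thousand read pairs each) and runs one 2000X sample (~111,000 pairs)
end-to-end for signature recovery; the whole suite completes in about two
minutes on a single core, the acceptance script in under a minute.  These
sizes were chosen as the smallest at which the binomial envelopes around
the 5% detection threshold are comfortably separated from the planted
fractions.

## Known limitations

* The nuclear side of WGS is out of scope: the percentage of total reads
  mapped to the nuclear genome, and kinship coefficients, enter only as
  optional metadata.
* Haplogroup assignment, phylogenetic mixture deconvolution and BLAST
  discovery of novel NUMTs are not implemented; external labels and
  catalogs are accepted as inputs.
* The substitution-only consensus cannot capture a majority indel
  haplotype during remapping; at the stringent thresholds in use a 1-bp
  indel costs ~0.7% similarity, which never rejects a read, so this has no
  effect on acceptance.
* SAM export of origin-spanning alignments keeps the full CIGAR with a
  `ZC:i:1` tag rather than splitting the record; consumers that insist on
  strictly linear coordinates should split on import.
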