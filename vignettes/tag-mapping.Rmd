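---
title: "Mapping peptide sequence tags onto six-frame translated genomes"
author: "pstmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peptide sequence tags onto six-frame translated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstmap)
```

## The problem and the approach

Automated structural annotation of eukaryotic genomes is error-prone:
exon/intron boundaries, start codons and entire genes are mispredicted,
especially in intron-rich genomes with short intergenic regions. Shotgun
proteomics offers direct evidence of translation. Instead of searching
spectra against a predicted protein database (which can only confirm what
was predicted), this package takes the *sequence-tag* route: each MS/MS
spectrum is partially interpreted de novo into a **peptide sequence tag
(PST)** — a short run of 3–5 confidently called residues together with the
masses of the two fragment ions flanking it, `mn` on the N-terminal side
and `mc` on the C-terminal side. PSTs are then located directly on the
six-frame translation of the genome, with no gene models in the loop, so
evidence can fall where no gene was predicted.

A **hit** is a genomic placement of a PST that survives three filters:

1. the tag matches the translated frame exactly (I and L, being isobaric,
   are treated as equivalent);
2. extending outward from the tag to tryptic boundaries (after K/R, not
   before P; segment ends also qualify, since a stop codon truncates the
   reading frame) explains *both* flank masses within an absolute
   tolerance, allowing a bounded number of amino-acid modifications;
3. the inferred peptide carries at most the allowed number of internal
   missed-cleavage sites.

The flank arithmetic is monoisotopic throughout. `mn` follows the b-ion
convention (residue sum + one proton) and `mc` the y-ion convention
(residue sum + water + proton); both offsets are configurable in
`mass_constants()` because tag generators differ in how they reference
their ion ladders. A modification may sit on any eligible residue of the
inferred peptide; only modifications falling in a flank shift that flank's
mass, and one mass budget (`max_mods`, default 1) covers both flanks of a
placement.

Hits are then **clustered**: per contig and strand, hits sorted by start
join a cluster while the gap (bases strictly between the running cluster
end and the next hit start) is at most `maxdist`. Clusters must contain at
least `minhit` hits and `minpep` distinct (I/L-normalized) peptides.
Because exons of one gene change reading frame across introns, frames are
deliberately *not* separated during clustering — the gap threshold, not
translation, bridges introns.

Finally clusters are **qualified** against an existing GFF3 annotation
with four labels:

* `IN` / `OUT` / `CROSS` — cluster span fully inside at least one mRNA /
  overlapping none / straddling one;
* `ANNOTATED` / `UNANNOTATED` — at least one hit fully contained in a
  CDS, or none;
* `DUBIOUS` / `POSSIBLE` / `SURE` — 0–1 typical spectra; ≥2 typical
  spectra but <3 distinct peptides; ≥2 typical spectra and ≥3 distinct
  peptides. A *typical* spectrum is one whose every hit, genome-wide,
  falls inside the cluster — evidence specific to that region;
* `OK` / `CHECK` — every hit CDS-contained, or at least one not.

`UNANNOTATED + SURE` clusters are candidate novel coding regions;
`ANNOTATED + SURE + CHECK` clusters flag gene models worth revisiting
(wrong exons, alternative start codons). `clusters_to_gff3()` writes
`match`/`match_part` features so the evidence can be inspected in a genome
viewer next to the annotation.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `tolerance` | 0.5 | Da | absolute flank-mass tolerance; suited to ion-trap fragment accuracy. It deliberately absorbs small near-isobaric confusions (e.g. DD = 230.05 vs ET = 230.09 Da) without expanding the tag alphabet |
| `max_mods` | 1 | count | modifications available to explain both flanks of one placement |
| `modifications` | C +57.02146, M +15.99491 | Da | carbamidomethyl-cysteine and oxidized methionine; the "+57/+16" labels are nominal only |
| `missed_cleavages` | 1 | count | internal K/R sites allowed in the inferred peptide |
| `maxdist` | 5000 | nt | maximal inter-hit gap within a cluster — chosen for a genome whose intron median (531 nt) and intergenic median (2529 nt) are uncomfortably close; 5 kb covers nearly all introns while limiting gene merging |
| `minhit`, `minpep` | 3, 2 | count | evidence floor per cluster |

Only I/L are collapsed during tag matching. K/Q and other near-isobaric
pairs are *not* expanded: the 0.5 Da flank tolerance already tolerates
them on the mass side, and expanding tags would multiply spurious matches.

## Coordinates and numerical conventions

All internal coordinates are 1-based inclusive on the forward strand (the
IRanges/GFF3 convention), so interval work and GFF3 I/O need no
conversion anywhere. Codons containing `N` break translated segments
rather than translating to `X`, so ambiguous sequence can never support a
tag match. Flank extension is pruned once the accumulated residue mass
exceeds the flank mass plus tolerance (plus any negative modification
delta that could compensate); this makes verification linear in practice.
When several boundary pairs verify at one tag position all are reported —
the clusterer tolerates them — but exact duplicate placements of one
spectrum collapse to the fewest-modification explanation. Contigs shorter
than a codon yield zero segments; empty PST sets yield empty (but valid)
outputs at every stage.

## What the simulator emulates

`synth_genome()` builds a contig of multi-exon genes with random protein
sequences, codon-aligned CDS pieces, and log-normal length samplers
parameterized by their medians: CDS pieces 137 nt, introns 531 nt,
intergenic spacers 2529 nt, with Poisson(7) introns per gene — the
feature statistics of a compact, intron-rich nuclear genome. Gene length
then emerges near its observed ~4.8 kb median, which is why no separate
gene-length sampler exists; likewise exons carry no UTRs here, so the
exon sampler *is* the CDS sampler. The log-normal shape (σ = 0.5 in log
space) is a modelling choice: strictly positive and right-skewed like
real feature lengths, with only the medians constrained by data. Genes
alternate strand along the contig, reflecting interleaved gene
orientation and keeping the strand-aware clusterer meaningful. Base
composition is uniform (GC 0.5).

`synth_psts()` digests each protein with trypsin and samples peptides
that are *interior* to a single CDS piece — one residue of context on
each side within the same piece, ending on K/R — so that their tryptic
boundaries survive on the genome and a splice-unaware mapper can recover
them. Tags are sampled interior to the peptide (at least one flanking
residue on each side), because a PST is defined by its two flanking
fragment ions; a tag spanning the whole peptide would carry no flanking
evidence at all. Flank masses receive Gaussian noise (default sd 0.1 Da,
a realistic ion-trap scale; set 0 for noise-free data), and decoy PSTs
(random tags, flank masses uniform over the plausible range) can be mixed
in at a configurable fraction as a simple null model.

What the simulator does **not** emulate: spectrum-level error structure
(residue transpositions, charge-state confusions, systematic calibration
drift), peptides spanning exon junctions, UTRs, nonuniform codon usage or
base composition, and paralogous sequence. Passing tests on synthetic
data therefore demonstrate the correctness of the mapping, clustering and
qualification machinery under the stated genome statistics — not the
end-to-end sensitivity achievable on real spectra, which depends mostly
on the upstream tag caller.

## Design choices where the design was open

* **Flank-mass offsets.** Tag generators do not agree on whether ion
  masses are proton- or hydrogen-referenced; the b/y convention is the
  default and both offsets are user-settable rather than hard-coded.
* **Segment ends as cleavage boundaries.** A stop codon truncates the
  frame, so a peptide abutting a segment end cannot display its K/R
  context; treating segment ends as boundaries (both for the N- and
  C-side) recovers those placements. Configurable behaviour was not
  worth the interface cost.
* **Strand-aware clustering** is the default (`strand_aware = FALSE`
  exists for annotations with unreliable strands). Opposite-strand genes
  overlap rarely enough that collapsing strands mostly adds confusion.
* **`minpep` counts distinct I/L-normalized peptide strings**, not
  distinct tags: two spectra reading different tags from the same peptide
  are one piece of peptide-level evidence.
* **CDS inclusion means full containment** in a single CDS feature;
  partial overlaps are tallied separately (`cds_cross`), since a
  straddling peptide is exactly the signal that an exon boundary may be
  wrong.
* **Typicality is genome-wide**: a spectrum hitting two distant regions
  is specific to neither.
* **IN requires containment in any single mRNA** — isoforms share exons,
  so containment in one isoform suffices.
* **Hit intervals cover the full inferred peptide**, not just the tag, so
  cluster spans reflect peptide evidence extents.

## Known limitations

* A cluster can swallow two neighbouring same-strand genes when the gap
  between their nearest hits falls under `maxdist`; the resulting merged
  cluster qualifies CROSS rather than IN. This is the price of a 5 kb
  gap threshold in a genome whose intergenic median is 2.5 kb, and it is
  visible occasionally in simulations (it does not reduce gene recovery —
  both genes are still matched). Lowering `maxdist` trades this against
  splitting genes with long introns.
* Peptides spanning exon junctions are invisible to the mapper by
  design; junction evidence accrues only through clustering.
* No statistical error control (FDR) is attached to hits or clusters;
  the label families are qualitative filters intended for expert review,
  not significance statements.

## Problem sizes used by the test suite

The package's own checks run entirely on simulated data: mapping is
verified against an exhaustive enumerate-all-tryptic-peptides oracle on
twenty random genomes of 0.6–1.5 kb; clustering against a
transitive-closure oracle on a thousand random hit configurations; and
the end-to-end recovery property on a 50-gene proteogenome (~370 kb,
roughly 400 PSTs) with noise-free tags, where every gene emitting at
least three PSTs over at least two peptides must be recovered by an
IN/ANNOTATED cluster and sensitivity must be exactly 1. Selectivity is
additionally checked to be non-increasing as the decoy fraction rises
over 0, 0.2 and 0.5.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_genes = 10, flank_mass_error_sd = 0, seed = 42)
paths <- synth_dataset(cfg, "demo")
res <- run_pipeline("demo/genome.fasta", "demo/annotation.gff3",
                    "demo/psts.tsv", "demo/out",
                    expected_ids = expected_gene_set(paths$truth))
res$eval
head(res$qualified[, c("cluster_id", "start", "end", "n_hits",
                       "n_peptides", "category", "annotation_label",
                       "confidence_label", "consistency_label")])
```
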