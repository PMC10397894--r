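---
title: "Screening doublesex splice sites for SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening doublesex splice sites for SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agdsx)
```

## The biological question

Somatic sex in *Anopheles gambiae* is set by sex-specific alternative
splicing of the *doublesex* (*dsx*) transcription-factor gene, AGAP004050 on
chromosome arm 2R (48,703,664–48,788,460, reverse strand). The female
transcript (*AgdsxF*, 8,667 bp of exon) retains exon 5; the male transcript
(*AgdsxM*, 6,975 bp) skips it, splicing the whole region out inside one long
intron. Exon 5 is therefore a cassette exon, and the splice signals that
flank it — the female-specific intron 4 acceptor and exon 5 donor — are the
places where a sequence change could plausibly flip the splicing outcome.
This package asks, over a population cohort of genotyped mosquitoes: do the
donor and acceptor splice sites of *dsx* carry SNPs, are any of them
sex-associated, and are any plausibly splice-relevant?

## Gene model and junction identity

A gene model is a set of transcripts, each an ordered list of 1-based
inclusive exon intervals in transcript (5'→3') order; on the minus strand
genomic coordinates decrease along the transcript. Intron *i* is the genomic
gap between exons *i* and *i*+1, so exons and introns tile the transcript
footprint exactly — a property the tests assert.

Because the male transcript skips an exon, male exon/intron ordinals are
shifted by one relative to female ordinals over the 3' half of the gene.
Junction identity is therefore keyed by **(kind, genomic coordinate of the
exonic edge base)**, never by ordinal: the acceptor that is "female intron 5"
and "male intron 4" is one physical junction, and it is classified shared. A
junction is *shared* iff it occurs in every transcript; otherwise it is
tagged with the transcripts that use it. Using the exonic edge base (rather
than the intronic GT/AG base) as the key is an arbitrary but fixed choice;
either convention works as long as it is applied uniformly.

Cassette exons are detected structurally: an exon of transcript A is a
cassette relative to transcript B when the exon *and both of its flanking
introns in A* lie inside a single intron of B. On the packaged model this
finds exactly one: female exon 5 (48,712,957–48,714,648) inside male
intron 4 (48,712,795–48,715,160).

A terminal exon has no donor and a first exon has no acceptor; requesting
one is an error. The 3'-terminal exon consequently contributes only its
acceptor to the site table.

## Splice-site windows

Every junction gets a 22-nt screening window:

* **Donor**: the last 6 exonic bases plus the first 16 intronic bases.
  The intron opens with the near-invariant `gt` dinucleotide (window
  offsets 6–7 in transcript orientation).
* **Acceptor**: the last 16 intronic bases plus the first 6 exonic bases.
  The intron closes with `NYag` (N = any base, Y = pyrimidine), preceded by
  a 12-nt polypyrimidine tract. In transcript orientation the offsets are:
  0–11 tract, 12 N, 13 Y, 14–15 `ag`, 16–21 exon.

Two conventions are fixed deliberately:

* The `N` of `NYag` is **not** part of the 12-nt tract; the tract is the 12
  bases preceding the 4-base pattern. The pyrimidine count is over those 12
  bases only.
* Window edges are inclusive on both sides. The variant at 48,712,962 sits
  exactly on the exon-side edge of the exon 5 donor window and is counted,
  consistent with the source screen.

Whether the `N` position itself should count as screenable is not settled
by the source material; it is included here at the plain "window" tier.

Sequences are rendered in transcript orientation (reverse-complemented on
the minus strand) with a `/` at the exon–intron boundary. Case encodes
annotation: intronic bases lower-case; exonic bases upper-case when coding.
The packaged model carries approximate coding bounds (the CDS runs from
within exon 2 to the start of exon 5; the exact UTR switch points between
splice windows are not annotated) — they are sufficient to reproduce the
published casing of every base inside the 12 windows, which is all they are
used for. Windows that run off the contig are truncated and flagged rather
than silently padded; non-ACGT bases are carried through upper-cased with a
warning.

The acceptor polypyrimidine score is the count of c/t in the tract, reported
against a literature consensus mean of 8.69 pyrimidines for *An. gambiae*
acceptor sites (a cited constant, configurable, never recomputed here). The
female intron 4 tract (`tttatgtttaac`) scores 8; the identical genomic
stretch inside male intron 4 necessarily scores the same, which is the
point: the cassette acceptor is not unusually weak. One curiosity the motif
validator surfaces: the male intron 4 acceptor closes with `aaag`, a purine
at the Y position, and is flagged non-canonical.

## Variant screen

From the VCF the screen keeps records that are FILTER=PASS, single-nucleotide
REF and ALT, one ALT allele, inside the gene span, in coordinate order;
multiallelic and non-SNP records are counted and dropped. Missing IDs become
`rs` + position. Genotypes are reduced to alt-allele dosages 0/1/2 with
missing calls as NA.

Each (variant, window) intersection is annotated with:

* **tier** — `dinucleotide` (on the invariant gt/ag), `NYag_Y` (acceptor Y),
  or `window` (anywhere else);
* **sex presence** — which sexes contain at least one called alt-carrying
  sample (`female_only`, `male_only`, `both`, `absent`). This is the
  descriptive summary the screen's conclusions rest on;
* a **Fisher exact test** on the 2×2 sex-by-allele-count table, an added
  inferential summary that never overrides the descriptive flags (it is
  skipped, with a flag, when a sex has no called samples);
* per-stratum **minor allele frequency**: within each (country, sex) cell,
  alt frequency *p* = alt alleles / (2 × called samples), MAF = min(*p*,
  1 − *p*); a cell with no called samples is undefined (NA), never zero.

Because "carried by 2% of males" can mean carrier frequency or allele
frequency, the MAF table reports called samples, alt-allele counts and
frequencies side by side so either reading can be checked.

**Splice relevance** is an informal judgement in the source material; here
it is operationalised as a fixed, exposed rule: a hit is splice-relevant iff

> tier ∈ {dinucleotide, NYag_Y}, **or**
> (tier = window **and** sex presence is exclusive to one sex **and**
> max per-stratum MAF ≥ 0.05).

The threshold (default 0.05) and the rule live in one place
(`splice_relevance()`). On the reported hits the rule reproduces the
published verdict: both exon 5 donor SNPs are plain window hits, present in
both sexes or far below threshold, hence *not* splice-relevant.

## Nucleotide diversity

Per window of length *L* (default 500 bp, tiling the span, last window
truncated at the edge):

$$\pi = \frac{1}{L}\sum_v \frac{2\,d_v\,(n_v - d_v)}{n_v\,(n_v-1)}$$

with \(n_v\) the called allele count and \(d_v\) the alt count at variant
*v*. This is the unbiased mean pairwise difference per site; the tests check
it against a brute-force enumeration of all allele pairs to 1e−12, and check
relabeling invariance (d → n − d), length-weighted additivity under window
concatenation, and unbiasedness under half-panel subsampling. Variants with
fewer than two called alleles are skipped and counted. The denominator is
the full window length — no site-accessibility mask is applied, so values
from masked pipelines are approximated in level, not matched; between-strata
*comparisons*, which is what the screen needs, are unaffected. Diploid
genotypes enter only through allele counts; phasing is irrelevant to π.
Strata with fewer than two samples are skipped with a warning. The 500-bp
window is a package default chosen to give ~170 windows across the 84.8-kb
locus; it is exposed as a parameter.

## The synthetic cohort generator

The generator exists so that every stage is runnable and testable without
the multi-gigabyte population callset. From one seed it produces:

* **Reference contig** — the gene span filled with uniform random bases,
  then every one of the 12 splice-site sequences written over it
  (reverse-complemented for forward-strand storage) at its published
  coordinates, after validating each against the model-derived window.
  The contig stores an `offset=` token in its FASTA header so the pipeline
  works in true genome coordinates; a uniform coordinate shift of the whole
  system (model, sites, contig) is supported and tested.
* **Cohort** — 655 samples (574 F / 81 M) expanded deterministically from
  the published per-site country/sex counts.
* **VCF** — planted variants at the nine reported splice-window positions
  with stratum-specific alt frequencies chosen to match the published
  statements (exon 5 donor pair: under 1% in females — 0.8% Burkina Faso F,
  0.5% Cameroon F — and 2% in Burkina Faso males; the seven intron 3
  acceptor SNPs at 2–10% in all strata), plus background SNPs at
  17,196 / 84,797 ≈ 0.203 sites/bp — the density observed at this locus in
  the real cohort. Background positions avoid the 22-nt windows by default
  so the windows contain exactly the planted set; each background variant
  gets one cohort-wide frequency drawn from a neutral 1/x site-frequency
  spectrum on [0.001, 0.5] (the background cohort is panmictic by
  construction). Genotypes are Binomial(2, p) per sample (Hardy–Weinberg);
  missingness is injected at a configurable rate (default 0, matching the
  near-complete PASS callset).

What the generator does **not** emulate: linkage disequilibrium and
coalescent genealogy (sites are independent — sufficient for frequency and
π recovery, wrong for haplotype statistics), population differentiation
(background frequencies are shared across strata, consistent with the
published finding of near-identical diversity between strata), sequencing
error, and accessibility masking. Passing tests therefore demonstrate
correctness of the *computations* on realistic marginal structure, not
robustness to LD or cohort substructure.

## Numerical and design choices

* Coordinates are 1-based inclusive `[low, high]` + strand throughout
  (matching VCF); transcript-order rendering (start > end on the minus
  strand) appears only in report columns.
* The whole fixture set is a pure function of the seed; argument evaluation
  is forced before seeding so nested generator calls cannot perturb the
  stream.
* Degenerate inputs fail loudly: zero-length exon gaps, overlapping exons,
  windows outside the contig, VCFs without genotypes, samples missing from
  metadata. Empty results (no junctions hit, empty region) are empty
  tables, not errors.
* Replicated statistical tests use 100–200 replicates at small cohort sizes
  (20–100 samples, 50–250 variants) and the full 655-sample cohort where
  the published stratum sizes are the point (MAF recovery); the brute-force
  π oracle runs at 20 samples × 50 variants.

## Known limitations

* Single-gene scope: the GFF3 reader handles one gene's exon features
  grouped by `Parent`; transcriptome-wide batch parsing is out of scope.
* The relevance rule is a sharp operationalisation of an informal judgement;
  its MAF threshold is a tunable, not an estimate.
* π levels are unmasked (see above) and the generator's background model is
  exchangeable across strata — between-stratum π differences in real data
  will exceed the simulated ones.
* No splice-strength models (position weight matrices, maximum-entropy
  scores), branch-point prediction, or enhancer/silencer motif scanning:
  the screen is positional and motif-anatomical by design.
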