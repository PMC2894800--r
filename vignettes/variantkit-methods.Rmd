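---
title: "variantkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{variantkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variantkit)
```

variantkit is a standalone toolkit for the computational core of a
genome-browser variation pipeline: discovering SNPs from quality-scored
resequencing reads, merging and quality-controlling variants, predicting
their consequences on transcripts, and post-processing population genotypes
into linkage-disequilibrium (LD) summaries and tag-SNP lists. This vignette
explains each method, its assumptions and tunable parameters, the numerical
choices made where the design was open, and what the synthetic-data
generator does and does not emulate.

## Coordinate model

All coordinates are 1-based, fully closed, on the forward genome strand.
Insertions are represented with `start = end + 1` (the insertion point sits
between the two flanking bases); insertion reference alleles and deletion
alternate alleles are written `"-"`. VCF's anchored-base indel style is
converted to this convention on read and restored on write, keeping a VCF
round trip lossless.

Transcripts are exon lists with optional CDS bounds. Two offset functions
drive all splice-site logic:

* `intron_offset()` — distance from an intronic base to the nearest intron
  edge, with the terminal intron base at offset 1. Offsets 1–2 are the
  essential splice dinucleotides, 3–8 the extended intronic splice region.
* `exon_edge_offset()` — distance into an exon from the nearest
  *intron-adjacent* boundary (transcript termini are not splice junctions).
  Offsets 1–3 add the "splice site" modifier to exonic classes.

Both take the minimum over the two candidate edges, which makes them
symmetric under reverse-complementing the genome; donor and acceptor ends
are deliberately not distinguished, because the positional rules being
implemented are symmetric ("the first 2 or the last 2 base pairs of an
intron"). This symmetric-minimum rule is a design choice: the alternative —
measuring only from the donor side in transcript orientation — would change
no class boundaries for the symmetric rule set used here.

Codons containing N translate to the unknown amino acid X rather than
raising an error, so scaffolds with ambiguity characters annotate cleanly.

## NQS SNP calling

A mismatch column becomes a SNP call only if the supporting read bases meet
the neighbourhood quality standard (NQS) and the site passes evidence
filters. Defaults (all exposed in `caller_config()`):

| parameter | default | meaning |
|---|---|---|
| `min_variant_phred` | 23 | variant base PHRED, inclusive |
| `min_flank_phred` | 15 | flanking base PHRED, exclusive |
| `exact_flank_bp` | 5 | bases each side that must align exactly |
| `mismatch_window_bp` | 10 | one-sided mismatch-count window |
| `max_flank_mismatches` | 1 | mismatches allowed in that window |
| `max_read_mismatches` | 30 | per-read mismatch cap |
| `max_site_depth` | 100 | aligned-read depth cap per site |
| `low_coverage_threshold` | 0.1x | coverage below which caps shrink |
| `low_coverage_scale` | 0.5 | shrink factor |
| `min_depth_for_minor_rule` | 4 | passing depth at which minor-allele support is required |
| `min_minor_reads` | 2 | minor-allele read support |
| `max_alleles_per_individual` | 2 | allele cap per individual per site |

Design choices worth noting:

* The "five bases align exactly" and "at most one mismatch in ten flanking
  base pairs" requirements are nested conditions: exact, gapless,
  high-quality match within ±5 bases (an indel in the flank fails it), and
  at most one mismatch within ±10. This makes both clauses simultaneously
  satisfiable.
* The ±10 window truncates at read ends rather than disqualifying the base;
  the exact ±5 flank, by contrast, must exist in full, so variant bases
  within 5 bp of a read end never pass.
* Depth against `max_site_depth` counts all aligned reads covering the site
  after the read-level filters, before NQS filtering; the cap applies to
  sites, not reads.
* Read-pair information is used only to drop improperly paired reads
  (`mate_status == "improperly_paired"`); unpaired reads are kept.
* The scale factor applied below 0.1x coverage is a parameter
  (`low_coverage_scale`, default 0.5) because no specific reduced values
  are published; the caps are floored after scaling.
* The minor-allele rule engages when two alleles are observed at passing
  depth ≥ 4; a site where every passing read carries the same non-reference
  allele (a homozygous difference) is reported without it.
* Indel calling is out of scope for the caller; indels enter the toolkit
  through VCF import only.

`sara_genotype()` applies the identical evidence machinery at known variant
loci and emits a SARA ("same as reference assembly") record when every
passing observation equals the reference — a computational genotyping assay.
Loci with any passing non-reference observation are left to `call_snps()`.

`coverage_ranges()` reduces an individual's alignments to maximal intervals
in two depth classes — exactly one read versus at least two — which is the
granularity used for display of resequencing coverage.

## Variant merging and QC

`normalize_strand()` rewrites reverse-strand reports onto the forward strand
(reverse-complementing all alleles; idempotent). `merge_variants()` collapses
records at identical coordinates into one record whose primary identifier
prefers dbSNP `rs` ids, then `ss` ids, then anything else (ties broken by
natural order); all other identifiers become synonyms and allele sets are
unioned. Records sharing a primary id at several coordinates contribute
multiple mappings to a single record. Allele-set compatibility is *not*
required for collapsing — the collapse key is coordinate identity alone.

`classify_failed()` implements four failure rules: more than three genomic
mappings (`MAPS_GT3`), no mapping at all (`NO_MAPPING`), no observed allele
matching the reference at any mapping (`NO_REF_ALLELE_MATCH`), and more than
three observed alleles (`GT3_ALLELES`). A user-supplied whitelist of ids
(for medically important variants known to be correct) exempts records from
failure. An `OTHER` flag value is reserved for future checks. Failed
variants are retained but carry no displayed mapping: `passing_variants()`
is the gate through which annotation and LD receive input.

## Consequence annotation

Every (variant, transcript) pair within 5 kb receives one consequence per
alternate allele from a closed vocabulary of 26 labels
(`consequence_types()`), ranked by estimated severity (rank 1 = most
severe); `rank_calls()` sorts by that order with transcript-id tie-breaks.
The decision order is: outside the transcript span → Upstream/Downstream by
transcript orientation (Intergenic beyond 5 kb); non-coding transcript →
Within mature miRNA or Within non-coding gene; intronic → Essential splice
site (offset ≤ 2), Splice site (3–8), else Intronic; exonic → 5' UTR / CDS /
3' UTR with a splice-site modifier when the base lies 1–3 bp from a splice
junction; CDS SNVs are classified by translating the reference and alternate
codons (Stop gained / Stop lost / Non-synonymous / Synonymous); CDS indels
are Frameshift coding when the length change is not a multiple of 3, and
indels spanning an exon/intron or CDS/UTR border are Complex InDel.

Open points resolved as package design choices:

* The 1–3 bp "into an exon" rule counts only intron-adjacent exon
  boundaries; a base 1–3 bp from a transcript terminus gets no modifier.
* Multi-allelic variants get one call per allele; when one allele gains a
  stop and another shifts the frame on the same transcript, the two calls
  collapse into the dedicated combined class.
* In-frame CDS indels that cross no border are labelled Non-synonymous
  coding, the closest available "affects the peptide" class (no dedicated
  in-frame-indel label exists in the vocabulary).
* Loss of the start codon is reported as Non-synonymous coding (no
  start-lost class exists).
* Regulatory region calls require an explicit BED input of regulatory
  features; each overlapped feature adds one call.
* A variant's summary consequence, where one is needed (CLI output), is the
  minimum rank across its calls.

## LD and tag SNPs

`maf()` is minor-allele count over twice the number of non-missing samples.
`em_haplotypes()` estimates two-locus haplotype frequencies from unphased
diploid genotypes by EM: only double heterozygotes are phase-ambiguous, and
the E-step splits them between coupling and repulsion in ratio
p~AB~·p~ab~ : p~Ab~·p~aB~. Initialization is at linkage equilibrium
(products of the observed allele frequencies, which are fixed by the
genotype margins), giving a deterministic start that also breaks ties
between symmetric likelihood modes. Convergence is declared when the largest
frequency change falls below `tol` (10^-9^, within 1000 iterations); the
log-likelihood trace is returned and is non-decreasing by construction of
EM. From the converged frequencies: D = p~AB~ − p~A~p~B~; D' = D/D~max~ with
D~max~ = min(p~A~p~b~, p~a~p~B~) for D > 0 and min(p~A~p~B~, p~a~p~b~) for
D < 0 (D' = 0 at D = 0); r² = D²/(p~A~p~a~p~B~p~b~). D' is reported as an
absolute value (the signed value is kept internally). Monomorphic loci are
excluded rather than reported as r² = 0, since r² is undefined there.
Missing genotypes are handled pairwise-complete.

`windowed_ld()` computes every same-sequence pair within a 100 kb window for
populations of at least 40 samples, discards pairs with r² < 0.05, and
returns the stored table that feeds tag-SNP selection (on-demand pairwise LD
is available separately through `em_haplotypes()`). `select_tag_snps()`
ranks variants by MAF (highest first, ties by ascending position) and walks
down the ranking, each retained variant removing every other retained
variant within the window whose pairwise r² exceeds 0.99. Removing the
*later-ranked* partner subsumes the published "lower MAF is removed" rule
and also resolves equal-MAF perfect-LD pairs, which a strictly-lower rule
would leave both retained.

## Synthetic data

`fixture_spec()` + `simulate_bundle()` generate a complete, deterministic
study from one seed (per-output sub-seeds are derived from it, so adding an
output does not shift the others): a 20 kb random reference; a 3-exon
plus-strand coding transcript, a 2-exon minus-strand coding transcript
(both with clean ORFs ending in TAA) and a miRNA gene with a mature
interval; one regulatory feature; 10x reads of length 50 at PHRED 35 with
five planted heterozygous SNPs; and a 100-sample population genotyped at
three two-locus blocks spanning perfect LD (p~AB~ = p~ab~ = 0.5), moderate
LD, and linkage equilibrium. Planted alternate alleles are carried by
alternating overlapping reads, so allele support is balanced near 50% by
construction rather than by sampling — this guarantees the minor-allele rule
is satisfiable at the default depth. The default error rate is 0; when
raised, errors receive low base qualities and never touch planted sites.

The generator emulates the *evidence structure* the methods consume — base
qualities, mismatch columns, unphased genotypes with known haplotype
frequencies — not realistic sequencing artifacts: no indel errors,
quality-by-cycle decay, mapping ambiguity, or coalescent population
structure (pairwise blocks only). Passing tests therefore demonstrate rule
correctness and estimator calibration, not robustness to real-data noise.

Problem sizes in the test suite (a per-base consequence sweep over a
transcript with ±5.1 kb flanks, caller oracles on ≤ 50-read sets, EM checks
on 40-sample tables, D' recovery over 200 replicates of 1000 samples,
tag-SNP brute force on ≤ 10-SNP instances) were chosen so each check
exercises every rule boundary while the whole suite runs in about a minute.

## Known limitations

No realignment, base-quality recalibration or genotype likelihoods in the
caller; no haplotype phasing beyond two loci; no HGVS notation, protein
domain overlap, or ancestral-allele context in the annotator; GTF/GFF3
reading covers the standard exon/CDS/mature-miRNA feature set, not
trans-splicing or incomplete terminal codons beyond truncation.
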