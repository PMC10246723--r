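---
title: "Quantifying cytosine base-editing outcomes in mosaic embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytosine base-editing outcomes in mosaic embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicbe)
```

## The problem

Cytosine base editors (CBEs) deaminate cytosines within a narrow window of
the protospacer (positions 5–7, numbered from the PAM-distal end), converting
C·G pairs to T·A without a double-strand break. When the editor is injected
into individual blastomeres of an 8-cell embryo, each blastomere becomes an
independent editing experiment over its two (2PN) or three (3PN) allele
copies, and the embryo as a whole is a mosaic. The analytical questions are:
which allele types does each blastomere carry, how many copies of each, what
fraction of allele copies acquired the targeted conversion, what unwanted
outcomes (bystander substitutions, indels) occurred, and did the editor leave
a footprint elsewhere — in the transcriptome (deaminase C·G→U·A signature),
in the genome (de novo SNVs), or at sequence-similar off-target sites.

`mosaicbe` implements this analysis stack end to end, together with a
synthetic-data generator that produces every input with known ground truth.
The generator defines the conditions under which the pipeline is validated;
it is not a tuning knob.

## Allele calling from amplicon reads

Reads are aligned to the amplicon reference semi-globally (the read aligns
end to end; reference overhangs are free) with affine gap penalties:
match +2, mismatch −3, gap open −8, gap extend −1, so a gap of length $L$
costs $8 + L$. `N` never matches. Ties are broken deterministically —
mismatch preferred over gap, then leftmost placement — so repeated runs give
byte-identical output. Equal-length reads with at most three mismatches take
a gapless fast path; with this scoring a gapped alignment of equal-length
sequences must pay two gap openings (≥18) and can recover at most 5 per
rescued mismatch, so the gapless alignment is provably optimal there.
Reads below 60% alignment identity are rejected and counted as unalignable.

Aligned reads are reduced to their difference signature inside the
*quantification window* (protospacer ±10 nt) and collapsed by identical
signature. Signatures with fewer than `min_reads = 5` reads or less than
`min_fraction = 0.10` of the blastomere's aligned reads are discarded as
sequencing noise (no published read-support cutoff exists for this design;
both thresholds are explicit arguments, and at depth 100 with 0.3% per-base
error they remove essentially all error signatures while retaining a 1-in-3
minority allele). Classification follows the category definitions: `intact`
(no window differences); `indel` (any indel overlapping the window — indels
dominate); `targeted_substitution` (C→T at target positions only); `NTS`
otherwise. Haplotype-defining substitutions outside the window (APOE codon
112 sits 138 bp upstream of codon 158 on the same amplicon) are genotyped
alongside the window but never enter the classification.

One design choice deserves emphasis: an allele carrying the targeted C→T
*plus* a bystander substitution is categorized NTS (each allele belongs to
exactly one category, and indel/NTS frequencies stay disjoint), but its
copies still count as converted in allelic-efficiency accounting. Tying
conversion to "clean" alleles only would deflate the conversion estimate by
the bystander rate and bias parameter recovery; the category frequencies and
the conversion rate answer different questions.

## Ploidy-aware genotyping

The single-blastomere genotyping rule is: one observed allele type ⇒
homozygous, 0% or 100% allelic editing efficiency; two observed types ⇒
heterozygous, 50% in 2PN blastomeres and 33.3% or 66.7% in 3PN blastomeres
depending on the copy number of the edited type. The published rule names
the two triploid efficiency classes but not the assignment; here the edited
type receives two of the three copies when its read fraction is ≥ 0.5 (a tie
favours two copies). Reads are drawn near-uniformly from copies, so the
fractions concentrate around 1/3 and 2/3; at depth 100 with ≤0.5% error the
misassignment probability is that of a Binomial(100, 1/3) exceeding 50 —
below 1 in 2000. Genotype class is defined by the edit status of the copies
(all / none / mixed), so two distinct edited types in a diploid blastomere
are `homozygous_edited` at 100%. Blastomeres showing more types than the
ploidy (whole-genome-amplification artifacts) are flagged `excess_alleles`
and excluded from allelic statistics but retained in reports.

APOE ε haplotypes are read directly from codons 112 and 158 of the called
allele sequence: ε2 = Cys/Cys, ε3 = Cys/Arg, ε3r = Arg/Cys, ε4 = Arg/Arg
(Arg = CGC, Cys = TGC). The label algebra is closed under codon-158 editing:
ε4→ε3r, ε3→ε2. Embryo summaries report the fraction of injected blastomeres
with at least one edited copy, the allelic conversion rate (mean allelic
efficiency, equivalently the copy-weighted converted fraction), the ε4-free
blastomere fraction, and copy-weighted pre/post allele-frequency tables over
{ε2, ε3, ε3r, ε4, NTS, indel, other}, each summing to 100%. The embryo's
parental genotype is taken from its un-injected blastomeres by majority
vote; a tie excludes the embryo with a warning. Two published percentages
(26/46 as 56.1%, 5/6 as 80%) are arithmetically inconsistent with their own
counts; this package reports plain ratios and does not attempt to reproduce
them.

NTS/indel frequencies come in two weightings: per allele *type* (duplication
of reads changes nothing — the per-locus reporting convention) and per
allele *copy* (the cohort accounting). The copy weighting is what recovers
the generator's per-copy bystander probability; the type weighting is biased
upward whenever both copies of a blastomere collapse into one signature.

## RNA and DNA off-target logic

RNA SNVs are filtered with inclusive thresholds — depth ≥ 20, Fisher strand
≤ 30, RMS mapping quality ≥ 20, quality-by-depth ≥ 2.0 — and records missing
any annotation are rejected with a per-record log message. Sites seen in
known-site lists or in un-injected blastomeres of the same embryo are
subtracted by exact (chrom, pos, ref, alt) identity. Because cDNA reads
either strand, the deaminase signature is counted as C→T *plus* G→A; the
C·G→U·A proportion is computed on the post-subtraction records (computing it
pre-subtraction is possible by passing the unsubtracted table — the function
is agnostic). The proportion of an empty set is reported as missing, never
zero. Editing rate is mutated reads over depth; expression uses
log2(RPKM + 1).

De novo WGS variants are identified by candidate regions (±200 bp around the
primary caller's variants, merged; the published description uses 200 bp
for SNVs and "adjacent 400 bp regions" for indels — both are the same single
`pad` parameter here), three-caller consensus keyed on (chrom, pos, ref,
alt) with a strict >10% allele-fraction floor (a variant at exactly 0.10 is
excluded; a caller without AF falls back to the minimum reported by the
others), trio subtraction keyed on (chrom, pos, alt), and repeat-BED /
known-site exclusion. All steps only shrink sets, so consensus ⊆ every
caller and de novo ⊆ consensus by construction.

The off-target scanner enumerates both strands for 20-mers within ≤3
mismatches of the protospacer followed by an NGG PAM. Genome `N` never
matches (it counts as a mismatch and fails a non-N PAM slot); the PAM's `N`
accepts any base. Sites are ranked by mismatch count, then position — the
published "top sites" carry no finer ordering criterion, so ordering beyond
the mismatch count is positional by decision. Bulges are not searched: the
prediction is mismatch-only.

## The synthetic-data generator

The generator emulates the study design: 8-cell embryos, 6 of 8 blastomeres
injected, 2PN or 3PN ploidy, parental APOE haplotypes cycling through a
10-embryo mixture that mirrors the reported cohorts (2PN: 5 ε3/ε3, 4 ε3/ε4,
1 ε4/ε4; 3PN: 7 ε3-only, 3 carrying one ε4). Per allele copy and
independently: each target C converts with probability `p_convert` (default
0.6, the scale of the reported allelic conversion), a bystander substitution
lands at a random non-target window position with `p_bystander` (default
0.02; the reported unwanted-mutation rate at this locus is below 2%), and a
1–3 nt deletion starts at a random window position with `p_indel` (default
0.01). Amplicon reads are drawn uniformly from the copies at depth 100 with
0.3% per-base substitution error (Phred-encoded); sequencing error is
substitution-only, so indels arise only as true editing outcomes — a
deliberate simplification that keeps allele identity unambiguous at this
scale. The amplicon is a fixed synthetic 240-nt sequence with the
protospacer ≥40 nt from either end and codons 112/158 at the true 138-bp
spacing; no amplicon geometry is published, so this is a free design choice,
not an inference about the study.

RNA SNV tables are generated directly as caller output (the real analysis
also starts from caller output): background counts are Poisson (default mean
100 per cell) with types uniform over the 12 substitution types, and the
BE3-like condition adds `rna_cu_excess × background` expected extra SNVs
that are exclusively C→T/G→A (default excess 10×, reproducing the order of
the reported burden elevation). Quality annotations are drawn to straddle
the filter thresholds so the filter always has work to do; since both
background and excess records share those distributions, the post-filter
C·G→U·A proportion has the closed form `(background/6 + excess) /
(background + excess)`. WGS call sets plant de novo and inherited variants,
detect each with per-caller sensitivity (default 0.95) plus Poisson
caller-specific false positives (default 10), and draw allele fractions
uniformly from `[0.02, 0.6]` so some true variants fall below the 10% floor.
Planted off-target genomes cycle mismatch counts 0–4 over alternating
strands with collision-free placement.

A single master seed drives everything; per-unit sub-seeds are derived
arithmetically, so embryo *k* is byte-identical regardless of cohort size
and identical configs reproduce identical FASTQ/FASTA/tables.

## What the tests show (and what they cannot)

The test suite validates the machinery, not the biology: the aligner equals
an independently written brute-force DP oracle on 1,000 random instances up
to (30, 60) nt; the scanner equals an exhaustive position-by-position oracle
on planted genomes (up to 50 kb in the acceptance suite, smaller in unit
tests); a 200-embryo 2PN cohort at `p_convert = 0.6`, depth 100, 0.3% error,
`p_bystander = 0.05` recovers both parameters within three binomial standard
errors (the recovery run sets `p_indel = 0` to isolate the two recovered
quantities); perfect simulated callers give de novo precision = recall = 1;
and the published contingency ratios (209/291 = 71.8%, 67/84 = 79.8%,
119/126 = 94.4%, 34/37 = 91.9%, 3/6 = 50%) are reproduced exactly from
their counts. The generator omits real-world structure — whole-genome
amplification chimeras and allele dropout, PCR bias between alleles, indel
sequencing error, linked variants, expression-dependent RNA coverage — so
passing tests demonstrate correctness of the computations under the stated
model, not performance on real embryo data.

Problem sizes in the shipped analyses (29 + 10 embryos, depth 100, 50 kb
scan genome, 10,000 pooled RNA SNVs) were chosen to make every statistic
stable at a few percent while keeping a full run in minutes on one CPU.

## Known limitations

- Triploid copy-number assignment trusts the read fraction; systematic
  allele-specific amplification bias would shift 33.3%/66.7% calls.
- The quantification window is a hard boundary: true edits outside
  protospacer ±10 nt (rare for CBEs) would be invisible, and the canonical
  allele sequence reconstructs window (plus haplotype-codon) differences
  only.
- Categories are per-allele, so one allele cannot contribute to both NTS and
  indel frequencies even if it carries both lesion types (indel wins).
- The scanner's mismatch-only model does not search DNA/RNA bulges, and
  ranking beyond the mismatch count is positional.
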