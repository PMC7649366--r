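---
title: "Mapping minor histocompatibility antigens by genotype segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping minor histocompatibility antigens by genotype segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhagmap)
```

## The problem

A minor histocompatibility antigen (mHAg) is a peptide derived from a
polymorphic protein, presented by an MHC molecule shared between two
individuals, and recognised as foreign by the T cells of the individual who
lacks the polymorphism. In an MHC-identical cohort — such as a panel of
Mauritian cynomolgus macaques sharing the same MHC haplotypes — an
alloreactive T cell clone that kills B cells from some panel members but
not others is reporting, through that binary reactivity pattern, a genetic
difference between the two groups. `mhagmap` turns that observation into a
candidate list: which non-synonymous SNP segregates with the reactive
pattern, what amino-acid change does it encode, which peptides should be
synthesised to fine-map the epitope, and how common is the allele in the
wider population.

## Reactivity typing

ELISpot wells report spot-forming cells (SFC): IFN-γ-secreting T cells per
well. The source assays report only binary outcomes per well, so the
positivity rule here is this package's own, deliberately conservative
choice. A well is positive when its count reaches the **maximum** of three
thresholds:

* `fold_over_background` × background mean (default 3×),
* background mean + `sd_multiplier` × background SD (default +3 SD),
* an `absolute_floor` (default 20 SFC).

The maximum (rather than any-of) keeps single noisy criteria from
promoting a well; all three are configurable through
`positivity_params()`. Raising any threshold can only demote wells — a
monotonicity property the test suite checks. Clones whose panel is all
positive or all negative carry no genetic contrast; they are flagged
unmappable and excluded from segregation with a warning.

## Segregation scoring

Scoring is *relative to the reference genome*, exactly as the discovery
design dictates, not relative to the cohort's majority allele: each animal
contributes 5 points at a site where it is homozygous for the alternate
allele, 3 where heterozygous, 0 where homozygous reference. The
segregation score of a site for a clone is the point sum over the mHAg⁺
group minus the point sum over the mHAg⁻ group.

Exclusivity is layered on top of the score because a score alone cannot
distinguish "alternate allele only in the positive group" from "alternate
allele everywhere but enriched". A site is `EXCLUSIVE` when no negative
animal carries the alternate allele and at least one positive animal does;
`PERFECT` when, additionally, *every* positive animal carries it. The
`PERFECT` grade is introduced here because recognition of every positive
animal's cells implies every positive animal carries the allele; the
default ranking prefers it.

Missing calls score 0 and never count as carrying, but they are tallied
(`n_missing`) and candidates whose grouped-animal missingness exceeds
`max_missing_frac` (default 20%) are dropped from the ranked list rather
than silently scored on partial data.

Ranking order: exclusivity class, then score (descending), then the number
of non-synonymous SNPs in the site's gene (descending — this package's
operationalisation of "prioritise polymorphic genes", which the source
workflow leaves unspecified), then site identifier, so output order is
fully deterministic.

## Coding annotation

Annotation uses a transcript model the package defines: CDS FASTA plus a
TSV of 1-based inclusive exon intervals with strand. Variant alleles on
minus-strand transcripts are complemented before codon substitution; both
codons are translated with the standard (vertebrate nuclear) genetic code
from `Biostrings::GENETIC_CODE`. Effects are `SYNONYMOUS`,
`NONSYNONYMOUS`, `NONSENSE` (alternate codon is a stop) or `NON_CODING`
(outside every CDS — a record, not an error). Only SNVs are annotated;
splice-site and indel effects are out of scope, matching the SNP-only
discovery design. Where a site overlaps several transcripts, one record
per transcript is emitted and downstream steps use the most severe effect.

A VCF reference allele that contradicts the CDS base is a hard error: it
means the transcript model and the genotype matrix disagree about the
genome, and every downstream amino acid would be wrong.

## Peptide design

For a candidate with variant residue $v$ in protein $P$, the screening set
is built from the window $[v-11, v+11]$ clipped to the protein, tiled with
15-mers overlapping by 11 (step 4). Interior variants give exactly three
variant-spanning 15-mers. Two design decisions cover cases the source
workflow never meets: windows shorter than 15 residues are emitted as a
single full-window peptide, and when stepping undershoots a clipped
window's end an extra end-anchored peptide completes coverage — the
simplest rules that never lose the variant.

Fine mapping intersects two adjacent stimulatory 15-mers (an 11-mer core
at the default tiling) and enumerates all 8- to 11-mers of that window:
$\sum_k \max(0, |w| - k + 1)$ peptides (10 for an 11-mer window). Wild-type
controls revert the variant residue to the reference. Peptide names are
first residue + last residue + length ("SW10"); collisions are legal and
disambiguated by coordinates in all outputs.

The built-in Mafa-A1\*063 motif (Ser1, Pro2, Asn3, C-terminal Trp, lengths
8–11) filters ladders to plausibly presentable peptides; other alleles can
be supplied via a YAML config (`inst/extdata/motifs.yaml`).

## Population frequency

Carrier frequency is the fraction of typed animals bearing at least one
alternate allele; with `aggregate_alts = TRUE`, decomposed multiallelic
columns are pooled so an animal carrying any alternate allele at a
position counts once (compound heterozygotes pool to two-copy carriers).
Missing animals leave the denominator and are reported separately — the
68-animal reference panel has no missing calls, so the choice is invisible
there but matters for general cohorts. Percentages are reported half-up at
two decimals; fractions retain full precision.

## The synthetic cohort generator

`generate_cohort()` produces every input with known truth. Its defaults
*are* the emulated study conditions and were fixed once, before any
end-to-end measurement:

* **21 animals, 69 clones, 2 carriers per clone** — the MHC-identical
  mapping panel, its clone count, and the canonical
  two-positives reactivity pattern.
* **5000 sites over ~100–230 genes** — a deliberately down-scaled exome
  (real exomes carry far more sites; 5000 keeps a full 200-clone screen
  in seconds while leaving thousands of competitor sites per clone).
* **Background allele frequencies uniform on 0.25–0.5** — the cohort
  emulates a severely bottlenecked island population in which surviving
  polymorphisms are mostly common. Rare background alleles private to two
  animals would be indistinguishable *in principle* from a causal variant
  for a clone whose carriers happen to coincide — real discovery data has
  exactly this ambiguity, but the generator's job is a ground truth that
  is actually true.
* **Distinct carrier sets per clone** (default) — two clones with the same
  carrier set would see each other's causal site as an equally perfect
  candidate, making "the" causal site ill-defined. A `distinct_patterns =
  FALSE` mode deliberately re-creates that degeneracy for testing the
  duplicate-pattern report.
* **ELISpot counts**: negative binomial with background mean 5 SFC,
  positive mean 200 SFC, dispersion size 30. The means are typical for
  strong clonal responses over clean backgrounds; the dispersion was
  chosen from the tail calculation (P(background ≥ 20) ≈ 5×10⁻⁶,
  P(positive < 20) ≈ 4×10⁻¹⁵) so that the zero-noise regime is cleanly
  separable, which the closed-loop contracts assume. ELISpot replicates
  are overdispersed relative to Poisson in practice, hence negative
  binomial rather than Poisson; the dispersion is configurable.
* **Causal alleles planted homozygous** by default, making the maximum
  score 5 × carriers exact; a `HET` mode exercises the 3-point path.

Genotyping error replaces a call with a uniformly chosen *different*
genotype class; missingness then masks calls independently. Every output
is a deterministic function of the parameters and the seed.

What the simulation does **not** emulate: linkage disequilibrium and
pedigree structure, MHC haplotype variation (all animals are assumed
MHC-identical, as in the mapping design), shared causal variants across
clones, splice or regulatory "cryptic" antigens, and realistic exome site
densities. Passing recovery tests therefore demonstrate correctness of the
scoring and design machinery under the stated generative model, not
discovery power on real exomes — in real data, clone panels of ten animals
and rare private variants make multiple tied candidates the norm rather
than the exception.

## Numerical and degenerate-input choices

* Half-calls (`0/.`) and `./.` both map to `MISSING`; phased separators
  are treated as unphased, since scoring needs only the genotype class.
* Multiallelic records decompose into one biallelic column per alternate
  allele (each allele is a biologically distinct candidate antigen);
  site identifiers gain an `:ALT` suffix only when needed for uniqueness.
* All coordinates are 1-based inclusive (VCF, transcript table, protein
  positions).
* Ties at every ranking level resolve lexicographically by site id;
  re-runs are byte-identical.
* Non-SNV VCF records are skipped with a warning rather than an error, so
  one structural variant does not abort a cohort load.

## Problem sizes used in validation

The packaged validation runs use a 200-clone, 21-animal, 5000-site cohort
for recovery measurements (clean and at 5% genotyping error), ≥1000
random site × grouping instances for oracle-agreement checks of the
scorer, and a 69-clone ten-target panel for the closed reactivity loop —
sizes chosen so the whole suite completes in about a minute while keeping
per-clone competitor counts in the thousands.

Under zero error the planted causal site is recovered at rank 1,
`PERFECT`, at the exact 5×carriers score, for every clone. Under 5%
genotyping error the strict recovery rate drops to roughly
$0.95^{21} \approx 34\%$ — the probability that no grouped call at the
causal site was corrupted — because the strict criterion demands a perfect
uncorrupted column; rank-1 identification alone degrades far more slowly.

## Known limitations

* No statistical significance model for segregation scores: the scorer is
  deterministic, as in the original design; a calibrated null would be a
  natural extension.
* No MHC binding-affinity prediction or proteasomal-processing model —
  motif filtering is a hard anchor-residue test.
* Whole-file VCF streaming only (no indexed random access, no BAM/CRAM).
* The annotation dialect (`GENE`, `TRID`, `CDSPOS` INFO keys) is this
  package's own minimal convention, not a standard annotator format.
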