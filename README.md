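# mhagmap

Discovery of minor histocompatibility antigens (mHAgs) by genotype
segregation in MHC-identical cohorts.

Minor histocompatibility antigens are polymorphic peptides presented by MHC
molecules; T cells from an MHC-identical donor recognise them as foreign.
Because mHAg expression can be restricted to hematopoietic cells, they are
candidate targets for graft-versus-leukemia and HIV-reservoir-reduction
immunotherapies, and mapping them in non-human primates (specifically
Mauritian cynomolgus macaques, whose bottlenecked population yields
MHC-identical panels) enables preclinical testing of such strategies.

`mhagmap` implements the computational chain of that discovery workflow as a
tidy, fully tested R pipeline:

1. **Reactivity typing** — IFN-γ ELISpot count tables are binarized per well
   (positive iff SFC ≥ max(fold × background, background + k·SD, floor)) and
   each T cell clone's target panel is split into mHAg⁺ / mHAg⁻ animal
   groups.
2. **Segregation scoring** — every variant site is scored against the
   reference genome per animal (homozygous mismatch = 5 points,
   heterozygous = 3, homozygous match = 0); the segregation score of a site
   for a clone is

   `score = Σ points(mHAg⁺ animals) − Σ points(mHAg⁻ animals)`

   with sites classified `EXCLUSIVE` (no mHAg⁻ animal carries the
   alternate allele, at least one mHAg⁺ does) or `PERFECT` (additionally,
   *every* mHAg⁺ animal carries it).
3. **Coding annotation** — candidate SNPs are translated on a transcript
   model (standard genetic code, strand-aware) and classified
   synonymous / non-synonymous / nonsense; ranking keeps only
   non-synonymous sites.
4. **Epitope design** — variant-centered 15-mers overlapping by 11 residues
   (three per interior variant), the shared 11-mer window of two
   stimulatory peptides, exhaustive 8–11-mer truncation ladders, wild-type
   control peptides, and MHC-I anchor-motif filtering (built-in
   Mafa-A1\*063 motif: Ser1, Pro2, Asn3, C-terminal Trp, lengths 8–11).
   Peptides are named first residue + last residue + length ("SW10").
5. **Population frequency** — per-allele and pooled carrier percentages and
   alternate-allele frequencies over a genotyped cohort.
6. **Synthetic cohorts** — a ground-truthed generator (genotypes with
   configurable error/missingness, synthetic proteome with planted causal
   non-synonymous SNPs, negative-binomial ELISpot counts) for end-to-end
   validation of everything above.

Inputs are standard formats: VCF 4.2 (multiallelic records are decomposed
into one biallelic column per alternate allele), CDS FASTA plus a transcript
coordinate TSV, and reactivity TSVs. All user-facing functions take a data
frame first and return tibbles, so stages compose with the pipe.

## Worked example

Simulate a 21-animal panel with six clones, type the reactivity, and screen
for candidates:

```r
library(mhagmap)

params   <- simulation_params(n_animals = 21, n_sites = 400, n_clones = 6,
                              n_genes = 40, seed = 42)
bundle   <- simulate_reactivity(generate_cohort(params))
groupings <- derive_groupings(bundle$reactivity)
screen   <- screen_candidates(bundle$genotypes, groupings, bundle$annotations)
screen
#> <mhag_screen> 6 clone(s) x 400 site(s); 1698 ns-candidates (6 PERFECT, 0 EXCLUSIVE)
#> top candidates:
#> # A tibble: 5 × 7
#>   clone_id site_id   gene    aa_change score exclusivity    rank
#>   <chr>    <chr>     <chr>   <chr>     <int> <chr>         <int>
#> 1 T01      chr1:275  GENE001 V59L         10 PERFECT           1
#> 2 T01      chr1:2128 GENE005 V63E        -10 NON_EXCLUSIVE     2
#> ...
```

Each clone's rank-1 candidate is its planted causal SNP, classified
`PERFECT` with the maximal score 10 = 5 points × 2 homozygous carriers.
From a candidate, design the peptide screen:

```r
top   <- dplyr::filter(tidy(screen), rank == 1, clone_id == "T01")
rec   <- dplyr::filter(bundle$annotations, site_id == top$site_id,
                       !is.na(transcript_id))
prot  <- protein_with_variant(bundle$proteome, rec)
tiles <- tile_variant_15mers(prot, rec$protein_pos)
tiles
#> # A tibble: 3 × 6
#>   name  sequence        start   end length variant_offset
#> 1 PA15  PRRSLTEATQHLARA    48    62     15             12
#> 2 LA15  LTEATQHLARASSFA    52    66     15              8
#> 3 TF15  TQHLARASSFALDPF    56    70     15              4

intersect_stimulatory(tiles[1, ], tiles[2, ])
#> 1 LA11  LTEATQHLARA    52    62     11              8
```

Three 15-mers span the variant; two adjacent stimulatory peptides share an
11-mer core, from which `enumerate_kmers()` builds the 8–11-mer ladder
(10 peptides) used to fine-map the minimal optimal epitope, and
`motif_match()` filters them against an MHC-I anchor motif.

Cohort prevalence of a candidate allele, here on the packaged 68-animal
APOBEC3C panel (63 homozygous reference, 4 G>T and 1 G>A heterozygotes at
`NC_027902.1:80990325`):

```r
carrier_frequency(apobec3c_frequency_panel(), aggregate_alts = TRUE)
#>   site_id              n_animals n_het n_carriers carrier_pct alt_allele_freq
#> 1 NC_027902.1:80990325        68     5          5        7.35          0.0368
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/mhagmap` (stages `simulate`, `call-reactivity`, `segregate`,
`annotate`, `design-peptides`, `motif-filter`, `frequency`, `run-all`).

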