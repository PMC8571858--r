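# herbarcode

Character-based DNA barcoding for plant collections that mix historic
herbarium specimens with fresh tissue, using the nuclear ribosomal internal
transcribed spacers (ITS1 and ITS2).

Herbaria hold century-old vouchers whose DNA is degraded to varying,
age-independent degrees; whether such material can still yield usable
barcodes — and whether archived or database sequences are even labelled
with the right species — are routine questions for anyone doing
collections-based systematics. `herbarcode` is aimed at that audience. It
provides, as plain R functions over standard formats (CSV, aligned FASTA,
JSON, TSV, Newick):

- **Specimen QC** — purity summaries (OD260/280, OD260/230, mean ± sample
  SD), amplification and complete-sequence success rates, collection-year
  stratification by amplification outcome, and the OLS regression of DNA
  concentration on specimen age,
  `y = β₀ + β₁·(reference_year − collection_year)`.
- **ITS annotation** — transfer of ITS1/5.8S/ITS2 intervals from an
  annotated reference by global (Needleman–Wunsch) alignment, and masking
  of the conserved 5.8S columns.
- **Diagnostic sites** — detection of species-diagnostic columns on the
  masked alignment: a column is diagnostic for species set *S* when all
  determinate members of *S* share one state (A/C/G/T or the deletion
  state DEL) that no determinate member outside *S* carries, with per-species
  coverage enforced. Indistinguishable sibling pairs are detected and
  scored jointly for clade-shared sites. Queries are classified against
  the resulting barcode table.
- **Distance trees** — p-distance or Jukes–Cantor
  (`d = −(3/4)·ln(1 − 4p/3)`) with pairwise or complete gap deletion,
  deterministic Saitou–Nei neighbor joining (exact on additive matrices),
  column-bootstrap support with a required explicit seed, and
  monophyly-based flagging of putatively misidentified accessions.
- **Synthetic data** — a seed-deterministic generator of labeled ITS
  alignments with planted diagnostic sites (deletions included), planted
  mislabels, and herbarium-style metadata, so the whole pipeline is
  testable offline.

## Worked example

The package ships transcriptions of the study's two specimen tables
(52 herbarium + 7 fresh records). QC in three calls:

```r
library(herbarcode)
tab1 <- system.file("extdata", "table1_herbarium_specimens.csv",
                    package = "herbarcode")
herb <- load_specimen_table(tab1, source_class = "herbarium")

summarize_purity(herb, "od_260_280")
#> od_260_280: 2.11 +/- 0.79 (n = 52, range 1.47-7.42)

success_rates(herb)
#>                           label numerator denominator  fraction percent
#> 1                     amplified        41          52 0.7884615    78.8
#> 2                 full_sequence        31          52 0.5961538    59.6
#> 3 full_sequence_among_amplified        31          41 0.7560976    75.6

regress_concentration_on_age(herb)
#> y = 0.095x + 14.8  (r^2 = 0.0178, p = 0.35, n = 51)
#> x: age in years = 2019 - collection_year
```

Four of five herbarium specimens amplified, three of five yielded a
complete ITS1+ITS2 sequence, and concentration shows no significant trend
with age across the 119-year collection range — degraded DNA, not old DNA,
is the limiting factor.

On the sequence side, a synthetic collection whose planted barcode
structure mirrors the study system:

```r
sim <- simulate_alignment(study_barcode_config(seed = 1))
bt  <- find_diagnostic_sites(sim$alignment)
bt
#> barcode_table: 37 diagnostic sites over 440 scanned columns
#>  code                                     species column position target_state ...
#>    A1                           Phalaris aquatica     47       47            T
#>   ...
#>    C1                       Phalaris coerulescens     75       75          DEL
#>   ...
#>    P1                           Phalaris paradoxa    117      117            C
#>  B-C1 Phalaris brachystachys;Phalaris canariensis    156      156            G
#>   ...
#> no diagnostic site: Phalaris lemmonii, Phalaris angusta
#> indistinguishable: Phalaris brachystachys / Phalaris canariensis
```

Eight of twelve species carry species-specific sites (positions are
1-based on the 5.8S-masked ITS1+ITS2 columns), one site is a diagnostic
deletion, the sibling pair shares nine clade-diagnostic sites but cannot
be separated from each other, and two species lack diagnostics entirely.
`neighbor_joining()`, `bootstrap_support()` and `flag_misassignments()`
take it from there; `run_pipeline()` wires all stages together with a
reproducibility manifest, and `inst/scripts/herbarcode-pipeline.R` is a
shell wrapper over it. `inst/scripts/reproduce_genbank.R` documents how to
rerun the analysis on the real GenBank collection (network + MAFFT
required).

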