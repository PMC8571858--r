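---
title: "Methods: herbarium ITS barcoding, diagnostic sites and distance trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: herbarium ITS barcoding, diagnostic sites and distance trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbarcode)
```

`herbarcode` implements a character-based DNA-barcoding workflow for plant
collections that mix historic herbarium specimens with fresh tissue, built
around the nuclear ribosomal internal transcribed spacers (ITS1 and ITS2).
The workflow has four stages: specimen quality control, ITS annotation and
5.8S masking, diagnostic-site detection and classification, and
distance-tree analysis with misassignment flagging. A seed-deterministic
synthetic-data generator makes every stage testable without any external
download. This vignette records the methods, the tunable parameters, and
the design decisions taken where the procedure was genuinely open.

## Specimen quality control

A specimen record carries the standard DNA-extraction QC measurements:
concentration (ng/µl), the OD260/280 and OD260/230 purity ratios
(dimensionless; ~1.8 and 1.8–2.2 respectively indicate pure DNA), the PCR
amplification outcome, and whether a complete ITS1+ITS2 sequence was
obtained. Summaries use the sample standard deviation (denominator
*n* − 1); that choice is load-bearing, because for small fresh-tissue
panels the population formula visibly changes the second decimal.
"Complete sequence" is taken from the presence of a sequence-database
accession in the record, with partial sequences carried as an explicit
flag so they are never counted as complete.

The degradation question — does specimen age predict DNA yield? — is
answered by ordinary least squares of concentration on **specimen age**,

$$y = \beta_0 + \beta_1 x, \qquad x = \text{reference year} - \text{collection year},$$

with undated records excluded and counted. The reference year defaults to
2019, the harvest year of the fresh material, so `x` is the specimen's age
at the time of the study. Measuring age from the earliest collection year
instead (or using raw calendar years) leaves the test of zero slope and
$r^2$ unchanged but flips the sign of the slope and moves the intercept;
with the age-at-study encoding the packaged herbarium table reproduces the
reported regression line, so that encoding is the default and is recorded
in the result's `x_definition` field. Zero-variance responses are reported
with $r^2 = 0$ rather than the numerical noise of `mss/(mss + rss)`.

Amplification failure, by contrast, is summarised by stratifying collection
year on the amplification outcome: the failed and successful strata are
each reported as mean ± SD of collection year, which is how the historic
material shows its age-dependent PCR failure even though concentration does
not correlate with age.

## Coordinates, annotation transfer and masking

All interval coordinates are 1-based and inclusive, both internally and in
every report. This is deliberately the native R convention (shared with
IRanges-style containers) rather than 0-based half-open arithmetic; with a
single convention everywhere there is no boundary translation to get wrong,
and reported positions match the familiar barcode-table style.

ITS1/5.8S/ITS2 intervals for a reference sequence come from configuration
(annotation JSON); they are transferred to each new sequence through a
global Needleman–Wunsch alignment (match +1, mismatch −1, linear gap −2 by
default — the smallest scheme that is reliable for near-identical ITS
sequences, and configurable). The aligner is implemented in C++ with a
fully deterministic traceback: on ties it prefers a gap in the target, then
the diagonal, then a gap in the reference. The order matters in exactly one
degenerate situation: when the target has lost a region entirely, tie
preference for target gaps keeps the unmatched reference suffix as one
contiguous gap block, so the transferred interval is empty and the transfer
fails loudly naming the missing region, instead of silently smearing stray
residues into it. Interval boundaries map through the alignment by
cumulative target-residue counts; target insertions inside a region extend
it, and boundaries falling in reference gap columns inherit the nearest
left boundary.

Diagnostic analysis excludes the conserved 5.8S gene: `mask_58s()` sets the
column mask to `FALSE` on every alignment column between the first and last
5.8S residue of **any** member (each member's interval projected through
its own gaps), which also covers gap columns inside the gene. Masking only
ever turns columns off, so it is idempotent and monotone. Reported site
positions count mask-true columns only, i.e. they are positions on the
concatenated ITS1+ITS2 coordinate system.

## Diagnostic sites

A column is diagnostic for a target species set $S$ when

1. every determinate member of $S$ carries one identical state,
2. that state is absent from every determinate member outside $S$, and
3. every species in the alignment has at least `min_coverage` (default 1)
   determinate member at the column.

States are A, C, G, T, and DEL — the gap character is a scoreable deletion
allele, which is how single-column diagnostic deletions are found alongside
SNPs. `N` is always indeterminate. IUPAC ambiguity codes are indeterminate
by default: a Sanger ambiguity neither confirms nor vetoes a site, it
simply removes that member from both tests at that column. The alternative
`ambiguity = "expand"` policy makes an ambiguity code contribute every base
it denotes, which is stricter (an `R` makes its species polymorphic {A, G}
at the column). Condition 3 prevents diagnostics driven purely by missing
data: a species that is entirely indeterminate at a column disqualifies the
column rather than silently passing the exclusion test.

By default every species is tested as a singleton target. Pairs of species
whose per-species state sets are identical at every masked column — in an
alignment that is polymorphic at all — are reported as indistinguishable
and additionally tested as a joint group target, which surfaces
clade-shared sites: columns separating the pair from all other species
without separating its members. Larger group targets are only tested when
supplied explicitly; an automatic search over all species subsets would be
combinatorial and is not warranted by the single observed sibling-pair
case. Site codes follow the conventional letter scheme of the study system
(T, B-C, A, C, M, P, CA, CR, AR) with ordinals in ascending masked-column
order; for other species the capitalised leading letter(s) of the epithet
are used, extended with further epithet letters only when two targets that
actually carry sites would collide.

Classification of a query scores every diagnostic site whose column the
query covers with a determinate state (`tested`), counting agreements with
the target state (`matched`). The verdict is `assigned` only when exactly
one singleton target matches all of its tested sites and out-scores every
other target; a winning group target or any tie is `ambiguous` (with the
tied species listed), and no match at all is `unassigned`. This
deliberately never assigns on partial contradictory evidence.

## Distances, neighbor joining, bootstrap

Distances are computed over mask-true columns using only the four bases:
for distance purposes gaps, `N` and ambiguity codes are missing data
(unlike the barcode module, where the gap is an allele — the two policies
serve different questions and are documented per consumer). Pairwise
deletion compares each pair over the columns where both are determinate;
complete deletion keeps only columns determinate in every member. The
default model is Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$,
the minimal-assumption correction, with the raw mismatch proportion
(p-distance) available; the transform is refused (with an error naming the
pair) when $p \ge 0.75$. A pair with zero comparable columns is an error,
not a silent `NaN`.

Neighbor joining is the classic agglomeration minimising
$Q(i,j) = (n-2)\,d(i,j) - R_i - R_j$; ties take the lowest pair of active
indices (original input order, merged clusters appended), so the tree is a
deterministic function of the matrix. On additive matrices this
reconstructs the generating topology and branch lengths exactly, which the
test suite asserts against random trees. Negative branch lengths — which
NJ can produce on non-additive input — are clamped to zero in the returned
tree, with the raw values kept in an attribute, so displayed trees are
valid while nothing is lost. Trees are `ape` `phylo` objects; Newick IO
goes through `ape`.

Bootstrap support resamples mask-true columns with replacement, rebuilds
the NJ tree per replicate, and scores each internal edge of the reference
tree by the percentage of replicates containing the same unrooted
bipartition (supports live on internal edges only; an unrooted tree has no
meaningful support on pendant edges). The default is 100 replicates and a
**required explicit seed** — there is no silent default seed, so every
support value in an artifact is reproducible by construction. Replicates
in which some pair loses all comparable columns are dropped, counted and
warned about, and supports are percentages of the replicates actually
used.

## Misassignment flagging

A species with two or more leaves is monophyletic on the unrooted tree iff
some edge bipartition isolates exactly its leaves. For each
non-monophyletic species the flagging procedure repeatedly removes one
leaf until the remainder is monophyletic: at each step it considers the
leaves of the species' minimal spanning clade (the smallest bipartition
side containing all remaining members) and removes the leaf whose removal
most reduces the number of foreign leaves in that clade. Ties prefer a
foreign leaf over a member — the "intruder" reading, which is what the
exhaustive minimal-removal search selects when an intruder sits beside a
cherry of true members — and then the lowest accession id. Every removed
leaf is a misassignment candidate, attributed to the majority species
among its three nearest leaves by patristic distance. Single-leaf species
cannot be tested and are listed separately. The greedy procedure is
validated against an exhaustive minimal-leaf-removal search on small trees
in the test suite.

Two species with identical sequences (an indistinguishable pair) can never
both be monophyletic once the tie-breaking order interleaves their leaves;
flags inside such a pair reflect genuine unresolvability of the marker,
not misidentification, and the barcode table's indistinguishable-group
report is the right lens for that situation.

## The synthetic generator

`simulate_alignment()` emulates the structure the analysis assumes: one
template per species derived from a random root ITS (defaults 220/160/220
nt for ITS1/5.8S/ITS2, a 600 nt total chosen inside the 588–602 nt span
observed in the study genus), planted species-diagnostic substitutions and
deletions, within-species polymorphism, mislabeled accessions, and `N`
missing data. Background inter-species divergence (default 0.03 per site,
a genus-scale level of ITS variation) is modelled as substitutions shared
by a random subset of 2 to (units − 2) species units: subsets of that size
can never fabricate a single-species diagnostic site, so the planted truth
is exactly the set of singleton diagnostics and recovery can be asserted
with precision = recall = 1. Species declared as an indistinguishable pair
evolve as one unit. Within-species polymorphism (default 0.002 per member
per site) avoids planted columns, gaps arise only from planted DEL sites
(no indel process), and all randomness flows from one explicit seed, so
identical configurations regenerate byte-identical fixture bundles.
`study_barcode_config()` is a canned configuration whose per-species
planted-site counts mirror the published barcode-table structure (five
sites for *P. truncata* through none for *P. lemmonii* and *P. angusta*,
nine clade-shared sites for the sibling pair, one deletion site); it sets
within-species polymorphism to zero because a sibling pair stays
detectable as indistinguishable only while the two species' state sets
remain identical.

`simulate_specimen_metadata()` draws concentration lognormal and
independent of collection year (the true regression slope is zero),
amplification success from a logistic in year (older specimens fail more,
reproducing the failed-vs-amplified year stratification qualitatively),
and purity ratios normal around 1.95 with occasional injected outliers.

What the generator does **not** emulate: rate heterogeneity across sites,
indel evolution, chimeric or low-quality chromatogram artefacts, and
alignment error — inputs are born aligned. Tests passing on synthetic data
therefore validate the detection and tree machinery, not the upstream
Sanger editing and multiple-alignment steps, which are out of scope (the
package ingests pre-aligned FASTA; an external aligner such as MUSCLE or
MAFFT produces it).

## Problem sizes and numerical choices

The test suite runs the oracle-equality checks on 100 random alignments
(up to 12 species × 4 members × ~600 columns), NJ additive recovery on 50
random 5–12 leaf trees (branch lengths 0.05–1, recovery asserted to
1e-9), misassignment flagging on 20 seeded runs of 6 species × 3 members
with 1–2 planted mislabels, and the exhaustive minimal-removal oracle on
12-leaf trees. These sizes were chosen as the smallest that exercise every
code path with non-trivial combinatorics. Floating-point policy: branch
lengths are serialised at full precision (`%.17g`), equality tests on
means/SDs use 1e-12 tolerances, and display rounding (one decimal for
percentages, two for ratios) never feeds back into computation.

## Known limitations

- Diagnostic-site detection is per-column; it will not find multi-column
  (haplotype) diagnostics.
- Indistinguishable-group detection is restricted to pairs; larger groups
  must be supplied as explicit targets.
- The greedy misassignment procedure is validated against exhaustive
  search only at small scale; adversarial topologies could make it
  over-flag, though ties preferring foreign leaves remove the common
  failure mode.
- The distance model menu is deliberately small (p-distance,
  Jukes–Cantor); likelihood-based models and trees are out of scope.
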