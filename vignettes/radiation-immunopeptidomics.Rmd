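---
title: "Methods: radiation immunopeptidomics and proteogenomics with radpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiation immunopeptidomics and proteogenomics with radpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpep)
```

`radpep` analyses how ionizing radiation reshapes a tumour cell's proteome
and its MHC class I immunopeptidome. This vignette is the package's own
account of the models it implements, the parameters that matter, the
choices made where the design was genuinely open, and what the synthetic
data can and cannot demonstrate.

## From somatic variants to neoantigen context sequences

The proteogenomic stage consumes variants as a Strelka-dialect VCF — read
mapping and variant calling themselves are out of scope — together with
transcript models in a minimal one-row-per-transcript TSV (exon intervals
inline, 1-based inclusive genomic coordinates). Full GTF semantics are
deliberately avoided: the consequence caller needs only exon geometry, CDS
bounds, strand and biotypes, and a minimal format keeps every test
hermetic. Externally all coordinates are 1-based inclusive, matching the
VCF and protein conventions; interval arithmetic inside the package works
on position vectors so no half-open/closed conversion bugs can arise.

Filtering follows the standard somatic workflow: only `PASS` records with
mutation read coverage of at least 10 reads survive, with depth taken from
`DP` for SNVs and `DPI` for indels. Both FORMAT and INFO placements are
accepted because callers differ; FORMAT wins when both are present, and the
`TUMOR` sample is preferred since the coverage criterion concerns the
mutated reads. Depth that is absent is treated as absent — never as zero —
and such variants are rejected with a logged reason rather than silently
passed.

Consequence calling is a deliberately narrow stand-in for a full variant
effect predictor: SNVs/MNVs are mapped through splicing and strand to their
codon and classified by the translated change; indels are classified by
length modulo 3. Transcripts whose gene biotype is not `protein_coding`, or
which carry the `NMD_mediated_decay` transcript biotype, yield `non_coding`
calls and are excluded — the biotype label is honoured as-is, with no
rule-based NMD prediction. A reference-allele mismatch against the contig
is an error, not a skip: it almost always indicates a coordinate bug and
should surface loudly.

Context pairs use a 31-residue window because 31 is odd and the tool
lineage this stage emulates centres the variant: 15 residues of flank
either side of the altered position, truncated at the protein termini
without padding or recentring (a substitution at protein position 3 yields
an 18-mer: two left-flank residues, the site, and the full right flank).
For truncating consequences (stop-gain, frameshift, stop-loss) the mutant
window runs from the left flank to the new C terminus, and a pair is
emitted only when at least 8 mutant residues remain — the minimum MHC
ligand length, below which no candidate ligand can span the lesion.
Frameshift translation continues through the mutated CDS to its first new
stop; read-through into the 3' UTR is not modelled, which shortens a small
minority of frameshift contexts. Population-frequency filtering keeps
variants with a highest observed population allele frequency strictly
below 1%; absent frequency means the variant was never observed in the
surveys and is retained, the common case for true somatic mutations.

## Label-free proteome quantitation

Protein abundance is rolled up as the sum of the three most abundant
unique peptides per protein ("Hi-3"); a peptide shared between proteins is
excluded from all of them, since assigning it to any one would bias both.
Summing rather than averaging matches area-based abundance semantics; a
`agg = "mean"` switch exists and differs only by a constant when exactly
three peptides are available.

Scalar normalisation multiplies each sample by one factor chosen against a
feature-wise geometric-mean pseudo-reference:
`factor = exp(median(log(reference/sample)))` over shared features, with
the factors then recentred to geometric mean 1. The recentring is what
makes the operation idempotent (re-normalising a normalised matrix yields
factors of 1 to within 1e-9) and leaves every sample's median log-ratio to
the recomputed reference at zero. The pseudo-reference was chosen over a
designated reference run because it is robust and requires no arbitrary
choice of run.

Missing values are imputed by maximum likelihood under a per-feature
Gaussian across the samples of each condition × time-point group: the EM
fixed point sets each missing entry to the observed within-group mean.
Imputation is deliberately grouped within conditions — imputing globally
would shrink true treatment effects toward zero. Features fully missing in
a group cannot be imputed and stay missing, flagged in the output. A
heuristic warning fires when the input looks unlogged (maximum above 50).

The moderated t-test shrinks per-feature pooled variances *s²* toward a
prior *s₀²* under the scaled inverse-chi-square model. The prior degrees of
freedom *d₀* are estimated by method of moments on log *s²* (solving
`trigamma(d0/2) = var(e) - trigamma(df/2)` with a Newton iteration for the
inverse trigamma), and the moderated t is referred to `d0 + df` degrees of
freedom, capped at the pooled residual df across features; when the
variances are under-dispersed the prior df is infinite and the prior
variance is the arithmetic mean of the *s²* — both conventions chosen to
agree exactly with the established empirical-Bayes implementation, which
the test suite uses as an independent oracle on a shared fixture.
Per-time-point contrasts are fitted (rather than one joint model) because
the volcano analysis is presented per time point; the two-way
treatment × time interaction question is answered separately by a
per-feature balanced fixed-effects ANOVA, computed by projection with a
shared design matrix for speed and falling back to per-feature fits when
missingness breaks the balance. Features with an empty design cell or no
residual df are flagged rather than given a p-value.

Volcano classes use raw p-values at the stated cutoffs (p < 1e-5,
|log₂FC| > 1), with BH q-values reported alongside rather than substituted
— the classification mirrors the thresholds as stated, and the q-values
let a user re-threshold. Over-representation is a generic one-sided Fisher
exact per gene set with BH correction; the default foreground takes
log₂FC > 0.58 (1.5-fold, increased direction only) at p < 0.05.

## Immunopeptidome analytics

Peptide-level FDR control collapses records to the best search score per
distinct sequence, separately for targets and decoys, then scans candidate
thresholds (the observed target scores) for the smallest at which the
decoy/target ratio falls strictly below α. The strict inequality is the
conservative tie policy: a threshold where the estimated FDR equals α
exactly is rejected, so lowering α can never add peptides and boundary ties
are excluded. Decoys are constructed by sequence reversal keeping the
terminal residue, mirroring common search-engine practice.

Binder classification is strict at both rank thresholds — below 0.5 is a
strong binder, below 2 a binder — so a peptide at exactly 0.5 is a binder
but not strong. Peptide identity throughout the set algebra is the bare
sequence; modified forms collapse onto their sequence, matching how unique
peptides are counted, with peptidoform identity used only inside the PTM
module. Radiation-specific peptides are those present in at least one
irradiated sample and absent from every control sample *including* the
expanded control pool; enlarging the pool can therefore only shrink the
set, a property the tests exercise. Unique-peptide counts are reported
both per condition and per condition × time point, since deduplication
across time points is a presentational choice.

Because external binding predictors are out of scope, synthetic data are
scored by a mock position-weight model: anchor positions (P2 and the C
terminus, with allele-specific preferred residues) concentrate 70% of the
probability mass, and a peptide's %rank is its empirical quantile among
100,000 seeded random peptides per allele and length (reduced in tests
where calibration precision is not the point). The rank distribution is
tie-heavy at the weak end — most random peptides share the minimal motif
score — which is harmless for thresholding at 0.5/2 but means ranks are
not uniform over [0, 100] as a real predictor's would be.

The packaged `table1_ct26.tsv` is a curated table of
radiation-specific strong binders from the CT26 immunopeptidome (108 rows; sequence, allele, %rank,
UniProt-style entry, protein name, footnote flags) and serves as a fixture
for the ranking/multi-peptide analytics.

## Cross-correlation, PTM ratios, PRM quantitation

The proteome/immunopeptidome join is an inner join on accession; the
immunopeptidome side rolls up *all* associated peptides per source protein
(not top-3), with shared peptides contributing to every source protein and
flagged ambiguous, so rolled-up intensity over-counts exactly by the
ambiguity multiplicity — a bookkeeping identity the tests assert.
Quadrants are assigned by the sign pair of the fold changes; a zero fold
change is a measure-zero tie and gets no quadrant rather than an arbitrary
side. Significance classes use unadjusted p < 0.05 per axis as stated for
the visualisation, with BH q-values reported alongside.

PTM ratios divide distinct modified peptidoforms by distinct unmodified
peptides per sample. The positional analysis restricts to 9-mers and uses
the global unmodified 9-mer count as denominator for every position — the
alternative (per-position denominators) would make positions incomparable
since every unmodified peptide is unmodified at all positions. Counts, not
intensities, are used. Conditions are compared per position with a paired
two-sided t-test across replicates, BH-adjusted over the nine positions. A
pseudocount of 0.5 replaces zero cells only in the per-PTM comparison
(where single modification types are often absent from one condition) and
is flagged whenever applied.

The PRM standard curve is an unweighted OLS fit of light/heavy ratio
against spiked light amount (default series 0, 5, 10, 25, 50, 100, 150 fmol
against a constant 100 fmol heavy spike); a 1/x-weighted fit is available
for strongly heteroscedastic series. Degenerate inputs — fewer than three
points, zero variance in the amounts, or all-equal ratios — are errors, and
a warning fires when the fitted intercept exceeds twice the residual SD.
Back-calculated amounts outside the calibrated range are flagged as
extrapolated (range boundaries included). Copies per cell use the exact SI
Avogadro constant and assume 100% peptide recovery, so they are upper
bounds on true presentation; values are reported unrounded with a rounded
display companion. Heavy labels are mass offsets attached to a residue
position (e.g. `Label:13C(6)15N(2)` at +8.01420 Da on lysine), never
sequence edits, and fragment arithmetic satisfies
`b_i + y_(n−i) = MH⁺ + proton` for every i, a conservation identity the
suite checks to 1e-9 Da.

## The synthetic-data module

The generators produce every pipeline input with the statistical structure
the analyses assume, under one master seed split into named substreams so
each stage reproduces byte-identically when re-run alone. Defaults encode
the study conditions: triplicate biological replicates; immunopeptidome
time points at 24 and 48 h with global irradiated intensity multipliers of
1.49 and 3.17; proteome time points at 0/24/48/72 h; 8–12-mer peptides with
a 9-mer mode; H-2-Kd/Dd/Ld-style anchor motifs; read depths drawn uniformly
over 5–20 so both sides of the 10-read filter are represented; population
allele frequencies straddling the 1% cutoff; the seven-point PRM series;
and 3 × 10⁸ input cells with true endogenous amounts of 51.3 and 99.6 fmol,
the amounts consistent with roughly 100 and 200 copies per cell. The
expanded control pool size is a parameter (default 3) since the number of
additional historical control runs is inherently study-specific. Peptide
intensities are log-normal because label-free areas are dominated by
multiplicative noise. Proteome effects are injected as time-scaled log₂
fold changes under treatment only, giving the interaction structure the
two-way ANOVA is meant to detect, and missingness probability rises
logistically as abundance falls.

What the generators do *not* emulate bounds what green tests can show:
there is no retention-time or spectrum-level structure, no chromatographic
alignment error, no allele-specific detection bias, no correlation between
a protein's abundance and its peptides' presentation, and decoy scores are
drawn from the same null as false-target scores by construction. Passing
recovery tests therefore demonstrate that the estimators are correct under
their stated models — not that those models capture every pathology of
real LC-MS/MS data.

Because the canonical carrier-protein sequence for the worked neoantigen
example cannot be fetched in an offline analysis, the package ships a
deterministic *synthetic* stand-in protein (`synthetic_mtch1_protein()`,
389 residues) embedding the wild-type 9-mer KYLSVQGQL so that its glycine
sits at position 367; `locate_peptide_variant()` run on the real sequence
would return the same coordinates by the same mechanism.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use deliberately desk-scale
problems: a simulated proteome of 400 proteins (the quantifiable-proteome
scale reduced an order of magnitude), immunopeptidome universes of a few
hundred peptides, 5,000 features for type-I-error estimation, 100
repetitions for realized-FDP estimation, and mock-rank references of
1,000–20,000 peptides in tests versus 100,000 at the default. Equality
tolerances follow the quantity: mass arithmetic to 1e-9 Da (1e-4 where the
frozen expected value is printed to five decimals), normalisation
idempotence to 1e-9, exact recovery demanded wherever the construction is
noise-free, and 3-standard-error bands for noisy regression recovery. The
inverse-trigamma Newton solver iterates to a relative step below 1e-10,
and the prior-df estimate falls back to infinity whenever the observed
log-variance dispersion is at or below its expected sampling floor.

## Known limitations

- Consequence calling handles SNVs, length-matched MNVs (classified as
  substitutions), and simple anchored indels wholly inside the CDS;
  splice-site and UTR effects are out of scope, and a variant partially
  overlapping the CDS is an error.
- Frameshift contexts stop at the mutated CDS's end when no new stop is
  reached (no UTR read-through).
- The mock %rank scorer is a calibration device for synthetic data, not a
  binding predictor; real analyses should import predictor output via the
  peptide table's rank columns.
- The immunopeptidome differential-expression route reuses the proteome
  moderated-t machinery on all-peptide roll-ups; whether that exactly
  matches any particular upstream software's peptide-ratio pipeline is not
  asserted.
- `copies_per_cell` assumes complete recovery; true per-cell copy numbers
  are higher than measured amounts imply by the (unknown) recovery factor's
  inverse.
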