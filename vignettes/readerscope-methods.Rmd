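---
title: "Methods: quantifying reader-bound histone codes and mapping their nucleosomes"
author: "readerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying reader-bound histone codes and mapping their nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerscope)
```

This vignette records the models, parameter choices and numerical
conventions behind the package, and what the synthetic-data tests do
and do not demonstrate about real data.

## 1. Peptide chemistry model

Histone ChIP eluates are propionylated, trypsinized, and propionylated
again. The package encodes the consequences of that chemistry rather
than the bench protocol itself:

* **Cleavage.** Propionylated lysines are not cleaved, so
  `digest_protein()` cuts C-terminal to arginine only. No
  proline-blocking rule is applied (the histone tail peptides of
  interest contain no R-P junctions, and the simple rule keeps the
  digest a strict partition of the protein).
* **Propionyl placement.** Unmodified and monomethyl lysines retain a
  free ε-amine and receive one propionyl group; di-/tri-methyl and
  acetyl lysines do not. Every tryptic peptide carries an N-terminal
  propionyl from the second derivatization round. The label channel
  (d0 or d5) applies to *all* propionyl groups on a peptide, so a
  channel swap shifts the mass by 5.0313837 Da per propionyl group and
  changes nothing else — an invariant the tests exercise.
* **Masses.** All residue and modification masses are derived in one
  place from atomic monoisotopic masses, so mass additivity is exact in
  double precision. The build was cross-checked against an independent
  residue-summation oracle before any quantification code was written.

A practical consequence worth stating: trimethyl (+42.04695) and
acetyl (+42.01057) differ by 36.4 mDa, i.e. ~45 ppm at m/z ≈ 800.
The default isobaric-grouping tolerance of **10 ppm** (Orbitrap-class
precursor accuracy) therefore separates me3 from ac but merges true
positional isomers, which is the intended behaviour. The tolerance is
an argument everywhere it is used.

## 2. Superposition deconvolution

Co-eluting positional isomers share a precursor XIC; only fragment
ions distinguish them. For an isobaric group the package builds a
template matrix `A` (rows: the union of theoretical singly charged b/y
m/z slots, merged at the fragment tolerance; columns: members, each
normalized to unit total), matches the observed MS/MS spectrum onto
the slots (unmatched slots contribute observed intensity 0, penalizing
absent site-determining ions), and solves non-negative least squares
with the Lawson–Hanson algorithm. Proportions are the solution
normalized to sum 1.

Choices made where the field leaves room:

* **NNLS rather than an integer-programming formulation.** The
  superposition model is the same; NNLS is convex, deterministic, and
  directly checkable against an exhaustive simplex grid search (step
  0.001), which the test suite and acceptance script do on random 2–3
  member groups.
* **Fragment match tolerance 20 ppm** (fragment mass accuracy is
  typically looser than precursor accuracy).
* **Indeterminacy flags.** The six diacetyl H4 isomers do not all
  possess an ion unique to themselves; distinguishability is a
  property of the template matrix, not of single ions. Members whose
  site-determining ions (where they exist) are absent from the
  spectrum are flagged rather than silently zeroed.
* **Area apportionment.** When several MS/MS scans sample one
  chromatographic peak, the scan nearest in retention time to the XIC
  apex is used; exact ties are resolved by the total-intensity-weighted
  mean of the per-scan proportions. The apex is the maximum of a
  3-point moving average, earliest on ties; the integration window is
  ±30 s around the apex (trapezoidal rule).
* **Zero denominators.** d0/d5 ratios with a zero denominator are
  reported as flagged sentinels (`Inf` / `missing`), never dropped or
  coerced to 0/0.

## 3. Differential statistics

Fold changes are `log2(mean ChIP % / mean input %)` over replicates; a
pseudocount of 0.01 percentage points enters only when either term is
zero, and the cell is flagged. Tests are classical equal-variance
two-tailed t-tests on raw percentages (a log-space option and a Welch
option exist behind flags; the classical form on raw percentages is
the default to match the stated analysis wording). BH correction is
applied within one ChIP-vs-input comparison — one family per
comparison, matching the way such supplementary tables are organized —
via `stats::p.adjust`, with a hand-computed step-up procedure as the
test oracle.

## 4. ChIP-seq signal model

Coordinates are 0-based half-open throughout (BED convention); SAM
input is converted on read. The tag position is the 5′ end per strand
(leftmost aligned base for `+`, rightmost for `−`), which is the
convention under which shifting forward tags by +75 bp and reverse
tags by −75 bp moves both toward the fragment midpoint. "Uniquely
aligned" is enforced as MAPQ ≥ 20 at read time, since alignment is
upstream of this package. Chromosome-edge shifts clamp rather than
drop, so the library size is unaffected.

Window counting, 5-million-read normalization, and control
subtraction with clipping at zero are all scalar operations verified
exactly against brute-force per-tag scans. Browser tracks follow two
conventions: 75-bp-shifted tags in 200-bp tiles normalized to 5M
reads (ChIP), and read centers in 20-bp tiles (RNA).

## 5. Island calling

The island grid is 200-bp non-overlapping windows — independent of
the 1-Mb/100-kb sliding windows used for chromosome-scale display. A
window with count *k* is **eligible** when the Poisson upper tail
P(X ≥ k) at the background rate λ is ≤ p₀ = 0.2; eligible windows
separated by at most **1 ineligible window** merge (islands touching
at a boundary merge), and an island's score is the sum of its eligible
windows' −log₁₀ p. λ comes from the control library scaled to the
sample depth when a control exists, else from the genome-wide sample
mean.

The score threshold is calibrated by Monte Carlo: simulate null
genomes (i.i.d. Poisson counts), aggregate islands, and pick the
threshold whose expected number of passing null islands equals the
requested E-value (`island_score_threshold()`, seeded and separate, so
`find_islands()` itself stays deterministic). The cited clustering
approach's closed-form score asymptotics are deliberately not
reproduced; equivalence is at the level of the island definition. A
wider gap allowance was tried during development and rejected: at
λ ≈ 0.2 per window it lets the null process bridge long runs of
single-tag windows, inflating the calibrated threshold and blurring
island boundaries.

Desk-scale calibration: recovery and null-calibration runs use a
10-Mb genome; the genome-wide default E-value of 100 scales to ~1
island per 10 Mb, which is what the tests and the acceptance script
configure.

## 6. Gene-level interpretation

* **Promoter** = the 2-kb interval strictly upstream of the TSS
  (excluding the TSS base), strand-aware, clamped at chromosome ends.
* **Island category** priority is promoter > gene body > intergenic
  when an island spans several; single assignment is required for
  category fraction tables.
* **Promoter binding** is ≥1 bp overlap between any island and the
  promoter, under half-open semantics (an island ending exactly at the
  promoter start does not bind).
* **Promoter ranking** scores each promoter by the Poisson upper tail
  of its sample tag count at the control-derived expectation
  (control count + 1 pseudocount, rescaled by the library-size ratio);
  ties break by descending fold, then gene id — fully deterministic.
  The underlying ranking statistic is a declared choice; only
  "ranked by P-values" is externally fixed.
* **Expression classes**: genes ranked by RPKM; top 30% high, bottom
  30% silent (counts via `floor(0.3 n)`), remainder medium; ties break
  by gene id. The partition is rank-based, hence invariant to RPKM
  rescaling. RPKM uses summed exon length when exons are provided,
  else the TSS–TES span. A gene is "expressed" iff RPKM ≥ 1.
* **Metagene profiles**: 2-kb flanks in 100-bp windows (20 per side)
  and the gene body rescaled to 40 equal bins; per-window signal is
  max(0, sample − control) on depth-normalized densities per 100 bp;
  minus-strand genes are orientation-flipped; the class profile is the
  unweighted gene mean. Genes shorter than one bin are excluded with a
  warning.
* **Pattern groups** are keyed by the exact five-protein bound/unbound
  vector, ordered by descending size with the all-unbound group forced
  last and genes ordered by id within groups.
* **Knockdown response** counts top-N bound genes with |log2 FC| at or
  beyond log2(cutoff); "at least a two-fold reduction" is inclusive of
  the boundary.

## 7. What the synthetic data emulates — and what it does not

The spectra generator produces Gaussian elution peaks per isobaric
group (width 6 s), MS1 scans every 2 s, MS/MS scans near each apex
whose fragment intensities mix the member templates in proportion to
the planted abundances, and expectation-preserving multiplicative
log-normal noise (σ = 0.05, i.e. signal-to-noise ≈ 20). Fragment
templates are uniform over b/y ions: adequate because deconvolution
uses relative template *shape*, not chemistry-accurate intensity
prediction. Not emulated: isotope envelopes, charge-state
distributions beyond the catalog charge, chimeric precursor windows,
retention-time drift, or real Orbitrap noise structure. Passing
recovery tests therefore demonstrate the correctness of the
quantification logic under the stated noise model, not robustness to
every real-world artifact.

The genome generator plants piecewise-constant Poisson tag rates
(background 0.5 tags/kb/strand by default), multiplies the rate inside
planted islands by their fold, and offsets each fragment's single-end
tag ±75 bp from the midpoint so the shift step re-centers it. Genes
are placed without overlap with planted 30/40/30 expression tertiles
(mean RPKM 30 / 3 / 0.05, log-normal within-class spread). The
miniature study (`make_study_fixture()`: one 10-Mb chromosome, 200
genes, five proteins) uses a deeper background of 2 tags/kb/strand —
the per-base density a deeply sequenced small genome would show — so
class-mean metagene curves are stable; activator-like proteins are
enriched 8-fold over promoters+bodies of high-expression genes and
4-fold over medium genes, repressor-like proteins mirror this on
silent genes and add 50-kb intergenic heterochromatin blocks. Not
emulated: sequence composition, mappability, copy-number variation,
fragment-length dispersion, or PCR duplication beyond the
per-position collision that deduplication removes.

## 8. Problem sizes and determinism

Test and acceptance runs use: 100 random isobaric groups for the
grid-search comparison; 20 seeded spectra for degree-of-acetylation
recovery; 20 seeded 10-Mb genomes with five planted 10-kb 8-fold
islands (plus 25 null genomes) for island calling; 50 random fixtures
for the exact signal-model checks; 1000 random vectors for BH; one
miniature study for stratification. Every generator is a pure
function of (scenario, seed); identical seeds give byte-identical
outputs, and the acceptance script derives all its randomness from a
single `--seed`.

## 9. Known limitations

* No de novo identification or database search: candidate proteoforms
  come from user-built catalogs, and the modification alphabet is
  me1/me2/me3/ac plus the propionyl labels.
* Monoisotopic masses only; no isotope-envelope fine structure.
* Single-end tags only; no paired-end or fragment-length modeling.
* The quantification assumes equal ionization efficiency across
  proteoforms of a family (standard for relative abundances within a
  peptide family, but a real instrument bias the generator does not
  model).
* `estimate_lambda()` assumes a globally homogeneous background;
  copy-number-variable genomes would need a local background model.
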