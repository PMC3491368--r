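# readerscope

Proteogenomics of histone-code *reader* proteins: what combinatorial
histone marks do bromodomain proteins (Brd2/3/4) and chromodomain
proteins (HP1α/β) sit on, and where in the genome are the nucleosomes
they bind?

The package implements both analysis arms of a ChIP-qMS + ChIP-seq
study design, for epigenomics groups who have (a) LC-MS/MS peak lists
of propionylated histone peptides from reader ChIPs and (b) aligned
ChIP-seq/RNA-seq reads for the same readers — plus a synthetic-data
module that plants known ground truth so every stage can be validated
without any external download.

## The two arms

**Quantitative MS of histone proteoforms.** Histones are derivatized
with d0- or d5-propionic anhydride and trypsinized; free and
monomethyl lysines (and peptide N-termini) carry propionyl groups, so
trypsin cuts after arginine only. For a peptide family such as H4
4–17 (`GKGGKGLGKGGAKR`, carrying K5/K8/K12/K16) the package
enumerates all site-level modification assignments, computes
monoisotopic masses and b/y fragment ladders, and groups *isobaric
positional isomers* (e.g. the six diacetyl arrangements) that only
fragment ions can distinguish. Quantification extracts precursor ion
chromatograms (XICs), integrates peak areas, and resolves mixed MS/MS
spectra of co-eluting isomers by solving the superposition model

    min ‖A·x − o‖²  subject to  x ≥ 0,

where the columns of `A` are theoretical fragment templates of the
group members and `o` is the observed matched intensity vector
(non-negative least squares); mixing proportions are `x` normalized
to sum 1. Relative abundances per family sum to 100%, and ChIP vs
input log₂ fold changes are tested across replicates with a classical
two-sample t-test and Benjamini–Hochberg correction per comparison.

**ChIP-seq of reader-bound nucleosomes.** Aligned single-end tags are
kept at most once per genomic position per strand, shifted 75 bp
toward the fragment midpoint (half the nucleosomal DNA), counted in
windows (1 Mb sliding / 100 kb step for chromosome-scale views;
200 bp tiles for browser tracks and island calling), normalized to a
depth of 5 million reads, and control-subtracted with negative values
clipped to zero. Enriched domains ("islands") are runs of windows
whose Poisson upper-tail probability passes an eligibility threshold,
merged across small gaps and filtered by an aggregate score
calibrated to a genome-wide E-value. Downstream: promoter (2 kb
upstream of the TSS) / gene-body / intergenic fractions, per-gene
promoter binding with combinatorial five-protein patterns, RPKM
expression tertiles (top 30% / middle 40% / bottom 30%), metagene
profiles, and knockdown-response summaries for the top-bound genes.

## Worked example

Quantify the degree of acetylation of the H4 4–17 peptide from a
simulated run with a known truth vector (un/mono/di/tri/tetra =
50 / 30.5 / 12 / 7 / 0.5%):

```r
library(readerscope)

cat2  <- build_catalog(h4_acetyl_proteoforms(), charge = 2)
cat2
#> <ProteoformCatalog> 16 forms, 5 isobaric groups, charge 2

truth <- h4_truth_from_doa(c(50, 30.5, 12, 7, 0.5), cat2)
sim   <- simulate_spectra(spectra_scenario(cat2, truth,
                                           noise_sigma = 0.05, seed = 42))
ab    <- quantify_peaklist(sim$peaklist, cat2)
degree_of_acetylation(ab)
#>   n_acetyl class percent
#> 1        0    un  49.615
#> 2        1  mono  30.667
#> 3        2    di  12.338
#> 4        3   tri   6.868
#> 5        4 tetra   0.511
```

The five class totals are percentages of all H4 4–17 molecules and
sum to 100; at a signal-to-noise ratio of 20 the planted vector is
recovered within ~0.5 percentage points per class. An observed ChIP
abundance of 9.3% tetra-acetyl H4 against a 0.5% genomic background
corresponds to

```r
fc <- fold_change(9.3, 0.5)
#> log2 FC = 4.22 (18.6-fold)
```

On the sequencing side, `call_islands()` takes deduplicated ChIP and
control tag sets and returns scored islands; `promoter_bound()`,
`combinatorial_patterns()`, `expression_classes()` and
`metagene_profile()` reproduce the promoter-binding and
expression-stratification analyses. `make_study_fixture()` builds a
complete miniature study (10 Mb genome, 200 genes, five reader
proteins plus input) with all truths attached.

A thin CLI over the same functions is installed at
`inst/scripts/readerscope.R` (subcommands `quantify`, `signal`,
`islands`, `simulate`).

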