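# A miniature end-to-end study: a 10-Mb genome with 200 genes in planted
# expression tertiles, five reader proteins (three activator-like
# bromodomain readers enriched at promoters and bodies of expressed genes,
# two repressor-like chromodomain readers on silent gene bodies and
# intergenic blocks), a matched input library, RNA-seq counts, matched
# acetylation truth for the qMS arm, and a planted knockdown response.

# degree-of-acetylation class vectors (un, mono, di, tri, tetra; sum 100)
.DOA_PROFILES <- list(
  input = c(50, 30.5, 12, 7, 0.5),
  activator = c(15, 25, 27, 23, 10),
  repressor = c(70, 25, 4, 0.9, 0.1)
)

#' Interval-overlap Jaccard index
#'
#' Jaccard between the unions of two interval sets (same chromosome
#' space): total overlap length / total union length.
#'
#' @param a,b data.frames with chrom, start, end (half-open).
#' @return Scalar in [0, 1].
#' @export
interval_jaccard <- function(a, b) {
  ga <- GenomicRanges::reduce(.as_granges(a))
  gb <- GenomicRanges::reduce(.as_granges(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(1)
  inter / uni
}

# planted island table for one protein given gene classes
.protein_islands <- function(genes, role, folds = c(strong = 8, weak = 4),
                             intergenic = NULL) {
  strong_cls <- if (role == "activator") "high" else "silent"
  weak_cls <- "medium"
  mk <- function(sel, fold) {
    g <- genes[sel, ]
    if (!nrow(g)) return(NULL)
    plus <- g$strand == "+"
    data.frame(chrom = g$chrom,
               start = ifelse(plus, g$start - 2000, g$start),
               end = ifelse(plus, g$end, g$end + 2000),
               fold = fold)
  }
  out <- rbind(mk(genes$true_class == strong_cls, folds[["strong"]]),
               mk(genes$true_class == weak_cls, folds[["weak"]]))
  if (!is.null(intergenic)) out <- rbind(out, intergenic)
  out[order(out$chrom, out$start), ]
}

#' Build the miniature five-protein study fixture
#'
#' Generates, deterministically from the seed: gene models with planted
#' expression tertiles, per-protein ChIP tag libraries with planted
#' enrichment (activators: promoters + bodies of high-expression genes at
#' 8-fold and of medium genes at 4-fold; repressors: silent gene bodies at
#' 8-fold, medium at 4-fold, plus intergenic heterochromatin blocks), a
#' matched input library, RNA-seq counts, per-sample acetylation truth
#' vectors, and a knockdown log2 fold-change table in which 75% of the
#' top-bound activator genes carry at least a two-fold reduction and 8%
#' at least a two-fold increase.
#'
#' @param seed RNG seed fixing the whole fixture.
#' @param genome_size Chromosome length (one chromosome), default 1e7.
#' @param n_genes Number of genes, default 200.
#' @param background_rate Background tag rate per bp per strand, default
#'   2e-3 (a deeply sequenced small genome).
#' @return List of class `StudyFixture`: `chrom_sizes`, `genes` (with
#'   true_rpkm/true_class), `proteins` (names), `roles`, `chip_tags`
#'   (named list of tag data.frames), `control_tags`, `truth_islands`
#'   (per protein), `rna` (simulate_rnaseq output), `doa_truth` (named
#'   list of length-5 class vectors), `knockdown` (data.frame id, log2fc
#'   + attr planted fractions).
#' @export
make_study_fixture <- function(seed = 1, genome_size = 1e7, n_genes = 200,
                               background_rate = 2e-3) {
  chrom_sizes <- c(chr1 = genome_size)
  genes <- place_genes(chrom_sizes, n_genes, seed = seed)
  proteins <- c("Brd2", "Brd3", "Brd4", "HP1a", "HP1b")
  roles <- c(Brd2 = "activator", Brd3 = "activator", Brd4 = "activator",
             HP1a = "repressor", HP1b = "repressor")

  set.seed(seed + 101)
  # repressor-specific intergenic heterochromatin blocks
  blocks <- data.frame(
    chrom = "chr1",
    start = sort(round(stats::runif(4, 0.05, 0.95) * (genome_size - 6e4))),
    fold = 6
  )
  blocks$end <- blocks$start + 5e4

  scen <- genome_scenario(chrom_sizes, genes = genes,
                          background_rate = background_rate, seed = seed)
  chip_tags <- list()
  truth_islands <- list()
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    isl <- .protein_islands(
      genes, roles[[p]],
      intergenic = if (roles[[p]] == "repressor") blocks else NULL
    )
    sim <- simulate_chip_reads(scen, islands = isl, seed = seed + i)
    chip_tags[[p]] <- sim$tags
    truth_islands[[p]] <- isl
  }
  control <- simulate_chip_reads(scen, islands = NULL,
                                 seed = seed + 100)$tags

  rna <- simulate_rnaseq(scen, seed = seed + 200)

  doa_truth <- list(
    input = .DOA_PROFILES$input,
    Brd2 = .DOA_PROFILES$activator, Brd3 = .DOA_PROFILES$activator,
    Brd4 = .DOA_PROFILES$activator,
    HP1a = .DOA_PROFILES$repressor, HP1b = .DOA_PROFILES$repressor
  )

  # planted knockdown response for the strongly bound (high-class) genes:
  # 75% reduced >= 2-fold, 8% increased >= 2-fold, remainder unchanged
  set.seed(seed + 300)
  n <- nrow(genes)
  fc <- stats::rnorm(n, 0, 0.15)
  high_idx <- which(genes$true_class == "high")
  n_red <- round(0.75 * length(high_idx))
  n_up <- round(0.08 * length(high_idx))
  pick <- sample(high_idx)
  fc[pick[seq_len(n_red)]] <- stats::runif(n_red, -3, -1.2)
  fc[pick[n_red + seq_len(n_up)]] <- stats::runif(n_up, 1.2, 2)
  knockdown <- data.frame(id = genes$id, log2fc = fc)
  attr(knockdown, "planted_reduced") <- n_red / length(high_idx)
  attr(knockdown, "planted_increased") <- n_up / length(high_idx)

  structure(list(chrom_sizes = chrom_sizes, genes = genes,
                 proteins = proteins, roles = roles,
                 chip_tags = chip_tags, control_tags = control,
                 truth_islands = truth_islands, rna = rna,
                 doa_truth = doa_truth, knockdown = knockdown,
                 background_rate = background_rate, seed = seed),
            class = "StudyFixture")
}

#' @export
print.StudyFixture <- function(x, ...) {
  cat(sprintf(
    "<StudyFixture> %s bp genome, %d genes, %d ChIP libraries + control\n",
    format(sum(x$chrom_sizes), big.mark = ","), nrow(x$genes),
    length(x$chip_tags)))
  invisible(x)
}

#' Write a study fixture to disk in pipeline-consumable formats
#'
#' Tags as BED6, genes as BED6 (+ true columns in a TSV), RNA counts,
#' knockdown table and truth islands as TSV.
#'
#' @param fx A `StudyFixture`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_study_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wbed <- function(tags, path) {
    bed <- data.frame(tags$chrom, tags$pos,
                      tags$pos + 1L, ".", 0, tags$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (p in names(fx$chip_tags)) {
    wbed(fx$chip_tags[[p]], file.path(dir, paste0("chip_", p, ".bed")))
    utils::write.table(fx$truth_islands[[p]],
                       file.path(dir, paste0("truth_islands_", p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wbed(fx$control_tags, file.path(dir, "control.bed"))
  gene_bed <- data.frame(fx$genes$chrom, fx$genes$start, fx$genes$end,
                         fx$genes$id, 0, fx$genes$strand)
  utils::write.table(gene_bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fx$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$rna$counts, file.path(dir, "rna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$knockdown, file.path(dir, "knockdown_log2fc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(fx$chrom_sizes),
               length = as.numeric(fx$chrom_sizes)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
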