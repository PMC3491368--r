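# Ground-truthed synthetic genomes: Poisson background ChIP tags with
# planted enrichment islands, RNA-seq counts from planted RPKM values,
# and gene placement with planted expression tertiles.

#' Define a genome-simulation scenario
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param genes Optional gene table (id, chrom, start, end, strand) with a
#'   `true_rpkm` column for the RNA-seq simulator.
#' @param background_rate Background tag rate per bp per strand, default
#'   5e-4 (0.5 tags/kb/strand).
#' @param islands Optional data.frame chrom, start, end, fold of planted
#'   enrichment regions (fold multiplies the local rate).
#' @param rna_library_size RNA-seq mapped library size, default 1e7.
#' @param seed RNG seed.
#' @return List of class `GenomeScenario`.
#' @export
genome_scenario <- function(chrom_sizes, genes = NULL,
                            background_rate = 5e-4, islands = NULL,
                            rna_library_size = 1e7, seed = 1) {
  if (!is.null(islands) && nrow(islands)) {
    lim <- chrom_sizes[islands$chrom]
    if (any(islands$start < 0) || any(islands$end > lim)) {
      stop("planted islands must lie within chromosome bounds")
    }
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes,
                 background_rate = background_rate, islands = islands,
                 rna_library_size = rna_library_size, seed = seed),
            class = "GenomeScenario")
}

# sample fragment midpoints from a piecewise-constant rate and emit
# strand-split tags offset +/- `offset` bp from the midpoint
.sample_tags <- function(chrom, len, segments, rate2, offset, frag_half) {
  # segments: data.frame start, end, fold covering [0, len)
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    n <- stats::rpois(1, rate2 * seg$fold * (seg$end - seg$start))
    if (n == 0) next
    mid <- stats::runif(n, seg$start, seg$end)
    plus <- stats::runif(n) < 0.5
    pos <- ifelse(plus, mid - offset, mid + offset)
    out[[i]] <- data.frame(chrom = chrom, pos = floor(pos),
                           strand = ifelse(plus, "+", "-"))
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  tags <- do.call(rbind, out)
  tags$pos <- pmin(pmax(tags$pos, 0), len - 1)
  tags
}

# non-overlapping segment cover of [0, len) from planted intervals
.segment_cover <- function(len, planted) {
  if (is.null(planted) || !nrow(planted)) {
    return(data.frame(start = 0, end = len, fold = 1))
  }
  planted <- planted[order(planted$start), ]
  edges <- sort(unique(c(0, len, planted$start, planted$end)))
  seg <- data.frame(start = edges[-length(edges)], end = edges[-1])
  seg$fold <- 1
  for (i in seq_len(nrow(planted))) {
    hit <- seg$start >= planted$start[i] & seg$end <= planted$end[i]
    seg$fold[hit] <- pmax(seg$fold[hit], planted$fold[i])
  }
  seg
}

#' Simulate ChIP-seq tags with planted enrichment islands
#'
#' Background fragment midpoints follow a homogeneous Poisson process
#' (rate = 2 x `background_rate`, both strands); planted islands multiply
#' the local rate by their fold.  Each fragment yields one single-end tag
#' on a random strand, offset 75 bp upstream (+) or downstream (-) of the
#' midpoint, so the standard 75-bp shift re-centers tags on midpoints.
#'
#' @param scenario A `GenomeScenario`.
#' @param fold_override Optional global multiplier on the background rate
#'   (e.g. to scale library size).
#' @param islands Overrides `scenario$islands` (e.g. per protein).
#' @param offset Tag offset from the fragment midpoint, default 75.
#' @param seed Overrides `scenario$seed`.
#' @return List: `tags` (data.frame chrom, pos, strand), `truth_islands`.
#' @export
simulate_chip_reads <- function(scenario, fold_override = 1,
                                islands = scenario$islands, offset = 75,
                                seed = scenario$seed) {
  set.seed(seed)
  out <- list()
  for (ch in names(scenario$chrom_sizes)) {
    len <- scenario$chrom_sizes[[ch]]
    pl <- if (!is.null(islands)) islands[islands$chrom == ch, ] else NULL
    seg <- .segment_cover(len, pl)
    out[[ch]] <- .sample_tags(ch, len, seg,
                              2 * scenario$background_rate * fold_override,
                              offset, 75)
  }
  tags <- do.call(rbind, out)
  rownames(tags) <- NULL
  list(tags = tags, truth_islands = islands)
}

#' Simulate an RNA-seq count table (and optional reads)
#'
#' Per-gene counts are Poisson with mean
#' `true_rpkm x length/1000 x library/1e6` (the inverse of the RPKM
#' formula); optional read-level output places fixed-length reads
#' uniformly within each gene for center-based browser tracks.
#'
#' @param scenario A `GenomeScenario` whose `genes` carry `true_rpkm`.
#' @param reads Also emit read intervals, default FALSE.
#' @param read_length Read length for read-level output, default 75.
#' @param seed Overrides `scenario$seed`.
#' @return List: `counts` (data.frame id, count, length_bp, true_rpkm),
#'   `library_size`, and `reads` (data.frame chrom, start, end) if
#'   requested.
#' @export
simulate_rnaseq <- function(scenario, reads = FALSE, read_length = 75,
                            seed = scenario$seed) {
  set.seed(seed)
  genes <- scenario$genes
  if (is.null(genes) || is.null(genes$true_rpkm)) {
    stop("scenario genes must carry true_rpkm")
  }
  len <- genes$end - genes$start
  mu <- genes$true_rpkm * len / 1000 * scenario$rna_library_size / 1e6
  counts <- stats::rpois(nrow(genes), mu)
  res <- list(
    counts = data.frame(id = genes$id, count = counts, length_bp = len,
                        true_rpkm = genes$true_rpkm),
    library_size = scenario$rna_library_size
  )
  if (reads) {
    idx <- rep(seq_len(nrow(genes)), counts)
    start <- floor(stats::runif(length(idx), genes$start[idx],
                                pmax(genes$start[idx] + 1,
                                     genes$end[idx] - read_length)))
    res$reads <- data.frame(chrom = genes$chrom[idx], start = start,
                            end = start + read_length)
  }
  res
}

#' Place non-overlapping genes on a synthetic genome
#'
#' Genes are laid out with uniform random lengths and inter-gene spacing
#' wide enough to keep promoters and flanks disjoint; strands alternate at
#' random.  Planted RPKM values span three well-separated tertiles (high /
#' medium / silent).
#'
#' @param chrom_sizes Named numeric chromosome lengths.
#' @param n_genes Number of genes.
#' @param length_range Gene length range (bp), default 2000-8000.
#' @param spacing_range Inter-gene gap range (bp), default 10000-30000.
#' @param rpkm_levels Mean RPKM per class (high, medium, silent), default
#'   c(30, 3, 0.05).
#' @param seed RNG seed.
#' @return Gene table with columns id, chrom, start, end, strand,
#'   true_rpkm, true_class.
#' @export
place_genes <- function(chrom_sizes, n_genes, length_range = c(2000, 8000),
                        spacing_range = c(10000, 30000),
                        rpkm_levels = c(high = 30, medium = 3,
                                        silent = 0.05),
                        seed = 1) {
  set.seed(seed)
  chroms <- names(chrom_sizes)
  rows <- list()
  i <- 0
  ci <- 1
  cursor <- spacing_range[1]
  while (i < n_genes) {
    len <- round(stats::runif(1, length_range[1], length_range[2]))
    gap <- round(stats::runif(1, spacing_range[1], spacing_range[2]))
    if (cursor + len + gap > chrom_sizes[[chroms[ci]]]) {
      ci <- ci + 1
      if (ci > length(chroms)) break
      cursor <- spacing_range[1]
      next
    }
    i <- i + 1
    rows[[i]] <- data.frame(
      id = sprintf("gene%03d", i), chrom = chroms[ci], start = cursor,
      end = cursor + len,
      strand = sample(c("+", "-"), 1)
    )
    cursor <- cursor + len + gap
  }
  genes <- do.call(rbind, rows)
  n <- nrow(genes)
  # planted 30/40/30 tertiles, assigned at random gene positions
  n_high <- floor(0.3 * n); n_silent <- floor(0.3 * n)
  cls <- sample(c(rep("high", n_high), rep("silent", n_silent),
                  rep("medium", n - n_high - n_silent)))
  mu <- rpkm_levels[cls]
  genes$true_rpkm <- mu * stats::rlnorm(n, -0.125, 0.5)  # within-class spread
  genes$true_class <- factor(cls, levels = c("high", "medium", "silent"))
  rownames(genes) <- NULL
  genes
}
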