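# Relating islands and signal to gene models: promoters, island category
# fractions, promoter binding and ranking, combinatorial 5-protein binding
# patterns, RPKM expression classes, metagene profiles, and
# knockdown-response summaries.

.genes_check <- function(genes) {
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$end <= genes$start)) stop("gene length must be > 0")
  genes
}

# strand-aware TSS (0-based position of the first transcribed base)
.tss <- function(genes) ifelse(genes$strand == "+", genes$start,
                               genes$end - 1L)

#' Promoter region of a gene
#'
#' The 2-kb region strictly upstream of the transcription start site,
#' strand-aware and clamped at chromosome ends: `[TSS - 2000, TSS)` for +
#' strand genes, `[TSS + 1, TSS + 2001)` i.e. `[gene end, gene end + 2000)`
#' for - strand genes.
#'
#' @param genes Gene table (id, chrom, start, end, strand).
#' @param upstream_bp Promoter width, default 2000.
#' @param chrom_sizes Optional named lengths for clamping.
#' @return data.frame id, chrom, start, end (half-open promoter
#'   intervals).
#' @export
promoter_region <- function(genes, upstream_bp = 2000,
                            chrom_sizes = NULL) {
  genes <- .genes_check(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - upstream_bp, genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream_bp)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[genes$chrom])
  }
  data.frame(id = genes$id, chrom = genes$chrom, start = start,
             end = end)
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = df$end)  # 1-based closed
  )
}

#' Classify islands into promoter / gene body / intergenic
#'
#' Each island is assigned a single category with priority promoter >
#' gene body > intergenic when it spans several.  Islands on chromosomes
#' absent from the annotation count as intergenic (with a warning).
#'
#' @param islands `IslandSet` or data.frame chrom, start, end.
#' @param genes Gene table.
#' @param upstream_bp Promoter width, default 2000.
#' @return List with `category` (factor per island) and `fractions`
#'   (named numeric over promoter/gene_body/intergenic, summing to 1).
#' @export
classify_islands <- function(islands, genes, upstream_bp = 2000) {
  genes <- .genes_check(genes)
  if (!nrow(islands)) {
    return(list(category = factor(character(),
                                  levels = c("promoter", "gene_body",
                                             "intergenic")),
                fractions = c(promoter = NA_real_, gene_body = NA_real_,
                              intergenic = NA_real_)))
  }
  if (any(!islands$chrom %in% genes$chrom)) {
    warning("islands on chromosomes absent from the annotation are ",
            "counted as intergenic")
  }
  prom <- promoter_region(genes, upstream_bp)
  gi <- .as_granges(islands)
  # disjoint seqlevels (annotation-free chromosomes) are expected here
  in_prom <- suppressWarnings(IRanges::overlapsAny(gi, .as_granges(prom)))
  in_body <- suppressWarnings(IRanges::overlapsAny(gi, .as_granges(genes)))
  category <- factor(ifelse(in_prom, "promoter",
                            ifelse(in_body, "gene_body", "intergenic")),
                     levels = c("promoter", "gene_body", "intergenic"))
  fr <- table(category) / length(category)
  list(category = category,
       fractions = stats::setNames(as.numeric(fr), names(fr)))
}

#' Is each gene's promoter bound by an island?
#'
#' TRUE iff any island overlaps the 2-kb upstream promoter by at least
#' 1 bp (half-open interval semantics).
#'
#' @param genes Gene table.
#' @param islands data.frame chrom, start, end.
#' @param upstream_bp Promoter width, default 2000.
#' @return Logical vector, one per gene.
#' @export
promoter_bound <- function(genes, islands, upstream_bp = 2000) {
  genes <- .genes_check(genes)
  if (!nrow(islands)) return(rep(FALSE, nrow(genes)))
  prom <- promoter_region(genes, upstream_bp)
  IRanges::overlapsAny(.as_granges(prom), .as_granges(islands))
}

#' Rank gene promoters by binding significance
#'
#' Scores every promoter by the Poisson upper-tail probability of its
#' sample tag count at the control-derived expectation (control count
#' rescaled by the library-size ratio, with a pseudocount).  Promoters are
#' returned in ascending p-value order, ties broken by descending fold
#' then by gene id.
#'
#' @param genes Gene table.
#' @param sample_tags,control_tags Shifted `TagSet`s.
#' @param upstream_bp Promoter width, default 2000.
#' @param pseudocount Added to the control expectation, default 1.
#' @return data.frame id, sample_count, control_count, fold, p, rank.
#' @export
rank_promoters <- function(genes, sample_tags, control_tags,
                           upstream_bp = 2000, pseudocount = 1) {
  genes <- .genes_check(genes)
  prom <- promoter_region(genes, upstream_bp)
  cnt <- function(ts, ch, s, e) {
    p <- ts$positions[[ch]]
    if (is.null(p)) return(0)
    .count_in(sort(c(p[["+"]], p[["-"]])), s, e)
  }
  n <- nrow(prom)
  s_raw <- c_raw <- numeric(n)
  for (i in seq_len(n)) {
    s_raw[i] <- cnt(sample_tags, prom$chrom[i], prom$start[i], prom$end[i])
    c_raw[i] <- cnt(control_tags, prom$chrom[i], prom$start[i],
                    prom$end[i])
  }
  ratio <- sample_tags$lib_size / control_tags$lib_size
  expectation <- (c_raw + pseudocount) * ratio
  p <- window_pvalue(s_raw, expectation)
  fold <- (s_raw + pseudocount) / ((c_raw + pseudocount) * ratio)
  ord <- order(p, -fold, genes$id)
  out <- data.frame(id = genes$id, sample_count = s_raw,
                    control_count = c_raw, fold = fold, p = p)[ord, ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Group genes by combinatorial promoter-binding pattern
#'
#' Groups genes sharing an identical bound/unbound vector across the five
#' reader proteins, orders groups by descending size with the all-unbound
#' pattern forced last, and orders genes by id within each group.
#'
#' @param binding Logical matrix (genes x proteins) with gene ids as row
#'   names; column order is the display order (e.g. Brd2, Brd3, Brd4,
#'   HP1a, HP1b).
#' @param expressed Optional logical vector per gene (kept alongside).
#' @return data.frame gene, pattern (e.g. "11100"), group_rank, group_size,
#'   expressed; genes in display order.
#' @export
combinatorial_patterns <- function(binding, expressed = NULL) {
  stopifnot(is.matrix(binding) || is.data.frame(binding))
  binding <- as.matrix(binding)
  mode(binding) <- "logical"
  ids <- rownames(binding)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(binding)))
  pattern <- apply(binding, 1, function(r) paste(as.integer(r),
                                                 collapse = ""))
  sizes <- table(pattern)
  all_unbound <- strrep("0", ncol(binding))
  pats <- names(sizes)
  ord <- order(-as.integer(sizes), pats)
  pats <- pats[ord]
  if (all_unbound %in% pats) {
    pats <- c(setdiff(pats, all_unbound), all_unbound)
  }
  rows <- list()
  for (g in seq_along(pats)) {
    sel <- which(pattern == pats[g])
    sel <- sel[order(ids[sel])]
    rows[[g]] <- data.frame(
      gene = ids[sel], pattern = pats[g], group_rank = g,
      group_size = length(sel),
      expressed = if (is.null(expressed)) NA else expressed[sel]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param gene_read_count Reads assigned to the gene.
#' @param gene_length_bp Gene length (> 0), typically summed exon bp.
#' @param mapped_library_size Total mapped reads (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(gene_read_count, gene_length_bp, mapped_library_size) {
  if (any(gene_length_bp <= 0)) stop("gene length must be > 0")
  if (any(mapped_library_size <= 0)) stop("library size must be > 0")
  gene_read_count / (gene_length_bp / 1000 * mapped_library_size / 1e6)
}

#' Stratify genes into high / medium / silent expression classes
#'
#' Top 30% of the RPKM ranking are "high", bottom 30% "silent", the
#' remaining 40% "medium" (counts via floor(0.3 n), so 10 genes split
#' 3/4/3).  Ties are broken deterministically by gene id.
#'
#' @param genes Gene table with an `rpkm` column (or pass `rpkm_values`).
#' @param rpkm_values Optional numeric vector overriding `genes$rpkm`.
#' @return Factor (high/medium/silent), one per gene, in input order.
#' @export
expression_classes <- function(genes, rpkm_values = NULL) {
  v <- if (is.null(rpkm_values)) genes$rpkm else rpkm_values
  n <- length(v)
  if (n < 10) stop("need >= 10 genes to stratify")
  ids <- if (is.data.frame(genes)) genes$id else as.character(seq_len(n))
  ord <- order(-v, ids)               # descending RPKM, ties by id
  n_high <- floor(0.3 * n)
  n_silent <- floor(0.3 * n)
  cls <- rep("medium", n)
  cls[ord[seq_len(n_high)]] <- "high"
  cls[ord[(n - n_silent + 1):n]] <- "silent"
  factor(cls, levels = c("high", "medium", "silent"))
}

# per-gene profile: upstream flank, rescaled body, downstream flank,
# orientation-flipped for - strand genes; density per 100 bp, depth-
# normalized, control-subtracted with clipping
.gene_profile <- function(gene, sample_tags, control_tags, flank,
                          flank_bin, body_bins, target) {
  ch <- gene$chrom
  sp <- sample_tags$positions[[ch]]
  cp <- control_tags$positions[[ch]]
  spos <- if (is.null(sp)) numeric(0) else sort(c(sp[["+"]], sp[["-"]]))
  cpos <- if (is.null(cp)) numeric(0) else sort(c(cp[["+"]], cp[["-"]]))
  s_scale <- target / sample_tags$lib_size
  c_scale <- target / control_tags$lib_size

  density <- function(starts, ends) {
    s_cnt <- .count_in(spos, starts, ends) * s_scale
    c_cnt <- .count_in(cpos, starts, ends) * c_scale
    width <- ends - starts
    pmax(0, s_cnt - c_cnt) / width * 100      # per 100 bp
  }
  n_flank <- flank / flank_bin
  up_starts <- gene$start - flank + (seq_len(n_flank) - 1) * flank_bin
  dn_starts <- gene$end + (seq_len(n_flank) - 1) * flank_bin
  body_edges <- gene$start + (gene$end - gene$start) *
    (0:body_bins) / body_bins
  up <- density(up_starts, up_starts + flank_bin)
  dn <- density(dn_starts, dn_starts + flank_bin)
  body <- density(body_edges[-(body_bins + 1)], body_edges[-1])
  prof <- c(up, body, dn)
  if (gene$strand == "-") prof <- rev(prof)
  prof
}

#' Mean metagene profile per expression class
#'
#' For every gene, tag density (per 100-bp window, normalized to the
#' target depth) is computed over the upstream 2-kb flank, the gene body
#' rescaled to a fixed number of bins, and the downstream 2-kb flank; the
#' control density is subtracted with negative values clipped to zero, and
#' minus-strand genes are orientation-flipped.  Profiles are averaged
#' (unweighted) within each expression class.
#'
#' @param sample_tags,control_tags Shifted `TagSet`s.
#' @param genes Gene table.
#' @param classes Factor per gene (e.g. from [expression_classes()]).
#' @param flank Flank width in bp, default 2000 (20 x 100-bp windows).
#' @param body_bins Number of body bins, default 40.
#' @param target Depth-normalization target, default 5e6.
#' @return Matrix class x bin (rows high/medium/silent); columns named
#'   u1..u20, b1..b40, d1..d20.  Genes shorter than `body_bins` bp are
#'   excluded with a warning.
#' @export
metagene_profile <- function(sample_tags, control_tags, genes, classes,
                             flank = 2000, body_bins = 40, target = 5e6) {
  genes <- .genes_check(genes)
  flank_bin <- 100
  short <- (genes$end - genes$start) < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than one bin excluded")
    genes <- genes[!short, ]
    classes <- classes[!short]
  }
  n_flank <- flank / flank_bin
  nbin <- 2 * n_flank + body_bins
  lev <- levels(classes)
  out <- matrix(0, length(lev), nbin, dimnames = list(
    lev, c(paste0("u", seq_len(n_flank)), paste0("b", seq_len(body_bins)),
           paste0("d", seq_len(n_flank)))))
  for (cl in lev) {
    sel <- which(classes == cl)
    if (!length(sel)) { out[cl, ] <- NA; next }
    profs <- vapply(sel, function(i) {
      .gene_profile(genes[i, ], sample_tags, control_tags, flank,
                    flank_bin, body_bins, target)
    }, numeric(nbin))
    out[cl, ] <- rowMeans(profs)
  }
  out
}

#' Knockdown response of top-ranked bound genes
#'
#' Intersects the top-N promoter-bound genes with an expression log2
#' fold-change table and reports the fractions with at least a
#' `fold_cutoff`-fold reduction or increase.
#'
#' @param ranked_bound_genes Character vector of gene ids, best first
#'   (e.g. `rank_promoters(...)$id`).
#' @param expression_log2fc Named numeric vector (or data.frame with
#'   columns id, log2fc) of knockdown-vs-control expression changes.
#' @param top_n Number of top genes to consider, default 100.
#' @param fold_cutoff Linear fold-change cutoff, default 2.
#' @return List: `table` (data.frame id, log2fc, flag), `fraction_reduced`,
#'   `fraction_increased`, `n_missing`.
#' @export
knockdown_response <- function(ranked_bound_genes, expression_log2fc,
                               top_n = 100, fold_cutoff = 2) {
  if (is.data.frame(expression_log2fc)) {
    expression_log2fc <- stats::setNames(expression_log2fc$log2fc,
                                         expression_log2fc$id)
  }
  top <- utils::head(ranked_bound_genes, top_n)
  fc <- expression_log2fc[top]
  missing <- is.na(fc)
  if (all(missing)) stop("no top-ranked gene found in the expression table")
  thr <- log2(fold_cutoff)
  tab <- data.frame(id = top, log2fc = unname(fc),
                    flag = ifelse(missing, "missing", "ok"))
  present <- fc[!missing]
  list(table = tab,
       fraction_reduced = mean(present <= -thr),
       fraction_increased = mean(present >= thr),
       n_missing = sum(missing))
}
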