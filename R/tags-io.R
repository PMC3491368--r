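# Readers for aligned sequencing tags (BED6, SAM text, BAM via Rsamtools)
# and for gene models / chromosome sizes.
#
# All coordinates inside the package are 0-based half-open (BED
# convention); SAM 1-based positions are converted on read.  The tag
# position is the 5' end per strand: the leftmost aligned base for +, the
# rightmost aligned base for -.

#' Read aligned tags
#'
#' Dispatches on extension: `.bed` (BED6), `.sam`, `.bam` (requires
#' Rsamtools).
#'
#' @param path Input file.
#' @param mapq_min Minimum mapping quality ("uniquely aligned" filter) for
#'   SAM/BAM input; default 20.
#' @return data.frame with columns chrom, pos (0-based 5' end), strand.
#' @export
read_tags <- function(path, mapq_min = 20) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    bed = read_tags_bed(path),
    sam = read_tags_sam(path, mapq_min),
    bam = read_tags_bam(path, mapq_min),
    stop("unknown tag format: .", ext)
  )
}

#' Read tags from a 6-column BED file
#'
#' The tag position is the 5' end: `start` for + strand records, `end - 1`
#' for - strand records.
#'
#' @param path BED6 file.
#' @return data.frame with columns chrom, pos, strand.
#' @export
read_tags_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("need 6-column BED (strand required)")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  data.frame(
    chrom = df$chrom,
    pos = ifelse(df$strand == "+", df$start, df$end - 1L),
    strand = df$strand
  )
}

# reference-consuming CIGAR length (M, D, N, =, X)
.cigar_reflen <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Read tags from a plain-text SAM file
#'
#' Keeps mapped single-end records with MAPQ at or above the threshold;
#' the 5' position of a reverse-strand record is derived from the CIGAR
#' reference length.
#'
#' @param path SAM file.
#' @param mapq_min Minimum MAPQ, default 20.
#' @return data.frame with columns chrom, pos, strand.
#' @export
read_tags_sam <- function(path, mapq_min = 20) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L & mapq >= mapq_min
  f <- f[keep]; flag <- flag[keep]
  if (!length(f)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  }
  chrom <- vapply(f, function(x) x[3], character(1))
  pos1 <- vapply(f, function(x) as.integer(x[4]), integer(1))
  cigar <- vapply(f, function(x) x[6], character(1))
  rev <- bitwAnd(flag, 16L) != 0L
  pos0 <- pos1 - 1L
  pos <- ifelse(rev, pos0 + as.integer(.cigar_reflen(cigar)) - 1L, pos0)
  data.frame(chrom = chrom, pos = pos,
             strand = ifelse(rev, "-", "+"))
}

#' Read tags from a BAM file (via Rsamtools)
#'
#' @param path BAM file.
#' @param mapq_min Minimum MAPQ, default 20.
#' @return data.frame with columns chrom, pos, strand.
#' @export
read_tags_bam <- function(path, mapq_min = 20) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package")
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth", "cigar", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  keep <- !is.na(b$mapq) & b$mapq >= mapq_min
  reflen <- .cigar_reflen(b$cigar[keep])
  rev <- as.character(b$strand[keep]) == "-"
  pos0 <- b$pos[keep] - 1L
  data.frame(
    chrom = as.character(b$rname[keep]),
    pos = ifelse(rev, pos0 + as.integer(reflen) - 1L, pos0),
    strand = ifelse(rev, "-", "+")
  )
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Read gene models from BED12 (or BED6) into a gene table
#'
#' @param path BED file; column 4 is the gene id.
#' @return data.frame with columns id, chrom, start, end, strand, and
#'   exon_bp (sum of block sizes for BED12, span length otherwise).
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("need at least 6 BED columns")
  exon_bp <- if (ncol(df) >= 12) {
    vapply(df[[11]], function(s) {
      sum(as.numeric(strsplit(sub(",$", "", s), ",")[[1]]))
    }, numeric(1))
  } else df[[3]] - df[[2]]
  data.frame(id = df[[4]], chrom = df[[1]], start = df[[2]], end = df[[3]],
             strand = df[[6]], exon_bp = unname(exon_bp))
}
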