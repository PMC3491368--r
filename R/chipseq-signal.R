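# The read-level ChIP-seq signal model: per-position-per-strand
# deduplication, 75-bp tag shifting toward the fragment midpoint, sliding-
# window counting, normalization to a 5-million-read depth, control
# subtraction with clipping at zero, and bedGraph track emission.

#' Build a deduplicated tag set
#'
#' Keeps at most one tag per (chromosome, position, strand); the library
#' size is the post-deduplication tag count.  Idempotent.
#'
#' @param tags data.frame with columns chrom, pos (0-based), strand
#'   ("+"/"-"), e.g. from [read_tags()]; or an existing `TagSet`.
#' @param chrom_sizes Named numeric vector of chromosome lengths; inferred
#'   (max position + 1) when omitted.
#' @return Object of class `TagSet`: per-chromosome, per-strand sorted
#'   unique position vectors plus `lib_size` and `chrom_sizes`.
#' @export
deduplicate <- function(tags, chrom_sizes = NULL) {
  if (inherits(tags, "TagSet")) return(tags)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  if (any(tags$pos < 0)) stop("positions must be >= 0")
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes) else
    sort(unique(tags$chrom))
  positions <- list()
  n <- 0L
  for (ch in chroms) {
    sub <- tags[tags$chrom == ch, ]
    positions[[ch]] <- list(
      `+` = sort(unique(sub$pos[sub$strand == "+"])),
      `-` = sort(unique(sub$pos[sub$strand == "-"]))
    )
    n <- n + length(positions[[ch]][["+"]]) + length(positions[[ch]][["-"]])
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(positions, function(p) {
      max(c(p[["+"]], p[["-"]], 0)) + 1
    }, numeric(1))
  }
  structure(list(positions = positions, lib_size = n,
                 chrom_sizes = chrom_sizes),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat(sprintf("<TagSet> %d tags on %d chromosome(s)\n", x$lib_size,
              length(x$positions)))
  invisible(x)
}

#' Shift tags toward the fragment midpoint
#'
#' Forward-strand positions move `+shift`, reverse-strand positions
#' `-shift` (half the nucleosomal DNA length re-centers tags on the
#' nucleosome dyad).  Positions are clamped to the chromosome bounds, so
#' the tag count is unchanged; shifted positions are re-uniqued per strand.
#'
#' @param tagset A `TagSet`.
#' @param shift Non-negative shift in bp, default 75.
#' @return A shifted `TagSet`.
#' @export
shift_tags <- function(tagset, shift = 75) {
  stopifnot(inherits(tagset, "TagSet"), shift >= 0)
  out <- tagset
  for (ch in names(tagset$positions)) {
    lim <- tagset$chrom_sizes[[ch]] - 1
    fwd <- pmin(tagset$positions[[ch]][["+"]] + shift, lim)
    rev <- pmax(tagset$positions[[ch]][["-"]] - shift, 0)
    out$positions[[ch]] <- list(`+` = sort(fwd), `-` = sort(rev))
  }
  # clamping can merge edge tags onto one position; lib_size tracks tags,
  # not unique positions, and is deliberately left unchanged
  out
}

# count of positions p with s <= p < e, positions sorted
.count_in <- function(positions, s, e) {
  findInterval(e - 0.5, positions) - findInterval(s - 0.5, positions)
}

# window start grid for one chromosome
.window_starts <- function(chrom_len, window_bp, step_bp) {
  last <- max(0, ceiling((chrom_len - window_bp) / step_bp) * step_bp)
  seq(0, last, by = step_bp)
}

#' Count tags in (sliding) windows
#'
#' Counts both strands' positions falling in each half-open window
#' `[start, start + window)` on a grid with the given step.  A window
#' larger than the step yields the sliding-window (overlapping) counting
#' used for Mb-scale binding patterns; `step == window` gives tiling
#' windows.
#'
#' @param tagset A (typically shifted) `TagSet`.
#' @param window_bp Window size in bp.
#' @param step_bp Step size in bp (<= window).
#' @return Object of class `WindowTrack`: data.frame chrom, start, end,
#'   value; attributes `window`, `step`, `normalized`.
#' @export
count_windows <- function(tagset, window_bp, step_bp = window_bp) {
  stopifnot(inherits(tagset, "TagSet"), window_bp >= step_bp, step_bp > 0)
  out <- list()
  for (ch in names(tagset$positions)) {
    starts <- .window_starts(tagset$chrom_sizes[[ch]], window_bp, step_bp)
    pos <- sort(c(tagset$positions[[ch]][["+"]],
                  tagset$positions[[ch]][["-"]]))
    cnt <- .count_in(pos, starts, starts + window_bp)
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window_bp, value = cnt)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  structure(track, class = c("WindowTrack", "data.frame"),
            window = window_bp, step = step_bp, normalized = FALSE)
}

#' Normalize a window track to a target sequencing depth
#'
#' Scales every window value by `target / library_size` so libraries of
#' different depths are comparable (default target: 5 million non-redundant
#' reads).
#'
#' @param track A `WindowTrack`.
#' @param library_size Library size (post-deduplication tag count), > 0.
#' @param target Target depth, default 5e6.
#' @return The normalized `WindowTrack`.
#' @export
normalize_depth <- function(track, library_size, target = 5e6) {
  if (library_size <= 0) stop("library_size must be > 0")
  track$value <- track$value * target / library_size
  attr(track, "normalized") <- TRUE
  track
}

#' Subtract a control track with clipping at zero
#'
#' value = max(0, sample - control), windows matched by coordinates; both
#' tracks must share the grid and the normalization target.
#'
#' @param sample_track,control_track `WindowTrack`s on identical grids.
#' @return A `WindowTrack` of the clipped differences.
#' @export
subtract_control <- function(sample_track, control_track) {
  if (nrow(sample_track) != nrow(control_track) ||
      !all(sample_track$chrom == control_track$chrom) ||
      !all(sample_track$start == control_track$start)) {
    stop("window grids do not match")
  }
  sample_track$value <- pmax(0, sample_track$value - control_track$value)
  sample_track
}

#' Emit bedGraph records
#'
#' Two modes mirror the browser-track conventions used for reader ChIPs
#' and RNA-seq:
#' \describe{
#'   \item{`chip-200bp-shifted`}{75-bp-shifted tags counted in 200-bp
#'     tiling windows, normalized to 5 million reads. `tagset` must
#'     already be shifted.}
#'   \item{`rna-20bp-centers`}{read centers counted in 20-bp tiling
#'     windows, raw counts. Needs `reads` (data.frame chrom, start, end).}
#' }
#' Zero windows are omitted; records are sorted, half-open and
#' non-overlapping.
#'
#' @param tagset A shifted `TagSet` (chip mode).
#' @param mode `"chip-200bp-shifted"` or `"rna-20bp-centers"`.
#' @param reads data.frame of read intervals (rna mode).
#' @param target Normalization target for chip mode, default 5e6.
#' @return data.frame chrom, start, end, value.
#' @export
bedgraph_tracks <- function(tagset = NULL,
                            mode = c("chip-200bp-shifted",
                                     "rna-20bp-centers"),
                            reads = NULL, target = 5e6) {
  mode <- match.arg(mode)
  if (mode == "chip-200bp-shifted") {
    stopifnot(inherits(tagset, "TagSet"))
    tr <- count_windows(tagset, 200, 200)
    tr <- normalize_depth(tr, tagset$lib_size, target)
    out <- tr[tr$value > 0, c("chrom", "start", "end", "value")]
  } else {
    if (is.null(reads)) stop("rna mode needs read intervals")
    centers <- floor((reads$start + reads$end - 1) / 2)
    ts <- deduplicate(data.frame(chrom = reads$chrom, pos = centers,
                                 strand = "+"))
    # centers are counted, duplicates included: tabulate per 20-bp tile
    out <- list()
    for (ch in unique(reads$chrom)) {
      cc <- centers[reads$chrom == ch]
      tile <- floor(cc / 20)
      tab <- table(tile)
      s <- as.integer(names(tab)) * 20L
      out[[ch]] <- data.frame(chrom = ch, start = s, end = s + 20L,
                              value = as.integer(tab))
    }
    out <- do.call(rbind, out)
    out <- out[order(out$chrom, out$start), ]
  }
  rownames(out) <- NULL
  out
}

#' Write bedGraph records to a file
#'
#' @param records data.frame chrom, start, end, value.
#' @param path Output file.
#' @param track_line Optional UCSC track line to prepend.
#' @export
write_bedgraph <- function(records, path, track_line = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
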