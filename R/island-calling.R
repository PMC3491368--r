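# Identification of enriched domains ("islands") from window-level tag
# counts: eligible windows under a Poisson background model are aggregated
# across small gaps, and aggregate island scores are thresholded at a level
# calibrated to a target genome-wide E-value.

#' Poisson upper-tail window probability
#'
#' P(X >= count) for X ~ Poisson(lambda).
#'
#' @param count Observed window tag count (>= 0).
#' @param lambda_background Background expectation per window (> 0).
#' @return Upper-tail probability.
#' @export
window_pvalue <- function(count, lambda_background) {
  if (any(lambda_background <= 0)) stop("lambda must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  stats::ppois(count - 1, lambda_background, lower.tail = FALSE)
}

# islands for one chromosome's eligible-window index/score vectors;
# `scores` is parallel to `idx` (scores of the eligible windows only)
.merge_eligible <- function(idx, scores, gap_allowance) {
  if (!length(idx)) {
    return(data.frame(first = integer(), last = integer(),
                      score = numeric()))
  }
  brk <- which(diff(idx) > gap_allowance + 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  data.frame(
    first = idx[starts], last = idx[ends],
    score = vapply(seq_along(starts), function(i) {
      sum(scores[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' Find enriched islands in a window-count track
#'
#' Windows with Poisson upper-tail probability at most `p0_eligibility`
#' are eligible and score `-log10(p)`; runs of eligible windows separated
#' by at most `gap_allowance_windows` ineligible windows are merged into
#' islands (islands touching at a boundary merge), and an island is kept
#' when its aggregate score (sum of its eligible windows' scores) reaches
#' `score_threshold`.  Deterministic for fixed inputs.
#'
#' @param window_counts A `WindowTrack` of raw counts on a non-overlapping
#'   grid (step == window).
#' @param lambda Background expectation per window (> 0). See
#'   [estimate_lambda()].
#' @param p0_eligibility Eligibility probability threshold, default 0.2.
#' @param gap_allowance_windows Maximum ineligible windows bridged,
#'   default 1 (200 bp at the 200-bp island grid).
#' @param score_threshold Minimum aggregate island score, default 0 (keep
#'   all); see [island_score_threshold()] for E-value calibration.
#' @return data.frame of class `IslandSet`: chrom, start, end, score,
#'   n_eligible, sorted and disjoint.
#' @export
find_islands <- function(window_counts, lambda, p0_eligibility = 0.2,
                         gap_allowance_windows = 1, score_threshold = 0) {
  if (!nrow(window_counts)) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), score = numeric(),
                                n_eligible = integer()),
                     class = c("IslandSet", "data.frame")))
  }
  if (attr(window_counts, "step") != attr(window_counts, "window")) {
    stop("island calling needs a non-overlapping window grid")
  }
  w <- attr(window_counts, "window")
  out <- list()
  for (ch in unique(window_counts$chrom)) {
    sub <- window_counts[window_counts$chrom == ch, ]
    pv <- window_pvalue(sub$value, lambda)
    elig <- which(pv <= p0_eligibility)
    isl <- .merge_eligible(elig, -log10(pmax(pv[elig], 1e-300)),
                           gap_allowance_windows)
    isl <- isl[isl$score >= score_threshold, , drop = FALSE]
    if (nrow(isl)) {
      out[[ch]] <- data.frame(
        chrom = ch,
        start = sub$start[isl$first],
        end = sub$end[isl$last],
        score = isl$score,
        n_eligible = vapply(seq_len(nrow(isl)), function(i) {
          sum(elig >= isl$first[i] & elig <= isl$last[i])
        }, integer(1))
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               score = numeric(), n_eligible = integer())
  rownames(res) <- NULL
  structure(res, class = c("IslandSet", "data.frame"), window = w)
}

#' Estimate the Poisson background rate per window
#'
#' From the control track when available (scaled to the sample library),
#' otherwise the genome-wide mean of the sample track.
#'
#' @param sample_track Raw-count `WindowTrack` for the ChIP library.
#' @param control_track Optional raw-count `WindowTrack` for the control.
#' @param sample_lib,control_lib Library sizes used to rescale the control
#'   mean onto the sample depth.
#' @return Scalar lambda (> 0).
#' @export
estimate_lambda <- function(sample_track, control_track = NULL,
                            sample_lib = NULL, control_lib = NULL) {
  if (!is.null(control_track)) {
    lam <- mean(control_track$value)
    if (!is.null(sample_lib) && !is.null(control_lib)) {
      lam <- lam * sample_lib / control_lib
    }
  } else {
    lam <- mean(sample_track$value)
  }
  max(lam, .Machine$double.eps)
}

#' Calibrate the island score threshold to a target E-value
#'
#' Simulates null genomes (i.i.d. Poisson window counts at `lambda` over
#' `n_windows` windows), runs the island aggregation, and returns the
#' score threshold at which the expected number of passing islands per
#' genome equals `evalue`.
#'
#' @param lambda Background expectation per window.
#' @param n_windows Number of windows in the genome.
#' @param evalue Target expected island count per null genome.
#' @param p0_eligibility,gap_allowance_windows As in [find_islands()].
#' @param nsim Number of simulated null genomes, default 20.
#' @param seed RNG seed for the calibration.
#' @return Scalar score threshold.
#' @export
island_score_threshold <- function(lambda, n_windows, evalue = 100,
                                   p0_eligibility = 0.2,
                                   gap_allowance_windows = 1,
                                   nsim = 20, seed = 1) {
  set.seed(seed)
  scores <- numeric(0)
  for (i in seq_len(nsim)) {
    cnt <- stats::rpois(n_windows, lambda)
    pv <- window_pvalue(cnt, lambda)
    elig <- which(pv <= p0_eligibility)
    isl <- .merge_eligible(elig, -log10(pmax(pv[elig], 1e-300)),
                           gap_allowance_windows)
    scores <- c(scores, isl$score)
  }
  need <- evalue * nsim
  if (length(scores) <= need) return(0)
  s <- sort(scores, decreasing = TRUE)
  # smallest threshold with expected passing count <= evalue
  (s[floor(need)] + s[floor(need) + 1]) / 2
}

#' Fold enrichment and significance of an island against a control
#'
#' fold = (sample + pc) / (control + pc) on depth-normalized counts;
#' the probability is the Poisson upper tail of the raw sample count at
#' the control-derived expectation.
#'
#' @param islands An `IslandSet`.
#' @param sample_tags,control_tags Shifted `TagSet`s.
#' @param pseudocount Added to both normalized counts, default 1.
#' @param target Depth-normalization target, default 5e6.
#' @return The islands data.frame with added columns sample_norm,
#'   control_norm, fold, probability.
#' @export
island_significance <- function(islands, sample_tags, control_tags,
                                pseudocount = 1, target = 5e6) {
  cnt <- function(ts, ch, s, e) {
    p <- ts$positions[[ch]]
    if (is.null(p)) return(0)
    .count_in(sort(c(p[["+"]], p[["-"]])), s, e)
  }
  n <- nrow(islands)
  s_raw <- c_raw <- numeric(n)
  for (i in seq_len(n)) {
    s_raw[i] <- cnt(sample_tags, islands$chrom[i], islands$start[i],
                    islands$end[i])
    c_raw[i] <- cnt(control_tags, islands$chrom[i], islands$start[i],
                    islands$end[i])
  }
  s_norm <- s_raw * target / sample_tags$lib_size
  c_norm <- c_raw * target / control_tags$lib_size
  expectation <- pmax(c_raw * sample_tags$lib_size / control_tags$lib_size,
                      .Machine$double.eps)
  islands$sample_norm <- s_norm
  islands$control_norm <- c_norm
  islands$fold <- (s_norm + pseudocount) / (c_norm + pseudocount)
  islands$probability <- window_pvalue(s_raw, expectation)
  islands
}

#' Call islands from ChIP and control tag sets
#'
#' Convenience pipeline: shift both libraries, count the ChIP on the
#' island grid, estimate lambda from the control, and run
#' [find_islands()] followed by [island_significance()].
#'
#' @param chip_tags,control_tags Deduplicated `TagSet`s (unshifted).
#' @param shift Tag shift in bp, default 75.
#' @param window_bp Island grid window, default 200.
#' @param p0_eligibility,gap_allowance_windows,score_threshold Passed to
#'   [find_islands()].
#' @return An `IslandSet` with significance columns.
#' @export
call_islands <- function(chip_tags, control_tags, shift = 75,
                         window_bp = 200, p0_eligibility = 0.2,
                         gap_allowance_windows = 1, score_threshold = 0) {
  chip_sh <- shift_tags(chip_tags, shift)
  ctrl_sh <- shift_tags(control_tags, shift)
  chip_cnt <- count_windows(chip_sh, window_bp, window_bp)
  ctrl_cnt <- count_windows(ctrl_sh, window_bp, window_bp)
  lam <- estimate_lambda(chip_cnt, ctrl_cnt, chip_tags$lib_size,
                         control_tags$lib_size)
  isl <- find_islands(chip_cnt, lam, p0_eligibility,
                      gap_allowance_windows, score_threshold)
  island_significance(isl, chip_sh, ctrl_sh)
}

#' Write islands to BED (and optionally a fold/probability TSV)
#'
#' BED score = min(1000, round(10 * aggregate score)), strand ".".
#'
#' @param islands An `IslandSet`.
#' @param path Output BED path.
#' @param tsv_path Optional TSV path for the full table.
#' @export
write_islands_bed <- function(islands, path, tsv_path = NULL) {
  bed <- data.frame(
    chrom = islands$chrom, start = islands$start, end = islands$end,
    name = sprintf("island_%d", seq_len(nrow(islands))),
    score = pmin(1000, round(10 * islands$score)),
    strand = "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(islands, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
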