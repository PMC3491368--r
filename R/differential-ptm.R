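# ChIP-vs-input differential statistics on PTM relative abundances:
# log2 fold changes, two-sample t-tests across replicates, and
# Benjamini-Hochberg correction per ChIP comparison.

#' log2 fold change of ChIP over input abundance
#'
#' A pseudocount is added to both terms only when either is zero (the cell
#' is then flagged).
#'
#' @param chip_percent,input_percent Non-negative relative abundances (%).
#' @param pseudocount Added to both terms when either is zero; default 0.01
#'   percentage points.
#' @return List with `log2fc` and `flag` (`"ok"`, `"pseudocount"`, or
#'   `"missing"` when both inputs are zero).
#' @export
fold_change <- function(chip_percent, input_percent, pseudocount = 0.01) {
  stopifnot(chip_percent >= 0, input_percent >= 0)
  if (chip_percent == 0 && input_percent == 0) {
    return(list(log2fc = NA_real_, flag = "missing"))
  }
  if (chip_percent == 0 || input_percent == 0) {
    return(list(log2fc = log2((chip_percent + pseudocount) /
                                (input_percent + pseudocount)),
                flag = "pseudocount"))
  }
  list(log2fc = log2(chip_percent / input_percent), flag = "ok")
}

#' Classical two-sample t-test p-value
#'
#' Two-tailed, unpaired, equal-variance (Student) by default; Welch
#' available behind a flag.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance form instead.
#' @return List with `p`, `t`, `df`, `flag` (`"ok"` or `"zero_variance"`,
#'   in which case p is NA).
#' @export
ttest_two_sample <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs >= 2 values")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    return(list(p = NA_real_, t = NA_real_, df = NA_real_,
                flag = "zero_variance"))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(p = fit$p.value, t = unname(fit$statistic),
       df = unname(fit$parameter), flag = "ok")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR control; NA p-values propagate to NA q-values with a
#' warning.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues)) warning("NA p-values propagated to NA q-values")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Fold-change/heatmap matrix with per-cell statistics
#'
#' For every (modified form, ChIP) pair, computes log2(mean ChIP abundance /
#' mean input abundance) across replicates, a two-tailed unpaired t-test
#' p-value, and BH q-values adjusted within each ChIP comparison (one BH
#' family per ChIP, matching per-comparison supplementary-table
#' organization).
#'
#' @param abundance Long data.frame with columns form, abundance, sample,
#'   replicate (an `AbundanceTable` or rbind of several).
#' @param input_sample Name of the input/whole-genome sample.
#' @param chip_samples Character vector of ChIP sample names; default all
#'   non-input samples.
#' @param pseudocount Passed to [fold_change()].
#' @param log_space Run the t-test on log2-transformed abundances.
#' @param welch Use the Welch t-test.
#' @return List of class `FoldChangeResult`: `log2fc` matrix (forms x
#'   ChIPs), `p` and `q` matrices, `flags` matrix, `stats` long data.frame.
#' @export
build_heatmap_matrix <- function(abundance, input_sample,
                                 chip_samples = NULL, pseudocount = 0.01,
                                 log_space = FALSE, welch = FALSE) {
  samples <- unique(abundance$sample)
  if (!input_sample %in% samples) stop("input sample not present")
  if (is.null(chip_samples)) chip_samples <- setdiff(samples, input_sample)
  forms <- unique(abundance$form)   # stable: first-appearance order

  get_reps <- function(form, sample) {
    abundance$abundance[abundance$form == form &
                          abundance$sample == sample]
  }
  fc <- p <- matrix(NA_real_, length(forms), length(chip_samples),
                    dimnames = list(forms, chip_samples))
  flg <- matrix("ok", length(forms), length(chip_samples),
                dimnames = list(forms, chip_samples))
  for (j in seq_along(chip_samples)) {
    for (i in seq_along(forms)) {
      a <- get_reps(forms[i], chip_samples[j])
      b <- get_reps(forms[i], input_sample)
      if (length(a) < 2 || length(b) < 2) {
        flg[i, j] <- "missing_replicates"
        if (length(a) >= 1 && length(b) >= 1) {
          r <- fold_change(mean(a), mean(b), pseudocount)
          fc[i, j] <- r$log2fc
        }
        next
      }
      r <- fold_change(mean(a), mean(b), pseudocount)
      fc[i, j] <- r$log2fc
      if (r$flag != "ok") flg[i, j] <- r$flag
      tt <- if (log_space) {
        ttest_two_sample(log2(a + pseudocount), log2(b + pseudocount),
                         welch)
      } else ttest_two_sample(a, b, welch)
      p[i, j] <- tt$p
      if (tt$flag != "ok") flg[i, j] <- tt$flag
    }
  }
  q <- p
  for (j in seq_along(chip_samples)) q[, j] <- bh_adjust(p[, j])
  stats_df <- data.frame(
    form = rep(forms, times = length(chip_samples)),
    chip = rep(chip_samples, each = length(forms)),
    log2fc = as.vector(fc), p = as.vector(p), q = as.vector(q),
    flag = as.vector(flg)
  )
  structure(list(log2fc = fc, p = p, q = q, flags = flg, stats = stats_df),
            class = "FoldChangeResult")
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat(sprintf("<FoldChangeResult> %d forms x %d ChIPs; %d cells q < 0.05\n",
              nrow(x$log2fc), ncol(x$log2fc),
              sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Write fold-change statistics to TSV
#'
#' Long layout: form, chip, log2fc, p, q, flag.
#'
#' @param result A `FoldChangeResult`.
#' @param path Output file.
#' @export
write_foldchange_tsv <- function(result, path) {
  utils::write.table(result$stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
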