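# Quantification of proteoform relative abundances from peak lists:
# XIC extraction, peak-area integration, d0/d5 channel pairing, and
# superposition (non-negative least squares) deconvolution of mixed MS/MS
# spectra from co-eluting isobaric positional isomers.

#' Extract an ion chromatogram
#'
#' Per MS1 scan, sums the intensity of all peaks within a ppm window of the
#' target m/z; scans with no matching peak contribute zero.
#'
#' @param pkl A `PeakList` with at least one MS1 scan.
#' @param target_mz Target m/z.
#' @param ppm_tolerance Half-window in ppm (must be > 0).
#' @return Object of class `XIC`: data.frame with columns rt, intensity;
#'   attributes `target_mz`, `ppm`.
#' @export
extract_xic <- function(pkl, target_mz, ppm_tolerance = 10) {
  if (ppm_tolerance <= 0) stop("ppm_tolerance must be > 0")
  ms1 <- Filter(function(s) s$level == 1, pkl$scans)
  if (!length(ms1)) stop("peak list has no MS1 scans")
  tol <- target_mz * ppm_tolerance * 1e-6
  trace <- data.frame(
    rt = vapply(ms1, function(s) s$rt, numeric(1)),
    intensity = vapply(ms1, function(s) {
      sum(s$intensity[abs(s$mz - target_mz) <= tol])
    }, numeric(1))
  )
  structure(trace, class = c("XIC", "data.frame"),
            target_mz = target_mz, ppm = ppm_tolerance)
}

#' Apex retention time of an XIC
#'
#' Maximum of a 3-point moving average of the trace; ties broken by the
#' earliest time.
#'
#' @param xic An `XIC`.
#' @return Retention time (s) of the apex.
#' @export
xic_apex <- function(xic) {
  y <- xic$intensity
  n <- length(y)
  if (n == 1) return(xic$rt[1])
  sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(y[1:2]); sm[n] <- mean(y[(n - 1):n])
  xic$rt[which.max(sm)]   # which.max takes the first (earliest) maximum
}

#' Integrate an XIC peak over a retention-time window
#'
#' Trapezoidal integral of the trace restricted to `rt_window`.
#'
#' @param xic An `XIC`.
#' @param rt_window Numeric length-2, `c(lo, hi)` in seconds.
#' @return Area (intensity * s), non-negative.
#' @export
integrate_peak <- function(xic, rt_window = range(xic$rt)) {
  sel <- xic$rt >= rt_window[1] & xic$rt <= rt_window[2]
  if (sum(sel) < 2) {
    warning("empty or single-point integration window; area = 0")
    return(0)
  }
  pracma::trapz(xic$rt[sel], xic$intensity[sel])
}

#' d0/d5 channel area ratio
#'
#' @param d0_area,d5_area Non-negative peak areas.
#' @return List with `ratio` (d0/d5; `Inf` when the d5 area is zero and the
#'   d0 area is not) and `flag` (`"ok"`, `"zero_denominator"`, or
#'   `"missing"` when both areas are zero).
#' @export
pair_channels <- function(d0_area, d5_area) {
  stopifnot(d0_area >= 0, d5_area >= 0)
  if (d0_area == 0 && d5_area == 0) {
    return(list(ratio = NA_real_, flag = "missing"))
  }
  if (d5_area == 0) return(list(ratio = Inf, flag = "zero_denominator"))
  list(ratio = d0_area / d5_area, flag = "ok")
}

# Build the template matrix for an isobaric group: rows are the union of
# theoretical singly charged b/y fragment m/z slots (merged within the match
# tolerance), columns are members; entries are the member's normalized
# template intensity at that slot.
.group_templates <- function(group, match_tolerance_ppm,
                             templates = NULL) {
  k <- length(group$proteoforms)
  frag <- lapply(group$proteoforms, function(p) fragment_ions(p, 1))
  if (is.null(templates)) {
    templates <- lapply(frag, function(f) rep(1, nrow(f)))  # uniform shape
  }
  all_mz <- sort(unlist(lapply(frag, function(f) f$mz)))
  # merge slots closer than the tolerance
  slots <- numeric(0)
  for (m in all_mz) {
    if (!length(slots) || (m - slots[length(slots)]) / m * 1e6 >
        match_tolerance_ppm) {
      slots <- c(slots, m)
    }
  }
  A <- matrix(0, nrow = length(slots), ncol = k)
  for (j in seq_len(k)) {
    tj <- templates[[j]] / sum(templates[[j]])
    for (i in seq_along(frag[[j]]$mz)) {
      s <- which.min(abs(slots - frag[[j]]$mz[i]))
      A[s, j] <- A[s, j] + tj[i]
    }
  }
  list(slots = slots, A = A)
}

#' Deconvolve a mixed MS/MS spectrum of an isobaric group
#'
#' Solves min ||A x - o|| subject to x >= 0 (Lawson-Hanson NNLS), where the
#' columns of A are normalized theoretical fragment-intensity templates of
#' the group members and o is the observed intensity matched to the
#' theoretical m/z slots (unmatched slots contribute observed intensity 0,
#' penalizing absent site-determining ions).  Proportions are x normalized
#' to sum 1.
#'
#' @param ms2_spectrum A scan (list with `mz`, `intensity`) or an MS2 scan
#'   from a `PeakList`.
#' @param isobaric_group One group as returned by [isobaric_groups()].
#' @param match_tolerance_ppm Fragment match tolerance (ppm), default 20.
#' @param templates Optional list of per-member fragment template
#'   intensities (same order/length as each member's [fragment_ions()]
#'   rows); default uniform.
#' @return Object of class `DeconvolutionResult`: list with `proportions`
#'   (sums to 1), `residual_norm`, `indeterminate` (logical per member:
#'   no site-determining ion observed), `n_matched`.
#' @export
deconvolve_isobaric <- function(ms2_spectrum, isobaric_group,
                                match_tolerance_ppm = 20, templates = NULL) {
  tpl <- .group_templates(isobaric_group, match_tolerance_ppm, templates)
  tol <- tpl$slots * match_tolerance_ppm * 1e-6
  o <- vapply(seq_along(tpl$slots), function(i) {
    sum(ms2_spectrum$intensity[abs(ms2_spectrum$mz - tpl$slots[i]) <= tol[i]])
  }, numeric(1))
  n_matched <- sum(o > 0)
  if (n_matched == 0) {
    stop("no fragment ions matched: identification failure")
  }
  fit <- pracma::lsqnonneg(tpl$A, o)
  x <- fit$x
  if (sum(x) == 0) {
    stop("deconvolution degenerate: all coefficients zero")
  }
  resnorm <- fit$resid.norm
  props <- x / sum(x)
  indet <- vapply(seq_along(isobaric_group$site_determining), function(j) {
    sd_mz <- isobaric_group$site_determining[[j]]
    if (!length(sd_mz)) return(FALSE)
    !any(vapply(sd_mz, function(m) {
      any(abs(ms2_spectrum$mz - m) / m * 1e6 <= match_tolerance_ppm &
            ms2_spectrum$intensity > 0)
    }, logical(1)))
  }, logical(1))
  structure(list(proportions = props, residual_norm = resnorm,
                 indeterminate = indet, n_matched = n_matched),
            class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat("<DeconvolutionResult> proportions:",
      paste(sprintf("%.3f", x$proportions), collapse = " "),
      sprintf(" (residual %.3g)\n", x$residual_norm))
  invisible(x)
}

#' Relative abundances within a peptide family
#'
#' Splits each isobaric precursor area by its deconvolved mixing
#' proportions, then expresses every proteoform's share as a percentage of
#' the family total.
#'
#' @param group_areas Numeric vector of precursor peak areas, one per
#'   isobaric group (in catalog group order).
#' @param deconvolutions List (same length) of `DeconvolutionResult`s or
#'   NULL for singleton groups.
#' @param catalog The `ProteoformCatalog` the groups came from.
#' @param sample,replicate Identifiers stored in the output.
#' @return data.frame of class `AbundanceTable`: columns form, abundance
#'   (percent, sums to 100), sample, replicate, flag.
#' @export
relative_abundance <- function(group_areas, deconvolutions, catalog,
                               sample = "s1", replicate = 1L) {
  stopifnot(length(group_areas) == length(catalog$groups))
  rows <- list()
  for (g in seq_along(catalog$groups)) {
    members <- catalog$groups[[g]]$members
    k <- length(members)
    props <- if (k == 1) 1 else {
      dc <- deconvolutions[[g]]
      if (is.null(dc)) rep(1 / k, k) else dc$proportions
    }
    flag <- rep("ok", k)
    if (k > 1 && !is.null(deconvolutions[[g]])) {
      flag[deconvolutions[[g]]$indeterminate] <- "indeterminate"
    }
    rows[[g]] <- data.frame(
      form = catalog$forms$id[members],
      area = group_areas[g] * props,
      flag = flag
    )
  }
  out <- do.call(rbind, rows)
  total <- sum(out$area)
  if (total == 0) {
    warning("family total area is zero; family dropped")
    return(structure(out[0, c("form", "flag")], class = c("AbundanceTable",
                                                          "data.frame")))
  }
  out$abundance <- out$area / total * 100
  out$sample <- sample
  out$replicate <- replicate
  out <- out[, c("form", "abundance", "sample", "replicate", "flag")]
  rownames(out) <- NULL
  structure(out, class = c("AbundanceTable", "data.frame"))
}

#' Quantify a peak list against a proteoform catalog
#'
#' End-to-end quantification of one run: for every isobaric group, extract
#' the precursor XIC at the catalog charge state, integrate the peak around
#' the apex, deconvolve the nearest-in-retention-time MS2 scan (ties:
#' intensity-weighted mean of per-scan proportions), and convert to
#' family-relative abundances.
#'
#' @param pkl A `PeakList`.
#' @param catalog A `ProteoformCatalog`.
#' @param ppm_precursor MS1 extraction tolerance (ppm).
#' @param ppm_fragment MS2 match tolerance (ppm).
#' @param rt_halfwidth Integration half-window around the XIC apex (s),
#'   default 30 s.
#' @param sample,replicate Identifiers for the output table.
#' @return An `AbundanceTable`.
#' @export
quantify_peaklist <- function(pkl, catalog, ppm_precursor = 10,
                              ppm_fragment = 20, rt_halfwidth = 30,
                              sample = "s1", replicate = 1L) {
  ngroup <- length(catalog$groups)
  areas <- numeric(ngroup)
  decons <- vector("list", ngroup)
  ms2 <- Filter(function(s) s$level == 2, pkl$scans)
  ms2_rt <- vapply(ms2, function(s) s$rt, numeric(1))
  ms2_pmz <- vapply(ms2, function(s) s$precursor_mz, numeric(1))

  for (g in seq_len(ngroup)) {
    grp <- catalog$groups[[g]]
    target <- precursor_mz(grp$mass, catalog$charge)
    xic <- extract_xic(pkl, target, ppm_precursor)
    apex <- xic_apex(xic)
    areas[g] <- integrate_peak(xic, c(apex - rt_halfwidth,
                                      apex + rt_halfwidth))
    if (length(grp$members) > 1 && length(ms2)) {
      hit <- which(abs(ms2_pmz - target) / target * 1e6 <= ppm_precursor)
      if (length(hit)) {
        d <- abs(ms2_rt[hit] - apex)
        near <- hit[d <= min(d) + 1e-9]
        fits <- lapply(ms2[near], function(sc) {
          tryCatch(deconvolve_isobaric(sc, grp, ppm_fragment),
                   error = function(e) NULL)
        })
        fits <- Filter(Negate(is.null), fits)
        if (length(fits)) {
          w <- vapply(ms2[near][seq_along(fits)],
                      function(sc) sum(sc$intensity), numeric(1))
          P <- vapply(fits, function(f) f$proportions,
                      numeric(length(grp$members)))
          P <- matrix(P, nrow = length(grp$members))
          props <- as.numeric(P %*% (w / sum(w)))
          decons[[g]] <- structure(
            list(proportions = props / sum(props),
                 residual_norm = mean(vapply(fits, function(f)
                   f$residual_norm, numeric(1))),
                 indeterminate = Reduce(`&`, lapply(fits, function(f)
                   f$indeterminate)),
                 n_matched = max(vapply(fits, function(f) f$n_matched,
                                        numeric(1)))),
            class = "DeconvolutionResult")
        }
      }
    }
  }
  relative_abundance(areas, decons, catalog, sample, replicate)
}

#' Degree-of-acetylation summary for the H4 4-17 family
#'
#' Sums relative abundances over configurations with the same acetyl count,
#' yielding the un/mono/di/tri/tetra-acetyl partition.
#'
#' @param abundance An `AbundanceTable` for the 16 K5/K8/K12/K16 acetyl
#'   configurations (missing configurations count as 0, with a warning).
#' @return data.frame with columns n_acetyl (0..4), class (un/mono/di/tri/
#'   tetra), percent (sums to 100).
#' @export
degree_of_acetylation <- function(abundance) {
  nac <- acetyl_count(abundance$form)
  if (nrow(abundance) < 16) {
    warning("fewer than 16 acetyl configurations present; missing forms ",
            "treated as 0")
  }
  percent <- vapply(0:4, function(k) sum(abundance$abundance[nac == k]),
                    numeric(1))
  data.frame(
    n_acetyl = 0:4,
    class = c("un", "mono", "di", "tri", "tetra"),
    percent = percent
  )
}

#' Write an abundance table to TSV
#'
#' @param abundance An `AbundanceTable` (or rbind of several).
#' @param path Output file.
#' @export
write_abundance_tsv <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
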