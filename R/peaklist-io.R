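# Peak-list containers and readers.
#
# The canonical in-package representation is a `PeakList`: an ordered list of
# centroided scans.  Three on-disk dialects are read: a documented TSV
# dialect (the fixture format), MGF, and mzML (through mzR when installed).

#' Construct a peak list
#'
#' @param scans List of scans; each scan is a list with `rt` (seconds),
#'   `level` (1 or 2), `precursor_mz` (NA for MS1), `mz` and `intensity`
#'   (equal-length numeric vectors).
#' @return Object of class `PeakList`.
#' @export
peaklist <- function(scans) {
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  if (is.unsorted(rt)) stop("retention times must be non-decreasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("mz and intensity must have equal length")
    }
    if (any(s$intensity < 0)) stop("intensities must be >= 0")
  }
  structure(list(scans = scans), class = "PeakList")
}

#' @export
print.PeakList <- function(x, ...) {
  lv <- vapply(x$scans, function(s) s$level, numeric(1))
  cat(sprintf("<PeakList> %d scans (%d MS1, %d MS2)\n", length(x$scans),
              sum(lv == 1), sum(lv == 2)))
  invisible(x)
}

#' Read a peak list
#'
#' Dispatches on file extension: `.tsv`/`.txt` (the package's TSV dialect),
#' `.mgf`, or `.mzML` (requires the mzR package).
#'
#' @param path Input file.
#' @return A `PeakList`.
#' @export
read_peaklist <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = ,
    txt = read_peaklist_tsv(path),
    mgf = read_peaklist_mgf(path),
    mzml = read_peaklist_mzml(path),
    stop("unknown peak-list format: .", ext)
  )
}

#' Read the TSV peak-list dialect
#'
#' Tab-separated columns: `scan`, `rt` (s), `level` (1|2), `precursor_mz`
#' (empty or NA for MS1), `peaks` (space-separated `mz:intensity` pairs).
#'
#' @param path Input file.
#' @return A `PeakList`.
#' @export
read_peaklist_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(peaks = "character"))
  scans <- lapply(seq_len(nrow(df)), function(i) {
    pk <- strsplit(trimws(df$peaks[i]), "\\s+")[[1]]
    pk <- pk[nzchar(pk)]
    mzint <- if (length(pk)) {
      m <- do.call(rbind, strsplit(pk, ":", fixed = TRUE))
      cbind(as.numeric(m[, 1]), as.numeric(m[, 2]))
    } else matrix(numeric(0), ncol = 2)
    list(rt = df$rt[i], level = df$level[i],
         precursor_mz = suppressWarnings(as.numeric(df$precursor_mz[i])),
         mz = mzint[, 1], intensity = mzint[, 2])
  })
  peaklist(scans)
}

#' Write the TSV peak-list dialect
#'
#' @param pkl A `PeakList`.
#' @param path Output file.
#' @export
write_peaklist_tsv <- function(pkl, path) {
  df <- data.frame(
    scan = seq_along(pkl$scans),
    rt = vapply(pkl$scans, function(s) s$rt, numeric(1)),
    level = vapply(pkl$scans, function(s) s$level, numeric(1)),
    precursor_mz = vapply(pkl$scans, function(s) {
      if (is.null(s$precursor_mz) || is.na(s$precursor_mz)) NA_real_
      else s$precursor_mz
    }, numeric(1)),
    peaks = vapply(pkl$scans, function(s) {
      paste(sprintf("%.6f:%.4f", s$mz, s$intensity), collapse = " ")
    }, character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MGF peak list
#'
#' Minimal MGF reader: BEGIN IONS/END IONS blocks with PEPMASS, RTINSECONDS
#' and m/z-intensity lines are treated as MS2 scans; MGF carries no MS1
#' scans.
#'
#' @param path Input file.
#' @return A `PeakList`.
#' @export
read_peaklist_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced blocks")
  scans <- lapply(seq_along(begins), function(i) {
    blk <- lines[(begins[i] + 1):(ends[i] - 1)]
    kv <- grep("=", blk, fixed = TRUE, value = TRUE)
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (!length(hit)) return(NA_real_)
      as.numeric(strsplit(sub(paste0("^", key, "="), "", hit[1]), "\\s+")[[1]][1])
    }
    pk <- grep("^[0-9]", blk, value = TRUE)
    mzint <- if (length(pk)) {
      m <- do.call(rbind, strsplit(trimws(pk), "\\s+"))
      cbind(as.numeric(m[, 1]), as.numeric(m[, 2]))
    } else matrix(numeric(0), ncol = 2)
    list(rt = get("RTINSECONDS"), level = 2, precursor_mz = get("PEPMASS"),
         mz = mzint[, 1], intensity = mzint[, 2])
  })
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  if (!any(is.na(rt))) scans <- scans[order(rt)]
  peaklist(scans)
}

#' Read an mzML peak list (via mzR)
#'
#' @param path Input mzML file (centroided).
#' @return A `PeakList`.
#' @export
read_peaklist_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  scans <- lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(ms, i)
    list(rt = h$retentionTime[i], level = h$msLevel[i],
         precursor_mz = if (h$msLevel[i] > 1) h$precursorMZ[i] else NA_real_,
         mz = pk[, 1], intensity = pk[, 2])
  })
  peaklist(scans)
}
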