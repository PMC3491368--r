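# Propionylation/trypsin chemistry of histone tails and proteoform
# enumeration.
#
# Chemistry model (two-round propionylation): free lysine epsilon-amines are
# propionylated at the protein level, which blocks tryptic cleavage at K, so
# trypsin cuts C-terminal to arginine only.  After digestion the new peptide
# N-termini are propionylated in a second round, so every tryptic peptide
# carries an N-terminal propionyl group.  Mono-methylated lysines retain a
# free amine and are propionylated; di-/tri-methylated and acetylated lysines
# are not.  The propionyl reagent is either light (d0) or heavy (d5); the
# channel applies to all propionyl groups on a peptide, N-terminus included.

#' Built-in histone reference sequences
#'
#' Mature human histone H3.1 and H4 sequences (initiator methionine removed,
#' so residue numbering matches the conventional PTM nomenclature, e.g. H4K16
#' is the K at position 16).
#'
#' @param protein "H3" or "H4".
#' @return Amino-acid string.
#' @export
histone_sequence <- function(protein = c("H4", "H3")) {
  protein <- match.arg(protein)
  path <- system.file("extdata", "histones_human.fasta",
                      package = "readerscope")
  lines <- readLines(path)
  headers <- grep("^>", lines)
  starts <- headers + 1
  ends <- c(headers[-1] - 1, length(lines))
  names <- sub("^>(\\S+).*", "\\1", lines[headers])
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- names
  unname(seqs[[protein]])
}

#' Digest a protein with trypsin under lysine-blocking propionylation
#'
#' Cleavage occurs C-terminal to arginine only (propionylated lysines are not
#' cleaved).  Spans for 0 up to `max_missed_cleavages` missed cleavages are
#' returned with 1-based inclusive protein coordinates.
#'
#' @param protein_sequence Uppercase amino-acid string.
#' @param max_missed_cleavages Non-negative integer.
#' @return data.frame with columns start, end, sequence, missed_cleavages.
#' @examples
#' digest_protein(substr(histone_sequence("H4"), 1, 20))
#' @export
digest_protein <- function(protein_sequence, max_missed_cleavages = 0) {
  aa <- strsplit(protein_sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("non-amino-acid character(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(aa)
  cut_after <- which(aa == "R")
  boundaries <- unique(c(cut_after, n))      # peptide end positions
  starts <- c(1L, head(boundaries, -1L) + 1L)
  starts <- starts[starts <= n]
  ends <- boundaries
  base <- data.frame(start = starts, end = ends)

  out <- list()
  for (mc in 0:max_missed_cleavages) {
    k <- nrow(base) - mc
    if (k < 1) break
    idx <- seq_len(k)
    out[[mc + 1]] <- data.frame(
      start = base$start[idx],
      end = base$end[idx + mc],
      missed_cleavages = mc
    )
  }
  res <- do.call(rbind, out)
  res$sequence <- substring(protein_sequence, res$start, res$end)
  res <- res[order(res$start, res$end), c("start", "end", "sequence",
                                          "missed_cleavages")]
  rownames(res) <- NULL
  res
}

#' Construct a fully assigned proteoform
#'
#' @param protein Protein name ("H3" or "H4" for the built-ins; free text
#'   otherwise).
#' @param start,end 1-based inclusive residue span on the protein.
#' @param sequence Peptide amino-acid string (length must equal the span).
#' @param mods Named character vector: one entry per lysine, names like
#'   `"K5"` (protein coordinates), values in `unmod`, `me1`, `me2`, `me3`,
#'   `ac`.
#' @param channel `"d0"` or `"d5"` propionyl label channel.
#' @return Object of class `Proteoform`.
#' @export
proteoform <- function(protein, start, end, sequence, mods = character(),
                       channel = c("d0", "d5")) {
  channel <- match.arg(channel)
  if (nchar(sequence) != end - start + 1) {
    stop("residue span length must equal sequence length")
  }
  aa <- strsplit(sequence, "")[[1]]
  k_sites <- start - 1L + which(aa == "K")
  want <- paste0("K", k_sites)
  if (!setequal(names(mods), want)) {
    stop("mods must name exactly the lysines in the span: ",
         paste(want, collapse = ", "))
  }
  mods <- mods[want]
  ok <- mods %in% c("unmod", "me1", "me2", "me3", "ac")
  if (!all(ok)) stop("unknown modification kind: ", mods[!ok][1])
  structure(
    list(protein = protein, start = start, end = end, sequence = sequence,
         mods = mods, channel = channel, n_terminal_propionyl = TRUE),
    class = "Proteoform"
  )
}

#' @export
print.Proteoform <- function(x, ...) {
  cat(sprintf("<Proteoform> %s %d-%d %s [%s] %s\n", x$protein, x$start,
              x$end, x$sequence, mod_string(x), x$channel))
  invisible(x)
}

# lysines that carry a propionyl group after derivatization
.propionylated_sites <- function(pf) {
  names(pf$mods)[pf$mods %in% c("unmod", "me1")]
}

#' Compact modification string of a proteoform
#'
#' Unmodified (hence propionylated) lysines print as `prop`, e.g.
#' `"K5ac-K8prop-K12ac-K16prop"`.
#'
#' @param pf A `Proteoform`.
#' @return Character scalar.
#' @export
mod_string <- function(pf) {
  lab <- ifelse(pf$mods == "unmod", "prop", pf$mods)
  if (!length(lab)) return("")
  paste0(names(pf$mods), lab, collapse = "-")
}

#' Enumerate candidate proteoforms over a peptide span
#'
#' Takes the Cartesian product of the allowed modification kinds per lysine
#' site; every combination is returned as a fully assigned proteoform with
#' the propionyl placement rules applied.
#'
#' @param protein,start,end,sequence As in [proteoform()].
#' @param allowed Named list, one entry per lysine (names like `"K5"`), each
#'   a character vector of allowed kinds.
#' @param channel Label channel for all enumerated forms.
#' @return List of `Proteoform` objects (length = product of choices).
#' @export
enumerate_proteoforms <- function(protein, start, end, sequence, allowed,
                                  channel = "d0") {
  aa <- strsplit(sequence, "")[[1]]
  k_sites <- paste0("K", start - 1L + which(aa == "K"))
  if (!setequal(names(allowed), k_sites)) {
    stop("allowed must cover exactly the lysines in the span: ",
         paste(k_sites, collapse = ", "))
  }
  if (any(!lengths(allowed))) stop("allowed set per site must be non-empty")
  allowed <- allowed[k_sites]
  grid <- expand.grid(allowed, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    mods <- as.character(grid[i, , drop = TRUE])
    names(mods) <- k_sites
    proteoform(protein, start, end, sequence, mods, channel)
  })
}

# per-site modification delta incl. propionyl labeling, in peptide order
.site_deltas <- function(pf) {
  prop_kind <- if (pf$channel == "d5") "propionyl-d5" else "propionyl-d0"
  vapply(seq_along(pf$mods), function(i) {
    kind <- pf$mods[[i]]
    d <- MOD_MASS[[kind]]
    if (kind %in% c("unmod", "me1")) d <- d + MOD_MASS[[prop_kind]]
    d
  }, numeric(1))
}

#' Monoisotopic mass of a proteoform
#'
#' Residue masses + water + all modification deltas, including the
#' N-terminal propionyl and side-chain propionyl groups in the proteoform's
#' label channel.
#'
#' @param pf A `Proteoform`.
#' @return Neutral monoisotopic mass (Da).
#' @export
monoisotopic_mass <- function(pf) {
  stopifnot(inherits(pf, "Proteoform"))
  prop_kind <- if (pf$channel == "d5") "propionyl-d5" else "propionyl-d0"
  m <- peptide_mass(pf$sequence) + sum(.site_deltas(pf))
  if (pf$n_terminal_propionyl) m <- m + MOD_MASS[[prop_kind]]
  m
}

#' Theoretical b/y fragment ions of a proteoform
#'
#' Enumerates b1..b(n-1) and y1..y(n-1) for every charge up to
#' `max_fragment_charge`.  Modification deltas (including propionyl labels)
#' are apportioned to the fragments containing the modified site; the
#' N-terminal propionyl travels with the b series.
#'
#' @param pf A `Proteoform`.
#' @param max_fragment_charge Maximum fragment charge (default 1).
#' @return data.frame of class `FragmentPattern` with columns series,
#'   ordinal, charge, mz.
#' @export
fragment_ions <- function(pf, max_fragment_charge = 1) {
  stopifnot(inherits(pf, "Proteoform"))
  aa <- strsplit(pf$sequence, "")[[1]]
  n <- length(aa)
  res <- RESIDUE_MASS[aa]
  delta <- numeric(n)
  k_idx <- as.integer(sub("^K", "", names(pf$mods))) - pf$start + 1L
  delta[k_idx] <- .site_deltas(pf)
  prop_kind <- if (pf$channel == "d5") "propionyl-d5" else "propionyl-d0"
  nterm <- if (pf$n_terminal_propionyl) MOD_MASS[[prop_kind]] else 0

  cum <- cumsum(res + delta)
  b_neutral <- nterm + cum[seq_len(n - 1)]          # residue sum, no water
  y_neutral <- cum[n] - cum[seq_len(n - 1)] + WATER_MASS
  y_neutral <- rev(y_neutral)                       # y1 = C-terminal residue

  rows <- list()
  for (z in seq_len(max_fragment_charge)) {
    rows[[length(rows) + 1L]] <- data.frame(
      series = "b", ordinal = seq_len(n - 1), charge = z,
      mz = (b_neutral + z * PROTON_MASS) / z
    )
    rows[[length(rows) + 1L]] <- data.frame(
      series = "y", ordinal = seq_len(n - 1), charge = z,
      mz = (y_neutral + z * PROTON_MASS) / z
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("FragmentPattern", class(out))
  attr(out, "proteoform") <- pf
  out
}

#' Group proteoforms that are isobaric at a mass tolerance
#'
#' Partitions proteoforms sharing a peptide sequence into groups whose
#' pairwise monoisotopic mass deviation is within `mass_tolerance_ppm`.
#' For each member the site-determining fragment m/z values (singly charged
#' b/y ions not shared with any other group member at the same tolerance)
#' are recorded: these are the ions that distinguish positional isomers.
#'
#' @param proteoforms List of `Proteoform` objects with a common sequence.
#' @param mass_tolerance_ppm Grouping tolerance, default 10 ppm.
#' @return List of groups; each group is a list with `members` (indices into
#'   the input), `mass` (mean group mass), `proteoforms`,
#'   `site_determining` (list of numeric m/z vectors per member).
#' @export
isobaric_groups <- function(proteoforms, mass_tolerance_ppm = 10) {
  if (!length(proteoforms)) return(list())
  seqs <- vapply(proteoforms, function(p) p$sequence, character(1))
  if (length(unique(seqs)) != 1) {
    stop("all proteoforms must share the peptide sequence")
  }
  masses <- vapply(proteoforms, monoisotopic_mass, numeric(1))
  ord <- order(masses)
  groups <- list()
  cur <- ord[1]
  for (i in ord[-1]) {
    # complete linkage: new member must sit within tolerance of the group's
    # lightest member, so pairwise deviation stays bounded
    if ((masses[i] - masses[cur[1]]) / masses[cur[1]] * 1e6 <=
        mass_tolerance_ppm) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
    }
  }
  groups[[length(groups) + 1L]] <- cur

  lapply(groups, function(idx) {
    frags <- lapply(proteoforms[idx], function(p) fragment_ions(p, 1)$mz)
    site_det <- lapply(seq_along(idx), function(j) {
      mine <- frags[[j]]
      others <- unlist(frags[-j])
      if (!length(others)) return(mine)
      keep <- vapply(mine, function(m) {
        !any(abs(others - m) / m * 1e6 <= mass_tolerance_ppm)
      }, logical(1))
      mine[keep]
    })
    list(members = idx, mass = mean(masses[idx]),
         proteoforms = proteoforms[idx], site_determining = site_det)
  })
}

#' Build a proteoform catalog with isobaric grouping
#'
#' The catalog is the hand-off from the chemistry layer to quantification:
#' a table of forms with neutral masses and precursor m/z plus the isobaric
#' group structure at the stated tolerance.
#'
#' @param proteoforms List of `Proteoform`s sharing a peptide sequence.
#' @param charge Precursor charge state used for XIC extraction.
#' @param mass_tolerance_ppm Isobaric grouping tolerance (ppm).
#' @return List of class `ProteoformCatalog` with elements `forms`
#'   (data.frame: id, protein, start, end, sequence, mods, channel, mass,
#'   mz, group), `proteoforms`, `groups`, `charge`.
#' @export
build_catalog <- function(proteoforms, charge = 2, mass_tolerance_ppm = 10) {
  groups <- isobaric_groups(proteoforms, mass_tolerance_ppm)
  masses <- vapply(proteoforms, monoisotopic_mass, numeric(1))
  group_of <- integer(length(proteoforms))
  for (g in seq_along(groups)) group_of[groups[[g]]$members] <- g
  forms <- data.frame(
    id = vapply(proteoforms, function(p) {
      paste0(p$protein, p$start, "-", p$end, ":", mod_string(p), ":",
             p$channel)
    }, character(1)),
    protein = vapply(proteoforms, function(p) p$protein, character(1)),
    start = vapply(proteoforms, function(p) p$start, numeric(1)),
    end = vapply(proteoforms, function(p) p$end, numeric(1)),
    sequence = vapply(proteoforms, function(p) p$sequence, character(1)),
    mods = vapply(proteoforms, mod_string, character(1)),
    channel = vapply(proteoforms, function(p) p$channel, character(1)),
    mass = masses,
    mz = precursor_mz(masses, charge),
    group = group_of
  )
  structure(list(forms = forms, proteoforms = proteoforms, groups = groups,
                 charge = charge),
            class = "ProteoformCatalog")
}

#' @export
print.ProteoformCatalog <- function(x, ...) {
  cat(sprintf("<ProteoformCatalog> %d forms, %d isobaric groups, charge %d\n",
              nrow(x$forms), length(x$groups), x$charge))
  invisible(x)
}

#' Write a proteoform catalog to TSV
#'
#' @param catalog A `ProteoformCatalog`.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$forms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The 16 acetyl configurations of the H4 4-17 tail peptide
#'
#' Convenience constructor for the canonical H4 GKGGKGLGKGGAKR peptide
#' (residues 4-17) with every acetyl/propionyl combination of K5, K8, K12
#' and K16.
#'
#' @param channel Label channel.
#' @return List of 16 `Proteoform`s ordered by acetyl count then site.
#' @export
h4_acetyl_proteoforms <- function(channel = "d0") {
  seq4_17 <- substr(histone_sequence("H4"), 4, 17)
  pfs <- enumerate_proteoforms(
    "H4", 4, 17, seq4_17,
    allowed = list(K5 = c("unmod", "ac"), K8 = c("unmod", "ac"),
                   K12 = c("unmod", "ac"), K16 = c("unmod", "ac")),
    channel = channel
  )
  nac <- vapply(pfs, function(p) sum(p$mods == "ac"), numeric(1))
  pfs[order(nac)]
}

#' Number of acetyl groups on a proteoform or mods string
#'
#' @param x A `Proteoform` or a mods string such as
#'   `"K5ac-K8prop-K12ac-K16prop"`.
#' @return Integer acetyl count.
#' @export
acetyl_count <- function(x) {
  if (inherits(x, "Proteoform")) return(sum(x$mods == "ac"))
  lengths(regmatches(x, gregexpr("(?<=[0-9])ac", x, perl = TRUE)))
}
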