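# Ground-truthed synthetic LC-MS/MS spectra: co-eluting isobaric modified
# peptides with Gaussian elution profiles, fragment intensities
# proportional to the planted mixing pattern, and multiplicative
# log-normal noise.  Every generator is a pure function of
# (scenario, seed).

#' Define a spectra-simulation scenario
#'
#' @param catalog A `ProteoformCatalog`.
#' @param truth Named numeric vector of true relative abundances (%), one
#'   per catalog form id, summing to 100.
#' @param rt_apex Optional numeric vector of apex retention times (s), one
#'   per isobaric group; default 120 s spacing from 180 s.
#' @param rt_sigma Gaussian elution width (s), default 6.
#' @param noise_sigma Multiplicative log-normal sigma, default 0.05
#'   (signal-to-noise ~ 20).
#' @param baseline Additive baseline intensity per peak, default 0.
#' @param channel_design `"labelfree"` (d0 only) or `"paired"` (the truth
#'   sample in d0 plus an `input_truth` in d5).
#' @param input_truth Second abundance vector (%) for the d5 channel in
#'   paired mode.
#' @param ms1_interval MS1 scan spacing (s), default 2.
#' @param n_ms2 MS2 scans per multi-member group near the apex, default 3.
#' @param base_intensity Total MS1 intensity scale, default 1e6.
#' @param seed RNG seed.
#' @return List of class `SpectraScenario`.
#' @export
spectra_scenario <- function(catalog, truth, rt_apex = NULL, rt_sigma = 6,
                             noise_sigma = 0.05, baseline = 0,
                             channel_design = c("labelfree", "paired"),
                             input_truth = NULL, ms1_interval = 2,
                             n_ms2 = 3, base_intensity = 1e6, seed = 1) {
  channel_design <- match.arg(channel_design)
  ids <- catalog$forms$id
  if (!setequal(names(truth), ids)) {
    stop("truth must name every catalog form id")
  }
  truth <- truth[ids]
  if (abs(sum(truth) - 100) > 1e-6) stop("abundances must sum to 100")
  ngroup <- length(catalog$groups)
  if (is.null(rt_apex)) rt_apex <- 180 + 120 * (seq_len(ngroup) - 1)
  stopifnot(length(rt_apex) == ngroup)
  if (channel_design == "paired") {
    if (is.null(input_truth)) stop("paired mode needs input_truth")
    input_truth <- input_truth[ids]
    if (abs(sum(input_truth) - 100) > 1e-6) {
      stop("abundances must sum to 100")
    }
  }
  structure(list(catalog = catalog, truth = truth, rt_apex = rt_apex,
                 rt_sigma = rt_sigma, noise_sigma = noise_sigma,
                 baseline = baseline, channel_design = channel_design,
                 input_truth = input_truth, ms1_interval = ms1_interval,
                 n_ms2 = n_ms2, base_intensity = base_intensity,
                 seed = seed),
            class = "SpectraScenario")
}

# multiplicative log-normal noise, expectation-preserving
.lnoise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  x * stats::rlnorm(length(x), meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a peak list from a spectra scenario
#'
#' MS1 scans sample every isobaric group's Gaussian elution at its
#' precursor m/z (per channel in paired mode, with the d5 channel shifted
#' by its propionyl-label mass); MS2 scans near each group's apex mix the
#' member fragment templates in proportion to the planted within-group
#' abundances.
#'
#' @param scenario A `SpectraScenario`.
#' @return List: `peaklist` (a `PeakList`) and `truth` (data.frame form,
#'   abundance, channel).
#' @export
simulate_spectra <- function(scenario) {
  set.seed(scenario$seed)
  cat <- scenario$catalog
  ngroup <- length(cat$groups)
  charge <- cat$charge
  rt_grid <- seq(0, max(scenario$rt_apex) + 60,
                 by = scenario$ms1_interval)

  channels <- if (scenario$channel_design == "paired") c("d0", "d5") else
    "d0"
  # per channel: group m/z and group total abundance
  ch_info <- lapply(channels, function(ch) {
    truth <- if (ch == "d0") scenario$truth else scenario$input_truth
    gmz <- vapply(seq_len(ngroup), function(g) {
      grp <- cat$groups[[g]]
      mass <- grp$mass
      if (ch == "d5") {
        # relabel every propionyl group (side chains + N-terminus)
        pf <- grp$proteoforms[[1]]
        nprop <- length(.propionylated_sites(pf)) + 1
        mass <- mass + nprop * (MOD_MASS[["propionyl-d5"]] -
                                  MOD_MASS[["propionyl-d0"]])
      }
      precursor_mz(mass, charge)
    }, numeric(1))
    gtot <- vapply(cat$groups, function(grp) {
      sum(truth[cat$forms$id[grp$members]])
    }, numeric(1))
    list(truth = truth, gmz = gmz, gtot = gtot)
  })
  names(ch_info) <- channels

  scans <- list()
  for (rt in rt_grid) {
    mz <- numeric(0); inten <- numeric(0)
    for (ch in channels) {
      info <- ch_info[[ch]]
      amp <- info$gtot / 100 * scenario$base_intensity *
        exp(-(rt - scenario$rt_apex)^2 / (2 * scenario$rt_sigma^2))
      keep <- amp > scenario$base_intensity * 1e-6
      if (any(keep)) {
        mz <- c(mz, info$gmz[keep])
        inten <- c(inten, .lnoise(amp[keep], scenario$noise_sigma) +
                     scenario$baseline)
      }
    }
    scans[[length(scans) + 1]] <- list(rt = rt, level = 1,
                                       precursor_mz = NA_real_,
                                       mz = mz, intensity = inten)
  }

  # MS2 scans at the apex of each multi-member group (d0 channel carries
  # the deconvolution information; the paired d5 input is assumed to share
  # isomer proportions only through its own MS2 scans, generated too)
  ms2 <- list()
  for (ch in channels) {
    info <- ch_info[[ch]]
    for (g in seq_len(ngroup)) {
      grp <- cat$groups[[g]]
      if (length(grp$members) < 2) next
      frac <- info$truth[cat$forms$id[grp$members]]
      if (sum(frac) == 0) next
      frac <- frac / sum(frac)
      grp_ch <- grp
      if (ch != "d0") {
        grp_ch$proteoforms <- lapply(grp$proteoforms, function(p) {
          p$channel <- ch
          p
        })
      }
      tpl <- .group_templates(grp_ch, match_tolerance_ppm = 1e-3)
      base <- as.numeric(tpl$A %*% frac) * scenario$base_intensity / 10
      for (k in seq_len(scenario$n_ms2)) {
        rt <- scenario$rt_apex[g] + (k - (scenario$n_ms2 + 1) / 2) *
          scenario$ms1_interval / 2
        ms2[[length(ms2) + 1]] <- list(
          rt = rt, level = 2, precursor_mz = info$gmz[g],
          mz = tpl$slots,
          intensity = .lnoise(base, scenario$noise_sigma) +
            scenario$baseline
        )
      }
    }
  }
  all_scans <- c(scans, ms2)
  rts <- vapply(all_scans, function(s) s$rt, numeric(1))
  pkl <- peaklist(all_scans[order(rts)])
  truth_tab <- do.call(rbind, lapply(channels, function(ch) {
    data.frame(form = cat$forms$id,
               abundance = unname(ch_info[[ch]]$truth), channel = ch)
  }))
  list(peaklist = pkl, truth = truth_tab)
}

#' Write a simulated spectra fixture to disk
#'
#' Writes the TSV peak list plus a `truth_abundance.tsv` table.
#'
#' @param sim Result of [simulate_spectra()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_spectra_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peaklist_tsv(sim$peaklist, file.path(dir, "spectra.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' A degree-of-acetylation truth vector over the 16 H4 configurations
#'
#' Distributes class totals (un/mono/di/tri/tetra percentages summing to
#' 100) uniformly over the configurations with that acetyl count, yielding
#' a valid truth vector for [spectra_scenario()] with
#' [h4_acetyl_proteoforms()] catalogs.
#'
#' @param class_percent Numeric length-5 (un, mono, di, tri, tetra).
#' @param catalog Catalog built from [h4_acetyl_proteoforms()].
#' @return Named truth vector (%).
#' @export
h4_truth_from_doa <- function(class_percent, catalog) {
  stopifnot(length(class_percent) == 5,
            abs(sum(class_percent) - 100) < 1e-6)
  nac <- acetyl_count(catalog$forms$mods)
  counts <- choose(4, 0:4)
  truth <- class_percent[nac + 1] / counts[nac + 1]
  stats::setNames(truth, catalog$forms$id)
}
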