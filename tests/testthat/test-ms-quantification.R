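make_ms1 <- function(rt, mz, intensity) {
  list(rt = rt, level = 1, precursor_mz = NA_real_, mz = mz,
       intensity = intensity)
}

test_that("XIC extraction applies the ppm window per scan", {
  pkl <- peaklist(list(
    make_ms1(0, c(500.004, 500.006), c(10, 20)),
    make_ms1(1, c(499.996, 500.0049), c(5, 7)),
    make_ms1(2, numeric(0), numeric(0))
  ))
  x <- extract_xic(pkl, 500, 10)       # 10 ppm of 500 = 0.005
  expect_equal(x$intensity, c(10, 12, 0))
  expect_error(extract_xic(pkl, 500, 0), "ppm")

  # two in-window peaks in one scan sum
  pkl2 <- peaklist(list(make_ms1(0, c(500.001, 499.999), c(3, 4))))
  expect_equal(extract_xic(pkl2, 500, 10)$intensity, 7)
})

test_that("peak integration is a trapezoidal rule with linear scaling", {
  x <- structure(data.frame(rt = 0:3, intensity = c(0, 10, 10, 0)),
                 class = c("XIC", "data.frame"))
  expect_equal(integrate_peak(x, c(0, 3)), 20)
  x2 <- x; x2$intensity <- 2 * x$intensity
  expect_equal(integrate_peak(x2, c(0, 3)), 40)
  x0 <- x; x0$intensity <- rep(0, 4)
  expect_equal(integrate_peak(x0, c(0, 3)), 0)
  expect_warning(a <- integrate_peak(x, c(10, 11)), "empty")
  expect_equal(a, 0)
})

test_that("channel pairing handles zero denominators explicitly", {
  expect_equal(pair_channels(1000, 500)$ratio, 2)
  expect_equal(pair_channels(500, 500)$ratio, 1)
  z <- pair_channels(10, 0)
  expect_equal(z$ratio, Inf)
  expect_equal(z$flag, "zero_denominator")
  expect_equal(pair_channels(0, 0)$flag, "missing")
})

test_that("NNLS deconvolution recovers noiseless mixtures exactly", {
  pfs <- h4_acetyl_proteoforms()
  nac <- vapply(pfs, acetyl_count, numeric(1))
  grp <- isobaric_groups(pfs[nac == 1], 10)[[1]]
  tpl <- readerscope:::.group_templates(grp, 1e-3)

  # synthetic 0.7/0.3 two-member mixture of members 1 and 2
  mix <- 0.7 * tpl$A[, 1] + 0.3 * tpl$A[, 2]
  sub <- list(members = grp$members[1:2], mass = grp$mass,
              proteoforms = grp$proteoforms[1:2],
              site_determining = grp$site_determining[1:2])
  dc <- deconvolve_isobaric(list(mz = tpl$slots, intensity = mix), sub, 20)
  expect_equal(dc$proportions, c(0.7, 0.3), tolerance = 1e-6)
  expect_false(any(dc$indeterminate))

  # pure single isomer
  pure <- deconvolve_isobaric(list(mz = tpl$slots, intensity = tpl$A[, 3]),
                              grp, 20)
  expect_equal(pure$proportions[3], 1, tolerance = 1e-8)
  expect_equal(sum(pure$proportions[-3]), 0, tolerance = 1e-8)

  # scale invariance
  sc <- deconvolve_isobaric(list(mz = tpl$slots, intensity = 1e4 * mix),
                            sub, 20)
  expect_equal(sc$proportions, dc$proportions, tolerance = 1e-10)

  # nothing matched -> identification failure
  expect_error(
    deconvolve_isobaric(list(mz = 1e5, intensity = 1), grp, 20),
    "no fragment")
})

test_that("NNLS agrees with the exhaustive simplex grid oracle under noise", {
  set.seed(41)
  pfs <- h4_acetyl_proteoforms()
  nac <- vapply(pfs, acetyl_count, numeric(1))
  di <- isobaric_groups(pfs[nac == 2], 10)[[1]]
  for (rep in 1:10) {
    k <- sample(2:3, 1)
    sel <- sort(sample(6, k))
    grp <- list(members = di$members[sel], mass = di$mass,
                proteoforms = di$proteoforms[sel],
                site_determining = di$site_determining[sel])
    tpl <- readerscope:::.group_templates(grp, 1e-3)
    truth <- as.numeric(stats::rgamma(k, 2)); truth <- truth / sum(truth)
    obs <- as.numeric(tpl$A %*% truth) *
      rlnorm(nrow(tpl$A), 0, 0.05)
    dc <- deconvolve_isobaric(list(mz = tpl$slots, intensity = obs), grp,
                              20)
    gx <- oracle_grid_search(tpl$A, obs)
    expect_lt(max(abs(dc$proportions - gx)), 0.005)
  }
})

test_that("relative abundances normalize to 100 and split isobaric areas", {
  cat2 <- build_catalog(h4_acetyl_proteoforms(), 2)
  # construct areas: all mass on two groups
  areas <- c(300, 100, 0, 0, 0)
  expect_warning(
    ab0 <- relative_abundance(rep(0, 5), vector("list", 5), cat2),
    "zero")
  expect_equal(nrow(ab0), 0)

  dc <- vector("list", 5)
  ab <- relative_abundance(areas, dc, cat2)
  expect_equal(sum(ab$abundance), 100, tolerance = 1e-9)
  # first group (tetra-acetyl, lightest) is a singleton: 300/400
  g1_form <- cat2$forms$id[cat2$groups[[1]]$members]
  expect_equal(ab$abundance[ab$form == g1_form], 75)

  # isobaric pair split 0.5/0.5 plus a distinct form
  pfs <- h4_acetyl_proteoforms()
  nac <- vapply(pfs, acetyl_count, numeric(1))
  mini <- build_catalog(c(pfs[nac == 0], pfs[which(nac == 1)[1:2]]), 2)
  expect_length(mini$groups, 2)
  pair_g <- which(vapply(mini$groups, function(g) length(g$members),
                         numeric(1)) == 2)
  dc2 <- vector("list", 2)
  dc2[[pair_g]] <- structure(list(proportions = c(0.5, 0.5),
                                  residual_norm = 0,
                                  indeterminate = c(FALSE, FALSE),
                                  n_matched = 10),
                             class = "DeconvolutionResult")
  areas2 <- ifelse(seq_len(2) == pair_g, 400, 200)
  ab2 <- relative_abundance(areas2, dc2, mini)
  expect_equal(sort(ab2$abundance), c(100, 100, 100) / 3,
               tolerance = 1e-9)
})

test_that("degree-of-acetylation totals follow the binomial configuration counts", {
  cat2 <- build_catalog(h4_acetyl_proteoforms(), 2)
  # uniform 6.25% over all 16 configurations
  ab <- data.frame(form = cat2$forms$id, abundance = rep(100 / 16, 16))
  doa <- degree_of_acetylation(ab)
  expect_equal(doa$percent, c(6.25, 25, 37.5, 25, 6.25))
  expect_equal(sum(doa$percent), 100)

  # all abundance on the tetra form
  tetra <- cat2$forms$id[acetyl_count(cat2$forms$mods) == 4]
  ab2 <- data.frame(form = cat2$forms$id,
                    abundance = ifelse(cat2$forms$id == tetra, 100, 0))
  expect_equal(degree_of_acetylation(ab2)$percent, c(0, 0, 0, 0, 100))

  expect_warning(degree_of_acetylation(ab2[1:10, ]), "16")
})

test_that("simulated runs are re-quantified within 2 points per acetyl class", {
  cat2 <- build_catalog(h4_acetyl_proteoforms(), 2)
  truth_doa <- c(50, 30.5, 12, 7, 0.5)
  truth <- h4_truth_from_doa(truth_doa, cat2)
  errs <- vapply(1:5, function(s) {
    sim <- simulate_spectra(spectra_scenario(cat2, truth,
                                             noise_sigma = 0.05,
                                             seed = 100 + s))
    doa <- degree_of_acetylation(quantify_peaklist(sim$peaklist, cat2))
    max(abs(doa$percent - truth_doa))
  }, numeric(1))
  expect_lt(max(errs), 2)

  # permutation invariance of the relative-abundance layer: quantify with
  # a catalog built from a permuted proteoform list
  set.seed(9)
  perm <- sample(16)
  cat_p <- build_catalog(h4_acetyl_proteoforms()[perm], 2)
  sim <- simulate_spectra(spectra_scenario(cat2, truth, noise_sigma = 0,
                                           seed = 5))
  ab_a <- quantify_peaklist(sim$peaklist, cat2)
  ab_b <- quantify_peaklist(sim$peaklist, cat_p)
  m <- merge(ab_a, ab_b, by = "form")
  expect_equal(m$abundance.x, m$abundance.y, tolerance = 1e-6)
})

test_that("peak-list TSV and MGF readers round-trip scans", {
  pkl <- peaklist(list(
    make_ms1(1, c(400.1, 500.2), c(10, 20)),
    list(rt = 2, level = 2, precursor_mz = 500.2,
         mz = c(200.05, 300.07), intensity = c(5, 9))
  ))
  tmp <- tempfile(fileext = ".tsv")
  write_peaklist_tsv(pkl, tmp)
  rt <- read_peaklist(tmp)
  expect_equal(length(rt$scans), 2)
  expect_equal(rt$scans[[1]]$mz, pkl$scans[[1]]$mz, tolerance = 1e-6)
  expect_equal(rt$scans[[2]]$precursor_mz, 500.2)

  mgf <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan1", "PEPMASS=500.2 1000",
               "RTINSECONDS=2", "CHARGE=2+", "200.05 5", "300.07 9",
               "END IONS"), mgf)
  pm <- read_peaklist(mgf)
  expect_equal(pm$scans[[1]]$precursor_mz, 500.2)
  expect_equal(pm$scans[[1]]$intensity, c(5, 9))
})
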