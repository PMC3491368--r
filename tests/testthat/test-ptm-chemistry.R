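test_that("tryptic digestion under lysine-blocking propionylation cleaves after R only", {
  h4_n <- substr(histone_sequence("H4"), 1, 20)
  d <- digest_protein(h4_n)
  expect_true(any(d$start == 4 & d$end == 17 &
                    d$sequence == "GKGGKGLGKGGAKR"))
  # no internal R in 0-missed-cleavage peptides
  expect_false(any(grepl("R.", d$sequence[d$missed_cleavages == 0])))

  # no cleavage site at all -> single whole-input peptide
  d2 <- digest_protein("GKGAKG")
  expect_equal(nrow(d2), 1)
  expect_equal(c(d2$start, d2$end), c(1, 6))

  # missed cleavages enumerate merged spans
  d3 <- digest_protein("GKRAKR", max_missed_cleavages = 1)
  expect_setequal(paste(d3$start, d3$end), c("1 3", "4 6", "1 6"))

  expect_error(digest_protein("GKXR"), "non-amino-acid")
})

test_that("digestion at 0 missed cleavages partitions the protein", {
  for (prot in c("H3", "H4")) {
    s <- histone_sequence(prot)
    d <- digest_protein(s)
    expect_equal(paste(d$sequence, collapse = ""), s)
    expect_equal(d$start[-1], head(d$end, -1) + 1)
  }
})

test_that("proteoform enumeration sizes equal the product of per-site choices", {
  seq4_17 <- substr(histone_sequence("H4"), 4, 17)
  pfs <- enumerate_proteoforms(
    "H4", 4, 17, seq4_17,
    allowed = list(K5 = c("unmod", "ac"), K8 = c("unmod", "ac"),
                   K12 = c("unmod", "ac"), K16 = c("unmod", "ac")))
  expect_length(pfs, 16)
  nac <- vapply(pfs, acetyl_count, numeric(1))
  expect_equal(sum(nac == 2), choose(4, 2))  # six diacetyl isomers

  pfs1 <- enumerate_proteoforms("H3", 9, 17, "KSTGGKAPR",
                                allowed = list(K9 = c("me1", "me2", "me3"),
                                               K14 = "unmod"))
  expect_length(pfs1, 3)
  expect_error(
    enumerate_proteoforms("H3", 9, 17, "KSTGGKAPR",
                          allowed = list(K4 = "ac", K14 = "unmod")),
    "exactly the lysines")
})

test_that("monoisotopic masses match the residue-summation oracle", {
  expect_equal(peptide_mass("GG"), 132.053492, tolerance = 1e-8)

  pfs <- h4_acetyl_proteoforms()
  for (pf in pfs[c(1, 5, 11, 16)]) {
    expect_equal(monoisotopic_mass(pf), oracle_proteoform_mass(pf),
                 tolerance = 1e-10)
  }

  # d0 -> d5 swap adds 5.0313837 Da per propionyl group (side chains +
  # N-terminus)
  seq4_17 <- substr(histone_sequence("H4"), 4, 17)
  mods <- c(K5 = "unmod", K8 = "ac", K12 = "unmod", K16 = "me1")
  m_d0 <- monoisotopic_mass(proteoform("H4", 4, 17, seq4_17, mods, "d0"))
  m_d5 <- monoisotopic_mass(proteoform("H4", 4, 17, seq4_17, mods, "d5"))
  n_prop <- 3 + 1   # K5, K12 (unmod), K16 (me1) + N-terminus
  expect_equal(m_d5 - m_d0, n_prop * 5.0313837, tolerance = 1e-6)

  # trimethyl vs acetyl near-isobar
  m_me3 <- monoisotopic_mass(proteoform("H3", 9, 17, "KSTGGKAPR",
                                        c(K9 = "me3", K14 = "unmod")))
  m_ac <- monoisotopic_mass(proteoform("H3", 9, 17, "KSTGGKAPR",
                                       c(K9 = "ac", K14 = "unmod")))
  expect_equal(m_me3 - m_ac, 0.0363855, tolerance = 1e-6)
})

test_that("mass additivity holds exactly for modification differences", {
  seq4_17 <- substr(histone_sequence("H4"), 4, 17)
  base <- proteoform("H4", 4, 17, seq4_17,
                     c(K5 = "unmod", K8 = "unmod", K12 = "unmod",
                       K16 = "unmod"))
  plus2 <- proteoform("H4", 4, 17, seq4_17,
                      c(K5 = "ac", K8 = "unmod", K12 = "ac",
                        K16 = "unmod"))
  # ac replaces propionyl on the modified sites
  delta <- 2 * (42.0105646837 - 56.02621474784)
  expect_equal(monoisotopic_mass(plus2) - monoisotopic_mass(base), delta,
               tolerance = 1e-9)
})

test_that("precursor m/z follows the proton-transfer identity", {
  expect_equal(precursor_mz(1000, 1), 1001.00728, tolerance = 1e-5)
  expect_equal(precursor_mz(1000, 2), 501.00728, tolerance = 1e-5)
  for (m in c(132.05, 800.3, 1549.9)) {
    expect_equal(precursor_mz(m, 1) - m, 1.00727646688, tolerance = 1e-12)
  }
  expect_error(precursor_mz(1000, 0), "charge")
})

test_that("fragment ions satisfy counts, complementarity, and isomer structure", {
  pfs <- h4_acetyl_proteoforms()
  for (pf in pfs[c(1, 7, 16)]) {
    fr <- fragment_ions(pf, 1)
    expect_equal(sum(fr$series == "b"), 13)
    expect_equal(sum(fr$series == "y"), 13)
    prec1 <- precursor_mz(monoisotopic_mass(pf), 1)
    b <- fr$mz[fr$series == "b"]
    y <- fr$mz[fr$series == "y"]
    n <- length(b) + 1
    for (i in seq_len(n - 1)) {
      expect_equal(b[i] + y[n - i], prec1 + 1.00727646688,
                   tolerance = 1e-9)
    }
  }

  # K8ac/K12ac positional isomers differ only at fragments separating the
  # two sites (peptide positions 5..8 for b, complements for y)
  seq4_17 <- substr(histone_sequence("H4"), 4, 17)
  a <- fragment_ions(proteoform("H4", 4, 17, seq4_17,
                                c(K5 = "unmod", K8 = "ac", K12 = "unmod",
                                  K16 = "unmod")))
  b <- fragment_ions(proteoform("H4", 4, 17, seq4_17,
                                c(K5 = "unmod", K8 = "unmod", K12 = "ac",
                                  K16 = "unmod")))
  differ <- abs(a$mz - b$mz) > 1e-6
  # b ions: K8 is peptide position 5, K12 position 9; b5..b8 differ
  b_differ <- a$ordinal[a$series == "b"][differ[a$series == "b"]]
  expect_equal(sort(b_differ), 5:8)
  y_differ <- a$ordinal[a$series == "y"][differ[a$series == "y"]]
  expect_equal(sort(y_differ), (14 - 8):(14 - 5))
})

test_that("isobaric grouping partitions forms by mass at tolerance", {
  pfs <- h4_acetyl_proteoforms()
  nac <- vapply(pfs, acetyl_count, numeric(1))
  di <- pfs[nac == 2]
  g <- isobaric_groups(di, 10)
  expect_length(g, 1)
  expect_length(g[[1]]$members, 6)
  # members are pairwise distinguishable by their fragment sets even
  # where no single ion is unique to one member
  frags <- lapply(g[[1]]$proteoforms, function(p) fragment_ions(p)$mz)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(abs(frags[[i]] - frags[[j]])), 1e-3)
  }

  # me3 vs ac single-site forms: 0.0364 Da apart, ~45 ppm at ~810 Da
  me3 <- proteoform("H3", 9, 17, "KSTGGKAPR", c(K9 = "me3", K14 = "unmod"))
  ac <- proteoform("H3", 9, 17, "KSTGGKAPR", c(K9 = "ac", K14 = "unmod"))
  expect_length(isobaric_groups(list(me3, ac), 10), 2)
  expect_length(isobaric_groups(list(me3)), 1)
  expect_length(isobaric_groups(list()), 0)

  # groups partition the input
  g_all <- isobaric_groups(pfs, 10)
  expect_setequal(unlist(lapply(g_all, `[[`, "members")), seq_along(pfs))

  # channel swap never changes group structure or fragment counts
  pfs_d5 <- h4_acetyl_proteoforms(channel = "d5")
  g_d5 <- isobaric_groups(pfs_d5, 10)
  expect_equal(lapply(g_all, `[[`, "members"),
               lapply(g_d5, `[[`, "members"))
})
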