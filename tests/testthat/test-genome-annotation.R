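toy_genes <- function() {
  data.frame(id = c("gA", "gB", "gC"),
             chrom = "chr1",
             start = c(10000, 30000, 50000),
             end = c(14000, 36000, 52000),
             strand = c("+", "-", "+"))
}

test_that("promoter regions are 2 kb strictly upstream, strand-aware, clamped", {
  g <- toy_genes()
  p <- promoter_region(g)
  expect_equal(c(p$start[1], p$end[1]), c(8000, 10000))   # + strand
  expect_equal(c(p$start[2], p$end[2]), c(36000, 38000))  # - strand
  g2 <- data.frame(id = "g", chrom = "chr1", start = 500, end = 3000,
                   strand = "+")
  p2 <- promoter_region(g2)
  expect_equal(c(p2$start, p2$end), c(0, 500))            # clamped
})

test_that("island classification uses promoter > gene body > intergenic priority", {
  g <- toy_genes()
  isl <- data.frame(chrom = "chr1",
                    start = c(8500, 9500, 11000, 20000),
                    end = c(9000, 10500, 12000, 21000))
  # wholly in promoter; spanning promoter+body; in body; intergenic
  r <- classify_islands(isl, g)
  expect_equal(as.character(r$category),
               c("promoter", "promoter", "gene_body", "intergenic"))
  expect_equal(sum(r$fractions), 1)

  # gene-free chromosome -> all intergenic, with a warning
  isl2 <- data.frame(chrom = "chrU", start = 0, end = 1000)
  expect_warning(r2 <- classify_islands(isl2, g), "intergenic")
  expect_equal(unname(r2$fractions["intergenic"]), 1)
})

test_that("island classification agrees with a naive interval scan", {
  set.seed(17)
  for (rep in 1:5) {
    n_g <- 15
    starts <- sort(sample(seq(5000, 4e5, by = 100), n_g))
    g <- data.frame(id = sprintf("g%02d", 1:n_g), chrom = "chr1",
                    start = starts, end = starts + sample(1000:4000, n_g,
                                                          replace = TRUE),
                    strand = sample(c("+", "-"), n_g, replace = TRUE))
    isl <- data.frame(chrom = "chr1",
                      start = sort(sample(seq(0, 4.2e5, by = 50), 30)))
    isl$end <- isl$start + sample(200:3000, 30, replace = TRUE)
    r <- classify_islands(isl, g)
    p <- promoter_region(g)
    brute <- vapply(seq_len(nrow(isl)), function(i) {
      in_p <- any(oracle_overlaps(isl$start[i], isl$end[i], p$start,
                                  p$end))
      in_b <- any(oracle_overlaps(isl$start[i], isl$end[i], g$start,
                                  g$end))
      if (in_p) "promoter" else if (in_b) "gene_body" else "intergenic"
    }, character(1))
    expect_equal(as.character(r$category), brute)
  }
})

test_that("promoter binding respects half-open boundary semantics", {
  g <- toy_genes()
  expect_true(promoter_bound(g, data.frame(chrom = "chr1", start = 7900,
                                           end = 8100))[1])
  # island ending exactly at the promoter start does not overlap
  expect_false(promoter_bound(g, data.frame(chrom = "chr1", start = 7000,
                                            end = 8000))[1])
  expect_equal(promoter_bound(g, data.frame(chrom = character(),
                                            start = numeric(),
                                            end = numeric())),
               rep(FALSE, 3))

  # naive oracle agreement on random fixtures
  set.seed(23)
  for (rep in 1:5) {
    isl <- data.frame(chrom = "chr1",
                      start = sample(seq(0, 6e4, by = 10), 40))
    isl$end <- isl$start + sample(50:5000, 40, replace = TRUE)
    got <- promoter_bound(g, isl)
    p <- promoter_region(g)
    brute <- vapply(seq_len(3), function(i) {
      any(oracle_overlaps(p$start[i], p$end[i], isl$start, isl$end))
    }, logical(1))
    expect_equal(got, brute)
  }
})

test_that("promoter ranking is monotone in enrichment with deterministic ties", {
  g <- toy_genes()
  cs <- c(chr1 = 1e5)
  # gA promoter [8000,10000) heavily tagged; gC promoter [48000,50000) at
  # background; gB promoter [36000,38000) empty
  mk <- function(pos) deduplicate(data.frame(chrom = "chr1", pos = pos,
                                             strand = "+"), cs)
  smp <- mk(c(seq(8010, 9990, by = 40), seq(48010, 49990, by = 400),
              seq(60000, 99000, by = 400)))
  ctrl <- mk(c(seq(8010, 9990, by = 400), seq(48010, 49990, by = 400),
               seq(60000, 99000, by = 400)))
  r <- rank_promoters(g, smp, ctrl)
  expect_equal(r$id[1], "gA")
  # identical counts -> tie broken lexicographically by id
  smp2 <- mk(seq(60000, 99000, by = 400))
  r2 <- rank_promoters(g, smp2, smp2)
  expect_equal(r2$id, c("gA", "gB", "gC"))
})

test_that("combinatorial pattern groups are ordered by size with all-unbound last", {
  b <- matrix(FALSE, 4, 5,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("Brd2", "Brd3", "Brd4", "HP1a", "HP1b")))
  b["g1", 1:3] <- TRUE; b["g2", 1:3] <- TRUE; b["g4", 1] <- TRUE
  r <- combinatorial_patterns(b)
  grp <- unique(r[, c("pattern", "group_rank", "group_size")])
  expect_equal(grp$pattern, c("11100", "10000", "00000"))
  expect_equal(grp$group_size, c(2, 1, 1))
  expect_equal(sum(r$pattern == "00000"), 1)
  expect_equal(tail(r$pattern, 1), "00000")

  # all genes all-unbound: single group, last and only
  b0 <- matrix(FALSE, 3, 5)
  r0 <- combinatorial_patterns(b0)
  expect_equal(unique(r0$pattern), "00000")

  # random matrices: groups partition genes, sizes match brute-force
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    m <- matrix(runif(n * 5) < 0.4, n, 5,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
    r <- combinatorial_patterns(m)
    expect_equal(nrow(r), n)
    expect_setequal(r$gene, rownames(m))
    brute <- table(apply(m, 1, function(x) paste(as.integer(x),
                                                 collapse = "")))
    got <- unique(r[, c("pattern", "group_size")])
    expect_equal(got$group_size[match(names(brute), got$pattern)],
                 unname(as.integer(brute)))
    sizes <- unique(r[, c("pattern", "group_rank", "group_size")])
    non_zero <- sizes[sizes$pattern != "00000", ]
    expect_true(all(diff(non_zero$group_size) <= 0))
    if ("00000" %in% sizes$pattern) {
      expect_equal(tail(sizes$pattern, 1), "00000")
    }
  }
})

test_that("RPKM and expression classes follow the 30/40/30 rank rule", {
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  expect_error(rpkm(10, 0, 1e7), "length")
  expect_true(rpkm(20, 2000, 1e7) >= 1)    # expressed flag threshold

  g <- data.frame(id = sprintf("g%02d", 1:10))
  v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  cls <- expression_classes(g, v)
  expect_equal(as.integer(table(cls)), c(3, 4, 3))
  expect_equal(as.character(cls[1:3]), rep("high", 3))
  expect_equal(as.character(cls[8:10]), rep("silent", 3))

  # rank-based: rescaling RPKM leaves the partition unchanged
  expect_equal(expression_classes(g, v * 1000), cls)
  # all-equal values: deterministic assignment by id
  cls_eq <- expression_classes(g, rep(2, 10))
  expect_equal(as.character(cls_eq),
               c(rep("high", 3), rep("medium", 4), rep("silent", 3)))
  expect_error(expression_classes(g[1:5, , drop = FALSE], v[1:5]), "10")
})

test_that("metagene profiles are flat for uniform signal and orientation-invariant", {
  cs <- c(chr1 = 1e5)
  # deterministic uniform tag grid: one + tag every 10 bp
  uni <- deduplicate(data.frame(chrom = "chr1",
                                pos = seq(0, 99990, by = 10),
                                strand = "+"), cs)
  empty_ctrl <- deduplicate(data.frame(chrom = "chr1", pos = 1,
                                       strand = "+"), cs)
  empty_ctrl$positions$chr1[["+"]] <- numeric(0)
  empty_ctrl$lib_size <- uni$lib_size     # same depth, zero tags
  g <- data.frame(id = c("p", "m"), chrom = "chr1",
                  start = c(20000, 60000), end = c(24000, 64000),
                  strand = c("+", "-"))
  cls <- factor(c("high", "high"), levels = c("high", "medium", "silent"))
  prof <- metagene_profile(uni, empty_ctrl, g, cls)
  expect_equal(diff(range(prof["high", ])), 0, tolerance = 1e-9)

  # flipping strand leaves a symmetric gene's contribution unchanged
  g1 <- g[1, ]; g1f <- g1; g1f$strand <- "-"
  p1 <- metagene_profile(uni, empty_ctrl, g1,
                         factor("high", levels = "high"))
  p2 <- metagene_profile(uni, empty_ctrl, g1f,
                         factor("high", levels = "high"))
  expect_equal(unname(p1[1, ]), unname(rev(p2[1, ])))

  # genes shorter than one bin are excluded with a warning
  gs <- rbind(g, data.frame(id = "tiny", chrom = "chr1", start = 100,
                            end = 120, strand = "+"))
  expect_warning(metagene_profile(uni, empty_ctrl, gs,
                                  factor(c("high", "high", "high"))),
                 "excluded")
})

test_that("knockdown response reports reduction/increase fractions", {
  r <- knockdown_response(c("a", "b", "c", "d"),
                          c(a = -1.5, b = -0.9, c = 0, d = 1.2),
                          top_n = 4, fold_cutoff = 2)
  expect_equal(r$fraction_reduced, 0.25)
  expect_equal(r$fraction_increased, 0.25)

  r0 <- knockdown_response(c("a", "b"), c(a = 0, b = 0), top_n = 2)
  expect_equal(r0$fraction_reduced + r0$fraction_increased, 0)

  set.seed(3)
  fc <- setNames(rnorm(50, 0, 1.5), sprintf("g%02d", 1:50))
  r3 <- knockdown_response(names(fc), fc, top_n = 30)
  expect_true(r3$fraction_reduced >= 0 && r3$fraction_increased >= 0)
  expect_lte(r3$fraction_reduced + r3$fraction_increased, 1)

  expect_error(knockdown_response("zz", c(a = 1)), "no top-ranked")
})
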