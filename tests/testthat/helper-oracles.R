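# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: masses come from a frozen residue table
# (cross-checked against pyteomics before the build), interval and window
# logic from naive scans, statistics from first-principles formulas.

# frozen monoisotopic residue masses (Da)
ORACLE_RESIDUE <- c(
  G = 57.02146372057, A = 71.03711378471, S = 87.03202840427,
  P = 97.05276384885, V = 99.06841391299, T = 101.04767846841,
  C = 103.00918478471, L = 113.08406397713, I = 113.08406397713,
  N = 114.04292744114, D = 115.02694302383, Q = 128.05857750528,
  K = 128.09496301400, E = 129.04259308797, M = 131.04048491299,
  H = 137.05891185845, F = 147.06841391299, R = 156.10111102360,
  Y = 163.06332853255, W = 186.07931294986
)
ORACLE_WATER <- 18.0105646837
ORACLE_PROTON <- 1.00727646688
ORACLE_MOD <- c(me1 = 14.01565006414, me2 = 28.03130012828,
                me3 = 42.04695019242, ac = 42.0105646837,
                prop_d0 = 56.02621474784, prop_d5 = 61.05759847649)

# residue-summation mass oracle for a proteoform
oracle_proteoform_mass <- function(pf) {
  aa <- strsplit(pf$sequence, "")[[1]]
  prop <- if (pf$channel == "d5") ORACLE_MOD[["prop_d5"]] else
    ORACLE_MOD[["prop_d0"]]
  m <- sum(ORACLE_RESIDUE[aa]) + ORACLE_WATER + prop  # N-terminal propionyl
  for (kind in pf$mods) {
    m <- m + switch(kind,
      unmod = prop,
      me1 = ORACLE_MOD[["me1"]] + prop,
      me2 = ORACLE_MOD[["me2"]],
      me3 = ORACLE_MOD[["me3"]],
      ac = ORACLE_MOD[["ac"]]
    )
  }
  m
}

# exhaustive simplex grid search for the deconvolution problem
oracle_grid_search <- function(A, o, step = 0.001) {
  k <- ncol(A)
  grid <- seq(0, 1, by = step)
  best <- NULL; best_cost <- Inf
  if (k == 2) {
    X <- rbind(grid, 1 - grid)
  } else if (k == 3) {
    g <- expand.grid(x1 = grid, x2 = grid)
    g <- g[g$x1 + g$x2 <= 1 + 1e-12, ]
    X <- rbind(g$x1, g$x2, 1 - g$x1 - g$x2)
  } else stop("oracle supports 2-3 members")
  # scale-free comparison: fit the best scalar multiple per candidate
  AX <- A %*% X
  num <- colSums(AX * o)
  den <- colSums(AX^2)
  s <- ifelse(den > 0, num / den, 0)
  cost <- colSums((sweep(AX, 2, s, `*`) - o)^2)
  X[, which.min(cost)]
}

# brute-force BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# two-tailed classical (equal-variance) t-test p via the t CDF
oracle_ttest_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

# naive per-tag window membership scan
oracle_window_counts <- function(positions, starts, window) {
  vapply(starts, function(s) {
    sum(positions >= s & positions < s + window)
  }, numeric(1))
}

# naive interval overlap test (half-open)
oracle_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# random tag fixture on a small genome
random_tags <- function(n, chrom_len, chroms = "chr1") {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(chrom_len, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# WindowTrack from raw values on a fixed non-overlapping grid
make_track <- function(values, window = 200, chrom = "chr1") {
  starts <- (seq_along(values) - 1) * window
  structure(
    data.frame(chrom = rep(chrom, length(values)), start = starts,
               end = starts + window, value = values),
    class = c("WindowTrack", "data.frame"),
    window = window, step = window, normalized = FALSE
  )
}
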