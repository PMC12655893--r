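toy_table <- function(m, genera = NULL) {
  # m: samples x taxa
  if (is.null(genera)) genera <- sprintf("G%02d", seq_len(ncol(m)))
  AbundanceTable(t(m), lineage = lineage_for(genera))
}

test_that("total-sum scaling normalizes samples and refuses empty ones", {
  expect_equal(unname(totalSumScale(matrix(c(2, 2), 1))), matrix(0.5, 1, 2))
  rel <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, byrow = TRUE,
    dimnames = list(c("a", "b"), NULL))
  expect_equal(totalSumScale(rel), rel)  # idempotent
  m <- matrix(c(1, 2, 0, 0), 2, byrow = TRUE, dimnames = list(c("a", "b"), NULL))
  expect_error(totalSumScale(m), "b")
  ab <- toy_table(matrix(1:6, 2, dimnames = list(c("s1", "s2"), NULL)))
  rel2 <- abundanceMatrix(totalSumScale(ab))
  expect_equal(unname(rowSums(rel2)), c(1, 1))
  pm <- abundanceMatrix(totalSumScale(ab, 1e6))
  expect_equal(unname(rowSums(pm)), c(1e6, 1e6))
})

test_that("ACE matches its hand-evaluated breakdown and flags fallbacks", {
  a <- aceIndex(c(1, 1, 2, 15))
  expect_equal(a$S_abund, 1)
  expect_equal(a$S_rare, 3)
  expect_equal(a$N_rare, 4)
  expect_equal(a$F[1], 2)
  expect_equal(a$C_ace, 0.5)
  expect_equal(a$gamma2, 0)
  expect_equal(a$ace, 7)
  expect_false(a$fallback)

  b <- aceIndex(c(20, 30, 40))  # no rare taxa
  expect_equal(b$ace, 3)
  expect_true(b$fallback)

  expect_identical(aceIndex(c(0, 0, 1, 1, 2, 15))$ace, a$ace)
  expect_error(aceIndex(c(1.5, 2)), "integers")
})

test_that("ACE agrees with the direct-formula oracle and with vegan", {
  set.seed(17)
  for (i in 1:100) {
    counts <- rpois(60, lambda = sample(c(1, 3, 20), 1))
    if (sum(counts > 0) < 2) next
    expect_equal(aceIndex(counts)$ace, oracle_ace(counts))
  }
  counts <- c(rep(1, 8), rep(2, 5), rep(3, 4), 7, 9, 25, 60, 120)
  expect_equal(aceIndex(counts)$ace,
    unname(vegan::estimateR(counts)["S.ACE"]))
})

test_that("Bray-Curtis is a bounded semimetric with the textbook values", {
  x <- c(2, 2); y <- c(1, 3)
  d <- brayCurtisMatrix(rbind(a = x, b = y))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(brayCurtisMatrix(rbind(a = c(1, 0), b = c(0, 9)))["a", "b"], 1)
  set.seed(5)
  m <- matrix(rexp(60), 6)
  d2 <- brayCurtisMatrix(m)
  expect_equal(d2, t(d2))
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_error(brayCurtisMatrix(rbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("PCoA recovers Euclidean configurations and degenerates cleanly", {
  # collinear points at distances 1, 1, 2 live on one axis
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  res <- pcoaOrdination(d)
  expect_equal(res$varianceExplained[1], 100)

  set.seed(23)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    conf <- matrix(rnorm(n * 3), n)
    d2 <- as.matrix(dist(conf))
    res2 <- pcoaOrdination(d2)
    rec <- as.matrix(dist(res2$coordinates))
    expect_lt(max(abs(rec - d2)), 1e-9)
    expect_lt(max(abs(colMeans(res2$coordinates))), 1e-9)
    expect_true(all(diff(res2$eigenvalues) <= 1e-12))
    expect_lte(sum(res2$varianceExplained), 100 + 1e-9)
  }

  z <- pcoaOrdination(matrix(0, 4, 4))
  expect_true(all(z$coordinates == 0))
  expect_true(all(z$eigenvalues == 0))
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM hits the separation and enumeration landmarks", {
  # two tight blocks far apart: all between > all within so R = 1
  conf <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(6, 10, 0.01), 3))
  d <- as.matrix(dist(conf))
  g <- rep(c("u", "v"), each = 3)
  res <- anosimTest(d, g)
  expect_equal(res$R, 1)
  expect_identical(res$mode, "exhaustive")  # 20 distinct labelings
  expect_equal(res$p, 2 / 20)               # observed + its mirror

  # 2+2 with a unique maximal R: 6 assignments, observed + mirror tie
  conf2 <- rbind(matrix(rnorm(4, 0, 0.01), 2), matrix(rnorm(4, 5, 0.01), 2))
  d2 <- as.matrix(dist(conf2))
  res2 <- anosimTest(d2, rep(c("u", "v"), each = 2))
  expect_equal(res2$p, 1 / 3)

  expect_error(anosimTest(d, c("u", "u", "u", "u", "u", "v")), "singleton")
  expect_error(anosimTest(d, rep("u", 6)), "2 groups")
})

test_that("ANOSIM R agrees with vegan and Monte-Carlo matches exhaustive", {
  set.seed(77)
  m <- matrix(rexp(8 * 12), 8)
  d <- brayCurtisMatrix(totalSumScale(m))
  g <- rep(c("u", "v"), each = 4)
  mine <- anosimTest(d, g)
  ref <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(mine$R, unname(ref$statistic))

  # 3+3: exhaustive p versus a seeded Monte-Carlo run
  d6 <- d[1:6, 1:6]
  g6 <- rep(c("u", "v"), each = 3)
  ex <- anosimTest(d6, g6)
  mc <- anosimTest(d6, g6, nPermutations = 1999, seed = 3,
    exhaustiveLimit = 1)
  se <- sqrt(ex$p * (1 - ex$p) / 1999)
  expect_lt(abs(mc$p - ex$p), 2 * se + 2 / 2000)
})

test_that("core-taxon counting reduces to set arithmetic", {
  m <- matrix(5, 4, 10)  # identical groups, all taxa everywhere
  rownames(m) <- c("TN_1", "TA_1", "SN_1", "SA_1")
  des <- data.frame(sample_id = rownames(m),
    variety = c("T", "T", "S", "S"), soil = c("N", "A", "N", "A"))
  ab <- toy_table(m); colnames(ab) <- rownames(m)
  core <- coreTaxa(ab, des)
  expect_equal(core$intersection, core$union)
  expect_equal(core$sharedPercent, 100)

  # planted universe: 7 of 10 taxa shared by all four groups
  m2 <- m
  m2[1, 8] <- 0; m2[2, 9] <- 0; m2[3, 10] <- 0
  ab2 <- toy_table(m2); colnames(ab2) <- rownames(m2)
  core2 <- coreTaxa(ab2, des)
  expect_equal(core2$intersection, 7)
  expect_equal(core2$union, 10)
  expect_equal(core2$sharedPercent, 70)

  # disjoint groups share nothing
  m3 <- diag(4) * 5
  rownames(m3) <- rownames(m)
  ab3 <- toy_table(m3); colnames(ab3) <- rownames(m3)
  expect_equal(coreTaxa(ab3, des)$intersection, 0)
})

test_that("top-taxa ranking clamps, breaks ties lexicographically, ignores order", {
  m <- matrix(c(5, 5, 1, 5, 5, 1), 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), NULL))
  ab <- toy_table(m, genera = c("Zeta", "Alpha", "Midge"))
  top <- topTaxa(ab, n = 10)
  expect_length(top, 3)                 # clamped to richness
  expect_equal(top[1:2], c("Alpha", "Zeta"))  # equal abundance: lexicographic
  ab2 <- ab[, c("s2", "s1")]
  expect_identical(topTaxa(ab2, n = 10), top)
  expect_error(topTaxa(ab, rank = "variant"), "rank")
})

test_that("rank aggregation sums genus members", {
  counts <- t(matrix(c(3, 7, 10, 1, 2, 3), 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), NULL)))
  lin <- c(lineage_for("Bradyrhizobium"),
    sub("s__Bradyrhizobium_sp", "s__B_liaoningense", lineage_for("Bradyrhizobium")),
    lineage_for("Sphingomonas"))
  ab <- AbundanceTable(counts, lineage = lin)
  colnames(ab) <- c("s1", "s2")
  agg <- aggregateTaxa(ab, "genus")
  expect_equal(dim(agg), c(2L, 2L))
  expect_equal(unname(abundanceMatrix(agg)[, "Bradyrhizobium"]), c(10, 3))
})

test_that("Kruskal-Wallis screen reproduces the tie-free hand value", {
  m <- matrix(c(1, 2, 3, 10, 11, 12), 6, 1, dimnames = list(paste0("s", 1:6), "t1"))
  scr <- kruskalWallisScreen(m, rep(c("u", "v"), each = 3))
  expect_equal(scr$H, 3.857, tolerance = 1e-3)
  expect_equal(scr$p, 0.0495, tolerance = 1e-3)
  expect_true(scr$pass)

  # two groups: decision agrees with the rank-sum test at matched alpha
  set.seed(31)
  for (i in 1:20) {
    v <- rlnorm(10, sample(c(0, 1.5), 1))
    g <- rep(c("u", "v"), each = 5)
    kw <- kruskalWallisScreen(matrix(v, 10, 1), g)
    ws <- wilcox.test(v[g == "u"], v[g == "v"], exact = FALSE, correct = FALSE)
    expect_equal(kw$pass, ws$p.value < 0.05)
    expect_equal(kw$p, ws$p.value, tolerance = 0.05)
  }

  # all-tied taxon is a defined non-discovery
  tied <- kruskalWallisScreen(matrix(1, 6, 1), rep(c("u", "v"), each = 3))
  expect_equal(tied$p, 1)
  expect_false(tied$pass)
})

test_that("the small-sample exact Spearman null matches cor.test", {
  set.seed(41)
  for (n in 7:9) {
    for (i in 1:10) {
      x <- rnorm(n); y <- rnorm(n)
      S <- sum((rank(x) - rank(y))^2)
      mine <- jipbiome:::.spearman_exact_p(matrix(S, 1, 1), n)[1, 1]
      ref <- suppressWarnings(cor.test(x, y, method = "spearman")$p.value)
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})

test_that("taxon-physiology correlations honour ranks, signs and BH structure", {
  set.seed(13)
  m <- matrix(rexp(8 * 5), 8, dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  phys <- data.frame(sample_id = rep(rownames(m), 2),
    indicator = rep(c("MDA", "SPAD"), each = 8),
    value = c(log(m[, 1]) * 3 + 5, rnorm(8)))
  res <- correlateTaxaPhysiology(m, phys)
  expect_equal(res$rho["t1", "MDA"], 1)   # monotone transform
  # perfect rank agreement at n = 8: exact two-sided p is 2/8!
  expect_equal(res$p["t1", "MDA"], 2 / factorial(8))
  # BH never shrinks a p value and preserves its ordering
  expect_true(all(res$q >= res$p - 1e-15, na.rm = TRUE))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))

  # textbook reversal
  m2 <- cbind(x = c(1, 2, 3, 4))
  rownames(m2) <- paste0("s", 1:4)
  phys2 <- data.frame(sample_id = paste0("s", 1:4), indicator = "y",
    value = c(4, 3, 2, 1))
  res2 <- correlateTaxaPhysiology(m2, phys2)
  expect_equal(res2$rho["x", "y"], -1)

  # constant vectors are reported missing
  m3 <- cbind(flat = rep(2, 8), ok = rexp(8))
  rownames(m3) <- rownames(m)
  res3 <- correlateTaxaPhysiology(m3, phys)
  expect_true(all(is.na(res3$rho["flat", ])))
  expect_error(correlateTaxaPhysiology(m[1:3, , drop = FALSE], phys), "4 shared")
})
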