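make_cp <- function(F0 = 200, F300 = 400, FJ = 600, FI = 800, Fm = 1000,
                    area = 100) {
  structure(list(F0 = F0, F300 = F300, FJ = FJ, FI = FI, Fm = Fm,
    tFmUs = 5e5, t0Us = 20, area = area, areaVt = area / (Fm - F0)),
    class = "CardinalPoints")
}

test_that("cardinal points at exact grid samples are read off exactly", {
  t <- sort(unique(c(10^seq(log10(20), log10(1e6), length.out = 100),
    300, 2000, 30000)))
  f <- 300 + 1200 * (1 - exp(-(t / 1000) / 3))
  tr <- new("FluorescenceTransient", sampleId = "x", timeUs = t, fluorescence = f)
  cp <- extractCardinalPoints(tr)
  expect_identical(cp$F300, f[t == 300])
  expect_identical(cp$FJ, f[t == 2000])
  expect_identical(cp$FI, f[t == 30000])
  expect_identical(cp$Fm, max(f))
})

test_that("degenerate transients produce the documented errors", {
  t <- defaultTimeGrid()
  flat <- new("FluorescenceTransient", sampleId = "flat", timeUs = t,
    fluorescence = rep(500, length(t)))
  expect_error(extractCardinalPoints(flat), "no variable fluorescence")
  late <- new("FluorescenceTransient", sampleId = "late",
    timeUs = t[t > 100], fluorescence = seq_along(t[t > 100]))
  expect_error(extractCardinalPoints(late), "cannot estimate F0")
})

test_that("generator round-trip recovers F0 and Fm within 0.5%", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_transient_params()
    cp <- extractCardinalPoints(simulateTransient(p))
    expect_lt(abs(cp$F0 - p$F0) / p$F0, 0.005)
    expect_lt(abs(cp$Fm - p$Fm) / p$Fm, 0.005)
  }
})

test_that("Vt normalization follows the defining formula and endpoints", {
  cp <- make_cp(F0 = 200, Fm = 1200)
  tr <- new("FluorescenceTransient", sampleId = "x",
    timeUs = c(20, 100, 1000), fluorescence = c(200, 700, 1200))
  nc <- relativeVariableFluorescence(tr, cp)
  expect_equal(nc$vt, c(0, 0.5, 1))
  # every processed transient ends at Vt = 1 at t(Fm)
  p <- transientParams()
  tr2 <- simulateTransient(p)
  cp2 <- extractCardinalPoints(tr2)
  nc2 <- relativeVariableFluorescence(tr2, cp2)
  expect_lt(abs(nc2$vt[which(tr2@timeUs == cp2$tFmUs)] - 1), 1e-12)
})

test_that("the JIP-test chain reproduces the hand-evaluated example", {
  r <- jipTest(make_cp())
  expect_equal(r$Mo, 1.0)
  expect_equal(r$VJ, 0.5)
  expect_equal(r$Wk, 0.5)
  expect_equal(r$phi_Po, 0.8)
  expect_equal(r$psi_o, 0.5)
  expect_equal(r$RC_ABS, 0.4)
  expect_equal(r$PI_ABS, 1.6)
  expect_equal(jipTest(make_cp(F0 = 300, Fm = 1500))$phi_Po, 0.8)
  # per-reaction-center fluxes close algebraically
  expect_equal(r$DIo_RC, r$ABS_RC - r$TRo_RC)
  expect_equal(r$ETo_RC, r$TRo_RC * r$psi_o)
  # both RC/CSm closures
  expect_equal(r$RC_CSm, 0.4 * 1000)
  expect_equal(jipTest(make_cp(), simpleRCCS = TRUE)$RC_CSm, 0.8 * 1000)
})

test_that("phi_Eo equals phi_Po * psi_o to machine precision", {
  set.seed(7)
  for (i in 1:200) {
    F0 <- runif(1, 100, 500)
    Fm <- F0 + runif(1, 500, 3000)
    FJ <- runif(1, F0 + 1, Fm)
    F300 <- runif(1, F0, FJ)
    r <- jipTest(make_cp(F0, F300, FJ, runif(1, FJ, Fm), Fm))
    expect_identical(r$phi_Eo, r$phi_Po * r$psi_o)
  }
})

test_that("undefined and infinite parameter regimes are flagged, not silent", {
  expect_warning(r <- jipTest(make_cp(F300 = 200, FJ = 200)), "Wk undefined")
  expect_true(is.na(r$Wk))
  r2 <- suppressWarnings(jipTest(make_cp(F0 = 0)))  # phi_Po = 1
  expect_true(is.infinite(r2$PI_ABS))
  expect_true(r2$piAbsInfinite)
})

test_that("PI_ABS increases in phi_Po and psi_o over the unit-square grid", {
  phis <- seq(0.05, 0.95, by = 0.05)
  psis <- seq(0.05, 0.95, by = 0.05)
  pi_at <- function(phi, psi) {
    F0 <- 200
    Fm <- F0 / (1 - phi)
    FJ <- F0 + (1 - psi) * (Fm - F0)
    F300 <- F0 + (FJ - F0) / 4   # fixes Mo = VJ so RC/ABS = phi_Po
    jipTest(make_cp(F0, F300, FJ, min(FJ + 1, Fm), Fm))$PI_ABS
  }
  grid <- outer(phis, psis, Vectorize(pi_at))
  expect_true(all(apply(grid, 2, diff) > 0))
  expect_true(all(apply(grid, 1, diff) > 0))
})

test_that("difference kinetics are antisymmetric and expose the K-band", {
  base <- transientParams(kappa = 0, noiseSd = 0)
  stressed <- transientParams(kappa = 0.2, noiseSd = 0)
  ncC <- relativeVariableFluorescence(simulateTransient(base))
  ncS <- relativeVariableFluorescence(simulateTransient(stressed))
  expect_equal(max(abs(deltaVt(ncC, ncC)$deltaVt)), 0)
  d1 <- deltaVt(ncS, ncC)
  d2 <- deltaVt(ncC, ncS)
  expect_equal(d1$deltaVt, -d2$deltaVt)
  expect_gt(d1$kBand, 0)
  # resampling path: control on a different grid
  ncC2 <- relativeVariableFluorescence(simulateTransient(base, defaultTimeGrid(97)))
  d3 <- deltaVt(ncS, ncC2)
  expect_lt(max(abs(d3$deltaVt - d1$deltaVt)), 1e-3)
  short <- ncC
  short$timeUs <- short$timeUs[10:50]; short$vt <- short$vt[10:50]
  expect_error(deltaVt(ncS, short), "grid")
})

test_that("group summaries are order-invariant with exact zero sd for clones", {
  e <- simulateExperiment(nPerGroup = 3, seed = 2)
  jip <- jipTestAll(e$transients)
  des <- sampleDesign(e$transients)
  g1 <- jipGroupTable(jip, des)
  perm <- jip[rev(seq_len(nrow(jip))), ]
  expect_equal(jipGroupTable(perm, des), g1)

  clones <- jip[rep(1, 3), ]
  clones$sample_id <- c("TN_01", "TN_02", "TN_03")
  des3 <- toy_design(clones$sample_id, variety = rep("T", 3), soil = rep("N", 3))
  expect_warning(gt <- jipGroupTable(clones, des3), NA)
  expect_true(all(gt$sd == 0))
  expect_true(all(gt$n == 3))
  expect_setequal(gt$group, "TN")
})
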