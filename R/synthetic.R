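#' Default OJIP acquisition grid
#'
#' 120 log-spaced time points from 20 microseconds to 1 second, matching
#' the duration of the saturating red-light pulse used for fast
#' fluorescence induction.
#'
#' @param n number of points.
#' @return numeric vector of times in microseconds.
#' @export
defaultTimeGrid <- function(n = 120) {
  10^seq(log10(20), log10(1e6), length.out = n)
}

#' Parameters of the synthetic OJIP rise model
#'
#' The generator models the relative variable fluorescence as a mixture
#' of three exponential rise phases (J, I, P) plus an optional fast
#' K-component reflecting donor-side (OEC) impairment:
#' \deqn{V(t) = \sum_{x \in \{J,I,P\}} w_x (1 - e^{-s/\tau_x}) +
#'   \kappa (1 - e^{-s/\tau_K}),}
#' where \eqn{s = \max(t - 20\,\mu s, 0)} is time since the 20-us
#' instrument origin, so the first measurable point is exactly F0. This
#' is a phenomenological shape model with controllable cardinal points,
#' not a mechanistic PSII energy-flux model.
#'
#' @param F0 initial fluorescence (a.u.), > 0.
#' @param Fm maximum fluorescence (a.u.), > F0.
#' @param wJ,wI,wP non-negative phase weights; normalized to sum to 1.
#' @param tauJ,tauI,tauP phase time constants in ms, `tauJ < tauI < tauP`.
#' @param kappa K-band amplitude, >= 0.
#' @param tauK K-band time constant in ms (~0.3 ms, the K step).
#' @param noiseSd additive Gaussian noise standard deviation (a.u.).
#' @param seed integer seed used when noise is drawn; `NULL` uses the
#'   current RNG stream.
#' @return a validated list of class `TransientParams`.
#' @export
transientParams <- function(F0 = 500, Fm = 2500, wJ = 0.5, wI = 0.3, wP = 0.2,
                            tauJ = 1, tauI = 10, tauP = 150,
                            kappa = 0, tauK = 0.3, noiseSd = 0, seed = NULL) {
  if (F0 <= 0) stop("F0 must be positive")
  if (Fm <= F0) stop("Fm must exceed F0")
  w <- c(wJ = wJ, wI = wI, wP = wP)
  if (any(w < 0)) stop("phase weights must be non-negative")
  if (sum(w) <= 0) stop("at least one phase weight must be positive")
  w <- w / sum(w)
  if (!(tauJ < tauI && tauI < tauP)) stop("time constants must satisfy tauJ < tauI < tauP")
  if (kappa < 0) stop("kappa must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  structure(list(F0 = F0, Fm = Fm, wJ = unname(w[1]), wI = unname(w[2]),
    wP = unname(w[3]), tauJ = tauJ, tauI = tauI, tauP = tauP,
    kappa = kappa, tauK = tauK, noiseSd = noiseSd, seed = seed),
    class = "TransientParams")
}

# raw (un-renormalized) phase-mixture V(t); t in microseconds
.model_v_raw <- function(params, timeUs) {
  s <- pmax(timeUs / 1000 - 0.02, 0)  # ms since the 20-us origin
  params$wJ * (1 - exp(-s / params$tauJ)) +
    params$wI * (1 - exp(-s / params$tauI)) +
    params$wP * (1 - exp(-s / params$tauP)) +
    params$kappa * (1 - exp(-s / params$tauK))
}

#' Noise-free model relative variable fluorescence
#'
#' Evaluates the generating model's V(t) renormalized so that V at
#' `tMaxUs` equals 1 — i.e. the Vt value a perfect JIP-test extraction
#' would recover from a noise-free transient on a grid ending at
#' `tMaxUs`.
#'
#' @param params a `TransientParams`.
#' @param timeUs times in microseconds.
#' @param tMaxUs grid endpoint used for renormalization.
#' @return numeric vector of Vt values.
#' @export
transientModelVt <- function(params, timeUs, tMaxUs = 1e6) {
  .model_v_raw(params, timeUs) / .model_v_raw(params, tMaxUs)
}

#' Simulate one OJIP transient
#'
#' F(t) = F0 + (Fm - F0) * Vt(t) + Gaussian noise, with Vt the phase
#' mixture renormalized to 1 at the grid endpoint. `noiseSd = 0` gives a
#' deterministic curve with F(20 us) = F0 and max F = Fm exactly.
#'
#' @param params a [transientParams()] object.
#' @param grid time points in microseconds, strictly increasing, within
#'   [10 us, 2 s].
#' @param sampleId identifier for the returned transient.
#' @return A [FluorescenceTransient-class].
#' @export
simulateTransient <- function(params, grid = defaultTimeGrid(), sampleId = "sim") {
  stopifnot(inherits(params, "TransientParams"))
  if (any(grid < 10 | grid > 2e6))
    stop("time grid must lie within [10 us, 2 s]")
  if (any(diff(grid) <= 0)) stop("time grid must be strictly increasing")
  vt <- .model_v_raw(params, grid) / .model_v_raw(params, max(grid))
  f <- params$F0 + (params$Fm - params$F0) * vt
  if (params$noiseSd > 0)
    f <- f + .with_seed(params$seed, stats::rnorm(length(grid), 0, params$noiseSd))
  new("FluorescenceTransient", sampleId = sampleId,
    timeUs = as.numeric(grid), fluorescence = f)
}

#' Default per-group stress shifts for the four-treatment design
#'
#' Stressed (saline-alkaline, soil A) groups get a raised K-band and a
#' lowered Fm; the sensitive variety (S) is shifted more strongly than
#' the tolerant one (T), and its J-phase weight rises (lowering psi_o).
#' Unstressed groups are unshifted.
#'
#' @return named list of per-group shift lists with elements
#'   `kappaAdd`, `fmScale`, `wjScale`.
#' @export
defaultStressDeltas <- function() {
  list(
    TN = list(kappaAdd = 0,    fmScale = 1,    wjScale = 1),
    SN = list(kappaAdd = 0,    fmScale = 1,    wjScale = 1),
    TA = list(kappaAdd = 0.05, fmScale = 0.95, wjScale = 1.05),
    SA = list(kappaAdd = 0.25, fmScale = 0.75, wjScale = 1.25)
  )
}

.apply_delta <- function(params, delta) {
  p <- unclass(params)
  p$kappa <- p$kappa + (delta$kappaAdd %||% 0)
  p$Fm <- p$F0 + (p$Fm - p$F0) * (delta$fmScale %||% 1)
  p$wJ <- p$wJ * (delta$wjScale %||% 1)
  do.call(transientParams, p[setdiff(names(p), "seed")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full four-group fluorescence experiment
#'
#' Per-sample parameters are drawn with lognormal jitter (default CV 5%)
#' around group means obtained by applying `deltas` to `control`;
#' ground-truth group parameters are returned alongside the transients.
#'
#' @param nPerGroup samples per group (>= 2).
#' @param control baseline [transientParams()] (the TN condition).
#' @param deltas per-group shifts, see [defaultStressDeltas()].
#' @param seed integer seed driving jitter and noise.
#' @param grid acquisition grid in microseconds.
#' @param jitterCv lognormal coefficient of variation of per-sample
#'   parameters.
#' @param noiseSd per-point additive noise (a.u.).
#' @return list with `transients` (a [TransientSet-class]) and
#'   `groupParams` (named list of the true group-mean parameters).
#' @export
simulateExperiment <- function(nPerGroup = 10, control = transientParams(),
                               deltas = defaultStressDeltas(), seed = 1,
                               grid = defaultTimeGrid(), jitterCv = 0.05,
                               noiseSd = 0) {
  if (nPerGroup < 2) stop("need at least 2 samples per group")
  groups <- c("TN", "TA", "SN", "SA")
  groupParams <- lapply(groups, function(g) .apply_delta(control, deltas[[g]] %||% list()))
  names(groupParams) <- groups
  .jb_log("INFO", "simulateExperiment seed=%d nPerGroup=%d", seed, nPerGroup)
  sdlog <- sqrt(log(1 + jitterCv^2))
  .with_seed(seed, {
    curves <- list()
    design <- data.frame(sample_id = character(), variety = character(),
      soil = character(), stringsAsFactors = FALSE)
    for (g in groups) {
      gp <- groupParams[[g]]
      for (i in seq_len(nPerGroup)) {
        id <- sprintf("%s_%02d", g, i)
        jit <- function(x) x * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        fv <- jit(gp$Fm - gp$F0)
        f0 <- jit(gp$F0)
        p <- transientParams(F0 = f0, Fm = f0 + fv,
          wJ = jit(gp$wJ), wI = jit(gp$wI), wP = jit(gp$wP),
          tauJ = jit(gp$tauJ), tauI = max(jit(gp$tauI), gp$tauJ * 2),
          tauP = max(jit(gp$tauP), gp$tauI * 2),
          kappa = if (gp$kappa > 0) jit(gp$kappa) else 0,
          tauK = gp$tauK, noiseSd = noiseSd)
        tr <- simulateTransient(p, grid, sampleId = id)
        curves[[id]] <- list(time_us = tr@timeUs, fluorescence = tr@fluorescence)
        design <- rbind(design, data.frame(sample_id = id,
          variety = substr(g, 1, 1), soil = substr(g, 2, 2),
          stringsAsFactors = FALSE))
      }
    }
    list(transients = suppressWarnings(TransientSet(curves, design)),
      groupParams = groupParams)
  })
}

#' Parameters of the Dirichlet-multinomial community generator
#'
#' @param nTaxa number of taxa.
#' @param nPerGroup samples per group.
#' @param depth sequencing depth per sample (identical across samples).
#' @param baseLog base log-abundance profile (length `nTaxa`); defaults
#'   to a linear ramp spanning about e^6-fold between the most and least
#'   abundant taxon. Normalized so exp(baseLog) sums to 1.
#' @param markers list of planted differential taxa, each a list with
#'   `taxon` (index or lineage), `group` (target group), `log2fc`
#'   (log2 effect added in that group).
#' @param theta Dirichlet overdispersion (> 0); total concentration is
#'   about 1/theta.
#' @param seed integer seed.
#' @return list of class `CommunityParams` including generated lineages.
#' @export
communityParams <- function(nTaxa = 200, nPerGroup = 6, depth = 1e5,
                            baseLog = NULL, markers = list(),
                            theta = 0.001, seed = NULL) {
  if (theta <= 0) stop("theta must be positive")
  if (depth <= 0) stop("sequencing depth must be positive")
  if (is.null(baseLog)) baseLog <- seq(3, -3, length.out = nTaxa)
  if (length(baseLog) != nTaxa) stop("baseLog must have length nTaxa")
  baseLog <- baseLog - log(sum(exp(baseLog)))
  phyla <- sprintf("P%02d", (seq_len(nTaxa) - 1) %% 8 + 1)
  lineage <- sprintf(
    "k__Bacteria;p__%s;c__C%s;o__O%s;f__F%03d;g__G%03d;s__S%04d",
    phyla, phyla, phyla, (seq_len(nTaxa) - 1) %% 40 + 1, seq_len(nTaxa), seq_len(nTaxa))
  markers <- lapply(markers, function(m) {
    if (is.character(m$taxon)) {
      idx <- match(m$taxon, lineage)
      if (is.na(idx)) stop("marker taxon not found: ", m$taxon)
      m$taxon <- idx
    }
    if (m$taxon < 1 || m$taxon > nTaxa) stop("marker taxon index out of range")
    m
  })
  structure(list(nTaxa = nTaxa, nPerGroup = nPerGroup, depth = depth,
    baseLog = baseLog, markers = markers, theta = theta, seed = seed,
    lineage = lineage), class = "CommunityParams")
}

#' Simulate a Dirichlet-multinomial abundance table
#'
#' Per sample, relative abundances are drawn from a Dirichlet with
#' concentration `exp(baseLog + group effects) / theta` and counts from
#' a multinomial at the stated depth, so every sample total equals the
#' depth exactly.
#'
#' @param params a [communityParams()] object.
#' @param design optional design data.frame; defaults to `nPerGroup`
#'   samples in each of TN, TA, SN, SA.
#' @param seed integer seed; defaults to `params$seed`.
#' @return An [AbundanceTable-class] with the design in `colData`.
#' @export
simulateAbundance <- function(params, design = NULL, seed = params$seed) {
  stopifnot(inherits(params, "CommunityParams"))
  if (is.null(design)) {
    groups <- c("TN", "TA", "SN", "SA")
    design <- data.frame(
      sample_id = unlist(lapply(groups, function(g)
        sprintf("%s_%02d", g, seq_len(params$nPerGroup)))),
      variety = rep(substr(groups, 1, 1), each = params$nPerGroup),
      soil = rep(substr(groups, 2, 2), each = params$nPerGroup),
      stringsAsFactors = FALSE)
  }
  design <- .validate_design(design)
  for (m in params$markers)
    if (!m$group %in% design$group)
      stop("marker target group absent from design: ", m$group)
  .jb_log("INFO", "simulateAbundance seed=%s depth=%g",
    if (is.null(seed)) "NULL" else as.character(seed), params$depth)
  counts <- .with_seed(seed, {
    vapply(seq_len(nrow(design)), function(j) {
      eff <- params$baseLog
      for (m in params$markers)
        if (design$group[j] == m$group)
          eff[m$taxon] <- eff[m$taxon] + log(2) * m$log2fc
      alpha <- exp(eff) / params$theta
      p <- stats::rgamma(params$nTaxa, shape = alpha)
      p <- p / sum(p)
      as.numeric(stats::rmultinom(1, size = params$depth, prob = p))
    }, numeric(params$nTaxa))
  })
  colnames(counts) <- design$sample_id
  AbundanceTable(counts, lineage = params$lineage, design = design)
}

#' A taxon-to-indicator linkage for the physiology generator
#'
#' @param indicator physiological indicator name (e.g. "MDA").
#' @param taxon lineage string (or genus name) of the linked taxon.
#' @param beta slope on log10 relative abundance.
#' @param alpha intercept.
#' @param sigma Gaussian noise sd, >= 0.
#' @return list of class `LinkageParams`.
#' @export
linkageParams <- function(indicator, taxon, beta = 1, alpha = 0, sigma = 0) {
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(indicator = indicator, taxon = taxon, beta = beta,
    alpha = alpha, sigma = sigma), class = "LinkageParams")
}

#' Simulate physiology indicators linked to taxa
#'
#' For each linkage, indicator = alpha + beta * log10(relative abundance
#' + pseudocount) + N(0, sigma^2) per sample, with pseudocount 1/depth.
#'
#' @param design design data.frame covering the table's samples.
#' @param table an [AbundanceTable-class].
#' @param linkages list of [linkageParams()] objects.
#' @param seed integer seed.
#' @return long data.frame `sample_id`, `indicator`, `value`.
#' @export
simulatePhysiology <- function(design, table, linkages, seed = 1) {
  design <- .validate_design(design)
  .check_design_cover(sampleIds(table), design, "abundance table")
  m <- abundanceMatrix(table)  # samples x taxa
  depth <- rowSums(m)
  rel <- m / depth
  .jb_log("INFO", "simulatePhysiology seed=%d", seed)
  .with_seed(seed, {
    rows <- lapply(linkages, function(lk) {
      stopifnot(inherits(lk, "LinkageParams"))
      j <- match(lk$taxon, colnames(m))
      if (is.na(j)) {
        gen <- rowData(table)$genus
        j <- match(lk$taxon, gen)
      }
      if (is.na(j)) stop("linked taxon not found in table: ", lk$taxon)
      x <- log10(rel[, j] + 1 / depth)
      data.frame(sample_id = rownames(m), indicator = lk$indicator,
        value = lk$alpha + lk$beta * x + stats::rnorm(nrow(m), 0, lk$sigma),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
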