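#' Extract cardinal points from an OJIP transient
#'
#' F0 is the fluorescence at the 20-us origin (interpolated when the
#' grid brackets 20 us, else the earliest point at or before 50 us);
#' F300 (the K step), FJ (2 ms) and FI (30 ms) are interpolated linearly
#' in log-time; Fm is the curve maximum (first index on ties) and the
#' area is the trapezoidal integral of (Fm - F) from t(F0) to t(Fm) in
#' a.u. x ms.
#'
#' @param transient a [FluorescenceTransient-class] spanning at least
#'   [50 us, 300 ms] with >= 30 points.
#' @return list of class `CardinalPoints` with elements `F0`, `F300`,
#'   `FJ`, `FI`, `Fm`, `tFmUs`, `t0Us`, `area` (a.u. x ms) and `areaVt`
#'   (dimensionless Vt x ms).
#' @export
extractCardinalPoints <- function(transient) {
  stopifnot(is(transient, "FluorescenceTransient"))
  t_us <- transient@timeUs
  f <- transient@fluorescence
  if (length(t_us) < 30 || min(t_us) > 50 || max(t_us) < 3e5)
    stop("cannot estimate F0: transient must span at least [50 us, 300 ms] with >= 30 points")
  if (min(t_us) <= 20 && max(t_us) >= 20) {
    F0 <- .interp_logtime(t_us, f, 20)
    t0 <- 20
  } else {
    F0 <- f[1]
    t0 <- t_us[1]
  }
  imax <- which.max(f)           # first index attaining the maximum
  Fm <- f[imax]
  tFm <- t_us[imax]
  if (Fm <= F0) stop("no variable fluorescence: Fm does not exceed F0")
  F300 <- .interp_logtime(t_us, f, 300)
  FJ <- .interp_logtime(t_us, f, 2000)
  FI <- .interp_logtime(t_us, f, 30000)
  keep <- t_us >= t0 & t_us <= tFm
  tt <- c(t0, t_us[keep & t_us > t0])
  ff <- c(F0, f[keep & t_us > t0])
  area <- sum(diff(tt) / 1000 * (2 * Fm - ff[-length(ff)] - ff[-1]) / 2)
  structure(list(F0 = F0, F300 = F300, FJ = FJ, FI = FI, Fm = Fm,
    tFmUs = tFm, t0Us = t0, area = area, areaVt = area / (Fm - F0)),
    class = "CardinalPoints")
}

#' Relative variable fluorescence Vt
#'
#' O-P normalization: Vt = (Ft - F0)/(Fm - F0) on the transient's grid.
#'
#' @param transient a [FluorescenceTransient-class].
#' @param cp its [extractCardinalPoints()]; computed when omitted.
#' @return list of class `NormalizedCurve` with `timeUs` and `vt`.
#' @export
relativeVariableFluorescence <- function(transient, cp = extractCardinalPoints(transient)) {
  vt <- (transient@fluorescence - cp$F0) / (cp$Fm - cp$F0)
  structure(list(sampleId = transient@sampleId,
    timeUs = transient@timeUs, vt = vt), class = "NormalizedCurve")
}

#' Difference kinetics between stress and control
#'
#' Pointwise delta-Vt = Vt(stress) - Vt(control) on the stress grid; the
#' control curve is resampled by log-time linear interpolation when its
#' grid differs. The positive maximum over the 200-400 us window is
#' reported as the K-band amplitude.
#'
#' @param stress,control `NormalizedCurve` objects.
#' @return list of class `NormalizedCurve` with `timeUs`, `deltaVt` and
#'   `kBand`.
#' @export
deltaVt <- function(stress, control) {
  stopifnot(inherits(stress, "NormalizedCurve"), inherits(control, "NormalizedCurve"))
  if (min(control$timeUs) > min(stress$timeUs) * 1.0001 ||
      max(control$timeUs) < max(stress$timeUs) * 0.9999)
    stop("control grid does not cover the stress grid")
  vc <- if (isTRUE(all.equal(stress$timeUs, control$timeUs))) control$vt
    else .interp_logtime(control$timeUs, control$vt, stress$timeUs)
  dv <- stress$vt - vc
  win <- stress$timeUs >= 200 & stress$timeUs <= 400
  structure(list(timeUs = stress$timeUs, deltaVt = dv,
    kBand = if (any(win)) max(dv[win]) else NA_real_),
    class = "NormalizedCurve")
}

#' Derive the JIP-test parameter set from cardinal points
#'
#' Implements the standard JIP-test chain: VJ = (FJ - F0)/(Fm - F0),
#' VI likewise, Wk = (F300 - F0)/(FJ - F0), phi_Po = Fv/Fm =
#' (Fm - F0)/Fm, psi_o = 1 - VJ, phi_Eo = phi_Po * psi_o, Mo =
#' 4 (F300 - F0)/(Fm - F0) (per ms), Sm = Area/(Fm - F0) (Vt x ms),
#' RC/ABS = phi_Po * (VJ/Mo), the per-reaction-center energy fluxes
#' (ABS/RC = Mo/VJ/phi_Po, TRo/RC = Mo/VJ, ETo/RC = (Mo/VJ) psi_o,
#' DIo/RC = ABS/RC - TRo/RC) and
#' PI_ABS = RC/ABS * [phi_Po/(1 - phi_Po)] * [psi_o/(1 - psi_o)].
#'
#' RC/CSm defaults to RC/ABS * Fm; setting `simpleRCCS = TRUE`
#' uses the simpler closure phi_Po * Fm (absorption-per-cross-section
#' approximated by Fm) instead.
#'
#' @param cp a `CardinalPoints` object.
#' @param simpleRCCS use the phi_Po * Fm variant of RC/CSm.
#' @return named list of class `JIPTestResult`. `Wk` is `NA` with a
#'   warning when FJ = F0; `PI_ABS` is `Inf` (flagged) when phi_Po or
#'   psi_o reaches 1.
#' @export
jipTest <- function(cp, simpleRCCS = FALSE) {
  stopifnot(inherits(cp, "CardinalPoints"))
  fv <- cp$Fm - cp$F0
  VJ <- (cp$FJ - cp$F0) / fv
  VI <- (cp$FI - cp$F0) / fv
  if (cp$FJ == cp$F0) {
    warning("Wk undefined: FJ equals F0", call. = FALSE)
    Wk <- NA_real_
  } else Wk <- (cp$F300 - cp$F0) / (cp$FJ - cp$F0)
  phi_Po <- fv / cp$Fm
  psi_o <- 1 - VJ
  phi_Eo <- phi_Po * psi_o
  Mo <- 4 * (cp$F300 - cp$F0) / fv
  Sm <- cp$areaVt
  RC_ABS <- phi_Po * (VJ / Mo)
  TRo_RC <- Mo / VJ
  ABS_RC <- TRo_RC / phi_Po
  ETo_RC <- TRo_RC * psi_o
  DIo_RC <- ABS_RC - TRo_RC
  RC_CSm <- if (simpleRCCS) phi_Po * cp$Fm else RC_ABS * cp$Fm
  infinite <- phi_Po >= 1 || psi_o >= 1
  PI_ABS <- if (infinite) Inf else
    RC_ABS * (phi_Po / (1 - phi_Po)) * (psi_o / (1 - psi_o))
  structure(list(VJ = VJ, VI = VI, Wk = Wk, phi_Po = phi_Po, psi_o = psi_o,
    phi_Eo = phi_Eo, Mo = Mo, Sm = Sm, RC_ABS = RC_ABS, ABS_RC = ABS_RC,
    TRo_RC = TRo_RC, ETo_RC = ETo_RC, DIo_RC = DIo_RC, RC_CSm = RC_CSm,
    PI_ABS = PI_ABS, piAbsInfinite = infinite), class = "JIPTestResult")
}

#' Run the JIP test over a TransientSet
#'
#' @param ts a [TransientSet-class].
#' @param simpleRCCS see [jipTest()].
#' @return data.frame, one row per sample, `sample_id` plus the
#'   [jipTest()] parameters. Samples whose extraction fails are dropped
#'   with a warning.
#' @export
jipTestAll <- function(ts, simpleRCCS = FALSE) {
  stopifnot(is(ts, "TransientSet"))
  rows <- list()
  for (id in sampleIds(ts)) {
    res <- tryCatch({
      cp <- extractCardinalPoints(transients(ts)[[id]])
      jipTest(cp, simpleRCCS = simpleRCCS)
    }, error = function(e) {
      warning(sprintf("sample '%s' skipped: %s", id, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res))
      rows[[id]] <- data.frame(sample_id = id,
        as.data.frame(res[setdiff(names(res), "piAbsInfinite")]),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot wide JIP results to the long physiology layout
#'
#' @param results output of [jipTestAll()].
#' @return long data.frame `sample_id`, `indicator`, `value` directly
#'   consumable by [compareGroups()].
#' @export
jipLong <- function(results) {
  pars <- setdiff(names(results), "sample_id")
  out <- do.call(rbind, lapply(pars, function(p)
    data.frame(sample_id = results$sample_id, indicator = p,
      value = results[[p]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Per-group mean/sd/n summary of JIP parameters
#'
#' @param results output of [jipTestAll()].
#' @param design design data.frame covering the result samples.
#' @return data.frame `group`, `parameter`, `mean`, `sd`, `n`; design
#'   groups with no samples are omitted with a warning.
#' @export
jipGroupTable <- function(results, design) {
  design <- .validate_design(design)
  .check_design_cover(results$sample_id, design, "JIP results")
  grp <- design$group[match(results$sample_id, design$sample_id)]
  missing_groups <- setdiff(unique(design$group), grp)
  if (length(missing_groups))
    warning("group(s) without samples omitted: ",
      paste(missing_groups, collapse = ", "), call. = FALSE)
  pars <- setdiff(names(results), "sample_id")
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sub <- results[grp == g, , drop = FALSE]
    do.call(rbind, lapply(pars, function(p) data.frame(group = g, parameter = p,
      mean = mean(sub[[p]]), sd = stats::sd(sub[[p]]), n = nrow(sub),
      stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out
}
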