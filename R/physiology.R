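#' Percent change relative to a reference
#'
#' 100 * (value - reference) / reference, the convention used when
#' reporting stress-induced increases or decreases of physiological
#' indicators.
#'
#' @param value,reference numeric (vectorized); `reference` must be
#'   non-zero.
#' @param digits decimals for the rounded report (default 1).
#' @return numeric percent change (unrounded); the rounded value is in
#'   attribute `rounded`.
#' @export
percentChange <- function(value, reference, digits = 1) {
  if (any(reference == 0)) stop("reference must be non-zero")
  pc <- 100 * (value - reference) / reference
  attr(pc, "rounded") <- round(pc, digits)
  pc
}

#' Fold ratio between two measurements
#'
#' Used for e.g. comparing ion concentrations between saline-alkaline
#' and normal soil. Censored inputs (values only known as below a
#' detection bound) are refused.
#'
#' @param numerator,denominator numeric scalars; denominator > 0.
#' @param censored logical length-2 (numerator, denominator) or scalar.
#' @return one-row data.frame with `numerator`, `denominator`, `fold`
#'   (raw) and `fold_rounded` (1 decimal).
#' @export
foldRatio <- function(numerator, denominator, censored = FALSE) {
  if (any(censored))
    stop("refusing fold ratio on censored (detection-bound) values")
  if (denominator <= 0) stop("denominator must be positive")
  fold <- numerator / denominator
  data.frame(numerator = numerator, denominator = denominator,
    fold = fold, fold_rounded = round(fold, 1))
}

#' Fold ratios of soil properties between two soils
#'
#' Computes, per property, the A/N (or any chosen pair) fold ratio from
#' a long soil table as read by [readSoilTable()]. Properties with a
#' censored value on either side are skipped with a warning.
#'
#' @param soil data.frame from [readSoilTable()].
#' @param properties which properties to compare; default all shared.
#' @param numeratorSoil,denominatorSoil soil ids (default A over N).
#' @return data.frame `property`, `numerator`, `denominator`, `fold`,
#'   `fold_rounded`.
#' @export
soilFoldRatios <- function(soil, properties = NULL,
                           numeratorSoil = "A", denominatorSoil = "N") {
  num <- soil[soil$soil_id == numeratorSoil, ]
  den <- soil[soil$soil_id == denominatorSoil, ]
  if (is.null(properties)) properties <- intersect(num$property, den$property)
  rows <- list()
  for (p in properties) {
    a <- num[num$property == p, ][1, ]
    n <- den[den$property == p, ][1, ]
    if (is.na(a$value) || is.na(n$value)) next
    if (a$censored || n$censored) {
      warning(sprintf("property '%s' skipped: censored value", p), call. = FALSE)
      next
    }
    fr <- foldRatio(a$value, n$value)
    rows[[p]] <- data.frame(property = p, fr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance star coding
#'
#' "****" for p < 1e-4, "***" for p < 1e-3, "**" for p < 0.01, "*" for
#' p < 0.05, otherwise "ns".
#'
#' @param p numeric vector of p values in [0, 1].
#' @return character vector of the same length.
#' @export
starCode <- function(p) {
  .assert_prob(p, "p value")
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 1e-2, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

#' Compare varieties within a soil stratum
#'
#' Two-sided t-test of the tolerant (T) versus sensitive (S) variety for
#' one indicator within one soil stratum, Welch (unequal variance) by
#' default. The t statistic is oriented as mean(T) - mean(S).
#'
#' @param physiology long data.frame (`sample_id`, `indicator`, `value`).
#' @param design design data.frame.
#' @param indicator indicator name to test.
#' @param stratum soil stratum, "N" or "A".
#' @param welch use the Welch unequal-variance test (default); `FALSE`
#'   pools variances.
#' @return one-row data.frame: `indicator`, `stratum`, per-variety mean,
#'   sd and n, `t`, `df`, `p`, `stars`.
#' @export
compareGroups <- function(physiology, design, indicator, stratum, welch = TRUE) {
  design <- .validate_design(design)
  .check_design_cover(unique(physiology$sample_id), design, "physiology table")
  sub <- physiology[physiology$indicator == indicator, ]
  if (!nrow(sub)) stop("indicator not found: ", indicator)
  des <- design[match(sub$sample_id, design$sample_id), ]
  sub <- sub[des$soil == stratum, ]
  des <- des[des$soil == stratum, ]
  xT <- sub$value[des$variety == "T"]
  xS <- sub$value[des$variety == "S"]
  if (length(xT) < 2 || length(xS) < 2)
    stop("need at least 2 samples per variety within the stratum")
  tt <- stats::t.test(xT, xS, var.equal = !welch)
  data.frame(indicator = indicator, stratum = stratum,
    mean_T = mean(xT), sd_T = stats::sd(xT), n_T = length(xT),
    mean_S = mean(xS), sd_S = stats::sd(xS), n_S = length(xS),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, stars = starCode(tt$p.value),
    stringsAsFactors = FALSE)
}

#' Compare all indicators in both strata
#'
#' Convenience wrapper running [compareGroups()] for every indicator in
#' each soil stratum with enough samples.
#'
#' @inheritParams compareGroups
#' @return data.frame, one row per (indicator, stratum).
#' @export
compareAllGroups <- function(physiology, design, welch = TRUE) {
  out <- list()
  for (ind in unique(physiology$indicator))
    for (st in c("N", "A")) {
      row <- tryCatch(compareGroups(physiology, design, ind, st, welch = welch),
        error = function(e) NULL)
      if (!is.null(row)) out[[paste(ind, st)]] <- row
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
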