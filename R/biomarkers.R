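#' Linear-discriminant effect-size biomarker discovery
#'
#' Two-stage LEfSe-style screen restricted to a two-group comparison:
#' a Kruskal-Wallis screen at `alpha` followed, for the survivors, by a
#' bootstrapped linear-discriminant effect size on per-million
#' abundances. Each of `nBoot` rounds subsamples a fraction `subsample`
#' of every group (without replacement), fits the one-dimensional
#' discriminant of the surviving features with a small ridge on the
#' pooled within-class covariance, and scores each feature as half the
#' sum of its raw class-mean difference and its share (unit-norm
#' discriminant loading times the projected class separation) of the
#' discriminant axis. The reported effect size is the log10 of the
#' bootstrap mean, floored at 1 (so scores are >= 0); a biomarker passes
#' when p < `alpha` and the score exceeds `ldaThreshold`.
#'
#' @param x an [AbundanceTable-class] of counts, or a samples x taxa
#'   abundance matrix (rescaled internally to per-million).
#' @param grouping two group labels, one per sample, >= 3 samples each.
#' @param alpha Kruskal-Wallis screening level.
#' @param ldaThreshold log10 effect-size cutoff (2 by convention).
#' @param nBoot bootstrap rounds (30 by convention).
#' @param subsample per-group subsampling fraction (2/3 by convention).
#' @param seed integer seed for the bootstrap.
#' @return data.frame of class `BiomarkerResult`: `taxon`, `p`,
#'   `enriched` (group with the higher mean per-million abundance),
#'   `lda` (log10 effect size, `NA` for screen failures), `passes`.
#' @export
ldaEffectSize <- function(x, grouping, alpha = 0.05, ldaThreshold = 2,
                          nBoot = 30, subsample = 2 / 3, seed = NULL) {
  m <- if (is(x, "AbundanceTable")) abundanceMatrix(totalSumScale(x, 1e6))
    else {
      mm <- as.matrix(x)
      totalSumScale(mm, 1e6)
    }
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(m))
    stop("grouping length must match the number of samples")
  lev <- sort(unique(grouping))
  if (length(lev) != 2)
    stop("the biomarker stage compares exactly two groups")
  if (any(table(grouping) < 3))
    stop("need at least 3 samples per group")
  .jb_log("INFO", "ldaEffectSize seed=%s nBoot=%d",
    if (is.null(seed)) "NULL" else as.character(seed), nBoot)
  screen <- kruskalWallisScreen(m, grouping, alpha = alpha)
  mean1 <- colMeans(m[grouping == lev[1], , drop = FALSE])
  mean2 <- colMeans(m[grouping == lev[2], , drop = FALSE])
  enriched <- ifelse(mean1 >= mean2, lev[1], lev[2])
  lda <- rep(NA_real_, ncol(m))
  surv <- which(screen$pass)
  if (length(surv)) {
    eff <- .with_seed(seed, {
      acc <- matrix(0, nBoot, length(surv))
      i1 <- which(grouping == lev[1]); i2 <- which(grouping == lev[2])
      k1 <- max(2L, ceiling(length(i1) * subsample))
      k2 <- max(2L, ceiling(length(i2) * subsample))
      for (b in seq_len(nBoot)) {
        s1 <- sample(i1, k1); s2 <- sample(i2, k2)
        sub <- m[c(s1, s2), surv, drop = FALSE]
        cls <- rep(1:2, c(k1, k2))
        acc[b, ] <- .lda_feature_effects(sub, cls)
      }
      colMeans(acc)
    })
    lda[surv] <- log10(pmax(eff, 1))
  }
  out <- data.frame(taxon = colnames(m), p = screen$p, enriched = enriched,
    lda = lda, passes = screen$pass & !is.na(lda) & lda > ldaThreshold,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("BiomarkerResult", class(out))
  out
}

# per-feature effect contributions of one discriminant fit:
# 0.5 * (|raw class-mean difference| + |unit loading| * projected
# class-mean separation), on the per-million scale
.lda_feature_effects <- function(sub, cls) {
  m1 <- colMeans(sub[cls == 1, , drop = FALSE])
  m2 <- colMeans(sub[cls == 2, , drop = FALSE])
  gm <- m1 - m2
  sw <- (crossprod(scale(sub[cls == 1, , drop = FALSE], scale = FALSE)) +
         crossprod(scale(sub[cls == 2, , drop = FALSE], scale = FALSE))) /
        (nrow(sub) - 2)
  ridge <- max(mean(diag(sw)), 1) * 1e-6
  w <- tryCatch(solve(sw + diag(ridge, ncol(sub)), gm),
    error = function(e) gm)
  wu <- w / sqrt(sum(w^2))
  delta <- abs(sum(wu * gm))           # projected class-mean separation
  0.5 * (abs(gm) + abs(wu) * delta)
}
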