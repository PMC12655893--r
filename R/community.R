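#' Total-sum scaling
#'
#' Rescales each sample so its taxa sum to `scale` (1 for relative
#' abundance, 1e6 for the per-million scale used by the biomarker
#' stage).
#'
#' @param x an [AbundanceTable-class] or a samples x taxa matrix.
#' @param scale target sample sum.
#' @return same class as `x`, rescaled. Idempotent on already-scaled
#'   input.
#' @export
totalSumScale <- function(x, scale = 1) {
  if (is(x, "AbundanceTable")) {
    m <- assay(x, "counts")          # taxa x samples
    tot <- colSums(m)
    if (any(tot <= 0))
      stop("cannot normalize empty sample(s): ",
        paste(colnames(m)[tot <= 0], collapse = ", "))
    assay(x, "counts") <- sweep(m, 2, tot / scale, "/")
    metadata(x)$normalized <- scale
    return(x)
  }
  m <- as.matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("cannot normalize empty sample(s): ",
      paste(rownames(m)[tot <= 0], collapse = ", "))
  sweep(m, 1, tot / scale, "/")
}

#' Chao-Lee ACE richness estimate
#'
#' Abundance-based coverage estimator with the conventional
#' rare/abundant cutoff of 10: with `S_rare` rare taxa (1..cutoff
#' individuals), `N_rare` individuals among them, `F1` singletons and
#' coverage `C = 1 - F1/N_rare`,
#' \deqn{ACE = S_{abund} + S_{rare}/C + (F_1/C)\,\gamma^2,}
#' where \eqn{\gamma^2} is the truncated squared coefficient of
#' variation. When there are no rare taxa or coverage is zero the
#' estimate falls back to the observed richness, flagged.
#'
#' @param counts non-negative integer vector of per-taxon counts (zeros
#'   allowed and ignored).
#' @param rareThreshold rare/abundant cutoff (default 10).
#' @return list of class `ACEBreakdown`: `S_obs`, `S_abund`, `S_rare`,
#'   `N_rare`, `F` (frequency counts F_1..F_cutoff), `C_ace`, `gamma2`,
#'   `ace`, `fallback`.
#' @export
aceIndex <- function(counts, rareThreshold = 10) {
  if (any(counts < 0) || !all(.is_wholenumber(counts)))
    stop("counts must be non-negative integers")
  counts <- round(counts[counts > 0])
  S_obs <- length(counts)
  rare <- counts[counts <= rareThreshold]
  S_rare <- length(rare)
  S_abund <- S_obs - S_rare
  N_rare <- sum(rare)
  F_i <- vapply(seq_len(rareThreshold), function(i) sum(rare == i), numeric(1))
  out <- list(S_obs = S_obs, S_abund = S_abund, S_rare = S_rare,
    N_rare = N_rare, F = F_i, C_ace = NA_real_, gamma2 = NA_real_,
    ace = S_obs, fallback = TRUE)
  if (S_rare == 0) return(structure(out, class = "ACEBreakdown"))
  C_ace <- 1 - F_i[1] / N_rare
  out$C_ace <- C_ace
  if (C_ace == 0 || N_rare < 2) return(structure(out, class = "ACEBreakdown"))
  i <- seq_len(rareThreshold)
  gamma2 <- max(S_rare / C_ace * sum(i * (i - 1) * F_i) /
    (N_rare * (N_rare - 1)) - 1, 0)
  out$gamma2 <- gamma2
  out$ace <- S_abund + S_rare / C_ace + (F_i[1] / C_ace) * gamma2
  out$fallback <- FALSE
  structure(out, class = "ACEBreakdown")
}

#' Per-sample ACE richness for an abundance table
#'
#' @param x an [AbundanceTable-class] of counts.
#' @param rareThreshold see [aceIndex()].
#' @return data.frame `sample_id`, `S_obs`, `ace`, `fallback`.
#' @export
aceTable <- function(x, rareThreshold = 10) {
  m <- abundanceMatrix(x)
  rows <- lapply(rownames(m), function(s) {
    a <- aceIndex(m[s, ], rareThreshold)
    data.frame(sample_id = s, S_obs = a$S_obs, ace = a$ace,
      fallback = a$fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over taxa, computed on
#' (typically total-sum-scaled) non-negative data.
#'
#' @param x an [AbundanceTable-class] or samples x taxa matrix.
#' @return symmetric matrix with zero diagonal, samples in rows/columns.
#' @export
brayCurtisMatrix <- function(x) {
  m <- if (is(x, "AbundanceTable")) abundanceMatrix(x) else as.matrix(x)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative data")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
      paste(rownames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered -D^2/2 matrix. No
#' Lingoes/Cailliez correction is applied; negative eigenvalues are
#' reported separately and excluded from the variance-explained
#' denominator.
#'
#' @param d distance matrix (symmetric, zero diagonal) or `dist`.
#' @return list of class `OrdinationResult`: `coordinates` (samples x
#'   positive axes, centered), `eigenvalues` (descending, all),
#'   `varianceExplained` (% per positive axis),
#'   `negativeEigenvalues`.
#' @export
pcoaOrdination <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(m)
  if (all(m == 0)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(m), "PC1"))
    return(structure(list(coordinates = coords, eigenvalues = rep(0, n),
      varianceExplained = 0, negativeEigenvalues = numeric(0)),
      class = "OrdinationResult"))
  }
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-10
  pos <- which(eig > tol)
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_along(pos))
  coords <- sweep(coords, 2, colMeans(coords))  # numerically re-center
  structure(list(coordinates = coords, eigenvalues = eig,
    varianceExplained = 100 * eig[pos] / sum(eig[pos]),
    negativeEigenvalues = eig[eig < -tol]),
    class = "OrdinationResult")
}

# all distinct permutations of a label multiset, as a matrix (rows);
# count guarded by the caller
.multiset_perms <- function(labels) {
  rec <- function(lab) {
    if (length(lab) <= 1L) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      for (p in rec(rest)) out[[length(out) + 1L]] <- c(u, p)
    }
    out
  }
  do.call(rbind, rec(labels))
}

.count_distinct_perms <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

.anosim_r <- function(rankD, within) {
  M <- length(rankD)
  (mean(rankD[!within]) - mean(rankD[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group
#' dissimilarities: R = (mean between-group rank - mean within-group
#' rank) / (M/2) with M = n(n-1)/2. When the number of distinct label
#' permutations is at most `exhaustiveLimit` the null distribution is
#' enumerated exactly; otherwise Monte-Carlo permutations are drawn and
#' p = (1 + #\{permuted R >= observed\}) / (1 + nPermutations).
#'
#' @param d distance matrix or `dist` object.
#' @param grouping group label per sample (>= 2 groups, >= 2 members
#'   each).
#' @param nPermutations Monte-Carlo permutation count (default 999).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param exhaustiveLimit switch to exact enumeration at or below this
#'   many distinct labelings.
#' @return list of class `AnosimResult`: `R`, `p`, `nPermutations`,
#'   `mode` ("exhaustive" or "montecarlo"), `seed`.
#' @export
anosimTest <- function(d, grouping, nPermutations = 999, seed = NULL,
                       exhaustiveLimit = 10000) {
  m <- as.matrix(d)
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(m))
    stop("grouping length must match the number of samples")
  tab <- table(grouping)
  if (length(tab) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(tab < 2)) stop("ANOSIM is undefined with singleton group(s): ",
    paste(names(tab)[tab < 2], collapse = ", "))
  low <- lower.tri(m)
  rankD <- rank(m[low])
  ii <- row(m)[low]; jj <- col(m)[low]
  obsR <- .anosim_r(rankD, grouping[ii] == grouping[jj])
  nDistinct <- .count_distinct_perms(grouping)
  if (nDistinct <= exhaustiveLimit) {
    perms <- .multiset_perms(grouping)
    stats <- apply(perms, 1, function(g) .anosim_r(rankD, g[ii] == g[jj]))
    p <- sum(stats >= obsR - 1e-12) / nrow(perms)
    mode <- "exhaustive"
    nPermutations <- nrow(perms)
  } else {
    .jb_log("INFO", "anosim Monte-Carlo seed=%s nperm=%d",
      if (is.null(seed)) "NULL" else as.character(seed), nPermutations)
    stats <- .with_seed(seed, vapply(seq_len(nPermutations), function(b) {
      g <- sample(grouping)
      .anosim_r(rankD, g[ii] == g[jj])
    }, numeric(1)))
    p <- (1 + sum(stats >= obsR - 1e-12)) / (1 + nPermutations)
    mode <- "montecarlo"
  }
  structure(list(R = obsR, p = p, nPermutations = nPermutations,
    mode = mode, seed = seed), class = "AnosimResult")
}

#' Core-taxon counting across groups
#'
#' A taxon is present in a group when its group-summed count reaches the
#' detection threshold. Reports per-group richness, the all-group
#' intersection, the union, and the shared percentage.
#'
#' @param x an [AbundanceTable-class].
#' @param design design data.frame (or `NULL` to use the attached one).
#' @param detection presence threshold on the group-summed count.
#' @return list of class `CoreTaxa`: `presence` (taxa x groups logical),
#'   `perGroupRichness`, `intersection`, `union`, `sharedPercent`.
#' @export
coreTaxa <- function(x, design = NULL, detection = 1) {
  if (is.null(design)) design <- sampleDesign(x)
  if (is.null(design)) stop("a design is required")
  design <- .validate_design(design)
  .check_design_cover(sampleIds(x), design, "abundance table")
  grp <- design$group[match(sampleIds(x), design$sample_id)]
  m <- assay(x, "counts")  # taxa x samples
  gsum <- vapply(sort(unique(grp)), function(g)
    rowSums(m[, grp == g, drop = FALSE]), numeric(nrow(m)))
  presence <- gsum >= detection
  inter <- sum(rowSums(presence) == ncol(presence))
  uni <- sum(rowSums(presence) > 0)
  structure(list(presence = presence,
    perGroupRichness = colSums(presence),
    intersection = inter, union = uni,
    sharedPercent = if (uni > 0) 100 * inter / uni else NA_real_),
    class = "CoreTaxa")
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' @param x an [AbundanceTable-class].
#' @param rank one of domain, phylum, class, order, family, genus,
#'   species.
#' @return An [AbundanceTable-class] with one row per rank value; taxa
#'   lacking the rank are pooled as "unclassified".
#' @export
aggregateTaxa <- function(x, rank = "genus") {
  rd <- rowData(x)
  if (!rank %in% colnames(rd)) stop("unknown rank: ", rank)
  lab <- as.character(rd[[rank]])
  if (all(is.na(lab)))
    stop("rank '", rank, "' is absent from every lineage")
  lab[is.na(lab)] <- "unclassified"
  m <- rowsum(assay(x, "counts"), group = lab, reorder = TRUE)
  AbundanceTable(m, lineage = rownames(m), design = sampleDesign(x))
}

#' Top-n most abundant taxa at a rank
#'
#' Taxa are aggregated to `rank`, ordered by total relative abundance
#' (ties broken lexicographically), and the first `n` names returned.
#'
#' @param x an [AbundanceTable-class] of counts.
#' @param n how many taxa (clamped to the richness).
#' @param rank taxonomic rank, or `NULL` to rank raw rows.
#' @return character vector of taxon names, most abundant first.
#' @export
topTaxa <- function(x, n = 50, rank = "genus") {
  agg <- if (is.null(rank)) x else aggregateTaxa(x, rank)
  rel <- totalSumScale(agg)
  tot <- rowSums(assay(rel, "counts"))
  ord <- order(-tot, rownames(rel))
  head(rownames(rel)[ord], n)
}

#' Kruskal-Wallis differential-abundance screen
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p value, per
#' taxon, on relative abundances across groups. All-tied taxa get H = 0,
#' p = 1.
#'
#' @param x an [AbundanceTable-class] or samples x taxa matrix.
#' @param grouping group label per sample.
#' @param alpha screening level for the pass flag.
#' @return data.frame `taxon`, `H`, `p`, `pass`.
#' @export
kruskalWallisScreen <- function(x, grouping, alpha = 0.05) {
  m <- if (is(x, "AbundanceTable")) abundanceMatrix(totalSumScale(x)) else as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  res <- apply(m, 2, function(v) {
    if (length(unique(v)) == 1L) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(v, grouping)
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  data.frame(taxon = colnames(m), H = res["H", ], p = res["p", ],
    pass = res["p", ] < alpha, row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank correlations between taxa and physiological indicators
#'
#' Spearman rank correlation (Pearson by flag) of each taxon's relative
#' abundance with each indicator across shared samples, with
#' Benjamini-Hochberg adjustment applied jointly across the whole taxon
#' x indicator grid. P values use the exact permutation null of the
#' rank statistic for untied pairs at n <= 9 samples (the
#' t-approximation is badly anticonservative in the far tail at such
#' sample sizes) and the t-approximation otherwise. Raw-p stars
#' (* p < 0.05, ** p < 0.01) mirror the usual heatmap annotation;
#' q-based flags at the same thresholds are also returned.
#'
#' @param x an [AbundanceTable-class] of counts (total-sum scaled
#'   internally) or a samples x taxa matrix of abundances.
#' @param physiology long data.frame (`sample_id`, `indicator`,
#'   `value`).
#' @param design optional design used to verify referential integrity.
#' @param method "spearman" (default) or "pearson".
#' @return list of class `CorrelationResult` with taxa x indicator
#'   matrices `rho`, `p`, `q`, `stars` (raw-p), `qflag`; constant
#'   vectors give `NA` entries.
#' @export
correlateTaxaPhysiology <- function(x, physiology, design = NULL,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- if (is(x, "AbundanceTable")) abundanceMatrix(totalSumScale(x)) else as.matrix(x)
  if (!is.null(design)) {
    design <- .validate_design(design)
    .check_design_cover(rownames(m), design, "abundance table")
    .check_design_cover(unique(physiology$sample_id), design, "physiology table")
  }
  wide <- .phys_wide(physiology)
  shared <- intersect(rownames(m), rownames(wide))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  m <- m[shared, , drop = FALSE]
  wide <- wide[shared, , drop = FALSE]
  n <- length(shared)
  if (method == "spearman") {
    mr <- apply(m, 2, rank)
    wr <- apply(wide, 2, rank)
  } else {
    mr <- m; wr <- wide
  }
  rho <- suppressWarnings(stats::cor(mr, wr))  # NA for constant vectors
  rho[!is.finite(rho)] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-14] <- 0
  if (method == "spearman" && n <= 9) {
    # exact permutation null for untied pairs; S = sum of squared rank
    # differences, computable from the rank cross-product
    untied_x <- apply(mr, 2, function(r) !anyDuplicated(r))
    untied_y <- apply(wr, 2, function(r) !anyDuplicated(r))
    S <- outer(colSums(mr^2), colSums(wr^2), "+") - 2 * crossprod(mr, wr)
    pe <- .spearman_exact_p(S, n)
    use <- outer(untied_x, untied_y, "&") & !is.na(rho)
    p[use] <- pe[use]
  }
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
    dimnames = dimnames(p))
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  qflag <- matrix("", nrow(q), ncol(q), dimnames = dimnames(q))
  qflag[!is.na(q) & q < 0.05] <- "*"
  qflag[!is.na(q) & q < 0.01] <- "**"
  structure(list(rho = rho, p = p, q = q, stars = stars, qflag = qflag,
    n = n, method = method), class = "CorrelationResult")
}

.jb_cache <- new.env(parent = emptyenv())

# all permutations of 1..n, built by iterative insertion (n <= 9)
.all_perms <- function(n) {
  P <- matrix(1L, 1, 1)
  if (n == 1) return(P)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (j in seq_len(k)) {
      left <- P[, seq_len(j - 1), drop = FALSE]
      right <- if (j <= k - 1) P[, j:(k - 1), drop = FALSE] else P[, 0, drop = FALSE]
      blocks[[j]] <- cbind(left, k, right, deparse.level = 0)
    }
    P <- do.call(rbind, blocks)
  }
  P
}

# exact two-sided p of Spearman's S (sum of squared rank differences)
# under the uniform permutation null; distribution cached per n
.spearman_exact_p <- function(S, n) {
  key <- paste0("spearman_cdf_", n)
  if (is.null(.jb_cache[[key]])) {
    P <- .all_perms(n)
    s_all <- rowSums(sweep(P, 2, seq_len(n))^2)
    tab <- tabulate(s_all + 1L, nbins = max(s_all) + 1L)
    .jb_cache[[key]] <- cumsum(tab) / length(s_all)
  }
  cdf <- .jb_cache[[key]]
  smax <- length(cdf) - 1L
  lookup <- function(s) {
    s <- round(s)
    lo <- cdf[min(s, smax) + 1L]                    # P(S <= s)
    hi <- if (s <= 0) 1 else 1 - cdf[min(s - 1, smax) + 1L]  # P(S >= s)
    min(1, 2 * min(lo, hi))
  }
  out <- vapply(as.numeric(S), lookup, numeric(1))
  matrix(out, nrow(S), ncol(S), dimnames = dimnames(S))
}

.phys_wide <- function(physiology) {
  ids <- unique(physiology$sample_id)
  inds <- unique(physiology$indicator)
  wide <- matrix(NA_real_, length(ids), length(inds),
    dimnames = list(ids, inds))
  for (k in seq_len(nrow(physiology)))
    wide[physiology$sample_id[k], physiology$indicator[k]] <- physiology$value[k]
  wide
}
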