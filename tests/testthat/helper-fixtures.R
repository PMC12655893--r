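options(jipbiome.verbose = FALSE)

# --- tiny on-disk fixtures, built in code -------------------------------

write_transient_csv <- function(curves, path = tempfile(fileext = ".csv")) {
  rows <- do.call(rbind, lapply(names(curves), function(id)
    data.frame(sample_id = id, time_us = curves[[id]]$time_us,
      fluorescence = curves[[id]]$fluorescence)))
  write.csv(rows, path, row.names = FALSE)
  path
}

write_design_csv <- function(design, path = tempfile(fileext = ".csv")) {
  write.csv(design[c("sample_id", "variety", "soil")], path, row.names = FALSE)
  path
}

toy_design <- function(ids = c("a", "b"),
                       variety = rep_len(c("T", "S"), length(ids)),
                       soil = rep_len("N", length(ids))) {
  data.frame(sample_id = ids, variety = variety, soil = soil,
    stringsAsFactors = FALSE)
}

toy_curve <- function(n = 60) {
  t <- 10^seq(log10(20), log10(5e5), length.out = n)
  list(time_us = t, fluorescence = 200 + 800 * (1 - exp(-(t / 1000) / 2)))
}

write_abundance_tsv <- function(m, lineage, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(lineage = lineage, m, check.names = FALSE)
  colnames(df) <- c("lineage", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

lineage_for <- function(genus, phylum = "Pseudomonadota") {
  sprintf("k__Bacteria;p__%s;c__Cx;o__Ox;f__Fx;g__%s;s__%s_sp", phylum, genus, genus)
}

# --- independent oracles -------------------------------------------------

# direct Chao-Lee formula, written from the estimator's definition,
# independent of aceIndex()
oracle_ace <- function(counts, cutoff = 10) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  s_abund <- sum(counts > cutoff)
  s_rare <- sum(counts <= cutoff)
  if (s_rare == 0) return(s_obs)
  n_rare <- sum(counts[counts <= cutoff])
  f1 <- sum(counts == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0 || n_rare < 2) return(s_obs)
  top <- sum(vapply(1:cutoff, function(i) i * (i - 1) * sum(counts == i), numeric(1)))
  g2 <- max(s_rare / c_ace * top / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

# closed-form Vt of the generator's phase mixture, evaluated from its
# mathematical definition (time shifted to the 20-us origin,
# renormalized at the grid endpoint)
oracle_model_vt <- function(p, t_us, tmax_us = 1e6) {
  v <- function(t) {
    s <- max(t / 1000 - 0.02, 0)
    p$wJ * (1 - exp(-s / p$tauJ)) + p$wI * (1 - exp(-s / p$tauI)) +
      p$wP * (1 - exp(-s / p$tauP)) + p$kappa * (1 - exp(-s / p$tauK))
  }
  vapply(t_us, v, numeric(1)) / v(tmax_us)
}

random_transient_params <- function() {
  w <- runif(3, 0.1, 1)
  w <- w / sum(w)
  transientParams(
    F0 = runif(1, 300, 600), Fm = runif(1, 1500, 3500),
    wJ = w[1], wI = w[2], wP = w[3],
    tauJ = runif(1, 0.4, 1.2), tauI = runif(1, 5, 20),
    tauP = runif(1, 80, 300), kappa = runif(1, 0, 0.3))
}
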