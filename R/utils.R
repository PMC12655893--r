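# internal helpers: logging, seeded evaluation, interpolation, design checks

.jb_log <- function(level, fmt, ...) {
  if (!isTRUE(getOption("jipbiome.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s jipbiome: %s",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, sprintf(fmt, ...)))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL runs as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a deterministic 32-bit sub-seed from a base seed and an offset
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

# linear interpolation of y at target time, linear in log10(time)
.interp_logtime <- function(timeUs, y, atUs) {
  stats::approx(log10(timeUs), y, xout = log10(atUs), rule = 1)$y
}

# every id in `ids` must appear in design$sample_id
.check_design_cover <- function(ids, design, what = "input") {
  bad <- setdiff(ids, design$sample_id)
  if (length(bad))
    stop(sprintf("%s contains sample_ids absent from the design: %s",
      what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# strict numeric check helpers
.assert_prob <- function(p, what = "p") {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  invisible(TRUE)
}

.is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
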