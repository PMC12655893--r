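#' Construct an AbundanceTable
#'
#' Builds the central samples x taxa container from a taxon-by-sample
#' count matrix and its taxonomy lineages. Lineages are parsed into
#' ranks (domain, phylum, class, order, family, genus, species) from the
#' conventional `k__...;p__...;...;s__...` encoding.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns,
#'   non-negative.
#' @param lineage character vector of lineage strings, one per row of
#'   `counts`; defaults to `rownames(counts)`.
#' @param design optional design data.frame (`sample_id`, `variety`,
#'   `soil`, `group`) stored in `colData`.
#' @return An [AbundanceTable-class].
#' @export
AbundanceTable <- function(counts, lineage = rownames(counts), design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lineage)) stop("taxon lineages are required")
  rownames(counts) <- lineage
  rd <- DataFrame(lineage = lineage, .parse_lineage(lineage))
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(design)) {
    design <- .validate_design(design)
    .check_design_cover(colnames(counts), design, "abundance table")
    design <- design[match(colnames(counts), design$sample_id), ]
    cd <- DataFrame(variety = design$variety, soil = design$soil,
      group = design$group, row.names = colnames(counts))
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
    rowData = rd, colData = cd)
  new("AbundanceTable", se)
}

.RANKS <- c(k = "domain", d = "domain", p = "phylum", c = "class",
  o = "order", f = "family", g = "genus", s = "species")

.parse_lineage <- function(lineage) {
  out <- lapply(unique(unname(.RANKS)), function(r) rep(NA_character_, length(lineage)))
  names(out) <- unique(unname(.RANKS))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (tok in trimws(parts[[i]])) {
      if (grepl("^[a-z]__", tok)) {
        rank <- .RANKS[substr(tok, 1, 1)]
        val <- substring(tok, 4)
        if (!is.na(rank) && nzchar(val)) out[[rank]][i] <- val
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.validate_design <- function(design) {
  req <- c("sample_id", "variety", "soil")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design table is missing required column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$variety <- as.character(design$variety)
  design$soil <- as.character(design$soil)
  if (anyDuplicated(design$sample_id))
    stop("design sample_ids must be unique")
  if (!all(design$variety %in% c("T", "S")))
    stop("variety must be 'T' (tolerant) or 'S' (sensitive)")
  if (!all(design$soil %in% c("N", "A")))
    stop("soil must be 'N' (normal) or 'A' (saline-alkaline)")
  design$group <- paste0(design$variety, design$soil)
  design
}

#' Read a sample design table
#'
#' @param path CSV with header `sample_id,variety,soil`; `variety` in
#'   \{T, S\}, `soil` in \{N, A\}. The group factor (TN/TA/SN/SA) is
#'   derived.
#' @return data.frame with columns `sample_id`, `variety`, `soil`,
#'   `group`.
#' @export
readDesign <- function(path) {
  # colClasses: a lone "T" variety column must not become logical TRUE
  .validate_design(utils::read.csv(path, colClasses = "character"))
}

#' Read raw OJIP transients and join them to the design
#'
#' Long-format input: one row per acquisition point. Samples whose time
#' column is not strictly increasing are rejected with a diagnostic;
#' samples present only in the data or only in the design are kept where
#' possible and reported as orphans.
#'
#' @param path CSV with header `sample_id,time_us,fluorescence`.
#' @param designPath CSV with header `sample_id,variety,soil`.
#' @return A [TransientSet-class].
#' @export
readTransients <- function(path, designPath) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "time_us", "fluorescence"), names(raw))
  if (length(miss))
    stop("transient table is missing required column(s): ", paste(miss, collapse = ", "))
  design <- readDesign(designPath)
  TransientSet(split(raw[c("time_us", "fluorescence")], raw$sample_id), design)
}

#' Construct a TransientSet from per-sample curves
#'
#' @param curves named list; each element a data.frame/list with
#'   `time_us` and `fluorescence`.
#' @param design design data.frame (see [readDesign()]).
#' @return A [TransientSet-class].
#' @export
TransientSet <- function(curves, design) {
  design <- .validate_design(design)
  keep <- list()
  for (id in names(curves)) {
    cur <- curves[[id]]
    if (any(diff(cur$time_us) <= 0)) {
      warning(sprintf("sample '%s' rejected: time_us is not strictly increasing", id),
        call. = FALSE)
      next
    }
    keep[[id]] <- new("FluorescenceTransient", sampleId = id,
      timeUs = as.numeric(cur$time_us), fluorescence = as.numeric(cur$fluorescence))
  }
  orphans <- c(setdiff(names(keep), design$sample_id),
    setdiff(design$sample_id, names(curves)))
  if (length(orphans))
    warning(sprintf("%d orphan sample id(s) not shared by data and design: %s",
      length(orphans), paste(orphans, collapse = ", ")), call. = FALSE)
  new("TransientSet", transients = keep, design = design, orphans = orphans)
}

#' Read a taxa-abundance table
#'
#' Tab-separated input with the taxonomy lineage in the first column and
#' one column per sample. Duplicate lineages are summed with a warning;
#' any negative cell is a hard error naming the offending taxon and
#' sample.
#'
#' @param path TSV path.
#' @param design optional design data.frame to attach.
#' @return An [AbundanceTable-class] (internally taxa x samples; use
#'   [abundanceMatrix()] for the samples x taxa view).
#' @export
readAbundanceTable <- function(path, design = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("abundance table needs a lineage column plus sample columns")
  lineage <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("abundance table contains non-numeric or missing cells")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative abundance for taxon '%s' in sample '%s'",
      lineage[neg[1, 1]], colnames(m)[neg[1, 2]]))
  if (anyDuplicated(lineage)) {
    warning("duplicated lineages summed: ",
      paste(unique(lineage[duplicated(lineage)]), collapse = ", "), call. = FALSE)
    m <- rowsum(m, group = lineage, reorder = FALSE)
    lineage <- rownames(m)
  }
  AbundanceTable(m, lineage = lineage, design = design)
}

#' Write an abundance table back to TSV
#'
#' @param x an [AbundanceTable-class].
#' @param path output path.
#' @export
writeAbundanceTable <- function(x, path) {
  df <- data.frame(lineage = lineages(x), assay(x, "counts"),
    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("lineage", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format physiology table
#'
#' @param path CSV with header `sample_id,indicator,value` (SPAD, MDA,
#'   SOD, POD, CAT, dry weight, ...).
#' @return data.frame with those columns, `value` numeric.
#' @export
readPhysiology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "indicator", "value"), names(df))
  if (length(miss))
    stop("physiology table is missing required column(s): ", paste(miss, collapse = ", "))
  df$value <- as.numeric(df$value)
  df
}

#' Read a soil physicochemical profile
#'
#' Left-censored entries written as `<bound` (for example `<0.02`) are
#' kept as bounds with `censored = TRUE`; they are refused by
#' [foldRatio()] rather than silently treated as measurements.
#'
#' @param path CSV with header `soil_id,property,value,unit`.
#' @return data.frame with columns `soil_id`, `property`, `value`
#'   (numeric; the bound for censored entries), `unit`, `censored`.
#' @export
readSoilTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("soil_id", "property", "value", "unit"), names(df))
  if (length(miss))
    stop("soil table is missing required column(s): ", paste(miss, collapse = ", "))
  cens <- grepl("^\\s*<", df$value)
  val <- as.numeric(sub("^\\s*<\\s*", "", df$value))
  if (anyNA(val)) stop("soil table has non-numeric value entries")
  if (any(val < 0)) stop("soil property values must be non-negative")
  data.frame(soil_id = df$soil_id, property = df$property, value = val,
    unit = df$unit, censored = cens, stringsAsFactors = FALSE)
}

#' Write any stage result as tidy long-format CSV
#'
#' One row per (unit, metric, value). Numeric values are text-formatted
#' with 17 significant digits so that [readTidy()] reproduces them
#' bit-for-bit.
#'
#' @param x a data.frame (one row per unit, metrics in columns), or a
#'   named list/vector of scalars (a single unit).
#' @param path output CSV path.
#' @param unitCols character; column(s) identifying the unit. Defaults
#'   to the first column for data.frames.
#' @return `path`, invisibly.
#' @export
writeTidy <- function(x, path, unitCols = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(unit = "result", as.data.frame(x[!vapply(x, is.null, logical(1))]),
      check.names = FALSE, stringsAsFactors = FALSE)
    unitCols <- "unit"
  }
  x <- as.data.frame(x)
  if (is.null(unitCols)) unitCols <- names(x)[1]
  metrics <- setdiff(names(x), unitCols)
  fmt <- function(v) {
    if (is.double(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  rows <- list()
  unit <- if (length(unitCols) == 1L) as.character(x[[unitCols]])
    else do.call(paste, c(lapply(unitCols, function(u) as.character(x[[u]])), sep = ":"))
  if (nrow(x) > 0)
    for (j in seq_along(metrics)) {
      rows[[j]] <- data.frame(unit = unit, metric = metrics[j],
        value = fmt(x[[metrics[j]]]), stringsAsFactors = FALSE)
    }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = character(), metric = character(), value = character())
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a tidy long-format CSV written by [writeTidy()]
#'
#' @param path CSV path.
#' @param wide if `TRUE`, pivot back to one row per unit with one column
#'   per metric.
#' @return data.frame; in long form `value` is numeric where every entry
#'   of a metric parses as a number, character otherwise.
#' @export
readTidy <- function(path, wide = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("unit", "metric", "value") %in% names(df)))
    stop("not a tidy file: expected columns unit, metric, value")
  num <- suppressWarnings(as.numeric(df$value))
  df$value_num <- num
  if (!wide) {
    # one numeric column when everything parses, else keep text alongside
    return(df)
  }
  units <- unique(df$unit)
  metrics <- unique(df$metric)
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  for (m in metrics) {
    sub <- df[df$metric == m, ]
    v <- sub$value_num
    if (anyNA(v) && !all(is.na(v))) v <- sub$value
    if (all(is.na(v))) v <- sub$value
    out[[m]] <- v[match(units, sub$unit)]
  }
  out
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values that parse as numbers are returned numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("bad config line (no '='): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
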