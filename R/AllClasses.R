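#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
#' @importFrom utils head
NULL

#' One dark-adapted OJIP induction curve
#'
#' A single fast chlorophyll-fluorescence transient: fluorescence versus
#' time since the onset of the saturating flash, for one leaf sample.
#' Times are in microseconds and must be strictly increasing.
#'
#' @slot sampleId length-one character identifier.
#' @slot timeUs numeric vector of acquisition times in microseconds.
#' @slot fluorescence numeric vector of fluorescence values (arbitrary
#'   units), same length as `timeUs`.
#'
#' @exportClass FluorescenceTransient
setClass("FluorescenceTransient",
  slots = c(sampleId = "character", timeUs = "numeric", fluorescence = "numeric"))

setValidity("FluorescenceTransient", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (length(object@timeUs) != length(object@fluorescence))
    msg <- c(msg, "timeUs and fluorescence must have equal length")
  if (length(object@timeUs) > 1L && any(diff(object@timeUs) <= 0))
    msg <- c(msg, "timeUs must be strictly increasing")
  if (anyNA(object@timeUs) || anyNA(object@fluorescence))
    msg <- c(msg, "timeUs and fluorescence must not contain NA")
  if (length(msg)) msg else TRUE
})

#' A set of transients joined to the experimental design
#'
#' Container pairing [FluorescenceTransient-class] objects with the
#' sample design table (variety T/S crossed with soil N/A giving groups
#' TN, TA, SN, SA). Samples present in the data but absent from the
#' design (or vice versa) are tracked in `orphans`.
#'
#' @slot transients named list of `FluorescenceTransient` objects.
#' @slot design data.frame with columns `sample_id`, `variety`, `soil`,
#'   `group`.
#' @slot orphans character vector of unmatched sample ids.
#'
#' @exportClass TransientSet
setClass("TransientSet",
  slots = c(transients = "list", design = "data.frame", orphans = "character"))

setValidity("TransientSet", function(object) {
  msg <- character()
  ids <- names(object@transients)
  if (length(ids) != length(unique(ids)))
    msg <- c(msg, "transient sample ids must be unique")
  if (!all(vapply(object@transients, is, logical(1), "FluorescenceTransient")))
    msg <- c(msg, "all elements must be FluorescenceTransient objects")
  req <- c("sample_id", "variety", "soil", "group")
  if (!all(req %in% names(object@design)))
    msg <- c(msg, sprintf("design must have columns %s", paste(req, collapse = ", ")))
  else if (anyDuplicated(object@design$sample_id))
    msg <- c(msg, "design sample_ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Samples-by-taxa abundance table
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding a taxon
#' (row) by sample (column) count matrix in the `counts` assay, with the
#' semicolon-delimited taxonomy lineage and its parsed ranks in
#' `rowData` and the sample design factors (when attached) in `colData`.
#' User-facing orientation is samples x taxa via [abundanceMatrix()].
#'
#' @exportClass AbundanceTable
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an AbundanceTable needs a 'counts' assay")
  else {
    m <- assay(object, "counts")
    if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "rows (taxa) must be named by their lineage")
  if (is.null(colnames(object)))
    msg <- c(msg, "columns (samples) must be named")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FluorescenceTransient", function(object) {
  cat(sprintf("FluorescenceTransient '%s': %d points, %.0f-%.0f us, F in [%.1f, %.1f]\n",
    object@sampleId, length(object@timeUs),
    min(object@timeUs), max(object@timeUs),
    min(object@fluorescence), max(object@fluorescence)))
})

setMethod("show", "TransientSet", function(object) {
  cat(sprintf("TransientSet: %d transients, %d design rows, %d orphan id(s)\n",
    length(object@transients), nrow(object@design), length(object@orphans)))
  if (nrow(object@design))
    cat("  groups:", paste(sort(unique(object@design$group)), collapse = " "), "\n")
})
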