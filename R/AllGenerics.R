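#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname accessors
#' @export
setGeneric("transients", function(x) standardGeneric("transients"))

#' @rdname accessors
#' @export
setGeneric("orphanSamples", function(x) standardGeneric("orphanSamples"))

#' @rdname accessors
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' Accessors for jipbiome data containers
#'
#' `sampleIds()` returns sample identifiers; `sampleDesign()` the design
#' data.frame; `transients()` the named list of
#' [FluorescenceTransient-class] objects; `orphanSamples()` ids present
#' on only one side of the data/design join; `abundanceMatrix()` the
#' samples x taxa numeric matrix; `lineages()` the taxonomy lineage
#' strings.
#'
#' @param x a [TransientSet-class] or [AbundanceTable-class].
#' @return See above.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleIds", "TransientSet", function(x) names(x@transients))

#' @rdname accessors
setMethod("sampleDesign", "TransientSet", function(x) x@design)

#' @rdname accessors
setMethod("transients", "TransientSet", function(x) x@transients)

#' @rdname accessors
setMethod("orphanSamples", "TransientSet", function(x) x@orphans)

#' @rdname accessors
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

#' @rdname accessors
setMethod("sampleDesign", "AbundanceTable", function(x) {
  cd <- as.data.frame(colData(x))
  if (!nrow(cd) || !"group" %in% names(cd)) return(NULL)
  cd$sample_id <- colnames(x)
  rownames(cd) <- NULL
  cd[, c("sample_id", setdiff(names(cd), "sample_id"))]
})

#' @rdname accessors
setMethod("abundanceMatrix", "AbundanceTable", function(x) t(assay(x, "counts")))

#' @rdname accessors
setMethod("lineages", "AbundanceTable", function(x) rownames(x))
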