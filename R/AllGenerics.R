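#' Extract marker genes from a catalog
#'
#' @param x a \code{\link{MarkerCatalog}}.
#' @param level \code{"main"}, \code{"fine"}, or \code{NULL} for both.
#' @param cellType optional cell type(s) to restrict to.
#' @param source optional source tag(s) to restrict to.
#' @return character vector of gene symbols (unique, catalog order).
#' @export
setGeneric("markerGenes", function(x, level = NULL, cellType = NULL,
                                   source = NULL) standardGeneric("markerGenes"))

#' Catalog entry table
#'
#' @param x a \code{\link{MarkerCatalog}}.
#' @return the underlying \code{DataFrame} of entries.
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))

#' Marker specifications of a simulation configuration
#'
#' @param x a \code{\link{SimConfig}}.
#' @return the \code{data.frame} of planted-marker specifications.
#' @export
setGeneric("markerSpecs", function(x) standardGeneric("markerSpecs"))

#' Number of datasets described by an object
#'
#' @param x a \code{\link{SimConfig}}.
#' @return integer count.
#' @export
setGeneric("nDatasets", function(x) standardGeneric("nDatasets"))

#' @rdname markerGenes
#' @export
setMethod("markerGenes", "MarkerCatalog", function(x, level = NULL,
                                                   cellType = NULL,
                                                   source = NULL) {
  e <- x@entries
  keep <- rep(TRUE, nrow(e))
  if (!is.null(level)) keep <- keep & e$level %in% level
  if (!is.null(cellType)) keep <- keep & e$cell_type %in% cellType
  if (!is.null(source)) keep <- keep & e$source %in% source
  unique(e$gene[keep])
})

#' @rdname catalogEntries
#' @export
setMethod("catalogEntries", "MarkerCatalog", function(x) x@entries)

#' @rdname markerSpecs
#' @export
setMethod("markerSpecs", "SimConfig", function(x) x@markerSpecs)

#' @rdname nDatasets
#' @export
setMethod("nDatasets", "SimConfig", function(x) x@nDatasets)
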