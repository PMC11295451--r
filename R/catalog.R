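#' Construct a marker catalog
#'
#' @param entries data.frame or DataFrame with columns \code{level}
#'   (\code{"main"}/\code{"fine"}), \code{cell_type}, \code{gene},
#'   \code{source}.
#' @return a \code{\link{MarkerCatalog}}.
#' @examples
#' markerCatalog(data.frame(level = "main", cell_type = "epithelial",
#'                          gene = "KRT18", source = "literature"))
#' @export
markerCatalog <- function(entries) {
  e <- S4Vectors::DataFrame(as.data.frame(entries))
  methods::new("MarkerCatalog", entries = e)
}

#' Packaged catalog of human prostate cell-type markers
#'
#' Candidate markers of prostate main cell types (epithelial, stromal) and
#' fine cell types (luminal, basal, club, hillock, endothelial, fibroblast,
#' smooth muscle, pericyte) collected from the prostate scRNA-seq
#' literature.  Entries tagged \code{source == "screened"} form the
#' up-regulation-screened main panels: 8 epithelial and 26 stromal genes.
#'
#' @return a \code{\link{MarkerCatalog}}.
#' @examples
#' cat <- prostateMarkerCatalog()
#' length(markerGenes(cat, level = "main", source = "screened"))
#' @export
prostateMarkerCatalog <- function() {
  path <- system.file("extdata", "prostate_marker_catalog.tsv",
                      package = "scMarkerEval", mustWork = TRUE)
  readMarkerCatalog(path)
}

#' Read / write a marker catalog TSV
#'
#' The TSV has a header and columns \code{level}, \code{cell_type},
#' \code{gene}, \code{source}.
#'
#' @param path file path.
#' @return \code{readMarkerCatalog}: a \code{\link{MarkerCatalog}};
#'   \code{writeMarkerCatalog}: the path, invisibly.
#' @export
readMarkerCatalog <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  markerCatalog(e)
}

#' @rdname readMarkerCatalog
#' @param catalog a \code{\link{MarkerCatalog}}.
#' @export
writeMarkerCatalog <- function(catalog, path) {
  writeTSV(as.data.frame(catalogEntries(catalog)), path)
}

#' Catalog derived from a simulation's planted markers
#'
#' Builds the candidate catalog matching a \code{\link{SimConfig}}'s truth
#' table, so the evaluation pipeline can be run on synthetic datasets:
#' every planted marker becomes a catalog entry for its target type at its
#' declared level.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return a \code{\link{MarkerCatalog}} with \code{source == "planted"}.
#' @export
syntheticCatalog <- function(config) {
  ms <- markerSpecs(config)
  markerCatalog(data.frame(level = ms$level, cell_type = ms$target_type,
                           gene = ms$gene, source = "planted",
                           stringsAsFactors = FALSE))
}
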