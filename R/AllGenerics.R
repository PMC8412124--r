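#' Species label of an object
#' @param x a DETable, Regulon, RegulonDB or OrthologMap.
#' @return a single character species label (for [OrthologMap-class], the
#'   `c(from, to)` pair).
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' Upregulated genes of a DE table
#'
#' Genes with adjusted p below `alpha` and fold-change in the requested
#' direction. The default direction is "up" because the analysis targets genes
#' upregulated in the disease tissue; "down" and "both" are available.
#'
#' @param x a [DETable-class].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param direction one of `"up"`, `"down"`, `"both"`.
#' @return character vector of gene symbols.
#' @export
setGeneric("upregulated",
           function(x, alpha = 0.05, direction = c("up", "down", "both"))
             standardGeneric("upregulated"))

#' Expressed (tested) genes of a DE table
#'
#' The enrichment universe: every gene that received a DE test result.
#' @param x a [DETable-class].
#' @return character vector of gene symbols.
#' @export
setGeneric("expressedGenes", function(x) standardGeneric("expressedGenes"))

#' Target genes of a regulon
#' @param x a [Regulon-class].
#' @return character vector of target symbols.
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' TF symbol of a regulon
#' @param x a [Regulon-class].
#' @return the TF gene symbol.
#' @export
setGeneric("tfId", function(x) standardGeneric("tfId"))

#' Member gene sets of a collection
#' @param x a [GeneSetCollection-class].
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Ortholog pairs of a map
#' @param x an [OrthologMap-class].
#' @return `data.frame` with columns `from`, `to`.
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
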