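#' @import methods
NULL

#' Differential-expression table for one species
#'
#' Container for per-gene differential-expression records: gene symbol, log2
#' fold-change, multiplicity-adjusted p-value and per-condition mean expression
#' (FPKM). A gene is *tested* when it carries an adjusted p-value; genes that a
#' DE tool filtered out (adjusted p reported as `NA`) are kept with
#' `tested = FALSE` and never enter the expressed-gene universe. The universe of
#' expressed genes used throughout enrichment is the set of tested genes.
#'
#' @slot species species label, e.g. `"human"` or `"zebrafish"`.
#' @slot genes `data.frame` with columns `gene_id`, `log2fc`, `padj`, `tested`
#'   and zero or more `mean_<condition>` columns holding non-negative mean
#'   expression values.
#'
#' @seealso [DETable()], [upregulated()], [expressedGenes()]
#' @export
setClass("DETable", representation(species = "character", genes = "data.frame"))

setValidity("DETable", function(object) {
  g <- object@genes
  msgs <- character()
  need <- c("gene_id", "log2fc", "padj", "tested")
  miss <- setdiff(need, names(g))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(object@species) != 1L || !nzchar(object@species))
    msgs <- c(msgs, "species must be a single non-empty label")
  if (any(!nzchar(trimws(g$gene_id))))
    msgs <- c(msgs, "gene_id must be non-empty")
  dup <- unique(g$gene_id[duplicated(.symKey(g$gene_id))])
  if (length(dup))
    msgs <- c(msgs, paste("duplicated gene_id:", paste(dup, collapse = ", ")))
  bad <- !is.na(g$padj) & (g$padj < 0 | g$padj > 1)
  if (any(bad))
    msgs <- c(msgs, "padj must lie in [0, 1] when present")
  if (any(is.na(g$padj) & g$tested))
    msgs <- c(msgs, "tested genes must carry an adjusted p-value")
  for (cn in grep("^mean_", names(g), value = TRUE))
    if (any(g[[cn]] < 0, na.rm = TRUE))
      msgs <- c(msgs, paste(cn, "has negative mean expression"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a DETable
#'
#' @param genes `data.frame` with at least `gene_id`, `log2fc`, `padj`; a
#'   `tested` column is derived as `!is.na(padj)` when absent. Per-condition
#'   mean expression goes in `mean_<condition>` columns.
#' @param species species label.
#' @return A [DETable-class] object.
#' @examples
#' de <- DETable(data.frame(gene_id = c("A", "B"), log2fc = c(1.2, -0.3),
#'                          padj = c(0.01, NA)), species = "human")
#' upregulated(de)
#' @export
DETable <- function(genes, species) {
  genes <- as.data.frame(genes)
  if (is.null(genes$tested)) genes$tested <- !is.na(genes$padj)
  genes$gene_id <- as.character(genes$gene_id)
  rownames(genes) <- NULL
  new("DETable", species = as.character(species), genes = genes)
}

#' A transcription factor regulon
#'
#' The set of genes a transcription factor is inferred to regulate, as
#' catalogued from ChIP-type experiments (ChIP-chip, ChIP-Seq, ChIP-PET,
#' DamID). Target symbols are deduplicated case-insensitively at construction.
#'
#' @slot tfId gene symbol of the factor.
#' @slot targets character vector of target gene symbols (non-empty, unique).
#' @slot species species label.
#' @export
setClass("Regulon", representation(tfId = "character", targets = "character",
                                   species = "character"))

setValidity("Regulon", function(object) {
  if (length(object@tfId) != 1L || !nzchar(object@tfId))
    return("tfId must be a single non-empty symbol")
  if (length(object@targets) == 0L)
    return("a regulon must have at least one target")
  if (anyDuplicated(.symKey(object@targets)))
    return("duplicate target symbols")
  if (any(!nzchar(trimws(object@targets))))
    return("empty target symbol")
  TRUE
})

#' @rdname Regulon-class
#' @param tfId gene symbol of the factor.
#' @param targets character vector of target symbols.
#' @param species species label.
#' @export
Regulon <- function(tfId, targets, species) {
  new("Regulon", tfId = as.character(tfId),
      targets = .dedupSyms(as.character(targets)),
      species = as.character(species))
}

#' A database of regulons for one species
#'
#' @slot regulons named list of [Regulon-class] objects (names are TF symbols).
#' @slot species species label; every member regulon must carry the same label.
#' @export
setClass("RegulonDB", representation(regulons = "list", species = "character"))

setValidity("RegulonDB", function(object) {
  if (length(object@regulons)) {
    if (!all(vapply(object@regulons, is, TRUE, "Regulon")))
      return("all elements must be Regulon objects")
    sp <- vapply(object@regulons, function(r) r@species, "")
    if (!all(sp == object@species))
      return("regulon species must all equal the database species")
    ids <- vapply(object@regulons, function(r) r@tfId, "")
    if (!identical(unname(.symKey(ids)), .symKey(names(object@regulons))))
      return("list names must match regulon tfId")
  }
  TRUE
})

#' @rdname RegulonDB-class
#' @param regulons list of [Regulon-class] objects.
#' @param species species label.
#' @export
RegulonDB <- function(regulons = list(), species) {
  names(regulons) <- vapply(regulons, function(r) r@tfId, "")
  new("RegulonDB", regulons = regulons, species = as.character(species))
}

#' A collection of named gene sets
#'
#' Generic gene-set container used for pathway collections, GO slices and the
#' DNA-binding transcription-factor universe (GO:0003700-style membership
#' lists). Read from and written to Broad-dialect GMT.
#'
#' @slot sets named list of character vectors (set_id -> gene symbols).
#' @slot descriptions named character vector of set descriptions.
#' @slot kind one of `"pathway"`, `"GO-CC"`, `"GO-BP"`, `"GO-MF"`,
#'   `"TF-universe"`.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character",
                        kind = "character"))

.gscKinds <- c("pathway", "GO-CC", "GO-BP", "GO-MF", "TF-universe")

setValidity("GeneSetCollection", function(object) {
  if (!(object@kind %in% .gscKinds))
    return(paste("kind must be one of:", paste(.gscKinds, collapse = ", ")))
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("set ids must be unique and non-missing")
    if (any(vapply(object@sets, length, 1L) == 0L))
      return("each set must be non-empty")
  }
  TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param kind collection kind.
#' @param descriptions optional named character vector of descriptions.
#' @export
GeneSetCollection <- function(sets = list(), kind = "pathway",
                              descriptions = NULL) {
  sets <- lapply(sets, function(s) .dedupSyms(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
  }
  new("GeneSetCollection", sets = sets,
      descriptions = descriptions, kind = kind)
}

#' A gene-symbol ortholog map between two species
#'
#' One-to-many and many-to-one pairs are both allowed (BioMart-style exports
#' are many-to-many); duplicate pairs collapse under set semantics. A source
#' gene absent from the map (or with a blank destination) has no homolog.
#'
#' @slot fromSpecies,toSpecies species labels.
#' @slot pairs `data.frame` with character columns `from`, `to`.
#' @export
setClass("OrthologMap", representation(fromSpecies = "character",
                                       toSpecies = "character",
                                       pairs = "data.frame"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  if (!all(c("from", "to") %in% names(p)))
    return("pairs must have columns 'from' and 'to'")
  if (nrow(p)) {
    if (any(!nzchar(trimws(p$from))) || any(!nzchar(trimws(p$to))))
      return("ortholog symbols must be non-empty")
    if (anyDuplicated(paste(.symKey(p$from), .symKey(p$to), sep = "\r")))
      return("duplicate ortholog pairs")
  }
  TRUE
})

#' @rdname OrthologMap-class
#' @param pairs `data.frame` with columns `from` and `to`; blank destinations
#'   are dropped (no homolog) and duplicate pairs collapse.
#' @param fromSpecies,toSpecies species labels.
#' @export
OrthologMap <- function(pairs, fromSpecies, toSpecies) {
  pairs <- data.frame(from = as.character(pairs$from),
                      to = as.character(pairs$to))
  pairs <- pairs[nzchar(trimws(pairs$from)) & nzchar(trimws(pairs$to)), ,
                 drop = FALSE]
  pairs <- pairs[!duplicated(paste(.symKey(pairs$from), .symKey(pairs$to),
                                   sep = "\r")), , drop = FALSE]
  rownames(pairs) <- NULL
  new("OrthologMap", fromSpecies = as.character(fromSpecies),
      toSpecies = as.character(toSpecies), pairs = pairs)
}

#' Universe-calibration result
#'
#' Result of scanning candidate expressed-gene universe sizes N for
#' consistency with a published enrichment row (see [calibrateUniverse()]).
#'
#' @slot windows named list (one element per tail convention) of integer
#'   vectors: every N that reproduces the anchor p at its printed precision.
#' @slot NChosen midpoint of the widest contiguous window of the best-fitting
#'   convention, or `NA` when no N fits.
#' @slot convention the best-fitting tail convention (`"GE"` or `"GT"`).
#' @slot uninformative `TRUE` when the anchor constrains nothing (its window
#'   spans the whole scanned range, e.g. k = 0 with p = 1).
#' @export
setClass("CalibrationResult",
         representation(windows = "list", NChosen = "integer",
                        convention = "character", uninformative = "logical"))
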