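#' @describeIn DETable-class species label
#' @export
setMethod("species", "DETable", function(x) x@species)

#' @describeIn Regulon-class species label
#' @export
setMethod("species", "Regulon", function(x) x@species)

#' @describeIn RegulonDB-class species label
#' @export
setMethod("species", "RegulonDB", function(x) x@species)

#' @describeIn OrthologMap-class `c(from, to)` species labels
#' @export
setMethod("species", "OrthologMap",
          function(x) c(from = x@fromSpecies, to = x@toSpecies))

#' @describeIn DETable-class genes with adjusted p < `alpha` in the requested
#'   fold-change direction; monotone in `alpha`
#' @param alpha significance level on the adjusted p-value.
#' @param direction one of `"up"`, `"down"`, `"both"`.
#' @export
setMethod("upregulated", "DETable", function(x, alpha = 0.05,
                                             direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  g <- x@genes
  sig <- !is.na(g$padj) & g$padj < alpha
  keep <- switch(direction,
                 up   = sig & g$log2fc > 0,
                 down = sig & g$log2fc < 0,
                 both = sig & g$log2fc != 0)
  g$gene_id[keep & !is.na(keep)]
})

#' @describeIn DETable-class the expressed-gene universe (tested genes)
#' @export
setMethod("expressedGenes", "DETable", function(x)
  x@genes$gene_id[x@genes$tested])

#' @describeIn DETable-class number of genes in the table
#' @export
setMethod("length", "DETable", function(x) nrow(x@genes))

setMethod("show", "DETable", function(object) {
  g <- object@genes
  cat(sprintf("DETable [%s]: %d genes, %d tested, %d upregulated (padj < 0.05)\n",
              object@species, nrow(g), sum(g$tested),
              length(upregulated(object))))
})

#' @describeIn Regulon-class target symbols
#' @export
setMethod("targets", "Regulon", function(x) x@targets)

#' @describeIn Regulon-class TF symbol
#' @export
setMethod("tfId", "Regulon", function(x) x@tfId)

#' @describeIn Regulon-class number of targets
#' @export
setMethod("length", "Regulon", function(x) length(x@targets))

setMethod("show", "Regulon", function(object) {
  cat(sprintf("Regulon %s [%s]: %d targets\n", object@tfId, object@species,
              length(object@targets)))
})

#' @describeIn RegulonDB-class number of regulons
#' @export
setMethod("length", "RegulonDB", function(x) length(x@regulons))

#' @describeIn RegulonDB-class TF symbols
#' @export
setMethod("names", "RegulonDB", function(x) names(x@regulons))

#' @describeIn RegulonDB-class extract one regulon by TF symbol
#'   (case-insensitive) or position
#' @param i TF symbol or index.
#' @export
setMethod("[[", "RegulonDB", function(x, i) {
  if (is.character(i)) {
    hit <- match(.symKey(i), .symKey(names(x@regulons)))
    if (is.na(hit)) stop("no regulon for TF '", i, "'", call. = FALSE)
    i <- hit
  }
  x@regulons[[i]]
})

setMethod("show", "RegulonDB", function(object) {
  cat(sprintf("RegulonDB [%s]: %d regulons\n", object@species,
              length(object@regulons)))
  if (length(object@regulons)) {
    sz <- vapply(object@regulons, length, 1L)
    cat("  ", paste(sprintf("%s(%d)", names(sz)[seq_len(min(6, length(sz)))],
                            sz[seq_len(min(6, length(sz)))]), collapse = " "),
        if (length(sz) > 6) "...\n" else "\n")
  }
})

#' @describeIn GeneSetCollection-class member sets
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class number of sets
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set ids
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class extract one set by id or position
#' @param i set id or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection [%s]: %d sets\n", object@kind,
              length(object@sets)))
})

#' @describeIn OrthologMap-class the pair table
#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)

#' @describeIn OrthologMap-class number of pairs
#' @export
setMethod("length", "OrthologMap", function(x) nrow(x@pairs))

setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap %s -> %s: %d pairs (%d source genes)\n",
              object@fromSpecies, object@toSpecies, nrow(object@pairs),
              length(unique(.symKey(object@pairs$from)))))
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult\n")
  for (cv in names(object@windows)) {
    w <- object@windows[[cv]]
    cat(sprintf("  %s: %d consistent N%s\n", cv, length(w),
                if (length(w)) sprintf(" in [%d, %d]", min(w), max(w)) else ""))
  }
  if (is.na(object@NChosen)) cat("  no universe size fits the anchor\n")
  else cat(sprintf("  chosen N = %d (convention %s)%s\n", object@NChosen,
                   object@convention,
                   if (object@uninformative) " [uninformative anchor]" else ""))
})
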