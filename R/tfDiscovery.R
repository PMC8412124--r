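#' Select candidate transcription factors from differential-expression output
#'
#' Candidates are the genes that are (i) differentially expressed in the
#' requested direction at level `alpha`, (ii) annotated as DNA-binding
#' transcription factors (members of the supplied TF universe, a
#' GO:0003700-style list), and (iii) present in the regulon database, so that
#' their target sets can actually be tested. TFs of prior interest can be
#' forced into the candidate list even when not differentially expressed;
#' forced symbols absent from the regulon database are reported in the result,
#' never silently dropped.
#'
#' Candidates are ordered by descending mean expression (the maximum over the
#' table's `mean_<condition>` columns; `NA` when the table carries none), ties
#' broken by symbol.
#'
#' @param de a [DETable-class].
#' @param tfUniverse a [GeneSetCollection-class] of kind `"TF-universe"`; the
#'   union of its sets is the TF annotation.
#' @param db a [RegulonDB-class].
#' @param forced character vector of TF symbols to include regardless of
#'   differential expression.
#' @param alpha significance level on the adjusted p-value.
#' @param direction fold-change direction: `"up"` (default), `"down"`,
#'   `"both"`.
#' @return `data.frame` with columns `tf_id`, `log2fc`, `padj`, `mean_expr`,
#'   `in_regulon_db`, `forced`, plus an attribute `missing_forced` naming
#'   forced symbols absent from the regulon database (also raised as a
#'   warning).
#' @examples
#' de <- DETable(data.frame(gene_id = c("T1", "G1"), log2fc = c(2, 1),
#'                          padj = c(0.01, 0.01)), "human")
#' tfu <- GeneSetCollection(list(TF = "T1"), kind = "TF-universe")
#' db <- RegulonDB(list(Regulon("T1", c("A", "B"), "human")), "human")
#' selectCandidateTFs(de, tfu, db)
#' @export
selectCandidateTFs <- function(de, tfUniverse, db, forced = character(),
                               alpha = 0.05, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(is(de, "DETable"), is(tfUniverse, "GeneSetCollection"),
            is(db, "RegulonDB"))
  if (tfUniverse@kind != "TF-universe")
    stop("tfUniverse must be a collection of kind 'TF-universe'", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)

  up <- upregulated(de, alpha, direction)
  tfSyms <- .symKey(unlist(tfUniverse@sets, use.names = FALSE))
  dbSyms <- .symKey(names(db))
  deSig <- up[.symKey(up) %in% tfSyms & .symKey(up) %in% dbSyms]

  forced <- .dedupSyms(as.character(forced))
  forced <- forced[!(.symKey(forced) %in% .symKey(deSig))]
  inDb <- .symKey(forced) %in% dbSyms
  missingForced <- forced[!inDb]
  if (length(missingForced))
    warning("forced TF(s) absent from the regulon database: ",
            paste(missingForced, collapse = ", "), call. = FALSE)
  forcedKept <- forced[inDb]

  ids <- c(deSig, forcedKept)
  g <- de@genes
  hit <- match(.symKey(ids), .symKey(g$gene_id))
  meanCols <- grep("^mean_", names(g), value = TRUE)
  meanExpr <- if (length(meanCols))
    apply(g[hit, meanCols, drop = FALSE], 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  else rep(NA_real_, length(ids))
  out <- data.frame(tf_id = ids,
                    log2fc = g$log2fc[hit],
                    padj = g$padj[hit],
                    mean_expr = as.numeric(meanExpr),
                    in_regulon_db = rep(TRUE, length(ids)),
                    forced = c(rep(FALSE, length(deSig)),
                               rep(TRUE, length(forcedKept))))
  ord <- order(-ifelse(is.na(out$mean_expr), -Inf, out$mean_expr), out$tf_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_forced") <- missingForced
  out
}
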