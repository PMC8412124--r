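#' Over-representation analysis of a gene list against a set collection
#'
#' Hypergeometric upper-tail test of the query list against each set in the
#' collection, restricted to the supplied universe, with Benjamini-Hochberg
#' adjustment across all tested sets. Query genes outside the universe are
#' dropped with a warning; set members outside the universe do not count
#' towards K.
#'
#' @param query character vector of query gene symbols (e.g. upregulated
#'   genes).
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of background gene symbols (the expressed
#'   genes, matching the TF-enrichment universe).
#' @param convention tail convention, see [hypergeomUpperTail()].
#' @return `data.frame` with one row per set: `set_id`, `name`, `K_expressed`,
#'   `k_up`, `p`, `padj`, sorted ascending by `padj` then `p`.
#' @export
ora <- function(query, collection, universe, convention = "GE") {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- .dedupSyms(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  uk <- .symKey(universe)
  query <- .dedupSyms(as.character(query))
  out <- !( .symKey(query) %in% uk)
  if (any(out)) {
    warning("query gene(s) outside the universe dropped: ",
            paste(query[out], collapse = ", "), call. = FALSE)
    query <- query[!out]
  }
  qk <- .symKey(query)
  N <- length(uk); n <- length(qk)
  rows <- lapply(names(collection@sets), function(id) {
    sk <- .symKey(collection@sets[[id]])
    K <- sum(sk %in% uk)
    k <- sum(sk %in% qk)
    data.frame(set_id = id,
               name = unname(collection@descriptions[id]),
               K_expressed = K, k_up = k,
               p = hypergeomUpperTail(N, K, n, k, convention))
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res))
    return(data.frame(set_id = character(), name = character(),
                      K_expressed = integer(), k_up = integer(),
                      p = numeric(), padj = numeric()))
  res$padj <- bhAdjust(res$p)
  res <- res[order(res$padj, res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count TF regulon targets inside the top enriched pathways
#'
#' For each of the `topN` most enriched pathway rows and each TF in the
#' database, counts the genes that are simultaneously regulon targets, pathway
#' members and in the query (upregulated) set; a pathway is flagged for a TF
#' when that count exceeds 1. The per-TF summary is the number of top
#' pathways so flagged — the structural readout for a dominant regulator
#' whose targets recur across all top pathways.
#'
#' @param rows pathway rows from [ora()] (already sorted by `padj`).
#' @param db a [RegulonDB-class].
#' @param collection the [GeneSetCollection-class] the rows were computed from
#'   (needed to recover pathway membership).
#' @param up character vector of upregulated gene symbols.
#' @param topN number of top rows to annotate (default 20; clamped with a
#'   warning when fewer rows exist).
#' @return list with `rows` (the top rows with one `count_<TF>` and one
#'   `multiple_<TF>` column per TF) and `summary` (named integer vector: per
#'   TF, the number of top pathways with count > 1).
#' @export
tfPathwayCounts <- function(rows, db, collection, up, topN = 20L) {
  stopifnot(is(db, "RegulonDB"), is(collection, "GeneSetCollection"))
  if (topN > nrow(rows)) {
    warning("topN = ", topN, " exceeds available rows (", nrow(rows),
            "); clamped", call. = FALSE)
    topN <- nrow(rows)
  }
  top <- rows[seq_len(topN), , drop = FALSE]
  upk <- .symKey(up)
  for (tf in names(db)) {
    tk <- .symKey(targets(db[[tf]]))
    cnt <- vapply(top$set_id, function(id) {
      sk <- .symKey(collection@sets[[id]])
      sum(sk %in% tk & sk %in% upk)
    }, 1L)
    top[[paste0("count_", tf)]] <- unname(cnt)
    top[[paste0("multiple_", tf)]] <- unname(cnt > 1L)
  }
  summ <- vapply(names(db), function(tf)
    sum(top[[paste0("multiple_", tf)]]), 1L)
  list(rows = top, summary = summ)
}
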