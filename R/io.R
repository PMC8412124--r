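#' Read a differential-expression table
#'
#' Reads a tab-separated DE output (one gene per row, header required) into a
#' [DETable-class]. Rows without an adjusted p-value are kept with
#' `tested = FALSE`: DE tools report `NA` for independently filtered genes, and
#' such genes must not enter the expressed universe.
#'
#' @param path file path to a tab-separated table with a header row.
#' @param species species label to attach.
#' @param columnMap named character vector mapping the required names
#'   `gene_id`, `log2fc`, `padj` (and optionally `mean_<condition>` columns) to
#'   the column names used in the file. Defaults to identity.
#' @return a [DETable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tlog2fc\tpadj", "A\t1.5\t0.01", "B\t-0.2\t0.8"), f)
#' readDETable(f, species = "human")
#' @export
readDETable <- function(path, species, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (!is.null(columnMap)) {
    hit <- match(columnMap, names(raw))
    if (anyNA(hit))
      stop("columnMap names columns absent from the file: ",
           paste(columnMap[is.na(hit)], collapse = ", "), call. = FALSE)
    names(raw)[hit] <- names(columnMap)
  }
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("DE table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw$gene_id <- as.character(raw$gene_id)
  raw$log2fc <- as.numeric(raw$log2fc)
  raw$padj <- as.numeric(raw$padj)
  dup <- unique(raw$gene_id[duplicated(.symKey(raw$gene_id))])
  if (length(dup))
    stop("duplicated gene_id in DE table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  raw$tested <- !is.na(raw$padj)
  keep <- c(need, "tested", grep("^mean_", names(raw), value = TRUE))
  DETable(raw[keep], species = species)
}

#' Write a differential-expression table
#'
#' Inverse of [readDETable()]; round-trips all columns as tab-separated UTF-8.
#' @param de a [DETable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path) {
  stopifnot(is(de, "DETable"))
  utils::write.table(de@genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Broad-dialect GMT: one set per line,
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set collapse (case-insensitively).
#'
#' @param path GMT file path.
#' @param kind collection kind: `"pathway"`, `"GO-CC"`, `"GO-BP"`, `"GO-MF"` or
#'   `"TF-universe"`.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, kind = "pathway") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    sets[[f[1]]] <- .dedupSyms(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  GeneSetCollection(sets, kind = kind, descriptions = desc)
}

#' Write gene sets in GMT format
#' @param gsc a [GeneSetCollection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc@sets), function(id) {
    d <- gsc@descriptions[id]
    if (is.na(d)) d <- ""
    paste(c(id, d, gsc@sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' Tab-separated `source<TAB>destination` pairs (BioMart-style export). Rows
#' with a blank destination contribute no pair (the source gene has no
#' homolog); duplicate pairs collapse under set semantics.
#'
#' @param path file path.
#' @param fromSpecies,toSpecies species labels of the two columns.
#' @param header `TRUE` when the file carries a header row.
#' @return an [OrthologMap-class].
#' @export
readOrthologMap <- function(path, fromSpecies, toSpecies, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(OrthologMap(data.frame(from = character(), to = character()),
                       fromSpecies, toSpecies))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf > 2L))
    stop(sprintf("ortholog map format error at line %d: more than 2 columns",
                 which(nf > 2L)[1] + header), call. = FALSE)
  pairs <- data.frame(from = vapply(f, `[`, "", 1),
                      to = vapply(f, function(x) if (length(x) >= 2) x[2] else "", ""))
  OrthologMap(pairs, fromSpecies, toSpecies)
}

#' Write an ortholog map
#' @param map an [OrthologMap-class].
#' @param path output file path.
#' @param header write a `from<TAB>to` header line.
#' @return `path`, invisibly.
#' @export
writeOrthologMap <- function(map, path, header = FALSE) {
  stopifnot(is(map, "OrthologMap"))
  lines <- paste(map@pairs$from, map@pairs$to, sep = "\t")
  if (header) lines <- c("from\tto", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an enrichment result table
#'
#' Emits the per-TF enrichment rows as TSV with columns `tf_id`, `K_expressed`,
#' `k_up`, `n_up`, `N_universe`, `p`, `enriched`; p-values are formatted in
#' scientific notation with 3 significant digits.
#'
#' @param rows `data.frame` as returned by [enrichTFs()].
#' @param path output file path.
#' @param allowEmpty allow writing a header-only file for zero rows.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(rows, path, allowEmpty = FALSE) {
  need <- c("tf_id", "K_expressed", "k_up", "n_up", "N_universe", "p", "enriched")
  if (!all(need %in% names(rows)))
    stop("enrichment rows must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(rows) == 0L && !allowEmpty)
    stop("refusing to write an empty enrichment table (set allowEmpty = TRUE)",
         call. = FALSE)
  out <- rows[need]
  out$p <- formatC(out$p, format = "e", digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an enrichment table written by [writeEnrichmentTable()]
#' @param path file path.
#' @return `data.frame` with the enrichment columns (`p` numeric at the 3
#'   significant digits it was written with).
#' @export
readEnrichmentTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read an expression matrix with sample metadata
#'
#' The expression file is TSV with samples in rows (first column `sample_id`,
#' remaining columns one gene each, FPKM values); the metadata file is TSV with
#' columns `sample_id`, `group` and optionally `age` (years). Returns genes x
#' samples in the canonical Bioconductor orientation.
#'
#' @param path expression TSV (samples in rows).
#' @param metaPath sample metadata TSV.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `fpkm`
#'   and colData `group` (and `age` when present).
#' @export
readExpressionMatrix <- function(path, metaPath) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "sample_id")
    stop("expression table must start with a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample ids in expression table", call. = FALSE)
  m <- t(as.matrix(x[, -1, drop = FALSE]))
  colnames(m) <- x$sample_id
  meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("sample metadata must have columns sample_id and group", call. = FALSE)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata is missing samples present in the expression table",
         call. = FALSE)
  if (any(m < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  cd <- S4Vectors::DataFrame(group = meta$group, row.names = meta$sample_id)
  if ("age" %in% names(meta)) cd$age <- meta$age
  SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = m),
                                             colData = cd)
}

#' Write an expression matrix and its sample metadata
#' @param se a `SummarizedExperiment` with assay `fpkm` and colData `group`
#'   (and optionally `age`).
#' @param path expression TSV path (samples in rows).
#' @param metaPath metadata TSV path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path, metaPath) {
  m <- SummarizedExperiment::assay(se, "fpkm")
  out <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  meta <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
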