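#' Transfer a regulon to another species through an ortholog map
#'
#' The destination regulon is the union of all homologs of all source targets,
#' deduplicated. One-to-many homologs are all retained (BioMart exports are
#' many-to-many and no canonical-homolog rule is imposed); many-to-one pairs
#' collapse under set semantics, so the destination can be smaller than the
#' number of mapped source genes. The TF's own identity is mapped through the
#' same pairs when present (e.g. human SPI1 -> zebrafish spi1b is map content,
#' not code); a TF without a homolog keeps its source symbol.
#'
#' @param regulon a [Regulon-class]; its species must equal the map's source
#'   species.
#' @param map an [OrthologMap-class].
#' @return list with elements `regulon` (the transferred [Regulon-class], or
#'   `NULL` when no target has a homolog) and `report`, a list with
#'   `source_count`, `mapped_count` (source genes with >= 1 homolog),
#'   `expanded_count` (destination set size) and `dropped` (source genes with
#'   no homolog).
#' @examples
#' map <- OrthologMap(data.frame(from = c("A", "A", "B"),
#'                               to = c("a1", "a2", "b")), "human", "zebrafish")
#' transferRegulon(Regulon("TF", c("A", "B", "C"), "human"), map)$report
#' @export
transferRegulon <- function(regulon, map) {
  stopifnot(is(regulon, "Regulon"), is(map, "OrthologMap"))
  if (regulon@species != map@fromSpecies)
    stop(sprintf("species mismatch: regulon is '%s', map is from '%s'",
                 regulon@species, map@fromSpecies), call. = FALSE)
  pk <- .symKey(map@pairs$from)
  tk <- .symKey(regulon@targets)
  hits <- pk %in% tk
  dest <- .dedupSyms(map@pairs$to[hits])
  mappedSrc <- unique(pk[hits])
  dropped <- regulon@targets[!(tk %in% mappedSrc)]
  report <- list(source_count = length(regulon@targets),
                 mapped_count = length(mappedSrc),
                 expanded_count = length(dest),
                 dropped = dropped)
  if (!length(dest)) return(list(regulon = NULL, report = report))
  tfDest <- map@pairs$to[pk == .symKey(regulon@tfId)]
  newId <- if (length(tfDest)) tfDest[1] else regulon@tfId
  list(regulon = Regulon(newId, dest, map@toSpecies), report = report)
}

#' Transfer a whole regulon database across species
#'
#' Element-wise [transferRegulon()]; TFs whose destination regulon is empty
#' (no target has a homolog) are excluded with a warning.
#'
#' @param db a [RegulonDB-class] of the map's source species.
#' @param map an [OrthologMap-class].
#' @return list with `db` (the transferred [RegulonDB-class]) and `reports`
#'   (per-source-TF transfer reports, named by source TF symbol).
#' @export
transferDB <- function(db, map) {
  stopifnot(is(db, "RegulonDB"), is(map, "OrthologMap"))
  if (db@species != map@fromSpecies)
    stop(sprintf("species mismatch: database is '%s', map is from '%s'",
                 db@species, map@fromSpecies), call. = FALSE)
  res <- lapply(db@regulons, transferRegulon, map = map)
  reports <- lapply(res, `[[`, "report")
  regs <- lapply(res, `[[`, "regulon")
  empty <- vapply(regs, is.null, TRUE)
  if (any(empty))
    warning("regulon(s) with no mappable target dropped in transfer: ",
            paste(names(db)[empty], collapse = ", "), call. = FALSE)
  list(db = RegulonDB(regs[!empty], species = map@toSpecies),
       reports = reports)
}
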