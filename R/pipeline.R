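#' Convert a gene-set collection of regulons to a RegulonDB
#'
#' Regulon GMT files use the TF symbol as the set id and its targets as the
#' set members.
#' @param gsc a [GeneSetCollection-class].
#' @param species species label to attach.
#' @return a [RegulonDB-class].
#' @export
gmtToRegulonDB <- function(gsc, species) {
  stopifnot(is(gsc, "GeneSetCollection"))
  RegulonDB(lapply(names(gsc@sets), function(tf)
    Regulon(tf, gsc@sets[[tf]], species)), species = species)
}

#' Convert a RegulonDB to a gene-set collection (for GMT output)
#' @param db a [RegulonDB-class].
#' @return a [GeneSetCollection-class] of kind `"TF-universe"`.
#' @export
regulonDBToGMT <- function(db) {
  stopifnot(is(db, "RegulonDB"))
  GeneSetCollection(lapply(db@regulons, targets), kind = "TF-universe")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.defaultRunParams <- list(alpha = 0.05, tail = "GE", direction = "up",
                          rho_min = 0.70, p_max = 0.05, top_n = 20L,
                          forced = character(), seed = 20210330L)

#' Run the full regulon-discovery pipeline
#'
#' Orchestrates candidate-TF selection, regulon enrichment, cross-species
#' transfer and re-enrichment, TF-target correlation, and pathway
#' over-representation with regulon intersection, from a single config. All
#' stages are pure functions of the input files and parameters; a rerun with
#' the same config and seed writes byte-identical tables. Outputs are TSV
#' plus a JSON run manifest (input/output MD5 hashes, parameters, package
#' version) and a human-readable summary; logging goes to `stderr` so tables
#' never mix with messages.
#'
#' The config (YAML file or named list) understands: `species`, `de`,
#' `regulons` (GMT), `tf_universe` (GMT); optional `to_species`, `de_to`,
#' `ortholog_map`, `expression` + `sample_meta`, `pathways` (GMT), `tf` (TF
#' whose targets are correlated; default the top enriched TF); parameters
#' `alpha`, `tail`, `direction`, `rho_min`, `p_max`, `top_n`, `forced`,
#' `seed`; and `out_dir`.
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param outDir overrides the config's `out_dir`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results (`candidates`,
#'   `enrichment`, `enrichment_transferred`, `correlations`, `pathways`,
#'   `summary_lines`, `manifest`).
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  prm <- utils::modifyList(.defaultRunParams,
                           config[intersect(names(config),
                                            names(.defaultRunParams))])
  prm$forced <- as.character(prm$forced)
  outDir <- outDir %||% config$out_dir
  if (is.null(outDir)) stop("config must provide out_dir", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[regulonScan] ", ...)

  inPaths <- config[intersect(names(config),
                              c("de", "regulons", "tf_universe", "de_to",
                                "ortholog_map", "expression", "sample_meta",
                                "pathways"))]
  missing <- unlist(inPaths)[!file.exists(unlist(inPaths))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)

  species <- config$species %||% "human"
  de <- .stage("read-de", readDETable(config$de, species))
  db <- .stage("read-regulons",
               gmtToRegulonDB(readGMT(config$regulons, "TF-universe"), species))
  tfu <- .stage("read-tf-universe", readGMT(config$tf_universe, "TF-universe"))

  log("discover: selecting candidate TFs")
  cand <- .stage("discover",
                 selectCandidateTFs(de, tfu, db, forced = prm$forced,
                                    alpha = prm$alpha,
                                    direction = prm$direction))
  log("enrich: ", nrow(cand), " candidate TF(s)")
  enr <- .stage("enrich",
                enrichTFs(cand, db, de, alpha = prm$alpha,
                          convention = prm$tail, direction = prm$direction))

  enrTo <- NULL
  if (!is.null(config$ortholog_map) && !is.null(config$de_to)) {
    toSpecies <- config$to_species %||% "zebrafish"
    map <- .stage("read-map",
                  readOrthologMap(config$ortholog_map, species, toSpecies,
                                  header = isTRUE(config$ortholog_map_header)))
    deTo <- .stage("read-de-to", readDETable(config$de_to, toSpecies))
    log("transfer: mapping regulons to ", toSpecies)
    tr <- .stage("transfer", suppressWarnings(transferDB(db, map)))
    # destination ids of candidates whose transferred regulon survived
    candTo <- vapply(cand$tf_id, function(tf) {
      res <- transferRegulon(db[[tf]], map)
      if (is.null(res$regulon)) NA_character_ else tfId(res$regulon)
    }, "")
    candTo <- candTo[!is.na(candTo)]
    log("re-enrich: ", length(candTo), " transferred candidate(s)")
    enrTo <- .stage("re-enrich",
                    enrichTFs(unname(candTo), tr$db, deTo, alpha = prm$alpha,
                              convention = prm$tail,
                              direction = prm$direction))
  }

  corRes <- NULL
  if (!is.null(config$expression)) {
    expr <- .stage("read-expression",
                   readExpressionMatrix(config$expression, config$sample_meta))
    corTF <- config[["tf"]] %||% (if (nrow(enr)) enr$tf_id[1] else NULL)
    if (!is.null(corTF)) {
      log("correlate: ", corTF, " vs its targets")
      corRes <- .stage("correlate", suppressWarnings(
        correlateTFTargets(expr, corTF, targets(db[[corTF]]),
                           rhoMin = prm$rho_min, pMax = prm$p_max)))
    }
  }

  pwRes <- NULL
  if (!is.null(config$pathways)) {
    pwc <- .stage("read-pathways", readGMT(config$pathways, "pathway"))
    log("pathways: ORA over ", length(pwc), " sets")
    up <- upregulated(de, prm$alpha, prm$direction)
    pwRows <- .stage("pathway-ora", suppressWarnings(
      ora(up, pwc, expressedGenes(de), convention = prm$tail)))
    pwRes <- .stage("pathway-tf-counts", suppressWarnings(
      tfPathwayCounts(pwRows, db, pwc, up, topN = prm$top_n)))
  }

  # ---- outputs -------------------------------------------------------------
  wrote <- character()
  put <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    wrote <<- c(wrote, p)
    p
  }
  candOut <- cand
  attr(candOut, "missing_forced") <- NULL
  put(candOut, "candidates.tsv")
  pEnr <- file.path(outDir, sprintf("enrichment_%s.tsv", species))
  writeEnrichmentTable(enr, pEnr, allowEmpty = TRUE)
  wrote <- c(wrote, pEnr)
  if (!is.null(enrTo)) {
    pTo <- file.path(outDir, sprintf("enrichment_%s.tsv",
                                     config$to_species %||% "zebrafish"))
    writeEnrichmentTable(enrTo, pTo, allowEmpty = TRUE)
    wrote <- c(wrote, pTo)
  }
  if (!is.null(corRes)) put(corRes$rows, "correlations.tsv")
  if (!is.null(pwRes)) put(pwRes$rows, "pathways_top.tsv")

  hit <- enr$tf_id[enr$enriched]
  summaryLines <- c(
    sprintf("candidates: %d (%s)", nrow(cand),
            paste(cand$tf_id, collapse = ", ")),
    if (length(hit))
      sprintf("enriched TF regulons (p < 0.05): %s",
              paste(hit, collapse = ", "))
    else "no TF regulon enriched (p < 0.05)")
  if (!is.null(enrTo)) {
    hitTo <- enrTo$tf_id[enrTo$enriched]
    summaryLines <- c(summaryLines,
                      if (length(hitTo))
                        sprintf("conserved enrichment in %s: %s",
                                config$to_species %||% "zebrafish",
                                paste(hitTo, collapse = ", "))
                      else sprintf("no conserved enrichment in %s",
                                   config$to_species %||% "zebrafish"))
  }
  if (!is.null(corRes))
    summaryLines <- c(summaryLines,
                      sprintf("correlated targets (rho > %.2f, p < %.2g): %d of %d",
                              prm$rho_min, prm$p_max, corRes$n_passing,
                              nrow(corRes$rows)))
  if (!is.null(pwRes))
    summaryLines <- c(summaryLines,
                      sprintf("top-%d pathways with multiple targets: %s",
                              nrow(pwRes$rows),
                              paste(sprintf("%s=%d", names(pwRes$summary),
                                            pwRes$summary), collapse = ", ")))
  pSum <- file.path(outDir, "summary.txt")
  writeLines(summaryLines, pSum)
  wrote <- c(wrote, pSum)

  manifest <- list(
    tool = "regulonScan",
    version = as.character(utils::packageVersion("regulonScan")),
    parameters = prm,
    inputs = lapply(inPaths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(wrote, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done: ", length(wrote) + 1L, " files in ", outDir)
  invisible(list(candidates = cand, enrichment = enr,
                 enrichment_transferred = enrTo, correlations = corRes,
                 pathways = pwRes, summary_lines = summaryLines,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
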