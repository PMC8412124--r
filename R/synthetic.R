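#' Configuration for the planted-regulon simulator
#'
#' Defines the synthetic study: a gene universe, a set of planted TFs with
#' regulon sizes and enrichment odds, a two-group expression design, and an
#' ortholog map. Defaults emulate the scale of a cortical-tuber bulk RNA-seq
#' reanalysis: a ~17,000-gene expressed universe, 269 upregulated genes,
#' 12 case vs 10 control samples, and one dominant planted regulator with a
#' 600-gene regulon whose targets enter the upregulated set at odds 6.
#'
#' @param seed integer seed; every random draw in [generateDataset()] comes
#'   from this stream, so outputs are bit-reproducible per seed.
#' @param nGenes universe size (symbols beyond the planted TFs).
#' @param nUp number of upregulated genes to plant (among non-TF genes).
#' @param tfs `data.frame` with columns `tf_id`, `size` (regulon size) and
#'   `theta` (odds multiplier for a regulon gene to be upregulated; 1 = null).
#' @param nSamples named vector `c(case = , control = )`.
#' @param latentLoading correlation loading in `[0, 1)` linking a TF's
#'   standardized log-expression to its targets' log-expression. The implied
#'   large-sample Spearman correlation is `6/pi * asin(latentLoading / 2)`.
#' @param noiseSd log2-scale expression noise standard deviation.
#' @param orthologRetention probability that a gene has at least one homolog.
#' @param homologMultiplicity probability weights over 1..3 homologs for a
#'   retained gene.
#' @param species,toSpecies species labels for the generated data and map.
#' @return a validated config (class `syntheticConfig`).
#' @export
syntheticConfig <- function(seed = 20210330,
                            nGenes = 17000, nUp = 269,
                            tfs = data.frame(tf_id = "TF1", size = 600,
                                             theta = 6),
                            nSamples = c(case = 12, control = 10),
                            latentLoading = 0.8, noiseSd = 1,
                            orthologRetention = 0.7,
                            homologMultiplicity = c(0.80, 0.15, 0.05),
                            species = "human", toSpecies = "zebrafish") {
  stopifnot(is.data.frame(tfs),
            all(c("tf_id", "size", "theta") %in% names(tfs)))
  if (nUp >= nGenes) stop("nUp must be smaller than nGenes", call. = FALSE)
  if (any(tfs$theta <= 0)) stop("theta must be positive", call. = FALSE)
  if (latentLoading < 0 || latentLoading >= 1)
    stop("latentLoading must lie in [0, 1)", call. = FALSE)
  if (any(tfs$size >= nGenes))
    stop("regulon size must be smaller than nGenes", call. = FALSE)
  if (!all(c("case", "control") %in% names(nSamples)))
    stop("nSamples needs named entries 'case' and 'control'", call. = FALSE)
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 nUp = as.integer(nUp), tfs = tfs,
                 nSamples = nSamples, latentLoading = latentLoading,
                 noiseSd = noiseSd, orthologRetention = orthologRetention,
                 homologMultiplicity = homologMultiplicity /
                   sum(homologMultiplicity),
                 species = species, toSpecies = toSpecies),
            class = "syntheticConfig")
}

#' Generate a complete synthetic dataset with planted regulon structure
#'
#' Produces, from one seeded stream: (i) a gene universe; (ii) per-TF regulons
#' sampled uniformly at their configured sizes; (iii) an upregulated set of
#' exactly `nUp` genes in which each TF's regulon genes enter with odds
#' `theta` relative to background (successive weighted sampling without
#' replacement); (iv) a log-normal FPKM expression matrix in which each
#' target's log2-expression carries the configured loading on its TF's
#' standardized log2-expression, and upregulated genes receive their drawn
#' log2 fold-change as a case-group mean shift; (v) a DE table whose adjusted
#' p-values are below 0.05 exactly for the planted upregulated set (the DE
#' test itself is upstream of this pipeline and is not re-run); (vi) an
#' ortholog map drawn per retention/multiplicity; and (vii) a TF-universe and
#' a pathway gene-set collection.
#'
#' Planted TFs with `theta > 1` are themselves marked upregulated (an active
#' regulator is modelled as overexpressed, as for the dominant regulator the
#' defaults emulate); null TFs (`theta = 1`) are expressed but not
#' differentially expressed.
#'
#' @param cfg a [syntheticConfig()].
#' @param components character subset of
#'   `c("expression", "de", "regulons", "orthologs", "genesets")` to build;
#'   the remaining elements are returned as `NULL`. Restricting components
#'   changes nothing about what is generated for the ones requested.
#' @return list with elements `expr` (`SummarizedExperiment`), `de`
#'   ([DETable-class]), `db` ([RegulonDB-class]), `map`
#'   ([OrthologMap-class]), `tfUniverse` and `pathways`
#'   ([GeneSetCollection-class]), and `truth` (list: the planted upregulated
#'   set and per-TF regulons).
#' @export
generateDataset <- function(cfg,
                            components = c("expression", "de", "regulons",
                                           "orthologs", "genesets")) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  components <- match.arg(components, several.ok = TRUE)
  .withSeed(cfg$seed, {
    genes <- sprintf("g%05d", seq_len(cfg$nGenes))
    tfIds <- as.character(cfg$tfs$tf_id)
    allIds <- c(tfIds, genes)

    # (ii) regulons: uniform draws from the non-TF universe
    regs <- lapply(seq_len(nrow(cfg$tfs)), function(i)
      Regulon(tfIds[i], sample(genes, cfg$tfs$size[i]), cfg$species))
    names(regs) <- tfIds
    db <- RegulonDB(regs, species = cfg$species)

    # (iii) upregulated set: odds theta for regulon members (max over TFs)
    w <- rep(1, cfg$nGenes)
    for (i in seq_len(nrow(cfg$tfs))) {
      hit <- match(targets(regs[[i]]), genes)
      w[hit] <- pmax(w[hit], cfg$tfs$theta[i])
    }
    upTFs <- tfIds[cfg$tfs$theta > 1]
    if (cfg$nUp <= length(upTFs))
      stop("infeasible config: nUp must exceed the number of planted (theta > 1) TFs",
           call. = FALSE)
    upGenes <- sample(genes, cfg$nUp - length(upTFs), prob = w)
    up <- c(upTFs, upGenes)

    # DE quantities for every gene (drawn regardless of requested components
    # so that the stream stays aligned)
    lfc <- stats::rnorm(length(allIds), 0, 0.25)
    padj <- stats::runif(length(allIds), 0.05, 1)
    isUp <- allIds %in% up
    lfc[isUp] <- 0.4 + stats::rgamma(sum(isUp), shape = 2, scale = 0.6)
    padj[isUp] <- stats::runif(sum(isUp), 1e-8, 0.049)

    expr <- NULL
    mu <- stats::rnorm(length(allIds), mean = 3, sd = 1.5)
    if ("expression" %in% components) {
      ns <- sum(cfg$nSamples)
      caseIdx <- seq_len(cfg$nSamples[["case"]])
      z <- matrix(stats::rnorm(length(allIds) * ns), length(allIds), ns)
      lam <- cfg$latentLoading
      # TF rows keep their own noise as the latent factor
      for (i in seq_len(nrow(cfg$tfs))) {
        zt <- z[i, ]
        ti <- match(targets(regs[[i]]), allIds)
        z[ti, ] <- lam * matrix(zt, length(ti), ns, byrow = TRUE) +
          sqrt(1 - lam^2) * z[ti, ]
      }
      logexpr <- mu + cfg$noiseSd * z
      logexpr[isUp, caseIdx] <- logexpr[isUp, caseIdx] + lfc[isUp]
      m <- 2^logexpr
      dimnames(m) <- list(allIds, sprintf("s%02d", seq_len(ns)))
      cd <- S4Vectors::DataFrame(
        group = rep(c("case", "control"), cfg$nSamples[c("case", "control")]),
        age = round(stats::runif(ns, 1, 40), 1),
        row.names = colnames(m))
      expr <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = m), colData = cd)
    }

    de <- NULL
    if ("de" %in% components) {
      gm <- if (!is.null(expr)) {
        m <- SummarizedExperiment::assay(expr, "fpkm")
        grp <- SummarizedExperiment::colData(expr)$group
        data.frame(mean_case = rowMeans(m[, grp == "case", drop = FALSE]),
                   mean_control = rowMeans(m[, grp == "control", drop = FALSE]))
      } else data.frame(mean_case = 2^(mu + ifelse(isUp, lfc, 0)),
                        mean_control = 2^mu)
      de <- DETable(data.frame(gene_id = allIds, log2fc = lfc, padj = padj,
                               gm), species = cfg$species)
    }

    map <- NULL
    if ("orthologs" %in% components) {
      keep <- stats::runif(length(allIds)) < cfg$orthologRetention
      mult <- sample(1:3, length(allIds), replace = TRUE,
                     prob = cfg$homologMultiplicity)
      src <- rep(allIds[keep], mult[keep])
      suff <- unlist(lapply(mult[keep], function(k) c("", "b", "c")[seq_len(k)]),
                     use.names = FALSE)
      map <- OrthologMap(data.frame(from = src,
                                    to = paste0("z", tolower(src), suff)),
                         cfg$species, cfg$toSpecies)
    }

    tfUniverse <- NULL; pathways <- NULL
    if ("genesets" %in% components) {
      tfUniverse <- GeneSetCollection(list(DNA_BINDING_TF = tfIds),
                                      kind = "TF-universe")
      nPw <- 50L
      pw <- lapply(seq_len(nPw), function(i)
        sample(allIds, sample(30:150, 1)))
      names(pw) <- sprintf("PW%03d", seq_len(nPw))
      pathways <- GeneSetCollection(pw, kind = "pathway")
    }

    list(expr = expr, de = de,
         db = if ("regulons" %in% components) db else NULL,
         map = map, tfUniverse = tfUniverse, pathways = pathways,
         truth = list(upregulated = up,
                      regulons = lapply(regs, targets)))
  })
}
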