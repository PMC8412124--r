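# Published per-TF DE values and overlap counts used by the count-faithful
# fixture: log2 fold-change, adjusted p, targets among expressed genes (K) and
# among upregulated genes (k), per species. TFs without a catalogued regulon
# carry NA counts.
.t1Human <- data.frame(
  tf_id  = c("SPI1", "IRF8", "GBX2", "IKZF1", "TP53", "REL", "RELA", "RELB",
             "NFKB1", "NFKB2"),
  log2fc = c(1.607, 2.184, 3.360, 1.230, 0.268, -0.296, 0.074, 0.720, 0.340,
             0.508),
  padj   = c(0.016, 0.004, 0.039, 0.004, 0.967, 0.925, 0.998, 0.511, 0.860,
             0.752),
  K      = c(6020L, 754L, 185L, 101L, 3930L, NA, 870L, NA, NA, NA),
  k      = c(136L, 24L, 2L, 4L, 73L, NA, 36L, NA, NA, NA),
  fpkm   = c(17.91, 10.78, 1.18, 1.89, NA, NA, NA, NA, NA, NA))

.t1Zebrafish <- data.frame(
  tf_id  = c("spi1b", "irf8", "gbx2", "ikzf1", "tp53", "rel", "rela", "relb",
             "nfkb1", "nfkb2"),
  log2fc = c(1.431, 0.572, 0.017, 0.962, 0.572, -0.682, -0.694, 0.663, 0.032,
             0.288),
  padj   = c(0.041, 0.224, 0.986, 0.039, 0.010, 0.020, 0.431, 0.049, 0.983,
             0.332),
  K      = c(6170L, 720L, 197L, 143L, 4362L, NA, 967L, NA, NA, NA),
  k      = c(737L, 78L, 6L, 16L, 353L, NA, 117L, NA, NA, NA),
  fpkm   = NA_real_)

.t1UpCount <- c(human = 269L, zebrafish = 1820L)
.t1SharedUp <- 18L  # upregulated targets shared by the SPI1- and IRF8-like regulons

# allocate up-target and non-up-target index blocks for one species:
# the first TF (SPI1-like) and the second (IRF8-like) share `.t1SharedUp`
# upregulated targets; all other memberships are pairwise disjoint.
.t1Blocks <- function(tab) {
  has <- which(!is.na(tab$K))
  upBlocks <- list(); nonBlocks <- list()
  upPtr <- .t1SharedUp; nonPtr <- 0L
  for (j in seq_along(has)) {
    i <- has[j]
    kUp <- tab$k[i]; kNon <- tab$K[i] - tab$k[i]
    if (j <= 2L) {  # SPI1-like and IRF8-like carry the shared prefix
      own <- kUp - .t1SharedUp
      upBlocks[[tab$tf_id[i]]] <- c(seq_len(.t1SharedUp),
                                    upPtr + seq_len(own))
      upPtr <- upPtr + own
    } else {
      upBlocks[[tab$tf_id[i]]] <- upPtr + seq_len(kUp)
      upPtr <- upPtr + kUp
    }
    nonBlocks[[tab$tf_id[i]]] <- nonPtr + seq_len(kNon)
    nonPtr <- nonPtr + kNon
  }
  list(up = upBlocks, non = nonBlocks, upUsed = upPtr, nonUsed = nonPtr)
}

.t1Species <- function(tab, nUp, N, prefix, speciesLabel) {
  tfUp <- !is.na(tab$padj) & tab$padj < 0.05 & tab$log2fc > 0
  nSynUp <- nUp - sum(tfUp)
  blocks <- .t1Blocks(tab)
  nSynNon <- N - nrow(tab) - nSynUp
  if (blocks$upUsed > nSynUp || blocks$nonUsed > nSynNon)
    stop("universe size ", N, " is too small to satisfy the printed counts",
         call. = FALSE)
  upSyn <- sprintf("%sU%05d", prefix, seq_len(nSynUp))
  nonSyn <- sprintf("%sB%05d", prefix, seq_len(nSynNon))
  regs <- lapply(names(blocks$up), function(tf)
    Regulon(tf, c(upSyn[blocks$up[[tf]]], nonSyn[blocks$non[[tf]]]),
            speciesLabel))
  names(regs) <- names(blocks$up)
  genes <- data.frame(
    gene_id = c(tab$tf_id, upSyn, nonSyn),
    log2fc = c(tab$log2fc, rep(1.5, nSynUp), rep(0, nSynNon)),
    padj = c(tab$padj, rep(0.01, nSynUp), rep(0.5, nSynNon)),
    mean_case = c(tab$fpkm, rep(8, nSynUp), rep(5, nSynNon)))
  list(de = DETable(genes, speciesLabel),
       db = RegulonDB(regs, speciesLabel),
       upSyn = upSyn, blocks = blocks)
}

# pair one human index block with one zebrafish block so that the image of the
# human block is exactly the zebrafish block (cyclic reuse absorbs size
# differences in either direction: surplus destinations become one-to-many
# pairs, surplus sources become many-to-one)
.t1PairBlocks <- function(hSyms, zSyms) {
  h <- length(hSyms); z <- length(zSyms)
  if (h == 0L || z == 0L) return(NULL)
  if (z >= h)
    data.frame(from = hSyms[((seq_len(z) - 1L) %% h) + 1L], to = zSyms)
  else
    data.frame(from = hSyms, to = zSyms[((seq_len(h) - 1L) %% z) + 1L])
}

#' Count-faithful two-species fixture shaped like a published enrichment table
#'
#' Builds fully synthetic human and zebrafish DE tables and regulon databases
#' whose overlap counts exactly match a published TF-enrichment table: the
#' human table has 269 upregulated genes with per-TF (expressed, upregulated)
#' target counts (6020, 136), (754, 24), (185, 2), (101, 4), (3930, 73),
#' (870, 36); the zebrafish table has 1820 upregulated genes with counts
#' (6170, 737), (720, 78), (197, 6), (143, 16), (4362, 353), (967, 117); and
#' 18 of the 24 upregulated IRF8-like targets are also SPI1-like targets. The
#' TF rows themselves carry the published log2 fold-changes and adjusted
#' p-values, so candidate selection recovers the four upregulated database TFs.
#'
#' The fixture also builds an ortholog map under which transferring the human
#' database reproduces the zebrafish database exactly (one-to-many and
#' many-to-one pairs absorb the size differences), and a TF-universe
#' collection in which exactly 24 upregulated human genes appear.
#'
#' Target symbols are synthetic; only the TF symbols and the printed counts
#' are data. Universe sizes default to the values calibrated from the
#' published anchor rows (see [calibrateUniverse()]) but any size large
#' enough to hold the counts is valid — the overlap counts do not depend
#' on it.
#'
#' @param NHuman,NZebrafish expressed-gene universe sizes.
#' @return list with `human` and `zebrafish` (each `list(de, db)`), `map`
#'   (human -> zebrafish [OrthologMap-class]) and `tfUniverse`.
#' @export
table1Fixture <- function(NHuman = 16997, NZebrafish = 20475) {
  hu <- .t1Species(.t1Human, .t1UpCount[["human"]], NHuman, "H", "human")
  zf <- .t1Species(.t1Zebrafish, .t1UpCount[["zebrafish"]], NZebrafish, "z",
                   "zebrafish")

  # ortholog map: TF identities plus per-regulon block pairing; the shared
  # 18-gene prefix maps one-to-one so both regulon images stay exact
  pairs <- list(data.frame(from = .t1Human$tf_id, to = .t1Zebrafish$tf_id))
  shared <- data.frame(from = hu$upSyn[seq_len(.t1SharedUp)],
                       to = zf$upSyn[seq_len(.t1SharedUp)])
  pairs <- c(pairs, list(shared))
  for (tf in names(hu$blocks$up)) {
    ztf <- .t1Zebrafish$tf_id[match(tf, .t1Human$tf_id)]
    hUp <- setdiff(hu$blocks$up[[tf]], seq_len(.t1SharedUp))
    zUp <- setdiff(zf$blocks$up[[ztf]], seq_len(.t1SharedUp))
    hTarg <- c(hu$upSyn[hUp],
               targets(hu$db[[tf]])[!(targets(hu$db[[tf]]) %in% hu$upSyn)])
    zTarg <- c(zf$upSyn[zUp],
               targets(zf$db[[ztf]])[!(targets(zf$db[[ztf]]) %in% zf$upSyn)])
    pairs <- c(pairs, list(.t1PairBlocks(hTarg, zTarg)))
  }
  map <- OrthologMap(do.call(rbind, pairs), "human", "zebrafish")

  # GO:0003700-style TF universe: the TF symbols plus 20 further upregulated
  # genes, so exactly 24 upregulated genes fall in the term
  goSet <- c(.t1Human$tf_id, hu$upSyn[seq(length(hu$upSyn) - 19L,
                                          length(hu$upSyn))])
  tfUniverse <- GeneSetCollection(list(DNA_BINDING_TF_ACTIVITY = goSet),
                                  kind = "TF-universe")
  list(human = list(de = hu$de, db = hu$db),
       zebrafish = list(de = zf$de, db = zf$db),
       map = map, tfUniverse = tfUniverse)
}
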