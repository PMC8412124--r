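# Independent oracles and small fixture builders shared by the suite.

# all n! permutations of 1..n (insertion construction)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

# hypergeometric tail by exhaustive enumeration of all C(N, n) draws:
# the universe is 1..N with 1..K annotated; count draws whose overlap with the
# annotated items meets the tail condition
enumHyperTail <- function(N, K, n, k, convention = "GE") {
  if (n == 0L) {
    ov <- 0L
    hit <- if (convention == "GE") ov >= k else ov > k
    return(as.numeric(hit))
  }
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  if (convention == "GE") mean(ov >= k) else mean(ov > k)
}

# two-sided exact Spearman p by brute-force enumeration of all n! permutations
bruteSpearmanP <- function(rho, n) {
  perms <- allPermutations(n)
  S <- rowSums((perms - matrix(seq_len(n), nrow(perms), n, byrow = TRUE))^2)
  rhoPerm <- 1 - 6 * S / (n * (n^2 - 1))
  mean(abs(rhoPerm) >= abs(rho) - 1e-9)
}

# quick DE table: `up` genes significant-positive, `flat` genes tested null,
# `untested` genes without an adjusted p
makeDE <- function(up = character(), flat = character(),
                   untested = character(), species = "human",
                   meanExpr = NULL) {
  ids <- c(up, flat, untested)
  g <- data.frame(gene_id = ids,
                  log2fc = c(rep(2, length(up)), rep(0.1, length(flat)),
                             rep(0, length(untested))),
                  padj = c(rep(0.01, length(up)), rep(0.6, length(flat)),
                           rep(NA_real_, length(untested))))
  if (!is.null(meanExpr)) g$mean_case <- meanExpr
  DETable(g, species = species)
}

# small expression SummarizedExperiment from a genes x samples matrix
makeExpr <- function(m, group = NULL, age = NULL) {
  if (is.null(group)) group <- rep("case", ncol(m))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  cd <- S4Vectors::DataFrame(group = group, row.names = colnames(m))
  if (!is.null(age)) cd$age <- age
  SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = m),
                                             colData = cd)
}
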