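#' Spearman rank correlation coefficient
#'
#' Pearson correlation of midranks (average ranks for ties). A constant vector
#' has no defined rank correlation and is an error.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return the rank correlation in `[-1, 1]`.
#' @examples
#' spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

# exact null frequency table of S = sum of squared rank differences for
# tie-free ranks 1..n: subset-sum dynamic program over which ranks occupy the
# first `pos` positions. Equivalent to enumerating all n! permutations; cached
# per n for the session.
.spearmanNullCache <- new.env(parent = emptyenv())

.spearmanNullFreq <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearmanNullCache[[key]])) return(.spearmanNullCache[[key]])
  Smax <- n * (n^2 - 1) / 3
  nMask <- bitwShiftL(1L, n)
  dp <- matrix(0, nMask, Smax + 1)
  dp[1, 1] <- 1
  pc <- vapply(0:(nMask - 1L), function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L), 1L)
  for (m in (0:(nMask - 1L))[order(pc)]) {
    if (m == 0L) next
    pos <- pc[m + 1L]
    for (j in 0:(n - 1L)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(m, bit) > 0L) {
        d2 <- (pos - (j + 1L))^2
        prev <- m - bit
        if (d2 <= Smax)
          dp[m + 1L, (d2 + 1L):(Smax + 1L)] <-
            dp[m + 1L, (d2 + 1L):(Smax + 1L)] + dp[prev + 1L, 1:(Smax + 1L - d2)]
      }
    }
  }
  freq <- dp[nMask, ]
  .spearmanNullCache[[key]] <- freq
  freq
}

#' P-value for a Spearman correlation
#'
#' Two-sided p-value P(|rho_perm| >= |rho|). In `"exact"` mode the full
#' permutation null of the rank statistic is used: the distribution of
#' S = sum of squared rank differences over all n! permutations of tie-free
#' ranks, computed by an exact dynamic program (identical to exhaustive
#' enumeration, feasible well beyond the n where enumeration stops being
#' interactive). Exact mode covers n <= `maxExact` (default 10); larger n
#' require a Monte-Carlo permutation sample (`nPerm`) or `"approx"` mode, the
#' usual two-sided t approximation with t = rho*sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom.
#'
#' The exact null assumes tie-free ranks; callers with tied data should use
#' the approximation (see [correlateTFTargets()], which does this fallback
#' automatically).
#'
#' @param rho observed rank correlation.
#' @param n number of paired samples (>= 3).
#' @param mode `"exact"` or `"approx"`.
#' @param nPerm optional Monte-Carlo sample size for exact mode with large n.
#' @param maxExact largest n for which the full exact null is computed.
#' @return two-sided p-value in `(0, 1]` (Monte-Carlo uses the add-one
#'   estimator `(1 + hits) / (1 + nPerm)`).
#' @examples
#' spearmanP(1, 3, "exact")   # 2/6: of 3! permutations, |rho| = 1 twice
#' @export
spearmanP <- function(rho, n, mode = c("exact", "approx"), nPerm = NULL,
                      maxExact = 10L) {
  mode <- match.arg(mode)
  .assertScalarNumber(rho, "rho"); .assertScalarNumber(n, "n")
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (abs(rho) > 1 + 1e-12) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (mode == "approx") {
    r <- min(max(rho, -1), 1)
    if (abs(r) == 1) return(2 * stats::pt(-Inf, n - 2))  # 0-adjacent; never > 1
    t <- r * sqrt((n - 2) / (1 - r^2))
    return(min(1, 2 * stats::pt(-abs(t), n - 2)))
  }
  if (n <= maxExact) {
    freq <- .spearmanNullFreq(n)
    Smax <- n * (n^2 - 1) / 3
    S <- seq(0, Smax)
    rhoPerm <- 1 - 6 * S / (n * (n^2 - 1))
    hits <- abs(rhoPerm) >= abs(rho) - 1e-9
    return(sum(freq[hits]) / factorial(n))
  }
  if (is.null(nPerm))
    stop("exact mode with n > ", maxExact,
         " requires a Monte-Carlo sample size (nPerm)", call. = FALSE)
  r0 <- seq_len(n)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    rp <- stats::cor(r0, sample(n))
    if (abs(rp) >= abs(rho) - 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (1 + nPerm)
}

# shared worker: correlation row for one gene pair / gene-covariate pair
.corRow <- function(a, b, x, y, mode = c("auto", "exact", "approx"),
                    maxExact = 10L) {
  mode <- match.arg(mode)
  n <- length(x)
  rho <- spearmanRho(x, y)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  useExact <- switch(mode,
                     exact = TRUE, approx = FALSE,
                     auto = !ties && n <= maxExact)
  if (useExact && ties) {
    warning("tied ranks: falling back to the t approximation", call. = FALSE)
    useExact <- FALSE
  }
  p <- spearmanP(rho, n, if (useExact) "exact" else "approx")
  data.frame(gene_a = a, gene_b = b, rho = rho, p = p, n = n,
             method = if (useExact) "exact-permutation" else "t-approximation")
}

#' Correlate a TF's expression with its target genes
#'
#' Spearman correlation of the TF's expression with each target across all
#' samples, plus the count of targets passing a one-sided rho threshold
#' (rho > `rhoMin`, as such filters are conventionally printed) together with
#' a two-sided p-value below `pMax`.
#'
#' @param expr a `SummarizedExperiment` with assay `fpkm` (genes x samples),
#'   e.g. from [readExpressionMatrix()] or [generateDataset()].
#' @param tf TF gene symbol; must be present in `expr` (error otherwise).
#' @param targetSet character vector of target symbols; absent targets are
#'   skipped with a warning.
#' @param rhoMin one-sided rho threshold (default 0.70).
#' @param pMax p-value threshold (default 0.05).
#' @param mode p-value mode per pair: `"auto"` (exact when tie-free and
#'   n <= 10, else t approximation), `"exact"`, `"approx"`.
#' @return list with `rows` (one correlation row per present target) and
#'   `n_passing`.
#' @export
correlateTFTargets <- function(expr, tf, targetSet, rhoMin = 0.70,
                               pMax = 0.05, mode = "auto") {
  m <- SummarizedExperiment::assay(expr, "fpkm")
  rk <- .symKey(rownames(m))
  ti <- match(.symKey(tf), rk)
  if (is.na(ti)) stop("TF '", tf, "' absent from the expression matrix",
                      call. = FALSE)
  targetSet <- .dedupSyms(as.character(targetSet))
  hit <- match(.symKey(targetSet), rk)
  if (anyNA(hit))
    warning("target(s) absent from the expression matrix skipped: ",
            paste(targetSet[is.na(hit)], collapse = ", "), call. = FALSE)
  present <- targetSet[!is.na(hit)]
  hit <- hit[!is.na(hit)]
  xv <- m[ti, ]
  rows <- do.call(rbind, c(lapply(seq_along(hit), function(j)
    .corRow(tf, present[j], xv, m[hit[j], ], mode)),
    list(make.row.names = FALSE)))
  if (is.null(rows))
    rows <- data.frame(gene_a = character(), gene_b = character(),
                       rho = numeric(), p = numeric(), n = integer(),
                       method = character())
  list(rows = rows, n_passing = sum(rows$rho > rhoMin & rows$p < pMax))
}

#' Correlate a gene's expression with a sample covariate within one group
#'
#' Spearman correlation of expression with a per-sample covariate (typically
#' age in years) restricted to samples of one group label.
#'
#' @param expr a `SummarizedExperiment` with assay `fpkm` and the covariate in
#'   `colData`.
#' @param gene gene symbol.
#' @param covariate colData column name (default `"age"`).
#' @param group group label selecting the samples (matched against the
#'   `group` colData column).
#' @param mode p-value mode as in [correlateTFTargets()].
#' @return a one-row correlation `data.frame` (`gene_a`, `gene_b` = covariate
#'   name, `rho`, `p`, `n`, `method`).
#' @export
correlateCovariate <- function(expr, gene, covariate = "age", group,
                               mode = "auto") {
  cd <- SummarizedExperiment::colData(expr)
  if (!(covariate %in% names(cd)))
    stop("covariate '", covariate, "' absent from sample metadata",
         call. = FALSE)
  sel <- which(cd$group == group)
  if (length(sel) < 3L)
    stop("group '", group, "' has fewer than 3 samples", call. = FALSE)
  cv <- cd[[covariate]][sel]
  if (anyNA(cv))
    stop("missing '", covariate, "' for sample(s): ",
         paste(rownames(cd)[sel][is.na(cv)], collapse = ", "), call. = FALSE)
  m <- SummarizedExperiment::assay(expr, "fpkm")
  gi <- match(.symKey(gene), .symKey(rownames(m)))
  if (is.na(gi)) stop("gene '", gene, "' absent from the expression matrix",
                      call. = FALSE)
  .corRow(gene, covariate, m[gi, sel], as.numeric(cv), mode)
}
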