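#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing an overlap at least (`"GE"`, the standard
#' over-representation tail, P(X >= k)) or strictly greater than (`"GT"`,
#' P(X > k)) the observed count `k`, when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#'
#' The sum is accumulated in log space from `log`-scale point masses, so tails
#' far below 1e-20 retain full relative precision. Under `"GT"` with
#' `k = min(K, n)` the empty sum returns exactly 0 — the only case in which a
#' 0 is produced.
#'
#' @param N universe size.
#' @param K number of annotated genes in the universe.
#' @param n draw (query) size.
#' @param k observed overlap.
#' @param convention `"GE"` (default) or `"GT"`.
#' @return the tail probability in `[0, 1]`.
#' @examples
#' hypergeomUpperTail(10, 5, 4, 4)           # 5/210
#' hypergeomUpperTail(10, 5, 4, 0)           # 1
#' @export
hypergeomUpperTail <- function(N, K, n, k, convention = c("GE", "GT")) {
  convention <- match.arg(convention)
  for (v in c("N", "K", "n", "k")) .assertScalarNumber(get(v), v)
  if (k < 0) stop("domain error: k >= 0 violated", call. = FALSE)
  if (K > N) stop("domain error: K <= N violated", call. = FALSE)
  if (n > N) stop("domain error: n <= N violated", call. = FALSE)
  if (k > min(K, n)) stop("domain error: k <= min(K, n) violated", call. = FALSE)
  lo <- if (convention == "GE") k else k + 1
  hi <- min(K, n)
  if (lo > hi) return(0)
  if (lo <= 0) return(1)  # the whole sample space, exactly
  i <- seq.int(lo, hi)
  p <- exp(.logSumExp(stats::dhyper(i, K, N - K, n, log = TRUE)))
  min(p, 1)
}

#' Overlap of a regulon with the expressed and upregulated gene sets
#'
#' @param regulon a [Regulon-class]; its species must match the DE table's.
#' @param de a [DETable-class].
#' @param alpha significance level defining the upregulated set.
#' @param direction fold-change direction, as in [upregulated()].
#' @return named integer vector `c(K_expressed, k_up)`: targets among expressed
#'   genes and among upregulated genes (case-insensitive symbol matching).
#' @export
regulonOverlap <- function(regulon, de, alpha = 0.05, direction = "up") {
  stopifnot(is(regulon, "Regulon"), is(de, "DETable"))
  if (regulon@species != de@species)
    stop(sprintf("species mismatch: regulon is '%s', DE table is '%s'",
                 regulon@species, de@species), call. = FALSE)
  tk <- .symKey(regulon@targets)
  c(K_expressed = sum(tk %in% .symKey(expressedGenes(de))),
    k_up = sum(tk %in% .symKey(upregulated(de, alpha, direction))))
}

#' Hypergeometric enrichment of candidate TF regulons
#'
#' For each candidate TF, tests whether its regulon's targets are
#' over-represented among the upregulated genes relative to the expressed-gene
#' universe. A TF is flagged `enriched` at p < 0.05; no correction across TFs
#' is applied at this stage (multiplicity correction belongs to the pathway
#' overlay, which tests hundreds of sets).
#'
#' @param candidates character vector of TF symbols, or the `data.frame`
#'   returned by [selectCandidateTFs()]. Every candidate must have a regulon in
#'   `db`.
#' @param db a [RegulonDB-class].
#' @param de a [DETable-class] of the same species.
#' @param alpha significance level defining the upregulated set.
#' @param convention tail convention, see [hypergeomUpperTail()].
#' @param direction fold-change direction.
#' @return `data.frame` with one row per TF, columns `tf_id`, `K_expressed`,
#'   `k_up`, `n_up`, `N_universe`, `p`, `enriched`, sorted by ascending p.
#' @export
enrichTFs <- function(candidates, db, de, alpha = 0.05,
                      convention = c("GE", "GT"), direction = "up") {
  convention <- match.arg(convention)
  stopifnot(is(db, "RegulonDB"), is(de, "DETable"))
  if (is.data.frame(candidates)) candidates <- candidates$tf_id
  candidates <- as.character(candidates)
  missing <- candidates[!(.symKey(candidates) %in% .symKey(names(db)))]
  if (length(missing))
    stop("candidate TF(s) without a regulon in the database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  N <- length(expressedGenes(de))
  nUp <- length(upregulated(de, alpha, direction))
  rows <- lapply(candidates, function(tf) {
    ov <- regulonOverlap(db[[tf]], de, alpha, direction)
    p <- hypergeomUpperTail(N, ov[["K_expressed"]], nUp, ov[["k_up"]],
                            convention)
    data.frame(tf_id = tf, K_expressed = ov[["K_expressed"]],
               k_up = ov[["k_up"]], n_up = nUp, N_universe = N, p = p,
               enriched = p < 0.05)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(tf_id = character(), K_expressed = integer(),
                      k_up = integer(), n_up = integer(),
                      N_universe = integer(), p = numeric(),
                      enriched = logical())
  out[order(out$p, out$tf_id), , drop = FALSE]
}

# does a computed p round to the printed value at `digits` significant digits?
.roundsTo <- function(p, printed, digits) {
  s <- signif(p, digits)
  abs(s - printed) <= 1e-9 * max(printed, .Machine$double.xmin)
}

# count significant digits in a printed number given as a string
.printedDigits <- function(x) {
  mant <- sub("^[+-]?", "", sub("[eE].*$", "", trimws(x)))
  digs <- gsub("[^0-9]", "", mant)
  digs <- sub("^0+", "", digs)
  max(nchar(digs), 1L)
}

#' Calibrate the expressed-gene universe size from a printed enrichment row
#'
#' Published enrichment tables often print the annotated-target count K, the
#' overlap k, the query size n and the p-value — but not the size N of the
#' expressed-gene universe the test was run against. This scans candidate N
#' over a plausible transcriptome range and returns every N at which the
#' recomputed tail probability rounds to the printed p at its printed
#' precision, for each requested tail convention. The chosen N is the midpoint
#' of the widest contiguous window of the best-fitting convention (the one
#' with the most consistent N values). An empty window is reported as a
#' no-solution result, never a fabricated N; an anchor whose window spans the
#' whole range (e.g. k = 0, p = 1) is flagged uninformative.
#'
#' @param K annotated (expressed) target count of the anchor row.
#' @param k upregulated target count of the anchor row.
#' @param n upregulated (query) gene count.
#' @param p the printed p-value, as a string (e.g. `"2.10e-7"`) so that its
#'   printed precision is known, or a number combined with `digits`.
#' @param NRange inclusive integer range of universe sizes to scan; the
#'   default 8000–40000 covers plausible expressed-transcriptome sizes.
#' @param conventions tail conventions to score.
#' @param digits printed significant digits; inferred when `p` is a string.
#' @return a [CalibrationResult-class].
#' @examples
#' ## forward-then-invert: build an anchor from a known N, recover it
#' p <- hypergeomUpperTail(17000, 6020, 269, 136)
#' cal <- calibrateUniverse(6020, 136, 269, signif(p, 3), digits = 3,
#'                          NRange = c(16000, 18000))
#' @export
calibrateUniverse <- function(K, k, n, p, NRange = c(8000, 40000),
                              conventions = c("GE", "GT"), digits = NULL) {
  if (is.character(p)) {
    if (is.null(digits)) digits <- .printedDigits(p)
    p <- as.numeric(p)
  }
  if (is.null(digits))
    stop("supply the printed p as a string, or give 'digits' explicitly",
         call. = FALSE)
  stopifnot(p > 0, p <= 1, length(NRange) == 2L)
  Nmin <- max(ceiling(NRange[1]), K, K + n - k)  # feasibility: N-K >= n-k, n <= N
  Ns <- seq.int(Nmin, floor(NRange[2]))
  windows <- lapply(conventions, function(cv) {
    pv <- vapply(Ns, function(N) hypergeomUpperTail(N, K, n, k, cv), 0)
    Ns[.roundsTo(pv, p, digits)]
  })
  names(windows) <- conventions
  sizes <- lengths(windows)
  if (all(sizes == 0L))
    return(new("CalibrationResult", windows = windows, NChosen = NA_integer_,
               convention = NA_character_, uninformative = FALSE))
  best <- names(windows)[which.max(sizes)]
  w <- windows[[best]]
  # widest contiguous run within the best convention's window
  runs <- split(w, cumsum(c(1, diff(w) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  new("CalibrationResult", windows = windows,
      NChosen = as.integer(floor(stats::median(run))), convention = best,
      uninformative = length(w) == length(Ns))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-controlling step-up adjustment (via [stats::p.adjust()]), capped at 1
#' and returned in the input order. Inputs outside `[0, 1]` are a domain error.
#'
#' @param pvals numeric vector of raw p-values.
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric", call. = FALSE)
  if (any(is.na(pvals) | pvals < 0 | pvals > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
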