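# internal helpers shared across modules

# case-insensitive matching key; symbols are matched case-insensitively but
# printed back in the convention of the species they came from
.symKey <- function(x) toupper(trimws(as.character(x)))

# deduplicate symbols case-insensitively, keeping the first spelling seen
.dedupSyms <- function(x) {
  x <- x[nzchar(trimws(x))]
  x[!duplicated(.symKey(x))]
}

.logSumExp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  invisible(x)
}

# run `expr` with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so simulation calls do not perturb the session
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
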