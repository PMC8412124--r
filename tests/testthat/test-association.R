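test_that("spearmanRho matches hand-computed midrank values", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1)), -1)
  # tie in x: Pearson on midranks [1, 2.5, 2.5, 4] vs [1, 3, 2, 4]
  # = 4.5 / sqrt(4.5 * 5) = 3 / sqrt(10)
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 3 / sqrt(10),
               tolerance = 1e-12)
  expect_error(spearmanRho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("spearmanRho is invariant under strictly monotone transforms", {
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r <- spearmanRho(x, y)
    expect_equal(spearmanRho(exp(x), y), r, tolerance = 1e-12)
    expect_equal(spearmanRho(x, y^3 + 2 * y), r, tolerance = 1e-12)
    expect_equal(spearmanRho(rank(x), rank(y)), r, tolerance = 1e-12)
  }
})

test_that("exact Spearman p equals brute-force permutation enumeration", {
  # of the 3! permutations at n = 3, |rho| = 1 occurs twice
  expect_equal(spearmanP(1, 3, "exact"), 2 / 6, tolerance = 1e-12)
  # rho = 0 is never exceeded in absolute value by nothing: p = 1
  expect_equal(spearmanP(0, 5, "exact"), 1)
  for (n in 4:7) {
    Smax <- n * (n^2 - 1) / 3
    for (S in unique(round(seq(0, Smax, length.out = 7)))) {
      rho <- 1 - 6 * S / (n * (n^2 - 1))
      expect_equal(spearmanP(rho, n, "exact"), bruteSpearmanP(rho, n),
                   tolerance = 1e-12,
                   label = sprintf("n=%d S=%d", n, S))
    }
  }
})

test_that("Monte-Carlo permutation p agrees with the exact value", {
  n <- 8
  rho <- 1 - 6 * 30 / (n * (n^2 - 1))
  pE <- spearmanP(rho, n, "exact")
  set.seed(101)
  B <- 2e4
  pMC <- spearmanP(rho, n, "exact", nPerm = B, maxExact = 7)
  se <- sqrt(pE * (1 - pE) / B)
  expect_lt(abs(pMC - pE), 3 * se + 2 / B)
})

test_that("exact and t-approximate p agree closely at n = 10 for moderate rho", {
  n <- 10
  for (S in seq(34, 330, by = 8)) {
    rho <- 1 - 6 * S / (n * (n^2 - 1))
    if (abs(rho) > 0.8) next
    expect_lt(abs(spearmanP(rho, n, "exact") - spearmanP(rho, n, "approx")),
              0.02, label = sprintf("S=%d", S))
  }
})

test_that("spearmanP validates its domain and gates large-n exact mode", {
  expect_error(spearmanP(0.5, 2), "at least 3")
  expect_error(spearmanP(1.5, 5), "rho")
  expect_error(spearmanP(0.5, 12, "exact"), "Monte-Carlo")
})

test_that("correlateTFTargets recovers planted coexpression and rejects null targets", {
  cfg <- syntheticConfig(seed = 4031, nGenes = 300, nUp = 30,
                         tfs = data.frame(tf_id = "TF1", size = 40, theta = 6),
                         latentLoading = 0.9)
  d <- generateDataset(cfg, components = c("expression", "de", "regulons"))
  res <- correlateTFTargets(d$expr, "TF1", d$truth$regulons$TF1)
  expect_equal(nrow(res$rows), 40L)
  expect_gte(res$n_passing / nrow(res$rows), 0.8)

  # genes outside the regulon share no latent factor with the TF
  nullGenes <- setdiff(rownames(SummarizedExperiment::assay(d$expr, "fpkm")),
                       c("TF1", d$truth$regulons$TF1))[1:60]
  res0 <- correlateTFTargets(d$expr, "TF1", nullGenes)
  expect_lte(res0$n_passing / nrow(res0$rows), 0.1)
})

test_that("correlateTFTargets handles identical targets, absent genes and thresholds", {
  m <- matrix(abs(rnorm(40)), 4, 10,
              dimnames = list(c("TF", "COPY", "G1", "G2"), NULL))
  m["COPY", ] <- m["TF", ]
  se <- makeExpr(m)
  res <- suppressWarnings(correlateTFTargets(se, "TF", c("COPY", "NOPE")))
  expect_equal(res$rows$gene_b, "COPY")
  expect_equal(res$rows$rho, 1)
  expect_equal(res$n_passing, 1L)
  expect_warning(correlateTFTargets(se, "TF", c("COPY", "NOPE")), "NOPE")
  expect_error(correlateTFTargets(se, "ABSENT", "COPY"), "absent")
})

test_that("correlateCovariate restricts to the group and validates inputs", {
  m <- matrix(abs(rnorm(30)), 3, 10,
              dimnames = list(c("G1", "G2", "G3"), NULL))
  age <- c(1:5, 31:35)
  grp <- rep(c("case", "control"), each = 5)
  m["G1", 1:5] <- 2^(age[1:5])  # strictly increasing with age in the case group
  se <- makeExpr(m, group = grp, age = age)
  row <- correlateCovariate(se, "G1", "age", "case")
  expect_equal(row$rho, 1)
  expect_equal(row$n, 5L)

  se2 <- makeExpr(m[, 1:7], group = c(rep("case", 2), rep("control", 5)),
                  age = age[1:7])
  expect_error(correlateCovariate(se2, "G1", "age", "case"), "fewer than 3")
  seNA <- makeExpr(m, group = grp, age = replace(age, 2, NA))
  expect_error(correlateCovariate(seNA, "G1", "age", "case"), "s02")
  expect_error(correlateCovariate(se, "G1", "bmi", "case"), "bmi")
})

test_that("covariate correlation recovers a planted rank correlation at n = 10", {
  # latent Pearson loading chosen so that the exact finite-n expectation of
  # the sample Spearman coefficient is 0.70 at n = 10 (bivariate normal)
  n <- 10
  eRho <- function(r) 6 / pi * (asin(r) / (n + 1) +
                                  (n - 2) / (n + 1) * asin(r / 2))
  r <- uniroot(function(r) eRho(r) - 0.7, c(0.5, 0.95))$root
  set.seed(4031)
  rs <- replicate(200, {
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    se <- makeExpr(matrix(2^y, 1, n, dimnames = list("G", NULL)),
                   group = rep("case", n), age = x)
    correlateCovariate(se, "G", "age", "case")$rho
  })
  expect_lt(abs(mean(rs) - 0.7), 0.05)
  expect_gte(mean(abs(rs - 0.7) <= 0.25), 0.8)
})

test_that("tied data fall back to the t approximation with a warning", {
  m <- matrix(c(1, 2, 2, 4, 5, 6,
                2, 1, 4, 3, 6, 5), 2, 6, byrow = TRUE,
              dimnames = list(c("TF", "G"), NULL))
  se <- makeExpr(m)
  expect_warning(res <- correlateTFTargets(se, "TF", "G", mode = "exact"),
                 "tied")
  expect_equal(res$rows$method, "t-approximation")
})
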