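smallCfg <- function(seed = 1, ...) {
  syntheticConfig(seed = seed, nGenes = 400, nUp = 40,
                  tfs = data.frame(tf_id = "TF1", size = 60, theta = 4),
                  nSamples = c(case = 6, control = 5), ...)
}

test_that("generateDataset is bit-reproducible per seed", {
  d1 <- generateDataset(smallCfg(7))
  d2 <- generateDataset(smallCfg(7))
  d3 <- generateDataset(smallCfg(8))
  expect_identical(d1$de@genes, d2$de@genes)
  expect_identical(SummarizedExperiment::assay(d1$expr, "fpkm"),
                   SummarizedExperiment::assay(d2$expr, "fpkm"))
  expect_identical(orthologPairs(d1$map), orthologPairs(d2$map))
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(d1$truth$upregulated, d3$truth$upregulated))
})

test_that("generated DE tables satisfy the planted-structure invariants", {
  for (seed in 1:5) {
    d <- generateDataset(smallCfg(seed), components = c("de", "regulons"))
    up <- upregulated(d$de)
    expect_length(up, 40L)
    expect_true(all(up %in% expressedGenes(d$de)))
    expect_setequal(up, d$truth$upregulated)
    expect_equal(length(d$db[["TF1"]]), 60L)
  }
})

test_that("infeasible and invalid configs are rejected at construction", {
  expect_error(syntheticConfig(nUp = 500, nGenes = 400), "nUp")
  expect_error(syntheticConfig(tfs = data.frame(tf_id = "T", size = 10,
                                                theta = 0)), "theta")
  expect_error(syntheticConfig(latentLoading = 1), "latentLoading")
  expect_error(syntheticConfig(nSamples = c(case = 3)), "nSamples")
})

test_that("ortholog maps follow the retention and multiplicity settings", {
  cfg <- syntheticConfig(seed = 5, nGenes = 2000, nUp = 50,
                         orthologRetention = 0.6,
                         homologMultiplicity = c(0.5, 0.5, 0))
  d <- generateDataset(cfg, components = "orthologs")
  src <- unique(orthologPairs(d$map)$from)
  retention <- length(src) / (cfg$nGenes + 1)
  expect_lt(abs(retention - 0.6), 3 * sqrt(0.6 * 0.4 / cfg$nGenes))
  mult <- table(table(orthologPairs(d$map)$from))
  expect_setequal(names(mult), c("1", "2"))
})

test_that("TF-target rank correlation converges to the loading-implied value", {
  lam <- 0.8
  cfg <- syntheticConfig(seed = 13, nGenes = 300, nUp = 30,
                         tfs = data.frame(tf_id = "TF1", size = 80, theta = 1),
                         nSamples = c(case = 100, control = 100),
                         latentLoading = lam)
  d <- generateDataset(cfg, components = c("expression", "regulons"))
  m <- SummarizedExperiment::assay(d$expr, "fpkm")
  rs <- vapply(d$truth$regulons$TF1, function(g)
    spearmanRho(m["TF1", ], m[g, ]), 0)
  implied <- 6 / pi * asin(lam / 2)
  expect_lt(abs(mean(rs) - implied), 0.05)
})

test_that("table1Fixture reproduces every published overlap count", {
  fx <- table1Fixture()
  hK <- c(SPI1 = 6020L, IRF8 = 754L, GBX2 = 185L, IKZF1 = 101L, TP53 = 3930L,
          RELA = 870L)
  hk <- c(SPI1 = 136L, IRF8 = 24L, GBX2 = 2L, IKZF1 = 4L, TP53 = 73L,
          RELA = 36L)
  for (tf in names(hK)) {
    ov <- regulonOverlap(fx$human$db[[tf]], fx$human$de)
    expect_equal(unname(ov["K_expressed"]), hK[[tf]], label = tf)
    expect_equal(unname(ov["k_up"]), hk[[tf]], label = tf)
  }
  zK <- c(spi1b = 6170L, irf8 = 720L, gbx2 = 197L, ikzf1 = 143L,
          tp53 = 4362L, rela = 967L)
  zk <- c(spi1b = 737L, irf8 = 78L, gbx2 = 6L, ikzf1 = 16L, tp53 = 353L,
          rela = 117L)
  for (tf in names(zK)) {
    ov <- regulonOverlap(fx$zebrafish$db[[tf]], fx$zebrafish$de)
    expect_equal(unname(ov["K_expressed"]), zK[[tf]], label = tf)
    expect_equal(unname(ov["k_up"]), zk[[tf]], label = tf)
  }
  expect_length(upregulated(fx$human$de), 269L)
  expect_length(upregulated(fx$zebrafish$de), 1820L)
  expect_equal(length(expressedGenes(fx$human$de)), 16997L)
})

test_that("the fixture's SPI1- and IRF8-like regulons share 18 upregulated targets", {
  fx <- table1Fixture()
  shared <- intersect(targets(fx$human$db[["IRF8"]]),
                      targets(fx$human$db[["SPI1"]]))
  up <- upregulated(fx$human$de)
  expect_length(intersect(shared, up), 18L)
})

test_that("table1Fixture rejects universes too small for the printed counts", {
  expect_error(table1Fixture(NHuman = 9000), "too small")
})
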