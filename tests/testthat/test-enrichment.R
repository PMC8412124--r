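test_that("hypergeomUpperTail matches hand-enumerable cases", {
  expect_equal(hypergeomUpperTail(10, 5, 4, 0, "GE"), 1)
  # of the 210 draws of 4 from 10, exactly C(5,4) = 5 contain 4 annotated
  expect_equal(hypergeomUpperTail(10, 5, 4, 4, "GE"), 5 / 210,
               tolerance = 1e-12)
  # empty strict tail at the maximum overlap is exactly 0
  expect_identical(hypergeomUpperTail(10, 5, 4, 4, "GT"), 0)
})

test_that("hypergeomUpperTail keeps relative precision in extreme tails", {
  p <- hypergeomUpperTail(20475, 6170, 1820, 737)
  ref <- stats::phyper(736, 6170, 20475 - 6170, 1820, lower.tail = FALSE)
  expect_lt(p, 1e-20)
  expect_equal(p, ref, tolerance = 1e-10)
})

test_that("hypergeometric tail obeys its structural identities", {
  set.seed(11)
  for (rep in 1:40) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- 0:min(K, n)
    ge <- vapply(ks, function(k) hypergeomUpperTail(N, K, n, k, "GE"), 0)
    gt <- vapply(ks, function(k) hypergeomUpperTail(N, K, n, k, "GT"), 0)
    # monotone decreasing in k; GE >= GT; GE(k) = GT(k - 1)
    expect_true(all(diff(ge) <= 1e-12))
    expect_true(all(ge >= gt - 1e-12))
    if (length(ks) > 1)
      expect_equal(ge[-1], gt[-length(gt)], tolerance = 1e-12)
    # point masses sum to one: GE at k = 0 is the whole sample space
    expect_equal(ge[1], 1, tolerance = 1e-12)
    expect_equal(sum(ge - gt), 1, tolerance = 1e-12)
    # symmetry in the roles of the annotated set and the draw
    k <- sample(ks, 1)
    expect_equal(hypergeomUpperTail(N, K, n, k),
                 hypergeomUpperTail(N, n, K, k), tolerance = 1e-12)
  }
})

test_that("hypergeomUpperTail names the violated precondition", {
  expect_error(hypergeomUpperTail(10, 11, 4, 1), "K <= N")
  expect_error(hypergeomUpperTail(10, 5, 11, 1), "n <= N")
  expect_error(hypergeomUpperTail(10, 5, 4, 5), "k <= min")
  expect_error(hypergeomUpperTail(10, 5, 4, -1), "k >= 0")
})

test_that("regulonOverlap counts expressed and upregulated targets", {
  de <- makeDE(up = "B", flat = c("A", "D"))
  reg <- Regulon("TF", c("A", "B", "C"), "human")
  expect_equal(regulonOverlap(reg, de),
               c(K_expressed = 2L, k_up = 1L))
  # matching is case-insensitive
  reg2 <- Regulon("TF", c("a", "b", "c"), "human")
  expect_equal(regulonOverlap(reg2, de), c(K_expressed = 2L, k_up = 1L))
  # all targets upregulated: K_expressed equals k_up
  de2 <- makeDE(up = c("A", "B", "C"))
  expect_equal(unname(diff(regulonOverlap(reg, de2))), 0L)
  expect_error(regulonOverlap(Regulon("TF", "A", "mouse"), de),
               "species mismatch")
})

test_that("enrichTFs reproduces the single-regulon enumeration case", {
  # targets {A,B}, expressed {A,B,C,D}, upregulated {A,B}:
  # p = C(2,2) C(2,0) / C(4,2) = 1/6
  de <- makeDE(up = c("A", "B"), flat = c("C", "D"))
  db <- RegulonDB(list(Regulon("T1", c("A", "B"), "human")), "human")
  row <- enrichTFs("T1", db, de)
  expect_equal(row$p, 1 / 6, tolerance = 1e-12)
  expect_equal(row[c("K_expressed", "k_up", "n_up", "N_universe")],
               data.frame(K_expressed = 2L, k_up = 2L, n_up = 2L,
                          N_universe = 4L))

  # zero overlap gives p = 1, not enriched
  db0 <- RegulonDB(list(Regulon("T0", c("C", "D"), "human")), "human")
  row0 <- enrichTFs("T0", db0, de)
  expect_equal(row0$p, 1)
  expect_false(row0$enriched)

  # identical counts give identical p; output sorted ascending by p
  db2 <- RegulonDB(list(Regulon("T1", c("A", "B"), "human"),
                        Regulon("T2", c("A", "B"), "human"),
                        Regulon("T0", c("C", "D"), "human")), "human")
  rows <- enrichTFs(c("T0", "T1", "T2"), db2, de)
  expect_equal(rows$p[rows$tf_id == "T1"], rows$p[rows$tf_id == "T2"])
  expect_false(is.unsorted(rows$p))

  expect_error(enrichTFs("NOPE", db, de), "without a regulon")
})

test_that("calibrateUniverse inverts a forward-built anchor", {
  p <- hypergeomUpperTail(17000, 6020, 269, 136)
  cal <- calibrateUniverse(6020, 136, 269, signif(p, 3), digits = 3,
                           NRange = c(16500, 17500))
  expect_true(17000 %in% cal@windows$GE)
  expect_false(cal@uninformative)
  expect_true(abs(cal@NChosen - 17000) < 100)
})

test_that("calibrateUniverse flags uninformative anchors and admits no-solution", {
  cal <- calibrateUniverse(50, 0, 20, "1.0", NRange = c(1000, 1200))
  expect_true(cal@uninformative)
  expect_equal(length(cal@windows$GE), 201L)

  # p too small to be attainable anywhere in the range: explicit no-solution
  cal2 <- calibrateUniverse(50, 5, 20, "1e-30", NRange = c(1000, 1100))
  expect_true(is.na(cal2@NChosen))
  expect_equal(lengths(cal2@windows), c(GE = 0L, GT = 0L))
})

test_that("bhAdjust matches hand-derived step-up values and its invariants", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.5, 0.01)), c(0.5, 0.02))
  expect_error(bhAdjust(c(0.5, 1.2)), "domain error")

  set.seed(7)
  for (rep in 1:20) {
    p <- sort(runif(sample(2:30, 1)))
    q <- bhAdjust(p)
    expect_true(all(diff(q) >= -1e-12))        # monotone on sorted input
    expect_true(all(q >= p - 1e-12))           # never below the raw p
    expect_true(all(q <= 1 + 1e-12))
  }
})
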