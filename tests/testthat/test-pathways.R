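test_that("ora reproduces the single-set enumeration case", {
  # query of 3 genes out of a 6-gene universe, one set equal to the query:
  # p = C(3,3)/C(6,3) = 1/20
  gsc <- GeneSetCollection(list(S1 = c("A", "B", "C")))
  rows <- ora(c("A", "B", "C"), gsc, c("A", "B", "C", "D", "E", "F"))
  expect_equal(rows$p, 0.05, tolerance = 1e-12)
  expect_equal(rows$padj, 0.05, tolerance = 1e-12)
  expect_equal(rows$K_expressed, 3L)
  expect_equal(rows$k_up, 3L)
})

test_that("ora handles disjoint sets, duplicates and degenerate inputs", {
  gsc <- GeneSetCollection(list(S1 = c("X", "Y"), S2 = c("X", "Y"),
                                S3 = c("Z", "W")))
  rows <- ora(c("A", "B"), gsc, c("A", "B", "X", "Y", "Z", "W"))
  expect_equal(rows$p, rep(1, 3))
  expect_equal(rows$p[rows$set_id == "S1"], rows$p[rows$set_id == "S2"])
  expect_equal(rows$padj[rows$set_id == "S1"], rows$padj[rows$set_id == "S2"])

  expect_warning(ora(c("A", "OUT"), gsc, c("A", "B", "X", "Y")), "OUT")
  expect_error(ora("A", gsc, character()), "empty universe")
})

test_that("ora output is sorted by adjusted p and BH set shrinks as a raw p grows", {
  set.seed(21)
  uni <- sprintf("G%03d", 1:60)
  sets <- lapply(1:8, function(i) sample(uni, 12))
  names(sets) <- sprintf("S%d", 1:8)
  query <- sample(uni, 15)
  rows <- ora(query, GeneSetCollection(sets), uni)
  expect_false(is.unsorted(rows$padj))
  # degrading the strongest set (removing its hits from the query's overlap)
  # never grows the BH-significant set
  nSig <- function(r) sum(r$padj < 0.05)
  weaker <- sets
  weaker[[rows$set_id[1]]] <- setdiff(weaker[[rows$set_id[1]]], query)
  weaker[[rows$set_id[1]]] <- c(weaker[[rows$set_id[1]]],
                                setdiff(uni, c(query, weaker[[rows$set_id[1]]]))[1:2])
  rows2 <- ora(query, GeneSetCollection(weaker), uni)
  expect_lte(nSig(rows2), nSig(rows))
})

test_that("tfPathwayCounts counts regulon targets inside top pathways", {
  gsc <- GeneSetCollection(list(P1 = c("A", "B", "C"), P2 = c("Z", "W", "Q")))
  uni <- c("A", "B", "C", "D", "Z", "W", "Q", "R")
  rows <- ora(c("A", "B"), gsc, uni)
  db <- RegulonDB(list(TF1 = Regulon("TF1", c("A", "B", "D"), "human"),
                       TF2 = Regulon("TF2", c("Z", "W"), "human")), "human")
  res <- suppressWarnings(tfPathwayCounts(rows, db, gsc, up = c("A", "B"),
                                          topN = 2))
  p1 <- res$rows[res$rows$set_id == "P1", ]
  expect_equal(p1$count_TF1, 2L)
  expect_true(p1$multiple_TF1)
  expect_equal(p1$count_TF2, 0L)
  expect_false(p1$multiple_TF2)
  expect_equal(res$summary, c(TF1 = 1L, TF2 = 0L))
  expect_warning(tfPathwayCounts(rows, db, gsc, up = c("A", "B"), topN = 5),
                 "clamped")
})

test_that("a dominant regulator flags every top pathway", {
  # each pathway carries two upregulated targets of the dominant TF, so the
  # per-TF summary saturates at topN while a sparse TF stays at zero
  nPw <- 20
  upTargets <- sprintf("T%02d", 1:40)
  filler <- sprintf("F%02d", 1:60)
  sets <- lapply(seq_len(nPw), function(i)
    c(upTargets[c(2 * i - 1, 2 * i)], filler[((3 * i) %% 60) + 1]))
  names(sets) <- sprintf("PW%02d", seq_len(nPw))
  gsc <- GeneSetCollection(sets)
  uni <- c(upTargets, filler, sprintf("U%03d", 1:400))
  db <- RegulonDB(list(DOM = Regulon("DOM", upTargets, "human"),
                       SPARSE = Regulon("SPARSE", "F01", "human")), "human")
  rows <- ora(upTargets, gsc, uni)
  res <- tfPathwayCounts(rows, db, gsc, up = upTargets, topN = nPw)
  expect_equal(unname(res$summary["DOM"]), nPw)
  expect_equal(unname(res$summary["SPARSE"]), 0L)
})
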