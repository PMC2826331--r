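pred_edges <- function(...) {
  do.call(rbind, lapply(list(...), function(r) {
    data.frame(contig1 = r[[1]], side1 = r[[2]], contig2 = r[[3]],
               side2 = r[[4]], stringsAsFactors = FALSE)
  }))
}

ro3 <- reference_order(data.frame(
  contig_id = c("c1", "c2", "c3"), orientation = "forward",
  start = c(1, 1001, 2001), end = c(900, 1900, 2900)))

test_that("perfect forward predictions give TPR = PPV = 1", {
  ev <- evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "L"),
                                        c("c2", "R", "c3", "L")), ro3)
  expect_equal(ev$TP, 2L)
  expect_equal(ev$FP, 0L)
  expect_equal(ev$P, 2L)
  expect_equal(ev$TPR, 1)
  expect_equal(ev$PPV, 1)
})

test_that("a correct pair with wrong facing is a flagged false positive", {
  ev <- evaluate_adjacencies(pred_edges(c("c1", "L", "c2", "L")), ro3)
  expect_equal(ev$TP, 0L)
  expect_equal(ev$FP, 1L)
  expect_match(ev$details$status, "pair-correct, orientation-wrong")
})

test_that("no predictions leave precision undefined", {
  ev <- evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "L"))[0, ], ro3)
  expect_equal(ev$TP, 0L)
  expect_equal(ev$FP, 0L)
  expect_true(is.na(ev$PPV))
  expect_output(print(ev), "undef")
})

test_that("reverse-oriented contigs swap the expected connectors", {
  ro <- reference_order(data.frame(
    contig_id = c("c1", "c2"), orientation = c("forward", "reverse"),
    start = c(1, 1001), end = c(900, 1900)))
  expect_equal(evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "R")), ro)$TP, 1L)
  expect_equal(evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "L")), ro)$TP, 0L)
})

test_that("circular evaluation adds the wrap-around connection", {
  evL <- evaluate_adjacencies(pred_edges(c("c3", "R", "c1", "L")), ro3)
  expect_equal(evL$TP, 0L)
  expect_equal(evL$P, 2L)
  evC <- evaluate_adjacencies(pred_edges(c("c3", "R", "c1", "L")), ro3,
                              circular = TRUE)
  expect_equal(evC$TP, 1L)
  expect_equal(evC$P, 3L)
})

test_that("edges touching excluded contigs are dropped with a warning", {
  expect_warning(
    ev <- evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "L"),
                                          c("c3", "R", "plasmid", "L")), ro3),
    "dropped")
  expect_equal(ev$TP, 1L)
  expect_equal(ev$FP, 0L)
})

test_that("TP + FP equals the number of scored unique predictions", {
  ev <- evaluate_adjacencies(pred_edges(c("c1", "R", "c2", "L"),
                                        c("c2", "L", "c1", "R"),  # duplicate
                                        c("c1", "R", "c3", "L")), ro3)
  expect_equal(ev$TP + ev$FP, 2L)
})

test_that("scores are invariant under relabeling and global reversal", {
  pred <- pred_edges(c("c1", "R", "c2", "L"), c("c1", "L", "c3", "R"))
  ev <- evaluate_adjacencies(pred, ro3)
  # relabeling
  relab <- c(c1 = "k9", c2 = "k5", c3 = "k7")
  ro_r <- reference_order(data.frame(
    contig_id = unname(relab[c("c1", "c2", "c3")]), orientation = "forward",
    start = c(1, 1001, 2001), end = c(900, 1900, 2900)))
  pred_r <- pred
  pred_r$contig1 <- unname(relab[pred$contig1])
  pred_r$contig2 <- unname(relab[pred$contig2])
  ev_r <- evaluate_adjacencies(pred_r, ro_r)
  expect_equal(ev_r$TPR, ev$TPR)
  expect_equal(ev_r$PPV, ev$PPV)
  # reversing the genome reverses order and flips orientations
  ro_rev <- reference_order(data.frame(
    contig_id = c("c3", "c2", "c1"), orientation = "reverse",
    start = c(1, 1001, 2001), end = c(900, 1900, 2900)))
  ev_rev <- evaluate_adjacencies(pred, ro_rev)
  expect_equal(ev_rev$TPR, ev$TPR)
  expect_equal(ev_rev$PPV, ev$PPV)
})

test_that("the reference order places contigs where they match most", {
  set.seed(31)
  genome <- stats::setNames(random_dna(6000), "chr")
  contigs <- c(a = substr(genome[[1]], 1, 2000),
               b = rc_oracle(substr(genome[[1]], 2001, 4000)),
               c = substr(genome[[1]], 4001, 6000))
  ro <- build_reference_order(contigs, genome)
  expect_equal(ro$contig_id, c("a", "b", "c"))
  expect_equal(ro$orientation, c("forward", "reverse", "forward"))
  expect_length(attr(ro, "excluded"), 0L)
})

test_that("unmatched contigs are excluded from the reference order", {
  set.seed(32)
  genome <- stats::setNames(random_dna(4000), "chr")
  contigs <- c(a = substr(genome[[1]], 1, 1500),
               stray = random_dna(500))
  ro <- build_reference_order(contigs, genome)
  expect_equal(ro$contig_id, "a")
  expect_equal(attr(ro, "excluded"), "stray")
})

test_that("among multiple placements the one with most q-gram hits wins", {
  matches <- data.frame(
    contig_id = "a", ref_genome = "finished", ref_record = "chr",
    sb = 1L, se = 100L, tb = c(101L, 5001L), te = c(200L, 5100L),
    qhits = c(50L, 120L), stringsAsFactors = FALSE)
  ro <- build_reference_order(c(a = strrep("A", 100)),
                              stats::setNames(strrep("A", 10000), "chr"),
                              matches = matches)
  expect_equal(ro$start, 5001)
})

test_that("N50 follows its definition", {
  expect_equal(n50(100), 100)
  expect_equal(n50(c(50, 50, 100)), 100)
  expect_equal(n50(c(10, 10, 10, 10)), 10)
  expect_equal(n50(c(2, 2, 2, 3)), 2)
  expect_error(n50(numeric(0)), "empty")
})
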