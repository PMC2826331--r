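test_that("projection follows the placement formulas in both conventions", {
  m <- data.frame(contig_id = "c1", ref_genome = "g", ref_record = "chr",
                  sb = 3L, se = 10L, tb = 100L, te = 107L, qhits = 1L,
                  stringsAsFactors = FALSE)
  raw <- project_match(m, c(c1 = 20L), convention = "raw")
  expect_equal(raw$pb, 97)
  expect_equal(raw$pe, 117)
  incl <- project_match(m, c(c1 = 20L))
  expect_equal(incl$pb, 98)
  expect_equal(incl$pe, 117)
  # full-length forward match projects onto itself
  mf <- transform(m, sb = 1L, se = 20L, tb = 501L, te = 520L)
  pf <- project_match(mf, c(c1 = 20L))
  expect_equal(c(pf$pb, pf$pe), c(501, 520))
  expect_equal(pf$orientation, "forward")
  # full-length reverse match projects onto itself
  mr <- transform(m, sb = 20L, se = 1L, tb = 501L, te = 520L)
  pr <- project_match(mr, c(c1 = 20L))
  expect_equal(c(pr$pb, pr$pe), c(501, 520))
  expect_equal(pr$orientation, "reverse")
})

test_that("displacement counts the signed gap and is undefined across genomes", {
  p <- function(pb, pe, g = "g1", rec = "chr") {
    data.frame(contig_id = "x", ref_genome = g, ref_record = rec,
               pb = pb, pe = pe, orientation = "forward",
               stringsAsFactors = FALSE)
  }
  expect_equal(displacement(p(1, 100), p(101, 200)), 0)
  expect_equal(displacement(p(1, 100), p(151, 250)), 50)
  expect_equal(displacement(p(1, 100), p(81, 180)), -20)
  expect_equal(displacement(p(151, 250), p(1, 100)), 50)  # order-free
  expect_true(is.na(displacement(p(1, 100), p(101, 200, g = "g2"))))
  expect_true(is.na(displacement(p(1, 100), p(101, 200, rec = "chr2"))))
})

test_that("adjacency score matches its closed form and behaves as a kernel", {
  params <- scoring_params()
  d_grid <- seq(-50000, 50000, by = 2500)
  tau_min <- 0.4
  for (tau in c(0.4, 0.8, 2.0)) {
    expect_equal(adjacency_score(d_grid, tau, params, tau_min),
                 oracle_score(d_grid, tau, tau_min = tau_min),
                 tolerance = 1e-15)
  }
  # phi = 0: even in d, strictly decreasing in |d|
  p0 <- scoring_params(phi = 0)
  s_pos <- adjacency_score(d_grid, 0.5, p0)
  expect_equal(s_pos, rev(s_pos))
  inc <- adjacency_score(seq(0, 50000, by = 500), 0.5, p0)
  expect_true(all(diff(inc) < 0))
  # doubling tau halves the phi = 0 score at d = 0 (tau scaling on)
  expect_equal(adjacency_score(0, 0.8, p0, tau_min = 0.4),
               adjacency_score(0, 0.4, p0, tau_min = 0.4) / 2)
  # phi = 1: mode sits at d = mu
  p1 <- scoring_params(phi = 1)
  s_mu <- adjacency_score(c(1000, 2000, 3000), 0.5, p1)
  expect_gt(s_mu[2], s_mu[1])
  expect_gt(s_mu[2], s_mu[3])
  expect_error(adjacency_score(0, 0, params), "positive")
  expect_error(adjacency_score(0, -1, params), "positive")
})

test_that("two abutting forward contigs weight exactly one connector pair", {
  tree <- star_tree("R1")   # tau(S, R1) = 0.5
  m <- data.frame(contig_id = c("c1", "c2"), ref_genome = "R1",
                  ref_record = "chr", sb = 1L, se = 100L,
                  tb = c(1L, 101L), te = c(100L, 200L), qhits = 90L,
                  stringsAsFactors = FALSE)
  lens <- c(c1 = 100L, c2 = 100L)
  g <- build_adjacency_graph(m, lens, tree, "S")
  tau <- 0.5
  want <- (1 / tau) * (0.9 * exp(0) + 0.1 * exp(-2000^2 / (2 * 1000^2)))
  expect_equal(g$W["c1:R", "c2:L"], want)
  expect_equal(g$W["c1:L", "c2:L"], 0)
  expect_equal(g$W["c1:R", "c2:R"], 0)
  expect_equal(g$W["c1:L", "c2:R"], 0)
  # intra edges are structurally zero
  expect_equal(g$W["c1:L", "c1:R"], 0)
  expect_equal(g$W["c2:L", "c2:R"], 0)
  # reversing the second contig moves the support to {r1, r2}
  m2 <- m
  m2$sb[2] <- 100L; m2$se[2] <- 1L
  g2 <- build_adjacency_graph(m2, lens, tree, "S")
  expect_equal(g2$W["c1:R", "c2:R"], want)
  expect_equal(g2$W["c1:R", "c2:L"], 0)
})

test_that("weights add over references", {
  tree <- star_tree(c("R1", "R2"))  # equal tau = 0.5
  one <- data.frame(contig_id = c("c1", "c2"), ref_genome = "R1",
                    ref_record = "chrA", sb = 1L, se = 100L,
                    tb = c(1L, 101L), te = c(100L, 200L), qhits = 90L,
                    stringsAsFactors = FALSE)
  both <- rbind(one, transform(one, ref_genome = "R2", ref_record = "chrB"))
  lens <- c(c1 = 100L, c2 = 100L)
  g1 <- build_adjacency_graph(one, lens, tree, "S", ref_genomes = "R1")
  g12 <- build_adjacency_graph(both, lens, tree, "S")
  expect_equal(g12$W["c1:R", "c2:L"], 2 * g1$W["c1:R", "c2:L"])
  # removing a reference never increases any weight
  expect_true(all(g12$W - g1$W >= -1e-12))
})

test_that("graph weights equal exhaustive pair enumeration on micro-instances", {
  set.seed(99)
  params <- scoring_params()
  for (k in 1:30) {
    inst <- random_micro_instance()
    tree <- star_tree(inst$refs, extra = stats::runif(length(inst$refs), 0.2, 1))
    tau <- vapply(inst$refs, function(r) tree_distance(tree, "S", r),
                  numeric(1))
    g <- build_adjacency_graph(inst$matches, inst$lens, tree, "S",
                               ref_genomes = inst$refs, params = params)
    want <- unlist(oracle_graph_weights(inst$matches, inst$lens, tau, params,
                                        d_cutoff = 200000))
    got <- unlist(graph_weight_map(g))
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 0)
    }
  }
})

test_that("graphs are symmetric with the full connector pair complement", {
  set.seed(100)
  inst <- random_micro_instance()
  tree <- star_tree(inst$refs)
  g <- build_adjacency_graph(inst$matches, inst$lens, tree, "S",
                             ref_genomes = inst$refs)
  expect_identical(g$W, t(g$W))
  n <- length(g$contig_ids)
  all_edges <- graph_edges(g, include_zero = TRUE)
  expect_equal(nrow(all_edges), choose(2 * n, 2) - n)  # adjacency edges
  expect_length(g$vertices, 2L * n)
})

test_that("reverse-complementing a contig permutes its connectors", {
  set.seed(101)
  tree <- star_tree("R1")
  m <- data.frame(contig_id = c("c1", "c2", "c3"), ref_genome = "R1",
                  ref_record = "chr", sb = c(1L, 1L, 20L),
                  se = c(100L, 100L, 1L),
                  tb = c(1L, 120L, 300L), te = c(100L, 219L, 319L),
                  qhits = 10L, stringsAsFactors = FALSE)
  lens <- c(c1 = 100L, c2 = 100L, c3 = 20L)
  g <- build_adjacency_graph(m, lens, tree, "S")
  # flip contig 2 in the input: its match coordinates mirror and strand flips
  m2 <- m
  m2$sb[2] <- 100L; m2$se[2] <- 1L
  g2 <- build_adjacency_graph(m2, lens, tree, "S")
  perm <- g$vertices
  perm[perm == "c2:L"] <- "tmp"
  perm[perm == "c2:R"] <- "c2:L"
  perm[perm == "tmp"] <- "c2:R"
  expect_equal(unname(g2$W[perm, perm]), unname(g$W))
  expect_equal(sort(g$W[upper.tri(g$W)]), sort(g2$W[upper.tri(g2$W)]))
})

test_that("constraints forbid to zero and force to the graph maximum", {
  edges <- data.frame(contig1 = c("c1", "c1"), side1 = "R",
                      contig2 = c("c2", "c3"), side2 = "L",
                      weight = c(7.5, 3), stringsAsFactors = FALSE)
  g <- adjacency_graph(c("c1", "c2", "c3"), edges)
  gf <- apply_constraints(g, data.frame(contig1 = "c1", side1 = "R",
                                        contig2 = "c2", side2 = "L",
                                        action = "forbid"))
  expect_equal(gf$W["c1:R", "c2:L"], 0)
  expect_true(gf$overridden["c1:R", "c2:L"])
  gF <- apply_constraints(g, data.frame(contig1 = "c2", side1 = "R",
                                        contig2 = "c3", side2 = "L",
                                        action = "force"))
  expect_equal(gF$W["c2:R", "c3:L"], 7.5)
  expect_equal(max_adjacency_weight(gF), 7.5)  # set-to-max keeps the maximum
  gFF <- apply_constraints(gF, data.frame(contig1 = "c2", side1 = "R",
                                          contig2 = "c3", side2 = "L",
                                          action = "force"))
  expect_equal(gFF$W["c2:R", "c3:L"], 7.5)
  expect_error(apply_constraints(g, data.frame(contig1 = "c1", side1 = "L",
                                               contig2 = "c1", side2 = "R",
                                               action = "forbid")),
               "intra")
})

test_that("forbids are applied before forces", {
  edges <- data.frame(contig1 = "c1", side1 = "R", contig2 = "c2",
                      side2 = "L", weight = 10, stringsAsFactors = FALSE)
  g <- adjacency_graph(c("c1", "c2", "c3"), edges)
  cons <- data.frame(contig1 = c("c2", "c1"), side1 = c("R", "R"),
                     contig2 = c("c3", "c2"), side2 = c("L", "L"),
                     action = c("force", "forbid"), stringsAsFactors = FALSE)
  g2 <- apply_constraints(g, cons)
  expect_equal(g2$W["c1:R", "c2:L"], 0)
  expect_equal(g2$W["c2:R", "c3:L"], 0)  # max after the forbid is 0
})
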