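test_that("modularity matches hand-evaluated fixtures", {
  # two disjoint unit-weight triangles, partitioned into the two triangles:
  # Q = 2 * (3/6 - (6/12)^2) = 0.5
  tri2 <- rbind(clique_edges(c("a1", "a2", "a3")),
                clique_edges(c("b1", "b2", "b3")))
  part <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2)
  expect_equal(modularity_q(tri2, part), 0.5)

  # one community scores exactly zero on any graph
  set.seed(43)
  e <- random_edges(9, 0.5, weighted = TRUE)
  v <- sprintf("v%02d", 1:9)
  expect_equal(modularity_q(e, stats::setNames(rep(1, 9), v), vertices = v), 0)

  # all-singleton partition: Q = -sum_i (k_i / 2m)^2
  deg <- stats::setNames(rep(0, 9), v)
  dd <- tapply(c(e$weight, e$weight), c(e$phys_a, e$phys_b), sum)
  deg[names(dd)] <- dd
  m <- sum(e$weight)
  expect_equal(modularity_q(e, stats::setNames(seq_len(9), v), vertices = v),
               -sum((deg / (2 * m))^2))

  # zero total weight is undefined
  expect_error(
    modularity_q(data.table::data.table(phys_a = character(0),
                                        phys_b = character(0),
                                        weight = numeric(0)),
                 c(a = 1), vertices = "a"),
    "zero total edge weight")
})

test_that("modularity agrees with the igraph implementation on random graphs", {
  set.seed(47)
  for (i in 1:10) {
    e <- random_edges(12, 0.35, weighted = TRUE)
    v <- sprintf("v%02d", 1:12)
    part <- stats::setNames(sample(1:3, 12, replace = TRUE), v)
    g <- igraph::graph_from_data_frame(
      e[, .(from = phys_a, to = phys_b, weight)], directed = FALSE,
      vertices = data.frame(name = v))
    ref <- igraph::modularity(g, membership = part[igraph::V(g)$name],
                              weights = igraph::E(g)$weight)
    expect_equal(modularity_q(e, part, vertices = v), ref, tolerance = 1e-12)
  }
})

test_that("multilevel partition separates two cliques joined by one edge", {
  e <- rbind(clique_edges(sprintf("a%02d", 1:10)),
             clique_edges(sprintf("b%02d", 1:10)),
             data.table::data.table(phys_a = "a01", phys_b = "b01", weight = 1))
  memb <- multilevel_partition(e, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[sprintf("a%02d", 1:10)])), 1)
  expect_equal(length(unique(memb[sprintf("b%02d", 1:10)])), 1)
  # the clique split is the exhaustive global optimum on a scaled version
  small <- rbind(clique_edges(c("a1", "a2", "a3", "a4")),
                 clique_edges(c("b1", "b2", "b3", "b4")),
                 data.table::data.table(phys_a = "a1", phys_b = "b1", weight = 1))
  best <- exhaustive_best_modularity(small, sort(unique(c(small$phys_a, small$phys_b))))
  got <- multilevel_partition(small, seed = 1)
  expect_equal(modularity_q(small, got), best$q, tolerance = 1e-9)
})

test_that("multilevel never exceeds the exhaustive optimum on small graphs", {
  set.seed(53)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    e <- random_edges(n, 0.45, weighted = i %% 2 == 0)
    if (nrow(e) == 0) next
    v <- sprintf("v%02d", 1:n)
    best <- exhaustive_best_modularity(e, v)
    memb <- multilevel_partition(e, seed = i, vertices = v)
    q <- modularity_q(e, memb, vertices = v)
    expect_lte(q, best$q + 1e-9)
    # and at least as good as the trivial one-community partition
    expect_gte(q, 0 - 1e-12)
  }
})

test_that("an edgeless graph returns singleton labels with a warning", {
  g <- sg_fixture(data.table::data.table(phys_a = character(0),
                                         phys_b = character(0),
                                         weight = numeric(0)),
                  vertices = c("a", "b", "c"))
  expect_warning(memb <- multilevel_partition(g, seed = 1), "no edges")
  expect_equal(length(unique(memb)), 3)
})

test_that("partitioning is deterministic under a fixed seed", {
  set.seed(59)
  e <- random_edges(40, 0.2, weighted = TRUE)
  m1 <- multilevel_partition(e, seed = 123)
  m2 <- multilevel_partition(e, seed = 123)
  expect_identical(m1, m2)
  g <- sg_fixture(e)
  cfg <- pipeline_config(min_network_size = 2)
  p1 <- iterative_split(g, cfg, seed = 7)
  p2 <- iterative_split(g, cfg, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$discarded, p2$discarded)
})

test_that("planted-partition graphs are recovered almost exactly", {
  set.seed(61)
  blocks <- rep(1:4, each = 12)
  ids <- sprintf("v%02d", seq_along(blocks))
  cmb <- t(utils::combn(seq_along(ids), 2))
  p <- ifelse(blocks[cmb[, 1]] == blocks[cmb[, 2]], 0.9, 0.05)
  keep <- stats::runif(nrow(cmb)) < p
  e <- data.table::data.table(phys_a = ids[cmb[keep, 1]],
                              phys_b = ids[cmb[keep, 2]], weight = 5)
  memb <- multilevel_partition(e, seed = 2, vertices = ids)
  expect_gte(adjusted_rand(memb[ids], blocks), 0.9)
})

test_that("iterative splitting recurses on oversized communities and discards small ones", {
  # three planted blocks: A = 200 physicians (two dense 90/110 halves bridged
  # by moderate cross weights so the full-graph optimum keeps A whole), a
  # 60-clique and a 15-clique; weak bridges connect the blocks
  a1 <- sprintf("x%03d", 1:90)
  a2 <- sprintf("y%03d", 1:110)
  b  <- sprintf("b%03d", 1:60)
  cc <- sprintf("c%03d", 1:15)
  cross <- data.table::CJ(phys_a = a1, phys_b = a2)
  cross[, weight := 0.92]
  bridges <- data.table::data.table(
    phys_a = c("x001", "x002", "y001", "b001"),
    phys_b = c("b001", "b002", "c001", "c002"),
    weight = 1)
  e <- rbind(clique_edges(a1), clique_edges(a2), clique_edges(b),
             clique_edges(cc), cross, bridges)
  g <- sg_fixture(e, vertices = c(a1, a2, b, cc))
  cfg <- pipeline_config()
  part <- iterative_split(g, cfg, seed = 11)
  expect_setequal(lengths(part$networks), c(110, 90, 60))
  expect_length(part$discarded, 15)
  expect_setequal(part$discarded, cc)
  # the split of A happened in a recursion, not at the top level
  expect_gte(max(part$modularity_trace$depth), 1)
  expect_length(part$oversized_terminal, 0)
})

test_that("a 25-clique is one terminal network with no recursion", {
  g <- sg_fixture(clique_edges(sprintf("v%02d", 1:25)))
  part <- iterative_split(g, pipeline_config(), seed = 1)
  expect_length(part$networks, 1)
  expect_equal(lengths(part$networks)[[1]], 25)
  expect_equal(nrow(part$modularity_trace), 1)
  expect_length(part$discarded, 0)
})

test_that("communities below the minimum size are all discarded", {
  g <- sg_fixture(clique_edges(sprintf("v%02d", 1:10)))
  expect_warning(part <- iterative_split(g, pipeline_config(), seed = 1),
                 "minimum network size")
  expect_length(part$networks, 0)
  expect_length(part$discarded, 10)
})

test_that("membership is conserved: retained plus discarded equals all vertices", {
  set.seed(67)
  e <- random_edges(60, 0.12, weighted = TRUE)
  g <- sg_fixture(e)
  part <- suppressWarnings(iterative_split(g, pipeline_config(min_network_size = 5,
                                                              max_network_size = 25),
                                           seed = 3))
  expect_setequal(c(part$assignment$physician_id, part$discarded), g$vertices)
  expect_equal(nrow(part$assignment) + length(part$discarded), length(g$vertices))
  # assignment is a partition: no physician appears twice
  expect_false(anyDuplicated(part$assignment$physician_id) > 0)
  # all retained networks respect the band unless flagged terminal-oversized
  szs <- lengths(part$networks)
  flagged <- names(part$networks) %in% part$oversized_terminal
  expect_true(all(szs[!flagged] <= 25))
  expect_true(all(szs >= 5))
})
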