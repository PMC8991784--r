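test_that("degree centrality and density match hand values", {
  expect_equal(degree_centrality(7, 5), 1.4)
  expect_equal(degree_centrality(0, 4), 0)
  expect_equal(degree_centrality(6, 4), 1.5)      # complete graph on 4
  expect_equal(edge_density(7, 5), 0.7)
  expect_equal(edge_density(6, 4), 1.0)
  expect_equal(edge_density(0, 6), 0)
  expect_warning(d <- edge_density(0, 1), "undefined")
  expect_true(is.na(d))
})

test_that("transitivity matches hand values and brute force on random graphs", {
  tri <- clique_edges(c("a", "b", "c"))
  expect_equal(transitivity_coefficient(tri, c("a", "b", "c")), 1.0)
  path <- data.table::data.table(phys_a = c("a", "b"), phys_b = c("b", "c"),
                                 weight = 1)
  expect_equal(transitivity_coefficient(path, c("a", "b", "c")), 0.0)
  expect_warning(tr <- transitivity_coefficient(path[0], c("a", "b", "c")),
                 "undefined")
  expect_true(is.na(tr))
  set.seed(71)
  for (i in 1:10) {
    e <- random_edges(12, 0.3)
    v <- sprintf("v%02d", 1:12)
    if (nrow(e) == 0) next
    got <- suppressWarnings(transitivity_coefficient(e, v))
    want <- brute_transitivity(e, v)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("spearman matrix matches the rank-then-Pearson oracle", {
  # perfect inverse monotone relation
  df <- data.frame(x = c(1, 2, 3, 4), y = c(8, 6, 4, 2), z = c(1, 1, 2, 5))
  sp <- spearman_matrix(df, columns = c("x", "y", "z"))
  expect_equal(sp$rho["x", "x"], 1.0)
  expect_equal(sp$rho["x", "y"], -1.0)
  expect_equal(sp$rho["x", "z"], spearman_oracle(df$x, df$z))

  set.seed(73)
  for (i in 1:5) {
    n <- 20
    df <- data.frame(a = rnorm(n), b = sample(1:4, n, TRUE),
                     c = rpois(n, 3), d = runif(n))
    df$b[3] <- NA  # pairwise deletion
    sp <- spearman_matrix(df, columns = names(df))
    for (p in utils::combn(names(df), 2, simplify = FALSE)) {
      expect_equal(sp$rho[p[1], p[2]],
                   spearman_oracle(df[[p[1]]], df[[p[2]]]),
                   tolerance = 1e-12)
    }
  }

  # constant column: undefined correlation reported as NA
  dfc <- data.frame(x = 1:6, y = rep(2, 6))
  spc <- spearman_matrix(dfc, columns = c("x", "y"))
  expect_true(is.na(spc$rho["x", "y"]))

  # p-values follow the t approximation
  set.seed(74)
  x <- rnorm(12); y <- x + rnorm(12)
  sp2 <- spearman_matrix(data.frame(x = x, y = y, z = rnorm(12)),
                         columns = c("x", "y", "z"))
  rho <- sp2$rho["x", "y"]
  tt <- rho * sqrt((12 - 2) / (1 - rho^2))
  expect_equal(sp2$p["x", "y"], 2 * stats::pt(abs(tt), 10, lower.tail = FALSE))

  expect_error(spearman_matrix(data.frame(x = 1:3, y = 1:3),
                               columns = c("x", "y")), "at least 4")
})

test_that("profiles of a hand-built two-network fixture match hand computation", {
  # network N1 = {a, b, c} (triangle), N2 = {d, e} (single edge); f discarded
  part <- partition_fixture(list(N1 = c("a", "b", "c"), N2 = c("d", "e")))
  edges <- data.table::data.table(
    phys_a = c("a", "a", "b", "d", "c"),
    phys_b = c("b", "c", "c", "e", "d"),
    weight = c(30, 40, 50, 25, 20))          # c-d crosses networks
  g <- sg_fixture(edges, vertices = c("a", "b", "c", "d", "e", "f"))
  physicians <- data.table::data.table(
    physician_id = c("a", "b", "c", "d", "e", "f"),
    specialty_code = c("gp", "gp", "ent", "gp", "urology", "gp"),
    practice_id = c("pr1", "pr1", "pr2", "pr3", "pr4", "pr5"),
    region_code = "R1")
  co <- rbind(
    # p1 -> N1: days a:2, b:1 (in N1), d:1 (N2): share 3/4
    visits("p1", "a", c("2016-01-01", "2016-01-02")),
    visits("p1", "b", "2016-01-03"),
    visits("p1", "d", "2016-01-04"),
    # p2 -> N1: all 3 days inside
    visits("p2", "c", c("2016-02-01", "2016-02-02")),
    visits("p2", "a", "2016-02-03"),
    # p3 -> N2: d 2 days, e 1 day, a 1 day: share 3/4
    visits("p3", "d", c("2016-03-01", "2016-03-02")),
    visits("p3", "e", "2016-03-03"),
    visits("p3", "a", "2016-03-04"))
  cohort <- structure(list(
    included_physicians = c("a", "b", "c", "d", "e", "f"),
    included_patients = c("p1", "p2", "p3"),
    qualifying_consultations = co,
    patient_groups = data.table::data.table(patient_id = c("p1", "p2", "p3"),
                                            group_id = 7L),
    config = pipeline_config()), class = "cohort_bundle")
  cfg <- pipeline_config()
  alloc <- allocate_patients(cohort, part, cfg)
  expect_equal(alloc$allocated_network_id, c("N1", "N1", "N2"))
  prof <- build_profiles(part, alloc, cohort, g, physicians, cfg)

  n1 <- prof[network_id == "N1"]
  expect_equal(n1$n_physicians, 3L)
  expect_equal(n1$n_patients, 2L)
  expect_equal(n1$n_specialties, 2L)            # gp, ent
  expect_equal(n1$n_practices, 2L)              # pr1, pr2
  expect_equal(n1$mean_physicians_per_practice, 1.5)
  expect_equal(n1$n_edges, 3L)                  # triangle
  expect_equal(n1$degree_centrality, 1)         # 3/3
  expect_equal(n1$density, 1)
  expect_equal(n1$transitivity, 1)
  expect_equal(n1$mean_shared_per_edge, 40)     # (30+40+50)/3
  expect_equal(n1$mean_degree, 2)               # 2*3/3
  # p1: 3 of 4 days in N1, 2 of 3 distinct physicians in N1
  # p2: 3/3 days, 2/2 physicians
  expect_equal(n1$prop_visits_within, mean(c(3 / 4, 1)))
  expect_equal(n1$prop_physicians_within, mean(c(2 / 3, 1)))

  n2 <- prof[network_id == "N2"]
  expect_equal(n2$n_physicians, 2L)
  expect_equal(n2$n_patients, 1L)
  expect_equal(n2$n_edges, 1L)                  # only d-e internal
  expect_equal(n2$degree_centrality, 0.5)
  expect_equal(n2$density, 1)
  expect_true(is.na(n2$transitivity))           # V < 3
  expect_equal(n2$mean_shared_per_edge, 25)
  expect_equal(n2$prop_visits_within, 3 / 4)
  expect_equal(n2$prop_physicians_within, 2 / 3)

  # a network of one practice only
  part1 <- partition_fixture(list(N1 = c("a", "b")))
  phys1 <- physicians[physician_id %in% c("a", "b")]
  co1 <- visits("p1", "a", "2016-01-01")
  cohort1 <- structure(list(included_physicians = c("a", "b"),
                            included_patients = "p1",
                            qualifying_consultations = co1,
                            patient_groups = data.table::data.table(
                              patient_id = "p1", group_id = 7L),
                            config = cfg), class = "cohort_bundle")
  alloc1 <- allocate_patients(cohort1, part1, cfg)
  prof1 <- build_profiles(part1, alloc1, cohort1,
                          sg_fixture(edges[1][, weight := 30],
                                     vertices = c("a", "b")),
                          phys1, cfg)
  expect_equal(prof1$n_practices, 1L)
  expect_equal(prof1$mean_physicians_per_practice, prof1$n_physicians)
})

test_that("central physicians are ranked by intra-network degree with id ties", {
  part <- partition_fixture(list(N1 = c("a", "b", "c", "d")))
  edges <- data.table::data.table(
    phys_a = c("a", "a", "a", "b"),
    phys_b = c("b", "c", "d", "c"),
    weight = 1)
  g <- sg_fixture(edges, vertices = c("a", "b", "c", "d"))
  cp <- central_physicians(part, g, top = 4)
  expect_equal(cp$physician_id, c("a", "b", "c", "d"))  # deg 3, 2, 2, 1: b<c tie
  expect_equal(cp$degree, c(3L, 2L, 2L, 1L))
})

test_that("mean degree times vertices equals twice the edges on pipeline output", {
  sim <- generate_bundle(sim_config(seed = 43))
  res <- run_pipeline(sim$bundle, pipeline_config(seed = 43))
  pr <- res$profiles
  expect_equal(pr$mean_degree * pr$n_physicians, 2 * pr$n_edges)
  expect_true(all(pr$density >= 0 & pr$density <= 1))
  expect_true(all(is.na(pr$transitivity) | (pr$transitivity >= 0 & pr$transitivity <= 1)))
  expect_true(all(pr$degree_centrality >= 0))
  # allocated patients spend on average more than half their days inside
  expect_true(all(pr$prop_visits_within > 0.5))
  # specialty shares sum to one within each network
  comp <- specialty_composition(res$partition, sim$bundle$physicians)
  sums <- comp[, sum(share), by = network_id]$V1
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
})
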