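# Relational Density Theory metrics: nodal distances, class size, relation
# counts, density measures, relational mass and the correlation pipeline.

test_that("true nodal distance matches hand enumeration, igraph, and the penalty rule", {
  # adjacent pair: zero intermediates
  sp2 <- space_with_edges(list(c("A1", "B1", 5)))
  expect_equal(true_nodal_distance(sp2, 1), 0)

  # linear five-member class: 0+1+2+3+0+1+2+0+1+0 = 10
  lin <- linear_class_space(h = 5)
  expect_equal(true_nodal_distance(lin, 1), 10)

  # independent cross-check with igraph shortest paths over all pairs
  g <- igraph::graph_from_data_frame(edge_list(lin)[, 1:2], directed = FALSE)
  d <- igraph::distances(g)
  labs <- sort(igraph::V(g)$name)
  total <- 0
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (a < b) total <- total + (d[labs[a], labs[b]] - 1)
    }
  }
  expect_equal(true_nodal_distance(lin, 1), total)

  # fully connected class collapses to zero
  full <- lin
  labs <- full$labels
  for (i in labs) for (j in labs) if (i != j) full <- edit_relation(full, i, j, 5)
  expect_equal(true_nodal_distance(full, 1), 0)

  # disconnected member: finite penalty (members - 1) per unreachable pair
  iso <- space_with_edges(list(c("A1", "B1", 5)), extra = "C1")
  expect_equal(true_nodal_distance(iso, 1), 2 + 2)  # (A1,C1), (B1,C1)

  # singleton class and sub-threshold edges
  expect_equal(true_nodal_distance(space_with_edges(list(), extra = "A1"), 1), 0)
  weak <- space_with_edges(list(c("A1", "B1", 0.5)))
  expect_equal(true_nodal_distance(weak, 1), 1)  # below threshold: penalty
})

test_that("empirical nodal distance is a pure function of the training structure", {
  tp3 <- rbind(c("A1", "B1"), c("B1", "C1"))
  sp3 <- space_with_edges(list(c("A1", "B1", 9), c("B1", "C1", 9)))
  expect_equal(empirical_nodal_distance(sp3, 1, tp3), 1)    # (A,C) via B

  # two-member class, pair directly trained: nothing untrained to measure
  sp2 <- space_with_edges(list(c("A1", "B1", 9)))
  expect_equal(empirical_nodal_distance(sp2, 1, rbind(c("A1", "B1"))), 0)

  # linear five-member class: untrained pairs contribute 1+2+3+1+2+1 = 10
  lin <- linear_class_space(h = 5)
  tp5 <- rbind(c("A1", "B1"), c("B1", "C1"), c("C1", "D1"), c("D1", "E1"))
  expect_equal(empirical_nodal_distance(lin, 1, tp5), 10)

  # perturbing h-values leaves it bit-identical
  pert <- lin
  pert$H[!is.na(pert$H)] <- stats::runif(sum(!is.na(pert$H)), -5, 50)
  expect_identical(empirical_nodal_distance(pert, 1, tp5),
                   empirical_nodal_distance(lin, 1, tp5))
})

test_that("class size counts roster members present, never comparison-only foils", {
  cfg <- make_fixture("cotter_stewart")
  sp <- new_clip_space()
  for (lab in c("A3", "B3", "C3", "D3")) sp <- ensure_clip(sp, lab)
  expect_equal(class_size(sp, 3, cfg$classes), 3L)   # D3 is not a member
  expect_equal(class_size(sp, 3), 4L)                # label-parsing fallback
  expect_equal(class_size(sp, 1, cfg$classes), 0L)
  sp <- ensure_clip(sp, "A1")
  expect_equal(class_size(sp, 1, cfg$classes), 1L)
})

test_that("relation counts respect thresholds, mirrors and class membership", {
  blank <- space_with_edges(list(), extra = c("A1", "B1"))
  expect_equal(num_relations(blank, 1), 0L)
  pair <- space_with_edges(list(c("A1", "B1", 2)), mirror = TRUE)
  expect_equal(num_relations(pair, 1), 2L)           # forward + mirror
  # sub-threshold and inter-class edges do not count
  mixed <- space_with_edges(list(c("A1", "B1", 2), c("B1", "C1", 1.0),
                                 c("A1", "B2", 8)))
  expect_equal(num_relations(mixed, 1), 1L)
})

test_that("mean transition probability behaves as an inverse effective relation count", {
  # singleton class with no relations: the early spike at 1.0
  solo <- space_with_edges(list(), extra = "A1")
  expect_equal(mean_transition_probability(solo, 1, beta_h = 0.1), 1.0)

  # beta = 0: exactly 1 / number of intra-class relations
  lin <- linear_class_space(h = 5)
  expect_equal(mean_transition_probability(lin, 1, beta_h = 0), 1 / 8)

  # equal h at any beta: still 1 / count; sharpening raises it
  expect_equal(mean_transition_probability(lin, 1, beta_h = 2), 1 / 8)
  sharp <- edit_relation(lin, "A1", "B1", 50)
  expect_gt(mean_transition_probability(sharp, 1, beta_h = 2), 1 / 8)

  # multi-member class with no intra-class relations: missing
  blank <- space_with_edges(list(), extra = c("A1", "B1"))
  expect_true(is.na(mean_transition_probability(blank, 1, 0.1)))

  # bounded in (0, 1] along a real training run
  cfg <- make_fixture("two_class_linear")
  a <- run_agent(cfg, seed = 12)
  v <- a$series$mean_transition_probability
  v <- v[is.finite(v)]
  expect_true(all(v > 0 & v <= 1))
})

test_that("class accuracy and mean h follow their defining arithmetic", {
  recs <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE),
                     class_id = c(1L, 1L, 1L, 1L))
  expect_equal(class_accuracy(recs, 1), 0.75)
  expect_true(is.na(class_accuracy(recs, 3)))

  sp <- space_with_edges(list(c("A1", "B1", 2), c("B1", "C1", 4)))
  expect_equal(mean_h(sp, 1), 3.0)
  expect_true(is.na(mean_h(space_with_edges(list(), extra = "A1"), 1)))
})

test_that("relational mass is the bilinear density-volume product", {
  expect_equal(relational_mass(0.25, 10), 2.5)
  expect_equal(relational_mass(0.4, 0), 0)
  expect_equal(relational_mass(3 * 0.25, 10), 3 * relational_mass(0.25, 10))
  expect_true(is.na(relational_mass(NA_real_, 10)))
})

test_that("mass correlations reproduce hand-computed Pearson coefficients", {
  meas <- rdt_measures()
  base <- data.frame(step = 1:5, class_id = 1L)
  for (m in c(meas$density, meas$volume)) base[[m]] <- NA_real_
  # density = -volume exactly -> r = -1; constant series -> missing;
  # the hand pair x = 1..5, y = (2,1,4,3,5) -> r = 0.8
  base$mean_transition_probability <- c(2, 1, 4, 3, 5)
  base$class_size <- 1:5
  base$mean_h <- -(1:5)
  base$num_relations <- 1:5
  base$class_accuracy <- rep(0.5, 5)
  out <- mass_correlations(list(base))
  s <- out$summary
  pick <- function(d, v) s$mean_r[s$density == d & s$volume == v]
  expect_equal(pick("mean_h", "num_relations"), -1.0)
  expect_equal(pick("mean_transition_probability", "class_size"), 0.8)
  expect_true(is.na(pick("class_accuracy", "class_size")))  # zero variance
  expect_equal(nrow(s), 12L)                                # 3 x 4 grid
})

test_that("density and class size stay inversely related across seeded mini-cohorts", {
  cfg <- make_fixture("two_class_linear")
  for (base in c(10L, 40L, 70L)) {
    cfg$base_seed <- base
    co <- run_cohort(cfg, keep_agents = FALSE)
    s <- co$correlations$summary
    r <- s$mean_r[s$density == "mean_transition_probability" &
                    s$volume == "class_size"]
    expect_lt(r, 0)
  }
})
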