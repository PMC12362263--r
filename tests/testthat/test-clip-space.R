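# The agent's memory: clip creation, the h-value update rule, the softmax
# transition rule, feedback, the relation editor, and graph/matrix views.

test_that("clips are created once, idempotently, with first sighting preserved", {
  space <- new_clip_space()
  space <- ensure_clip(space, "A1", step = 0L)
  expect_equal(n_clips(space), 1L)
  expect_equal(space$first_seen, 0L)
  space$step <- 7L
  space <- ensure_clip(space, "A1")
  expect_equal(n_clips(space), 1L)
  expect_equal(space$first_seen, 0L)

  # the full four-class linear design has 5 + 5 + 3 + 3 = 16 class members
  cfg <- make_fixture("cotter_stewart")
  for (lab in unlist(cfg$classes)) space <- ensure_clip(space, lab)
  expect_equal(n_clips(space), 16L)

  expect_error(ensure_clip(new_clip_space(), "A"), "malformed")
  expect_error(ensure_clip(new_clip_space(), "1A"), "malformed")
})

test_that("the h-value update rule matches direct substitution and has fixed point 1", {
  expect_equal(update_h(1, 0.001, 1), 2.0)
  expect_equal(update_h(1, 0.42, 0), 1.0)
  expect_equal(update_h(5, 0.5, 0), 3.0)

  # lambda = 0: |h - 1| strictly decreasing toward the fixed point, any start
  for (start in c(-10, 0.5, 7)) {
    for (gamma in c(0.001, 0.3, 1)) {
      h <- start
      gaps <- numeric(30)
      for (k in 1:30) {
        h <- update_h(h, gamma, 0)
        gaps[k] <- abs(h - 1)
      }
      expect_true(all(diff(gaps) <= 0))
      expect_lt(gaps[30], abs(start - 1))
    }
  }
})

test_that("feedback reinforces the chosen edge (and its mirror) and nothing else", {
  p <- agent_params(gamma = 0.001)
  space <- space_with_edges(list(), extra = c("A1", "B1", "B2"))
  space <- apply_feedback(space, "A1", "B1", correct = TRUE, params = p)
  i <- match("A1", space$labels)
  j <- match("B1", space$labels)
  expect_equal(space$H[i, j], 2.0)
  expect_equal(space$H[j, i], 2.0)          # mirrored reinforcement
  expect_equal(space$kind[i, j], "baseline")
  expect_equal(space$kind[j, i], "symmetry_trained")
  expect_equal(n_relations_total(space), 2L)

  space2 <- apply_feedback(space, "A1", "B2", correct = FALSE, params = p)
  k <- match("B2", space2$labels)
  expect_equal(space2$H[i, k], 0.0)         # 1 - 0 + (-1)
  expect_equal(space2$kind[i, k], "incorrect")
  # exactly the chosen edge and its mirror changed
  changed <- which((is.na(space$H) != is.na(space2$H)) |
                     (!is.na(space$H) & !is.na(space2$H) &
                        space$H != space2$H))
  expect_equal(length(changed), 2L)

  # additive chain with gamma = 0
  p0 <- agent_params(gamma = 0, mirror_updates = FALSE)
  sp <- space_with_edges(list(), extra = c("A1", "B1"))
  for (r in 1:3) sp <- apply_feedback(sp, "A1", "B1", TRUE, p0)
  expect_equal(sp$H[match("A1", sp$labels), match("B1", sp$labels)], 4.0)

  expect_error(apply_feedback(space, "Z9", "B1", TRUE, p), "unknown clip")
})

test_that("softmax transition probabilities match the independent oracle and its invariances", {
  space <- space_with_edges(list(c("A1", "B1", 1), c("A1", "B2", 2)))
  p <- transition_probabilities(space, "A1", c("B1", "B2"), beta = 1)
  expect_equal(p, oracle_softmax(c(1, 2), 1), tolerance = 1e-12)
  expect_equal(p, c(0.26894, 0.73106), tolerance = 1e-4)

  # equal h -> uniform; beta = 0 -> uniform regardless of h
  sp <- space_with_edges(list(c("A1", "B1", 3), c("A1", "B2", 3),
                              c("A1", "B3", 3)))
  expect_equal(transition_probabilities(sp, "A1", c("B1", "B2", "B3"), 2),
               rep(1 / 3, 3))
  expect_equal(transition_probabilities(space, "A1", c("B1", "B2"), 0),
               c(0.5, 0.5))

  # missing edges score at h0, sums conserved, shift invariance
  sp2 <- space_with_edges(list(c("A1", "B1", 4)), extra = c("B2", "B3"))
  p2 <- transition_probabilities(sp2, "A1", c("B1", "B2", "B3"), 0.5, h0 = 1)
  expect_equal(p2, oracle_softmax(c(4, 1, 1), 0.5), tolerance = 1e-12)
  for (beta in c(0, 0.1, 1, 4)) {
    expect_equal(sum(transition_probabilities(space, "A1", c("B1", "B2"),
                                              beta)), 1, tolerance = 1e-12)
  }
  shifted <- space_with_edges(list(c("A1", "B1", 101), c("A1", "B2", 102)))
  expect_equal(transition_probabilities(shifted, "A1", c("B1", "B2"), 1),
               p, tolerance = 1e-10)

  expect_error(transition_probabilities(space, "A1", character(0), 1),
               "non-empty")
})

test_that("comparison selection is seeded, respects limits, and tracks the softmax", {
  space <- space_with_edges(list(c("A1", "B1", 1), c("A1", "B2", 2)))
  expect_equal(select_comparison(space, "A1", "B1", beta = 1), "B1")

  set.seed(11)
  draws <- replicate(200, select_comparison(space, "A1", c("B1", "B2"),
                                            beta = 50))
  expect_true(all(draws == "B2"))           # argmax regime

  set.seed(99)
  freq <- mean(replicate(10000, select_comparison(
    space, "A1", c("B1", "B2"), beta = 1)) == "B2")
  expect_equal(freq, oracle_softmax(c(1, 2), 1)[2], tolerance = 0.02)
})

test_that("the relation editor sets, creates and logs relations with exact round trips", {
  space <- space_with_edges(list(c("A1", "B1", 2)), extra = "C1")
  space <- edit_relation(space, "A1", "B1", 0.5)
  expect_equal(weight_matrix(space)["A1", "B1"], 0.5)
  n0 <- n_relations_total(space)
  space <- edit_relation(space, "A1", "C1", 1.25)
  expect_equal(n_relations_total(space), n0 + 1L)
  expect_identical(weight_matrix(space)["A1", "C1"], 1.25)
  expect_equal(length(space$audit), 2L)
  expect_error(edit_relation(space, "A1", "Z9", 1), "unknown clip")
})

test_that("matrix and edge-list views describe the same graph, and files round-trip", {
  space <- space_with_edges(list(c("A1", "B1", 2.5), c("B1", "C1", -1.5),
                                 c("C1", "A1", 0.125)), extra = "D1")
  W <- weight_matrix(space)
  el <- edge_list(space)
  for (r in seq_len(nrow(el))) {
    expect_identical(W[el$source[r], el$target[r]], el$h[r])
  }
  expect_equal(sum(W != 0), nrow(el))

  rebuilt <- clip_space_from_edges(el, labels = space$labels)
  expect_same_graph(space, rebuilt)

  tsv <- tempfile(fileext = ".tsv")
  export_edge_list(space, tsv)
  expect_same_graph(space, import_edge_list(tsv, labels = space$labels))

  gml <- tempfile(fileext = ".graphml")
  export_graphml(space, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  ge <- igraph::as_data_frame(g, what = "edges")
  expect_setequal(paste(ge$from, ge$to, signif(ge$h, 10)),
                  paste(el$source, el$target, signif(el$h, 10)))
})
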