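# The matching-to-sample environment: block construction, feedback
# delivery, mastery gating, per-class tracking and entailment testing.

test_that("blocks have the designed trial counts and comparison sets include foils", {
  cfg <- make_fixture("cotter_stewart")
  lmap <- letter_map(cfg$universe)
  set.seed(1)
  sizes <- vapply(cfg$phases, function(ph) length(build_block(ph, lmap)$sample),
                  integer(1))
  expect_equal(sizes, c(48L, 48L, 24L, 24L, 72L))

  b3 <- build_block(cfg$phases[[3]], lmap)      # CD training, classes 1-2
  expect_true(all(vapply(b3$comparisons, identical, logical(1),
                         c("D1", "D2", "D3", "D4"))))
  # every pair presented exactly presentations_per_pair times
  expect_equal(unname(table(paste(b3$sample, b3$correct))),
               as.array(rep(12L, 2L)), ignore_attr = TRUE)

  bad <- phase_spec("bad", rbind(c("A1", "Z9")), 2)
  expect_error(build_block(bad, lmap), "outside the design")
})

test_that("feedback is train-only, accuracy spans argmax to chance regimes", {
  cfg <- make_fixture("two_class_linear")
  lmap <- letter_map(cfg$universe)
  ph <- cfg$phases[[1]]

  # argmax regime: strong correct edges, huge beta -> perfect block
  strong <- space_with_edges(list(c("A1", "B1", 50), c("A2", "B2", 50)),
                             extra = cfg$universe)
  p_hi <- agent_params(beta_h = 50)
  set.seed(3)
  r <- run_block(strong, ph, p_hi, lmap)
  expect_equal(r$accuracy, 1.0)

  # beta = 0: long-run accuracy converges to chance 1 / |comparisons|
  p_0 <- agent_params(beta_h = 0, mirror_updates = FALSE)
  set.seed(5)
  hits <- 0L
  n <- 0L
  sp <- new_clip_space()
  for (b in 1:40) {
    r <- run_block(sp, ph, p_0, lmap, block_index = b)
    sp <- r$space
    hits <- hits + sum(r$records$correct)
    n <- n + nrow(r$records)
  }
  ci <- stats::binom.test(hits, n, p = 0.5)$conf.int  # 2 comparisons here
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])

  # test mode leaves every h-value unchanged
  test_ph <- phase_spec("probe", ph$pairs, 4, mode = "test")
  set.seed(7)
  r2 <- run_block(strong, test_ph, agent_params(), lmap)
  expect_identical(r2$space$H, strong$H)
})

test_that("mastery gating repeats blocks, flags non-convergence, conserves trials", {
  cfg <- make_fixture("two_class_linear")
  lmap <- letter_map(cfg$universe)
  ph <- cfg$phases[[1]]
  params <- agent_params()

  set.seed(2)
  res <- run_phase_to_mastery(new_clip_space(), ph, params, lmap,
                              criterion = 0.9, max_blocks = 50L)
  expect_true(res$converged)
  expect_gte(res$final_accuracy, 0.9)
  block_size <- nrow(ph$pairs) * ph$presentations_per_pair
  expect_equal(nrow(res$records), res$blocks_used * block_size)

  # an unreachable criterion under beta = 0 hits max_blocks and is flagged
  set.seed(2)
  res2 <- run_phase_to_mastery(new_clip_space(), ph,
                               agent_params(beta_h = 0), lmap,
                               criterion = 1, max_blocks = 3L)
  expect_false(res2$converged)
  expect_equal(res2$blocks_used, 3L)

  # raising the criterion never needs fewer blocks (matched seeds)
  for (seed in 1:4) {
    used <- vapply(c(0.5, 0.75, 0.9), function(cr) {
      set.seed(seed)
      run_phase_to_mastery(new_clip_space(), ph, params, lmap,
                           criterion = cr, max_blocks = 50L)$blocks_used
    }, integer(1))
    expect_true(all(diff(used) >= 0))
  }
})

test_that("class success rates follow the empty-denominator rule", {
  recs <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                     class_id = c(1L, 1L, 1L, 1L, 2L))
  rates <- class_success_rates(recs)
  expect_equal(rates[["1"]], 0.75)
  expect_equal(rates[["2"]], 1.0)
  expect_false("3" %in% names(rates))
  expect_equal(length(class_success_rates(recs[0, ])), 0L)
})

test_that("entailment tests are feedback-free and resolve by derived edge strength", {
  cfg <- make_fixture("two_class_linear")
  lmap <- letter_map(cfg$universe)
  tags <- entailment_tags("A-C", 1:2)

  # strong derived A -> C edges dominate at large beta_t
  sp <- space_with_edges(list(c("A1", "C1", 30), c("A2", "C2", 30)),
                         extra = cfg$universe)
  set.seed(4)
  acc <- run_entailment_tests(sp, agent_params(beta_t = 50), tags, lmap,
                              presentations = 8L)
  expect_equal(unname(acc["A-C"]), 1.0)
  expect_identical(sp$H, space_with_edges(
    list(c("A1", "C1", 30), c("A2", "C2", 30)), extra = cfg$universe)$H)

  # an untrained agent sits at chance (2 comparisons here)
  blank <- new_clip_space()
  for (lab in cfg$universe) blank <- ensure_clip(blank, lab)
  set.seed(6)
  acc0 <- run_entailment_tests(blank, agent_params(), tags, lmap,
                               presentations = 200L)
  expect_equal(unname(acc0["A-C"]), 0.5, tolerance = 0.12)

  # the full-design tag list restricts D/E tags to classes 1-2
  tags_cs <- make_fixture("cotter_stewart")$entailment_tags
  de <- tags_cs[tags_cs$tag %in% c("D-C", "E-D", "A-E", "E-A"), ]
  expect_setequal(vapply(de$sample,
                         function(l) parse_stimulus_label(l)$class_id,
                         integer(1)), 1:2)
  expect_setequal(unique(tags_cs$tag),
                  c("A-C", "C-A", "C-B", "B-A", "D-C", "E-D", "A-E", "E-A"))
})
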