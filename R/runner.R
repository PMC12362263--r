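# Orchestration: single-agent runs, seeded multi-agent cohorts, and the
# side-by-side comparison of the two Network Enhancement scheduling
# conditions, with per-phase summary aggregation.

#' Run one agent through a full experiment
#'
#' Executes the configured phases in order with [run_phase_to_mastery()],
#' applies Network Enhancement per its schedule (after every mastered phase
#' under `"during_training"`, once before testing under
#' `"end_of_training"`), snapshots the RDT metric suite every
#' `rdt_sampling_stride` trials, and finishes with the entailment tests.
#' Fully deterministic given `seed`.
#'
#' @param config A validated experiment configuration
#'   (see [validate_config()] / [make_fixture()]).
#' @param seed Integer seed for this agent's random stream.
#' @return A list with `series` (RDT snapshot data frame), `phase_stats`
#'   (per-phase data frame: phase, trials_per_block, blocks_used,
#'   final_accuracy, converged), `test_accuracies` (named vector),
#'   `records` (full trial log), `ne_trace` (one row per enhancement
#'   application), `checkpoint` (relation count at the checkpoint step),
#'   `phase_boundaries`, `trained_pairs`, `space` and `seed`.
#' @export
run_agent <- function(config, seed) {
  config <- validate_config(config)
  set.seed(as.integer(seed))
  params <- config$agent
  ne <- config$ne
  lmap <- letter_map(config$universe)
  thr <- default_edge_threshold(params$h0)

  space <- new_clip_space()
  trained <- new.env(parent = emptyenv())
  trained$pairs <- matrix(character(0), 0L, 2L)
  trained$keys <- character(0)
  trained$version <- 0L

  ids <- names(config$classes)
  acc_correct <- stats::setNames(as.list(numeric(length(ids))), ids)
  acc_total <- acc_correct
  col <- new_rdt_collector(config$classes, params$beta_h, thr)
  stride <- config$rdt_sampling_stride
  checkpoint <- list(step = config$checkpoint_step,
                     n_relations = NA_integer_)
  n_seen <- 0L

  on_trial <- function(space, sample, correct_label, chosen, ok, feedback) {
    if (feedback) {
      key <- paste0(sample, ">", correct_label)
      if (!(key %in% trained$keys)) {
        trained$keys <- c(trained$keys, key)
        trained$pairs <- rbind(trained$pairs, c(sample, correct_label))
        trained$version <- trained$version + 1L
      }
      cl <- as.character(parse_stimulus_label(sample)$class_id)
      acc_correct[[cl]] <<- acc_correct[[cl]] + ok
      acc_total[[cl]] <<- acc_total[[cl]] + 1
    }
    if (length(space$labels) != n_seen) {       # new clips: refresh caches
      n_seen <<- length(space$labels)
      trained$version <- trained$version + 1L
    }
    if (space$step %% stride == 0L) {
      collect_snapshot(col, space, trained, acc_correct, acc_total)
    }
    if (!is.na(checkpoint$step) && space$step == checkpoint$step) {
      checkpoint$n_relations <<- n_relations_total(space)
    }
  }

  phase_rows <- vector("list", length(config$phases))
  rec_list <- vector("list", length(config$phases))
  ne_rows <- list()
  boundaries <- integer(0)

  for (p in seq_along(config$phases)) {
    ph <- config$phases[[p]]
    res <- run_phase_to_mastery(space, ph, params, lmap,
                                criterion = config$mastery_criterion,
                                max_blocks = config$max_blocks,
                                on_trial = on_trial)
    space <- res$space
    rec_list[[p]] <- res$records
    phase_rows[[p]] <- data.frame(
      phase = ph$name,
      trials_per_block = nrow(ph$pairs) * ph$presentations_per_pair,
      blocks_used = res$blocks_used,
      final_accuracy = res$final_accuracy,
      converged = res$converged,
      stringsAsFactors = FALSE)
    boundaries <- c(boundaries, space$step)
    if (identical(ne$schedule, "during_training")) {
      space <- apply_ne(space, ne)
      ne_rows[[length(ne_rows) + 1L]] <- attr(space, "ne_info")
      collect_snapshot(col, space, trained, acc_correct, acc_total)
    }
  }
  if (identical(ne$schedule, "end_of_training")) {
    space <- apply_ne(space, ne)
    ne_rows[[length(ne_rows) + 1L]] <- attr(space, "ne_info")
    collect_snapshot(col, space, trained, acc_correct, acc_total)
  }

  tests <- run_entailment_tests(space, params, config$entailment_tags, lmap,
                                config$test_presentations_per_tag)

  list(series = collector_series(col),
       phase_stats = do.call(rbind, phase_rows),
       test_accuracies = tests,
       records = do.call(rbind, rec_list),
       ne_trace = do.call(rbind, ne_rows),
       checkpoint = checkpoint,
       phase_boundaries = boundaries,
       trained_pairs = trained$pairs,
       space = space,
       seed = as.integer(seed))
}

#' Run a seeded cohort of independent agents
#'
#' Agent `i` runs with seed `base_seed + i`, so any single agent is
#' re-runnable in isolation and trajectories are invariant to `n_agents`.
#'
#' @param config Experiment configuration.
#' @param keep_agents Keep the per-agent raw results (default `TRUE`).
#' @return An object of class `cohort_result`: `per_phase` (data frame of
#'   per-phase means: trials_per_block, mean_blocks_to_mastery,
#'   mean_final_accuracy, n_converged), `test_accuracies` (tag means),
#'   `correlations` (output of [mass_correlations()]), `checkpoints`
#'   (per-agent relation counts at the checkpoint step), `seeds`,
#'   `n_agents`, `any_nonconverged`, and `agents` (per-agent raw results).
#' @export
run_cohort <- function(config, keep_agents = TRUE) {
  config <- validate_config(config)
  seeds <- config$base_seed + seq_len(config$n_agents)
  agents <- lapply(seeds, function(s) run_agent(config, s))

  stats_list <- lapply(agents, `[[`, "phase_stats")
  phases <- stats_list[[1L]]$phase
  per_phase <- data.frame(
    phase = phases,
    trials_per_block = stats_list[[1L]]$trials_per_block,
    mean_blocks_to_mastery = rowMeans(sapply(stats_list, `[[`, "blocks_used")),
    mean_final_accuracy = rowMeans(sapply(stats_list, `[[`, "final_accuracy")),
    n_converged = rowSums(sapply(stats_list, `[[`, "converged")),
    stringsAsFactors = FALSE)

  test_mat <- sapply(agents, `[[`, "test_accuracies")
  test_acc <- if (is.matrix(test_mat)) rowMeans(test_mat) else numeric(0)

  corr <- mass_correlations(lapply(agents, `[[`, "series"))
  checkpoints <- data.frame(
    agent = seq_along(agents),
    seed = seeds,
    step = vapply(agents, function(a) a$checkpoint$step, numeric(1)),
    n_relations = vapply(agents,
                         function(a) as.numeric(a$checkpoint$n_relations),
                         numeric(1)))
  nonconv <- any(!vapply(agents, function(a) all(a$phase_stats$converged),
                         logical(1)))
  if (nonconv) {
    warning("one or more agents did not reach the mastery criterion within ",
            "max_blocks", call. = FALSE)
  }
  structure(list(
    per_phase = per_phase,
    test_accuracies = test_acc,
    correlations = corr,
    checkpoints = checkpoints,
    seeds = seeds,
    n_agents = config$n_agents,
    any_nonconverged = nonconv,
    agents = if (keep_agents) agents else NULL,
    config = config
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$n_agents, " agents, NE schedule: ",
      x$config$ne$schedule, "\n", sep = "")
  print(x$per_phase, row.names = FALSE)
  invisible(x)
}

#' Compare the two Network Enhancement scheduling conditions
#'
#' Runs the configuration twice on identical seed sets: once with
#' enhancement deferred to the end of training and once with enhancement
#' at every mastery point, and tabulates per-phase means side by side
#' together with per-agent relation counts at the checkpoint step (before
#' the first enhancement, the end-of-training runs are the
#' no-enhancement reference).
#'
#' @param config Experiment configuration.
#' @param keep_agents Keep per-agent raw results in both cohorts.
#' @return A list with `end_of_training` and `during_training`
#'   (`cohort_result`s), `table` (side-by-side per-phase data frame) and
#'   `checkpoints` (per-agent, per-condition relation counts).
#' @export
compare_conditions <- function(config, keep_agents = TRUE) {
  config <- validate_config(config)
  cfg_end <- config
  cfg_end$ne$schedule <- "end_of_training"
  cfg_dur <- config
  cfg_dur$ne$schedule <- "during_training"
  end <- run_cohort(cfg_end, keep_agents)
  dur <- run_cohort(cfg_dur, keep_agents)
  tab <- data.frame(
    phase = end$per_phase$phase,
    trials_per_block = end$per_phase$trials_per_block,
    mean_blocks_end = end$per_phase$mean_blocks_to_mastery,
    mean_blocks_during = dur$per_phase$mean_blocks_to_mastery,
    mean_mastery_end = end$per_phase$mean_final_accuracy,
    mean_mastery_during = dur$per_phase$mean_final_accuracy,
    stringsAsFactors = FALSE)
  cp <- rbind(
    cbind(condition = "end_of_training", end$checkpoints),
    cbind(condition = "during_training", dur$checkpoints))
  list(end_of_training = end, during_training = dur,
       table = tab, checkpoints = cp)
}
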