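# The matching-to-sample task environment: phase schedules, block
# construction, differential feedback, mastery gating, per-class success
# tracking and derived-relation (entailment) testing.

#' Define a training or testing phase
#'
#' @param name Phase name, e.g. `"Phase 1: AB"`.
#' @param pairs Trained (sample, correct-comparison) pairs: a 2-column
#'   character matrix or a list of length-2 character vectors.
#' @param presentations_per_pair Times each pair is presented per block;
#'   block size is `nrow(pairs) * presentations_per_pair`.
#' @param mode `"train"`, `"mixed_train"` (feedback delivered, beta_h) or
#'   `"test"` (no feedback, beta_t).
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(name, pairs, presentations_per_pair,
                       mode = c("train", "mixed_train", "test")) {
  mode <- match.arg(mode)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  stopifnot(is.character(pairs), ncol(pairs) == 2L, nrow(pairs) >= 1L,
            is.numeric(presentations_per_pair), presentations_per_pair >= 1L)
  colnames(pairs) <- c("sample", "correct")
  classes_active <- sort(unique(vapply(
    pairs[, 1L], function(l) parse_stimulus_label(l)$class_id, integer(1))))
  structure(list(name = name, pairs = pairs,
                 presentations_per_pair = as.integer(presentations_per_pair),
                 classes_active = classes_active, mode = mode),
            class = "phase_spec")
}

#' Map role letters to the stimuli carrying them
#'
#' The comparison set of an MTS trial is every stimulus (across all classes,
#' including comparison-only foils) that carries the correct comparison's
#' role letter.
#'
#' @param universe Character vector of all stimulus labels in the design.
#' @return A named list, letter -> sorted labels.
#' @export
letter_map <- function(universe) {
  letters_of <- vapply(universe, function(l) parse_stimulus_label(l)$role,
                       character(1))
  lapply(split(universe, letters_of), sort)
}

#' Build one shuffled block of MTS trials for a phase
#'
#' Each trained pair appears `presentations_per_pair` times; presentation
#' order is shuffled (consumes the R random stream). The comparison set of
#' a trial is every stimulus sharing the correct comparison's role letter,
#' so comparison-only stimuli appear as foils.
#'
#' @param phase A [phase_spec()].
#' @param lmap A [letter_map()] over the design's stimulus universe.
#' @return A list with components `sample`, `correct` (character vectors)
#'   and `comparisons` (list of character vectors), one element per trial.
#' @export
build_block <- function(phase, lmap) {
  pairs <- phase$pairs
  comp_sets <- lapply(seq_len(nrow(pairs)), function(r) {
    letter <- parse_stimulus_label(pairs[r, 2L])$role
    comps <- lmap[[letter]]
    if (is.null(comps) || !(pairs[r, 2L] %in% comps) ||
        !(pairs[r, 1L] %in% unlist(lmap, use.names = FALSE))) {
      stop("phase '", phase$name, "' references stimuli outside the design: ",
           pairs[r, 1L], " -> ", pairs[r, 2L], call. = FALSE)
    }
    comps
  })
  idx <- rep(seq_len(nrow(pairs)), phase$presentations_per_pair)
  idx <- if (length(idx) > 1L) sample(idx) else idx
  list(sample = pairs[idx, 1L],
       correct = pairs[idx, 2L],
       comparisons = comp_sets[idx])
}

#' Run one block of trials
#'
#' Clips are auto-created on first sighting. In train modes each trial's
#' choice receives differential feedback via [apply_feedback()]; test mode
#' delivers no feedback and uses the testing temperature `beta_t`.
#'
#' @param space A `clip_space`.
#' @param phase A [phase_spec()].
#' @param params An [agent_params()].
#' @param lmap A [letter_map()] over the stimulus universe.
#' @param block_index Block number recorded in the trial log.
#' @param on_trial Optional callback `function(space, sample, correct_label,
#'   chosen, correct, feedback)` invoked after each trial (used by the
#'   experiment runner for metric snapshots).
#' @return A list with `space`, `records` (trial-log data frame) and
#'   `accuracy` (proportion correct in the block).
#' @export
run_block <- function(space, phase, params, lmap, block_index = 1L,
                      on_trial = NULL) {
  trials <- build_block(phase, lmap)
  n <- length(trials$sample)
  test_mode <- identical(phase$mode, "test")
  beta <- if (test_mode) params$beta_t else params$beta_h
  chosen <- character(n)
  correct <- logical(n)
  steps <- integer(n)
  for (t in seq_len(n)) {
    space$step <- space$step + 1L
    s <- trials$sample[t]
    comps <- trials$comparisons[[t]]
    if (!(s %in% space$labels)) space <- ensure_clip(space, s)
    for (cmp in comps) {
      if (!(cmp %in% space$labels)) space <- ensure_clip(space, cmp)
    }
    ch <- select_comparison(space, s, comps, beta, params$h0)
    ok <- identical(ch, trials$correct[t])
    if (!test_mode) space <- apply_feedback(space, s, ch, ok, params)
    chosen[t] <- ch
    correct[t] <- ok
    steps[t] <- space$step
    if (!is.null(on_trial)) {
      on_trial(space, s, trials$correct[t], ch, ok, !test_mode)
    }
  }
  records <- data.frame(
    step = steps,
    phase = phase$name,
    block = as.integer(block_index),
    sample = trials$sample,
    comparisons = vapply(trials$comparisons, paste, "", collapse = "|"),
    chosen = chosen,
    correct = correct,
    class_id = vapply(trials$sample,
                      function(l) parse_stimulus_label(l)$class_id,
                      integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(space = space, records = records, accuracy = mean(correct))
}

#' Repeat blocks of a training phase until the mastery criterion is met
#'
#' Blocks are repeated until block accuracy reaches `criterion` or
#' `max_blocks` is hit; non-convergence is flagged, never raised.
#' `blocks_used` is the "time" statistic of the per-phase summary table.
#'
#' @inheritParams run_block
#' @param criterion Mastery criterion in (0, 1] (block accuracy threshold).
#' @param max_blocks Upper bound on blocks before flagging non-convergence.
#' @return A list with `space`, `records` (all blocks), `blocks_used`,
#'   `final_accuracy` and `converged`.
#' @export
run_phase_to_mastery <- function(space, phase, params, lmap, criterion,
                                 max_blocks = 50L, on_trial = NULL) {
  stopifnot(criterion > 0, criterion <= 1, max_blocks >= 1L)
  recs <- vector("list", max_blocks)
  blocks <- 0L
  acc <- NA_real_
  repeat {
    blocks <- blocks + 1L
    r <- run_block(space, phase, params, lmap, block_index = blocks,
                   on_trial = on_trial)
    space <- r$space
    recs[[blocks]] <- r$records
    acc <- r$accuracy
    if (acc >= criterion || blocks >= max_blocks) break
  }
  list(space = space,
       records = do.call(rbind, recs[seq_len(blocks)]),
       blocks_used = blocks,
       final_accuracy = acc,
       converged = acc >= criterion)
}

#' Per-class success rates over a trial log
#'
#' @param records Trial-log data frame as produced by [run_block()].
#' @return A named numeric vector, class id -> proportion correct over all
#'   trials whose sample belongs to the class. Classes with no trials are
#'   absent from the result.
#' @export
class_success_rates <- function(records) {
  if (NROW(records) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- tapply(records$correct, records$class_id, mean)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Build entailment-test tag instances for a linear-series design
#'
#' Tags such as `"A-C"` denote testing the relation sample letter -> correct
#' letter within each listed class (e.g. A1 -> C1 for class 1).
#'
#' @param tags Character vector like `c("A-C", "C-A")`.
#' @param classes Integer vector of class ids the tags apply to.
#' @return A data frame with columns `tag`, `sample`, `correct`.
#' @export
entailment_tags <- function(tags, classes) {
  out <- do.call(rbind, lapply(tags, function(tg) {
    parts <- strsplit(tg, "-", fixed = TRUE)[[1L]]
    stopifnot(length(parts) == 2L)
    data.frame(tag = tg,
               sample = paste0(parts[1L], classes),
               correct = paste0(parts[2L], classes),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test derived (entailment) relations without feedback
#'
#' Every tag instance is presented `presentations` times with the testing
#' temperature `beta_t`; no h-value changes. Accuracy is reported per tag.
#'
#' @param space A trained `clip_space`.
#' @param params An [agent_params()].
#' @param tags A data frame from [entailment_tags()] (columns `tag`,
#'   `sample`, `correct`).
#' @param lmap A [letter_map()] over the stimulus universe.
#' @param presentations Presentations per tag instance (default 4).
#' @return A named numeric vector, tag -> accuracy.
#' @export
run_entailment_tests <- function(space, params, tags, lmap,
                                 presentations = 4L) {
  if (NROW(tags) == 0L) return(stats::setNames(numeric(0), character(0)))
  hits <- stats::setNames(numeric(length(unique(tags$tag))), unique(tags$tag))
  tot <- hits
  for (r in seq_len(nrow(tags))) {
    s <- tags$sample[r]
    corr <- tags$correct[r]
    comps <- lmap[[parse_stimulus_label(corr)$role]]
    if (!(s %in% space$labels)) space <- ensure_clip(space, s)
    for (cmp in comps) {
      if (!(cmp %in% space$labels)) space <- ensure_clip(space, cmp)
    }
    for (k in seq_len(presentations)) {
      ch <- select_comparison(space, s, comps, params$beta_t, params$h0)
      hits[tags$tag[r]] <- hits[tags$tag[r]] + (ch == corr)
      tot[tags$tag[r]] <- tot[tags$tag[r]] + 1
    }
  }
  hits / tot
}
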