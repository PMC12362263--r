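# The agent's episodic-compositional memory: a weighted directed graph of
# stimulus clips. Edge weights (h-values) drive comparison choice through a
# softmax transition rule and are updated by differential reinforcement with
# damping toward the resting value 1.

#' Parse a stimulus label into its role letter and class id
#'
#' Stimulus labels follow the `<letter><class>` convention of linear-series
#' equivalence designs, e.g. `"A1"` is the A-role member of class 1.
#'
#' @param label Character scalar such as `"A1"` or `"C4"`.
#' @return A list with elements `role` (character) and `class_id` (integer).
#' @export
parse_stimulus_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1L]]
  if (length(m) != 3L) {
    stop("malformed stimulus label '", label,
         "': expected <letter><class>, e.g. 'A1'", call. = FALSE)
  }
  list(role = m[2L], class_id = as.integer(m[3L]))
}

#' Create an empty clip space
#'
#' A clip space is the agent's memory: a set of stimulus clips plus a
#' weighted directed graph of relations between them. Internally the
#' relations are held as square matrices over the clips added so far;
#' `NA` cells are absent edges (the weight-matrix view reads them as 0).
#'
#' @return An object of class `clip_space` with fields `labels`, `class_id`,
#'   `role`, `first_seen`, `H` (h-value matrix), `kind` (relation kind
#'   matrix: `"baseline"`, `"symmetry_trained"`, `"derived"` or
#'   `"incorrect"`), `created` (creation-step matrix), `step` (trial
#'   counter) and `audit` (relation-editor log).
#' @export
new_clip_space <- function() {
  structure(list(
    labels     = character(0),
    class_id   = integer(0),
    role       = character(0),
    first_seen = integer(0),
    H          = matrix(NA_real_, 0L, 0L),
    kind       = matrix(NA_character_, 0L, 0L),
    created    = matrix(NA_integer_, 0L, 0L),
    step       = 0L,
    audit      = list()
  ), class = "clip_space")
}

#' @export
print.clip_space <- function(x, ...) {
  cat("<clip_space> ", length(x$labels), " clips, ",
      sum(!is.na(x$H)), " relations, step ", x$step, "\n", sep = "")
  invisible(x)
}

#' Number of clips in a clip space
#' @param space A `clip_space`.
#' @return Integer count.
#' @export
n_clips <- function(space) length(space$labels)

#' Number of stored relations (directed edges) in a clip space
#' @param space A `clip_space`.
#' @return Integer count of directed edges present (any kind, any h).
#' @export
n_relations_total <- function(space) sum(!is.na(space$H))

clip_index <- function(space, label) {
  i <- match(label, space$labels)
  if (anyNA(i)) {
    stop("unknown clip label(s): ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Ensure a stimulus clip exists in the clip space
#'
#' A clip is created the first time a stimulus is observed. Re-adding an
#' existing label is a no-op and preserves the original `first_seen_step`.
#'
#' @param space A `clip_space`.
#' @param label Stimulus label (must parse as `<letter><class>`).
#' @param step Step at which the stimulus was first seen; defaults to the
#'   space's current trial counter.
#' @return The (possibly grown) `clip_space`.
#' @export
ensure_clip <- function(space, label, step = space$step) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (label %in% space$labels) return(space)
  info <- parse_stimulus_label(label)
  n <- length(space$labels)
  space$labels     <- c(space$labels, label)
  space$class_id   <- c(space$class_id, info$class_id)
  space$role       <- c(space$role, info$role)
  space$first_seen <- c(space$first_seen, as.integer(step))
  grow <- function(m, fill) {
    out <- matrix(fill, n + 1L, n + 1L)
    if (n > 0L) out[seq_len(n), seq_len(n)] <- m
    out
  }
  space$H       <- grow(space$H, NA_real_)
  space$kind    <- grow(space$kind, NA_character_)
  space$created <- grow(space$created, NA_integer_)
  space
}

#' Projective-simulation h-value update
#'
#' One application of the reinforcement rule
#' `h' = h - gamma * (h - 1) + lambda`: the weight is damped toward the
#' resting value 1 and shifted by the reward `lambda`. With `lambda = 0`
#' the rule has fixed point 1 for any `gamma` in (0, 1].
#'
#' @param h Current h-value (finite numeric).
#' @param gamma Damping rate in \[0, 1\].
#' @param lam Reward increment (positive on correct, negative on incorrect).
#' @return The updated h-value. Vectorised over `h`.
#' @export
update_h <- function(h, gamma, lam) h - gamma * (h - 1) + lam

#' Agent parameters
#'
#' @param gamma Damping rate toward the resting h-value 1, in \[0, 1\].
#' @param beta_h Softmax temperature used during training; smaller values
#'   slow learning.
#' @param beta_t Softmax temperature used during derived-relation testing.
#' @param h0 Initial h-value for a newly created relation (also the value
#'   assumed for absent edges at choice time, so novel comparisons are
#'   choosable at chance).
#' @param reward_correct Reward `lambda` applied on a correct match.
#' @param reward_incorrect Reward `lambda` applied on an incorrect match.
#' @param mirror_updates If `TRUE` (default) the reverse edge
#'   (chosen -> sample) receives the same reward, the minimal mechanism by
#'   which symmetry relations arise during training.
#' @param global_damping If `TRUE`, every stored edge is additionally damped
#'   toward 1 once per feedback event (global forgetting). Off by default:
#'   the update rule already damps the reinforced edge, and per-trial global
#'   decay of all weights is incompatible with mixed-training performance
#'   after several hundred trials (see the methods vignette).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(gamma = 0.001, beta_h = 0.1, beta_t = 4, h0 = 1,
                         reward_correct = 1, reward_incorrect = -1,
                         mirror_updates = TRUE, global_damping = FALSE) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
            is.numeric(beta_h), beta_h >= 0,
            is.numeric(beta_t), beta_t >= 0,
            is.finite(h0), is.finite(reward_correct),
            is.finite(reward_incorrect),
            is.logical(mirror_updates), is.logical(global_damping))
  structure(list(gamma = gamma, beta_h = beta_h, beta_t = beta_t, h0 = h0,
                 reward_correct = reward_correct,
                 reward_incorrect = reward_incorrect,
                 mirror_updates = mirror_updates,
                 global_damping = global_damping),
            class = "agent_params")
}

#' Apply differential feedback to the clip space after a choice
#'
#' The edge sample -> chosen receives one h-value update with
#' `lambda = reward_correct` or `reward_incorrect`. Under `mirror_updates`
#' the reverse edge receives the same reward (created with kind
#' `"symmetry_trained"` on correct, `"incorrect"` otherwise). Edges are
#' initialised at `h0` when absent. A correct direct reinforcement upgrades
#' the forward edge's kind to `"baseline"`.
#'
#' @param space A `clip_space`; both clips must already exist.
#' @param sample Sample stimulus label.
#' @param chosen Chosen comparison label.
#' @param correct Logical: was the choice correct?
#' @param params An [agent_params()] object.
#' @return The updated `clip_space`.
#' @export
apply_feedback <- function(space, sample, chosen, correct, params) {
  i <- clip_index(space, sample)
  j <- clip_index(space, chosen)
  lam <- if (correct) params$reward_correct else params$reward_incorrect

  if (params$global_damping) {
    idx <- which(!is.na(space$H))
    if (length(idx)) space$H[idx] <- update_h(space$H[idx], params$gamma, 0)
  }

  touch <- function(space, a, b, forward) {
    if (is.na(space$H[a, b])) {
      space$H[a, b] <- update_h(params$h0, params$gamma, lam)
      space$kind[a, b] <- if (!correct) "incorrect"
                          else if (forward) "baseline" else "symmetry_trained"
      space$created[a, b] <- space$step
    } else {
      space$H[a, b] <-
        if (params$global_damping) space$H[a, b] + lam
        else update_h(space$H[a, b], params$gamma, lam)
      if (correct) {
        k <- space$kind[a, b]
        if (forward && !identical(k, "baseline")) space$kind[a, b] <- "baseline"
        if (!forward && identical(k, "derived")) {
          space$kind[a, b] <- "symmetry_trained"
        }
      }
    }
    space
  }

  space <- touch(space, i, j, forward = TRUE)
  if (params$mirror_updates && i != j) {
    space <- touch(space, j, i, forward = FALSE)
  }
  space
}

#' Softmax transition probabilities over a comparison set
#'
#' `p_i = exp(beta * h_i) / sum_k exp(beta * h_k)` over the comparison set
#' only, computed with max-subtraction for overflow safety. Absent edges are
#' scored at `h0`, so untrained comparisons are choosable at chance.
#'
#' @param space A `clip_space`; sample and comparisons must exist as clips.
#' @param sample Sample stimulus label.
#' @param comparisons Non-empty character vector of comparison labels.
#' @param beta Softmax temperature (>= 0; 0 gives the uniform distribution).
#' @param h0 Value assumed for missing edges (default 1).
#' @return Numeric probability vector over `comparisons`, summing to 1.
#' @export
transition_probabilities <- function(space, sample, comparisons, beta,
                                     h0 = 1) {
  if (length(comparisons) < 1L) {
    stop("comparison set must be non-empty", call. = FALSE)
  }
  i <- clip_index(space, sample)
  j <- clip_index(space, comparisons)
  h <- space$H[i, j]
  h[is.na(h)] <- h0
  z <- beta * h
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

#' Sample one comparison according to the softmax transition rule
#'
#' Uses R's global random-number stream; seed the stream (e.g. with
#' [set.seed()]) for reproducible choices.
#'
#' @inheritParams transition_probabilities
#' @return A single label from `comparisons`.
#' @export
select_comparison <- function(space, sample, comparisons, beta, h0 = 1) {
  p <- transition_probabilities(space, sample, comparisons, beta, h0)
  comparisons[sample.int(length(comparisons), 1L, prob = p)]
}

#' Directly set a relation's h-value (programmatic relation editor)
#'
#' Sets the edge `source -> target` to `new_h`, creating it with kind
#' `"derived"` if absent, and logs an audit entry.
#'
#' @param space A `clip_space`; both clips must exist.
#' @param source,target Clip labels.
#' @param new_h Finite replacement h-value.
#' @return The updated `clip_space`.
#' @export
edit_relation <- function(space, source, target, new_h) {
  stopifnot(is.numeric(new_h), length(new_h) == 1L, is.finite(new_h))
  i <- clip_index(space, source)
  j <- clip_index(space, target)
  old <- space$H[i, j]
  if (is.na(old)) {
    space$kind[i, j] <- "derived"
    space$created[i, j] <- space$step
  }
  space$H[i, j] <- new_h
  space$audit[[length(space$audit) + 1L]] <-
    list(step = space$step, source = source, target = target,
         old_h = old, new_h = new_h)
  space
}

#' Weight-matrix view of a clip space
#'
#' Absent edges read as 0. Rows are percept/sample stimuli, columns are
#' action/comparison stimuli.
#'
#' @param space A `clip_space`.
#' @param order `"label"` (alphabetical, default), `"class"` (grouped by
#'   class id then label) or `"added"` (insertion order).
#' @return A named numeric matrix.
#' @export
weight_matrix <- function(space, order = c("label", "class", "added")) {
  order <- match.arg(order)
  W <- space$H
  W[is.na(W)] <- 0
  dimnames(W) <- list(space$labels, space$labels)
  ord <- switch(order,
    label = base::order(space$labels),
    class = base::order(space$class_id, space$labels),
    added = seq_along(space$labels))
  W[ord, ord, drop = FALSE]
}

#' Edge-list view of a clip space
#'
#' @param space A `clip_space`.
#' @return A data frame with columns `source`, `target`, `h`, `kind`,
#'   `created_step`, one row per stored directed relation.
#' @export
edge_list <- function(space) {
  idx <- which(!is.na(space$H), arr.ind = TRUE)
  data.frame(
    source = space$labels[idx[, 1L]],
    target = space$labels[idx[, 2L]],
    h = space$H[idx],
    kind = space$kind[idx],
    created_step = space$created[idx],
    stringsAsFactors = FALSE
  )
}

#' Rebuild a clip space from an edge list
#'
#' Inverse of [edge_list()] (clips with no edges must be re-added
#' separately). Used for resuming or editing a saved clip space.
#'
#' @param edges A data frame with columns `source`, `target`, `h`, and
#'   optionally `kind` and `created_step`.
#' @param labels Optional character vector of clip labels to pre-create
#'   (covers isolated clips).
#' @return A `clip_space`.
#' @export
clip_space_from_edges <- function(edges, labels = NULL) {
  space <- new_clip_space()
  for (lab in unique(c(labels, edges$source, edges$target))) {
    space <- ensure_clip(space, lab, step = 0L)
  }
  kind <- if ("kind" %in% names(edges)) edges$kind else "derived"
  created <- if ("created_step" %in% names(edges)) edges$created_step else 0L
  kind <- rep_len(kind, nrow(edges))
  created <- rep_len(created, nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- clip_index(space, edges$source[r])
    j <- clip_index(space, edges$target[r])
    space$H[i, j] <- edges$h[r]
    space$kind[i, j] <- kind[r]
    space$created[i, j] <- as.integer(created[r])
  }
  space
}
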