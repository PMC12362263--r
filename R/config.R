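# Experiment configuration: construction, JSON (de)serialisation,
# validation with defaults, and the built-in study fixtures.

agent_default_keys <- c("gamma", "beta_h", "beta_t", "h0", "reward_correct",
                        "reward_incorrect", "mirror_updates",
                        "global_damping")
ne_default_keys <- c("k_neighbors", "alpha", "variant", "schedule",
                     "max_iterations", "tolerance", "self_anchor",
                     "exclude_trained_input")
top_level_keys <- c("classes", "comparison_only", "phases", "agent", "ne",
                    "mastery_criterion", "max_blocks", "n_agents",
                    "base_seed", "rdt_sampling_stride", "checkpoint_step",
                    "test_presentations_per_tag", "entailment_tags")

#' Validate and complete an experiment configuration
#'
#' Accepts a raw list (or a path to a JSON file), rejects unknown keys,
#' fills defaults (warning when agent/enhancement parameters are
#' defaulted), checks parameter ranges and referential integrity (every
#' phase pair and entailment tag must reference declared stimuli), and
#' returns a normalised configuration of class `experiment_config`.
#'
#' @param raw A named list, a JSON file path, or an already validated
#'   `experiment_config` (returned unchanged).
#' @return An `experiment_config` list with fields `classes` (named list
#'   class id -> member labels), `comparison_only`, `universe`, `phases`
#'   (list of [phase_spec()]), `agent`, `ne`, `mastery_criterion`,
#'   `max_blocks`, `n_agents`, `base_seed`, `rdt_sampling_stride`,
#'   `checkpoint_step`, `test_presentations_per_tag`, `entailment_tags`.
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "experiment_config")) return(raw)
  if (is.character(raw) && length(raw) == 1L) {
    raw <- jsonlite::read_json(raw, simplifyVector = FALSE)
  }
  if (!is.list(raw)) stop("config must be a list or a JSON path",
                          call. = FALSE)
  unknown <- setdiff(names(raw), top_level_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$classes) || !length(raw$classes)) {
    stop("config$classes: at least one class must be declared",
         call. = FALSE)
  }
  classes <- lapply(raw$classes, function(v) as.character(unlist(v)))
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    stop("config$classes must be a named map class_id -> member labels",
         call. = FALSE)
  }
  comparison_only <- as.character(unlist(raw$comparison_only))
  universe <- c(unlist(classes, use.names = FALSE), comparison_only)
  if (anyDuplicated(universe)) {
    stop("config: duplicated stimulus labels: ",
         paste(unique(universe[duplicated(universe)]), collapse = ", "),
         call. = FALSE)
  }
  for (lab in universe) parse_stimulus_label(lab)

  if (is.null(raw$phases) || !length(raw$phases)) {
    stop("config$phases: at least one phase is required", call. = FALSE)
  }
  phases <- lapply(raw$phases, function(ph) {
    if (inherits(ph, "phase_spec")) return(ph)
    unknown <- setdiff(names(ph),
                       c("name", "pairs", "presentations_per_pair", "mode"))
    if (length(unknown)) {
      stop("phase '", ph$name, "': unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pairs <- ph$pairs
    if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, unlist))
    phase_spec(ph$name, pairs, ph$presentations_per_pair,
               mode = if (is.null(ph$mode)) "train" else ph$mode)
  })
  for (ph in phases) {
    bad <- setdiff(c(ph$pairs), universe)
    if (length(bad)) {
      stop("phase '", ph$name, "' references undeclared stimuli: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  fill <- function(given, defaults, ctor, what) {
    given <- if (is.null(given)) list() else as.list(given)
    unknown <- setdiff(names(given), defaults)
    if (length(unknown)) {
      stop("config$", what, ": unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(defaults, names(given))
    if (length(missing)) {
      warning("config$", what, ": defaulting ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    do.call(ctor, given)
  }
  agent <- if (inherits(raw$agent, "agent_params")) raw$agent
           else fill(raw$agent, agent_default_keys, agent_params, "agent")
  ne <- if (inherits(raw$ne, "ne_params")) raw$ne
        else fill(raw$ne, ne_default_keys, ne_params, "ne")

  num1 <- function(x, default) {
    if (is.null(x)) default else as.numeric(x)
  }
  mastery <- num1(raw$mastery_criterion, 0.9)
  if (mastery <= 0 || mastery > 1) {
    stop("mastery_criterion must be in (0, 1]", call. = FALSE)
  }
  n_agents <- as.integer(num1(raw$n_agents, 15))
  if (n_agents < 1L) stop("n_agents must be >= 1", call. = FALSE)

  tags <- raw$entailment_tags
  tags <- if (is.null(tags)) {
    data.frame(tag = character(0), sample = character(0),
               correct = character(0), stringsAsFactors = FALSE)
  } else if (is.data.frame(tags)) {
    tags
  } else {
    do.call(rbind, lapply(tags, function(tg) {
      data.frame(tag = tg$tag, sample = tg$sample, correct = tg$correct,
                 stringsAsFactors = FALSE)
    }))
  }
  bad <- setdiff(c(tags$sample, tags$correct), universe)
  if (length(bad)) {
    stop("entailment_tags reference undeclared stimuli: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  structure(list(
    classes = classes,
    comparison_only = comparison_only,
    universe = universe,
    phases = phases,
    agent = agent,
    ne = ne,
    mastery_criterion = mastery,
    max_blocks = as.integer(num1(raw$max_blocks, 50)),
    n_agents = n_agents,
    base_seed = as.integer(num1(raw$base_seed, 1)),
    rdt_sampling_stride = as.integer(num1(raw$rdt_sampling_stride, 1)),
    checkpoint_step = as.integer(num1(raw$checkpoint_step, 500)),
    test_presentations_per_tag =
      as.integer(num1(raw$test_presentations_per_tag, 4)),
    entailment_tags = tags
  ), class = "experiment_config")
}

#' Serialise an experiment configuration to JSON
#'
#' @param config An `experiment_config` (or a raw list accepted by
#'   [validate_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- list(
    classes = config$classes,
    comparison_only = as.list(config$comparison_only),
    phases = lapply(config$phases, function(ph) {
      list(name = ph$name,
           pairs = lapply(seq_len(nrow(ph$pairs)),
                          function(r) as.list(unname(ph$pairs[r, ]))),
           presentations_per_pair = ph$presentations_per_pair,
           mode = ph$mode)
    }),
    agent = unclass(config$agent),
    ne = unclass(config$ne),
    mastery_criterion = config$mastery_criterion,
    max_blocks = config$max_blocks,
    n_agents = config$n_agents,
    base_seed = config$base_seed,
    rdt_sampling_stride = config$rdt_sampling_stride,
    checkpoint_step = config$checkpoint_step,
    test_presentations_per_tag = config$test_presentations_per_tag,
    entailment_tags = lapply(seq_len(nrow(config$entailment_tags)),
                             function(r) as.list(config$entailment_tags[r, ]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Built-in experiment fixtures
#'
#' Deterministic, fully specified configurations for tests and demos.
#'
#' `"cotter_stewart"` is the four-class linear-series (A-B-C-D-E) design:
#' classes 1-2 have five members, classes 3-4 three members, with D3, D4,
#' E3, E4 declared as comparison-only foils. Five phases: AB and BC for all
#' classes (4 pairs x 12 presentations = 48 trials per block), CD and DE
#' for classes 1-2 (2 x 12 = 24), then mixed training of all 12 pairs
#' (x 6 = 72), followed by entailment tests (A-C, C-A, C-B, B-A for all
#' classes; D-C, E-D, A-E, E-A for classes 1-2). Agent parameters:
#' gamma 0.001, K 1, beta_h 0.1, beta_t 4, alpha 0.7, mastery 0.9,
#' DNE, 15 agents.
#'
#' `"two_class_linear"` is a minimal 6-stimulus, 2-phase design;
#' `"one_to_many"` and `"many_to_one"` reproduce the classic
#' single-node training structures and differ only in pair orientation.
#'
#' @param kind One of `"cotter_stewart"`, `"two_class_linear"`,
#'   `"one_to_many"`, `"many_to_one"`.
#' @return A validated `experiment_config`.
#' @export
make_fixture <- function(kind = c("cotter_stewart", "two_class_linear",
                                  "one_to_many", "many_to_one")) {
  kind <- match.arg(kind)
  pairs_for <- function(from, to, cls) {
    cbind(paste0(from, cls), paste0(to, cls))
  }
  base <- list(
    agent = agent_params(),
    ne = ne_params(),
    mastery_criterion = 0.9, max_blocks = 50L,
    base_seed = 1L, rdt_sampling_stride = 1L, checkpoint_step = 500L,
    test_presentations_per_tag = 4L)

  cfg <- switch(kind,
    cotter_stewart = {
      classes <- list(`1` = paste0(c("A", "B", "C", "D", "E"), 1),
                      `2` = paste0(c("A", "B", "C", "D", "E"), 2),
                      `3` = paste0(c("A", "B", "C"), 3),
                      `4` = paste0(c("A", "B", "C"), 4))
      mixed <- rbind(pairs_for("A", "B", 1:4), pairs_for("B", "C", 1:4),
                     pairs_for("C", "D", 1:2), pairs_for("D", "E", 1:2))
      c(base, list(
        classes = classes,
        comparison_only = c("D3", "D4", "E3", "E4"),
        phases = list(
          phase_spec("Phase 1: AB", pairs_for("A", "B", 1:4), 12),
          phase_spec("Phase 2: BC", pairs_for("B", "C", 1:4), 12),
          phase_spec("Phase 3: CD", pairs_for("C", "D", 1:2), 12),
          phase_spec("Phase 4: DE", pairs_for("D", "E", 1:2), 12),
          phase_spec("Phase 5: Mixed", mixed, 6, mode = "mixed_train")),
        n_agents = 15L,
        entailment_tags = rbind(
          entailment_tags(c("A-C", "C-A", "C-B", "B-A"), 1:4),
          entailment_tags(c("D-C", "E-D", "A-E", "E-A"), 1:2))))
    },
    two_class_linear = {
      c(base, list(
        classes = list(`1` = c("A1", "B1", "C1"),
                       `2` = c("A2", "B2", "C2")),
        comparison_only = character(0),
        phases = list(
          phase_spec("Phase 1: AB", pairs_for("A", "B", 1:2), 6),
          phase_spec("Phase 2: BC", pairs_for("B", "C", 1:2), 6)),
        n_agents = 2L,
        entailment_tags = entailment_tags(c("A-C", "C-A", "B-A"), 1:2)))
    },
    one_to_many = {
      c(base, list(
        classes = list(`1` = paste0(c("A", "B", "C", "D"), 1),
                       `2` = paste0(c("A", "B", "C", "D"), 2)),
        comparison_only = character(0),
        phases = list(
          phase_spec("Phase 1: AB", pairs_for("A", "B", 1:2), 6),
          phase_spec("Phase 2: AC", pairs_for("A", "C", 1:2), 6),
          phase_spec("Phase 3: AD", pairs_for("A", "D", 1:2), 6)),
        n_agents = 2L,
        entailment_tags = entailment_tags(c("B-C", "C-B", "B-D"), 1:2)))
    },
    many_to_one = {
      c(base, list(
        classes = list(`1` = paste0(c("A", "B", "C", "D"), 1),
                       `2` = paste0(c("A", "B", "C", "D"), 2)),
        comparison_only = character(0),
        phases = list(
          phase_spec("Phase 1: BA", pairs_for("B", "A", 1:2), 6),
          phase_spec("Phase 2: CA", pairs_for("C", "A", 1:2), 6),
          phase_spec("Phase 3: DA", pairs_for("D", "A", 1:2), 6)),
        n_agents = 2L,
        entailment_tags = entailment_tags(c("B-C", "C-B", "B-D"), 1:2)))
    })
  validate_config(cfg)
}
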