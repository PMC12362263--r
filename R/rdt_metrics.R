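# Relational Density Theory instrumentation: relational-volume measures
# (true and empirical nodal distance, class size, number of relations),
# relational-density measures (mean transition probability, class accuracy,
# mean h-value), relational mass, and correlations across their time series.

#' Default edge-existence threshold for the metric suite
#'
#' An edge counts as an existing relation once its h-value has been
#' reinforced above the resting/initial value.
#'
#' @param h0 Initial edge weight (default 1).
#' @return `h0 + 1e-9`.
#' @export
default_edge_threshold <- function(h0 = 1) h0 + 1e-9

# Members of a class currently present in the clip space. With a roster
# (named list class_id -> labels) membership is roster-defined, so
# comparison-only foils such as D3 never count toward class 3; without a
# roster it falls back to the label-suffix class id.
class_members <- function(space, class_id, classes = NULL) {
  if (is.null(classes)) {
    return(space$labels[space$class_id == class_id])
  }
  roster <- classes[[as.character(class_id)]]
  if (is.null(roster)) return(character(0))
  intersect(roster, space$labels)
}

# Breadth-first shortest-path distances from src over a logical adjacency
# matrix; NA for unreachable vertices. Hand-rolled: graphs here have at
# most ~20 vertices and this runs once per trial per snapshot.
bfs_distances <- function(A, src) {
  n <- nrow(A)
  d <- rep(NA_integer_, n)
  d[src] <- 0L
  frontier <- src
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    nb <- which(colSums(A[frontier, , drop = FALSE]) > 0)
    nb <- nb[is.na(d[nb])]
    if (!length(nb)) break
    d[nb] <- lvl
    frontier <- nb
  }
  d
}

# Direction-agnostic adjacency over present clips at a threshold.
space_adjacency <- function(space, edge_threshold) {
  M <- !is.na(space$H) & space$H > edge_threshold
  M | t(M)
}

#' True nodal distance of a class
#'
#' Sum over all unordered member pairs of the number of intermediate nodes
#' on the shortest path in the *current* relational network (any relation
#' with `h > edge_threshold`, treated as undirected), including derived and
#' inter-class "incorrect" relations — hence the transient spikes when a
#' stimulus first appears as an untrained comparison. A directly connected
#' pair contributes 0; a disconnected pair contributes the finite penalty
#' `(number of present members - 1)`.
#'
#' @param space A `clip_space`.
#' @param class_id Class identifier.
#' @param classes Optional class roster (named list class_id -> labels).
#' @param edge_threshold h-value above which an edge exists
#'   (default [default_edge_threshold()]).
#' @return A single nonnegative number; 0 for singleton or absent classes.
#' @export
true_nodal_distance <- function(space, class_id, classes = NULL,
                                edge_threshold = default_edge_threshold()) {
  members <- class_members(space, class_id, classes)
  m <- length(members)
  if (m < 2L) return(0)
  A <- space_adjacency(space, edge_threshold)
  true_nodal_distance_impl(A, match(members, space$labels))
}

true_nodal_distance_impl <- function(A, idx) {
  m <- length(idx)
  penalty <- m - 1L
  total <- 0
  for (a in seq_len(m - 1L)) {
    d <- bfs_distances(A, idx[a])
    for (b in seq((a + 1L), m)) {
      db <- d[idx[b]]
      total <- total + if (is.na(db)) penalty else max(db - 1L, 0L)
    }
  }
  total
}

#' Empirical nodal distance of a class
#'
#' Nodal distance in the classical sense: the number of nodes linking two
#' class members *not* related by direct training, computed on the trained
#' relations only (a structural fact of the training protocol — h-values
#' never enter). On a simple shortest trained path every intermediate
#' vertex has at least two distinct trained partners, so each untrained
#' reachable pair contributes (shortest trained path length - 1); an
#' unreachable pair contributes 0. Contributions are summed over the class.
#'
#' @param space A `clip_space` (used for member presence).
#' @param class_id Class identifier.
#' @param trained_pairs 2-column character matrix of directly trained
#'   (sample, comparison) pairs.
#' @param classes Optional class roster.
#' @return A single nonnegative number.
#' @export
empirical_nodal_distance <- function(space, class_id, trained_pairs,
                                     classes = NULL) {
  members <- class_members(space, class_id, classes)
  m <- length(members)
  if (m < 2L || NROW(trained_pairs) == 0L) return(0)
  verts <- unique(c(members, trained_pairs[, 1L], trained_pairs[, 2L]))
  n <- length(verts)
  A <- matrix(FALSE, n, n)
  i <- match(trained_pairs[, 1L], verts)
  j <- match(trained_pairs[, 2L], verts)
  A[cbind(i, j)] <- TRUE
  A <- A | t(A)
  midx <- match(members, verts)
  pairkey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  trained_keys <- pairkey(trained_pairs[, 1L], trained_pairs[, 2L])
  total <- 0
  for (a in seq_len(m - 1L)) {
    d <- bfs_distances(A, midx[a])
    for (b in seq((a + 1L), m)) {
      if (pairkey(members[a], members[b]) %in% trained_keys) next
      db <- d[midx[b]]
      if (!is.na(db) && db > 1L) total <- total + (db - 1L)
    }
  }
  total
}

#' Class size (number of class members present in the clip space)
#'
#' @inheritParams true_nodal_distance
#' @return Integer count.
#' @export
class_size <- function(space, class_id, classes = NULL) {
  length(class_members(space, class_id, classes))
}

#' Number of intra-class relations
#'
#' Count of directed edges between class members (reflexive included) with
#' `h > edge_threshold`.
#'
#' @inheritParams true_nodal_distance
#' @return Integer count.
#' @export
num_relations <- function(space, class_id, classes = NULL,
                          edge_threshold = default_edge_threshold()) {
  members <- class_members(space, class_id, classes)
  if (!length(members)) return(0L)
  idx <- match(members, space$labels)
  H <- space$H[idx, idx, drop = FALSE]
  sum(!is.na(H) & H > edge_threshold)
}

#' Mean softmax transition probability between intra-class stimuli
#'
#' The softmax distribution at temperature `beta_h` is taken over the class's
#' own relation set: every stored edge between class members (baseline,
#' symmetry, derived — reflexive included), exactly as the agent's choice
#' rule turns h-values into transition probabilities. The measure is the
#' average probability *under that distribution* (the probability-weighted
#' mean, `sum(p^2)`): with comparable h-values it roughly equates to
#' 1 / the number of intra-class relations — hence roughly 1 / the number
#' of stimuli early in training — and it falls as training or enhancement
#' adds relations, while sharpening of a few dominant edges (larger
#' `beta_h` spreads) pulls it back up. A class consisting of a single
#' just-observed stimulus with no relations rests on itself (degenerate
#' distribution), which produces the characteristic early spike at 1.0.
#'
#' @inheritParams true_nodal_distance
#' @param beta_h Softmax temperature (the agent's training temperature).
#' @return Mean probability in (0, 1\], or `NA` for a multi-member class
#'   with no intra-class relations.
#' @export
mean_transition_probability <- function(space, class_id, beta_h,
                                        classes = NULL) {
  members <- class_members(space, class_id, classes)
  m <- length(members)
  if (m == 0L) return(NA_real_)
  idx <- match(members, space$labels)
  H <- space$H[idx, idx, drop = FALSE]
  h <- H[!is.na(H)]
  if (!length(h)) {
    # no relations yet: a singleton class rests on itself
    return(if (m == 1L) 1 else NA_real_)
  }
  z <- beta_h * h
  z <- z - max(z)
  p <- exp(z)
  p <- p / sum(p)
  sum(p * p)
}

#' Cumulative class accuracy over a trial log
#'
#' Correct matches divided by all trials whose sample belongs to the class,
#' from the start of the experiment.
#'
#' @param records Trial-log data frame.
#' @param class_id Class identifier.
#' @return Proportion correct, or `NA` if the class has no trials yet.
#' @export
class_accuracy <- function(records, class_id) {
  sel <- records$class_id == class_id
  if (!any(sel)) return(NA_real_)
  mean(records$correct[sel])
}

#' Mean intra-class h-value
#'
#' Arithmetic mean of intra-class edge weights above the threshold.
#' Unbounded, and skewable by outlier relations; unlike the mean transition
#' probability it does not depend on the softmax temperature.
#'
#' @inheritParams num_relations
#' @return Mean h, or `NA` if no qualifying edges exist.
#' @export
mean_h <- function(space, class_id, classes = NULL,
                   edge_threshold = default_edge_threshold()) {
  members <- class_members(space, class_id, classes)
  if (!length(members)) return(NA_real_)
  idx <- match(members, space$labels)
  H <- space$H[idx, idx, drop = FALSE]
  v <- H[!is.na(H) & H > edge_threshold]
  if (!length(v)) NA_real_ else mean(v)
}

#' Relational mass
#'
#' The product of a relational-density value and a relational-volume value,
#' `Rm = Rp * Rv`. Missing inputs propagate to a missing output.
#'
#' @param density Relational density (Rp).
#' @param volume Relational volume (Rv).
#' @return `density * volume`, vectorised.
#' @export
relational_mass <- function(density, volume) density * volume

#' Measure names of the RDT series
#' @return Named list with `density` and `volume` measure-name vectors.
#' @export
rdt_measures <- function() {
  list(density = c("mean_transition_probability", "class_accuracy", "mean_h"),
       volume = c("true_nodal_distance", "empirical_nodal_distance",
                  "class_size", "num_relations"))
}

#' Pearson correlations for every density x volume relational-mass pairing
#'
#' For each of the 3 density x 4 volume combinations, the Pearson r between
#' the two per-step series is computed per class per agent (pairwise
#' complete observations; zero-variance series give a missing r, never 0),
#' then averaged over classes and agents. The per-class and per-agent
#' coefficient distributions are returned for boxplot-style exports.
#'
#' @param series_list List of per-agent RDT series data frames (columns
#'   `step`, `class_id`, and the seven measure columns), as produced by
#'   [run_agent()].
#' @return A list with `summary` (data frame: density, volume, mean_r, n),
#'   `per_class` (data frame: agent, class_id, density, volume, r) and
#'   `per_agent` (data frame: agent, density, volume, r — class-averaged).
#' @export
mass_correlations <- function(series_list) {
  if (!is.data.frame(series_list[[1L]])) {
    stop("series_list must be a list of RDT series data frames",
         call. = FALSE)
  }
  meas <- rdt_measures()
  rows <- list()
  for (ag in seq_along(series_list)) {
    ser <- series_list[[ag]]
    for (cl in sort(unique(ser$class_id))) {
      sub <- ser[ser$class_id == cl, , drop = FALSE]
      for (d in meas$density) {
        for (v in meas$volume) {
          x <- sub[[d]]
          y <- sub[[v]]
          ok <- is.finite(x) & is.finite(y)
          r <- if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 &&
                   stats::sd(y[ok]) > 0) {
            stats::cor(x[ok], y[ok])
          } else {
            NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            agent = ag, class_id = cl, density = d, volume = v, r = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_class <- do.call(rbind, rows)
  agg <- function(df, by) {
    out <- stats::aggregate(r ~ ., data = df[c(by, "r")], FUN = mean,
                            na.rm = TRUE, na.action = stats::na.pass)
    out
  }
  per_agent <- agg(per_class, c("agent", "density", "volume"))
  summary_df <- stats::aggregate(
    r ~ density + volume, data = per_class, FUN = mean, na.rm = TRUE,
    na.action = stats::na.pass)
  names(summary_df)[names(summary_df) == "r"] <- "mean_r"
  counts <- stats::aggregate(
    r ~ density + volume, data = per_class,
    FUN = function(z) sum(is.finite(z)), na.action = stats::na.pass)
  summary_df$n <- counts$r[match(paste(summary_df$density, summary_df$volume),
                                 paste(counts$density, counts$volume))]
  summary_df$mean_r[!is.finite(summary_df$mean_r)] <- NA_real_
  list(summary = summary_df, per_class = per_class, per_agent = per_agent)
}

# ---- internal per-trial snapshot collector ---------------------------------

# Environment-based accumulator used by run_agent(): appends one row per
# class per sampled trial into a preallocated matrix (grown by doubling).
new_rdt_collector <- function(classes, beta_h, edge_threshold,
                              capacity = 4096L) {
  col <- new.env(parent = emptyenv())
  col$classes <- classes
  col$class_ids <- as.integer(names(classes))
  col$beta_h <- beta_h
  col$thr <- edge_threshold
  col$buf <- matrix(NA_real_, capacity, 9L)
  col$count <- 0L
  col$last_step <- -1L
  col$end_cache <- NULL          # per-class empirical nodal distance
  col$end_version <- -1L
  col
}

collect_snapshot <- function(col, space, trained, acc_correct, acc_total) {
  ncl <- length(col$class_ids)
  step <- space$step
  if (col$last_step == step) {
    col$count <- col$count - ncl     # post-enhancement snapshot replaces
  }
  if (col$count + ncl > nrow(col$buf)) {
    col$buf <- rbind(col$buf, matrix(NA_real_, nrow(col$buf), 9L))
  }
  if (col$end_version != trained$version) {
    col$end_cache <- vapply(col$class_ids, function(cl) {
      empirical_nodal_distance(space, cl, trained$pairs, col$classes)
    }, numeric(1))
    col$end_version <- trained$version
  }
  A <- space_adjacency(space, col$thr)
  for (k in seq_len(ncl)) {
    cl <- col$class_ids[k]
    members <- class_members(space, cl, col$classes)
    idx <- match(members, space$labels)
    tnd <- if (length(idx) < 2L) 0 else true_nodal_distance_impl(A, idx)
    key <- as.character(cl)
    acc <- if (acc_total[[key]] > 0) acc_correct[[key]] / acc_total[[key]]
           else NA_real_
    col$count <- col$count + 1L
    col$buf[col$count, ] <- c(
      step, cl, tnd, col$end_cache[k], length(members),
      num_relations(space, cl, col$classes, col$thr),
      mean_transition_probability(space, cl, col$beta_h, col$classes),
      acc,
      mean_h(space, cl, col$classes, col$thr))
  }
  col$last_step <- step
  invisible(col)
}

collector_series <- function(col) {
  out <- as.data.frame(col$buf[seq_len(col$count), , drop = FALSE])
  names(out) <- c("step", "class_id", "true_nodal_distance",
                  "empirical_nodal_distance", "class_size", "num_relations",
                  "mean_transition_probability", "class_accuracy", "mean_h")
  out$step <- as.integer(out$step)
  out$class_id <- as.integer(out$class_id)
  out
}
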