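# Result serialisation and static exports: trial logs, RDT series,
# correlation summaries, edge lists, weight matrices, GraphML, optional
# figures, and the run manifest.

#' Write a trial log as CSV
#'
#' Columns: step, phase, block, sample, comparisons (|-joined), chosen,
#' correct, class_id.
#'
#' @param records Trial-log data frame from [run_block()] / [run_agent()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write an RDT metric series as long-format CSV
#'
#' Columns: step, class_id, measure_name, value.
#'
#' @param series Wide RDT series data frame from [run_agent()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rdt_series <- function(series, path) {
  meas <- unlist(rdt_measures(), use.names = FALSE)
  long <- do.call(rbind, lapply(meas, function(m) {
    data.frame(step = series$step, class_id = series$class_id,
               measure_name = m, value = series[[m]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$step, long$class_id, long$measure_name), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write the relational-mass correlation summary as CSV
#'
#' One row per density x volume combination: mean r plus the |-joined
#' per-agent coefficients.
#'
#' @param correlations Output of [mass_correlations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_summary <- function(correlations, path) {
  s <- correlations$summary
  pa <- correlations$per_agent
  s$per_agent_r <- vapply(seq_len(nrow(s)), function(r) {
    v <- pa$r[pa$density == s$density[r] & pa$volume == s$volume[r]]
    paste(signif(v, 6), collapse = "|")
  }, character(1))
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-phase condition-comparison table as CSV
#'
#' @param comparison Output of [compare_conditions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}

#' Export a clip space as a tab-separated edge list
#'
#' Columns: source, target, h, kind, created_step.
#'
#' @param space A `clip_space`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(space, path) {
  utils::write.table(edge_list(space), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a clip space back from a tab-separated edge list
#'
#' @param path TSV path written by [export_edge_list()].
#' @param labels Optional labels for isolated clips.
#' @return A `clip_space`.
#' @export
import_edge_list <- function(path, labels = NULL) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  clip_space_from_edges(edges, labels)
}

#' Export the normalised weight matrix (heatmap data) as CSV
#'
#' The h-value matrix (absent edges 0) is min-max normalised; rows are
#' percept/sample stimuli, columns are action/comparison stimuli, grouped
#' by class. Values are written to 6 decimal places. Optionally renders a
#' heatmap image (figures are opt-in so headless runs produce data only).
#'
#' @param space A `clip_space`.
#' @param path Output CSV path.
#' @param image Optional PNG path for a heatmap rendering.
#' @param order Row/column ordering, see [weight_matrix()].
#' @return The normalised matrix, invisibly.
#' @export
export_heatmap_matrix <- function(space, path, image = NULL,
                                  order = "class") {
  W <- weight_matrix(space, order = order)
  if (length(W)) {
    rng <- range(W)
    if (rng[2] > rng[1]) {
      W <- (W - rng[1]) / (rng[2] - rng[1])
    } else if (rng[2] != 0) {
      W[] <- as.numeric(W != 0)
    }
  }
  utils::write.csv(round(W, 6), path, row.names = TRUE)
  if (!is.null(image) && length(W)) {
    grDevices::png(image, width = 900, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    n <- nrow(W)
    graphics::image(seq_len(n), seq_len(n), t(W[rev(seq_len(n)), ]),
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                    axes = FALSE, xlab = "sample (percept)",
                    ylab = "comparison (action)")
    graphics::axis(1, at = seq_len(n), labels = colnames(W), las = 2)
    graphics::axis(2, at = seq_len(n), labels = rev(rownames(W)), las = 2)
  }
  invisible(W)
}

#' Convert a clip space to an igraph graph
#'
#' @param space A `clip_space`.
#' @return A directed `igraph` graph with vertex attributes `class_id`,
#'   `role`, `first_seen` and edge attributes `h`, `kind`, `created_step`.
#' @export
as_igraph <- function(space) {
  edges <- edge_list(space)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = space$labels, class_id = space$class_id,
                          role = space$role, first_seen = space$first_seen,
                          stringsAsFactors = FALSE))
  g
}

#' Export a clip space as GraphML (optionally with a network figure)
#'
#' The GraphML file round-trips the full edge set. The optional figure
#' lays classes out in columns and draws edge opacity as the min-max
#' normalised weight floored at `opacity_floor` so weak relations stay
#' visible.
#'
#' @param space A `clip_space`.
#' @param path Output GraphML path.
#' @param image Optional PNG path.
#' @param opacity_floor Minimum edge opacity (default 0.33).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(space, path, image = NULL, opacity_floor = 0.33) {
  g <- as_igraph(space)
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(image) && length(space$labels)) {
    grDevices::png(image, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    cls <- space$class_id
    col_of <- match(cls, sort(unique(cls)))
    row_of <- stats::ave(seq_along(cls), cls, FUN = seq_along)
    layout <- cbind(col_of, -row_of)
    h <- pmax(edge_list(space)$h, 0)
    w <- if (max(h) > 0) h / max(h) else h
    op <- pmax(w, opacity_floor)
    igraph::plot.igraph(
      g, layout = layout,
      vertex.size = 18, vertex.color = "grey90",
      edge.color = grDevices::rgb(0.55, 0.05, 0.05, alpha = op),
      edge.width = 0.5 + 3 * w,
      edge.arrow.size = 0.3)
  }
  invisible(path)
}

#' Edge opacity scale used by the network figure
#'
#' Min-max normalised weights floored at `opacity_floor` (default 0.33) so
#' the weakest visible relation never becomes fully transparent.
#'
#' @param h Nonnegative edge weights.
#' @param opacity_floor Minimum opacity.
#' @return Numeric vector of opacities in \[`opacity_floor`, 1\].
#' @export
edge_opacity <- function(h, opacity_floor = 0.33) {
  stopifnot(all(h >= 0))
  w <- if (length(h) && max(h) > 0) h / max(h) else h
  pmax(w, opacity_floor)
}

#' Write the Network Enhancement application trace as CSV
#'
#' @param ne_trace Data frame from [run_agent()] (`$ne_trace`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ne_trace <- function(ne_trace, path) {
  ne_trace <- cbind(application = seq_len(NROW(ne_trace)), ne_trace)
  utils::write.csv(ne_trace, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration hash (md5 of its canonical JSON
#' serialisation, stable across re-serialisation), the seeds used, the
#' package version, a timestamp, and the output file inventory.
#'
#' @param config Experiment configuration.
#' @param seeds Integer vector of agent seeds.
#' @param files Character vector of emitted file paths.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seeds, files, path) {
  config <- validate_config(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_config(config, tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seeds = as.integer(seeds),
    software = paste0("relmass ",
                      as.character(utils::packageVersion("relmass"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write all artifacts of an experiment run to a directory
#'
#' Emits trial logs, RDT series, enhancement traces and graph exports per
#' agent, plus the cohort correlation summary and manifest.
#'
#' @param cohort A `cohort_result` (with `agents` kept).
#' @param dir Output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
write_cohort_results <- function(cohort, dir) {
  stopifnot(!is.null(cohort$agents))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(cohort$agents)) {
    a <- cohort$agents[[i]]
    pfx <- file.path(dir, sprintf("agent%02d", i))
    files <- c(files,
               write_trial_log(a$records, paste0(pfx, "_trials.csv")),
               write_rdt_series(a$series, paste0(pfx, "_rdt.csv")),
               write_ne_trace(a$ne_trace, paste0(pfx, "_ne.csv")),
               export_edge_list(a$space, paste0(pfx, "_edges.tsv")))
  }
  f <- file.path(dir, "per_phase.csv")
  utils::write.csv(cohort$per_phase, f, row.names = FALSE)
  files <- c(files, f,
             write_correlation_summary(cohort$correlations,
                                       file.path(dir, "correlations.csv")))
  write_manifest(cohort$config, cohort$seeds, files,
                 file.path(dir, "manifest.json"))
  invisible(files)
}
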