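# In-code fixtures shared across test files.

# A clip space with the given directed edges (list of c(source, target, h))
# and optional extra isolated clips; edge kinds default to "baseline" with
# a mirrored "symmetry_trained" reverse when mirror = TRUE.
space_with_edges <- function(edges, extra = character(0), mirror = FALSE) {
  space <- new_clip_space()
  labs <- unique(c(vapply(edges, `[`, character(1), 1L),
                   vapply(edges, `[`, character(1), 2L), extra))
  for (lab in labs) space <- ensure_clip(space, lab, step = 0L)
  for (e in edges) {
    i <- match(e[1L], space$labels)
    j <- match(e[2L], space$labels)
    h <- as.numeric(e[3L])
    space$H[i, j] <- h
    space$kind[i, j] <- "baseline"
    space$created[i, j] <- 0L
    if (mirror) {
      space$H[j, i] <- h
      space$kind[j, i] <- "symmetry_trained"
      space$created[j, i] <- 0L
    }
  }
  space
}

# Linearly trained five-member class (A1-B1-C1-D1-E1), baseline + mirror
# edges at the given h.
linear_class_space <- function(h = 5, mirror = TRUE) {
  rel <- list(c("A1", "B1", h), c("B1", "C1", h),
              c("C1", "D1", h), c("D1", "E1", h))
  space_with_edges(rel, mirror = mirror)
}

# Small fast configuration for runner tests.
mini_config <- function(...) {
  cfg <- make_fixture("two_class_linear")
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

expect_same_graph <- function(space_a, space_b) {
  ea <- edge_list(space_a)
  eb <- edge_list(space_b)
  ord <- function(e) e[order(e$source, e$target), c("source", "target", "h")]
  ea <- ord(ea)
  eb <- ord(eb)
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
}
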