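# Network Enhancement: the diffusion/de-noising step that consolidates the
# clip space and introduces derived (symmetry/transitivity/equivalence)
# relations. Two kernels are supported: SNE uses the symmetric localized
# matrix T, DNE the K-NN transition matrix P directly.

#' Network Enhancement parameters
#'
#' @param k_neighbors K of the K-nearest-neighbour localisation (>= 1).
#' @param alpha Diffusion retention weight, strictly inside (0, 1).
#' @param variant `"DNE"` (default; transition-matrix kernel, better class
#'   formation) or `"SNE"` (symmetric localized kernel).
#' @param schedule `"end_of_training"` (one application before testing) or
#'   `"during_training"` (one application at every mastery point).
#' @param max_iterations Iteration cap for the diffusion fixed point.
#' @param tolerance Convergence tolerance on `max |W_{t+1} - W_t|`.
#' @param self_anchor If `TRUE` (default) the diffusion kernel is made lazy,
#'   `(P + I) / 2`, mirroring the dominant-diagonal step of the reference
#'   Network Enhancement implementation. Linear MTS training graphs are
#'   bipartite, and without a self-anchored kernel the diffusion fixed point
#'   provably preserves edge parity, so odd-path derived relations
#'   (transitivity) could never form; see the methods vignette.
#' @param exclude_trained_input If `TRUE`, directly trained (baseline and
#'   mirrored-symmetry) edges are zeroed in the diffusion input matrix
#'   rather than merely being restored on write-back.
#' @return An object of class `ne_params`.
#' @export
ne_params <- function(k_neighbors = 1L, alpha = 0.7,
                      variant = c("DNE", "SNE"),
                      schedule = c("end_of_training", "during_training"),
                      max_iterations = 100L, tolerance = 1e-8,
                      self_anchor = TRUE, exclude_trained_input = FALSE) {
  variant <- match.arg(variant)
  schedule <- match.arg(schedule)
  stopifnot(is.numeric(k_neighbors), k_neighbors >= 1L,
            is.numeric(alpha), alpha > 0, alpha < 1,
            max_iterations >= 1L, tolerance > 0,
            is.logical(self_anchor), is.logical(exclude_trained_input))
  structure(list(k_neighbors = as.integer(k_neighbors), alpha = alpha,
                 variant = variant, schedule = schedule,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, self_anchor = self_anchor,
                 exclude_trained_input = exclude_trained_input),
            class = "ne_params")
}

#' K-nearest-neighbour transition probability matrix
#'
#' `P[i, j] = W[i, j] / sum_{k in N_i} W[i, k]` if `j` is one of the K
#' strongest neighbours of `i` (self excluded, ties broken by column
#' order), else 0. Rows whose neighbour weights are all zero become uniform
#' over all nodes, keeping P well-defined for isolated clips.
#'
#' @param W Nonnegative square weight matrix.
#' @param K Number of neighbours, `1 <= K <= nrow(W) - 1`.
#' @return A row-stochastic matrix of the same shape.
#' @export
knn_transition_matrix <- function(W, K) {
  n <- nrow(W)
  stopifnot(is.matrix(W), n == ncol(W), all(W >= 0))
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > n - 1L) stop("K must be <= nrow(W) - 1", call. = FALSE)
  P <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf                       # self is not a neighbour
    nb <- order(w, decreasing = TRUE)[seq_len(K)]   # stable: ties by order
    s <- sum(W[i, nb])
    if (s > 0) {
      P[i, nb] <- W[i, nb] / s
    } else {
      P[i, ] <- 1 / n
    }
  }
  P
}

#' Localized (symmetric) network from a transition matrix
#'
#' `T[i, j] = sum_k P[i, k] * P[j, k] / sum_v P[v, k]`, skipping zero
#' columns. T is symmetric by construction and measures local affinity,
#' prioritising connections within three orders of distance.
#'
#' @param P A row-stochastic matrix.
#' @return A symmetric matrix of the same shape.
#' @export
local_network <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  cs <- colSums(P)
  pos <- cs > 0
  if (!any(pos)) return(matrix(0, nrow(P), ncol(P), dimnames = dimnames(P)))
  Pp <- P[, pos, drop = FALSE]
  T <- Pp %*% (t(Pp) / cs[pos])
  dimnames(T) <- dimnames(P)
  T
}

#' Iterate the Network Enhancement diffusion to its fixed point
#'
#' Iterates `W_{t+1} = alpha * kernel %*% W_t %*% kernel +
#' (1 - alpha) * kernel` until `max |W_{t+1} - W_t| < tolerance` or
#' `max_iterations` is reached. For a row-stochastic kernel and
#' `alpha` in (0, 1) the map is a contraction with a unique fixed point.
#'
#' @param W0 Starting matrix (the clip space's nonnegative weights).
#' @param kernel Diffusion kernel: T for SNE, P (possibly self-anchored)
#'   for DNE.
#' @param alpha Retention weight in (0, 1).
#' @param max_iterations Iteration cap.
#' @param tolerance Convergence tolerance.
#' @return The converged matrix, with attributes `iterations` and
#'   `max_delta`.
#' @export
diffuse <- function(W0, kernel, alpha, max_iterations = 100L,
                    tolerance = 1e-8) {
  stopifnot(alpha >= 0, alpha < 1)
  W <- W0
  delta <- Inf
  growth <- 0L
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    Wn <- alpha * kernel %*% W %*% kernel + (1 - alpha) * kernel
    d <- max(abs(Wn - W))
    if (d > delta) growth <- growth + 1L else growth <- 0L
    if (growth >= 10L && max(abs(Wn)) > max(abs(W0)) * 1e6) {
      stop("network-enhancement diffusion is diverging (delta grew for 10 ",
           "consecutive iterations; |W| = ", format(max(abs(Wn))), ")",
           call. = FALSE)
    }
    delta <- d
    W <- Wn
    if (delta < tolerance) break
  }
  attr(W, "iterations") <- it
  attr(W, "max_delta") <- delta
  W
}

#' Apply Network Enhancement to a clip space
#'
#' Builds the nonnegative weight matrix from the clip space (negative
#' h-values clamp to 0; labels in alphabetical order for deterministic
#' tie-breaking), computes the K-NN transition matrix, the SNE localized
#' kernel if requested, runs the diffusion to its fixed point, rescales the
#' output to `[0, max input h]` (preserving zeros, so the training softmax
#' temperature keeps its meaning), and writes the result back.
#'
#' Write-back is consolidating, never punitive: directly trained edges
#' (kinds `"baseline"` and `"symmetry_trained"`) retain their
#' pre-enhancement h-values; other existing edges are raised to the
#' enhanced value when it exceeds their current weight (negative
#' "incorrect" weights learned from punishment are never reset by a zero
#' diffusion output); new edges (including reflexive ones) are created
#' with kind `"derived"`. Output entries below the diffusion's fixed-point
#' error bound (`max_delta / (1 - alpha)`, rescaled) are numerical residue
#' of the finite iteration, indistinguishable from zero, and are clamped
#' to zero rather than materialised as spurious epsilon relations.
#'
#' @param space A non-empty `clip_space`.
#' @param params An [ne_params()] object.
#' @return The enhanced `clip_space`, with attribute `"ne_info"` (a one-row
#'   data frame: step, iterations, max_delta, edges_before, edges_after).
#' @export
apply_ne <- function(space, params) {
  n <- length(space$labels)
  if (n < 2L) {
    attr(space, "ne_info") <- data.frame(
      step = space$step, iterations = 0L, max_delta = 0,
      edges_before = n_relations_total(space),
      edges_after = n_relations_total(space))
    return(space)
  }
  ord <- order(space$labels)
  idx <- seq_len(n)[ord]                       # space index in label order
  W <- space$H[idx, idx, drop = FALSE]
  kind <- space$kind[idx, idx, drop = FALSE]
  W[is.na(W)] <- 0
  W[W < 0] <- 0
  trained <- !is.na(kind) & kind %in% c("baseline", "symmetry_trained")
  if (params$exclude_trained_input) W[trained] <- 0

  K <- min(params$k_neighbors, n - 1L)
  P <- knn_transition_matrix(W, K)
  if (params$self_anchor) P <- (P + diag(n)) / 2
  kernel <- if (identical(params$variant, "SNE")) local_network(P) else P
  Wd <- diffuse(W, kernel, params$alpha, params$max_iterations,
                params$tolerance)
  iterations <- attr(Wd, "iterations")
  max_delta <- attr(Wd, "max_delta")

  max_in <- max(W)
  max_out <- max(Wd)
  scale <- if (max_in > 0 && max_out > 0) max_in / max_out else 1
  Wout <- Wd * scale
  residue <- max_delta / (1 - params$alpha) * scale
  Wout[Wout < residue] <- 0

  edges_before <- n_relations_total(space)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      v <- Wout[a, b]
      if (v <= 0 || trained[a, b]) next        # trained h re-imposed as-is
      ia <- idx[a]
      ib <- idx[b]
      cur <- space$H[ia, ib]
      if (is.na(cur)) {
        space$H[ia, ib] <- v
        space$kind[ia, ib] <- "derived"
        space$created[ia, ib] <- space$step
      } else if (v > cur) {
        space$H[ia, ib] <- v
      }
    }
  }
  attr(space, "ne_info") <- data.frame(
    step = space$step, iterations = iterations, max_delta = max_delta,
    edges_before = edges_before, edges_after = n_relations_total(space))
  space
}
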