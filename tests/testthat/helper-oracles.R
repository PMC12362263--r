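# Independent oracles, written straight from the defining expressions with
# explicit loops; they never call the package's own implementations.

# Softmax without max-subtraction.
oracle_softmax <- function(h, beta) {
  e <- exp(beta * h)
  e / sum(e)
}

# K-NN transition matrix: top-K neighbours of each row (self excluded,
# ties by column order), row-normalised over the neighbour set; all-zero
# neighbour mass gives a uniform row.
oracle_knn <- function(W, K) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    s <- 0
    for (j in nb) s <- s + W[i, j]
    if (s > 0) {
      for (j in nb) P[i, j] <- W[i, j] / s
    } else {
      P[i, ] <- 1 / n
    }
  }
  P
}

# Localized network, triple loop, zero columns skipped.
oracle_local_network <- function(P) {
  n <- nrow(P)
  T <- matrix(0, n, n)
  colsum <- numeric(n)
  for (k in seq_len(n)) colsum[k] <- sum(P[, k])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        if (colsum[k] > 0) acc <- acc + P[i, k] * P[j, k] / colsum[k]
      }
      T[i, j] <- acc
    }
  }
  T
}

# Explicit-loop matrix product.
oracle_matmul <- function(A, B) {
  n <- nrow(A)
  m <- ncol(B)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- sum(A[i, ] * B[, j])
    }
  }
  out
}

# Diffusion iteration to the fixed point.
oracle_diffuse <- function(W0, kernel, alpha, max_iterations = 100L,
                           tolerance = 1e-8) {
  W <- W0
  for (it in seq_len(max_iterations)) {
    Wn <- alpha * oracle_matmul(oracle_matmul(kernel, W), kernel) +
      (1 - alpha) * kernel
    d <- max(abs(Wn - W))
    W <- Wn
    if (d < tolerance) break
  }
  attr(W, "max_delta") <- d
  W
}

# Full enhancement pipeline on a clip space: returns the expected h-value
# matrix (in the space's own clip order) after one application, following
# the documented contract: alphabetical node order, negative h clamped to
# 0, K-NN kernel with lazy self-anchor, DNE/SNE kernel choice, diffusion,
# rescale to the input maximum, residue clamp, consolidating write-back
# with trained (baseline / symmetry_trained) edges preserved.
oracle_apply_ne_H <- function(space, params) {
  labs <- sort(space$labels)
  n <- length(labs)
  pos <- match(labs, space$labels)
  W <- space$H[pos, pos, drop = FALSE]
  kind <- space$kind[pos, pos, drop = FALSE]
  W[is.na(W)] <- 0
  W[W < 0] <- 0
  trained <- !is.na(kind) & kind %in% c("baseline", "symmetry_trained")
  if (isTRUE(params$exclude_trained_input)) W[trained] <- 0
  P <- oracle_knn(W, min(params$k_neighbors, n - 1L))
  if (isTRUE(params$self_anchor)) P <- (P + diag(n)) / 2
  kernel <- if (identical(params$variant, "SNE")) {
    oracle_local_network(P)
  } else {
    P
  }
  Wd <- oracle_diffuse(W, kernel, params$alpha, params$max_iterations,
                       params$tolerance)
  scale <- if (max(W) > 0 && max(Wd) > 0) max(W) / max(Wd) else 1
  Wout <- Wd * scale
  Wout[Wout < attr(Wd, "max_delta") / (1 - params$alpha) * scale] <- 0
  H <- space$H
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (trained[a, b] || Wout[a, b] <= 0) next
      ia <- pos[a]
      ib <- pos[b]
      cur <- H[ia, ib]
      if (is.na(cur) || Wout[a, b] > cur) H[ia, ib] <- Wout[a, b]
    }
  }
  H
}
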