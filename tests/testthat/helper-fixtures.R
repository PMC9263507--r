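# Small graph builders used across tests. All return validated
# connectivity matrices.

mat_from_edges <- function(n, edges) {
  # edges: list of c(i, j, w)
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  connectivity_matrix(w)
}

complete_graph <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  connectivity_matrix(w)
}

star_graph <- function(n_leaves, weight = 1) {
  n <- n_leaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- weight
  w[2:n, 1] <- weight
  connectivity_matrix(w)
}

path_graph <- function(n, weight = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- weight
  connectivity_matrix(w)
}

ring_lattice <- function(n, k) {
  # each node connected to its k nearest neighbours (k/2 each side)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  connectivity_matrix(w)
}

er_graph <- function(n, p, weighted = FALSE, seed = NULL) {
  gen <- function() {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    on <- runif(nrow(ut)) < p
    vals <- if (weighted) runif(sum(on), 0.1, 1) else rep(1, sum(on))
    w[ut[on, , drop = FALSE]] <- vals
    w[ut[on, c(2, 1), drop = FALSE]] <- vals
    connectivity_matrix(w)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

planted_club_graph <- function(n_core = 10, n_periph = 30, p_core = 0.9,
                               p_other = 0.1, seed = NULL) {
  gen <- function() {
    n <- n_core + n_periph
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    is_core_pair <- ut[, 1] <= n_core & ut[, 2] <= n_core
    p <- ifelse(is_core_pair, p_core, p_other)
    on <- runif(nrow(ut)) < p
    w[ut[on, , drop = FALSE]] <- 1
    w[ut[on, c(2, 1), drop = FALSE]] <- 1
    connectivity_matrix(w)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
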