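# Independent brute-force oracles for small graphs (N <= 8): exhaustive
# enumeration of simple paths gives shortest distances and betweenness
# without touching the package's shortest-path machinery.

enumerate_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  rec <- function(v, visited, len, path) {
    if (v == t) {
      out[[length(out) + 1]] <<- list(len = len, path = path)
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !visited[u]) {
        visited[u] <- TRUE
        rec(u, visited, len + 1 / w[v, u], c(path, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, 0, s)
  out
}

brute_force_paths <- function(x, tie_tol = 1e-12) {
  w <- unclass(x)
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- enumerate_simple_paths(w, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    mn <- min(lens)
    d[s, t] <- d[t, s] <- mn
    shortest <- which(lens <= mn + tie_tol)
    sigma <- length(shortest)
    for (pi in shortest) {
      inner <- setdiff(paths[[pi]]$path, c(s, t))
      bc[inner] <- bc[inner] + 1 / sigma
    }
  }
  list(distances = d, betweenness = bc)
}

# Simulated clinical covariates for statistical tests. Sex counts are
# fixed (skewed but never constant) so the design is always full rank.
random_covariates <- function(n, female_frac = 0.1) {
  sex <- rep("M", n)
  sex[sample.int(n, max(2, round(female_frac * n)))] <- "F"
  data.frame(age = rnorm(n, 33, 6), sex = sex)
}
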