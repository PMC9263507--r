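#' Null-model settings
#'
#' Degree-preserving (Maslov-Sneppen) rewired networks are the reference
#' class for small-worldness and rich-club normalization. Defaults: 100
#' null networks, 10 attempted-successful swaps per edge, seeded.
#'
#' @param n_null number of null networks (>= 1).
#' @param rewires_per_edge successful double-edge swaps per edge.
#' @param seed integer seed; \code{NULL} draws from the current RNG stream.
#' @export
null_model_config <- function(n_null = 100, rewires_per_edge = 10,
                              seed = NULL) {
  stopifnot(n_null >= 1, rewires_per_edge >= 1)
  structure(list(n_null = as.integer(n_null),
                 rewires_per_edge = as.integer(rewires_per_edge),
                 seed = seed),
            class = "null_model_config")
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seeds below 2^31 derived from a root seed.
derive_seeds <- function(seed, n, stream = "") {
  if (is.null(seed)) return(rep(list(NULL), n))
  h <- sum(utf8ToInt(stream)) %% 10000L
  as.list(with_local_seed(seed + h, sample.int(2147483646L, n)))
}

# igraph view of a connectivity matrix; zero entries are absent edges.
conn_graph <- function(x, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  m <- unclass(x)
  if (mode == "binary") m <- (m > 0) * 1
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path distance matrix
#'
#' Edge lengths are \code{1/weight} by default (strong FA connections are
#' short), the standard convention for FA-weighted networks; alternatives
#' \code{"neglog"} (\code{-log w}, for weights in (0,1]) and
#' \code{"binary"} (hop count) are available. Unreachable pairs are
#' \code{Inf}, the diagonal is 0, and the result is symmetric.
#'
#' @param x connectivity matrix.
#' @param transform edge-length transform.
#' @export
shortest_distances <- function(x, transform = c("inverse", "neglog", "binary")) {
  transform <- match.arg(transform)
  g <- conn_graph(x, mode = if (transform == "binary") "binary" else "weighted")
  w <- igraph::E(g)$weight
  len <- switch(transform,
                inverse = 1 / w,
                neglog = -log(w),
                binary = rep(1, length(w)))
  d <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

# Onnela weighted local clustering: geometric mean of triangle weights
# normalized by the network maximum, over the k(k-1) neighbour pairs.
onnela_clustering <- function(w) {
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  a13 <- (w / mx)^(1 / 3)
  tri <- diag(a13 %*% a13 %*% a13)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(cc)
}

binary_clustering <- function(w) {
  a <- (w > 0) * 1
  tri <- diag(a %*% a %*% a)
  k <- rowSums(a)
  as.numeric(ifelse(k >= 2, tri / (k * (k - 1)), 0))
}

#' Nodal graph-theory metrics
#'
#' For each node: \code{dc} binary degree centrality, \code{strength} sum
#' of incident weights, \code{bc} betweenness centrality (fractional over
#' tied shortest paths, \code{1/weight} edge lengths in weighted mode),
#' \code{nlp} nodal shortest path length (mean finite distance to the
#' other nodes), \code{ncc} nodal clustering coefficient (triangle density
#' in binary mode, Onnela geometric-mean variant in weighted mode) and
#' \code{ne} nodal efficiency (mean inverse distance to the other nodes,
#' with unreachable pairs contributing 0).
#'
#' @param x connectivity matrix (N >= 3 for clustering).
#' @param mode \code{"weighted"} (default) or \code{"binary"}.
#' @param atlas optional node atlas; adds a label column.
#' @return data.frame with one row per node.
#' @export
nodal_metrics <- function(x, mode = c("weighted", "binary"), atlas = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_connectivity_matrix(x))
  n <- nrow(x)
  if (n < 3) stop("clustering coefficient needs at least 3 nodes", call. = FALSE)
  w <- unclass(x)
  d <- shortest_distances(x, transform = if (mode == "binary") "binary" else "inverse")
  diag(d) <- NA
  nlp <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NA_real_
  })
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  ne <- rowSums(inv, na.rm = TRUE) / (n - 1)
  g <- conn_graph(x, mode = "weighted")
  ew <- igraph::E(g)$weight
  bc <- igraph::betweenness(g, directed = FALSE,
                            weights = if (mode == "binary") rep(1, length(ew))
                                      else 1 / ew)
  out <- data.frame(
    node = seq_len(n),
    dc = rowSums(w > 0),
    strength = rowSums(w),
    bc = as.numeric(bc),
    nlp = nlp,
    ncc = if (mode == "binary") binary_clustering(w) else onnela_clustering(w),
    ne = as.numeric(ne))
  if (!is.null(atlas)) out$label <- atlas$label[out$node]
  out
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Repeated double-edge swaps: two edges (a,b) and (c,d) with four
#' distinct endpoints are replaced by (a,d) and (c,b) when neither new
#' edge already exists. The binary degree sequence is preserved exactly
#' and each rewired edge carries its original weight to its new endpoints.
#' Attempts are capped, so tiny graphs with no valid swap (for example a
#' triangle) return unchanged, with the achieved swap count in the
#' \code{"n_swaps"} attribute.
#'
#' @param x connectivity matrix.
#' @param config \code{\link{null_model_config}} (its
#'   \code{rewires_per_edge} and \code{seed} are used).
#' @export
rewire_preserving_degree <- function(x, config = null_model_config()) {
  stopifnot(is_connectivity_matrix(x))
  w <- unclass(x)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) return(x)
  target <- config$rewires_per_edge * m
  with_local_seed(config$seed, {
    wc <- w + 0            # force a copy: the kernel mutates in place
    edges0 <- ut - 1L      # 0-based for the compiled kernel
    storage.mode(edges0) <- "integer"
    res <- rewire_swaps(edges0, wc, as.integer(target),
                        as.integer(100L * target))
    out <- connectivity_matrix(wc, subject_id = attr(x, "subject_id"))
    attr(out, "n_swaps") <- res$n_swaps
    out
  })
}

#' Global graph-theory metrics with small-worldness
#'
#' Computes the global clustering coefficient \code{cp} (mean nodal
#' clustering), characteristic path length \code{lp} (mean finite
#' pairwise distance), global efficiency \code{eglob} (mean inverse
#' distance over all pairs, unreachable = 0), mean connection
#' \code{strength}, and the small-world indices against degree-preserving
#' nulls: \code{gamma} = cp / mean null cp, \code{lambda} = lp / mean null
#' lp, \code{sigma} = gamma / lambda. \code{sigma > 1} flags small-world
#' organization.
#'
#' @param x connectivity matrix with at least one edge.
#' @param nulls \code{\link{null_model_config}}; \code{NULL} skips the
#'   small-world indices.
#' @param mode metric mode as in \code{\link{nodal_metrics}}.
#' @return one-row data.frame.
#' @export
global_metrics <- function(x, nulls = null_model_config(), mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  stopifnot(is_connectivity_matrix(x))
  if (sum(unclass(x) > 0) == 0)
    stop("global metrics are undefined on an edgeless matrix", call. = FALSE)
  base <- global_cp_lp(x, mode)
  out <- data.frame(cp = base$cp, lp = base$lp, eglob = base$eglob,
                    strength = mean(rowSums(unclass(x))),
                    gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  if (!is.null(nulls)) {
    seeds <- derive_seeds(nulls$seed, nulls$n_null, "smallworld")
    null_cp <- null_lp <- numeric(nulls$n_null)
    for (b in seq_len(nulls$n_null)) {
      cfg <- null_model_config(1, nulls$rewires_per_edge, seeds[[b]])
      r <- rewire_preserving_degree(x, cfg)
      nb <- global_cp_lp(r, mode)
      null_cp[b] <- nb$cp
      null_lp[b] <- nb$lp
    }
    out$gamma <- out$cp / mean(null_cp)
    out$lambda <- out$lp / mean(null_lp)
    out$sigma <- out$gamma / out$lambda
  }
  out
}

global_cp_lp <- function(x, mode) {
  w <- unclass(x)
  n <- nrow(w)
  cc <- if (mode == "binary") binary_clustering(w) else onnela_clustering(w)
  d <- shortest_distances(x, transform = if (mode == "binary") "binary" else "inverse")
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  list(cp = mean(cc),
       lp = if (length(fin)) mean(fin) else NA_real_,
       eglob = mean(inv))
}

#' Area under the curve over a sparsity grid
#'
#' Trapezoidal integral of a metric measured at each sparsity threshold,
#' the conventional aggregate when analysing thresholded networks.
#' @param values metric values, one per threshold.
#' @param sparsities strictly increasing thresholds.
#' @export
auc_over_sparsity <- function(values, sparsities) {
  stopifnot(length(values) == length(sparsities),
            all(diff(sparsities) > 0))
  if (length(values) < 2) return(NA_real_)
  sum(diff(sparsities) * (head(values, -1) + values[-1]) / 2)
}
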