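#' Rich-club coefficient at one degree level
#'
#' The club at level k is the set of nodes with binary degree strictly
#' greater than k. Two coefficients are reported side by side:
#' \code{phi}, the density of connections within the club
#' (\code{2 E_club / (n_club (n_club - 1))}), and \code{phi_w}, the mean
#' weight of the club edges that are present. With fewer than two club
#' members both are undefined and flagged, never silently zero.
#'
#' @param x connectivity matrix.
#' @param k degree level (>= 0).
#' @return list with \code{phi}, \code{phi_w}, \code{n_club},
#'   \code{n_club_edges}, \code{defined}.
#' @export
rich_club_coefficient <- function(x, k) {
  stopifnot(is_connectivity_matrix(x), k >= 0)
  w <- unclass(x)
  deg <- rowSums(w > 0)
  club <- which(deg > k)
  nc <- length(club)
  if (nc < 2)
    return(list(phi = NA_real_, phi_w = NA_real_, n_club = nc,
                n_club_edges = 0L, defined = FALSE))
  sub <- w[club, club, drop = FALSE]
  ew <- sub[upper.tri(sub)]
  present <- ew[ew > 0]
  list(phi = length(present) / (nc * (nc - 1) / 2),
       phi_w = if (length(present)) mean(present) else NA_real_,
       n_club = nc,
       n_club_edges = length(present),
       defined = TRUE)
}

#' Rich-club curve over a range of degree levels
#'
#' @param x connectivity matrix.
#' @param k_values degree levels; default 0 to max degree - 1.
#' @return data.frame with columns k, phi, phi_w, n_club, defined.
#' @export
rich_club_curve <- function(x, k_values = NULL) {
  deg <- rowSums(unclass(x) > 0)
  if (is.null(k_values)) {
    kmax <- max(deg)
    if (kmax < 1) stop("edgeless matrix has no rich-club curve", call. = FALSE)
    k_values <- 0:(kmax - 1)
  }
  rows <- lapply(k_values, function(k) {
    rc <- rich_club_coefficient(x, k)
    data.frame(k = k, phi = rc$phi, phi_w = rc$phi_w,
               n_club = rc$n_club, defined = rc$defined)
  })
  do.call(rbind, rows)
}

#' Normalized rich-club curve against degree-preserving nulls
#'
#' \code{phi_norm(k) = phi(k) / mean(phi_null(k))} over rewired null
#' networks that preserve the degree sequence. Levels where the observed
#' coefficient or every null coefficient is undefined stay flagged
#' undefined. Values above 1 at high k indicate a rich club denser than
#' degree alone explains.
#'
#' @param x connectivity matrix.
#' @param nulls \code{\link{null_model_config}}.
#' @param k_values degree levels as in \code{\link{rich_club_curve}}.
#' @return data.frame with columns k, phi, phi_w, phi_norm, n_club, defined.
#' @export
normalized_rich_club <- function(x, nulls = null_model_config(),
                                 k_values = NULL) {
  obs <- rich_club_curve(x, k_values)
  seeds <- derive_seeds(nulls$seed, nulls$n_null, "richclub")
  null_phi <- matrix(NA_real_, nrow(obs), nulls$n_null)
  for (b in seq_len(nulls$n_null)) {
    cfg <- null_model_config(1, nulls$rewires_per_edge, seeds[[b]])
    r <- rewire_preserving_degree(x, cfg)
    null_phi[, b] <- rich_club_curve(r, obs$k)$phi
  }
  mean_null <- rowMeans(null_phi, na.rm = TRUE)
  obs$phi_norm <- ifelse(obs$defined & is.finite(mean_null) & mean_null > 0,
                         obs$phi / mean_null, NA_real_)
  obs$defined <- obs$defined & !is.na(obs$phi_norm)
  obs
}

#' Identify hub nodes from a cohort of connectomes
#'
#' Node degrees are computed per subject and averaged across every
#' supplied subject (all comparison groups pooled), giving one averaged
#' degree profile. Hubs are then either the nodes whose averaged degree
#' is at least one standard deviation above the profile mean
#' (\code{method = "sd_rule"}; population SD over nodes) or the
#' \code{k_top} nodes of highest averaged degree
#' (\code{method = "top_k"}, default \code{k_top = 13}). Ties at the
#' selection boundary are broken in favour of the smaller node index.
#'
#' @param matrices list of connectivity matrices with identical N.
#' @param method \code{"top_k"} or \code{"sd_rule"}.
#' @param k_top club size for \code{top_k}.
#' @param ranking \code{"degree"} (binary degree, default) or
#'   \code{"strength"}.
#' @return object of class \code{hub_set}: list with \code{hubs} (node
#'   indices, descending averaged degree), \code{mean_degree} (profile),
#'   \code{threshold}, \code{method}, \code{k_top}.
#' @export
identify_hubs <- function(matrices, method = c("top_k", "sd_rule"),
                          k_top = 13, ranking = c("degree", "strength")) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  if (!length(matrices)) stop("need at least one subject", call. = FALSE)
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("subjects have mixed node counts: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  prof <- rowMeans(vapply(matrices, function(m) {
    w <- unclass(m)
    if (ranking == "degree") rowSums(w > 0) else rowSums(w)
  }, numeric(ns[1])))
  n <- length(prof)
  # descending profile, smaller index first on ties
  ord <- order(-prof, seq_len(n))
  if (method == "top_k") {
    stopifnot(k_top >= 1, k_top <= n)
    hubs <- ord[seq_len(k_top)]
    threshold <- prof[hubs[k_top]]
  } else {
    pop_sd <- sqrt(mean((prof - mean(prof))^2))
    threshold <- mean(prof) + pop_sd
    hubs <- ord[prof[ord] >= threshold]
    k_top <- NA_integer_
  }
  structure(list(hubs = hubs, mean_degree = prof, threshold = threshold,
                 method = method, k_top = k_top, ranking = ranking),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set (%s): %d hubs, threshold %.3f\n",
              x$method, length(x$hubs), x$threshold))
  cat("  nodes:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Hub report table
#'
#' One row per hub, ranked by descending averaged degree, with atlas
#' labels when an atlas is supplied — the shape used to report rich-club
#' regions per comparison pair.
#' @param hub_set result of \code{\link{identify_hubs}}.
#' @param atlas optional node atlas.
#' @param comparison identifier of the group pair the cohort pooled.
#' @export
hub_table <- function(hub_set, atlas = NULL, comparison = NA_character_) {
  df <- data.frame(rank = seq_along(hub_set$hubs),
                   node = hub_set$hubs,
                   mean_degree = hub_set$mean_degree[hub_set$hubs],
                   comparison = comparison)
  if (!is.null(atlas)) df$label <- atlas$label[df$node]
  df[, intersect(c("rank", "node", "label", "mean_degree", "comparison"),
                 names(df))]
}

#' Classify edges by hub membership
#'
#' Every present edge is labelled \code{rich_club} (both endpoints hubs),
#' \code{feeder} (exactly one hub endpoint) or \code{local} (no hub
#' endpoint); the three classes partition the edge set.
#'
#' @param x connectivity matrix.
#' @param hubs \code{hub_set} or integer vector of hub node indices.
#' @return data.frame with columns i, j, weight, class.
#' @export
classify_edges <- function(x, hubs) {
  stopifnot(is_connectivity_matrix(x))
  hub_idx <- if (inherits(hubs, "hub_set")) hubs$hubs else as.integer(hubs)
  if (length(hub_idx) && max(hub_idx) > nrow(x))
    stop("hub index exceeds node count", call. = FALSE)
  w <- unclass(x)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  n_hub_ends <- (ut[, 1] %in% hub_idx) + (ut[, 2] %in% hub_idx)
  data.frame(i = ut[, 1], j = ut[, 2], weight = w[ut],
             class = c("local", "feeder", "rich_club")[n_hub_ends + 1])
}

#' All hub-hub (rich-club) node pairs
#'
#' The candidate edge set for between-group rich-club comparisons: every
#' unordered pair of hub nodes, whether or not an edge is present in any
#' one subject.
#' @param hubs \code{hub_set} or integer hub indices.
#' @export
rich_club_pairs <- function(hubs) {
  hub_idx <- sort(if (inherits(hubs, "hub_set")) hubs$hubs else as.integer(hubs))
  if (length(hub_idx) < 2)
    return(data.frame(i = integer(0), j = integer(0)))
  cmb <- utils::combn(hub_idx, 2)
  data.frame(i = cmb[1, ], j = cmb[2, ])
}

#' Count abnormal connections per node
#'
#' Given abnormal (significantly increased or decreased) edges, counts
#' the abnormal edges incident to each node, split by direction. The sum
#' of all per-node counts is twice the number of edges (each edge has two
#' endpoints).
#'
#' @param abnormal_edges data.frame with columns i, j, direction
#'   (\code{"increased"}/\code{"decreased"}).
#' @param n_nodes total node count for the output table.
#' @return data.frame with columns node, n_increased, n_decreased, n_total.
#' @export
count_abnormal_per_node <- function(abnormal_edges, n_nodes) {
  inc <- dec <- integer(n_nodes)
  if (nrow(abnormal_edges)) {
    for (r in seq_len(nrow(abnormal_edges))) {
      nodes <- c(abnormal_edges$i[r], abnormal_edges$j[r])
      if (abnormal_edges$direction[r] == "increased")
        inc[nodes] <- inc[nodes] + 1L
      else dec[nodes] <- dec[nodes] + 1L
    }
  }
  data.frame(node = seq_len(n_nodes), n_increased = inc,
             n_decreased = dec, n_total = inc + dec)
}
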