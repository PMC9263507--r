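#' Classify a connection by resting-state network membership
#'
#' Looks both endpoints up in the atlas and labels the connection
#' \code{intra} when they belong to the same resting-state network and
#' \code{inter} otherwise. The lookup is symmetric in the endpoints: the
#' network pair is reported in sorted order.
#'
#' @param i,j node indices (1-based atlas indices).
#' @param atlas node atlas.
#' @param direction optional \code{"increased"}/\code{"decreased"} tag
#'   carried through to the result.
#' @return data.frame row: i, j, network_a, network_b, kind, direction.
#' @export
classify_connection <- function(i, j, atlas, direction = NA_character_) {
  n <- nrow(atlas)
  if (any(c(i, j) < 1) || any(c(i, j) > n))
    stop("node index outside atlas range", call. = FALSE)
  ra <- atlas$rsn[i]; rb <- atlas$rsn[j]
  if (anyNA(ra) || anyNA(rb))
    stop("node(s) lack an RSN assignment", call. = FALSE)
  nets <- t(apply(cbind(ra, rb), 1, sort))
  out <- data.frame(i = i, j = j,
                    network_a = unname(nets[, 1]),
                    network_b = unname(nets[, 2]),
                    kind = ifelse(ra == rb, "intra", "inter"),
                    direction = direction)
  rownames(out) <- NULL
  out
}

#' Summarize classified connections by network pair and direction
#'
#' Contingency counts per (network pair, kind, direction); the counts sum
#' to the number of input connections and the summary is invariant to the
#' input order.
#'
#' @param connections data.frame from \code{\link{classify_connection}}.
#' @return data.frame: network_a, network_b, kind, direction, count.
#' @export
summarize_rsn <- function(connections) {
  if (!nrow(connections))
    return(data.frame(network_a = character(0), network_b = character(0),
                      kind = character(0), direction = character(0),
                      count = integer(0)))
  key <- paste(connections$network_a, connections$network_b,
               connections$kind, connections$direction, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(network_a = vapply(parts, `[`, "", 1),
                    network_b = vapply(parts, `[`, "", 2),
                    kind = vapply(parts, `[`, "", 3),
                    direction = vapply(parts, `[`, "", 4),
                    count = as.integer(tab))
  out <- out[order(out$network_a, out$network_b, out$direction), ]
  rownames(out) <- NULL
  out
}
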