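#' Streamline summary records
#'
#' Deterministic tractography is consumed at the level of streamline
#' summaries: for each streamline, the pair of atlas regions it connects,
#' the per-step FA samples along it, the minimum FA, and the maximum
#' turning angle between adjacent steps. Records are held in a data.frame
#' with columns \code{region_a}, \code{region_b} (1-based region indices,
#' \code{NA} = endpoint not assigned to any region), \code{min_fa},
#' \code{max_turn_angle} (degrees) and \code{fa_values} (list column of
#' numeric vectors).
#'
#' @param region_a,region_b integer region indices (NA for unassigned).
#' @param fa_values list of numeric FA vectors, one per streamline.
#' @param min_fa minimum FA along each streamline; computed from
#'   \code{fa_values} when omitted.
#' @param max_turn_angle maximum inter-step turning angle, degrees.
#' @return data.frame of streamline records.
#' @export
streamline_records <- function(region_a, region_b, fa_values,
                               min_fa = NULL, max_turn_angle) {
  if (!is.list(fa_values)) fa_values <- list(fa_values)
  n <- length(fa_values)
  if (is.null(min_fa))
    min_fa <- vapply(fa_values, function(v) if (length(v)) min(v) else NA_real_,
                     numeric(1))
  bad <- which(vapply(seq_len(n), function(i) {
    v <- fa_values[[i]]
    length(v) > 0 && min_fa[i] > min(v) + 1e-12
  }, logical(1)))
  if (length(bad))
    stop("min_fa exceeds the minimum of fa_values for record(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(max_turn_angle < 0 | max_turn_angle > 180, na.rm = TRUE))
    stop("max_turn_angle must lie in [0, 180] degrees", call. = FALSE)
  df <- data.frame(region_a = as.integer(region_a),
                   region_b = as.integer(region_b),
                   min_fa = as.numeric(min_fa),
                   max_turn_angle = as.numeric(max_turn_angle))
  df$fa_values <- fa_values
  df
}

#' Apply the streamline inclusion rules
#'
#' Keeps streamlines that a tracker with an FA termination threshold of
#' 0.2 and an angle threshold of 45 degrees would have retained: minimum
#' FA along the streamline at least \code{fa_min}, maximum turning angle
#' strictly below \code{angle_max}, both endpoints assigned to atlas
#' regions, and the two endpoints in different regions. Record order is
#' preserved; an empty result is allowed.
#'
#' @param records streamline record data.frame.
#' @param fa_min FA floor (default 0.2).
#' @param angle_max exclusive angle ceiling in degrees (default 45).
#' @export
filter_streamlines <- function(records, fa_min = 0.2, angle_max = 45) {
  keep <- !is.na(records$region_a) & !is.na(records$region_b) &
    records$region_a != records$region_b &
    !is.na(records$min_fa) & records$min_fa >= fa_min &
    !is.na(records$max_turn_angle) & records$max_turn_angle < angle_max
  records[keep, , drop = FALSE]
}

#' Build an FA-weighted interregional connection matrix
#'
#' The weight of the edge between regions i and j is the average FA of the
#' streamlines connecting them. Two readings of "average FA" exist:
#' \code{"per_streamline"} (default) first averages FA within each
#' streamline and then averages those streamline means, so every
#' streamline counts equally regardless of its length;
#' \code{"pooled"} averages all FA samples of all contributing
#' streamlines in one pool, which weights long streamlines more.
#'
#' @param records filtered streamline record data.frame.
#' @param n_nodes number of atlas regions.
#' @param averaging \code{"per_streamline"} or \code{"pooled"}.
#' @param subject_id identifier for the resulting matrix.
#' @return \code{\link{connectivity_matrix}} with zero weight for region
#'   pairs that no streamline connects.
#' @export
build_fabirc <- function(records, n_nodes,
                         averaging = c("per_streamline", "pooled"),
                         subject_id = NA_character_) {
  averaging <- match.arg(averaging)
  w <- matrix(0, n_nodes, n_nodes)
  if (nrow(records)) {
    if (any(records$region_a > n_nodes | records$region_b > n_nodes,
            na.rm = TRUE))
      stop("streamline region index exceeds n_nodes", call. = FALSE)
    if (any(is.na(records$region_a) | is.na(records$region_b)))
      stop("unassigned endpoints present; run filter_streamlines first",
           call. = FALSE)
    i <- pmin(records$region_a, records$region_b)
    j <- pmax(records$region_a, records$region_b)
    key <- paste(i, j)
    if (averaging == "per_streamline") {
      sl_mean <- vapply(records$fa_values, mean, numeric(1))
      agg <- tapply(sl_mean, key, mean)
    } else {
      sums <- tapply(vapply(records$fa_values, sum, numeric(1)), key, sum)
      lens <- tapply(vapply(records$fa_values, length, numeric(1)), key, sum)
      agg <- sums / lens
    }
    parts <- strsplit(names(agg), " ", fixed = TRUE)
    ii <- as.integer(vapply(parts, `[`, "", 1))
    jj <- as.integer(vapply(parts, `[`, "", 2))
    w[cbind(ii, jj)] <- as.numeric(agg)
    w[cbind(jj, ii)] <- as.numeric(agg)
  }
  connectivity_matrix(w, subject_id = subject_id)
}

#' Read/write streamline records as TSV
#'
#' Columns: region_a, region_b, min_fa, max_turn_angle, fa_values
#' (semicolon-joined floats). Unassigned endpoints are written as NA.
#' @param path file path.
#' @export
read_streamlines <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  fa <- lapply(strsplit(as.character(df$fa_values), ";", fixed = TRUE),
               as.numeric)
  streamline_records(df$region_a, df$region_b, fa,
                     min_fa = df$min_fa,
                     max_turn_angle = df$max_turn_angle)
}

#' @rdname read_streamlines
#' @param records streamline record data.frame.
#' @export
write_streamlines <- function(records, path) {
  out <- records
  out$fa_values <- vapply(records$fa_values, function(v)
    paste(formatC(v, digits = 8, format = "g"), collapse = ";"), "")
  write_tsv_stable(out, path, digits = 8)
  invisible(path)
}
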