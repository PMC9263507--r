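#' @useDynLib richclubnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif rbinom quantile lm pt qt cor complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

RSN_LEVELS <- c("DMN", "SN", "VN", "SMN", "PAC", "EXN", "ORB", "OLF", "THA", "OTHER")

#' Construct and validate a connectivity matrix
#'
#' A connectivity matrix is the atomic input of the pipeline: a symmetric,
#' non-negative, zero-diagonal \code{N x N} matrix of FA-based edge weights
#' for one subject. Asymmetric inputs (which streamline counting can
#' produce) are symmetrized by averaging with the transpose; asymmetry
#' larger than \code{asym_tol} is recorded in the \code{"asymmetry"}
#' attribute and raises a warning rather than an error.
#'
#' @param weights numeric \code{N x N} matrix of non-negative edge weights.
#' @param subject_id subject identifier carried with the matrix.
#' @param asym_tol maximum absolute asymmetry tolerated silently.
#' @return a matrix of class \code{connectivity_matrix} with attributes
#'   \code{subject_id} and \code{asymmetry}.
#' @export
connectivity_matrix <- function(weights, subject_id = NA_character_,
                                asym_tol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop(sprintf("matrix must be square, got %d x %d",
                 nrow(weights), ncol(weights)), call. = FALSE)
  if (nrow(weights) < 2)
    stop("connectivity matrix needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights))
    stop("matrix contains NA/NaN entries", call. = FALSE)
  if (any(weights < 0))
    stop("matrix contains negative entries", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > asym_tol)
    warning(sprintf("matrix asymmetry %.3g exceeds %.1g; symmetrizing by averaging",
                    asym, asym_tol), call. = FALSE)
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  dimnames(w) <- NULL
  structure(w,
            subject_id = subject_id,
            asymmetry = asym,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x)
  ne <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("connectivity_matrix: %d nodes, %d edges, subject '%s'\n",
              n, ne, attr(x, "subject_id")))
  cat(sprintf("  density %.3f, weight range [%.3f, %.3f]\n",
              ne / (n * (n - 1) / 2),
              if (ne > 0) min(x[x > 0]) else NA_real_,
              if (ne > 0) max(x) else NA_real_))
  invisible(x)
}

is_connectivity_matrix <- function(x) inherits(x, "connectivity_matrix")

#' Read a connectivity matrix from delimited text
#'
#' Matrices are stored as headerless \code{N x N} numeric grids, one row per
#' line (TSV by default, CSV accepted). The result is validated with
#' \code{\link{connectivity_matrix}}.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param subject_id subject identifier; defaults to the file stem.
#' @export
read_matrix <- function(path, delimiter = "\t", subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          colClasses = "numeric", strip.white = TRUE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix file %s is not square: %d rows, %d columns",
                 path, nrow(m), ncol(m)), call. = FALSE)
  connectivity_matrix(m, subject_id = subject_id)
}

#' Write a connectivity matrix as delimited text
#'
#' Values are printed at a fixed 10-significant-digit precision so the
#' write/read round trip is the identity on validated matrices.
#'
#' @param x connectivity matrix.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
write_matrix <- function(x, path, delimiter = "\t") {
  txt <- apply(unclass(x), 1, function(row)
    paste(formatC(row, digits = 10, format = "g"), collapse = delimiter))
  writeLines(txt, path)
  invisible(path)
}

#' Threshold a matrix to a target sparsity
#'
#' Retains exactly \code{round(sparsity * N(N-1)/2)} strongest edges and
#' zeroes the rest, keeping the surviving weights. Ties at the cutoff are
#' broken deterministically in favour of the lexicographically smaller
#' \code{(i, j)} node pair.
#'
#' @param x connectivity matrix.
#' @param sparsity fraction of possible edges to retain, in (0, 1).
#' @export
apply_sparsity <- function(x, sparsity) {
  stopifnot(is_connectivity_matrix(x))
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      sparsity <= 0 || sparsity >= 1)
    stop("sparsity must be a single fraction in (0, 1)", call. = FALSE)
  n <- nrow(x)
  m_keep <- round(sparsity * n * (n - 1) / 2)
  if (m_keep < 1)
    stop(sprintf("sparsity %.4f retains zero edges at N=%d", sparsity, n),
         call. = FALSE)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  w <- x[ut]
  present <- w > 0
  ord <- order(-w[present], ut[present, 1], ut[present, 2])
  keep_rows <- which(present)[ord][seq_len(min(m_keep, sum(present)))]
  out <- matrix(0, n, n)
  ij <- ut[keep_rows, , drop = FALSE]
  out[ij] <- w[keep_rows]
  out[ij[, c(2, 1), drop = FALSE]] <- w[keep_rows]
  connectivity_matrix(out, subject_id = attr(x, "subject_id"))
}

#' Default sparsity grid
#'
#' The threshold grid used when sparsity-resolved analysis is requested:
#' 0.10 to 0.34 in steps of 0.01, a conventional range for 90-node
#' structural networks that keeps the weakest threshold above the
#' connectedness floor of \code{N - 1} edges.
#' @export
default_sparsity_grid <- function() seq(0.10, 0.34, by = 0.01)

#' Read a node atlas table
#'
#' An atlas is a TSV with a header row and columns \code{index} (1-based
#' region number), \code{label}, \code{hemisphere} (\code{L}/\code{R}) and
#' \code{rsn} (one of the 10 resting-state-network tokens: DMN, SN, VN,
#' SMN, PAC, EXN, ORB, OLF, THA, OTHER). An optional \code{alt_rsn} column
#' records secondary assignments for regions the literature places
#' ambiguously; summaries always use the primary label.
#'
#' @param path atlas file; defaults to the bundled 90-region AAL table.
#' @return data.frame of class \code{node_atlas}.
#' @export
read_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal90_rsn_synthetic.tsv",
                        package = "richclubnet", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("index", "label", "hemisphere", "rsn")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("atlas is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(df)
  if (!identical(as.integer(df$index), seq_len(n)))
    stop("atlas indices must run 1..N without gaps", call. = FALSE)
  dup <- df$label[duplicated(df$label)]
  if (length(dup))
    stop("duplicate atlas labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_rsn <- setdiff(unique(df$rsn), RSN_LEVELS)
  if (length(bad_rsn))
    stop("unknown rsn tokens: ", paste(bad_rsn, collapse = ", "),
         " (allowed: ", paste(RSN_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere must be L or R", call. = FALSE)
  if (!"alt_rsn" %in% names(df)) df$alt_rsn <- NA_character_
  df$alt_rsn[!nzchar(trimws(ifelse(is.na(df$alt_rsn), "", df$alt_rsn)))] <- NA_character_
  class(df) <- c("node_atlas", "data.frame")
  df
}

#' The bundled 90-region AAL atlas with RSN assignments
#'
#' A reconstruction: the resting-state-network membership of each AAL
#' region follows the standard anatomical groupings (visual cortex regions
#' to VN, basal ganglia to SN, and so on); it is shipped as an editable
#' table, not a canonical lookup.
#' @export
aal90_atlas <- function() read_atlas(NULL)

#' Read a subject table
#'
#' TSV with a header; required columns \code{subject_id}, \code{group},
#' \code{age}, \code{sex}; optional clinical columns (disease_course, cd4,
#' cd4_cd8_ratio) and six \code{tscore_*} cognitive-domain columns.
#' @param path file path.
#' @export
read_subjects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("subject table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$age <= 0)) stop("ages must be positive", call. = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be coded M/F", call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values", call. = FALSE)
  df
}

#' Write a subject table
#' @param subjects data.frame as returned by \code{\link{read_subjects}}.
#' @param path output path.
#' @export
write_subjects <- function(subjects, path) {
  write_tsv_stable(subjects, path)
  invisible(path)
}

# Deterministic TSV writer: fixed significant digits, no quoting, no
# row names, so identical inputs produce byte-identical files.
write_tsv_stable <- function(df, path, digits = 10) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- formatC(df2[[j]], digits = digits, format = "g")
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Domain names for the six-domain neuropsychological battery, in the
# order used throughout: verbal fluency, attention/working memory,
# executive function, learning/recall, processing speed, fine motor.
TSCORE_DOMAINS <- c("verbal_fluency", "attention_wm", "executive",
                    "learning_recall", "speed", "fine_motor")
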