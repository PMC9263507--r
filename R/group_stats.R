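# Build a covariate design matrix (intercept + age + sex, or any numeric
# columns); sex given as M/F is coded 1/0.
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cv <- as.data.frame(covariates)
  if (nrow(cv) != n)
    stop(sprintf("covariates have %d rows but values have %d", nrow(cv), n),
         call. = FALSE)
  for (j in names(cv)) {
    if (is.character(cv[[j]]) || is.factor(cv[[j]])) {
      v <- as.character(cv[[j]])
      if (all(v %in% c("M", "F"))) cv[[j]] <- as.numeric(v == "M")
      else stop("non-numeric covariate column '", j,
                "' is not M/F coded", call. = FALSE)
    }
  }
  if (anyNA(cv)) stop("covariates contain missing values", call. = FALSE)
  x <- cbind("(Intercept)" = 1, as.matrix(cv))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("collinear covariates; rank-deficient column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  x
}

#' Residualize values on covariates
#'
#' Ordinary-least-squares residuals of \code{values} on an intercept plus
#' the covariate columns, fitted on all supplied subjects pooled (never
#' per group), so that a group contrast applied afterwards is not
#' absorbed by the adjustment.
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data.frame of covariates (e.g. age, sex); sex given
#'   as M/F is recoded 1/0. \code{NULL} removes only the mean.
#' @return numeric residual vector.
#' @export
adjust_covariates <- function(values, covariates = NULL) {
  n <- length(values)
  x <- covariate_design(covariates, n)
  if (n < ncol(x) + 2)
    stop("need at least covariate count + 3 subjects (intercept included)",
         call. = FALSE)
  as.numeric(qr.resid(qr(x), values))
}

#' Two-sample t-test on residuals
#'
#' Pooled-variance two-sided test by default (Welch available), signed as
#' group A minus group B. A zero pooled variance (for example identical
#' constant samples) yields the degenerate convention t = 0, p = 1 with
#' \code{degenerate = TRUE}.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @return list with t, p, df, degenerate.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    if (sp2 <= 0)
      return(list(t = 0, p = 1, df = na + nb - 2, degenerate = TRUE))
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    if (va + vb <= 0)
      return(list(t = 0, p = 1, df = na + nb - 2, degenerate = TRUE))
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Covariate-adjusted comparison of one measure
#'
#' The unit statistical step of all group comparisons: pool both groups,
#' residualize on the covariates, and t-test the residuals between
#' groups.
#'
#' @param values_a,values_b per-subject measurements.
#' @param cov_a,cov_b per-group covariate data.frames (same columns).
#' @param variant test variant, see \code{\link{two_sample_t}}.
#' @return list with t, p, df, degenerate.
#' @export
compare_values <- function(values_a, values_b, cov_a = NULL, cov_b = NULL,
                           variant = "pooled") {
  na <- length(values_a)
  v <- c(values_a, values_b)
  covs <- if (is.null(cov_a) && is.null(cov_b)) NULL else rbind(cov_a, cov_b)
  res <- adjust_covariates(v, covs)
  # residuals at floating-point noise level (e.g. a metric constant across
  # subjects) carry no information: degenerate by convention
  if (max(abs(res)) < 1e-9 * (1 + max(abs(v))))
    return(list(t = 0, p = 1, df = length(v) - 2, degenerate = TRUE))
  two_sample_t(res[seq_len(na)], res[-seq_len(na)], variant = variant)
}

# Core engine: compare two (subjects x units) matrices column by column
# with covariate adjustment, returning the comparison table.
compare_matrix_columns <- function(mat_a, mat_b, cov_a, cov_b,
                                   alpha = 0.05, m = ncol(mat_a),
                                   variant = "pooled") {
  stopifnot(ncol(mat_a) == ncol(mat_b))
  nunit <- ncol(mat_a)
  t <- p <- numeric(nunit)
  degen <- logical(nunit)
  for (u in seq_len(nunit)) {
    r <- compare_values(mat_a[, u], mat_b[, u], cov_a, cov_b, variant)
    t[u] <- r$t; p[u] <- r$p; degen[u] <- r$degenerate
  }
  p_bonf <- pmin(1, m * p)
  data.frame(unit = seq_len(nunit), t = t, p = p, p_bonf = p_bonf,
             direction = ifelse(t >= 0, "increased", "decreased"),
             significant_raw = p < alpha,
             significant_corrected = p_bonf < alpha,
             degenerate = degen)
}

# Per-subject nodal metric matrices for a list of connectomes.
cohort_metric_matrices <- function(matrices, mode = "weighted",
                                   metrics = c("dc", "bc", "nlp", "ncc", "ne")) {
  per_subj <- lapply(matrices, nodal_metrics, mode = mode)
  out <- lapply(metrics, function(mt)
    do.call(rbind, lapply(per_subj, function(df) df[[mt]])))
  names(out) <- metrics
  out
}

#' Node-wise group comparison of nodal metrics
#'
#' For every node and every requested metric: residualize the per-subject
#' values on age and sex (pooled across both groups), pooled-variance
#' t-test, and Bonferroni correction within the metric family (m = number
#' of nodes per metric, not nodes x metrics).
#'
#' @param matrices_a,matrices_b lists of connectivity matrices.
#' @param cov_a,cov_b covariate data.frames (age, sex) per group.
#' @param mode metric mode.
#' @param metrics metric names from \code{\link{nodal_metrics}}.
#' @param alpha significance level.
#' @param atlas optional atlas for labels.
#' @param variant test variant.
#' @return data.frame: metric, node, label, t, p, p_bonf, direction,
#'   significance flags.
#' @export
nodal_comparison <- function(matrices_a, matrices_b, cov_a, cov_b,
                             mode = "weighted",
                             metrics = c("dc", "bc", "nlp", "ncc", "ne"),
                             alpha = 0.05, atlas = NULL,
                             variant = "pooled") {
  if (is.null(cov_a) || is.null(cov_b))
    stop("covariates are required for nodal comparison; pass age and sex",
         call. = FALSE)
  ma <- cohort_metric_matrices(matrices_a, mode, metrics)
  mb <- cohort_metric_matrices(matrices_b, mode, metrics)
  n_nodes <- ncol(ma[[1]])
  out <- do.call(rbind, lapply(metrics, function(mt) {
    tab <- compare_matrix_columns(ma[[mt]], mb[[mt]], cov_a, cov_b,
                                  alpha = alpha, m = n_nodes,
                                  variant = variant)
    tab$metric <- mt
    names(tab)[names(tab) == "unit"] <- "node"
    tab
  }))
  if (!is.null(atlas)) out$label <- atlas$label[out$node]
  rownames(out) <- NULL
  out[, intersect(c("metric", "node", "label", "t", "p", "p_bonf",
                    "direction", "significant_raw", "significant_corrected",
                    "degenerate"), names(out))]
}

#' Edge-wise group comparison over a candidate pair list
#'
#' For each node pair (typically the hub-hub pairs from
#' \code{\link{rich_club_pairs}}): per-subject edge weights are
#' residualized on the covariates and t-tested between groups. Positive t
#' marks an increased (enhanced) connection, negative t a decreased one.
#' Pairs with zero weight in every subject of both groups are skipped
#' and reported with \code{skipped = TRUE}.
#'
#' @param matrices_a,matrices_b lists of connectivity matrices.
#' @param pairs data.frame with columns i, j.
#' @param cov_a,cov_b covariate data.frames.
#' @param alpha significance level.
#' @param m Bonferroni family size; defaults to the number of tested
#'   (non-skipped) pairs.
#' @param atlas optional atlas for labels.
#' @param variant test variant.
#' @export
edge_comparison <- function(matrices_a, matrices_b, pairs, cov_a, cov_b,
                            alpha = 0.05, m = NULL, atlas = NULL,
                            variant = "pooled") {
  wa <- vapply(matrices_a, function(x) unclass(x)[cbind(pairs$i, pairs$j)],
               numeric(nrow(pairs)))
  wb <- vapply(matrices_b, function(x) unclass(x)[cbind(pairs$i, pairs$j)],
               numeric(nrow(pairs)))
  wa <- matrix(wa, nrow = nrow(pairs)); wb <- matrix(wb, nrow = nrow(pairs))
  testable <- rowSums(wa != 0) + rowSums(wb != 0) > 0
  if (is.null(m)) m <- sum(testable)
  t <- p <- rep(NA_real_, nrow(pairs))
  degen <- logical(nrow(pairs))
  for (e in which(testable)) {
    r <- compare_values(wa[e, ], wb[e, ], cov_a, cov_b, variant)
    t[e] <- r$t; p[e] <- r$p; degen[e] <- r$degenerate
  }
  out <- data.frame(i = pairs$i, j = pairs$j, t = t, p = p,
                    p_bonf = pmin(1, m * p),
                    direction = ifelse(is.na(t), NA_character_,
                                       ifelse(t >= 0, "increased", "decreased")),
                    significant_raw = !is.na(p) & p < alpha,
                    significant_corrected = !is.na(p) & pmin(1, m * p) < alpha,
                    skipped = !testable,
                    degenerate = degen)
  if (!is.null(atlas)) {
    out$label_i <- atlas$label[out$i]
    out$label_j <- atlas$label[out$j]
  }
  out
}

#' Classify a neuropsychological profile against the ANI pattern
#'
#' Asymptomatic neurocognitive impairment requires scores at least one
#' standard deviation below the adjusted mean in at least two of the six
#' cognitive domains; the boundary is inclusive (a score exactly at
#' mean - SD counts). Whether daily functioning is preserved is an input
#' flag, not computed here.
#'
#' @param tscores named numeric vector of six domain T-scores.
#' @param adjusted_means,sds named numeric vectors over the same domains.
#' @param daily_living_intact logical; \code{FALSE} forces
#'   \code{"normal"} (symptomatic impairment is outside the ANI label).
#' @return \code{"ANI_pattern"} or \code{"normal"}.
#' @export
classify_ani <- function(tscores, adjusted_means, sds,
                         daily_living_intact = TRUE) {
  domains <- names(adjusted_means)
  if (is.null(domains) || !length(domains))
    stop("adjusted_means must be a named vector of domains", call. = FALSE)
  missing <- setdiff(domains, names(tscores))
  if (length(missing))
    stop("missing T-score domain(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(tscores[domains]))
    stop("T-scores contain missing values", call. = FALSE)
  n_impaired <- sum(tscores[domains] <= adjusted_means - sds[domains])
  if (n_impaired >= 2 && daily_living_intact) "ANI_pattern" else "normal"
}

#' Partial Pearson correlation controlling for covariates
#'
#' Both variables are residualized on the covariates (with intercept) and
#' the Pearson correlation of the residuals is computed; the p-value uses
#' a t reference distribution with n - 2 - q degrees of freedom, q being
#' the number of covariate columns. With no covariates this reduces
#' exactly to a plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of covariates or \code{NULL}.
#' @return list with r, p, df, degenerate.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= q + 2)
    stop("need more than covariate count + 2 observations", call. = FALSE)
  design <- covariate_design(covariates, n)
  qd <- qr(design)
  rx <- qr.resid(qd, x)
  ry <- qr.resid(qd, y)
  if (stats::sd(rx) < 1e-12 * (1 + max(abs(x))) ||
      stats::sd(ry) < 1e-12 * (1 + max(abs(y))))
    return(list(r = NA_real_, p = NA_real_, df = n - 2 - q, degenerate = TRUE))
  r <- stats::cor(rx, ry)
  df <- n - 2 - q
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, degenerate = FALSE)
}
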