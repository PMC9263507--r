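#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' Expects \code{matrices/*.tsv}, \code{subjects.tsv} and optionally
#' \code{atlas.tsv}; every writer output is parseable by this reader.
#' @param dir cohort directory.
#' @return list with \code{subjects}, \code{matrices}, \code{atlas}.
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  mat_dir <- file.path(dir, "matrices")
  matrices <- lapply(subjects$subject_id, function(id)
    read_matrix(file.path(mat_dir, paste0(id, ".tsv"))))
  names(matrices) <- subjects$subject_id
  atlas_path <- file.path(dir, "atlas.tsv")
  atlas <- if (file.exists(atlas_path)) read_atlas(atlas_path) else aal90_atlas()
  if (!"subgroup" %in% names(subjects)) subjects$subgroup <- NA_character_
  list(subjects = subjects, matrices = matrices, atlas = atlas)
}

#' Run the full connectome analysis pipeline
#'
#' Executes, in order: (optional) cohort simulation or loading, global
#' metrics with small-world indices per subject, node-wise group
#' comparisons for each comparison pair, hub identification on the
#' averaged degree profile of each pair's pooled subjects, rich-club
#' (hub-hub) edge comparisons with abnormal-connection calls, mapping of
#' abnormal connections onto resting-state networks, per-node
#' abnormal-connection counts, and clinical correlations of
#' raw-significant nodal findings within the patient group. All tables
#' are written as TSV under \code{out_dir} together with a JSON manifest
#' (config echo, seed, versions, file checksums). Reruns with the same
#' inputs and seed are byte-identical.
#'
#' @param cohort cohort list (from \code{\link{generate_cohort}} or
#'   \code{\link{read_cohort}}); \code{NULL} generates the default
#'   synthetic cohort from \code{seed}.
#' @param out_dir output directory.
#' @param comparisons list of 2-vectors of group labels.
#' @param mode metric mode.
#' @param hub_method,k_top hub rule (default: top 13 averaged-degree nodes).
#' @param alpha significance level.
#' @param nulls \code{\link{null_model_config}} for small-worldness;
#'   \code{NULL} skips the null-model indices.
#' @param atlas node atlas.
#' @param seed root seed; drives simulation (when \code{cohort} is NULL)
#'   and the null-model substreams.
#' @param verbose print stage progress.
#' @return invisibly, a list with every result table and the manifest.
#' @export
run_pipeline <- function(cohort = NULL, out_dir,
                         comparisons = list(c("HIV", "HC"),
                                            c("ANI", "NONHAND")),
                         mode = "weighted",
                         hub_method = "top_k", k_top = 13,
                         alpha = 0.05,
                         nulls = null_model_config(seed = seed),
                         atlas = NULL,
                         seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    say("stage simulate: default synthetic cohort, seed %d", seed)
    cohort <- generate_cohort(cohort_config(seed = seed))
  }
  if (is.null(atlas))
    atlas <- if (!is.null(cohort$atlas)) cohort$atlas else aal90_atlas()
  subjects <- cohort$subjects
  if (!"subgroup" %in% names(subjects)) subjects$subgroup <- NA_character_
  for (cmp in comparisons) {
    for (g in cmp)
      if (!any(subject_matches_group(subjects$group, subjects$subgroup, g)))
        stop("pipeline config error: group '", g,
             "' has no subjects", call. = FALSE)
  }
  results <- list()

  say("stage global: per-subject global metrics (%d subjects)",
      length(cohort$matrices))
  glob <- do.call(rbind, lapply(names(cohort$matrices), function(id) {
    gm <- global_metrics(cohort$matrices[[id]], nulls = nulls, mode = mode)
    cbind(data.frame(subject_id = id), gm)
  }))
  results$global_metrics <- glob
  write_tsv_stable(glob, file.path(out_dir, "global_metrics.tsv"))

  cmp_names <- vapply(comparisons, paste, "", collapse = "_vs_")
  global_cmp <- nodal_cmp <- hub_tabs <- edge_cmp <- rsn_sum <-
    abnormal_counts <- vector("list", length(comparisons))
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    cname <- cmp_names[ci]
    say("stage compare: %s", cname)
    ga <- cohort_group(cohort, cmp[1])
    gb <- cohort_group(cohort, cmp[2])

    # global-metric group comparison (covariate-adjusted)
    ga_ids <- ga$subjects$subject_id; gb_ids <- gb$subjects$subject_id
    gmat_a <- as.matrix(glob[match(ga_ids, glob$subject_id),
                             c("cp", "lp", "eglob", "strength", "sigma")])
    gmat_b <- as.matrix(glob[match(gb_ids, glob$subject_id),
                             c("cp", "lp", "eglob", "strength", "sigma")])
    keep <- colSums(is.na(gmat_a)) == 0 & colSums(is.na(gmat_b)) == 0
    gtab <- compare_matrix_columns(gmat_a[, keep, drop = FALSE],
                                   gmat_b[, keep, drop = FALSE],
                                   ga$covariates, gb$covariates,
                                   alpha = alpha, m = sum(keep))
    gtab$metric <- colnames(gmat_a)[keep]
    gtab$comparison <- cname
    global_cmp[[ci]] <- gtab[, c("comparison", "metric", "t", "p", "p_bonf",
                                 "direction", "significant_raw",
                                 "significant_corrected")]

    # node-wise comparison table
    ntab <- nodal_comparison(ga$matrices, gb$matrices,
                             ga$covariates, gb$covariates,
                             mode = mode, alpha = alpha, atlas = atlas)
    ntab$comparison <- cname
    nodal_cmp[[ci]] <- ntab

    # hub ranking on the pooled subjects of this pair
    pooled <- c(ga$matrices, gb$matrices)
    hubs <- identify_hubs(pooled, method = hub_method, k_top = k_top)
    hub_tabs[[ci]] <- hub_table(hubs, atlas = atlas, comparison = cname)

    # rich-club edge comparison over hub-hub pairs
    pairs <- rich_club_pairs(hubs)
    etab <- edge_comparison(ga$matrices, gb$matrices, pairs,
                            ga$covariates, gb$covariates,
                            alpha = alpha, atlas = atlas)
    etab$comparison <- cname
    edge_cmp[[ci]] <- etab

    abn <- etab[!etab$skipped & etab$significant_raw, , drop = FALSE]
    if (nrow(abn)) {
      rsn <- classify_connection(abn$i, abn$j, atlas, abn$direction)
      sum_tab <- summarize_rsn(rsn)
    } else {
      sum_tab <- summarize_rsn(data.frame(network_a = character(0),
                                          network_b = character(0),
                                          kind = character(0),
                                          direction = character(0)))
    }
    sum_tab$comparison <- rep(cname, nrow(sum_tab))
    rsn_sum[[ci]] <- sum_tab
    cnt <- count_abnormal_per_node(abn, n_nodes = nrow(atlas))
    cnt <- cnt[cnt$n_total > 0, , drop = FALSE]
    cnt$label <- atlas$label[cnt$node]
    cnt$comparison <- rep(cname, nrow(cnt))
    abnormal_counts[[ci]] <- cnt
  }
  results$global_comparison <- do.call(rbind, global_cmp)
  results$nodal_comparison <- do.call(rbind, nodal_cmp)
  results$hubs <- do.call(rbind, hub_tabs)
  results$edge_comparison <- do.call(rbind, edge_cmp)
  results$rsn_summary <- do.call(rbind, rsn_sum)
  results$abnormal_counts <- do.call(rbind, abnormal_counts)
  write_tsv_stable(results$global_comparison,
                   file.path(out_dir, "global_comparison.tsv"))
  write_tsv_stable(results$nodal_comparison,
                   file.path(out_dir, "nodal_comparison.tsv"))
  write_tsv_stable(results$hubs, file.path(out_dir, "hubs.tsv"))
  write_tsv_stable(results$edge_comparison,
                   file.path(out_dir, "edge_comparison.tsv"))
  write_tsv_stable(results$rsn_summary, file.path(out_dir, "rsn_summary.tsv"))
  write_tsv_stable(results$abnormal_counts,
                   file.path(out_dir, "abnormal_counts.tsv"))

  say("stage correlate: clinical correlations in the patient group")
  results$correlations <- clinical_correlations(cohort, results$nodal_comparison,
                                                mode = mode, alpha = alpha)
  write_tsv_stable(results$correlations,
                   file.path(out_dir, "correlations.tsv"))

  manifest <- list(
    package = "richclubnet",
    package_version = as.character(utils::packageVersion("richclubnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = list(comparisons = cmp_names, mode = mode,
                  hub_method = hub_method, k_top = k_top, alpha = alpha,
                  n_null = if (is.null(nulls)) 0L else nulls$n_null,
                  n_subjects = nrow(subjects)),
    files = as.list(tools::md5sum(sort(list.files(out_dir, "\\.tsv$",
                                                  full.names = TRUE)))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# Correlate each raw-significant nodal finding (patient-vs-control
# comparison) with the clinical variables, controlling age and sex,
# within patients having complete data.
clinical_correlations <- function(cohort, nodal_cmp, mode = "weighted",
                                  alpha = 0.05) {
  sig <- nodal_cmp[nodal_cmp$significant_raw &
                     nodal_cmp$comparison == nodal_cmp$comparison[1], ,
                   drop = FALSE]
  out <- data.frame(metric = character(0), node = integer(0),
                    label = character(0), variable = character(0),
                    r = numeric(0), p = numeric(0), n = integer(0),
                    significant = logical(0))
  if (!nrow(sig)) return(out)
  pat <- cohort_group(cohort, "HIV")
  clin_vars <- intersect(c("disease_course", "cd4", "cd4_cd8_ratio",
                           paste0("tscore_", TSCORE_DOMAINS)),
                         names(pat$subjects))
  metr <- cohort_metric_matrices(pat$matrices, mode = mode,
                                 metrics = unique(sig$metric))
  rows <- list()
  for (r in seq_len(nrow(sig))) {
    vals <- metr[[sig$metric[r]]][, sig$node[r]]
    for (v in clin_vars) {
      y <- pat$subjects[[v]]
      ok <- !is.na(y) & !is.na(vals)
      if (sum(ok) < 8) next
      pc <- partial_correlation(vals[ok], y[ok],
                                pat$covariates[ok, , drop = FALSE])
      rows[[length(rows) + 1]] <-
        data.frame(metric = sig$metric[r], node = sig$node[r],
                   label = if ("label" %in% names(sig)) sig$label[r]
                           else NA_character_,
                   variable = v, r = pc$r, p = pc$p, n = sum(ok),
                   significant = !is.na(pc$p) && pc$p < alpha)
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
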