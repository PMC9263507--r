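# Default planted hub regions: the 13 AAL regions reported as rich-club
# hubs (putamen, precuneus, calcarine, caudate, thalamus, superior and
# middle occipital gyri, cuneus), as 1-based AAL indices.
DEFAULT_HUB_NODES <- c(74L, 73L, 68L, 67L, 44L, 72L, 77L, 50L, 43L, 49L,
                       71L, 51L, 46L)

# Per-subgroup six-domain T-score models (means, SDs) emulating the
# clinical battery's group-level dispersion.
DEFAULT_TSCORE_MODEL <- list(
  ANI = list(mean = c(verbal_fluency = 41.25, attention_wm = 38.08,
                      executive = 49.64, learning_recall = 39.10,
                      speed = 40.35, fine_motor = 40.40),
             sd = c(verbal_fluency = 8.67, attention_wm = 5.82,
                    executive = 10.75, learning_recall = 6.83,
                    speed = 8.25, fine_motor = 11.60)),
  NONHAND = list(mean = c(verbal_fluency = 48.75, attention_wm = 44.39,
                          executive = 59.79, learning_recall = 47.13,
                          speed = 47.83, fine_motor = 46.90),
                 sd = c(verbal_fluency = 5.91, attention_wm = 6.76,
                        executive = 8.93, learning_recall = 6.43,
                        speed = 8.68, fine_motor = 7.58)))

#' Configuration of a synthetic connectome cohort
#'
#' Defaults emulate the study conditions the pipeline is built for: 90
#' AAL nodes, 48 patients (split into 24 + 24 cognitive subgroups) and 48
#' controls, a planted 13-node hub core wired more densely than the
#' periphery, FA-like edge weights, and demographics / neuropsychological
#' scores with realistic group-level means and dispersions.
#'
#' All subjects share a single binary topology and base-weight draw;
#' between-subject variation enters through edge-weight noise and the
#' planted group effects only. The binary hub architecture is therefore
#' stable across subjects and groups, and a cohort with no planted
#' effects is an exact null for every group comparison. Pair connection
#' probability is \code{base_density + hub_degree_boost * (number of hub
#' endpoints)}.
#'
#' @param n_nodes node count (default 90).
#' @param n_patients,n_controls group sizes (default 48 each; the first
#'   half of the patients forms the ANI subgroup, the second half the
#'   NONHAND subgroup).
#' @param hub_nodes planted hub indices (default: 13 regions covering the
#'   bilateral putamen, precuneus, calcarine cortex, caudate, superior
#'   and middle occipital gyri, cuneus and left thalamus).
#' @param base_density baseline pair connection probability.
#' @param hub_degree_boost added probability per hub endpoint.
#' @param fa_mean,fa_sd group-level edge FA distribution, truncated to
#'   [0.2, 0.8].
#' @param subject_noise_sd SD of per-subject weight noise.
#' @param effect_edges data.frame(i, j, delta, group): planted FA shifts
#'   on specific edges for one group (group in HIV, HC, ANI, NONHAND).
#' @param effect_nodes data.frame(node, delta, group): planted FA shifts
#'   on every edge incident to a node.
#' @param age_model,sex_model per-group age mean/SD and male probability.
#' @param tscore_model per-subgroup six-domain T-score means and SDs.
#' @param seed integer root seed.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_nodes = 90,
                          n_patients = 48, n_controls = 48,
                          hub_nodes = DEFAULT_HUB_NODES,
                          base_density = 0.15,
                          hub_degree_boost = 0.3,
                          fa_mean = 0.5, fa_sd = 0.1,
                          subject_noise_sd = 0.04,
                          effect_edges = NULL,
                          effect_nodes = NULL,
                          age_model = list(HIV = c(32.25, 5.67),
                                           HC = c(34.52, 6.52)),
                          sex_model = list(HIV = 46 / 48, HC = 44 / 48),
                          tscore_model = DEFAULT_TSCORE_MODEL,
                          seed = 1L) {
  stopifnot(n_nodes >= 2, n_patients >= 2, n_controls >= 2,
            base_density > 0, base_density < 1,
            hub_degree_boost >= 0,
            all(hub_nodes >= 1), all(hub_nodes <= n_nodes),
            !anyDuplicated(hub_nodes))
  if (n_patients %% 2 != 0)
    stop("n_patients must be even to split into ANI/NONHAND halves",
         call. = FALSE)
  check_effects <- function(eff, what) {
    if (is.null(eff)) return(invisible())
    if (any(abs(eff$delta) > 0.2))
      stop(what, ": |delta| > 0.2 can push FA outside [0, 1] after the ",
           "[0.2, 0.8] base range; refusing before sampling", call. = FALSE)
    if (!all(eff$group %in% c("HIV", "HC", "ANI", "NONHAND")))
      stop(what, ": unknown target group", call. = FALSE)
  }
  check_effects(effect_edges, "effect_edges")
  check_effects(effect_nodes, "effect_nodes")
  structure(list(n_nodes = n_nodes, n_patients = n_patients,
                 n_controls = n_controls, hub_nodes = as.integer(hub_nodes),
                 base_density = base_density,
                 hub_degree_boost = hub_degree_boost,
                 fa_mean = fa_mean, fa_sd = fa_sd,
                 subject_noise_sd = subject_noise_sd,
                 effect_edges = effect_edges, effect_nodes = effect_nodes,
                 age_model = age_model, sex_model = sex_model,
                 tscore_model = tscore_model, seed = as.integer(seed)),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# Sample one group topology: upper-tri presence pattern plus base weights.
sample_group_topology <- function(cfg) {
  n <- cfg$n_nodes
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_hub_ends <- (ut[, 1] %in% cfg$hub_nodes) + (ut[, 2] %in% cfg$hub_nodes)
  p <- pmin(0.99, cfg$base_density + cfg$hub_degree_boost * n_hub_ends)
  present <- stats::runif(nrow(ut)) < p
  if (!is.null(cfg$effect_edges)) {
    forced <- paste(pmin(cfg$effect_edges$i, cfg$effect_edges$j),
                    pmax(cfg$effect_edges$i, cfg$effect_edges$j))
    present[paste(ut[, 1], ut[, 2]) %in% forced] <- TRUE
  }
  base_w <- rep(0, nrow(ut))
  base_w[present] <- rtrunc_norm(sum(present), cfg$fa_mean, cfg$fa_sd,
                                 0.2, 0.8)
  list(ut = ut, present = present, base_w = base_w)
}

subject_matches_group <- function(group, subgroup, target) {
  group == target | (!is.na(subgroup) & subgroup == target)
}

#' Generate a synthetic cohort of FA-weighted connectomes
#'
#' Produces per-subject connectivity matrices (shared within-group binary
#' topology, subject-level weight noise, planted group effects),
#' demographics, clinical variables, six-domain T-scores, and a
#' ground-truth record of everything planted. Fully reproducible from the
#' config seed.
#'
#' @param config \code{\link{cohort_config}}.
#' @return list with \code{subjects} (data.frame), \code{matrices} (named
#'   list of \code{\link{connectivity_matrix}}), \code{truth} (planted
#'   hubs and effects plus the config).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_nodes
    # One topology and base-weight draw shared by every subject: hub
    # architecture is stable across groups (as in stable-hub cohorts),
    # and group differences come only from planted effects, so a cohort
    # without effects is an exact null for the group comparisons.
    base_topo <- sample_group_topology(config)
    topo <- list(HIV = base_topo, HC = base_topo)
    n_pat <- config$n_patients; n_con <- config$n_controls
    groups <- c(rep("HIV", n_pat), rep("HC", n_con))
    subgroups <- c(rep("ANI", n_pat / 2), rep("NONHAND", n_pat / 2),
                   rep(NA_character_, n_con))
    ids <- sprintf("sub%03d", seq_along(groups))

    subjects <- data.frame(subject_id = ids, group = groups,
                           subgroup = subgroups, stringsAsFactors = FALSE)
    subjects$age <- NA_real_; subjects$sex <- NA_character_
    # Sex counts are fixed (not Bernoulli draws) and spread over the
    # subgroup halves, matching skewed real-world cohorts while keeping
    # the sex covariate non-constant within every compared subgroup.
    assign_sex <- function(n, p_male) {
      n_f <- max(1L, round((1 - p_male) * n))
      sex <- rep("M", n)
      sex[sample.int(n, n_f)] <- "F"
      sex
    }
    for (g in c("HIV", "HC")) {
      sel <- which(subjects$group == g)
      am <- config$age_model[[g]]
      subjects$age[sel] <- round(rtrunc_norm(length(sel), am[1], am[2], 18, 55), 1)
      if (g == "HIV") {
        half <- length(sel) / 2
        subjects$sex[sel[seq_len(half)]] <-
          assign_sex(half, config$sex_model[[g]])
        subjects$sex[sel[half + seq_len(half)]] <-
          assign_sex(half, config$sex_model[[g]])
      } else {
        subjects$sex[sel] <- assign_sex(length(sel), config$sex_model[[g]])
      }
    }
    hiv <- subjects$group == "HIV"
    subjects$disease_course <- NA_real_
    subjects$disease_course[hiv] <- round(rtrunc_norm(sum(hiv), 40.98, 31.08,
                                                      3, 180), 1)
    subjects$cd4 <- NA_real_
    subjects$cd4[hiv] <- round(rtrunc_norm(sum(hiv), 586.48, 173.13, 100, 1500))
    subjects$cd4_cd8_ratio <- NA_real_
    subjects$cd4_cd8_ratio[hiv] <- round(rtrunc_norm(sum(hiv), 0.805, 0.50,
                                                     0.05, 3), 2)
    for (dom in TSCORE_DOMAINS) subjects[[paste0("tscore_", dom)]] <- NA_real_
    for (sg in names(config$tscore_model)) {
      sel <- which(!is.na(subjects$subgroup) & subjects$subgroup == sg)
      mdl <- config$tscore_model[[sg]]
      for (dom in TSCORE_DOMAINS)
        subjects[[paste0("tscore_", dom)]][sel] <-
          round(stats::rnorm(length(sel), mdl$mean[[dom]], mdl$sd[[dom]]), 1)
    }

    matrices <- vector("list", nrow(subjects))
    names(matrices) <- ids
    for (s in seq_len(nrow(subjects))) {
      tp <- topo[[subjects$group[s]]]
      wv <- tp$base_w
      np <- sum(tp$present)
      wv[tp$present] <- wv[tp$present] +
        stats::rnorm(np, 0, config$subject_noise_sd)
      if (!is.null(config$effect_edges)) {
        for (r in seq_len(nrow(config$effect_edges))) {
          ee <- config$effect_edges[r, ]
          if (subject_matches_group(subjects$group[s], subjects$subgroup[s],
                                    ee$group)) {
            sel <- tp$ut[, 1] == min(ee$i, ee$j) & tp$ut[, 2] == max(ee$i, ee$j)
            wv[sel] <- wv[sel] + ee$delta
          }
        }
      }
      if (!is.null(config$effect_nodes)) {
        for (r in seq_len(nrow(config$effect_nodes))) {
          en <- config$effect_nodes[r, ]
          if (subject_matches_group(subjects$group[s], subjects$subgroup[s],
                                    en$group)) {
            sel <- tp$present & (tp$ut[, 1] == en$node | tp$ut[, 2] == en$node)
            wv[sel] <- wv[sel] + en$delta
          }
        }
      }
      wv[tp$present] <- pmin(1, pmax(0.01, wv[tp$present]))
      w <- matrix(0, n, n)
      w[tp$ut] <- wv
      w[tp$ut[, c(2, 1)]] <- wv
      matrices[[s]] <- connectivity_matrix(w, subject_id = ids[s])
    }

    truth <- list(hub_nodes = config$hub_nodes,
                  effect_edges = config$effect_edges,
                  effect_nodes = config$effect_nodes,
                  group_mean_degree = lapply(topo, function(tp) {
                    a <- matrix(0, n, n)
                    a[tp$ut[tp$present, , drop = FALSE]] <- 1
                    rowSums(a + t(a))
                  }),
                  seed = config$seed)
    list(subjects = subjects, matrices = matrices, truth = truth,
         config = config)
  })
}

#' Subset a cohort's matrices and covariates by group
#'
#' \code{group} may be HIV, HC, ANI or NONHAND; the two subgroup labels
#' select the corresponding halves of the patient group, so a subject is
#' never double-counted within one comparison.
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param group group label.
#' @return list with \code{matrices}, \code{covariates} (age, sex) and
#'   \code{subjects}.
#' @export
cohort_group <- function(cohort, group) {
  s <- cohort$subjects
  sel <- subject_matches_group(s$group, s$subgroup, group)
  if (!any(sel)) stop("no subjects in group '", group, "'", call. = FALSE)
  list(matrices = cohort$matrices[sel],
       covariates = data.frame(age = s$age[sel], sex = s$sex[sel]),
       subjects = s[sel, , drop = FALSE])
}

#' Write a cohort to disk in the pipeline's file formats
#'
#' Emits \code{matrices/<subject_id>.tsv}, \code{subjects.tsv}, a copy of
#' the atlas and \code{ground_truth.json} under \code{dir}.
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @param atlas node atlas to copy alongside.
#' @export
write_cohort <- function(cohort, dir, atlas = aal90_atlas()) {
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$matrices))
    write_matrix(cohort$matrices[[id]], file.path(mat_dir, paste0(id, ".tsv")))
  write_subjects(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_tsv_stable(as.data.frame(atlas), file.path(dir, "atlas.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Generate synthetic streamline records
#'
#' For each requested region pair, draws streamlines whose per-streamline
#' mean FA is centred on the pair's true mean (between-streamline SD
#' \code{between_sd}, within-streamline step jitter \code{within_sd}, FA
#' clamped into [0.21, 0.95] so every usable record clears the 0.2
#' tracking floor) and whose turning angles stay below 45 degrees.
#' Optionally appends contaminant records that each violate one
#' inclusion rule (low FA, wide angle, unassigned endpoint, or
#' self-loop); the \code{contaminant} column carries the ground truth.
#'
#' @param pairs data.frame with columns i, j, mean_fa (in [0.2, 1)),
#'   n_streamlines.
#' @param contaminant_fraction contaminants to append, as a fraction of
#'   the clean record count.
#' @param between_sd,within_sd FA variation parameters.
#' @param seed integer seed.
#' @return streamline record data.frame with an added logical
#'   \code{contaminant} column, order randomized.
#' @export
generate_streamlines <- function(pairs, contaminant_fraction = 0,
                                 between_sd = 0.05, within_sd = 0.02,
                                 seed = 1L) {
  stopifnot(all(pairs$mean_fa >= 0.2), all(pairs$mean_fa < 1))
  with_local_seed(seed, {
    rows <- list()
    for (r in seq_len(nrow(pairs))) {
      ns <- pairs$n_streamlines[r]
      if (ns < 1) next
      for (s in seq_len(ns)) {
        len <- sample(10:30, 1)
        target <- pairs$mean_fa[r] + stats::rnorm(1, 0, between_sd)
        fa <- pmin(0.95, pmax(0.21, target + stats::rnorm(len, 0, within_sd)))
        rows[[length(rows) + 1]] <- list(a = pairs$i[r], b = pairs$j[r],
                                         fa = fa,
                                         angle = stats::runif(1, 5, 44.9),
                                         contaminant = FALSE)
      }
    }
    n_clean <- length(rows)
    n_contam <- round(contaminant_fraction * n_clean)
    kinds <- rep(c("low_fa", "wide_angle", "unassigned", "self_loop"),
                 length.out = max(n_contam, 0))
    for (ci in seq_len(n_contam)) {
      src <- pairs[1 + (ci - 1) %% nrow(pairs), ]
      fa <- pmin(0.95, pmax(0.21, src$mean_fa + stats::rnorm(15, 0, within_sd)))
      a <- src$i; b <- src$j; angle <- stats::runif(1, 5, 44.9)
      switch(kinds[ci],
             low_fa = { fa[sample(length(fa), 1)] <- stats::runif(1, 0.05, 0.19) },
             wide_angle = { angle <- stats::runif(1, 45, 90) },
             unassigned = { b <- NA_integer_ },
             self_loop = { b <- a })
      rows[[length(rows) + 1]] <- list(a = a, b = b, fa = fa,
                                       angle = angle, contaminant = TRUE)
    }
    ord <- sample(length(rows))
    rows <- rows[ord]
    rec <- streamline_records(
      region_a = vapply(rows, function(x) as.integer(x$a), integer(1)),
      region_b = vapply(rows, function(x) as.integer(x$b), integer(1)),
      fa_values = lapply(rows, `[[`, "fa"),
      max_turn_angle = vapply(rows, `[[`, numeric(1), "angle"))
    rec$contaminant <- vapply(rows, `[[`, logical(1), "contaminant")
    rec
  })
}
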