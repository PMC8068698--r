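#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: input tables (or a
#' synthetic [cohort_config()]), preprocessing thresholds, factor-analysis
#' settings, clustering and comparison settings, and seeds. All
#' randomness in [run_pipeline()] flows from `seed` through
#' [stage_seed()].
#'
#' @param cohort a [cohort_config()] to simulate from, or `NULL` to read
#'   `wave1_path`/`wave2_path`.
#' @param wave1_path,wave2_path CSV wave tables (see [read_wave_table()]);
#'   ignored when `cohort` is given.
#' @param item_meta_w1,item_meta_w2 item metadata for the two waves (only
#'   needed when reading from files).
#' @param max_missing missing-item screening cut-off (subjects with more
#'   missing items are excluded).
#' @param z_thresh univariate outlier cut-off in SDs.
#' @param alpha_outlier Mahalanobis tail probability.
#' @param discretise_levels number of ordinal levels the wave-1 analogue
#'   scores are discretised to.
#' @param n_factors number of factors, or `"auto"` to run
#'   [parallel_analysis()].
#' @param n_sim parallel-analysis simulations (when `n_factors = "auto"`).
#' @param k_w1,k_w2 cluster numbers at which the wave trees are cut.
#' @param k_range cluster numbers profiled with [ch_profile()].
#' @param n_restarts TSVQ 2-means restarts.
#' @param n_perm Fowlkes-Mallows permutations.
#' @param fm_k cut levels `c(k_a, k_b)` for the cross-wave comparison;
#'   defaults to `c(min(k_w1, k_w2), min(k_w1, k_w2))`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            wave1_path = NULL, wave2_path = NULL,
                            item_meta_w1 = NULL, item_meta_w2 = NULL,
                            max_missing = 5, z_thresh = 3,
                            alpha_outlier = 0.001,
                            discretise_levels = 4,
                            n_factors = 6, n_sim = 100,
                            k_w1 = 7, k_w2 = 6,
                            k_range = 2:10, n_restarts = 10,
                            n_perm = 1000, fm_k = NULL,
                            seed = 1L) {
  cfg <- list(cohort = cohort, wave1_path = wave1_path,
              wave2_path = wave2_path, item_meta_w1 = item_meta_w1,
              item_meta_w2 = item_meta_w2, max_missing = max_missing,
              z_thresh = z_thresh, alpha_outlier = alpha_outlier,
              discretise_levels = discretise_levels,
              n_factors = n_factors, n_sim = n_sim,
              k_w1 = k_w1, k_w2 = k_w2, k_range = k_range,
              n_restarts = n_restarts, n_perm = n_perm,
              fm_k = fm_k %||% rep(min(k_w1, k_w2), 2),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(...)))
}

# preprocess one wave: screening -> EM imputation -> item-level outlier
# screen -> (analogue only) KDE discretisation
preprocess_wave <- function(rm, cfg, wave_name) {
  scr <- screen_missing(rm, max_missing = cfg$max_missing)
  pipeline_log(wave_name, "missing screen: kept %d of %d subjects",
               length(scr$report$kept_ids), length(rm$subject_ids))
  em <- em_impute(scr$matrix)
  pipeline_log(wave_name, "EM imputation: %d iterations, converged = %s",
               em$n_iter, em$converged)
  x <- em$matrix$scores
  out <- remove_outliers(x, z_thresh = cfg$z_thresh,
                         alpha = cfg$alpha_outlier)
  kept <- subset_subjects(em$matrix, which(out$keep))
  pipeline_log(wave_name, "item-level outlier screen: removed %d",
               sum(!out$keep))
  is_analogue <- kept$item_meta$type == "analogue"
  cuts <- NULL
  if (any(is_analogue)) {
    sc <- kept$scores
    cuts <- vector("list", ncol(sc))
    for (j in which(is_analogue)) {
      kd <- kde_discretise(sc[, j], cfg$discretise_levels,
                           range = c(kept$item_meta$lower[j],
                                     kept$item_meta$upper[j]))
      sc[, j] <- kd$levels
      cuts[[j]] <- kd$cutpoints
    }
    kept <- rating_matrix(sc, ordinal_items(ncol(sc),
                                            cfg$discretise_levels),
                          kept$subject_ids)
    pipeline_log(wave_name, "discretised %d analogue items to %d levels",
                 sum(is_analogue), cfg$discretise_levels)
  }
  report <- screening_report(
    kept_ids = kept$subject_ids,
    excluded_missing_ids = scr$report$excluded_missing_ids,
    excluded_univariate_ids = out$report$excluded_univariate_ids,
    excluded_multivariate_ids = out$report$excluded_multivariate_ids,
    thresholds = list(max_missing = cfg$max_missing,
                      z_thresh = cfg$z_thresh,
                      alpha = cfg$alpha_outlier,
                      mahalanobis_cutoff =
                        out$report$thresholds$mahalanobis_cutoff))
  list(matrix = kept, report = report, cutpoints = cuts)
}

# factor stage on one preprocessed wave: polychoric EFA, scores, score-
# level outlier screen
factor_wave <- function(rm, cfg, wave_name) {
  R <- polychoric_matrix(rm)
  nf <- cfg$n_factors
  if (identical(nf, "auto")) {
    pa <- parallel_analysis(rm, n_sim = cfg$n_sim,
                            seed = stage_seed(cfg$seed, 11))
    nf <- max(pa$n_factors, 1L)
    pipeline_log(wave_name, "parallel analysis suggests %d factors", nf)
  }
  model <- efa(R, nf, n_obs = nrow(rm$scores))
  pipeline_log(wave_name, "EFA: %d factors explain %.1f%% of variance",
               nf, 100 * model$total_variance)
  fs <- factor_scores(rm, R, model)
  out <- remove_outliers(fs$scores, z_thresh = cfg$z_thresh,
                         alpha = cfg$alpha_outlier)
  pipeline_log(wave_name, "score-level outlier screen: removed %d",
               sum(!out$keep))
  scores <- fs$scores[out$keep, , drop = FALSE]
  scores <- scale(scores)                    # re-standardize after removal
  list(corr = R, model = model,
       scores = matrix(as.numeric(scores), nrow(scores), ncol(scores),
                       dimnames = dimnames(fs$scores[out$keep, ,
                                                     drop = FALSE])),
       score_report = out$report)
}

#' Run the end-to-end profile-mapping pipeline
#'
#' Executes simulate (optional) -> preprocess -> polychoric EFA ->
#' factor scores -> hybrid clustering per wave -> cross-wave
#' Fowlkes-Mallows comparison -> transition table with equal-split tests
#' -> group x domain ANOVA, and writes a report bundle (CONSORT-style
#' exclusion counts, loading tables, CH/silhouette profiles, cluster
#' profiles with effect-size stars, FM result, transition table) to
#' `out_dir`. Deterministic given `config$seed`: a rerun with the same
#' seeds produces byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return (invisibly) a list with all intermediate results: `waves`
#'   (preprocessed matrices and reports), `factors`, `trees`,
#'   `partitions`, `profiles`, `ch`, `silhouette`, `fm`, `transitions`,
#'   `anova`, and `truth` when simulated.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$cohort)) {
    pipeline_log("simulate", "generating cohort (n = %d, seed = %d)",
                 config$cohort$n_subjects, config$cohort$seed)
    sim <- generate_cohort(config$cohort)
    w1 <- sim$wave1; w2 <- sim$wave2; truth <- sim$truth
  } else {
    w1 <- read_wave_table(config$wave1_path, config$item_meta_w1)
    w2 <- read_wave_table(config$wave2_path, config$item_meta_w2)
  }
  p1 <- preprocess_wave(w1, config, "wave1")
  p2 <- preprocess_wave(w2, config, "wave2")
  f1 <- factor_wave(p1$matrix, config, "wave1")
  f2 <- factor_wave(p2$matrix, config, "wave2")

  t1 <- hybrid_tree(f1$scores, seed = stage_seed(config$seed, 21),
                    n_restarts = config$n_restarts)
  t2 <- hybrid_tree(f2$scores, seed = stage_seed(config$seed, 22),
                    n_restarts = config$n_restarts)
  part1 <- cut_tree(t1, config$k_w1)
  part2 <- cut_tree(t2, config$k_w2)
  names(part1) <- rownames(f1$scores)
  names(part2) <- rownames(f2$scores)
  pipeline_log("cluster", "wave1 cut at k = %d, wave2 at k = %d",
               config$k_w1, config$k_w2)
  ch1 <- ch_profile(f1$scores, t1, config$k_range)
  ch2 <- ch_profile(f2$scores, t2, config$k_range)
  sil1 <- silhouette_scores(stats::dist(f1$scores), part1)
  sil2 <- silhouette_scores(stats::dist(f2$scores), part2)
  prof1 <- cluster_profiles(f1$scores, part1)
  prof2 <- cluster_profiles(f2$scores, part2)

  fm <- fm_permutation_test(t1, config$fm_k[1], t2, config$fm_k[2],
                            n_perm = config$n_perm,
                            seed = stage_seed(config$seed, 31))
  pipeline_log("compare", "FM index %.3f, p = %.4g", fm$b_index,
               fm$p_value)
  tt <- transition_table(part1, part2,
                         k_w1 = config$k_w1, k_w2 = config$k_w2)
  tt <- cellwise_ztests(tt)
  row_tests <- lapply(seq_len(nrow(tt$counts)), function(i)
    if (sum(tt$counts[i, ]) > 0) equal_split_chi2(tt$counts[i, ]) else NULL)
  an1 <- rm_anova(f1$scores, unclass(part1))
  an2 <- rm_anova(f2$scores, unclass(part2))

  result <- list(
    waves = list(w1 = p1, w2 = p2),
    factors = list(w1 = f1, w2 = f2),
    trees = list(w1 = t1, w2 = t2),
    partitions = list(w1 = part1, w2 = part2),
    profiles = list(w1 = prof1, w2 = prof2),
    ch = list(w1 = ch1, w2 = ch2),
    silhouette = list(w1 = sil1, w2 = sil2),
    fm = fm, transitions = tt, row_tests = row_tests,
    anova = list(w1 = an1, w2 = an2),
    truth = truth, config = config)

  if (!is.null(truth)) {
    # recovery diagnostics against the planted structure
    ari <- function(a, b) {
      m <- match_partitions(a, b)
      adjusted_rand(m$a, m$b)
    }
    result$recovery <- list(
      ari_w1 = ari(part1, truth$labels_w1),
      ari_w2 = ari(part2, truth$labels_w2))
    pipeline_log("report", "ARI vs planted labels: wave1 %.3f, wave2 %.3f",
                 result$recovery$ari_w1, result$recovery$ari_w2)
  }
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  invisible(result)
}

# adjusted Rand index (pair counting with chance correction)
adjusted_rand <- function(a, b) {
  M <- table(a, b)
  n <- sum(M)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.numeric(M))
  r <- sum_comb(rowSums(M)); c <- sum_comb(colSums(M))
  expected <- r * c / choose(n, 2)
  mx <- (r + c) / 2
  if (mx == expected) return(1)
  (idx - expected) / (mx - expected)
}

write_report_bundle <- function(result, out_dir) {
  f <- function(...) file.path(out_dir, ...)
  consort <- lapply(result$waves, function(w) {
    r <- w$report
    list(kept = length(r$kept_ids),
         excluded_missing = length(r$excluded_missing_ids),
         excluded_univariate = length(r$excluded_univariate_ids),
         excluded_multivariate = length(r$excluded_multivariate_ids),
         thresholds = r$thresholds)
  })
  jsonlite::write_json(consort, f("consort.json"), auto_unbox = TRUE,
                       digits = NA)
  write_loading_table(result$factors$w1$model, f("loadings_w1.csv"))
  write_loading_table(result$factors$w2$model, f("loadings_w2.csv"))
  utils::write.csv(result$ch$w1, f("ch_profile_w1.csv"), row.names = FALSE)
  utils::write.csv(result$ch$w2, f("ch_profile_w2.csv"), row.names = FALSE)
  utils::write.csv(result$profiles$w1, f("cluster_profiles_w1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$profiles$w2, f("cluster_profiles_w2.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(b_index = result$fm$b_index, p_value = result$fm$p_value,
         null_mean = result$fm$null_mean, null_var = result$fm$null_var,
         k_a = result$fm$k_a, k_b = result$fm$k_b,
         n_permutations = result$fm$n_permutations,
         n_shared = result$fm$n_shared, seed = result$fm$seed),
    f("fm_result.json"), auto_unbox = TRUE, digits = NA)
  write_transition_table(result$transitions, f("transitions.csv"),
                         f("transitions.json"))
  write_dendrogram(result$trees$w1, f("dendrogram_w1.json"),
                   f("dendrogram_w1.csv"))
  write_dendrogram(result$trees$w2, f("dendrogram_w2.json"),
                   f("dendrogram_w2.csv"))
  if (!is.null(result$recovery))
    jsonlite::write_json(result$recovery, f("recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
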