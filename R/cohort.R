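#' Configuration for the synthetic two-wave cohort generator
#'
#' Defines the generating model for a synthetic questionnaire cohort
#' followed over two developmental waves (childhood and adolescence).
#' Subjects belong to latent behavioural-profile clusters at each wave;
#' cluster membership at wave 2 is drawn from a planted row-stochastic
#' transition matrix. Latent factor scores are the cluster prototype plus
#' Normal noise; item scores follow an orthogonal common-factor model whose
#' implied correlation matrix has unit diagonal. Wave-1 items are rendered
#' as visual-analogue scores in millimetres, wave-2 items as 4-point
#' ordinal ratings discretised at fixed latent thresholds.
#'
#' The defaults emulate the study design the package targets: 40 items
#' loading on 6 orthogonal factors (conduct, hyperactivity/impulsivity,
#' inattention, emotional control, anxiety, motor problems), 7 childhood
#' profiles and 6 adolescence profiles dominated by a large "no problems"
#' group, and a transition matrix whose mass concentrates on remission with
#' specific enriched routes (e.g. childhood anxiety to adolescent emotional
#' problems, motor/hyperactivity to inattention).
#'
#' @param n_subjects number of subjects.
#' @param n_items number of questionnaire items.
#' @param n_factors number of orthogonal latent factors.
#' @param loading_strength loading of each item on its factor, in (0, 1].
#' @param cluster_prototypes_w1,cluster_prototypes_w2 clusters x factors
#'   matrices of prototype factor-score means, in SD units.
#' @param cluster_weights_w1 probability vector over wave-1 clusters.
#' @param transition_matrix row-stochastic clusters_w1 x clusters_w2 matrix.
#' @param noise_sd SD of subject-level factor-score noise around the
#'   prototype: a scalar applied to every cluster, or a list with
#'   components `w1` and `w2` giving one SD per cluster. The default
#'   reflects the floor effect of problem questionnaires: the large
#'   no-problems group is homogeneous (SD 0.25) while problem profiles
#'   are more heterogeneous (SD 0.5).
#' @param missing_rate per-cell MCAR missingness probability.
#' @param n_uni_outliers,n_multi_outliers numbers of planted univariate and
#'   multivariate outlier subjects (wave 1).
#' @param analogue_range wave-1 visual-analogue scale range (mm).
#' @param ordinal_levels_w2 number of wave-2 ordinal categories.
#' @param seed master seed; all stages derive their own seed from it via
#'   [stage_seed()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 3000,
                          n_items = 40,
                          n_factors = 6,
                          loading_strength = 0.7,
                          cluster_prototypes_w1 = default_prototypes_w1(n_factors),
                          cluster_prototypes_w2 = default_prototypes_w2(n_factors),
                          cluster_weights_w1 = default_cluster_weights_w1(),
                          transition_matrix = default_transition_matrix(),
                          noise_sd = list(
                            w1 = c(0.2, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                            w2 = c(0.5, 0.2, 0.5, 0.5, 0.5, 0.5)),
                          missing_rate = 0.02,
                          n_uni_outliers = 15,
                          n_multi_outliers = 10,
                          analogue_range = c(0, 100),
                          ordinal_levels_w2 = 4,
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_items = n_items,
              n_factors = n_factors, loading_strength = loading_strength,
              cluster_prototypes_w1 = as.matrix(cluster_prototypes_w1),
              cluster_prototypes_w2 = as.matrix(cluster_prototypes_w2),
              cluster_weights_w1 = cluster_weights_w1,
              transition_matrix = as.matrix(transition_matrix),
              noise_sd = noise_sd, missing_rate = missing_rate,
              n_uni_outliers = n_uni_outliers,
              n_multi_outliers = n_multi_outliers,
              analogue_range = analogue_range,
              ordinal_levels_w2 = as.integer(ordinal_levels_w2),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

# per-cluster noise SD vector for one wave
noise_vec <- function(cfg, wave = c("w1", "w2")) {
  wave <- match.arg(wave)
  k <- nrow(cfg[[paste0("cluster_prototypes_", wave)]])
  ns <- cfg$noise_sd
  if (is.list(ns)) rep_len(ns[[wave]], k) else rep(ns, k)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (any(unlist(noise_sd) < 0)) stop("noise_sd must be non-negative")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must lie in [0, 1)")
    if (loading_strength <= 0 || loading_strength > 1)
      stop("loading_strength must lie in (0, 1]")
    if (ncol(cluster_prototypes_w1) != n_factors ||
        ncol(cluster_prototypes_w2) != n_factors)
      stop("prototype matrices must have n_factors columns")
    if (abs(sum(cluster_weights_w1) - 1) > 1e-12)
      stop("cluster_weights_w1 must sum to 1")
    if (length(cluster_weights_w1) != nrow(cluster_prototypes_w1))
      stop("cluster_weights_w1 length must match wave-1 prototype count")
    if (nrow(transition_matrix) != nrow(cluster_prototypes_w1) ||
        ncol(transition_matrix) != nrow(cluster_prototypes_w2))
      stop("transition_matrix must be clusters_w1 x clusters_w2")
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-12))
      stop("every transition_matrix row must sum to 1")
    if (n_uni_outliers + n_multi_outliers > n_subjects)
      stop("planted outliers exceed the number of subjects")
  })
  invisible(cfg)
}

# factor order: conduct, hyperactivity, inattention, emotion, anxiety, motor
#' @rdname cohort_config
#' @export
default_prototypes_w1 <- function(n_factors = 6) {
  stopifnot(n_factors == 6)
  p <- rbind(
    C1a_noproblems = rep(-0.5, 6),
    C1b_anxiety    = c(0, 0, 0, 0, 1.8, 0),
    C2a_anx_hyper  = c(0, 1.8, 0, 0, 1.2, 0),
    C2b_mot_hyp_em = c(0, 1.5, 0, 1.5, 0, 1.5),
    C3_inattention = c(0, 0, 1.8, 0, 0, 0),
    C4a_emotion    = c(0, 0, 0, 1.8, 0, 0),
    C4b_conduct    = c(1.8, 0, 0, 0, 0, 0))
  colnames(p) <- c("conduct", "hyperactivity", "inattention",
                   "emotion", "anxiety", "motor")
  p
}

#' @rdname cohort_config
#' @export
default_prototypes_w2 <- function(n_factors = 6) {
  stopifnot(n_factors == 6)
  p <- rbind(
    A1a_inattention = c(0, 0, 1.8, 0, 0, 0),
    A1b_noproblems  = rep(-0.5, 6),
    A2_anx_motor    = c(0, 0, 0, 0, 1.5, 1.5),
    A3a_emotion     = c(0, 0, 0, 1.8, 0, 0),
    A3b_anx_em_inat = c(0, 0, 1.2, 1.2, 1.2, 0),
    A4_hyperactive  = c(0, 1.8, 0, 0, 0, 0))
  colnames(p) <- c("conduct", "hyperactivity", "inattention",
                   "emotion", "anxiety", "motor")
  p
}

#' @rdname cohort_config
#' @export
default_cluster_weights_w1 <- function() {
  c(C1a_noproblems = 0.50, C1b_anxiety = 0.10, C2a_anx_hyper = 0.06,
    C2b_mot_hyp_em = 0.06, C3_inattention = 0.10, C4a_emotion = 0.08,
    C4b_conduct = 0.10)
}

#' @rdname cohort_config
#' @export
default_transition_matrix <- function() {
  tm <- rbind(
    C1a_noproblems = c(0.04, 0.60, 0.08, 0.15, 0.10, 0.03),
    C1b_anxiety    = c(0.04, 0.45, 0.08, 0.30, 0.10, 0.03),
    C2a_anx_hyper  = c(0.05, 0.45, 0.10, 0.20, 0.15, 0.05),
    C2b_mot_hyp_em = c(0.35, 0.40, 0.08, 0.07, 0.05, 0.05),
    C3_inattention = c(0.10, 0.45, 0.05, 0.25, 0.10, 0.05),
    C4a_emotion    = c(0.08, 0.50, 0.07, 0.20, 0.10, 0.05),
    C4b_conduct    = c(0.08, 0.40, 0.07, 0.10, 0.30, 0.05))
  colnames(tm) <- c("A1a_inattention", "A1b_noproblems", "A2_anx_motor",
                    "A3a_emotion", "A3b_anx_em_inat", "A4_hyperactive")
  tm
}

# simple-structure loading matrix: items assigned round-robin to factors
planted_loadings <- function(n_items, n_factors, loading_strength) {
  L <- matrix(0, n_items, n_factors)
  fac <- rep(seq_len(n_factors), length.out = n_items)
  L[cbind(seq_len(n_items), fac)] <- loading_strength
  rownames(L) <- sprintf("item_%03d", seq_len(n_items))
  colnames(L) <- sprintf("F%d", seq_len(n_factors))
  L
}

# model-implied per-item SD given the cluster mixture on the latent factors
implied_item_sd <- function(L, psi, proto, weights, noise) {
  mu <- colSums(proto * weights)
  between <- colSums(weights * sweep(proto, 2, mu)^2)
  fac_var <- sum(weights * noise^2) + between
  sqrt(as.numeric(L^2 %*% fac_var) + psi)
}

#' Generate a synthetic two-wave cohort
#'
#' Draws a cohort from the generating model described in [cohort_config()]
#' and returns the two wave tables together with the planted ground truth
#' (loadings, cluster labels, latent scores, outlier ids) used by recovery
#' tests. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with elements `wave1` and `wave2` (each a
#'   [rating_matrix()]), and `truth`: a `ground_truth` list with fields
#'   `loadings`, `labels_w1`, `labels_w2`, `latent_scores_w1`,
#'   `latent_scores_w2`, `outlier_ids`, plus the planted prototypes and
#'   transition matrix.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  p <- config$n_items
  q <- config$n_factors
  L <- planted_loadings(p, q, config$loading_strength)
  psi <- 1 - rowSums(L^2)
  ids <- sprintf("S%04d", seq_len(n))

  # stage 1: cluster labels
  set.seed(stage_seed(config$seed, 1))
  labels_w1 <- sample.int(nrow(config$cluster_prototypes_w1), n,
                          replace = TRUE, prob = config$cluster_weights_w1)
  labels_w2 <- vapply(labels_w1, function(g) {
    sample.int(ncol(config$transition_matrix), 1,
               prob = config$transition_matrix[g, ])
  }, integer(1))

  # stage 2: latent factor scores (prototype + per-cluster noise)
  ns1 <- noise_vec(config, "w1")
  ns2 <- noise_vec(config, "w2")
  set.seed(stage_seed(config$seed, 2))
  s1 <- config$cluster_prototypes_w1[labels_w1, , drop = FALSE] +
    matrix(stats::rnorm(n * q), n, q) * ns1[labels_w1]
  s2 <- config$cluster_prototypes_w2[labels_w2, , drop = FALSE] +
    matrix(stats::rnorm(n * q), n, q) * ns2[labels_w2]
  dimnames(s1) <- dimnames(s2) <- list(ids, colnames(L))

  # stage 3: item scores = loadings . scores + unique noise
  set.seed(stage_seed(config$seed, 3))
  y1 <- s1 %*% t(L) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(psi), p)
  y2 <- s2 %*% t(L) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(psi), p)

  # wave 1: affine map of the latent item score onto the analogue scale,
  # placing +-3.5 model-implied SDs across the range, then truncation
  sd1 <- implied_item_sd(L, psi, config$cluster_prototypes_w1,
                         config$cluster_weights_w1, ns1)
  lo <- config$analogue_range[1]; hi <- config$analogue_range[2]
  mid <- (lo + hi) / 2
  slope <- (hi - lo) / 7
  x1 <- sweep(y1, 2, sd1, "/") * slope + mid
  x1 <- pmin(pmax(x1, lo), hi)

  # wave 2: discretise at fixed equiprobable-Normal latent thresholds
  w2_weights <- as.numeric(config$cluster_weights_w1 %*%
                             config$transition_matrix)
  sd2 <- implied_item_sd(L, psi, config$cluster_prototypes_w2,
                         w2_weights, ns2)
  Lv <- config$ordinal_levels_w2
  qs <- stats::qnorm(seq_len(Lv - 1) / Lv)
  x2 <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    x2[, j] <- findInterval(y2[, j], sd2[j] * qs) + 1L
  }

  wave1 <- rating_matrix(x1, analogue_items(p, config$analogue_range), ids)
  wave2 <- rating_matrix(x2, ordinal_items(p, Lv), ids)

  # stage 4: planted outliers (wave 1), then stage 5/6: MCAR missingness
  outlier_ids <- character(0)
  if (config$n_uni_outliers + config$n_multi_outliers > 0) {
    pl <- plant_outliers(wave1, config$n_uni_outliers,
                         config$n_multi_outliers,
                         seed = stage_seed(config$seed, 4))
    wave1 <- pl$matrix
    outlier_ids <- pl$outlier_ids
  }
  if (config$missing_rate > 0) {
    wave1 <- plant_missingness(wave1, config$missing_rate,
                               seed = stage_seed(config$seed, 5))
    wave2 <- plant_missingness(wave2, config$missing_rate,
                               seed = stage_seed(config$seed, 6))
  }

  truth <- structure(list(
    loadings = L, uniquenesses = psi,
    labels_w1 = stats::setNames(labels_w1, ids),
    labels_w2 = stats::setNames(labels_w2, ids),
    latent_scores_w1 = s1, latent_scores_w2 = s2,
    outlier_ids = outlier_ids,
    prototypes_w1 = config$cluster_prototypes_w1,
    prototypes_w2 = config$cluster_prototypes_w2,
    transition_matrix = config$transition_matrix), class = "ground_truth")
  list(wave1 = wave1, wave2 = wave2, truth = truth)
}

#' Plant MCAR missingness into a rating matrix
#'
#' Each cell is masked independently with probability `rate` (missing
#' completely at random). Deterministic given `seed`.
#'
#' @param matrix a [rating_matrix()].
#' @param rate per-cell missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return a `rating_matrix` with additional `NA` cells.
#' @export
plant_missingness <- function(matrix, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  set.seed(seed)
  sc <- matrix$scores
  mask <- stats::runif(length(sc)) < rate
  sc[mask] <- NA
  rating_matrix(sc, matrix$item_meta, matrix$subject_ids)
}

#' Plant univariate and multivariate outliers
#'
#' `n_uni` randomly chosen subjects get one randomly chosen item set to the
#' column mean + 5 column SDs (clamped to the declared scale range for
#' analogue items, which still leaves the cell beyond 3 SD on a 0--100 mm
#' scale). `n_multi` subjects get a correlated-pattern shift along the
#' smallest-variance principal direction of the sample, scaled so that each
#' coordinate stays within `z_cap` SDs of its mean while the squared
#' Mahalanobis distance exceeds the screening cut-off
#' [mahalanobis_cutoff()]`(p, alpha)`.
#'
#' @param matrix a [rating_matrix()] (or plain numeric matrix).
#' @param n_uni,n_multi outlier counts; their sum must not exceed the
#'   number of subjects.
#' @param seed integer seed.
#' @param z_cap per-coordinate cap (in SDs) for multivariate outliers.
#' @param alpha tail probability defining the Mahalanobis cut-off.
#' @return list with `matrix` (modified), `outlier_ids`, `uni_ids`,
#'   `multi_ids`.
#' @export
plant_outliers <- function(matrix, n_uni, n_multi, seed,
                           z_cap = 2.5, alpha = 0.001) {
  is_rm <- inherits(matrix, "rating_matrix")
  sc <- if (is_rm) matrix$scores else as.matrix(matrix)
  n <- nrow(sc); p <- ncol(sc)
  if (n_uni + n_multi > n) stop("outlier counts exceed number of subjects")
  if (n_uni + n_multi == 0) {
    return(list(matrix = matrix, outlier_ids = character(0),
                uni_ids = character(0), multi_ids = character(0)))
  }
  set.seed(seed)
  ids <- rownames(sc) %||% as.character(seq_len(n))
  chosen <- sample.int(n, n_uni + n_multi)
  uni <- chosen[seq_len(n_uni)]
  multi <- chosen[n_uni + seq_len(n_multi)]

  mu <- colMeans(sc, na.rm = TRUE)
  sds <- apply(sc, 2, stats::sd, na.rm = TRUE)
  for (i in uni) {
    j <- sample.int(p, 1)
    sc[i, j] <- mu[j] + 5 * sds[j]
  }
  if (n_multi > 0) {
    S <- stats::cov(sc, use = "pairwise.complete.obs")
    ev <- eigen(S, symmetric = TRUE)
    # a correlated-pattern shift: every coordinate at z_cap SDs, signs from
    # the smallest-variance principal direction, so the squared Mahalanobis
    # distance is large while no single coordinate is extreme
    v <- ev$vectors[, p]
    s <- sign(v); s[s == 0] <- 1
    xnew <- mu + z_cap * s * sds
    d2 <- tryCatch(stats::mahalanobis(rbind(xnew), mu, S),
                   error = function(e) NULL)
    if (!is.null(d2)) {                      # verifiable only when cov is
      cutoff <- mahalanobis_cutoff(p, alpha) # non-singular (n > p + 1)
      if (d2 <= cutoff)
        stop("cannot plant a multivariate outlier within the per-coordinate cap")
    }
    for (i in multi) {
      sgn <- if (stats::runif(1) < 0.5) -1 else 1
      sc[i, ] <- mu + sgn * z_cap * s * sds
    }
  }
  if (is_rm) {
    # clamp analogue items to their declared range (keeps validation happy)
    for (j in seq_len(p)) {
      m <- matrix$item_meta[j, ]
      if (m$type == "analogue")
        sc[, j] <- pmin(pmax(sc[, j], m$lower), m$upper)
      else
        sc[, j] <- pmin(pmax(round(sc[, j]), 1), m$levels)
    }
    out <- rating_matrix(sc, matrix$item_meta, matrix$subject_ids)
  } else out <- sc
  list(matrix = out, outlier_ids = ids[sort(chosen)],
       uni_ids = ids[uni], multi_ids = ids[multi])
}

#' Serialise planted ground truth as JSON
#'
#' @param truth a `ground_truth` object from [generate_cohort()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(lapply(unclass(truth), function(x) {
    if (is.matrix(x)) list(values = unname(x), rownames = rownames(x),
                           colnames = colnames(x)) else x
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
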