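# fixtures built in code, shared across test files

# ordinal data from a known orthogonal factor model: latent scores iid
# N(0,1), items = L s + unique noise, discretised at given thresholds
make_ordinal_factor_data <- function(n, loadings, thresholds = c(-0.5, 0.5),
                                     seed = 1) {
  set.seed(seed)
  p <- nrow(loadings); q <- ncol(loadings)
  psi <- 1 - rowSums(loadings^2)
  s <- matrix(rnorm(n * q), n, q)
  y <- s %*% t(loadings) + matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi), p)
  x <- apply(y, 2, function(col) findInterval(col, thresholds) + 1L)
  list(x = x, scores = s, loadings = loadings, psi = psi)
}

# simple-structure loading matrix: `per` items per factor, loading `a`
simple_loadings <- function(n_factors, per = 6, a = 0.7) {
  L <- matrix(0, n_factors * per, n_factors)
  for (f in seq_len(n_factors)) L[(f - 1) * per + seq_len(per), f] <- a
  L
}

# well-separated Gaussian blobs
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(g)
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[g, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# adjusted Rand index used as recovery oracle (via mclust when available)
ari_oracle <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else phasemap:::adjusted_rand(a, b)
}

# brute-force mutual clusters: check every subset against the definition
brute_mutual_clusters <- function(D) {
  n <- nrow(D)
  out <- list()
  for (m in seq_len(2^n - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(S) < 2 || length(S) >= n) next
    if (max(D[S, S]) < min(D[S, -S, drop = FALSE]))
      out[[length(out) + 1L]] <- S
  }
  out
}

set_key <- function(sets) sort(vapply(sets, paste, "", collapse = ","))

# brute-force silhouette from the definition
brute_silhouette <- function(D, labels) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# brute-force Fowlkes-Mallows by pair enumeration
brute_fm <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  Tt <- sum(same_a & same_b)
  if (Tt == 0) return(0)
  Tt / sqrt(sum(same_a) * sum(same_b))
}
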