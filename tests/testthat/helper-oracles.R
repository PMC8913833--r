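# Independent brute-force oracles and graph generators used across the suite.
# These deliberately avoid the package's BFS-based code path: distances come
# from Floyd-Warshall, efficiencies from direct enumeration over pairs.

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

geff_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- fw_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

eloc_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    geff_oracle(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# Spearman via the classic rank-difference formula (valid without ties)
spearman_rank_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

random_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (step in seq_len(k %/% 2)) {
      j <- ((i - 1 + step) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# single-group cohort from an explicit per-time-point template matrix
single_group_config <- function(target, n_time_points = 2, seed = 1,
                                n_subjects = 11, group = "g") {
  tmpl <- stats::setNames(rep(list(target), n_time_points),
                          as.character(seq_len(n_time_points)))
  templates <- list(tmpl)
  names(templates) <- group
  cohort_config(n_subjects_per_group = n_subjects,
                n_time_points = n_time_points,
                templates = templates, seed = seed)
}

identity_template <- function(panel = default_panel()) {
  m <- diag(length(panel))
  dimnames(m) <- list(panel, panel)
  m
}
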