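# Independent oracles and tiny fixtures used across the test files.
# Everything here is deliberately brute-force and shares no code with the
# implementations it checks.

# all-pairs shortest paths by Floyd-Warshall on a logical adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# random connected undirected graph on n nodes: random spanning tree plus
# random extra edges
random_connected_adj <- function(n, p_extra = 0.3) {
  adj <- matrix(FALSE, n, n)
  for (v in seq_len(n)[-1]) {
    u <- sample(v - 1, 1)
    adj[u, v] <- adj[v, u] <- TRUE
  }
  extra <- which(upper.tri(adj) & !adj)
  on <- extra[runif(length(extra)) < p_extra]
  adj[on] <- TRUE
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# Spearman rho from first principles: explicit average ranks, explicit
# Pearson formula
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-tailed permutation p for Spearman via full enumeration
oracle_spearman_p <- function(x, y) {
  obs <- oracle_spearman_rho(x, y)
  perms <- perms_of(length(y))
  rhos <- apply(perms, 1, function(p) oracle_spearman_rho(x, y[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))))
}

# exact two-tailed p for the rank-sum W over all group-1 assignments
oracle_wilcoxon_p <- function(g1, g2) {
  pool <- c(g1, g2)
  r <- rank(pool)
  n1 <- length(g1); N <- length(pool)
  mu <- n1 * (N + 1) / 2
  Wobs <- sum(r[seq_len(n1)])
  Ws <- apply(combn(N, n1), 2, function(ix) sum(r[ix]))
  mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-12)
}

# Kruskal-Wallis H by the textbook rank-sum formula with tie correction
oracle_kw_h <- function(groups) {
  pool <- unlist(groups)
  r <- rank(pool)
  N <- length(pool)
  ri <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(ri, function(x) sum(x)^2 / length(x), 0)) - 3 * (N + 1)
  ties <- table(pool)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# raw JT count by direct double loop over ordered group pairs
oracle_jt_count <- function(groups) {
  total <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (u in groups[[i]]) for (v in groups[[j]])
      total <- total + (u < v) + 0.5 * (u == v)
  total
}

# exact two-tailed permutation p for JT (enumerate pooled assignments)
oracle_jt_p <- function(groups) {
  obs <- oracle_jt_count(groups)
  pool <- unlist(groups)
  sizes <- lengths(groups)
  ni <- sum(sizes)
  mu_parts <- (sum(sizes)^2 - sum(sizes^2)) / 4
  perms <- perms_of(ni)
  jts <- apply(perms, 1, function(p) {
    g <- split(pool[p], rep(seq_along(sizes), sizes))
    oracle_jt_count(g)
  })
  mean(abs(jts - mu_parts) >= abs(obs - mu_parts) - 1e-12)
}

# closed-form posterior for two 1-D Gaussians with shared variance and
# uniform priors
oracle_gaussian_posterior <- function(x, m0, m1, s2) {
  d1 <- exp(-(x - m1)^2 / (2 * s2))
  d0 <- exp(-(x - m0)^2 / (2 * s2))
  d1 / (d0 + d1)
}

# hand-built 6-area path parcellation with types
toy_path_parcellation <- function(types = c(5, 4, 3, 3, 2, 1)) {
  n <- length(types)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  nm <- LETTERS[seq_len(n)]
  dimnames(adj) <- list(nm, nm)
  parcellation(data.frame(name = nm, structural_type = types), adj)
}

# small projection table over the toy path parcellation
toy_table <- function(parc, records) {
  projection_table(records, parc$areas$name)
}
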