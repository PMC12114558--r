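# Independent brute-force oracles used to validate the implementation paths.
# Each is written from the definition, without calling the package function
# it checks.

# Spearman rho and t-approximation p for two vectors, from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(r = r, p = if (abs(r) >= 1 - 1e-15) 0 else p)
}

# All-pairs co-occurrence edge list by direct enumeration.
oracle_edges <- function(mat, r_threshold = 0.6, p_threshold = 0.01) {
  ids <- rownames(mat)
  out <- NULL
  for (i in seq_len(nrow(mat) - 1)) for (j in (i + 1):nrow(mat)) {
    s <- oracle_spearman(mat[i, ], mat[j, ])
    if (abs(s$r) > r_threshold && s$p < p_threshold) {
      out <- rbind(out, data.frame(source = ids[i], target = ids[j],
                                   r = s$r, stringsAsFactors = FALSE))
    }
  }
  out
}

# Exact betweenness centrality by exhaustive shortest-path enumeration
# (BFS distances, then recursive enumeration of every geodesic).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0))
        if (d[w] == Inf) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    d
  }
  paths_between <- function(s, t, d) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[, t] > 0)) {
      if (d[v] == d[t] - 1) {
        for (p in paths_between(s, v, d)) out <- c(out, list(c(p, t)))
      }
    }
    out
  }
  btw <- rep(0, n)
  for (s in 1:(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(d[t])) next
      ps <- paths_between(s, t, d)
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(ps)
      }
    }
  }
  setNames(btw, rownames(adj))
}

# Recursive permutation enumerator (independent of the package's).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  prev <- oracle_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(setdiff(seq_len(n), k)[prev], nrow(prev)))
    out <- rbind(out, block)
  }
  out
}

# Exhaustive Mantel p-value: share of all n! permutations (identity
# included) whose statistic is >= the observed one.
oracle_mantel_exhaustive <- function(m1, m2, method = "spearman") {
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut], method = method)
  perms <- oracle_perms(n)
  rs <- apply(perms, 1, function(ord) {
    mp <- m2[ord, ord]
    cor(v1, mp[ut], method = method)
  })
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Marginal RDA explained percentage via explicit projection:
# trace(H Yc Yc' H) / trace(Yc Yc') with H the hat matrix of [1, x].
oracle_rda_marginal <- function(Y, x) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- cbind(1, x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  Yhat <- H %*% Yc
  100 * sum(Yhat^2) / sum(Yc^2)
}

# Modularity of a partition from the definition
# Q = sum_c (e_cc / m - (d_c / 2m)^2).
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    inside <- sum(membership[edges[, 1]] == cc & membership[edges[, 2]] == cc)
    deg <- sum(membership[edges[, 1]] == cc) + sum(membership[edges[, 2]] == cc)
    q <- q + inside / m - (deg / (2 * m))^2
  }
  q
}
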