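# Fixtures and independent brute-force oracles used across the suite.

# Random symmetric positive-weight connectivity matrix.
rand_sym_matrix <- function(n, label = "") {
  w <- matrix(exp(rnorm(n * n, sd = 0.6)), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  connectivity_matrix(w, label = label)
}

# Random group of `size` positive-weight undirected networks on n nodes.
rand_group <- function(size, n, name = "g") {
  network_group(lapply(seq_len(size), function(k) {
    rand_sym_matrix(n, label = sprintf("%s_%d", name, k))
  }), name = name)
}

# Apply the same node permutation to every member of a group.
permute_group <- function(g, perm) {
  network_group(lapply(g$members, function(m) {
    connectivity_matrix(m$weights[perm, perm], directed = m$directed,
                        label = m$label)
  }), name = g$name)
}

# Multiply every weight of every member by a constant.
scale_group <- function(g, c) {
  network_group(lapply(g$members, function(m) {
    connectivity_matrix(m$weights * c, directed = m$directed,
                        label = m$label)
  }), name = g$name)
}

# ---- brute-force shortest-path machinery (independent of igraph) ----------

# All simple paths between s and t in an undirected graph given by a
# distance matrix with NA for absent edges.
all_simple_paths_bf <- function(dist, s, t) {
  n <- nrow(dist)
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!is.na(dist[cur, nxt]) && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(s)
  out
}

path_length_bf <- function(dist, path) {
  sum(vapply(seq_len(length(path) - 1L),
             function(i) dist[path[i], path[i + 1L]], numeric(1L)))
}

# Edge betweenness by literal enumeration: for each unordered node pair,
# find all shortest simple paths and attribute 1/(number of shortest paths)
# to each edge on each of them. Returns a matrix of per-edge counts.
edge_betweenness_bf <- function(w_mat, exponent = 1, tol = 1e-9) {
  dist <- 1 / (w_mat^exponent)
  dist[w_mat == 0] <- NA
  diag(dist) <- NA
  n <- nrow(w_mat)
  eb <- matrix(0, n, n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_simple_paths_bf(dist, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_length_bf, numeric(1L), dist = dist)
      short <- paths[lens <= min(lens) + tol]
      for (p in short) {
        for (i in seq_len(length(p) - 1L)) {
          a <- p[i]; b <- p[i + 1L]
          eb[a, b] <- eb[a, b] + 1 / length(short)
          eb[b, a] <- eb[b, a] + 1 / length(short)
        }
      }
    }
  }
  eb
}

# Node betweenness by the same enumeration (interior vertices only).
node_betweenness_bf <- function(w_mat, tol = 1e-9) {
  dist <- 1 / w_mat
  dist[w_mat == 0] <- NA
  diag(dist) <- NA
  n <- nrow(w_mat)
  nb <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_simple_paths_bf(dist, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_length_bf, numeric(1L), dist = dist)
      short <- paths[lens <= min(lens) + tol]
      for (p in short) {
        interior <- p[-c(1L, length(p))]
        nb[interior] <- nb[interior] + 1 / length(short)
      }
    }
  }
  nb
}

# All-pairs shortest distances by Floyd-Warshall (independent of igraph).
floyd_warshall_bf <- function(w_mat) {
  d <- 1 / w_mat
  d[w_mat == 0] <- Inf
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Closeness vitality by literal remove-and-recompute.
vitality_bf <- function(w_mat) {
  wiener <- function(m) {
    d <- floyd_warshall_bf(m)
    if (any(is.infinite(d))) return(NA_real_)
    sum(d) / 2
  }
  total <- wiener(w_mat)
  vapply(seq_len(nrow(w_mat)), function(v) {
    rest <- wiener(w_mat[-v, -v, drop = FALSE])
    if (is.na(total) || is.na(rest)) NA_real_ else total - rest
  }, numeric(1L))
}

# Exhaustive half-subset box oracle: enumerate all choose(n1, h1) x
# choose(n2, h2) subset pairs, recompute per-rank medians/sds and the log2
# deltas, and take 16th/84th percentiles (linear interpolation).
exhaustive_boxes_bf <- function(g1, g2) {
  rank_mat <- function(g) t(vapply(g$members, extract_ranked_weights,
                                   numeric(length(extract_ranked_weights(g$members[[1]])))))
  r1 <- rank_mat(g1); r2 <- rank_mat(g2)
  h1 <- nrow(r1) %/% 2L; h2 <- nrow(r2) %/% 2L
  s1 <- combn(nrow(r1), h1, simplify = FALSE)
  s2 <- combn(nrow(r2), h2, simplify = FALSE)
  stat <- function(R) list(m = apply(R, 2, median), s = apply(R, 2, sd))
  dm <- NULL; ds <- NULL
  for (a in s1) {
    for (b in s2) {
      t1 <- stat(r1[a, , drop = FALSE]); t2 <- stat(r2[b, , drop = FALSE])
      dmv <- ifelse(t1$m > 0 & t2$m > 0, log2(t2$m / t1$m), NA_real_)
      dsv <- ifelse(t1$s > 0 & t2$s > 0, log2(t2$s / t1$s), NA_real_)
      dm <- rbind(dm, dmv); ds <- rbind(ds, dsv)
    }
  }
  pct <- function(m, p) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_real_ else unname(quantile(col, p))
  })
  data.frame(delta_m_low = pct(dm, 0.16), delta_m_high = pct(dm, 0.84),
             delta_std_low = pct(ds, 0.16), delta_std_high = pct(ds, 0.84))
}

# Spearman rho closed form for tie-free data: 1 - 6 sum(d^2) / (m (m^2 - 1)).
spearman_bf <- function(a, b) {
  d <- rank(a) - rank(b)
  m <- length(a)
  1 - 6 * sum(d^2) / (m * (m^2 - 1))
}
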