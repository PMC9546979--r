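# Topological metric rankings and the transform over them.

path3 <- function() {
  # A - B - C with equal unit weights; no A-C link
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  m[2, 3] <- m[3, 2] <- 1
  connectivity_matrix(m)
}

star4 <- function() {
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- 1
  connectivity_matrix(m + t(m))
}

triangle <- function() {
  m <- matrix(1, 3, 3); diag(m) <- 0
  connectivity_matrix(m)
}

test_that("edge betweenness matches hand enumeration on a 3-node path", {
  eb <- edge_betweenness_ranking(path3(), exponent = 1)
  expect_equal(as.numeric(eb), c(2, 2))
})

test_that("exponent zero reduces to unweighted edge betweenness", {
  set.seed(600)
  w <- rand_sym_matrix(5)
  a <- edge_betweenness_ranking(w, exponent = 0)
  ones <- connectivity_matrix((w$weights > 0) * 1)
  b <- edge_betweenness_ranking(ones, exponent = 1)
  expect_equal(as.numeric(a), as.numeric(b))
})

test_that("edge and node betweenness match brute-force path enumeration", {
  for (s in 1:3) {
    set.seed(610 + s)
    w <- rand_sym_matrix(5)
    eb <- edge_betweenness_ranking(w, exponent = 1)
    oracle <- edge_betweenness_bf(w$weights, exponent = 1)
    expect_equal(as.numeric(eb),
                 sort(oracle[upper.tri(oracle)], decreasing = TRUE))

    nb <- node_metric_ranking(w, "betweenness")
    expect_equal(as.numeric(nb),
                 sort(node_betweenness_bf(w$weights), decreasing = TRUE))
  }
  # and with a weight exponent on a 6-node graph
  set.seed(614)
  w6 <- rand_sym_matrix(6)
  eb2 <- edge_betweenness_ranking(w6, exponent = 2)
  o2 <- edge_betweenness_bf(w6$weights, exponent = 2)
  expect_equal(as.numeric(eb2), sort(o2[upper.tri(o2)], decreasing = TRUE))
})

test_that("node metrics match hand values on canonical small graphs", {
  expect_equal(as.numeric(node_metric_ranking(triangle(), "clustering")),
               c(1, 1, 1))
  expect_equal(as.numeric(node_metric_ranking(star4(), "betweenness")),
               c(3, 0, 0, 0))
})

test_that("vitality equals literal remove-and-recompute brute force", {
  for (s in 1:3) {
    set.seed(620 + s)
    w <- rand_sym_matrix(5)
    v <- node_metric_ranking(w, "vitality")
    expect_equal(as.numeric(v), sort(vitality_bf(w$weights),
                                     decreasing = TRUE))
  }
})

test_that("vitality flags nodes whose removal disconnects the graph", {
  v <- node_metric_ranking(path3(), "vitality")
  vals <- as.numeric(v)
  expect_true(any(is.na(vals)))     # removing the middle node disconnects
  expect_equal(sum(is.na(vals)), 1L)
})

test_that("negative weights are a domain error for path metrics", {
  m <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(edge_betweenness_ranking(connectivity_matrix(m)), "negative")
})

test_that("metric transform with the weight metric is delta_transform exactly", {
  set.seed(630)
  g1 <- rand_group(4, 5)
  g2 <- rand_group(4, 5)
  a <- delta_transform(g1, g2)
  b <- metric_delta_transform(g1, g2, metric = "weight")
  expect_identical(a$delta_m, b$delta_m)
  expect_identical(a$delta_std, b$delta_std)
  expect_identical(a$defined, b$defined)
})

test_that("identical groups give an all-zero metric profile", {
  set.seed(631)
  g <- rand_group(4, 6)
  for (metric in c("edge_betweenness", "clustering", "betweenness")) {
    p <- metric_delta_transform(g, g, metric = metric)
    expect_equal(p$delta_m[p$defined], rep(0, sum(p$defined)))
    expect_equal(p$delta_std[p$defined], rep(0, sum(p$defined)))
  }
})

test_that("edge betweenness profiles ignore a global weight rescaling", {
  set.seed(632)
  g1 <- rand_group(5, 6)
  p <- metric_delta_transform(g1, scale_group(g1, 2),
                              metric = "edge_betweenness", exponent = 1)
  expect_equal(p$delta_m[p$defined], rep(0, sum(p$defined)))
  expect_equal(p$delta_std[p$defined], rep(0, sum(p$defined)))
})

test_that("profile smoothing averages blocks of consecutive ranks", {
  p <- rankdelta:::new_delta_profile(as.numeric(1:8), rep(1, 8),
                                     rep(TRUE, 8))
  s <- smooth_profile(p, block = 4)
  expect_equal(s$delta_m, c(2.5, 6.5))
  expect_equal(s$delta_std, c(1, 1))
  expect_identical(s$rank, c(1L, 5L))

  expect_identical(smooth_profile(p, block = 1), p)

  # trailing partial block averaged over its actual size
  s3 <- smooth_profile(p, block = 3)
  expect_equal(s3$delta_m, c(2, 5, 7.5))

  # constant profile is unchanged in value
  pc <- rankdelta:::new_delta_profile(rep(0.7, 9), rep(-0.2, 9), rep(TRUE, 9))
  sc <- smooth_profile(pc, block = 4)
  expect_equal(sc$delta_m, rep(0.7, 3))
  expect_equal(sc$delta_std, rep(-0.2, 3))

  # undefined ranks are excluded from their block's average
  pd <- rankdelta:::new_delta_profile(c(1, NA, 3, 4), rep(1, 4),
                                      c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(smooth_profile(pd, block = 2)$delta_m, c(1, 3.5))
})

test_that("ranking stability matches identity, antitone and formula oracles", {
  set.seed(640)
  m <- rand_sym_matrix(5)
  g_same <- network_group(rep(list(m), 3L))
  s <- ranking_stability(g_same)
  expect_equal(s$rho, rep(1, 3))

  # a pair whose weight vectors are exact rank reverses
  v <- matrix(0, 4, 4); v[upper.tri(v)] <- 1:6; v <- v + t(v)
  r <- matrix(0, 4, 4); r[upper.tri(r)] <- 6:1; r <- r + t(r)
  g_rev <- network_group(list(v, r))
  expect_equal(ranking_stability(g_rev)$rho, -1)

  # closed-form oracle on tie-free random pairs, canonical link order
  g <- rand_group(4, 6)
  s2 <- ranking_stability(g)
  vecs <- vapply(g$members, function(mm) mm$weights[upper.tri(mm$weights)],
                 numeric(15))
  for (i in seq_len(nrow(s2$pairs))) {
    expect_equal(s2$rho[i], spearman_bf(vecs[, s2$pairs[i, 1]],
                                        vecs[, s2$pairs[i, 2]]))
  }
})

test_that("constant weight vectors make stability undefined, flagged", {
  const <- connectivity_matrix(matrix(1, 4, 4) - diag(4))
  set.seed(641)
  g <- network_group(list(const, rand_sym_matrix(4)))
  expect_warning(s <- ranking_stability(g), "constant")
  expect_true(s$undefined[1])
})
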