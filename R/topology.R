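# Topological link/node metric rankings and the transform over them.
#
# Path-based metrics use the distance convention d = 1 / w^exponent: strong
# links are short distances. All off-diagonal weights must be positive for
# these metrics to be defined.

to_igraph <- function(w, weights = NULL) {
  mode <- if (w$directed) "directed" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(w$weights, mode = mode,
                                           weighted = TRUE, diag = FALSE)
  g
}

# Path-based metrics need positive link weights for 1/w to be a distance.
# Exact zeros follow the adjacency-matrix convention: they mean "no link",
# not a zero-weight link. Negative weights have no distance interpretation.
check_positive_weights <- function(w) {
  m <- w$weights
  off <- if (w$directed) m[row(m) != col(m)] else m[upper.tri(m)]
  if (any(off < 0)) {
    stop(sprintf("metric undefined: matrix%s has negative link weights",
                 label_msg(w$label)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Edge betweenness ranking of a network
#'
#' Raises link weights to `exponent`, interprets edge length as
#' `1 / w^exponent` (strong link = short distance), computes unnormalised
#' edge betweenness (the number of shortest node pairs' paths crossing each
#' edge) and returns the values sorted in decreasing order. `exponent = 0`
#' reduces to unweighted betweenness.
#'
#' @param w A [connectivity_matrix()] with non-negative weights; exact zeros
#'   follow the adjacency convention (absent link), negative weights are a
#'   domain error.
#' @param exponent Weight exponent alpha (default 1).
#' @return A `metric_ranking` object: a descending numeric vector with
#'   attributes `metric` and `element_kind = "link"`.
#' @export
edge_betweenness_ranking <- function(w, exponent = 1) {
  if (!inherits(w, "connectivity_matrix")) w <- connectivity_matrix(w)
  check_positive_weights(w)
  g <- to_igraph(w)
  d <- 1 / (igraph::E(g)$weight^exponent)
  eb <- igraph::edge_betweenness(g, weights = d, directed = w$directed)
  new_metric_ranking(sort(eb, decreasing = TRUE, method = "radix"),
                     sprintf("edge_betweenness(alpha=%g)", exponent), "link")
}

#' Node metric ranking of a network
#'
#' Computes one of three node-based metrics and returns the per-node values
#' sorted in decreasing order:
#' * `clustering` — weighted clustering coefficient in the geometric-mean
#'   (Onnela) form, with weights scaled by the network maximum;
#' * `betweenness` — node betweenness centrality with edge distance `1/w`;
#' * `vitality` — closeness vitality: the change in the sum of all-pairs
#'   shortest-path distances (distance `1/w`) when the node is removed.
#'
#' @param w A [connectivity_matrix()] with non-negative weights (zeros mean
#'   absent links; the distance-based metrics need positive weights on the
#'   links that exist).
#' @param metric `"clustering"`, `"betweenness"` or `"vitality"`.
#' @return A `metric_ranking` object (`element_kind = "node"`). Vitality is
#'   `NA` (flagged undefined) for nodes whose removal disconnects the graph.
#' @export
node_metric_ranking <- function(w, metric = c("clustering", "betweenness",
                                              "vitality")) {
  metric <- match.arg(metric)
  if (!inherits(w, "connectivity_matrix")) w <- connectivity_matrix(w)
  check_positive_weights(w)
  vals <- switch(metric,
    clustering = onnela_clustering(w$weights),
    betweenness = {
      g <- to_igraph(w)
      igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                          directed = w$directed)
    },
    vitality = closeness_vitality(w))
  new_metric_ranking(sort(unname(vals), decreasing = TRUE, method = "radix",
                          na.last = TRUE),
                     metric, "node")
}

# Onnela geometric-mean weighted clustering on an undirected weight matrix:
# C_i = (A^3)_ii / (k_i (k_i - 1)) with A = (w / max(w))^(1/3).
onnela_clustering <- function(m) {
  a <- (m / max(m))^(1 / 3)
  diag(a) <- 0
  num <- diag(a %*% a %*% a)
  k <- rowSums(m > 0)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, num / denom, 0)
  out
}

# Closeness vitality with distance 1/w: Wiener index of the graph minus the
# Wiener index with the node removed. NA where removal disconnects the graph.
closeness_vitality <- function(w) {
  g <- to_igraph(w)
  dist_sum <- function(gr) {
    d <- igraph::distances(gr, weights = 1 / igraph::E(gr)$weight)
    if (any(is.infinite(d))) return(NA_real_)
    sum(d) / 2
  }
  total <- dist_sum(g)
  vapply(seq_len(w$n_nodes), function(v) {
    rest <- dist_sum(igraph::delete_vertices(g, v))
    if (is.na(total) || is.na(rest)) NA_real_ else total - rest
  }, numeric(1L))
}

new_metric_ranking <- function(values, metric, element_kind) {
  structure(values, metric = metric, element_kind = element_kind,
            class = "metric_ranking")
}

# Resolve a metric spec to a per-member ranking function.
metric_ranking_fun <- function(metric, exponent = 1) {
  switch(metric,
    weight = extract_ranked_weights,
    edge_betweenness = function(m) {
      as.numeric(edge_betweenness_ranking(m, exponent = exponent))
    },
    clustering = ,
    betweenness = ,
    vitality = function(m) as.numeric(node_metric_ranking(m, metric)),
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Rank-difference transform over a topological metric
#'
#' Identical pipeline to [delta_transform()], but the per-network descending
#' ranking is taken over a link or node metric instead of the raw link
#' weights: per-rank group medians and standard deviations of the metric,
#' then their between-group log2 ratios. With `metric = "weight"` this is
#' exactly [delta_transform()].
#'
#' @inheritParams delta_transform
#' @param metric `"weight"`, `"edge_betweenness"`, `"clustering"`,
#'   `"betweenness"` or `"vitality"`.
#' @param exponent Weight exponent for `edge_betweenness`.
#' @return A `delta_profile` (length L for link metrics, n for node metrics).
#' @export
metric_delta_transform <- function(g1, g2, metric = "weight", exponent = 1,
                                   n_resamples = 0L, seed = NULL,
                                   exhaustive = FALSE) {
  fun <- metric_ranking_fun(metric, exponent)
  delta_pipeline(g1, g2, fun, metric,
                 n_resamples = n_resamples, seed = seed,
                 exhaustive = exhaustive)
}

#' Smooth a delta profile over consecutive ranks
#'
#' Averages `delta_m`, `delta_std` and box edges over non-overlapping blocks
#' of `block` consecutive ranking positions (a trailing partial block is
#' averaged over its actual size). Undefined ranks are omitted from their
#' block's average; a block is undefined only if all its ranks are. Used to
#' de-noise profiles from high-dimensional networks, e.g. averaging over 4
#' consecutive links. The reported rank of each block is its strongest rank.
#'
#' @param p A `delta_profile`.
#' @param block Block length (default 4); `block = 1` is the identity.
#' @return A smoothed `delta_profile` of length `ceiling(L / block)`.
#' @export
smooth_profile <- function(p, block = 4L) {
  stopifnot(inherits(p, "delta_profile"))
  if (!is_count(block)) stop("`block` must be a positive integer",
                             call. = FALSE)
  if (block == 1L) return(p)
  L <- length(p$rank)
  grp <- (p$rank - 1L) %/% block
  starts <- tapply(p$rank, grp, min)
  blockmean <- function(x, defined = p$defined) {
    x <- ifelse(defined, x, NA_real_)
    as.numeric(tapply(x, grp, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }))
  }
  dm <- blockmean(p$delta_m)
  ds <- blockmean(p$delta_std)
  boxes <- NULL
  if (!is.null(p$boxes)) {
    boxes <- as.data.frame(lapply(p$boxes, blockmean))
  }
  out <- new_delta_profile(dm, ds, !is.na(dm) & !is.na(ds), boxes = boxes,
                           n1 = p$n1, n2 = p$n2, metric = p$metric)
  out$rank <- as.integer(starts)
  out
}

#' Ranking stability within a network group
#'
#' For every unordered pair of group members, the Spearman rank correlation
#' between their link-weight vectors taken in a fixed canonical link order
#' (pairing link identity across subjects — the vectors are *not* re-sorted,
#' which would make every correlation trivially 1). High values mean the
#' group's subjects agree on which links are strong; unstable rankings
#' produce fuzzy delta-plane structures.
#'
#' @param g A [network_group()] with at least 2 members.
#' @return An object of class `stability_distribution`: a list with `rho`
#'   (length `choose(n, 2)`), the member index `pairs` matrix, and
#'   `undefined` flagging pairs where a constant weight vector made the
#'   correlation undefined.
#' @export
ranking_stability <- function(g) {
  stopifnot(inherits(g, "network_group"))
  n <- length(g$members)
  if (n < 2L) stop("ranking stability needs at least 2 networks",
                   call. = FALSE)
  vecs <- vapply(g$members, link_vector, numeric(n_links(g$members[[1L]])))
  pairs <- t(combn(n, 2L))
  rho <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- vecs[, pairs[r, 1L]]
    b <- vecs[, pairs[r, 2L]]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, numeric(1L))
  if (anyNA(rho)) {
    warning(sprintf("%d pair(s) had a constant weight vector: rho undefined",
                    sum(is.na(rho))), call. = FALSE)
  }
  structure(list(rho = rho, pairs = pairs, undefined = is.na(rho),
                 group = g$name),
            class = "stability_distribution")
}

#' @export
print.stability_distribution <- function(x, ...) {
  cat(sprintf(
    "<stability_distribution '%s': %d pairs, median rho = %.3f%s>\n",
    x$group, length(x$rho), median(x$rho, na.rm = TRUE),
    if (any(x$undefined)) sprintf(", %d undefined", sum(x$undefined)) else ""))
  invisible(x)
}
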