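#' Extract a network's link weights, ranked in decreasing order
#'
#' Off-diagonal weights (upper triangle only for undirected matrices, all
#' off-diagonal cells for directed ones) sorted so that rank 1 is the
#' strongest link. Ties keep a stable order, which does not affect any
#' downstream statistic.
#'
#' @param w A [connectivity_matrix()] (or a plain square matrix, treated as
#'   undirected).
#' @return Numeric vector of length `n(n-1)/2` (undirected) or `n(n-1)`
#'   (directed), non-increasing.
#' @examples
#' w <- connectivity_matrix(matrix(c(0, 2, 2, 0), 2, 2))
#' extract_ranked_weights(w)
#' @export
extract_ranked_weights <- function(w) {
  if (!inherits(w, "connectivity_matrix")) w <- connectivity_matrix(w)
  sort(link_vector(w), decreasing = TRUE, method = "radix")
}

# n_members x L matrix of ranked weights, one row per member.
ranked_weight_matrix <- function(g) {
  L <- n_links(g$members[[1L]])
  t(vapply(g$members, extract_ranked_weights, numeric(L)))
}

#' Per-rank medians and standard deviations of a network group
#'
#' For each ranking position r, the median and the sample standard deviation
#' (n-1 denominator) of the r-th ranked link weight across the group's
#' members. These are statistics of order statistics: link identity plays no
#' role, only each network's weight hierarchy.
#'
#' @param g A [network_group()] with at least 2 members.
#' @return A list of class `rank_statistics` with elements `medians`, `stds`
#'   (length-L vectors, rank 1 = strongest) and `group_size`.
#' @examples
#' g <- network_group(list(matrix(c(0, 3, 3, 0), 2, 2),
#'                         matrix(c(0, 5, 5, 0), 2, 2)))
#' group_rank_statistics(g)
#' @export
group_rank_statistics <- function(g) {
  stopifnot(inherits(g, "network_group"))
  if (length(g$members) < 2L) {
    stop("group rank statistics need at least 2 networks per group",
         call. = FALSE)
  }
  rank_stats_from_matrix(ranked_weight_matrix(g), length(g$members))
}

rank_stats_from_matrix <- function(R, group_size) {
  structure(list(medians = col_medians(R), stds = col_sds(R),
                 group_size = group_size),
            class = "rank_statistics")
}

# Per-rank log2 ratios of two rank_statistics (second over first). Ranks
# where either ratio has a non-positive numerator or denominator are flagged
# undefined; no epsilon is added (weights such as -log10 p can be exactly 0).
delta_from_stats <- function(s1, s2) {
  ok_m <- s1$medians > 0 & s2$medians > 0
  ok_s <- s1$stds > 0 & s2$stds > 0
  dm <- ds <- rep(NA_real_, length(ok_m))
  dm[ok_m] <- log2(s2$medians[ok_m] / s1$medians[ok_m])
  ds[ok_s] <- log2(s2$stds[ok_s] / s1$stds[ok_s])
  list(delta_m = dm, delta_std = ds, defined = ok_m & ok_s)
}

new_delta_profile <- function(delta_m, delta_std, defined, boxes = NULL,
                              n1 = NA_integer_, n2 = NA_integer_,
                              metric = "weight") {
  L <- length(delta_m)
  structure(
    list(rank = seq_len(L),
         delta_m = delta_m, delta_std = delta_std, defined = defined,
         color_value = if (L > 1L) (L - seq_len(L)) / (L - 1) else rep(1, L),
         boxes = boxes, n1 = n1, n2 = n2, metric = metric),
    class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf(
    "<delta_profile: %d ranks (%d defined), metric '%s', groups %s vs %s%s>\n",
    length(x$rank), sum(x$defined), x$metric, x$n1, x$n2,
    if (is.null(x$boxes)) "" else ", with uncertainty boxes"))
  invisible(x)
}

#' @export
as.data.frame.delta_profile <- function(x, ...) {
  d <- data.frame(rank = x$rank, delta_m = x$delta_m, delta_std = x$delta_std,
                  color_value = x$color_value, defined = x$defined)
  if (!is.null(x$boxes)) d <- cbind(d, as.data.frame(x$boxes))
  d
}

#' The rank-difference transform between two network groups
#'
#' Ranks every network's link weights, computes per-rank group medians and
#' standard deviations, and returns their between-group log2 ratios:
#' `delta_m[r] = log2(M_g2[r] / M_g1[r])` and
#' `delta_std[r] = log2(Std_g2[r] / Std_g1[r])`. Positive values mean the
#' second group has the larger median (respectively, variability) at that
#' ranking position. Ranks where either ratio involves a non-positive value
#' are flagged undefined and excluded from plots.
#'
#' @param g1,g2 [network_group()] objects with identical node count and
#'   directedness; group sizes may differ (each must be at least 2).
#' @param n_resamples If greater than 0, attach per-rank uncertainty boxes
#'   from `n_resamples` random half-subsets of each group (see
#'   [subsample_uncertainty()]).
#' @param seed Integer seed controlling the resampling (ignored when no boxes
#'   are requested).
#' @param exhaustive If `TRUE`, enumerate all half-subset pairs instead of
#'   resampling (feasible for small groups); `n_resamples` is then ignored.
#' @return An object of class `delta_profile` with elements `rank`,
#'   `delta_m`, `delta_std`, `defined`, `color_value` and optionally `boxes`.
#' @examples
#' toy <- generate_toy_example(seed = 1)
#' delta_transform(toy$g1, toy$g2)
#' @export
delta_transform <- function(g1, g2, n_resamples = 0L, seed = NULL,
                            exhaustive = FALSE) {
  metric_delta_transform(g1, g2, metric = "weight",
                         n_resamples = n_resamples, seed = seed,
                         exhaustive = exhaustive)
}

# Shared pipeline: `ranking_fun(member)` returns one member's descending
# metric-ranking vector. delta_transform is the metric = "weight" case.
delta_pipeline <- function(g1, g2, ranking_fun, metric_name,
                           n_resamples = 0L, seed = NULL,
                           exhaustive = FALSE) {
  stopifnot(inherits(g1, "network_group"), inherits(g2, "network_group"))
  if (group_n_nodes(g1) != group_n_nodes(g2)) {
    stop(sprintf("groups differ in node count (%d vs %d)",
                 group_n_nodes(g1), group_n_nodes(g2)), call. = FALSE)
  }
  if (group_directed(g1) != group_directed(g2)) {
    stop("groups differ in directedness", call. = FALSE)
  }
  if (length(g1$members) < 2L || length(g2$members) < 2L) {
    stop("each group needs at least 2 networks", call. = FALSE)
  }
  r1 <- ranking_matrix(g1, ranking_fun)
  r2 <- ranking_matrix(g2, ranking_fun)
  d <- delta_from_stats(rank_stats_from_matrix(r1, nrow(r1)),
                        rank_stats_from_matrix(r2, nrow(r2)))
  if (!any(d$defined)) {
    warning("all ranking positions are undefined (non-positive medians or ",
            "standard deviations in at least one group)", call. = FALSE)
  }
  boxes <- NULL
  if (exhaustive || n_resamples > 0L) {
    boxes <- boxes_from_ranked(r1, r2, n_resamples = n_resamples,
                               seed = seed, exhaustive = exhaustive)
  }
  new_delta_profile(d$delta_m, d$delta_std, d$defined, boxes = boxes,
                    n1 = length(g1$members), n2 = length(g2$members),
                    metric = metric_name)
}

ranking_matrix <- function(g, ranking_fun) {
  first <- ranking_fun(g$members[[1L]])
  out <- matrix(NA_real_, length(g$members), length(first))
  out[1L, ] <- first
  for (i in seq_along(g$members)[-1L]) out[i, ] <- ranking_fun(g$members[[i]])
  out
}

#' Subsampling uncertainty boxes for a delta profile
#'
#' Recomputes the transform on random half-subsets of each group (sizes
#' `floor(n/2)`, drawn without replacement, independently per group) and
#' attaches, per rank and per metric, the 16th and 84th percentiles across
#' resamples. Each box depicts where the corresponding point would fall if
#' only half of the data were available.
#'
#' @param g1,g2 [network_group()] objects with at least 4 members each.
#' @param n_resamples Number of random half-subset pairs (default 200).
#' @param seed Integer seed; the result is fully deterministic given it.
#' @param exhaustive If `TRUE`, enumerate every pair of half-subsets instead
#'   of sampling (all `choose(n1, n1/2) * choose(n2, n2/2)` combinations);
#'   use only for small groups.
#' @return A `delta_profile` as from [delta_transform()], with a `boxes`
#'   data frame (`delta_m_low`, `delta_m_high`, `delta_std_low`,
#'   `delta_std_high`).
#' @export
subsample_uncertainty <- function(g1, g2, n_resamples = 200L, seed = NULL,
                                  exhaustive = FALSE) {
  if (!exhaustive && n_resamples < 1L) {
    stop("`n_resamples` must be at least 1", call. = FALSE)
  }
  if (length(g1$members) < 4L || length(g2$members) < 4L) {
    stop("uncertainty boxes need at least 4 networks per group ",
         "(half-groups must support a standard deviation)", call. = FALSE)
  }
  delta_transform(g1, g2, n_resamples = n_resamples, seed = seed,
                  exhaustive = exhaustive)
}

# Boxes from precomputed ranked matrices. Percentiles use the linear
# interpolation convention (stats::quantile type 7).
boxes_from_ranked <- function(r1, r2, n_resamples = 200L, seed = NULL,
                              exhaustive = FALSE) {
  n1 <- nrow(r1); n2 <- nrow(r2)
  h1 <- n1 %/% 2L; h2 <- n2 %/% 2L
  if (h1 < 2L || h2 < 2L) {
    stop("uncertainty boxes need at least 4 networks per group ",
         "(half-groups must support a standard deviation)", call. = FALSE)
  }
  if (exhaustive) {
    s1 <- combn(n1, h1, simplify = FALSE)
    s2 <- combn(n2, h2, simplify = FALSE)
    pairs <- expand.grid(i = seq_along(s1), j = seq_along(s2))
    idx1 <- s1[pairs$i]; idx2 <- s2[pairs$j]
  } else {
    idx <- with_seed(seed, lapply(seq_len(n_resamples), function(k) {
      list(sample.int(n1, h1), sample.int(n2, h2))
    }))
    idx1 <- lapply(idx, `[[`, 1L)
    idx2 <- lapply(idx, `[[`, 2L)
  }
  B <- length(idx1)
  L <- ncol(r1)
  dm <- ds <- matrix(NA_real_, B, L)
  for (b in seq_len(B)) {
    d <- delta_from_stats(
      rank_stats_from_matrix(r1[idx1[[b]], , drop = FALSE], h1),
      rank_stats_from_matrix(r2[idx2[[b]], , drop = FALSE], h2))
    dm[b, ] <- d$delta_m
    ds[b, ] <- d$delta_std
  }
  pct <- function(m, p) {
    apply(m, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) NA_real_ else quantile(col, p, names = FALSE)
    })
  }
  data.frame(delta_m_low = pct(dm, 0.16), delta_m_high = pct(dm, 0.84),
             delta_std_low = pct(ds, 0.16), delta_std_high = pct(ds, 0.84))
}

#' Multiplicative ratio implied by a log2 difference
#'
#' Converts a Delta-M or Delta-Std value back to the multiplicative
#' group-2-over-group-1 ratio it encodes: a Delta of 3 corresponds to an
#' eight-fold increase, -1 to a halving.
#'
#' @param delta Finite numeric vector of log2 differences.
#' @return `2^delta`.
#' @examples
#' fold_change(c(3, 0, -1))
#' @export
fold_change <- function(delta) {
  stopifnot(is.numeric(delta))
  2^delta
}
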