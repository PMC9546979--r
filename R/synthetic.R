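#' Synthetic benchmark generators
#'
#' Seeded generators for the six synthetic validation models used to
#' illustrate the rank-difference transform: three *static* models in which
#' link weights are drawn directly, and three *dynamic* models in which
#' weights are absolute Pearson correlations between short node time series.
#'
#' In the static models an increasing index l = 1, 2, ... is associated to
#' each link (canonical upper-triangle order; the mapping is immaterial since
#' draws are independent across links). Group 1 always draws link l from
#' N(l, 1). Group 2 draws from, by variant: (1) N(l^2, 1) — supralinearly
#' stronger links; (2) N(l, l) — same mean, variance growing with l;
#' (3) N(l^2, l) — both. The second parameter of N(., .) is a variance.
#'
#' In the dynamic models each network draws a common pattern `pi` of `tau`
#' uniform(0, 1) values; node i's series is `pi + amp_i * U(-1, 1)` per
#' sample, and the link weight is the absolute Pearson correlation between
#' the two node series. Group 1 uses amplitudes `alpha_i ~ U(0, 1)`. Group 2
#' uses, by variant: (1) `beta_i ~ U(0, 8)` — much noisier dynamics; (2)
#' `beta_i ~ U(0, 0.2)` for nodes i <= 10 and exponential with mean 4
#' otherwise — ten tightly synchronised nodes; (3) `beta_i ~ U(0, 0.3 i)` —
#' node-dependent heterogeneity. Amplitudes and pattern are redrawn per
#' network, so networks are exchangeable within a group.
#'
#' @param variant Model variant, 1, 2 or 3.
#' @param group Which group to generate, 1 or 2 (group 1 is identical across
#'   variants).
#' @param n_networks Networks per group (study default 10,000).
#' @param n_nodes Nodes per network (default 20).
#' @param tau Samples per node time series in the dynamic models (default 8).
#' @param seed Integer seed; generation is fully reproducible given it. The
#'   two groups use internally decorrelated streams, so the same `seed` may
#'   be passed for both.
#' @return A [network_group()] of undirected `connectivity_matrix` objects.
#' @name synthetic_models
NULL

group_seed <- function(seed, group) {
  if (is.null(seed)) return(NULL)
  as.integer(seed) + (as.integer(group) - 1L) * 1000003L
}

#' @rdname synthetic_models
#' @export
generate_static_group <- function(variant, group, n_networks = 10000L,
                                  n_nodes = 20L, seed = NULL) {
  check_model_args(variant, group, n_networks, n_nodes)
  if (n_networks < 2L) stop("`n_networks` must be at least 2", call. = FALSE)
  L <- (n_nodes * (n_nodes - 1L)) %/% 2L
  l <- seq_len(L)
  if (group == 1L) {
    mean_l <- l; sd_l <- rep(1, L)
  } else {
    mean_l <- switch(variant, l^2, l, l^2)
    sd_l <- switch(variant, rep(1, L), sqrt(l), sqrt(l))
  }
  with_seed(group_seed(seed, group), {
    members <- lapply(seq_len(n_networks), function(k) {
      w <- matrix(0, n_nodes, n_nodes)
      w[upper.tri(w)] <- rnorm(L, mean_l, sd_l)
      w <- w + t(w)
      connectivity_matrix(w, directed = FALSE,
                          label = sprintf("static%d_g%d_%04d", variant, group, k))
    })
    network_group(members, name = sprintf("static%d_g%d", variant, group))
  })
}

#' @rdname synthetic_models
#' @export
generate_dynamic_group <- function(variant, group, n_networks = 10000L,
                                   n_nodes = 20L, tau = 8L, seed = NULL) {
  check_model_args(variant, group, n_networks, n_nodes)
  if (!is_count(tau, min = 3L)) stop("`tau` must be at least 3", call. = FALSE)
  if (variant == 2L && group == 2L && n_nodes < 11L) {
    stop("dynamic model 2 needs at least 11 nodes (the i <= 10 split is ",
         "undefined otherwise)", call. = FALSE)
  }
  with_seed(group_seed(seed, group), {
    members <- lapply(seq_len(n_networks), function(k) {
      pi_t <- runif(tau)
      amp <- if (group == 1L) runif(n_nodes) else switch(variant,
        runif(n_nodes, 0, 8),
        c(runif(10L, 0, 0.2), rexp(n_nodes - 10L, rate = 1 / 4)),
        runif(n_nodes, 0, 0.3 * seq_len(n_nodes)))
      series <- matrix(rep(pi_t, each = n_nodes), n_nodes, tau) +
        amp * matrix(runif(n_nodes * tau, -1, 1), n_nodes, tau)
      w <- abs(cor(t(series)))
      w[is.na(w)] <- 0  # degenerate zero-variance series map to weight 0
      diag(w) <- 0
      connectivity_matrix(w, directed = FALSE,
                          label = sprintf("dynamic%d_g%d_%04d", variant, group, k))
    })
    network_group(members, name = sprintf("dynamic%d_g%d", variant, group))
  })
}

check_model_args <- function(variant, group, n_networks, n_nodes) {
  if (!is_count(variant) || !variant %in% 1:3) {
    stop("`variant` must be 1, 2 or 3", call. = FALSE)
  }
  if (!is_count(group) || !group %in% 1:2) {
    stop("`group` must be 1 or 2", call. = FALSE)
  }
  if (!is_count(n_networks)) stop("`n_networks` must be a positive integer",
                                  call. = FALSE)
  if (!is_count(n_nodes, min = 3L)) stop("`n_nodes` must be at least 3",
                                         call. = FALSE)
}

#' Generate a small two-group toy example
#'
#' Two groups of three undirected 4-node networks with positive weights,
#' mirroring the minimal worked setting of the method's schematic: a handful
#' of networks per condition, six links each. Group 2's weights are scaled up
#' and noisier than group 1's. Intended for documentation and smoke tests.
#'
#' @param seed Integer seed.
#' @return A list with elements `g1` and `g2`, both [network_group()]s of
#'   size 3.
#' @examples
#' toy <- generate_toy_example(seed = 1)
#' delta_transform(toy$g1, toy$g2)
#' @export
generate_toy_example <- function(seed = NULL) {
  with_seed(seed, {
    mk <- function(scale, spread, grp, k) {
      w <- matrix(0, 4L, 4L)
      w[upper.tri(w)] <- scale * exp(spread * rnorm(6L)) * (6:1)
      connectivity_matrix(w + t(w), label = sprintf("toy_g%d_%d", grp, k))
    }
    g1 <- network_group(lapply(1:3, function(k) mk(1, 0.15, 1L, k)), "g1")
    g2 <- network_group(lapply(1:3, function(k) mk(1.6, 0.35, 2L, k)), "g2")
    list(g1 = g1, g2 = g2)
  })
}
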