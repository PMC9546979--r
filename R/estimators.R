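#' Absolute-Pearson connectivity matrix
#'
#' Undirected functional connectivity: `w[i, j]` is the absolute value of the
#' Pearson correlation between channels i and j, in `[0, 1]`.
#'
#' @param rec A [recording()].
#' @return An undirected [connectivity_matrix()].
#' @export
pearson_abs <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  check_channel_variance(rec)
  w <- abs(cor(t(rec$data)))
  diag(w) <- 0
  connectivity_matrix(w, directed = FALSE, label = "pearson_abs")
}

check_channel_variance <- function(rec) {
  v <- apply(rec$data, 1L, function(x) max(x) - min(x))
  bad <- which(v == 0)
  if (length(bad)) {
    stop(sprintf("channel(s) %s have zero variance: correlation undefined",
                 paste(rec$channel_labels[bad], collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Granger-causality connectivity matrix
#'
#' Directed connectivity: `w[i, j]` is `-log10` of the p-value of the Granger
#' F-test for "channel i improves the AR(`order`) prediction of channel j".
#' The test compares the restricted regression of `x_j[t]` on its own
#' `order` lags against the regression augmented with `order` lags of
#' channel i; under no coupling the p-value is uniform, giving weight
#' distributions centred near small values.
#'
#' @param rec A [recording()]; needs more than `3 * order + 2` samples.
#' @param order Autoregressive model order (default 1).
#' @return A directed [connectivity_matrix()] with non-negative weights.
#' @export
granger_neglog10p <- function(rec, order = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (!is_count(order)) stop("`order` must be a positive integer",
                             call. = FALSE)
  Tn <- ncol(rec$data)
  if (Tn <= 3L * order + 2L) {
    stop(sprintf("Granger with order %d needs more than %d samples, got %d",
                 order, 3L * order + 2L, Tn), call. = FALSE)
  }
  nch <- nrow(rec$data)
  nobs <- Tn - order
  # lag-embedding per channel: nobs x order matrix of x[t-1], ..., x[t-order]
  lags <- lapply(seq_len(nch), function(c) {
    vapply(seq_len(order), function(k) rec$data[c, (order + 1L - k):(Tn - k)],
           numeric(nobs))
  })
  targets <- lapply(seq_len(nch), function(c) rec$data[c, (order + 1L):Tn])
  ones <- rep(1, nobs)
  rss <- function(X, y, pair) {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      stop(sprintf("rank-deficient Granger regression for pair %s", pair),
           call. = FALSE)
    }
    sum(fit$residuals^2)
  }
  rss_restricted <- vapply(seq_len(nch), function(j) {
    rss(cbind(ones, lags[[j]]), targets[[j]], rec$channel_labels[j])
  }, numeric(1L))
  df2 <- nobs - (2L * order + 1L)
  w <- matrix(0, nch, nch)
  for (j in seq_len(nch)) {
    for (i in seq_len(nch)) {
      if (i == j) next
      pair <- paste(rec$channel_labels[i], "->", rec$channel_labels[j])
      rss_full <- rss(cbind(ones, lags[[j]], lags[[i]]), targets[[j]], pair)
      f <- ((rss_restricted[j] - rss_full) / order) / (rss_full / df2)
      p <- pf(f, order, df2, lower.tail = FALSE)
      w[i, j] <- -log10(p)
    }
  }
  connectivity_matrix(w, directed = TRUE, label = "granger")
}

#' Mutual-information connectivity matrix
#'
#' Undirected connectivity: `w[i, j]` is the Kraskov–Stögbauer–Grassberger
#' k-nearest-neighbour estimate (algorithm 1, max-norm) of the mutual
#' information between channels i and j, in nats, clipped below at 0.
#' Duplicate sample values (which break nearest-neighbour counting) are
#' broken by an infinitesimal deterministic jitter.
#'
#' @param rec A [recording()].
#' @param k Number of neighbours (default 3); must be below the sample count.
#' @return An undirected [connectivity_matrix()].
#' @export
mutual_information <- function(rec, k = 3L) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  if (!is_count(k)) stop("`k` must be a positive integer", call. = FALSE)
  if (k >= n - 1L) {
    stop(sprintf("k = %d too large for %d samples", k, n), call. = FALSE)
  }
  x <- dejitter(rec$data)
  nch <- nrow(x)
  w <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      mi <- max(0, ksg_mi_cpp(x[i, ], x[j, ], as.integer(k)))
      w[i, j] <- mi
      w[j, i] <- mi
    }
  }
  connectivity_matrix(w, directed = FALSE, label = "mutual_information")
}

# Break exact ties within each channel by an infinitesimal rank-based offset
# (deterministic, no RNG): tied values are spread by multiples of an epsilon
# far below the data scale.
dejitter <- function(data) {
  t(apply(data, 1L, function(x) {
    if (!anyDuplicated(x)) return(x)
    scale <- max(diff(range(x)), 1e-12)
    x + (rank(x, ties.method = "first") / length(x)) * scale * 1e-10
  }))
}

#' Transfer-entropy connectivity matrix
#'
#' Directed connectivity: `w[i, j]` is the transfer entropy from channel i to
#' channel j — the reduction in uncertainty about j's next value from knowing
#' i's past, beyond j's own past. Estimated as the nearest-neighbour
#' (Frenzel–Pompe) conditional mutual information
#' `I(x_i past; x_j future | x_j past)` with `history` lags for both source
#' and target, in nats, clipped below at 0.
#'
#' @param rec A [recording()].
#' @param history Number of past samples conditioned on (default 1).
#' @param k Number of neighbours (default 3).
#' @return A directed [connectivity_matrix()].
#' @export
transfer_entropy <- function(rec, history = 1L, k = 3L) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  if (!is_count(history)) stop("`history` must be a positive integer",
                               call. = FALSE)
  if (!is_count(k)) stop("`k` must be a positive integer", call. = FALSE)
  if (n <= history + 2L) {
    stop(sprintf("transfer entropy with history %d needs more than %d samples",
                 history, history + 2L), call. = FALSE)
  }
  x <- dejitter(rec$data)
  nch <- nrow(x)
  h <- as.integer(history)
  idx <- (h + 1L):n
  emb <- function(v) vapply(seq_len(h), function(g) v[idx - g],
                            numeric(length(idx)))
  futures <- lapply(seq_len(nch), function(c) x[c, idx])
  pasts <- lapply(seq_len(nch), function(c) emb(x[c, ]))
  w <- matrix(0, nch, nch)
  for (i in seq_len(nch)) {
    for (j in seq_len(nch)) {
      if (i == j) next
      te <- fp_te_cpp(futures[[j]], pasts[[j]], pasts[[i]], as.integer(k))
      w[i, j] <- max(0, te)
    }
  }
  connectivity_matrix(w, directed = TRUE, label = "transfer_entropy")
}

#' Reconstruct a network group from a recording
#'
#' The full reconstruction pipeline: optional zero-phase band-pass filtering,
#' optional stride decimation, splitting into non-overlapping windows of
#' `tau` samples, and one connectivity matrix per window. Each window is
#' treated as an independent group member.
#'
#' @param rec A [recording()].
#' @param metric One of `"pearson"`, `"granger"`, `"mi"`, `"te"`.
#' @param tau Window length in samples (default 128).
#' @param band Optional band name or `c(low, high)` Hz, applied before
#'   decimation and windowing.
#' @param stride Optional decimation stride (applied after filtering).
#' @param order,history,k Estimator settings passed through to
#'   [granger_neglog10p()], [transfer_entropy()] and [mutual_information()].
#' @param name Group name for the result.
#' @return A [network_group()] with one member per window.
#' @export
reconstruct_networks <- function(rec, metric = c("pearson", "granger", "mi",
                                                 "te"),
                                 tau = 128L, band = NULL, stride = NULL,
                                 order = 1L, history = 1L, k = 3L,
                                 name = "reconstructed") {
  metric <- match.arg(metric)
  if (!is.null(band)) rec <- bandpass_filter(rec, band)
  if (!is.null(stride) && stride > 1L) rec <- decimate_by_stride(rec, stride)
  windows <- split_windows(rec, tau)
  if (length(windows) == 0L) {
    stop("recording too short: no complete window of length tau", call. = FALSE)
  }
  est <- switch(metric,
    pearson = function(wd) pearson_abs(wd),
    granger = function(wd) granger_neglog10p(wd, order = order),
    mi = function(wd) mutual_information(wd, k = k),
    te = function(wd) transfer_entropy(wd, history = history, k = k))
  members <- lapply(seq_along(windows), function(i) {
    m <- est(windows[[i]])
    m$label <- sprintf("%s_w%03d", metric, i)
    m
  })
  network_group(members, name = name)
}
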