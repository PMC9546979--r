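#' Construct a connectivity matrix
#'
#' Wraps a square weighted adjacency matrix describing one subject's (or one
#' trial's, or one time window's) network. Self-links are excluded from every
#' downstream computation: the diagonal is ignored and stored as zero.
#'
#' @param weights Square numeric matrix of connectivity strengths.
#' @param directed Logical; if `FALSE` (default) the off-diagonal entries must
#'   be symmetric to within `1e-9` and each link is counted once.
#' @param label Free-text identifier used in error messages and output files.
#' @return An object of class `connectivity_matrix`.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' connectivity_matrix(w)
#' @export
connectivity_matrix <- function(weights, directed = FALSE, label = "") {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(weights) != ncol(weights)) {
    stop(sprintf("connectivity matrix%s must be square, got %d x %d",
                 label_msg(label), nrow(weights), ncol(weights)), call. = FALSE)
  }
  if (nrow(weights) < 2L) {
    stop("a connectivity matrix needs at least 2 nodes", call. = FALSE)
  }
  if (anyNA(weights)) {
    stop(sprintf("connectivity matrix%s contains missing values",
                 label_msg(label)), call. = FALSE)
  }
  if (!directed) {
    asym <- max(abs(weights - t(weights)))
    if (asym > 1e-9) {
      stop(sprintf(
        "matrix%s is flagged undirected but asymmetric (max |w - t(w)| = %g)",
        label_msg(label), asym), call. = FALSE)
    }
  }
  weights <- unname(weights)
  diag(weights) <- 0
  structure(
    list(weights = weights, n_nodes = nrow(weights),
         directed = isTRUE(directed), label = as.character(label)),
    class = "connectivity_matrix")
}

label_msg <- function(label) {
  if (!is.null(label) && nzchar(label)) paste0(" '", label, "'") else ""
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix%s: %d nodes, %s, %d links>\n",
              label_msg(x$label), x$n_nodes,
              if (x$directed) "directed" else "undirected", n_links(x)))
  invisible(x)
}

# Number of ranked links: n(n-1)/2 undirected, n(n-1) directed.
n_links <- function(w) {
  n <- w$n_nodes
  if (w$directed) n * (n - 1L) else (n * (n - 1L)) %/% 2L
}

# Canonical link order: column-major upper triangle for undirected matrices,
# column-major off-diagonal for directed ones. Fixed once; every operation
# that pairs link identity across networks uses this order.
link_vector <- function(w) {
  m <- w$weights
  if (w$directed) m[row(m) != col(m)] else m[upper.tri(m)]
}

#' Construct a group of connectivity matrices
#'
#' An ordered collection of same-shape [connectivity_matrix()] objects,
#' representing one experimental condition (e.g. the control group).
#'
#' @param members List of `connectivity_matrix` objects sharing node count and
#'   directedness.
#' @param name Free-text group name.
#' @return An object of class `network_group`.
#' @export
network_group <- function(members, name = "") {
  if (!is.list(members) || length(members) < 1L) {
    stop("`members` must be a non-empty list of connectivity matrices",
         call. = FALSE)
  }
  members <- lapply(members, function(m) {
    if (inherits(m, "connectivity_matrix")) m else connectivity_matrix(m)
  })
  n <- members[[1L]]$n_nodes
  dir <- members[[1L]]$directed
  for (i in seq_along(members)) {
    if (members[[i]]$n_nodes != n) {
      stop(sprintf(
        "group '%s': member %d has %d nodes but member 1 has %d",
        name, i, members[[i]]$n_nodes, n), call. = FALSE)
    }
    if (members[[i]]$directed != dir) {
      stop(sprintf("group '%s': member %d differs in directedness", name, i),
           call. = FALSE)
    }
  }
  structure(list(members = members, name = as.character(name)),
            class = "network_group")
}

#' @export
print.network_group <- function(x, ...) {
  cat(sprintf("<network_group '%s': %d networks, %d nodes, %s>\n",
              x$name, length(x$members), x$members[[1L]]$n_nodes,
              if (x$members[[1L]]$directed) "directed" else "undirected"))
  invisible(x)
}

#' @export
length.network_group <- function(x) length(x$members)

group_n_nodes <- function(g) g$members[[1L]]$n_nodes
group_directed <- function(g) g$members[[1L]]$directed

#' Subset a network group
#'
#' @param g A [network_group()].
#' @param idx Integer indices of the members to keep.
#' @param name Optional new group name; defaults to the old one.
#' @return A `network_group` with the selected members, in the given order.
#' @export
subset_group <- function(g, idx, name = NULL) {
  stopifnot(inherits(g, "network_group"))
  network_group(g$members[idx], name = name %||% g$name)
}

#' Draw a random subset of a network group
#'
#' Used to emulate smaller cohorts (e.g. keeping 10% of the available
#' networks) when studying the robustness of the transform.
#'
#' @param g A [network_group()].
#' @param fraction Fraction of members to keep (at least one is kept).
#' @param seed Optional integer seed for reproducibility.
#' @return A `network_group` with `max(1, round(fraction * length(g)))`
#'   members drawn without replacement.
#' @export
thin_group <- function(g, fraction, seed = NULL) {
  stopifnot(inherits(g, "network_group"), fraction > 0, fraction <= 1)
  k <- max(1L, round(fraction * length(g$members)))
  idx <- with_seed(seed, sample.int(length(g$members), k))
  subset_group(g, sort(idx))
}
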