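# File formats: delimited-text matrices (comma or tab, headerless by
# default), plain-text group manifests (one matrix path per line, '#'
# comments), and delimited profile files.

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  }
  if (grepl("\t", first)) "\t" else ","
}

resolve_delimiter <- function(delimiter, path) {
  switch(delimiter,
         auto = detect_delimiter(path),
         comma = ",",
         tab = "\t",
         stop(sprintf("unknown delimiter '%s' (auto, comma or tab)",
                      delimiter), call. = FALSE))
}

#' Read a connectivity matrix from a delimited text file
#'
#' Expects an n x n numeric matrix, comma- or tab-separated, with no header
#' by default.
#'
#' @param path File path.
#' @param directed Logical directedness flag; undirected matrices are
#'   validated for symmetry.
#' @param delimiter `"auto"` (default), `"comma"` or `"tab"`.
#' @param header If `TRUE`, skip one header line.
#' @return A [connectivity_matrix()] labelled with the file name.
#' @export
read_connectivity_matrix <- function(path, directed = FALSE,
                                     delimiter = "auto", header = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file '%s' does not exist", path), call. = FALSE)
  }
  sep <- resolve_delimiter(delimiter, path)
  d <- tryCatch(
    read.table(path, sep = sep, header = FALSE, skip = as.integer(header),
               colClasses = "numeric"),
    error = function(e) {
      stop(sprintf("'%s' is not a numeric delimited matrix: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in '%s' is %d x %d, not square", path,
                 nrow(m), ncol(m)), call. = FALSE)
  }
  connectivity_matrix(m, directed = directed, label = basename(path))
}

#' Write a connectivity matrix to a delimited text file
#'
#' @param w A [connectivity_matrix()].
#' @param path Output path.
#' @param delimiter `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(w, path, delimiter = "comma") {
  stopifnot(inherits(w, "connectivity_matrix"))
  sep <- if (delimiter == "tab") "\t" else ","
  write.table(format_full(w$weights), path, sep = sep, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision decimal rendering so that write + read round-trips bitwise.
format_full <- function(x) {
  out <- vapply(as.numeric(x), function(v) sprintf("%.17g", v),
                character(1L))
  dim(out) <- dim(x)
  out
}

#' Load a network group from a manifest file
#'
#' A manifest is a plain-text file with one matrix-file path per line
#' (relative paths are resolved against the manifest's directory); blank
#' lines and lines starting with `#` are ignored. All matrices must load,
#' be square, share the node count and pass the symmetry check when
#' undirected; errors name the offending file.
#'
#' @param manifest_path Path to the manifest.
#' @param directed Directedness of the matrices.
#' @param delimiter Matrix delimiter, `"auto"`, `"comma"` or `"tab"`.
#' @param header Whether matrix files carry one header line.
#' @param name Group name; defaults to the manifest file name without
#'   extension.
#' @return A [network_group()].
#' @export
load_group <- function(manifest_path, directed = FALSE, delimiter = "auto",
                       header = FALSE, name = NULL) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest '%s' does not exist", manifest_path),
         call. = FALSE)
  }
  lines <- trimws(readLines(manifest_path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop(sprintf("manifest '%s' lists no matrix files", manifest_path),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", lines), lines,
                  file.path(base, lines))
  members <- lapply(paths, read_connectivity_matrix, directed = directed,
                    delimiter = delimiter, header = header)
  network_group(members,
                name = name %||%
                  tools::file_path_sans_ext(basename(manifest_path)))
}

#' Save a network group as matrix files plus a manifest
#'
#' @param g A [network_group()].
#' @param outdir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the group name.
#' @return The manifest path, invisibly.
#' @export
save_group <- function(g, outdir, prefix = NULL) {
  stopifnot(inherits(g, "network_group"))
  prefix <- prefix %||% if (nzchar(g$name)) g$name else "group"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%05d.csv", prefix, seq_along(g$members))
  for (i in seq_along(g$members)) {
    write_connectivity_matrix(g$members[[i]], file.path(outdir, files[i]))
  }
  manifest <- file.path(outdir, paste0(prefix, ".txt"))
  writeLines(c(sprintf("# group %s: %d matrices, %d nodes", g$name,
                       length(g$members), group_n_nodes(g)),
               files), manifest)
  invisible(manifest)
}

profile_columns <- c("rank", "delta_m", "delta_std", "delta_m_low",
                     "delta_m_high", "delta_std_low", "delta_std_high",
                     "defined")

#' Save a delta profile to a delimited text file
#'
#' Columns: `rank, delta_m, delta_std, delta_m_low, delta_m_high,
#' delta_std_low, delta_std_high, defined`. Undefined ranks carry empty
#' value cells and `defined = false`. Profiles without boxes leave the box
#' columns empty. Values are written in full precision so that
#' [read_profile()] reproduces the profile exactly.
#'
#' @param p A `delta_profile`.
#' @param path Output path.
#' @param delimiter `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
save_profile <- function(p, path, delimiter = "comma") {
  stopifnot(inherits(p, "delta_profile"))
  sep <- if (delimiter == "tab") "\t" else ","
  L <- length(p$rank)
  empty <- rep(NA_real_, L)
  b <- p$boxes
  num <- cbind(delta_m = p$delta_m, delta_std = p$delta_std,
               delta_m_low = if (is.null(b)) empty else b$delta_m_low,
               delta_m_high = if (is.null(b)) empty else b$delta_m_high,
               delta_std_low = if (is.null(b)) empty else b$delta_std_low,
               delta_std_high = if (is.null(b)) empty else b$delta_std_high)
  chr <- format_full(num)
  dim(chr) <- dim(num)
  chr[is.na(num)] <- ""
  out <- data.frame(rank = p$rank, chr,
                    defined = ifelse(p$defined, "true", "false"))
  names(out) <- profile_columns
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delta profile written by [save_profile()]
#'
#' @param path Profile file path.
#' @param delimiter `"auto"` (default), `"comma"` or `"tab"`.
#' @return A `delta_profile`.
#' @export
read_profile <- function(path, delimiter = "auto") {
  if (!file.exists(path)) {
    stop(sprintf("profile '%s' does not exist", path), call. = FALSE)
  }
  sep <- resolve_delimiter(delimiter, path)
  d <- read.table(path, sep = sep, header = TRUE,
                  colClasses = c("integer", rep("numeric", 6L), "character"))
  if (!identical(names(d), profile_columns)) {
    stop(sprintf("'%s' does not have the profile column contract (%s)", path,
                 paste(profile_columns, collapse = ", ")), call. = FALSE)
  }
  boxes <- NULL
  if (any(!is.na(d$delta_m_low))) {
    boxes <- d[, c("delta_m_low", "delta_m_high", "delta_std_low",
                   "delta_std_high")]
    rownames(boxes) <- NULL
  }
  prof <- new_delta_profile(d$delta_m, d$delta_std, d$defined == "true",
                            boxes = boxes)
  prof$rank <- d$rank
  prof
}
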