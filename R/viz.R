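#' Plot a delta profile in the DeltaStd-DeltaM plane
#'
#' One marker per defined ranking position at `(delta_std, delta_m)`,
#' coloured from blue (weakest rank) to red (strongest). Positive values on
#' the Y axis mean the second group has the stronger links on average at
#' that rank; positive values on the X axis, the larger variability. If the
#' profile carries uncertainty boxes, a semi-transparent axis-aligned
#' rectangle spanning the 16th-84th half-subsample percentiles is drawn
#' behind each marker. Origin cross-hairs mark the no-difference point.
#'
#' @param p A `delta_profile` with at least one defined rank.
#' @param path Output file path; the device is chosen from its extension
#'   (`.png`, `.pdf` or `.svg`) unless `format` is given.
#' @param format Optional explicit image format (`"png"`, `"pdf"`, `"svg"`).
#' @param title Optional plot title.
#' @param box_opacity Box fill opacity in (0, 1] (default 0.2).
#' @param point_size Marker size (default 2).
#' @param width,height,dpi Device size in inches and resolution.
#' @return The output path, invisibly. The ggplot object is attached as
#'   attribute `"plot"`.
#' @export
plot_delta_plane <- function(p, path, format = NULL, title = NULL,
                             box_opacity = 0.2, point_size = 2,
                             width = 6, height = 5, dpi = 150) {
  stopifnot(inherits(p, "delta_profile"))
  if (!any(p$defined)) {
    stop("cannot plot: no ranking position has a defined delta value",
         call. = FALSE)
  }
  if (!(box_opacity > 0 && box_opacity <= 1)) {
    stop("`box_opacity` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!nzchar(format)) format <- "png"
  }
  if (!format %in% c("png", "pdf", "svg")) {
    stop(sprintf("unsupported image format '%s' (png, pdf or svg)", format),
         call. = FALSE)
  }
  n_undef <- sum(!p$defined)
  if (n_undef > 0L) {
    message(sprintf("omitting %d undefined ranking position(s) from the plot",
                    n_undef))
  }
  d <- as.data.frame(p)
  d <- d[d$defined, , drop = FALSE]
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_std,
                                        y = .data$delta_m)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey40")
  if (!is.null(p$boxes)) {
    gg <- gg + ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$delta_std_low, xmax = .data$delta_std_high,
                   ymin = .data$delta_m_low, ymax = .data$delta_m_high,
                   fill = .data$color_value),
      alpha = box_opacity, colour = NA)
  }
  gg <- gg +
    ggplot2::geom_point(ggplot2::aes(colour = .data$color_value),
                        size = point_size) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   limits = c(0, 1), guide = "none") +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::labs(x = expression(Delta * Std), y = expression(Delta * M),
                  title = title) +
    ggplot2::theme_classic()
  ggplot2::ggsave(path, gg, device = format, width = width, height = height,
                  dpi = dpi)
  out <- invisible(path)
  attr(out, "plot") <- gg
  invisible(out)
}

#' @importFrom ggplot2 .data
NULL
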