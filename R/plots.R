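#' Draw an AHA 17-segment bullseye polar map
#'
#' Renders per-segment values in the package's fixed angular convention
#' (anterior up, septum left; see [aha_segment_of()]): rings base
#' (outside) to apex (center), basal/mid rings in six 60-degree sectors,
#' apical ring in four 90-degree sectors, apex as the central disc.
#'
#' @param values numeric vector of 17 per-segment values.
#' @param file optional output file; `.png` uses the png device when
#'   available, otherwise a `.pdf` fallback is written.
#' @param limits value range mapped onto the palette.
#' @param palette function(n) returning colors (default blue-green-red,
#'   the under/equal/over convention of score-error maps).
#' @param main plot title.
#' @return invisibly, the file written (or `NULL` when drawn on the
#'   current device).
#' @export
plot_bullseye <- function(values, file = NULL, limits = range(values),
                          palette = NULL, main = "") {
  stopifnot(length(values) == 17L)
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#2166ac", "#1a9850", "#d73027"))
  cols <- palette(64L)
  if (diff(range(limits)) == 0) limits <- limits + c(-1, 1)
  idx <- pmin(pmax(round((values - limits[1]) / diff(limits) * 63) + 1, 1), 64)
  file <- open_plot_file(file, 480, 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  graphics::title(main)
  radii <- c(1, 0.75, 0.5, 0.25)   # outer radius of basal/mid/apical/apex
  sector <- function(r0, r1, a0, a1, col) {
    th <- seq(a0, a1, length.out = 40) * pi / 180
    graphics::polygon(c(r1 * cos(th), r0 * cos(rev(th))),
                      c(r1 * sin(th), r0 * sin(rev(th))),
                      col = col, border = "white")
  }
  for (s in 1:6) {   # basal #1..#6 then mid #7..#12
    a0 <- c(60, 120, 180, 240, 300, 0)[s]
    sector(radii[2], radii[1], a0, a0 + 60, cols[idx[s]])
    sector(radii[3], radii[2], a0, a0 + 60, cols[idx[s + 6]])
  }
  for (s in 13:16) {
    a0 <- c(45, 135, 225, 315)[s - 12]
    sector(radii[4], radii[3], a0, a0 + 90, cols[idx[s]])
  }
  th <- seq(0, 360, length.out = 90) * pi / 180
  graphics::polygon(radii[4] * cos(th), radii[4] * sin(th),
                    col = cols[idx[17]], border = "white")
  invisible(file)
}

#' Plot a joint histogram (log10(count + 1) color scale)
#'
#' @param jh a [joint_histogram()] result.
#' @param file optional output file (see [plot_bullseye()]).
#' @param main title.
#' @return invisibly, the file written.
#' @export
plot_joint_histogram <- function(jh, file = NULL, main = "") {
  file <- open_plot_file(file, 480, 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  mid <- (jh$edges[-1] + jh$edges[-length(jh$edges)]) / 2
  graphics::image(mid, mid, log10(jh$counts + 1),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "reference (PET) voxel value",
                  ylab = "test voxel value", main = main, useRaster = TRUE)
  invisible(file)
}

open_plot_file <- function(file, width, height) {
  if (is.null(file)) return(NULL)
  if (grepl("\\.png$", file) && isTRUE(capabilities("png")[["png"]])) {
    grDevices::png(file, width, height)
  } else {
    file <- sub("\\.png$", ".pdf", file)
    grDevices::pdf(file, width / 96, height / 96)
  }
  file
}
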