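#' Plot a slow-mode fluctuation profile
#'
#' Normalized squared-fluctuation profile against node index, with optional
#' domain shading and hinge markers.
#'
#' @param profile per-node numeric vector.
#' @param annotation optional domain annotation for background shading.
#' @param hinges optional 0-based hinge node indices (vertical dashes).
#' @param path optional PNG path; when given, the plot is written there.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_profile <- function(profile, annotation = NULL, hinges = NULL,
                         path = NULL) {
  draw <- function() {
    n <- length(profile)
    plot(0:(n - 1), profile, type = "l", xlab = "node index",
         ylab = "normalized squared fluctuation",
         main = "slow-mode profile")
    if (!is.null(annotation)) {
      shade <- grDevices::adjustcolor(
        c("steelblue", "orange"), alpha.f = 0.15)
      for (i in seq_len(nrow(annotation))) {
        graphics::rect(annotation$start[i], 0, annotation$end[i],
                       max(profile), col = shade[1 + i %% 2], border = NA)
        graphics::mtext(annotation$label[i], side = 3, line = 0, cex = 0.7,
                        at = (annotation$start[i] + annotation$end[i]) / 2)
      }
      graphics::lines(0:(n - 1), profile)
    }
    if (!is.null(hinges) && length(hinges) > 0L)
      graphics::abline(v = hinges, lty = 2, col = "red")
  }
  if (is.null(path)) {
    draw()
  } else {
    grDevices::png(path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Plot a cross-correlation map as a heat map
#'
#' Blue-to-red diverging scale anchored at `[-1, 1]`: blue anti-phase,
#' red in-phase, white uncorrelated.
#'
#' @param map a [cross_correlation()] result (or bare matrix in `[-1,1]`).
#' @param path optional PNG path.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_correlation_map <- function(map, path = NULL) {
  cmat <- if (inherits(map, "cross_correlation")) map$matrix else map
  n <- nrow(cmat)
  pal <- grDevices::colorRampPalette(
    c("blue", "white", "orangered"))(101)
  draw <- function() {
    graphics::image(0:(n - 1), 0:(n - 1), t(cmat), zlim = c(-1, 1),
                    col = pal, xlab = "residue index",
                    ylab = "residue index", main = "cross-correlation map",
                    useRaster = TRUE)
  }
  if (is.null(path)) {
    draw()
  } else {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}
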