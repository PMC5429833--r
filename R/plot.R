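#' Phasor plot of a field
#'
#' Renders the per-pixel phasors as a 2D histogram, with the mono-exponential
#' reference locus (the universal semicircle, or the deviated locus of an
#' undersampled scheme) overlaid — the standard diagnostic view of phasor
#' analysis.
#'
#' @param field A `phasor_field`.
#' @param locus Optional `reference_locus` to overlay (red). When `NULL`,
#'   the universal semicircle is drawn for orientation.
#' @param bins Histogram bins per axis.
#' @param rois Optional list of [phasor_roi()]s to outline.
#' @param main Plot title.
#' @return Invisibly, the binned count matrix.
#' @export
plot_phasor <- function(field, locus = NULL, bins = 128L, rois = NULL,
                        main = "phasor plot") {
  stopifnot(inherits(field, "phasor_field"))
  pts <- valid_phasors(field)
  xlim <- c(-0.05, 1.05)
  ylim0 <- range(c(0, pts[, 2L], if (!is.null(locus)) locus$im), finite = TRUE)
  ylim <- ylim0 + c(-0.05, 0.05)
  bx <- seq(xlim[1L], xlim[2L], length.out = bins + 1L)
  by <- seq(ylim[1L], ylim[2L], length.out = bins + 1L)
  keep <- pts[, 1L] >= xlim[1L] & pts[, 1L] <= xlim[2L] &
    pts[, 2L] >= ylim[1L] & pts[, 2L] <= ylim[2L]
  cx <- cut(pts[keep, 1L], bx, include.lowest = TRUE)
  cy <- cut(pts[keep, 2L], by, include.lowest = TRUE)
  counts <- table(cx, cy)
  img <- log1p(unclass(counts))
  graphics::image(x = (bx[-1L] + bx[-length(bx)]) / 2,
                  y = (by[-1L] + by[-length(by)]) / 2,
                  z = img, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "Re", ylab = "Im", main = main, useRaster = TRUE)
  if (is.null(locus)) {
    th <- seq(0, pi, length.out = 181L)
    graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), col = "white",
                    lty = 2)
  } else {
    graphics::lines(locus$re, locus$im, col = "red", lwd = 2)
  }
  if (!is.null(rois)) {
    for (r in rois) {
      v <- rbind(r$vertices, r$vertices[1L, ])
      graphics::lines(v[, 1L], v[, 2L], col = r$color, lwd = 2)
    }
  }
  invisible(counts)
}
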