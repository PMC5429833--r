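#' Polygonal region of interest in phasor space
#'
#' A simple (non-self-intersecting) polygon drawn in the phasor plot,
#' used to select pixels by their phasor coordinates. ROIs are plain data
#' (vertex list + label + display color) and serialize to JSON via
#' [write_rois()], so "hand-drawn" selections are reproducible without a GUI.
#'
#' @param vertices Two-column matrix (re, im) of at least 3 vertices.
#' @param label Character label.
#' @param color Display color (any R color).
#' @return A `phasor_roi`.
#' @export
phasor_roi <- function(vertices, label, color = "red") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("ROI needs a 2-column matrix of at least 3 (re, im) vertices",
         call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("ROI vertices must be finite",
                                      call. = FALSE)
  if (polygon_self_intersects(vertices)) {
    stop("ROI polygon is self-intersecting; must be simple", call. = FALSE)
  }
  structure(list(vertices = vertices, label = as.character(label),
                 color = color),
            class = "phasor_roi")
}

#' Sector-shaped phasor ROI
#'
#' Convenience constructor for an annular-sector polygon: the natural ROI
#' shape for spectral phasors, where the angle encodes peak position and the
#' radius shrinks with baseline contamination, so a wedge selects one peak
#' position at any baseline level.
#'
#' @param angle_min,angle_max Phase range in radians (`atan2(im, re)`).
#' @param r_min,r_max Radial range.
#' @param label,color As in [phasor_roi()].
#' @param n_arc Vertices per arc.
#' @return A [phasor_roi()].
#' @export
roi_sector <- function(angle_min, angle_max, r_min = 0.02, r_max = 1.05,
                       label = "sector", color = "red", n_arc = 24L) {
  stopifnot(angle_max > angle_min, r_max > r_min, r_min >= 0)
  th <- seq(angle_min, angle_max, length.out = n_arc)
  v <- rbind(cbind(r_min * cos(th), r_min * sin(th)),
             cbind(r_max * cos(rev(th)), r_max * sin(rev(th))))
  phasor_roi(v, label, color)
}

## Proper-crossing test for non-adjacent edge pairs (simple-polygon check).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (bx - ox) * (ay - oy)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1L], a[2L], a[3L], a[4L], b[1L], b[2L])
      d2 <- cross2(a[1L], a[2L], a[3L], a[4L], b[3L], b[4L])
      d3 <- cross2(b[1L], b[2L], b[3L], b[4L], a[1L], a[2L])
      d4 <- cross2(b[1L], b[2L], b[3L], b[4L], a[3L], a[4L])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

## Even-odd point-in-polygon, boundary inclusive; vectorized over points.
points_in_polygon <- function(px, py, poly, eps = 1e-12) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    ## boundary: point within eps of segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2,
                                 0), 1) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    ## even-odd ray cast
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Segment pixels by phasor-space regions
#'
#' Assigns each valid pixel to the first ROI whose polygon contains its
#' phasor (even-odd rule, boundary inclusive). Overlapping ROIs are resolved
#' by ROI order, with a warning reporting the overlap fraction. Segmentation
#' is a pure function of phasor coordinates: pixels anywhere in the image
#' with the same phasor receive the same label.
#'
#' @param field A `phasor_field`.
#' @param rois List of [phasor_roi()]s.
#' @return A `segment_map`: integer array `labels` over the spatial grid
#'   (0 = unassigned) and a `legend` data frame (label, name, color, n).
#' @export
segment_phasors <- function(field, rois) {
  stopifnot(inherits(field, "phasor_field"))
  if (inherits(rois, "phasor_roi")) rois <- list(rois)
  stopifnot(length(rois) >= 1L,
            all(vapply(rois, inherits, logical(1), "phasor_roi")))
  re <- as.vector(field$re); im <- as.vector(field$im)
  valid <- as.vector(field$valid)
  lab <- integer(length(re))
  hits <- integer(length(re))
  for (r in seq_along(rois)) {
    inr <- valid & points_in_polygon(re, im, rois[[r]]$vertices)
    inr[is.na(inr)] <- FALSE
    hits <- hits + inr
    lab[inr & lab == 0L] <- r
  }
  n_overlap <- sum(hits > 1L)
  if (n_overlap > 0L) {
    warning(sprintf(
      "ROIs overlap: %d pixels (%.2f%% of assigned) matched >1 ROI; %s",
      n_overlap, 100 * n_overlap / max(sum(lab > 0L), 1L),
      "first ROI in list order wins"))
  }
  legend <- data.frame(
    label = seq_along(rois),
    name = vapply(rois, function(r) r$label, character(1)),
    color = vapply(rois, function(r) r$color[1L], character(1)),
    n = vapply(seq_along(rois), function(r) sum(lab == r), integer(1)))
  structure(list(labels = array(lab, dim(field$re)), legend = legend),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %s, %d segments, %d unassigned pixels\n",
              paste(dim(x$labels), collapse = " x "), nrow(x$legend),
              sum(x$labels == 0L)))
  print(x$legend)
  invisible(x)
}

#' Mean raw signal per segment
#'
#' Arithmetic mean of the raw (unnormalized) signals over the pixels of each
#' segment, per non-spatial step — the per-region average decay curves /
#' spectra of a phasor segmentation. Empty segments yield `NaN` means with
#' count 0.
#'
#' @param stack The [signal_stack()] the segmentation was computed from.
#' @param seg A [segment_phasors()] result.
#' @return Long-format data frame with columns `label`, `name`, `step`,
#'   `axis_value`, `mean_signal`, `n_pixels`.
#' @export
mean_signal_per_segment <- function(stack, seg) {
  stopifnot(inherits(stack, "signal_stack"), inherits(seg, "segment_map"))
  d <- dim(stack$data); nd <- length(d)
  if (!identical(unname(d[-nd]), unname(dim(seg$labels)))) {
    stop("stack and segment map have different spatial dimensions",
         call. = FALSE)
  }
  n <- stack$axis$n
  m <- matrix(stack$data, ncol = n)
  lab <- as.vector(seg$labels)
  out <- do.call(rbind, lapply(seq_len(nrow(seg$legend)), function(r) {
    sel <- lab == r
    cnt <- sum(sel)
    mu <- if (cnt > 0L) colMeans(m[sel, , drop = FALSE]) else rep(NaN, n)
    data.frame(label = r, name = seg$legend$name[r], step = seq_len(n),
               axis_value = stack$axis$values, mean_signal = mu,
               n_pixels = cnt, row.names = NULL)
  }))
  out
}

#' Back-project a phasor segmentation into image space
#'
#' Composites the segment colors over an optional grayscale background image
#' (alpha blending); unassigned pixels show the background only.
#'
#' @param seg A [segment_phasors()] result.
#' @param background Optional numeric array matching the spatial grid
#'   (e.g. the intensity image); rescaled to `[0, 1]`.
#' @param alpha Opacity of the segment colors over the background.
#' @return Numeric array (spatial dims x 3), RGB in `[0, 1]`.
#' @export
backproject <- function(seg, background = NULL, alpha = 0.7) {
  stopifnot(inherits(seg, "segment_map"))
  sdim <- dim(seg$labels)
  npix <- prod(sdim)
  bg <- if (is.null(background)) rep(0, npix) else {
    b <- as.vector(background)
    stopifnot(length(b) == npix)
    rng <- range(b, finite = TRUE)
    if (diff(rng) > 0) (b - rng[1L]) / diff(rng) else b * 0
  }
  out <- matrix(bg, npix, 3L)
  lab <- as.vector(seg$labels)
  cols <- grDevices::col2rgb(seg$legend$color) / 255
  for (r in seq_len(nrow(seg$legend))) {
    sel <- lab == r
    if (!any(sel)) next
    for (ch in 1:3) {
      out[sel, ch] <- (1 - alpha) * out[sel, ch] + alpha * cols[ch, r]
    }
  }
  array(out, c(sdim, 3L))
}
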