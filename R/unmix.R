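#' Reference component set for unmixing
#'
#' Two or three labeled reference phasors (endmembers). References normally
#' sit on the mono-exponential locus, but off-locus references are allowed
#' (e.g. a reference deliberately moved toward the center of a phasor cloud
#' for display); no automatic shifting is ever performed.
#'
#' @param points List of [phasor_point()]s (length 2 or 3), or a 2-column
#'   matrix of (re, im) rows.
#' @param labels Character labels, one per reference.
#' @param taus Optional generating decay constants (documentation only).
#' @return A `component_set`.
#' @export
component_set <- function(points, labels = NULL, taus = NULL) {
  if (is.matrix(points)) {
    points <- apply(points, 1L, function(r) phasor_point(r[1L], r[2L]),
                    simplify = FALSE)
  }
  k <- length(points)
  if (!k %in% c(2L, 3L)) {
    stop("a component_set holds 2 or 3 references", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("component", seq_len(k))
  if (length(labels) != k) stop("one label per reference", call. = FALSE)
  m <- t(vapply(points, function(p) c(p$re, p$im), numeric(2)))
  if (min(stats::dist(m)) < 1e-9) {
    stop("reference phasors must be pairwise distinct", call. = FALSE)
  }
  if (k == 3L && abs(signed_area(m[1L, ], m[2L, ], m[3L, ])) < 1e-9) {
    stop("three references are (near-)collinear; triangle unmixing ill-posed",
         call. = FALSE)
  }
  structure(list(refs = points, labels = labels, taus = taus, coords = m),
            class = "component_set")
}

#' Component set from decay constants on a sampling axis
#'
#' Places each reference at the phasor of `exp(-x/tau)` on the given axis,
#' i.e. on the (possibly deviated) mono-exponential locus.
#'
#' @param axis A [sampled_axis()].
#' @param taus 2 or 3 decay constants in axis units.
#' @param labels Optional labels (default the tau values).
#' @param harmonic Harmonic, default 1.
#' @return A `component_set`.
#' @export
component_set_from_taus <- function(axis, taus, labels = NULL, harmonic = 1L) {
  g <- mono_exp_phasor(axis, taus, harmonic)
  if (is.null(labels)) labels <- paste0("tau=", signif(taus, 4))
  pts <- lapply(seq_along(taus), function(i) phasor_point(Re(g[i]), Im(g[i])))
  component_set(pts, labels, taus = taus)
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d references: %s\n", length(x$refs),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

## Twice the signed area of triangle (a, b, c); sign encodes orientation.
signed_area <- function(a, b, c) {
  ((b[1L] - a[1L]) * (c[2L] - a[2L]) - (c[1L] - a[1L]) * (b[2L] - a[2L])) / 2
}

#' Three-component barycentric unmixing of a phasor
#'
#' The fraction of component i is the signed area of the triangle formed by
#' the phasor and the two opposing references, divided by the signed area of
#' the reference triangle. The three fractions are barycentric coordinates
#' and sum to exactly 1; points outside the reference triangle yield negative
#' fractions, which are reported as-is (display clamping is separate) so that
#' model violations stay visible.
#'
#' @param p A [phasor_point()].
#' @param refs A [component_set()] of 3.
#' @return Named numeric vector of 3 fractions (labels from `refs`), with
#'   attribute `"inside"` (`TRUE` when all fractions are in `[0, 1]`).
#' @export
unmix_three <- function(p, refs) {
  stopifnot(inherits(refs, "component_set"))
  if (length(refs$refs) != 3L) stop("unmix_three needs 3 references",
                                    call. = FALSE)
  m <- refs$coords
  q <- c(p$re, p$im)
  total <- signed_area(m[1L, ], m[2L, ], m[3L, ])
  f <- c(signed_area(q, m[2L, ], m[3L, ]),
         signed_area(m[1L, ], q, m[3L, ]),
         signed_area(m[1L, ], m[2L, ], q)) / total
  names(f) <- refs$labels
  attr(f, "inside") <- all(f >= -1e-12 & f <= 1 + 1e-12)
  f
}

#' Two-component unmixing of a phasor
#'
#' The fraction of the first component is the orthogonal projection parameter
#' of the phasor onto the segment from reference 2 to reference 1; fractions
#' sum to 1. Exact for noiseless mixtures, a least-squares projection for
#' noisy points off the chord.
#'
#' @param p A [phasor_point()].
#' @param refs A [component_set()] of 2.
#' @return Named numeric vector of 2 fractions, attribute `"inside"` as in
#'   [unmix_three()].
#' @export
unmix_two <- function(p, refs) {
  stopifnot(inherits(refs, "component_set"))
  if (length(refs$refs) != 2L) stop("unmix_two needs 2 references",
                                    call. = FALSE)
  r1 <- refs$coords[1L, ]; r2 <- refs$coords[2L, ]
  v <- r1 - r2
  f1 <- sum((c(p$re, p$im) - r2) * v) / sum(v * v)
  f <- c(f1, 1 - f1)
  names(f) <- refs$labels
  attr(f, "inside") <- all(f >= -1e-12 & f <= 1 + 1e-12)
  f
}

#' Per-pixel fraction maps from a phasor field
#'
#' Lifts [unmix_two()]/[unmix_three()] over all valid pixels of a field.
#' Raw (possibly negative or >1) fractions are retained for analysis; use
#' [fractions_rgb()] for a display composite with fractions clamped to
#' `[0, 1]`.
#'
#' @param field A `phasor_field`.
#' @param refs A [component_set()].
#' @return A `fraction_maps`: array `fractions` (spatial dims x n_components,
#'   `NA` where invalid), logical `clamp` marking pixels with any raw
#'   fraction outside `[0, 1]`, `labels`, and the `refs` used.
#' @export
fraction_maps <- function(field, refs) {
  stopifnot(inherits(field, "phasor_field"), inherits(refs, "component_set"))
  k <- length(refs$refs)
  sdim <- dim(field$re)
  re <- as.vector(field$re); im <- as.vector(field$im)
  valid <- as.vector(field$valid)
  fr <- matrix(NA_real_, length(re), k)
  m <- refs$coords
  if (k == 3L) {
    total <- signed_area(m[1L, ], m[2L, ], m[3L, ])
    ## vectorized barycentric coordinates
    f1 <- ((m[2L, 1L] - re) * (m[3L, 2L] - im) -
           (m[3L, 1L] - re) * (m[2L, 2L] - im)) / (2 * total)
    f2 <- ((re - m[1L, 1L]) * (m[3L, 2L] - m[1L, 2L]) -
           (m[3L, 1L] - m[1L, 1L]) * (im - m[1L, 2L])) / (2 * total)
    fr[, 1L] <- f1; fr[, 2L] <- f2; fr[, 3L] <- 1 - f1 - f2
  } else {
    v <- m[1L, ] - m[2L, ]
    f1 <- ((re - m[2L, 1L]) * v[1L] + (im - m[2L, 2L]) * v[2L]) / sum(v * v)
    fr[, 1L] <- f1; fr[, 2L] <- 1 - f1
  }
  fr[!valid, ] <- NA_real_
  clamp <- valid & apply(fr < -1e-12 | fr > 1 + 1e-12, 1L, any)
  clamp[!valid] <- FALSE
  structure(list(fractions = array(fr, c(sdim, k)),
                 clamp = array(clamp, sdim),
                 labels = refs$labels, refs = refs),
            class = "fraction_maps")
}

#' RGB display composite of fraction maps
#'
#' @param fm A [fraction_maps()] result with 3 components (mapped to R, G, B
#'   in order) or 2 components (R, G; B = 0).
#' @return Numeric array (spatial dims x 3) in `[0, 1]`; invalid pixels 0.
#' @export
fractions_rgb <- function(fm) {
  stopifnot(inherits(fm, "fraction_maps"))
  d <- dim(fm$fractions)
  k <- d[length(d)]
  sdim <- d[-length(d)]
  rgb <- array(0, c(sdim, 3L))
  fr <- matrix(fm$fractions, ncol = k)
  fr[is.na(fr)] <- 0
  fr <- pmin(pmax(fr, 0), 1)
  for (i in seq_len(min(k, 3L))) {
    rgb[slice.index(rgb, length(sdim) + 1L) == i] <- fr[, i]
  }
  rgb
}

#' @export
print.fraction_maps <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<fraction_maps> %s, components: %s, %d clamped pixels\n",
              paste(d[-length(d)], collapse = " x "),
              paste(x$labels, collapse = ", "), sum(x$clamp)))
  invisible(x)
}

#' Estimate component endmembers by extrapolating a phasor cloud
#'
#' Fits a total-least-squares (principal-axis) line through an elongated
#' two-component phasor cloud and intersects it with the mono-exponential
#' reference locus; the two intersection decay constants are the component
#' endmembers (the "red line" construction used to read off component T2s or
#' ADCs from a cloud). If the line misses the locus on one side — as happens
#' with noise — the locus point closest to the line is returned instead and
#' flagged.
#'
#' @param points Two-column matrix of (re, im) phasors (e.g. from
#'   [valid_phasors()]), at least 10 rows.
#' @param locus A `reference_locus`.
#' @param min_axis_ratio Minimum principal-axis standard-deviation ratio for
#'   the cloud to count as elongated (default 3).
#' @return List with `tau` (sorted c(tau_short, tau_long), axis units),
#'   `flags` per endpoint (`"intersect"` or `"nearest"`), `center` and
#'   `direction` of the fitted line, and `axis_ratio`.
#' @export
extrapolate_cloud_to_locus <- function(points, locus, min_axis_ratio = 3) {
  stopifnot(inherits(locus, "reference_locus"))
  points <- as.matrix(points)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 10L) {
    stop("need at least 10 phasor points to extrapolate a cloud",
         call. = FALSE)
  }
  ctr <- colMeans(points)
  cv <- stats::cov(points)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1L] <= 1e-20) {
    stop("degenerate cloud: all points (near-)identical", call. = FALSE)
  }
  ratio <- sqrt(ev$values[1L] / max(ev$values[2L], 1e-30))
  if (ratio < min_axis_ratio) {
    stop(sprintf(paste0(
      "phasor cloud is not elongated (principal-axis ratio %.2f < %.2f); ",
      "two-reference unmixing along a line is ill-posed for this cloud"),
      ratio, min_axis_ratio), call. = FALSE)
  }
  v <- ev$vectors[, 1L]           # direction of the TLS line
  nrm <- c(-v[2L], v[1L])         # unit normal

  ## signed offset of each locus point from the line
  off <- (locus$re - ctr[1L]) * nrm[1L] + (locus$im - ctr[2L]) * nrm[2L]
  sgn <- sign(off)
  cross_idx <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  taus <- numeric(0)
  for (i in cross_idx) {
    f <- function(tt) {
      g <- mono_exp_phasor(locus$axis, tt, locus$harmonic)
      (Re(g) - ctr[1L]) * nrm[1L] + (Im(g) - ctr[2L]) * nrm[2L]
    }
    taus <- c(taus, stats::uniroot(f, lower = locus$taus[i],
                                   upper = locus$taus[i + 1L],
                                   tol = 1e-10)$root)
  }
  flags <- rep("intersect", length(taus))
  if (length(taus) < 2L) {
    warning(sprintf(paste0("TLS line intersects the reference locus %d ",
                           "time(s); using nearest locus point(s)"),
                    length(taus)))
    ord <- order(abs(off))
    for (j in ord) {
      if (length(taus) >= 2L) break
      cand <- locus$taus[j]
      if (all(abs(log(cand / taus)) > 0.05) || length(taus) == 0L) {
        taus <- c(taus, cand)
        flags <- c(flags, "nearest")
      }
    }
  }
  ord <- order(taus)
  pick <- c(ord[1L], ord[length(ord)])   # shortest and longest tau
  list(tau = taus[pick], flags = flags[pick],
       center = ctr, direction = v, axis_ratio = ratio)
}
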