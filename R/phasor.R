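#' First-harmonic phasor of a single signal
#'
#' Computes the normalized discrete Fourier coefficient
#' \deqn{G = \frac{\sum_{k=0}^{n-1} s_k\, e^{+i 2\pi h k/n}}{\sum_{k=0}^{n-1} s_k}}
#' of a decay curve or spectrum and returns it as a point (Re, Im) in the
#' phasor plot. The kernel sign is fixed so that decaying signals have
#' Im >= 0 and the fast-decay limit (all signal in the first sample) maps to
#' (1, 0); the slow-decay limit (constant signal) maps to (0, 0). The index k
#' starts at 0 at the first acquired sample regardless of its absolute
#' time/b-value, so the phasor depends only on curve shape; absolute axis
#' values enter only through the reference locus (see
#' [build_reference_locus()]).
#'
#' The phasor is invariant under multiplication of the signal by any positive
#' scalar, and the phasor of a sum of signals is the integral-weighted vector
#' sum of the component phasors — the geometric linearity that all unmixing in
#' this package relies on.
#'
#' @param signal Numeric vector, length >= 3, finite, with positive total sum.
#' @param harmonic Positive integer harmonic, `harmonic < n/2`. The first
#'   harmonic is the standard phasor-plot coordinate.
#' @return A `phasor_point`: list with numeric fields `re` and `im`.
#' @examples
#' compute_phasor(exp(-(0:63) * 7.23 / 105))   # mono-exponential T2 decay
#' compute_phasor(c(1, rep(0, 63)))            # fast-decay limit -> (1, 0)
#' @export
compute_phasor <- function(signal, harmonic = 1L) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 3L) stop("signal must have at least 3 samples", call. = FALSE)
  if (any(!is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L || harmonic >= n / 2) {
    stop("harmonic must satisfy 1 <= harmonic < n/2", call. = FALSE)
  }
  total <- sum(signal)
  if (total <= 0) {
    stop("total signal must be positive for phasor normalization",
         call. = FALSE)
  }
  k <- 0:(n - 1L)
  g <- sum(signal * exp(2i * pi * harmonic * k / n)) / total
  phasor_point(Re(g), Im(g))
}

#' Construct a phasor point
#' @param re,im Real and imaginary phasor coordinates.
#' @return A `phasor_point`.
#' @export
phasor_point <- function(re, im) {
  structure(list(re = as.numeric(re), im = as.numeric(im)),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> (%.6f, %.6f)  |G| = %.6f  phase = %.6f rad\n",
              x$re, x$im, phasor_modulus(x), phasor_phase(x)))
  invisible(x)
}

#' Modulus and phase of a phasor point
#' @param p A `phasor_point` (or anything with `re`/`im` fields).
#' @return Numeric scalar.
#' @export
phasor_modulus <- function(p) sqrt(p$re^2 + p$im^2)

#' @rdname phasor_modulus
#' @export
phasor_phase <- function(p) atan2(p$im, p$re)

## Box mean filter with window shrink at image borders, via integral image.
## radius r means a (2r+1) x (2r+1) square neighborhood.
box_mean <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(nr); j <- seq_len(nc)
  i1 <- pmax(i - r, 1L); i2 <- pmin(i + r, nr)
  j1 <- pmax(j - r, 1L); j2 <- pmin(j + r, nc)
  s <- ii[cbind(rep(i2 + 1L, nc), rep(j2 + 1L, each = nr))] -
       ii[cbind(rep(i1,      nc), rep(j2 + 1L, each = nr))] -
       ii[cbind(rep(i2 + 1L, nc), rep(j1,      each = nr))] +
       ii[cbind(rep(i1,      nc), rep(j1,      each = nr))]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  matrix(s, nr, nc) / cnt
}

#' Per-pixel phasor field of a stack
#'
#' Computes the first-harmonic phasor of every pixel of a [signal_stack()].
#' A square mean filter (radius `mean_filter_radius`, shrinking at image
#' borders) is applied to each non-spatial step before the transform, and
#' pixels whose total (filtered) intensity falls below the threshold are
#' marked invalid and excluded from all downstream statistics.
#'
#' @param stack A [signal_stack()].
#' @param harmonic Harmonic number, default 1.
#' @param threshold Intensity threshold. With `threshold_type = "fraction"`
#'   (default) it is a fraction of the 99th-percentile total intensity
#'   (default 0.05); with `"absolute"` it is an absolute total-intensity
#'   value.
#' @param threshold_type `"fraction"` or `"absolute"`.
#' @param mean_filter_radius Integer >= 0; the standard pre-filter of phasor
#'   analysis uses radius 1.
#' @return A `phasor_field`: arrays `re`, `im`, `intensity` over the spatial
#'   grid, logical mask `valid`, plus the `axis` and `harmonic` used. Invalid
#'   pixels carry `NA` in `re`/`im`.
#' @export
compute_phasor_field <- function(stack, harmonic = 1L, threshold = 0.05,
                                 threshold_type = c("fraction", "absolute"),
                                 mean_filter_radius = 0L) {
  stopifnot(inherits(stack, "signal_stack"))
  threshold_type <- match.arg(threshold_type)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  mean_filter_radius <- as.integer(mean_filter_radius)
  if (mean_filter_radius < 0L) stop("mean_filter_radius must be >= 0",
                                    call. = FALSE)
  d <- dim(stack$data); nd <- length(d)
  n <- stack$axis$n
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L || harmonic >= n / 2) {
    stop("harmonic must satisfy 1 <= harmonic < n/2", call. = FALSE)
  }

  data <- stack$data
  if (mean_filter_radius > 0L) {
    if (nd == 3L) {
      for (k in seq_len(n)) {
        data[, , k] <- box_mean(data[, , k], mean_filter_radius)
      }
    } else {
      for (z in seq_len(d[3L])) for (k in seq_len(n)) {
        data[, , z, k] <- box_mean(data[, , z, k], mean_filter_radius)
      }
    }
  }

  sdim <- d[-nd]
  npix <- prod(sdim)
  m <- matrix(data, nrow = npix, ncol = n)
  total <- rowSums(m)
  k <- 0:(n - 1L)
  w <- exp(2i * pi * harmonic * k / n)
  g <- as.vector(m %*% w) / total

  valid <- is.finite(total) & total > 0
  if (threshold > 0) {
    thr <- if (threshold_type == "fraction") {
      threshold * stats::quantile(total[is.finite(total)], 0.99, names = FALSE)
    } else threshold
    valid <- valid & total >= thr
  }
  if (!any(valid)) {
    warning("no pixels pass the intensity threshold; empty phasor field")
  }
  re <- Re(g); im <- Im(g)
  re[!valid] <- NA_real_; im[!valid] <- NA_real_
  intensity <- pmax(total, 0)

  structure(list(re = array(re, sdim), im = array(im, sdim),
                 intensity = array(intensity, sdim),
                 valid = array(valid, sdim),
                 axis = stack$axis, harmonic = harmonic),
            class = "phasor_field")
}

#' Valid phasors of a field as a matrix
#'
#' @param field A `phasor_field`.
#' @return Two-column matrix `(re, im)` of the valid pixels, with attribute
#'   `"index"` giving their linear pixel indices.
#' @export
valid_phasors <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  idx <- which(field$valid)
  out <- cbind(re = as.vector(field$re)[idx], im = as.vector(field$im)[idx])
  attr(out, "index") <- idx
  out
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %s, harmonic %d, %d/%d valid pixels, axis kind %s\n",
    paste(dim(x$re), collapse = " x "), x$harmonic,
    sum(x$valid), length(x$valid), x$axis$kind))
  invisible(x)
}
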