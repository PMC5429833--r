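#' Image stack with a non-spatial sampling axis
#'
#' A `signal_stack` bundles a magnitude-valued image array with the
#' [sampled_axis()] describing its last (non-spatial) dimension. Supported
#' layouts are `nx x ny x n` (single slice) and `nx x ny x nz x n`
#' (multi-slice); the last dimension always matches `axis$n`.
#'
#' @param data Numeric array, 3- or 4-dimensional, last dimension of length
#'   `axis$n`. Values must be finite; magnitude data are non-negative, but
#'   small negative values (e.g. spectral baseline noise) are accepted when
#'   `allow_negative = TRUE`.
#' @param axis A [sampled_axis()].
#' @param pixdim Optional numeric spatial spacing metadata (mm per pixel).
#' @param allow_negative Accept negative sample values (spectra).
#' @return An object of class `signal_stack`.
#' @export
signal_stack <- function(data, axis, pixdim = NULL, allow_negative = FALSE) {
  stopifnot(inherits(axis, "sampled_axis"))
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) {
    stop("stack data must be a 3D (x, y, step) or 4D (x, y, z, step) array",
         call. = FALSE)
  }
  if (dim(data)[nd] != axis$n) {
    stop(sprintf("last data dimension (%d) does not match axis length (%d)",
                 dim(data)[nd], axis$n), call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("stack data must be finite", call. = FALSE)
  }
  if (!allow_negative && any(data < 0)) {
    stop(paste0("stack data contain negative values; magnitude data are ",
                "non-negative (use allow_negative = TRUE for raw spectra)"),
         call. = FALSE)
  }
  structure(list(data = data, axis = axis, pixdim = pixdim),
            class = "signal_stack")
}

#' Spatial dimensions of a stack
#' @param stack A [signal_stack()].
#' @return Integer vector of the spatial dimensions.
#' @export
spatial_dim <- function(stack) {
  stopifnot(inherits(stack, "signal_stack"))
  d <- dim(stack$data)
  d[-length(d)]
}

#' Restrict a stack to a subset of axis steps
#'
#' Returns the stack restricted to the selected non-spatial steps, with the
#' axis values subset accordingly. No interpolation is performed: downstream
#' phasor computation simply uses the reduced axis, which is how undersampled
#' acquisitions (e.g. keeping echo steps 2, 6, ..., 62, or 4, 20, 36, 52 of a
#' 64-echo train) are analyzed.
#'
#' @param stack A [signal_stack()].
#' @param indices Strictly increasing 1-based step indices (R convention,
#'   which coincides with printed echo-step numbering); at least 3.
#' @return A [signal_stack()] over the reduced axis.
#' @export
subsample_axis <- function(stack, indices) {
  stopifnot(inherits(stack, "signal_stack"))
  indices <- as.integer(indices)
  if (length(indices) < 3L) {
    stop("at least 3 steps are required for phasor analysis", call. = FALSE)
  }
  if (any(diff(indices) <= 0L)) {
    stop("indices must be strictly increasing", call. = FALSE)
  }
  if (indices[1L] < 1L || indices[length(indices)] > stack$axis$n) {
    stop("indices out of range of the sampling axis", call. = FALSE)
  }
  nd <- length(dim(stack$data))
  newdata <- if (nd == 3L) stack$data[, , indices, drop = FALSE] else
    stack$data[, , , indices, drop = FALSE]
  signal_stack(newdata,
               sampled_axis(stack$axis$values[indices], stack$axis$kind),
               pixdim = stack$pixdim, allow_negative = TRUE)
}

#' @export
print.signal_stack <- function(x, ...) {
  cat(sprintf("<signal_stack> %s, axis: %s (n=%d, %s)\n",
              paste(dim(x$data), collapse = " x "),
              x$axis$kind, x$axis$n, axis_unit(x$axis)))
  invisible(x)
}
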