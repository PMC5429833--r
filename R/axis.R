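#' Sampling axis of the non-spatial dimension
#'
#' A `sampled_axis` holds the ordered sample coordinates of the non-spatial
#' dimension of a quantitative MRI stack: echo times (ms) for T2 relaxometry,
#' b-values (s/mm^2) for diffusion, or chemical-shift coordinates (ppm or
#' channel index) for spectroscopic imaging. The axis kind determines unit
#' labels downstream, never the phasor mathematics.
#'
#' @param values Numeric vector of sample coordinates, strictly increasing.
#' @param kind One of `"echo_time"`, `"b_value"`, `"chemical_shift"`.
#' @return An object of class `sampled_axis` with fields `values`, `kind`, `n`.
#' @examples
#' sampled_axis(7.23 * (1:64), "echo_time")
#' sampled_axis(c(0, seq(300, 1200, length.out = 12)), "b_value")
#' @export
sampled_axis <- function(values,
                         kind = c("echo_time", "b_value", "chemical_shift")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a sampled_axis needs at least 2 sample coordinates", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("axis values must all be finite", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("axis values must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, kind = kind, n = length(values)),
            class = "sampled_axis")
}

#' Unit label of a sampling axis
#'
#' @param axis A [sampled_axis()].
#' @return A unit string: `"ms"`, `"s/mm^2"` or `"ppm"`.
#' @export
axis_unit <- function(axis) {
  stopifnot(inherits(axis, "sampled_axis"))
  switch(axis$kind,
         echo_time = "ms",
         b_value = "s/mm^2",
         chemical_shift = "ppm")
}

#' @export
print.sampled_axis <- function(x, ...) {
  cat(sprintf("<sampled_axis> kind=%s n=%d range=[%g, %g] %s\n",
              x$kind, x$n, x$values[1L], x$values[x$n], axis_unit(x)))
  invisible(x)
}
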