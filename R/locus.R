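## Phasor of a mono-exponential decay exp(-x_rel/tau) on a given axis.
## x_rel is measured from the first acquired sample, consistent with
## compute_phasor's k = 0 origin; the overall factor exp(-x_0/tau) cancels in
## the normalization.
mono_exp_phasor <- function(axis, tau, harmonic = 1L) {
  x <- axis$values - axis$values[1L]
  n <- axis$n
  k <- 0:(n - 1L)
  w <- exp(2i * pi * harmonic * k / n)
  vapply(tau, function(tt) {
    s <- exp(-x / tt)
    sum(s * w) / sum(s)
  }, complex(1))
}

#' Mono-exponential reference locus for a sampling scheme
#'
#' Builds the curve traced in the phasor plot by pure mono-exponential decays
#' `exp(-x/tau)` sampled on the given axis, over a logarithmic grid of decay
#' constants. For dense, long sampling this locus approaches the universal
#' semicircle of radius 0.5 centered at (0.5, 0); for truncated or
#' undersampled schemes (e.g. 4 extracted echoes) it deviates from the
#' semicircle, and average-T2/ADC quantification must use this deviated locus
#' rather than the semicircle law.
#'
#' The phasor phase `atan2(Im, Re)` is strictly monotone in tau along the
#' locus (verified at build time); [invert_phasor_to_tau()] exploits this to
#' map measured phasors back to average decay constants.
#'
#' @param axis A [sampled_axis()] (echo times or b-values).
#' @param tau_min,tau_max Range of decay constants, in axis units (ms for echo
#'   time; s/mm^2 for b-value, i.e. 1/D). Defaults: 0.1 x the median axis
#'   spacing up to 100 x the axis span.
#' @param n_grid Number of logarithmically spaced grid points (>= 64).
#' @param harmonic Harmonic number, default 1.
#' @return A `reference_locus`: fields `taus`, `re`, `im`, `phase`, `axis`,
#'   `harmonic`.
#' @export
build_reference_locus <- function(axis, tau_min = NULL, tau_max = NULL,
                                  n_grid = 512L, harmonic = 1L) {
  stopifnot(inherits(axis, "sampled_axis"))
  dx <- stats::median(diff(axis$values))
  span <- axis$values[axis$n] - axis$values[1L]
  if (is.null(tau_min)) tau_min <- 0.1 * dx
  if (is.null(tau_max)) tau_max <- 100 * span
  if (!(tau_min > 0 && tau_max > tau_min)) {
    stop("need 0 < tau_min < tau_max", call. = FALSE)
  }
  n_grid <- as.integer(n_grid)
  if (n_grid < 64L) stop("n_grid must be >= 64", call. = FALSE)

  taus <- exp(seq(log(tau_min), log(tau_max), length.out = n_grid))
  g <- mono_exp_phasor(axis, taus, harmonic)
  phase <- atan2(Im(g), Re(g))
  if (any(diff(phase) <= 0)) {
    stop(paste0("reference phase is not strictly monotone in tau over the ",
                "requested grid; the axis is unsuitable for phase inversion ",
                "on this tau range"), call. = FALSE)
  }
  structure(list(taus = taus, re = Re(g), im = Im(g), phase = phase,
                 axis = axis, harmonic = harmonic),
            class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf(
    "<reference_locus> %d taus in [%g, %g] %s, phase in [%.4f, %.4f] rad\n",
    length(x$taus), x$taus[1L], x$taus[length(x$taus)], axis_unit(x$axis),
    x$phase[1L], x$phase[length(x$phase)]))
  invisible(x)
}

## Monotone interpolator phase -> log(tau) over the locus grid.
locus_interpolator <- function(locus) {
  stats::splinefun(locus$phase, log(locus$taus), method = "monoH.FC")
}

#' Invert a measured phasor to an average decay constant
#'
#' Maps a phasor point to the decay constant whose reference phase equals the
#' point's phase `atan2(Im, Re)`, by bracketed root finding on the monotone
#' reference locus. Only the phase coordinate is used: multi-exponential
#' mixtures leave the locus radially (toward the chord), so the phase is the
#' standard average-lifetime estimator and the modulus is ignored.
#'
#' @param p A [phasor_point()].
#' @param locus A [build_reference_locus()] result for the same axis.
#' @param refine If `TRUE` (default), polish the grid-interpolated solution
#'   with `uniroot` on the exact forward model; otherwise use monotone spline
#'   interpolation only.
#' @return The decay constant in axis units (ms, or s/mm^2 for b-value axes),
#'   with attribute `"flag"` equal to `"ok"`, `"below_range"`, `"above_range"`
#'   or `"slow_limit"` (phasor at the origin, infinite tau).
#' @export
invert_phasor_to_tau <- function(p, locus, refine = TRUE) {
  stopifnot(inherits(locus, "reference_locus"))
  if (!is.finite(p$re) || !is.finite(p$im)) {
    stop("phasor point must be finite", call. = FALSE)
  }
  if (phasor_modulus(p) < 1e-12) {
    out <- Inf
    attr(out, "flag") <- "slow_limit"
    return(out)
  }
  ph <- phasor_phase(p)
  ng <- length(locus$phase)
  if (ph < locus$phase[1L]) {
    warning("phasor phase below reference range; clipped to tau_min")
    out <- locus$taus[1L]; attr(out, "flag") <- "below_range"
    return(out)
  }
  if (ph > locus$phase[ng]) {
    warning("phasor phase above reference range; clipped to tau_max")
    out <- locus$taus[ng]; attr(out, "flag") <- "above_range"
    return(out)
  }
  tau <- exp(locus_interpolator(locus)(ph))
  if (refine) {
    i <- findInterval(ph, locus$phase)
    lo <- locus$taus[max(i, 1L)]
    hi <- locus$taus[min(i + 1L, ng)]
    if (hi > lo) {
      f <- function(tt) {
        g <- mono_exp_phasor(locus$axis, tt, locus$harmonic)
        atan2(Im(g), Re(g)) - ph
      }
      tau <- tryCatch(
        stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root,
        error = function(e) tau)
    }
  }
  attr(tau, "flag") <- "ok"
  tau
}

#' Average decay-constant map from a phasor field
#'
#' Applies the phase inversion of [invert_phasor_to_tau()] to every valid
#' pixel of a phasor field (via the monotone locus interpolator, which is
#' exact to well below the locus grid spacing). For b-value axes the inverted
#' constant `tau_b = 1/D` (s/mm^2) is converted to an apparent diffusion
#' coefficient in 1e-9 m^2/s: `D = 1000 / tau_b` (since
#' 1e-3 mm^2/s = 1e-9 m^2/s).
#'
#' @param field A `phasor_field` computed on the same axis as `locus`.
#' @param locus A `reference_locus`.
#' @return A `param_map`: array `value` (ms for echo-time axes, 1e-9 m^2/s
#'   for b-value axes; `NA` where invalid), logical `valid`, logical
#'   `clamped` marking pixels whose phase fell outside the locus range, and
#'   `units`.
#' @export
tau_map <- function(field, locus) {
  stopifnot(inherits(field, "phasor_field"), inherits(locus, "reference_locus"))
  if (!isTRUE(all.equal(field$axis$values, locus$axis$values))) {
    stop("locus was built for a different sampling axis than the field",
         call. = FALSE)
  }
  ph <- atan2(as.vector(field$im), as.vector(field$re))
  valid <- as.vector(field$valid)
  ng <- length(locus$phase)
  clamped <- valid & (ph < locus$phase[1L] | ph > locus$phase[ng])
  phc <- pmin(pmax(ph, locus$phase[1L]), locus$phase[ng])
  val <- rep(NA_real_, length(ph))
  val[valid] <- exp(locus_interpolator(locus)(phc[valid]))

  if (field$axis$kind == "b_value") {
    val <- 1000 / val   # tau_b in s/mm^2  ->  ADC in 1e-9 m^2/s
    units <- "1e-9 m^2/s"
  } else {
    units <- axis_unit(field$axis)
  }
  structure(list(value = array(val, dim(field$re)),
                 valid = array(valid, dim(field$re)),
                 clamped = array(clamped, dim(field$re)),
                 units = units, kind = field$axis$kind),
            class = "param_map")
}

#' Convert between 1/D decay constants and ADC units
#'
#' The diffusion signal decays as `exp(-b D)`, so on a b-value axis the
#' phasor decay constant is `tau_b = 1/D` in s/mm^2. With b in s/mm^2, D is
#' in mm^2/s and `1e-3 mm^2/s = 1e-9 m^2/s`, giving `ADC[1e-9 m^2/s] =
#' 1000 / tau_b`.
#'
#' @param tau_b Decay constant(s) on a b-value axis, s/mm^2.
#' @return ADC in 1e-9 m^2/s.
#' @export
tau_to_adc <- function(tau_b) 1000 / tau_b

#' @rdname tau_to_adc
#' @param adc ADC in 1e-9 m^2/s.
#' @export
adc_to_tau <- function(adc) 1000 / adc

#' @export
print.param_map <- function(x, ...) {
  v <- x$value[x$valid]
  cat(sprintf("<param_map> %s, %d valid pixels, median %.4g %s\n",
              paste(dim(x$value), collapse = " x "), sum(x$valid),
              stats::median(v, na.rm = TRUE), x$units))
  invisible(x)
}
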