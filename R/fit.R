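#' @name exp_fitting
#' @title Mono- and bi-exponential least-squares fitting
#'
#' @description
#' Iterative nonlinear least-squares fitting of per-pixel decays, the
#' classical baseline that phasor quantification is validated against.
#' `fit_monoexp()` minimizes `sum(s_k - A exp(-x_k/tau))^2`, initialized
#' from a log-linear regression of the first half of the samples;
#' `fit_biexp()` minimizes over `(A1, tau1, A2, tau2)` with `tau1 < tau2`
#' enforced by sorting and multiple starting points to reduce local minima.
#' Fitting failures are flagged, never thrown: non-convergence, decay
#' constants outside `[0.01, 100] x` the axis span ("unrealistic"), and
#' degenerate bi-exponential solutions (near-equal taus or a vanishing
#' amplitude) set `converged`/`misfit`/`degenerate` flags in the result.
#'
#' The bi-exponential average is reported as the integral-weighted mean
#' `sum(A_i tau_i * tau_i) / sum(A_i tau_i)` by default — each component
#' weighted by its signal integral `A_i tau_i`, the same weighting as phasor
#' fractions — with the amplitude-weighted mean
#' `sum(A_i tau_i) / sum(A_i)` as an option.
#'
#' @param signal Numeric vector of non-negative samples.
#' @param axis A [sampled_axis()] (absolute sample coordinates are used).
#' @param n_starts Number of starting points for the bi-exponential fit.
#' @param weighting `"integral"` (default) or `"amplitude"` averaging.
#' @return A `fit_result`: `amplitudes`, `taus` (sorted increasing),
#'   `tau_avg`, `converged`, `misfit`, `degenerate`, `residual_norm`.
NULL

fit_result <- function(amplitudes, taus, tau_avg, converged, misfit,
                       degenerate, residual_norm) {
  structure(list(amplitudes = amplitudes, taus = taus, tau_avg = tau_avg,
                 converged = converged, misfit = misfit,
                 degenerate = degenerate, residual_norm = residual_norm),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> taus = %s, tau_avg = %.4g, converged = %s%s%s\n",
    paste(signif(x$taus, 5), collapse = "/"), x$tau_avg, x$converged,
    if (x$misfit) ", MISFIT" else "",
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

## log-linear initialization of (A, tau) from the early samples
loglin_init <- function(signal, x) {
  half <- seq_len(max(3L, floor(length(signal) / 2)))
  pos <- half[signal[half] > 0]
  if (length(pos) < 2L) return(c(A = max(signal), tau = diff(range(x))))
  co <- unname(stats::coef(stats::lm(log(signal[pos]) ~ x[pos])))
  tau0 <- if (is.finite(co[2L]) && co[2L] < 0) -1 / co[2L] else
    diff(range(x))
  c(A = exp(co[1L]), tau = unname(tau0))
}

tau_bounds <- function(axis) {
  span <- max(diff(range(axis$values)), stats::median(diff(axis$values)))
  c(0.01 * span, 100 * span)
}

#' @rdname exp_fitting
#' @export
fit_monoexp <- function(signal, axis) {
  stopifnot(inherits(axis, "sampled_axis"))
  signal <- as.numeric(signal)
  if (length(signal) < 3L) stop("need >= 3 samples", call. = FALSE)
  if (sum(signal) <= 0) stop("need positive total signal", call. = FALSE)
  x <- axis$values
  init <- loglin_init(signal, x)
  bounds <- tau_bounds(axis)
  init["tau"] <- min(max(init["tau"], bounds[1L]), bounds[2L])
  df <- data.frame(s = signal, x = x)
  fit <- tryCatch(
    suppressWarnings(stats::nls(s ~ A * exp(-x / tau), data = df,
               start = list(A = init[["A"]], tau = init[["tau"]]),
               algorithm = "port",
               lower = c(A = 0, tau = bounds[1L] / 10),
               upper = c(A = Inf, tau = bounds[2L] * 10),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(NA_real_, NA_real_, NA_real_, FALSE, TRUE, FALSE,
                      NA_real_))
  }
  co <- stats::coef(fit)
  conv <- fit$convInfo$isConv
  tau <- co[["tau"]]
  misfit <- !conv || tau < bounds[1L] || tau > bounds[2L]
  fit_result(co[["A"]], tau, tau, conv, misfit, FALSE,
             sqrt(sum(stats::residuals(fit)^2)))
}

#' @rdname exp_fitting
#' @export
fit_biexp <- function(signal, axis, n_starts = 3L,
                      weighting = c("integral", "amplitude")) {
  stopifnot(inherits(axis, "sampled_axis"))
  weighting <- match.arg(weighting)
  signal <- as.numeric(signal)
  if (length(signal) < 5L) stop("need >= 5 samples", call. = FALSE)
  if (sum(signal) <= 0) stop("need positive total signal", call. = FALSE)
  x <- axis$values
  mono <- fit_monoexp(signal, axis)
  tau0 <- if (is.finite(mono$taus[1L])) mono$taus[1L] else
    diff(range(x)) / 2
  a0 <- if (is.finite(mono$amplitudes[1L])) mono$amplitudes[1L] else
    max(signal)
  bounds <- tau_bounds(axis)
  spreads <- c(3, 6, 10, 20, 40)[seq_len(n_starts)]
  df <- data.frame(s = signal, x = x)
  best <- NULL
  for (sp in spreads) {
    start <- list(A1 = a0 / 2, lt1 = log(max(tau0 / sp, bounds[1L] / 5)),
                  A2 = a0 / 2, lt2 = log(min(tau0 * sp, bounds[2L] * 5)))
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(s ~ A1 * exp(-x / exp(lt1)) + A2 * exp(-x / exp(lt2)),
                 data = df, start = start, algorithm = "port",
                 lower = c(A1 = 0, lt1 = log(bounds[1L] / 10),
                           A2 = 0, lt2 = log(bounds[1L] / 10)),
                 upper = c(A1 = Inf, lt1 = log(bounds[2L] * 10),
                           A2 = Inf, lt2 = log(bounds[2L] * 10)),
                 control = stats::nls.control(maxiter = 300,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(fit_result(rep(NA_real_, 2), rep(NA_real_, 2), NA_real_,
                      FALSE, TRUE, FALSE, NA_real_))
  }
  co <- stats::coef(best$fit)
  a <- c(co[["A1"]], co[["A2"]])
  taus <- exp(c(co[["lt1"]], co[["lt2"]]))
  ord <- order(taus)
  a <- a[ord]; taus <- taus[ord]
  conv <- best$fit$convInfo$isConv
  misfit <- !conv || any(taus < bounds[1L] | taus > bounds[2L])
  degenerate <- taus[2L] / taus[1L] < 1.2 ||
    min(a) / max(sum(a), .Machine$double.eps) < 1e-3
  w <- if (weighting == "integral") a * taus else a
  tau_avg <- if (sum(w) > 0) sum(w * taus) / sum(w) else NA_real_
  fit_result(a, taus, tau_avg, conv, misfit, degenerate, sqrt(best$rss))
}

#' Per-pixel exponential-fit decay map
#'
#' Applies [fit_monoexp()] or [fit_biexp()] to every valid pixel of a stack,
#' producing a map comparable to [tau_map()] plus a misfit mask. This is the
#' slow iterative baseline; use it on modest grids.
#'
#' @param stack A [signal_stack()].
#' @param type `"mono"` or `"bi"`.
#' @param threshold,threshold_type Intensity threshold as in
#'   [compute_phasor_field()].
#' @param weighting Averaging for bi-exponential fits, see [fit_biexp()].
#' @return A `param_map` with extra logical array `misfit`.
#' @export
fit_map <- function(stack, type = c("mono", "bi"), threshold = 0.05,
                    threshold_type = c("fraction", "absolute"),
                    weighting = "integral") {
  stopifnot(inherits(stack, "signal_stack"))
  type <- match.arg(type)
  threshold_type <- match.arg(threshold_type)
  d <- dim(stack$data); nd <- length(d)
  n <- stack$axis$n
  m <- matrix(stack$data, ncol = n)
  total <- rowSums(m)
  thr <- if (threshold_type == "fraction") {
    threshold * stats::quantile(total, 0.99, names = FALSE)
  } else threshold
  valid <- total > 0 & total >= thr
  val <- rep(NA_real_, nrow(m))
  mis <- rep(FALSE, nrow(m))
  for (i in which(valid)) {
    fr <- if (type == "mono") fit_monoexp(m[i, ], stack$axis) else
      fit_biexp(m[i, ], stack$axis, weighting = weighting)
    val[i] <- fr$tau_avg
    mis[i] <- fr$misfit
  }
  units <- if (stack$axis$kind == "b_value") "1e-9 m^2/s" else
    axis_unit(stack$axis)
  if (stack$axis$kind == "b_value") val <- 1000 / val
  sdim <- d[-nd]
  structure(list(value = array(val, sdim), valid = array(valid, sdim),
                 clamped = array(FALSE, sdim), misfit = array(mis, sdim),
                 units = units, kind = stack$axis$kind),
            class = "param_map")
}
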