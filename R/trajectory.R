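#' Cyclic latent-trajectory parameters
#'
#' A heartbeat or ECG slice is embedded as the parameters of a closed curve
#' in a d-dimensional latent space: the first two coordinates trace the unit
#' circle at a (possibly learned) pace, the remaining `d - 2` coordinates are
#' time-constant shape coefficients. Three nested parameterisations are
#' supported:
#'
#' * `"DHB"` — frequency `f` (Hz), phase shift `tau` (s) and shape vector
#'   `b`; `d` stored numbers in total.
#' * `"P_DHB"` — pace variant for R-peak-aligned inputs: no shift is needed
#'   because every input starts at an R-peak; `d - 1` stored numbers.
#' * `"S_DHB"` — shape-only variant for single heartbeats whose time axis
#'   has been normalized to one cycle of phase in `[0, 1)`; `d - 2` stored
#'   numbers.
#'
#' @param variant One of `"DHB"`, `"P_DHB"`, `"S_DHB"`.
#' @param b Numeric vector of shape coefficients (length `d - 2`, may be
#'   empty when `d == 2` is not allowed; `d >= 3` is enforced).
#' @param f Frequency in cycles per second; required for `"DHB"` and
#'   `"P_DHB"`, must be `> 0`.
#' @param tau Phase shift in seconds; required for `"DHB"` only.
#'
#' @return An object of class `trajectory_params` with fields `variant`,
#'   `f`, `tau`, `b` and `d` (the latent dimension, `length(b) + 2`).
#' @export
trajectory_params <- function(variant = c("DHB", "P_DHB", "S_DHB"),
                              b, f = NULL, tau = NULL) {
  variant <- match.arg(variant)
  b <- as.numeric(b)
  d <- length(b) + 2L
  if (d < 3L) stop("latent dimension d must be >= 3 (need length(b) >= 1)",
                   call. = FALSE)
  if (variant %in% c("DHB", "P_DHB")) {
    if (is.null(f) || !is.finite(f) || f <= 0) {
      stop("variant ", variant, " requires frequency f > 0", call. = FALSE)
    }
  } else {
    f <- NULL
  }
  if (variant == "DHB") {
    if (is.null(tau) || !is.finite(tau)) {
      stop("variant DHB requires a finite shift tau", call. = FALSE)
    }
  } else {
    tau <- NULL
  }
  structure(list(variant = variant, f = f, tau = tau, b = b, d = d),
            class = "trajectory_params")
}

#' Number of stored parameters of an embedding
#'
#' Bookkeeping for the three variants: `d` for `"DHB"` (`f`, `tau`, `b`),
#' `d - 1` for `"P_DHB"` (`f`, `b`), `d - 2` for `"S_DHB"` (`b` only).
#'
#' @param params A `trajectory_params` object.
#' @return Integer count of stored numbers.
#' @export
param_count <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  length(params$b) + length(params$f) + length(params$tau)
}

#' Flatten an embedding to a plain numeric vector
#'
#' Layout is `(f, tau, b)` for `"DHB"`, `(f, b)` for `"P_DHB"` and `b` for
#' `"S_DHB"`; this is the vector that aggregation averages.
#'
#' @param params A `trajectory_params` object.
#' @return Numeric vector of length [param_count()].
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  c(params$f, params$tau, params$b)
}

#' Rebuild an embedding from its flattened form
#'
#' @param x Numeric vector as produced by [flatten_params()].
#' @param variant The parameterisation the vector belongs to.
#' @return A `trajectory_params` object.
#' @export
unflatten_params <- function(x, variant = c("DHB", "P_DHB", "S_DHB")) {
  variant <- match.arg(variant)
  switch(variant,
    DHB = trajectory_params("DHB", f = x[1], tau = x[2], b = x[-(1:2)]),
    P_DHB = trajectory_params("P_DHB", f = x[1], b = x[-1]),
    S_DHB = trajectory_params("S_DHB", b = x)
  )
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat(sprintf("<trajectory_params %s, d=%d>", x$variant, x$d))
  if (!is.null(x$f)) cat(sprintf(" f=%.4g Hz", x$f))
  if (!is.null(x$tau)) cat(sprintf(" tau=%.4g s", x$tau))
  cat("\n")
  invisible(x)
}

#' Evaluate the cyclic latent trajectory
#'
#' Computes the latent point `l(t)` of the closed curve induced by the
#' parameters. For `"DHB"`, `l(t) = (cos 2*pi*f*(t - tau),
#' sin 2*pi*f*(t - tau), b_3, ..., b_d)`; `"P_DHB"` drops the shift;
#' `"S_DHB"` fixes one cycle per time unit, so `t` is the cycle phase
#' (typically in `[0, 1)`).
#'
#' @param params A `trajectory_params` object.
#' @param t Time in seconds (phase for `"S_DHB"`); may be a vector.
#' @return If `t` is scalar, a numeric vector of length `d`; otherwise a
#'   `length(t) x d` matrix with one latent point per row.
#' @export
latent_trajectory <- function(params, t) {
  stopifnot(inherits(params, "trajectory_params"))
  if (anyNA(t) || any(!is.finite(t))) {
    stop("t must be finite", call. = FALSE)
  }
  phase <- switch(params$variant,
    DHB = params$f * (t - params$tau),
    P_DHB = params$f * t,
    S_DHB = t
  )
  out <- cbind(cos(2 * pi * phase), sin(2 * pi * phase),
               matrix(params$b, nrow = length(t), ncol = length(params$b),
                      byrow = TRUE))
  if (length(t) == 1L) as.numeric(out) else out
}

#' Period of the latent cycle
#'
#' `1 / f` seconds for the variants that carry a frequency; the shape-only
#' variant lives on a fixed unit cycle, so its period is 1 (one phase unit).
#' In beats per minute the heart rate is `60 * f`.
#'
#' @param params A `trajectory_params` object.
#' @return Positive scalar period.
#' @export
trajectory_period <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  if (is.null(params$f)) 1.0 else 1.0 / params$f
}

#' Root-mean-square reconstruction error
#'
#' `sqrt(mean((s - s_hat)^2))`, the per-sequence reconstruction quality
#' measure used throughout the package (units: mV).
#'
#' @param s Original signal values.
#' @param s_hat Reconstructed values; same length as `s`.
#' @return Non-negative scalar RMSE.
#' @export
rmse <- function(s, s_hat) {
  if (length(s) != length(s_hat)) {
    stop("rmse: 's' and 's_hat' must have equal length", call. = FALSE)
  }
  if (length(s) == 0) stop("rmse: inputs must be non-empty", call. = FALSE)
  sqrt(mean((s - s_hat)^2))
}
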