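#' Delay kernel specification
#'
#' A delay kernel weights past values of a state variable to determine its
#' present effect. Two kinds are supported:
#' \describe{
#'   \item{`"erlang"`}{the Gamma (Erlang) kernel of integer `shape` k and
#'     `rate` r (per minute), density \eqn{r^k \tau^{k-1} e^{-r\tau}/(k-1)!},
#'     mean `shape/rate`, variance `shape/rate^2`. Shape 1 is the weak kernel,
#'     shape 2 the strong kernel. Each shape corresponds to one replaced
#'     first-order process, and the kernel is an exact reduction of that chain
#'     (see [expand_chain()]).}
#'   \item{`"discrete"`}{a sharp lag of `lag` minutes: the limit of the Erlang
#'     kernel as shape grows with the mean held fixed (variance
#'     `shape/rate^2 -> 0`).}
#' }
#'
#' @param kind `"erlang"` or `"discrete"`.
#' @param shape Positive integer number of stages (erlang only).
#' @param rate Per-stage rate, 1/min (erlang only).
#' @param lag Lag in minutes (discrete only), `>= 0`.
#' @param target Name of the state variable whose past value is taken.
#' @return An object of class `"delay_spec"`.
#' @examples
#' delay_spec("erlang", shape = 1, rate = 4.6)   # weak kernel, mean 1/4.6 min
#' delay_spec("discrete", lag = 3.5)
#' @export
delay_spec <- function(kind = c("erlang", "discrete"), shape = NULL, rate = NULL,
                       lag = NULL, target = NULL) {
  kind <- match.arg(kind)
  if (kind == "erlang") {
    if (is.null(shape) || is.null(rate)) stop("erlang kernel needs `shape` and `rate`")
    if (shape < 1 || shape != round(shape)) stop("`shape` must be a positive integer")
    if (!is.finite(rate) || rate <= 0) stop("`rate` must be positive")
    structure(list(kind = "erlang", shape = as.integer(shape), rate = rate,
                   target = target), class = "delay_spec")
  } else {
    if (is.null(lag)) stop("discrete kernel needs `lag`")
    if (!is.finite(lag) || lag < 0) stop("`lag` must be >= 0 minutes")
    structure(list(kind = "discrete", lag = lag, target = target),
              class = "delay_spec")
  }
}

#' @export
print.delay_spec <- function(x, ...) {
  if (x$kind == "erlang")
    cat(sprintf("Erlang delay kernel: shape %d, rate %g /min (mean %g min)%s\n",
                x$shape, x$rate, x$shape / x$rate,
                if (is.null(x$target)) "" else paste0(" on ", x$target)))
  else
    cat(sprintf("Discrete delay: lag %g min%s\n", x$lag,
                if (is.null(x$target)) "" else paste0(" on ", x$target)))
  invisible(x)
}

#' Delay kernel density
#'
#' Density of the kernel at elapsed time `tau` (weight per minute). For the
#' Erlang kernel this is the normalized Erlang density of the given shape; for
#' a discrete delay the kernel is a Dirac mass and the density is zero away
#' from the lag (with `Inf` reported at the lag itself).
#'
#' @param spec A [delay_spec()].
#' @param tau Elapsed time, minutes, `>= 0` (vectorized).
#' @return Density values, per minute.
#' @examples
#' kernel_density(delay_spec("erlang", 1, 4.6), 0.5)  # 4.6 * exp(-4.6 * 0.5)
#' @export
kernel_density <- function(spec, tau) {
  stopifnot(inherits(spec, "delay_spec"))
  if (any(!is.finite(tau)) || any(tau < 0)) stop("`tau` must be >= 0")
  if (spec$kind == "erlang") {
    stats::dgamma(tau, shape = spec$shape, rate = spec$rate)
  } else {
    ifelse(tau == spec$lag, Inf, 0)
  }
}

#' Mean of a delay kernel, minutes
#' @param spec A [delay_spec()].
#' @return Mean delay, minutes.
#' @export
kernel_mean <- function(spec) {
  stopifnot(inherits(spec, "delay_spec"))
  if (spec$kind == "erlang") spec$shape / spec$rate else spec$lag
}
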