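#' Integrate a delay (or ordinary) differential system
#'
#' Thin deterministic wrapper around \pkg{deSolve}: ordinary systems go through
#' [deSolve::ode()], systems with discrete lags through [deSolve::dede()],
#' which advances by the method of steps with continuous interpolation of the
#' stored past solution. For lookback times before the start of integration
#' the supplied history function is used.
#'
#' @param rhs Function `f(t, y, lagged)` returning the derivative vector;
#'   `lagged(t_past)` returns the full state at `t_past` (only meaningful when
#'   `lags` is non-empty).
#' @param init Initial state vector at `times[1]`.
#' @param times Strictly increasing output time grid, minutes.
#' @param lags Numeric vector of discrete lags present in `rhs` (empty or
#'   `NULL` for a plain initial-value problem).
#' @param history Function `h(t)` giving the state for `t <=` `times[1]`;
#'   defaults to constant continuation of `init`.
#' @param method Solver passed to \pkg{deSolve} (default `"lsoda"`, which
#'   switches to an implicit scheme for stiff rate ratios).
#' @param atol,rtol Absolute/relative error tolerances.
#' @return Matrix of class `deSolve` (time column plus states).
#' @examples
#' # x'(t) = -x(t - pi/2) with history cos(t): the solution stays cos(t)
#' sol <- solve_delay_system(function(t, y, lagged) -lagged(t - pi / 2),
#'   init = 1, times = seq(0, 10, 0.01), lags = pi / 2,
#'   history = function(t) cos(t))
#' max(abs(sol[, 2] - cos(sol[, 1])))
#' @export
solve_delay_system <- function(rhs, init, times, lags = NULL, history = NULL,
                               method = "lsoda", atol = 1e-10, rtol = 1e-8) {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  t0 <- times[1]
  if (is.null(history)) history <- function(t) init
  n <- length(init)
  if (is.null(lags) || !length(lags)) {
    derivs <- function(t, y, parms) {
      # a zero-lag lookup degenerates to the current state
      d <- rhs(t, y, function(tp) if (tp < t0) history(tp) else y)
      list(d[seq_len(n)], if (length(d) > n) d[-seq_len(n)])
    }
    out <- deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                        method = method, atol = atol, rtol = rtol)
  } else {
    derivs <- function(t, y, parms) {
      lagged <- function(tp) {
        if (tp <= t0) history(tp)
        else if (tp >= t) y               # zero-lag lookup
        else deSolve::lagvalue(tp)
      }
      d <- rhs(t, y, lagged)
      list(d[seq_len(n)], if (length(d) > n) d[-seq_len(n)])
    }
    out <- deSolve::dede(y = init, times = times, func = derivs, parms = NULL,
                         method = method, atol = atol, rtol = rtol)
  }
  if (anyNA(out[, -1])) stop("integration produced NaN/NA state values")
  out
}

#' Integrate a circuit model
#'
#' Produces a dense trajectory of a [circuit_model()] on a user time grid.
#' Erlang-kernel models are expanded exactly into their first-order chains
#' before integration; discrete-delay variants are solved by the method of
#' steps. For the kernel-delayed CRS variants the trajectory gains a column
#' `c` holding the TF concentration the promoter actually sees (the delayed or
#' kernel-filtered rescaled transcript).
#'
#' @param model A [circuit_model()].
#' @param times Output time grid, minutes. Default `seq(0, 500, 0.05)`.
#' @param init Initial state (named or in `model$state_names` order). Default
#'   is the variant's canonical start: for the Hill-regulated variants
#'   `m0 = 1` (model I: `m = 1`) and all else 0; for the explicit-CRS
#'   variants an empty promoter, `a0 = 1`, all else 0.
#' @param history Function of time giving the pre-start state for delay
#'   variants; defaults to constant continuation of `init`.
#' @param method,atol,rtol Passed to [solve_delay_system()].
#' @return A data.frame of class `"circuit_trajectory"`: column `t_min` then
#'   one column per state (plus `c` for the delayed-CRS variants). The model
#'   is attached as attribute `"model"`. Excursions below `-1e-8` in any state
#'   mark the trajectory as a failed integration (error).
#' @examples
#' m <- circuit_model("I",
#'   synthesis = list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23),
#'   regulation = hill_regulation(40, 2))
#' traj <- integrate_model(m, times = seq(0, 100, 0.1))
#' tail(traj$c, 1)
#' @export
integrate_model <- function(model, times = seq(0, 500, 0.05), init = NULL,
                            history = NULL, method = "lsoda",
                            atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(model, "circuit_model"))
  run_model <- if (model$variant == "DDE_CRS" &&
                   model$delays[[1]]$kind == "erlang")
    expand_chain(model) else model
  if (is.null(init)) init <- default_init(run_model)
  if (run_model$variant == "DDE_CRS_chain" && length(init) == 4L) {
    # a length-4 start for the kernel model: chain stages consistent with a
    # constant pre-history at the starting m' level
    init <- c(init, rep(unname(init[4]), run_model$chain$shape))
    names(init) <- run_model$state_names
  }
  init <- .order_init(run_model, init)
  lags <- if (run_model$variant == "III")
    c(run_model$delays$tau_N, run_model$delays$tau_M)
  else if (run_model$variant == "DDE_CRS") run_model$delays[[1]]$lag
  lags <- if (!is.null(lags)) lags[lags > 0]
  if (!is.null(lags) && !length(lags)) {
    # zero lag degenerates to an ordinary initial-value problem
    lags <- NULL
  }
  rhs <- function(t, y, lagged) model_rhs(run_model, t, y, lagged)
  hist_fun <- if (!is.null(history)) {
    h <- history
    function(t) .order_init(run_model, h(t))
  }
  out <- solve_delay_system(rhs, init, times, lags = lags, history = hist_fun,
                            method = method, atol = atol, rtol = rtol)
  traj <- as.data.frame(out)
  names(traj) <- c("t_min", run_model$state_names)
  # TF concentration seen by the promoter, for the kernel-delayed variants
  if (run_model$variant == "DDE_CRS_chain") {
    traj$c <- traj[[paste0("s", run_model$chain$shape)]]
  } else if (run_model$variant == "DDE_CRS") {
    lag <- run_model$delays[[1]]$lag
    hist_mp <- if (!is.null(hist_fun)) function(t) hist_fun(t)[4]
      else function(t) init[4]
    tp <- traj$t_min - lag
    cvals <- numeric(length(tp))
    pre <- tp <= times[1]
    cvals[pre] <- vapply(tp[pre], hist_mp, numeric(1))
    if (any(!pre))
      cvals[!pre] <- stats::approx(traj$t_min, traj$mp, xout = tp[!pre])$y
    traj$c <- cvals
  }
  low <- min(vapply(traj[run_model$state_names], min, numeric(1)))
  if (low < -1e-8)
    stop("integration failure: state excursion below -1e-8 (min = ",
         signif(low, 4), "); tighten tolerances")
  structure(traj, model = model, class = c("circuit_trajectory", "data.frame"))
}

# canonical starting state per variant
default_init <- function(model) {
  init <- numeric(model$dimension)
  names(init) <- model$state_names
  if (model$variant == "I") init["m"] <- 1
  else if (model$variant %in% c("II", "chain", "III")) init["m0"] <- 1
  else if (model$variant == "QSS") init["c"] <- 0
  else init["a0"] <- 1
  init
}

.order_init <- function(model, init) {
  if (length(init) != model$dimension)
    stop("init has length ", length(init), ", expected ", model$dimension)
  if (!is.null(names(init)) && all(model$state_names %in% names(init)))
    init <- init[model$state_names]
  stats::setNames(as.numeric(init), model$state_names)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("Trajectory of variant %s: %d time points over [%g, %g] min\n",
              m$variant, nrow(x), x$t_min[1], x$t_min[nrow(x)]))
  print(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}

#' Plot a circuit trajectory
#'
#' @param x A `"circuit_trajectory"`.
#' @param variables State columns to draw (default: all but time).
#' @param phase If `TRUE` and two variables are given, draw the phase plane.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.circuit_trajectory <- function(x, variables = NULL, phase = FALSE, ...) {
  vars <- variables %||% setdiff(names(x), "t_min")
  if (phase) {
    if (length(vars) != 2) stop("phase-plane plot needs exactly two variables")
    graphics::plot(x[[vars[1]]], x[[vars[2]]], type = "l",
                   xlab = vars[1], ylab = vars[2], ...)
  } else {
    graphics::matplot(x$t_min, as.matrix(x[vars]), type = "l", lty = 1,
                      xlab = "time (min)", ylab = "level", ...)
    graphics::legend("topright", legend = vars, col = seq_along(vars), lty = 1,
                     bty = "n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate method for circuit models
#'
#' `simulate(model)` integrates the model from its canonical initial state
#' (see [integrate_model()]); with `nsim > 1` each replicate starts from an
#' independently perturbed steady state (see [perturbed_initials()]).
#'
#' @param object A [circuit_model()].
#' @param nsim Number of trajectories.
#' @param seed Seed used to draw perturbed starts when `nsim > 1`.
#' @param times,... Passed to [integrate_model()].
#' @param relative_amplitude Perturbation amplitude for `nsim > 1`.
#' @return A `"circuit_trajectory"` (or a list of them when `nsim > 1`).
#' @export
simulate.circuit_model <- function(object, nsim = 1, seed = NULL,
                                   times = seq(0, 500, 0.05),
                                   relative_amplitude = 0.2, ...) {
  if (nsim == 1)
    return(integrate_model(object, times = times, ...))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    init <- perturbed_initials(object, relative_amplitude)
    integrate_model(object, times = times, init = init, ...)
  })
}

#' Erlang-to-discrete kernel convergence check
#'
#' Integrates a kernel-delayed model family across increasing Erlang shapes at
#' a fixed mean delay and measures the sup-norm distance of each trajectory to
#' the discrete-lag trajectory of the same mean. As the shape grows the kernel
#' variance `shape/rate^2` shrinks to zero and the distances should fall.
#'
#' @param make_model Function of one [delay_spec()] returning a
#'   [circuit_model()] (the model family with the kernel as the free slot).
#' @param mean_lag Common kernel mean, minutes.
#' @param shapes Increasing integer Erlang shapes to test.
#' @param variable Trajectory column compared (default `"c"`).
#' @param times,init,... Passed to [integrate_model()].
#' @return A data.frame with columns `shape` and `distance` (sup-norm to the
#'   discrete-lag trajectory).
#' @export
erlang_to_discrete_limit_check <- function(make_model, mean_lag, shapes,
                                           variable = "c",
                                           times = seq(0, 200, 0.05),
                                           init = NULL, ...) {
  stopifnot(all(diff(shapes) > 0), all(shapes >= 1))
  ref_model <- make_model(delay_spec("discrete", lag = mean_lag))
  ref <- integrate_model(ref_model, times = times, init = init, ...)
  dist <- vapply(shapes, function(k) {
    m <- make_model(delay_spec("erlang", shape = k, rate = k / mean_lag))
    tr <- integrate_model(m, times = times, init = init, ...)
    max(abs(tr[[variable]] - ref[[variable]]))
  }, numeric(1))
  data.frame(shape = as.integer(shapes), distance = dist)
}
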