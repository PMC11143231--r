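#' Quantify oscillations in a trajectory
#'
#' Discards an initial transient, locates local maxima and minima of one
#' state variable (with quadratic refinement of peak times and a prominence
#' floor against numerical ripple), and summarizes periodicity:
#' \itemize{
#'   \item `period`: mean inter-peak interval, minutes (`frequency = 1/period`);
#'   \item `amplitude`: mean peak-to-trough excursion in state units;
#'   \item `decay_ratio`: per-cycle geometric amplitude ratio,
#'     \eqn{(A_k/A_1)^{1/(k-1)}} over consecutive peak-to-trough amplitudes —
#'     1 for a sustained limit cycle, below 1 for a damped spiral;
#'   \item `sustained`: `TRUE` when at least `min_peaks` peaks remain after
#'     the transient and `decay_ratio` lies within `1 +/- delta`.
#' }
#'
#' @param traj A `"circuit_trajectory"` (or data.frame with a `t_min` column).
#' @param variable Column to analyze (default `"c"`, the TF concentration or
#'   its delayed equivalent).
#' @param transient_fraction Fraction of the time span discarded before
#'   analysis (default 0.5).
#' @param delta Sustainedness band on `decay_ratio` (default 0.02).
#' @param min_peaks Minimum retained peaks for a periodicity call (default 4).
#' @param min_prominence Peak prominence floor as a fraction of the retained
#'   signal range (default 1e-6).
#' @return An object of class `"oscillation_summary"` with fields `sustained`,
#'   `period`, `frequency`, `amplitude`, `decay_ratio`, `n_peaks`,
#'   `analysis_window`, and `reason` when no periodicity call is possible.
#' @examples
#' tt <- seq(0, 300, 0.01)
#' traj <- data.frame(t_min = tt, c = sin(2 * pi * tt / 30))
#' summarize_oscillation(traj)$period  # ~ 30
#' @export
summarize_oscillation <- function(traj, variable = "c",
                                  transient_fraction = 0.5, delta = 0.02,
                                  min_peaks = 4L, min_prominence = 1e-6) {
  stopifnot(is.data.frame(traj), "t_min" %in% names(traj),
            variable %in% names(traj),
            transient_fraction >= 0, transient_fraction < 1)
  t <- traj$t_min
  y <- traj[[variable]]
  t0 <- t[1] + transient_fraction * (t[length(t)] - t[1])
  keep <- t >= t0
  t <- t[keep]; y <- y[keep]
  window <- c(t[1], t[length(t)])
  out <- list(sustained = FALSE, period = NULL, frequency = NULL,
              amplitude = NULL, decay_ratio = NULL, n_peaks = 0L,
              analysis_window = window, reason = NULL, variable = variable)

  rng <- diff(range(y))
  if (rng == 0) {
    out$reason <- "constant trajectory"
    return(structure(out, class = "oscillation_summary"))
  }
  prom <- min_prominence * rng
  pk <- .turning_points(t, y, -1, prom)
  tr <- .turning_points(t, y, +1, prom)
  out$n_peaks <- nrow(pk)
  if (nrow(pk) < min_peaks) {
    out$reason <- "insufficient peaks"
    return(structure(out, class = "oscillation_summary"))
  }
  out$period <- mean(diff(pk$t))
  # peak-to-trough amplitude of each cycle: peak minus the following trough
  amps <- vapply(seq_len(nrow(pk)), function(i) {
    nxt <- tr$t > pk$t[i]
    if (!any(nxt)) return(NA_real_)
    pk$y[i] - tr$y[which(nxt)[1]]
  }, numeric(1))
  amps <- amps[!is.na(amps) & amps > 0]
  if (length(amps) >= 2) {
    out$amplitude <- mean(amps)
    out$decay_ratio <- (amps[length(amps)] / amps[1])^(1 / (length(amps) - 1))
    out$sustained <- abs(out$decay_ratio - 1) <= delta
  } else {
    out$reason <- "insufficient full cycles"
  }
  if (out$sustained) out$frequency <- 1 / out$period
  structure(out, class = "oscillation_summary")
}

# local maxima (sgn = -1) or minima (sgn = +1) with quadratic refinement
.turning_points <- function(t, y, sgn, prominence) {
  d <- diff(sign(diff(y)))
  idx <- which(d == 2 * sgn) + 1L
  if (!length(idx)) return(data.frame(t = numeric(0), y = numeric(0)))
  ref <- vapply(idx, function(i) {
    y3 <- y[(i - 1):(i + 1)]; t3 <- t[(i - 1):(i + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (denom == 0) return(c(t3[2], y3[2]))
    # vertex of the parabola through the three samples
    dt <- (t3[3] - t3[1]) / 2
    shift <- 0.5 * (y3[1] - y3[3]) / denom
    c(t3[2] + shift * dt, y3[2] - 0.25 * (y3[1] - y3[3]) * shift)
  }, numeric(2))
  pts <- data.frame(t = ref[1, ], y = ref[2, ])
  # prominence: excursion from the local median level
  level <- stats::median(y)
  pts[abs(pts$y - level) >= prominence | abs(y[idx] - level) >= prominence, ,
      drop = FALSE]
}

#' @export
print.oscillation_summary <- function(x, ...) {
  if (x$sustained)
    cat(sprintf(
      "Sustained oscillation in `%s`: period %.4g min (freq %.4g /min), amplitude %.4g\n",
      x$variable, x$period, x$frequency, x$amplitude))
  else if (!is.null(x$period))
    cat(sprintf(
      "Damped oscillation in `%s`: period %.4g min, decay ratio %.4g per cycle\n",
      x$variable, x$period, x$decay_ratio))
  else
    cat(sprintf("No oscillation in `%s` (%s)\n", x$variable,
                x$reason %||% "no periodicity"))
  invisible(x)
}

#' Compare the two cooperative binding mechanisms on one scenario
#'
#' Runs a scenario (see [scenario_registry()]) once under the recruitment and
#' once under the stabilization mechanism with everything else identical, and
#' reports the per-mechanism oscillation summaries plus frequency and
#' amplitude differences. The two mechanisms share the same regulatory
#' function and fixed point; any difference in transient or oscillation is a
#' pure kinetic effect of how cooperativity enters the binding chain.
#'
#' @param scenario A scenario name or `"scenario_spec"` that carries a CRS
#'   parameterization.
#' @param ... Passed to [run_scenario()].
#' @return A list with elements `RM`, `SM` (scenario bundles),
#'   `summary_RM`, `summary_SM`, `delta_frequency` (RM minus SM, 1/min; `NA`
#'   unless both sustain), and `delta_amplitude`.
#' @export
compare_mechanisms <- function(scenario, ...) {
  bundles <- lapply(c(RM = "RM", SM = "SM"), function(mech)
    run_scenario(scenario, mechanism = mech, ...))
  s_rm <- bundles$RM$oscillation
  s_sm <- bundles$SM$oscillation
  freq <- function(s) if (isTRUE(s$sustained)) s$frequency else NA_real_
  amp <- function(s) if (!is.null(s$amplitude)) s$amplitude else NA_real_
  list(RM = bundles$RM, SM = bundles$SM,
       summary_RM = s_rm, summary_SM = s_sm,
       delta_frequency = freq(s_rm) - freq(s_sm),
       delta_amplitude = amp(s_rm) - amp(s_sm))
}
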