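# shared model builders for the test suite

lewis_syn <- list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23)
fig5_syn <- list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 4.6)

hill40 <- function(nH = 2) hill_regulation(Kd = 40, nH = nH)

model_I <- function() circuit_model("I", lewis_syn, regulation = hill40())

model_II <- function(beta1 = 1 / 20.8, beta2 = 1 / 2.8) {
  circuit_model("II", c(lewis_syn, list(beta1 = beta1, beta2 = beta2)),
                regulation = hill40())
}

model_III <- function() {
  circuit_model("III", c(lewis_syn, list(r1 = 10, r2 = 10)),
                regulation = hill40(),
                delays = list(tau_N = 20.8, tau_M = 2.8))
}

fig5_crs <- function(mechanism = "RM") {
  cooperative_rates(cooperativity_spec(mechanism, 0.246, 30, 10))
}

# kinetic-scale scan model: discrete-delay CRS circuit at scale factor f
fig6_model <- function(mechanism, f, tau = 3.5, gamma = 0.23) {
  crs <- cooperative_rates(cooperativity_spec(mechanism, f * 0.1, f * 43, 8.5))
  circuit_model("DDE_CRS",
                list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = gamma),
                crs = crs, delays = delay_spec("discrete", lag = tau))
}

# central finite-difference Jacobian of a model rhs at state x, holding the
# lagged state fixed at `lag_state` (so delay terms drop out of the result)
fd_jacobian <- function(model, x, lag_state = NULL) {
  lag <- if (!is.null(lag_state)) function(tp) lag_state
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (model_rhs(model, 0, xp, lag) - model_rhs(model, 0, xm, lag)) /
      (2 * h)
  }
  J
}
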