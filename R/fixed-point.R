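#' Steady state of a circuit model
#'
#' All variants share one scalar fixed-point condition for the protein level:
#' \eqn{\gamma \gamma_m c = \alpha \alpha_m R(c)} for the variants with a
#' separate transcript (I, II, chain, III, V, DDE_CRS), or
#' \eqn{\gamma c = \alpha R(c)} for the protein-only variants (IV, IV_full,
#' QSS), with `R` the model's regulatory function. Because `R` is monotone
#' decreasing, the root is unique; it is found by bracketed bisection. The
#' remaining state components follow algebraically, with the promoter
#' occupancies filled from detailed balance
#' (\eqn{a_1 = K_1 c a_0}, \eqn{a_2 = K_1 K_2 c^2 a_0},
#' \eqn{a_3 = K_1 K_2 K_3 c^3 a_0}).
#'
#' @param model A [circuit_model()].
#' @param tol Absolute tolerance on the protein root, molecules.
#' @return Named numeric steady-state vector (in `model$state_names` order),
#'   with the protein level attached as attribute `"c_star"`.
#' @examples
#' m <- circuit_model("I",
#'   synthesis = list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23),
#'   regulation = hill_regulation(40, 2))
#' fixed_point(m)  # c* ~ 161.8, m* ~ 8.27
#' @export
fixed_point <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "circuit_model"))
  syn <- model$synthesis
  A <- if (model$variant %in% c("IV_full", "IV", "QSS"))
    syn$alpha / syn$gamma
  else syn$alpha_m * syn$alpha / (syn$gamma_m * syn$gamma)
  g <- function(c) c - A * regulatory_value(model$regulation, c)
  hi <- A * 1.01 + 1
  if (g(hi) < 0) stop("failed to bracket the steady state")
  cs <- uniroot(g, c(0, hi), tol = tol)$root
  Rs <- regulatory_value(model$regulation, cs)

  state <- switch(model$variant,
    I = c(syn$alpha_m * Rs / syn$gamma_m, cs),
    II = c(syn$alpha_m * Rs / syn$beta1, syn$alpha_m * Rs / syn$gamma_m,
           syn$alpha * syn$alpha_m * Rs / (syn$gamma_m * syn$beta2), cs),
    chain = {
      mstar <- syn$alpha_m * Rs / syn$gamma_m
      c(rep(syn$alpha_m * Rs / syn$r1, syn$N + 1L), mstar,
        rep(syn$alpha * mstar / syn$r2, syn$M + 1L), cs)
    },
    III = {
      mstar <- syn$alpha_m * Rs / syn$gamma_m
      c(syn$alpha_m * Rs / syn$r1, mstar, syn$alpha * mstar / syn$r2, cs)
    },
    IV_full = c(.occupancies(model$regulation$Ks, cs), cs),
    IV = c(.occupancies(model$regulation$Ks, cs)[1:3], cs),
    QSS = cs,
    V = c(.occupancies(model$regulation$Ks, cs)[1:3],
          syn$alpha_m * Rs / syn$gamma_m, cs),
    DDE_CRS = c(.occupancies(model$regulation$Ks, cs)[1:3], cs),
    DDE_CRS_chain = c(.occupancies(model$regulation$Ks, cs)[1:3], cs,
                      rep(cs, model$chain$shape)))
  names(state) <- model$state_names
  attr(state, "c_star") <- cs
  state
}

# detailed-balance promoter occupancies (a0, a1, a2, a3) at concentration c
.occupancies <- function(Ks, c) {
  a0 <- adair_regulatory(c, Ks)
  c(a0, Ks[1] * c * a0, Ks[1] * Ks[2] * c^2 * a0,
    Ks[1] * Ks[2] * Ks[3] * c^3 * a0)
}

#' Quasi-steady-state reduction of a circuit model
#'
#' Eliminates the fast block of a model by setting its time derivatives to
#' zero: variant `"IV"` reduces to the scalar `"QSS"` model
#' \eqn{\dot c = \alpha R^{qss}(c) - \gamma c} (promoter equilibration), and
#' variants `"II"` and `"chain"` reduce to model `"I"` (instantaneous
#' elongation). The reduction preserves the fixed point exactly.
#'
#' @param model A [circuit_model()] of variant `"IV"`, `"II"` or `"chain"`.
#' @return The reduced [circuit_model()].
#' @export
qss_reduce <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  syn <- model$synthesis
  switch(model$variant,
    IV = circuit_model("QSS",
      synthesis = list(alpha = syn$alpha, gamma = syn$gamma),
      crs = model$crs),
    II = ,
    chain = circuit_model("I",
      synthesis = list(alpha_m = syn$alpha_m, gamma_m = syn$gamma_m,
                       alpha = syn$alpha, gamma = syn$gamma),
      regulation = model$regulation),
    stop("variant ", model$variant, " has no quasi-steady-state reduction here"))
}

#' Expand an Erlang delay kernel into its first-order chain
#'
#' The linear chain trick in the expanding direction: an Erlang kernel of
#' shape `k` and rate `r` acting on a variable is replaced by `k` auxiliary
#' first-order stages of rate `r`, growing the dimension by `k`. This is an
#' exact rewriting (a reduction, not an approximation), so trajectories of the
#' expanded system equal the solution of the integro-differential form.
#'
#' @param model A [circuit_model()] whose delays are all Erlang kernels
#'   (variant `"DDE_CRS"`).
#' @return A plain-ODE [circuit_model()] with states
#'   `(a0, a1, a2, mp, s1..sk)`; the promoter reads the last stage `sk`.
#' @export
expand_chain <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  if (model$variant != "DDE_CRS")
    stop("chain expansion applies to the kernel-delayed CRS variant")
  d <- model$delays[[1]]
  if (d$kind != "erlang")
    stop("a discrete delay is the infinite-shape kernel limit and cannot be ",
         "expanded into finitely many stages")
  out <- model
  out$variant <- "DDE_CRS_chain"
  out$chain <- list(shape = d$shape, rate = d$rate)
  out$delays <- NULL
  out$state_names <- c("a0", "a1", "a2", "mp", paste0("s", seq_len(d$shape)))
  out$dimension <- 4L + d$shape
  out
}
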