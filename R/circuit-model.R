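#' Build a single-gene autoinhibitory circuit model
#'
#' Constructs one member of a family of deterministic models of a gene whose
#' protein product represses its own transcription. The variants differ in the
#' level of mechanistic detail:
#' \describe{
#'   \item{`"I"`}{instantaneous transcription and translation; states `(m, c)`.
#'     \eqn{\dot m = \alpha_m R(c) - \gamma_m m}, \eqn{\dot c = \alpha m -
#'     \gamma c}.}
#'   \item{`"II"`}{adds the open DNA state `m0` and the translation initiation
#'     complex `c0` with effective elongation rates `beta1`, `beta2`; states
#'     `(m0, m, c0, c)`.}
#'   \item{`"chain"`}{step-by-step elongation: `N` transcript stages and `M`
#'     peptide stages, each advancing at single-step rates `r1`, `r2`; states
#'     `(m0, m1..mN, m, c0, c1..cM, c)`.}
#'   \item{`"III"`}{the elongation chains replaced by discrete delays
#'     `tau_N = N/r1` and `tau_M = M/r2`; states `(m0, m, c0, c)` with
#'     \eqn{\dot m = r_1 m_0(t-\tau_N) - \gamma_m m} and
#'     \eqn{\dot c = r_2 c_0(t-\tau_M) - \gamma c}.}
#'   \item{`"IV_full"`}{explicit mass-action kinetics of a three-site
#'     cis-regulatory system including the TF molecules sequestered by
#'     binding; states `(a0, a1, a2, a3, c)` with the conserved promoter
#'     fractions \eqn{a_0 + a_1 + a_2 + a_3 = 1}.}
#'   \item{`"IV"`}{as `IV_full` but neglecting the binding flux in the protein
#'     balance (TF copy number much larger than the 3 sites); states
#'     `(a0, a1, a2, c)`, \eqn{\dot c = \alpha a_0 - \gamma c}.}
#'   \item{`"QSS"`}{quasi-steady-state reduction of `IV`: the scalar
#'     \eqn{\dot c = \alpha R^{qss}(c) - \gamma c} with the Adair regulatory
#'     function.}
#'   \item{`"V"`}{explicit CRS plus a separate transcription step; states
#'     `(a0, a1, a2, m, c)`.}
#'   \item{`"DDE_CRS"`}{model V reduced by the linear chain trick: the rescaled
#'     transcript \eqn{m' = (\alpha/\gamma) m} drives the promoter through a
#'     delay kernel (weak, strong, or discrete); states `(a0, a1, a2, mp)`
#'     plus the kernel.}
#' }
#'
#' @param variant One of `"I"`, `"II"`, `"chain"`, `"III"`, `"IV_full"`,
#'   `"IV"`, `"QSS"`, `"V"`, `"DDE_CRS"`.
#' @param synthesis Named list of synthesis/degradation parameters (per
#'   minute): `alpha_m`, `gamma_m`, `alpha`, `gamma`, and per variant
#'   `beta1`/`beta2` (II), `r1`/`r2` and integer lengths `N`/`M` (chain), or
#'   `r1`/`r2` (III).
#' @param regulation A `"regulation_spec"` ([hill_regulation()] or
#'   [adair_regulation()]); required for variants I/II/chain/III, rejected for
#'   the explicit-CRS variants.
#' @param crs A `"crs_kinetics"` object ([cooperative_rates()]); required for
#'   variants IV_full/IV/QSS/V/DDE_CRS.
#' @param delays For `"III"`, a list with lags `tau_N`, `tau_M` in minutes
#'   (defaults `N/r1`, `M/r2` when `N`, `M` are given); for `"DDE_CRS"`, a
#'   single [delay_spec()] (default: weak kernel of rate `gamma`, the exact
#'   chain-trick reduction of model V).
#' @return An object of class `"circuit_model"`.
#' @seealso [fixed_point()], [integrate_model()], [linearize()], [classify()]
#' @examples
#' m1 <- circuit_model("I",
#'   synthesis = list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23),
#'   regulation = hill_regulation(40, 2))
#' fixed_point(m1)
#' @export
circuit_model <- function(variant, synthesis, regulation = NULL, crs = NULL,
                          delays = NULL) {
  variant <- match.arg(variant,
    c("I", "II", "chain", "III", "IV_full", "IV", "QSS", "V", "DDE_CRS"))
  syn <- .check_synthesis(variant, synthesis)

  crs_variants <- c("IV_full", "IV", "QSS", "V", "DDE_CRS")
  if (variant %in% crs_variants) {
    if (!is.null(regulation))
      stop("variant ", variant, " carries explicit promoter kinetics; ",
           "pass `crs`, not `regulation`")
    if (is.null(crs)) stop("variant ", variant, " requires `crs` kinetics")
    if (!inherits(crs, "crs_kinetics")) stop("`crs` must be a crs_kinetics object")
    regulation <- adair_regulation(equilibrium_constants(crs))
  } else {
    if (!is.null(crs))
      stop("variant ", variant, " uses a closed-form regulatory function; ",
           "pass `regulation`, not `crs`")
    if (is.null(regulation) || !inherits(regulation, "regulation_spec"))
      stop("variant ", variant, " requires a `regulation` spec")
  }

  delays <- .check_delays(variant, syn, delays)
  state_names <- .state_names(variant, syn, delays)
  structure(list(variant = variant, synthesis = syn, regulation = regulation,
                 crs = crs, delays = delays, state_names = state_names,
                 dimension = length(state_names)),
            class = "circuit_model")
}

.check_synthesis <- function(variant, syn) {
  if (!is.list(syn)) stop("`synthesis` must be a named list")
  need <- switch(variant,
    I = c("alpha_m", "gamma_m", "alpha", "gamma"),
    II = c("alpha_m", "gamma_m", "alpha", "gamma"),   # beta or r/N handled below
    chain = c("alpha_m", "gamma_m", "alpha", "gamma", "r1", "r2", "N", "M"),
    III = c("alpha_m", "gamma_m", "alpha", "gamma", "r1", "r2"),
    IV_full = c("alpha", "gamma"),
    IV = c("alpha", "gamma"),
    QSS = c("alpha", "gamma"),
    V = c("alpha_m", "gamma_m", "alpha", "gamma"),
    DDE_CRS = c("alpha_m", "gamma_m", "alpha", "gamma"))
  missing <- setdiff(need, names(syn))
  if (length(missing))
    stop("variant ", variant, " is missing synthesis parameter(s): ",
         toString(missing))
  if (variant == "II") {
    if (!all(c("beta1", "beta2") %in% names(syn))) {
      if (all(c("r1", "r2", "N", "M") %in% names(syn))) {
        syn$beta1 <- syn$r1 / syn$N   # effective elongation = single step / length
        syn$beta2 <- syn$r2 / syn$M
      } else {
        stop("variant II needs `beta1`/`beta2` (or `r1`,`r2`,`N`,`M` to derive them)")
      }
    }
    need <- c(need, "beta1", "beta2")
  }
  if (variant == "chain") {
    if (syn$N < 1 || syn$N != round(syn$N) || syn$M < 1 || syn$M != round(syn$M))
      stop("`N` and `M` must be positive integers")
    syn$N <- as.integer(syn$N); syn$M <- as.integer(syn$M)
  }
  rates <- setdiff(need, c("N", "M"))
  bad <- vapply(rates, function(nm) !is.finite(syn[[nm]]) || syn[[nm]] <= 0,
                logical(1))
  if (any(bad)) stop("non-positive synthesis rate(s): ", toString(rates[bad]))
  syn[unique(c(need, intersect(names(syn), c("r1", "r2", "N", "M"))))]
}

.check_delays <- function(variant, syn, delays) {
  if (variant == "III") {
    if (is.null(delays)) {
      if (all(c("N", "M") %in% names(syn)))
        delays <- list(tau_N = syn$N / syn$r1, tau_M = syn$M / syn$r2)
      else stop("variant III needs `delays = list(tau_N = , tau_M = )`")
    }
    if (!all(c("tau_N", "tau_M") %in% names(delays)))
      stop("variant III needs lags `tau_N` and `tau_M` (minutes)")
    if (delays$tau_N < 0 || delays$tau_M < 0) stop("lags must be >= 0")
    return(list(tau_N = delays$tau_N, tau_M = delays$tau_M))
  }
  if (variant == "DDE_CRS") {
    if (is.null(delays)) delays <- delay_spec("erlang", shape = 1,
                                              rate = syn$gamma, target = "mp")
    if (inherits(delays, "delay_spec")) delays <- list(delays)
    if (length(delays) != 1L || !inherits(delays[[1]], "delay_spec"))
      stop("variant DDE_CRS takes exactly one delay_spec")
    delays[[1]]$target <- "mp"
    return(delays)
  }
  if (!is.null(delays)) stop("variant ", variant, " takes no delays")
  NULL
}

.state_names <- function(variant, syn, delays) {
  switch(variant,
    I = c("m", "c"),
    II = c("m0", "m", "c0", "c"),
    chain = c("m0", paste0("m", seq_len(syn$N)), "m",
              "c0", paste0("c", seq_len(syn$M)), "c"),
    III = c("m0", "m", "c0", "c"),
    IV_full = c("a0", "a1", "a2", "a3", "c"),
    IV = c("a0", "a1", "a2", "c"),
    QSS = "c",
    V = c("a0", "a1", "a2", "m", "c"),
    DDE_CRS = c("a0", "a1", "a2", "mp"))
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("Single-gene autoinhibitory circuit, variant %s (%d state%s)\n",
              x$variant, x$dimension, if (x$dimension > 1) "s" else ""))
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  syn <- x$synthesis
  cat("  rates (/min):",
      paste(sprintf("%s = %g", names(syn), unlist(syn)), collapse = ", "), "\n")
  if (!is.null(x$crs)) print(x$crs) else print(x$regulation)
  if (x$variant == "III")
    cat(sprintf("  discrete lags: tau_N = %g min, tau_M = %g min\n",
                x$delays$tau_N, x$delays$tau_M))
  if (x$variant == "DDE_CRS") print(x$delays[[1]])
  invisible(x)
}

#' @export
coef.circuit_model <- function(object, ...) {
  out <- unlist(object$synthesis)
  if (!is.null(object$crs))
    out <- c(out, unlist(object$crs[c("k01", "k12", "k23", "k10", "k21", "k32")]))
  else if (object$regulation$form == "hill")
    out <- c(out, Kd = object$regulation$Kd, nH = object$regulation$nH)
  else out <- c(out, K1 = object$regulation$Ks[1], K2 = object$regulation$Ks[2],
                K3 = object$regulation$Ks[3])
  out
}

# does the model carry a discrete delay?
has_discrete_delay <- function(model) {
  if (model$variant == "III") return(TRUE)
  if (model$variant == "DDE_CRS") return(model$delays[[1]]$kind == "discrete")
  FALSE
}

# promoter occupancy-chain derivatives given the TF concentration seen by the
# promoter (cd); a = c(a0, a1, a2)
crs_block <- function(k, a, cd, a3 = 1 - sum(a)) {
  c(-k$k01 * a[1] * cd + k$k10 * a[2],
    -k$k12 * a[2] * cd + k$k21 * a[3] + k$k01 * a[1] * cd - k$k10 * a[2],
    -k$k23 * a[3] * cd + k$k32 * a3 + k$k12 * a[2] * cd - k$k21 * a[3])
}

#' Right-hand side of a circuit model
#'
#' Evaluates the time derivative of the state for any model variant. Delay
#' variants additionally require a lookup function for past states.
#'
#' @param model A [circuit_model()].
#' @param t Time, minutes.
#' @param state Numeric state vector, in the order of `model$state_names`.
#' @param lagged For discrete-delay variants, a function `f(t_past)` returning
#'   the full state vector at `t_past`; ignored otherwise.
#' @return The derivative vector, per minute.
#' @examples
#' m <- circuit_model("I",
#'   synthesis = list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23),
#'   regulation = hill_regulation(40, 2))
#' model_rhs(m, 0, c(m = 0, c = 0))  # c(alpha_m, 0)
#' @export
model_rhs <- function(model, t, state, lagged = NULL) {
  if (length(state) != model$dimension)
    stop("state has length ", length(state), ", expected ", model$dimension)
  if (has_discrete_delay(model) && is.null(lagged))
    stop("variant ", model$variant, " needs a `lagged` state lookup")
  syn <- model$synthesis
  k <- model$crs
  switch(model$variant,
    I = {
      R <- regulatory_value(model$regulation, state[2])
      c(syn$alpha_m * R - syn$gamma_m * state[1],
        syn$alpha * state[1] - syn$gamma * state[2])
    },
    II = {
      R <- regulatory_value(model$regulation, state[4])
      c(syn$alpha_m * R - syn$beta1 * state[1],
        syn$beta1 * state[1] - syn$gamma_m * state[2],
        syn$alpha * state[2] - syn$beta2 * state[3],
        syn$beta2 * state[3] - syn$gamma * state[4])
    },
    chain = {
      N <- syn$N; M <- syn$M
      cidx <- N + M + 4L
      R <- regulatory_value(model$regulation, state[cidx])
      mstates <- state[1:(N + 2L)]           # m0, m1..mN, m
      cstates <- state[(N + 3L):cidx]        # c0, c1..cM, c
      dm <- c(syn$alpha_m * R - syn$r1 * mstates[1],
              syn$r1 * mstates[1:N] - syn$r1 * mstates[2:(N + 1L)],
              syn$r1 * mstates[N + 1L] - syn$gamma_m * mstates[N + 2L])
      dc <- c(syn$alpha * mstates[N + 2L] - syn$r2 * cstates[1],
              syn$r2 * cstates[1:M] - syn$r2 * cstates[2:(M + 1L)],
              syn$r2 * cstates[M + 1L] - syn$gamma * cstates[M + 2L])
      c(dm, dc)
    },
    III = {
      R <- regulatory_value(model$regulation, state[4])
      m0_lag <- lagged(t - model$delays$tau_N)[1]
      c0_lag <- lagged(t - model$delays$tau_M)[3]
      c(syn$alpha_m * R - syn$r1 * state[1],
        syn$r1 * m0_lag - syn$gamma_m * state[2],
        syn$alpha * state[2] - syn$r2 * state[3],
        syn$r2 * c0_lag - syn$gamma * state[4])
    },
    IV_full = {
      a <- state[1:3]; a3 <- state[4]; cc <- state[5]
      da <- crs_block(k, a, cc, a3 = a3)
      da3 <- k$k23 * a[3] * cc - k$k32 * a3
      dc <- syn$alpha * a[1] - syn$gamma * cc +
        k$k10 * a[2] + k$k21 * a[3] + k$k32 * a3 -
        cc * (k$k01 * a[1] + k$k12 * a[2] + k$k23 * a[3])
      c(da, da3, dc)
    },
    IV = {
      a <- state[1:3]; cc <- state[4]
      c(crs_block(k, a, cc), syn$alpha * a[1] - syn$gamma * cc)
    },
    QSS = {
      R <- regulatory_value(model$regulation, state[1])
      syn$alpha * R - syn$gamma * state[1]
    },
    V = {
      a <- state[1:3]; m <- state[4]; cc <- state[5]
      c(crs_block(k, a, cc),
        syn$alpha_m * a[1] - syn$gamma_m * m,
        syn$alpha * m - syn$gamma * cc)
    },
    DDE_CRS = {
      d <- model$delays[[1]]
      if (d$kind == "discrete") {
        cd <- lagged(t - d$lag)[4]
        a <- state[1:3]; mp <- state[4]
        pref <- syn$alpha_m * syn$alpha / syn$gamma
        c(crs_block(k, a, cd), pref * a[1] - syn$gamma_m * mp)
      } else {
        stop("Erlang-kernel models are plain ODEs after chain expansion; ",
             "call expand_chain() first")
      }
    },
    DDE_CRS_chain = {
      ch <- model$chain
      a <- state[1:3]; mp <- state[4]
      s <- state[4L + seq_len(ch$shape)]
      cd <- s[ch$shape]                       # kernel-filtered m'
      pref <- syn$alpha_m * syn$alpha / syn$gamma
      ds <- ch$rate * (c(mp, s[-ch$shape]) - s)
      c(crs_block(k, a, cd), pref * a[1] - syn$gamma_m * mp, ds)
    })
}
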