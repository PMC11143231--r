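#' Cooperative-binding specification for a three-site cis-regulatory system
#'
#' Bundles the elementary transcription-factor (TF) binding rate `p`, the
#' unbinding rate `q`, and the cooperativity intensity `epsilon` together with
#' the mechanism through which cooperativity acts:
#' \describe{
#'   \item{`"RM"` (recruitment)}{already-bound TFs raise the binding rates of
#'     subsequent TFs by a factor `epsilon^i`.}
#'   \item{`"SM"` (stabilization)}{bound TFs lower the unbinding rates by a
#'     factor `epsilon^i`.}
#' }
#' The promoter carries three identical regulatory sites; transcription occurs
#' only from the fully unoccupied state.
#'
#' @param mechanism `"RM"` or `"SM"`.
#' @param p Binding rate, per minute per molecule. Must be positive.
#' @param q Unbinding rate, per minute. Must be positive.
#' @param epsilon Cooperativity intensity (dimensionless), `>= 1`. `epsilon = 1`
#'   is non-cooperative binding, for which the two mechanisms coincide.
#' @param n_sites Number of identical regulatory sites. Only 3 is supported.
#' @return An object of class `"cooperativity_spec"`.
#' @examples
#' cooperativity_spec("RM", p = 0.1, q = 31.3, epsilon = 5.5)
#' @export
cooperativity_spec <- function(mechanism = c("RM", "SM"), p, q, epsilon,
                               n_sites = 3L) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(q), length(q) == 1L,
            is.numeric(epsilon), length(epsilon) == 1L)
  if (!is.finite(p) || p <= 0) stop("binding rate `p` must be positive")
  if (!is.finite(q) || q <= 0) stop("unbinding rate `q` must be positive")
  if (!is.finite(epsilon) || epsilon < 1)
    stop("cooperativity intensity `epsilon` must be >= 1 ",
         "(anti-cooperativity is not supported)")
  if (n_sites != 3L) stop("only a three-site regulatory system is supported")
  structure(list(mechanism = mechanism, p = p, q = q, epsilon = epsilon,
                 n_sites = 3L),
            class = "cooperativity_spec")
}

#' @export
print.cooperativity_spec <- function(x, ...) {
  cat(sprintf(
    "Cooperative binding: %s, p = %g /min/molec, q = %g /min, epsilon = %g (3 sites)\n",
    if (x$mechanism == "RM") "recruitment" else "stabilization",
    x$p, x$q, x$epsilon))
  invisible(x)
}

#' Promoter binding/unbinding rates under a cooperative mechanism
#'
#' Maps a [cooperativity_spec()] to the six mass-action rates of the sequential
#' occupancy chain \eqn{a_0 \leftrightarrow a_1 \leftrightarrow a_2
#' \leftrightarrow a_3}. For the recruitment mechanism,
#' \eqn{k_{i,i+1} = \epsilon^i (3-i) p} and \eqn{k_{i+1,i} = (i+1) q}; for the
#' stabilization mechanism, \eqn{k_{i,i+1} = (3-i) p} and
#' \eqn{k_{i+1,i} = (i+1) q / \epsilon^i} (for \eqn{i = 0, 1, 2}). The
#' combinatorial factors count the free (occupied) sites available for binding
#' (unbinding).
#'
#' @param spec A [cooperativity_spec()].
#' @return An object of class `"crs_kinetics"`: list with forward rates
#'   `k01`, `k12`, `k23` (per minute per molecule), backward rates `k10`,
#'   `k21`, `k32` (per minute), and the `mechanism` tag.
#' @examples
#' cooperative_rates(cooperativity_spec("RM", 0.1, 31.3, 5.5))
#' @export
cooperative_rates <- function(spec) {
  if (!inherits(spec, "cooperativity_spec"))
    stop("`spec` must be a cooperativity_spec")
  i <- 0:2
  if (spec$mechanism == "RM") {
    kon <- spec$epsilon^i * (3 - i) * spec$p
    koff <- (i + 1) * spec$q
  } else {
    kon <- (3 - i) * spec$p
    koff <- (i + 1) * spec$q / spec$epsilon^i
  }
  structure(list(k01 = kon[1], k12 = kon[2], k23 = kon[3],
                 k10 = koff[1], k21 = koff[2], k32 = koff[3],
                 mechanism = spec$mechanism),
            class = "crs_kinetics")
}

#' @export
print.crs_kinetics <- function(x, ...) {
  cat(sprintf("CRS kinetics (%s):\n", x$mechanism))
  cat(sprintf("  binding   k01 = %g, k12 = %g, k23 = %g  (/min/molec)\n",
              x$k01, x$k12, x$k23))
  cat(sprintf("  unbinding k10 = %g, k21 = %g, k32 = %g  (/min)\n",
              x$k10, x$k21, x$k32))
  invisible(x)
}

#' Equilibrium association constants of the occupancy chain
#'
#' Componentwise ratios \eqn{K_1 = k_{01}/k_{10}}, \eqn{K_2 = k_{12}/k_{21}},
#' \eqn{K_3 = k_{23}/k_{32}} (per molecule). For rates built by
#' [cooperative_rates()] these reduce to \eqn{K_1 = 3p/q},
#' \eqn{K_2 = \epsilon p / q}, \eqn{K_3 = \epsilon^2 p / (3q)} for either
#' mechanism: the cooperativity factors cancel in the ratios, which is why the
#' two mechanisms share one equilibrium regulatory function.
#'
#' @param k A `"crs_kinetics"` object (or anything list-like with the six
#'   named rates).
#' @return An object of class `"equilibrium_constants"`: numeric vector
#'   `c(K1, K2, K3)`.
#' @examples
#' equilibrium_constants(cooperative_rates(cooperativity_spec("SM", 0.1, 31.3, 5.5)))
#' @export
equilibrium_constants <- function(k) {
  need <- c("k01", "k12", "k23", "k10", "k21", "k32")
  if (!all(need %in% names(k))) stop("`k` must carry the six rates ", toString(need))
  kk <- unlist(k[need])
  if (any(!is.finite(kk)) || any(kk <= 0))
    stop("all six kinetic rates must be positive and finite")
  structure(c(K1 = k$k01 / k$k10, K2 = k$k12 / k$k21, K3 = k$k23 / k$k32),
            class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat(sprintf("Equilibrium constants (per molecule): K1 = %g, K2 = %g, K3 = %g\n",
              x[["K1"]], x[["K2"]], x[["K3"]]))
  invisible(x)
}

#' Adair regulatory function of a three-site repressive promoter
#'
#' The quasi-steady-state probability that the promoter is fully unoccupied,
#' \deqn{R^{qss}(c) = (1 + c K_1 + c^2 K_1 K_2 + c^3 K_1 K_2 K_3)^{-1},}
#' which is the fraction of time transcription can proceed when the repressor
#' concentration is `c` molecules. Strictly decreasing from
#' \eqn{R^{qss}(0) = 1} towards 0.
#'
#' @param c TF concentration, molecules (vectorized, `>= 0`).
#' @param Ks An [equilibrium_constants()] object or numeric vector
#'   `c(K1, K2, K3)`.
#' @return Occupancy-free fraction in `(0, 1]`, same length as `c`.
#' @examples
#' Ks <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", 0.1, 31.3, 5.5)))
#' adair_regulatory(c(0, 40, 1e6), Ks)
#' @export
adair_regulatory <- function(c, Ks) {
  Ks <- .check_Ks(Ks)
  if (any(!is.finite(c)) || any(c < 0)) stop("concentration `c` must be >= 0")
  1 / (1 + c * Ks[1] + c^2 * Ks[1] * Ks[2] + c^3 * Ks[1] * Ks[2] * Ks[3])
}

# derivative dR/dc of the Adair function (used by linearization)
adair_deriv <- function(c, Ks) {
  Ks <- .check_Ks(Ks)
  poly <- 1 + c * Ks[1] + c^2 * Ks[1] * Ks[2] + c^3 * Ks[1] * Ks[2] * Ks[3]
  dpoly <- Ks[1] + 2 * c * Ks[1] * Ks[2] + 3 * c^2 * Ks[1] * Ks[2] * Ks[3]
  -dpoly / poly^2
}

.check_Ks <- function(Ks) {
  Ks <- unname(unlist(Ks))
  if (length(Ks) != 3L || any(!is.finite(Ks)) || any(Ks < 0))
    stop("`Ks` must be three non-negative finite equilibrium constants")
  Ks
}

#' Hill regulatory function (repressive)
#'
#' The phenomenological sigmoid \eqn{R(c) = 1 / (1 + (c/K_d)^{n_H})} with
#' apparent dissociation constant `Kd` (molecules) and Hill exponent `nH`.
#' Satisfies `R(Kd) = 1/2` exactly.
#'
#' @param c TF concentration, molecules (vectorized, `>= 0`).
#' @param Kd Apparent dissociation constant, molecules, `> 0`.
#' @param nH Hill exponent, dimensionless, `> 0`.
#' @return Value in `(0, 1]`, same length as `c`.
#' @examples
#' hill_regulatory(c(0, 40, 80), Kd = 40, nH = 2)
#' @export
hill_regulatory <- function(c, Kd, nH) {
  if (!is.finite(Kd) || Kd <= 0) stop("`Kd` must be positive")
  if (!is.finite(nH) || nH <= 0) stop("`nH` must be positive")
  if (any(!is.finite(c)) || any(c < 0)) stop("concentration `c` must be >= 0")
  1 / (1 + (c / Kd)^nH)
}

hill_deriv <- function(c, Kd, nH) {
  x <- (c / Kd)^nH
  ifelse(c == 0, if (nH >= 1) 0 else -Inf, -nH * x / (c * (1 + x)^2))
}

#' Regulation specification
#'
#' A small container selecting the closed-form regulatory function used by the
#' Hill-regulated model variants, either phenomenological (`hill_regulation()`)
#' or occupancy-derived (`adair_regulation()`). Evaluate with
#' [regulatory_value()].
#'
#' @param Kd,nH Hill parameters (see [hill_regulatory()]).
#' @return An object of class `"regulation_spec"`.
#' @examples
#' reg <- hill_regulation(Kd = 40, nH = 2)
#' regulatory_value(reg, 40)
#' @export
hill_regulation <- function(Kd, nH) {
  hill_regulatory(0, Kd, nH)  # validates
  structure(list(form = "hill", Kd = Kd, nH = nH), class = "regulation_spec")
}

#' @rdname hill_regulation
#' @param Ks Equilibrium constants (see [adair_regulatory()]).
#' @export
adair_regulation <- function(Ks) {
  Ks <- .check_Ks(Ks)
  structure(list(form = "adair", Ks = Ks), class = "regulation_spec")
}

#' Evaluate a regulation specification
#'
#' @param reg A `"regulation_spec"`.
#' @param c TF concentration, molecules.
#' @return `R(c)` in `(0, 1]`.
#' @export
regulatory_value <- function(reg, c) {
  stopifnot(inherits(reg, "regulation_spec"))
  if (reg$form == "hill") hill_regulatory(c, reg$Kd, reg$nH)
  else adair_regulatory(c, reg$Ks)
}

regulatory_deriv <- function(reg, c) {
  if (reg$form == "hill") hill_deriv(c, reg$Kd, reg$nH)
  else adair_deriv(c, reg$Ks)
}

#' @export
print.regulation_spec <- function(x, ...) {
  if (x$form == "hill")
    cat(sprintf("Hill regulation: Kd = %g molec, nH = %g\n", x$Kd, x$nH))
  else
    cat(sprintf("Adair regulation: K1 = %g, K2 = %g, K3 = %g (per molecule)\n",
                x$Ks[1], x$Ks[2], x$Ks[3]))
  invisible(x)
}

#' Effective phenomenological parameters of an Adair curve
#'
#' Maps equilibrium constants of the three-site occupancy chain to the
#' parameters of the Hill function that best characterizes the curve at its
#' midpoint: `Kd_eff` is the unique concentration at which
#' \eqn{R^{qss}(c) = 1/2} (equivalently \eqn{c K_1 + c^2 K_1 K_2 + c^3 K_1 K_2
#' K_3 = 1}), and `nH_eff` is the magnitude of the Hill-plot slope
#' \eqn{-d\log[R/(1-R)]/d\log c} evaluated there, which for the Adair form is
#' \deqn{n_H^{eff} = \frac{K_1 c + 2 K_1 K_2 c^2 + 3 K_1 K_2 K_3 c^3}
#'                        {K_1 c + K_1 K_2 c^2 + K_1 K_2 K_3 c^3}.}
#' For a true Hill function the slope is constant and the map is the identity;
#' for the three-site Adair curve `1 <= nH_eff <= 3`.
#'
#' @param Ks An [equilibrium_constants()] object or numeric `c(K1, K2, K3)`.
#' @param tol Absolute tolerance on the half-repression root, molecules.
#' @return A list with `Kd_eff` (molecules) and `nH_eff` (dimensionless).
#' @examples
#' Ks <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", 0.1, 31.3, 5.5)))
#' effective_hill(Ks)  # Kd_eff ~ 40, nH_eff ~ 1.96
#' @export
effective_hill <- function(Ks, tol = 1e-10) {
  Ks <- .check_Ks(Ks)
  if (Ks[1] <= 0) stop("K1 must be positive to locate the half-repression point")
  g <- function(c) c * Ks[1] + c^2 * Ks[1] * Ks[2] + c^3 * Ks[1] * Ks[2] * Ks[3] - 1
  lo <- 1e-9
  hi <- 1 / Ks[1]
  it <- 0L
  while (g(hi) < 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 200L) stop("failed to bracket the half-repression point ",
                        "(Ks = ", toString(signif(Ks, 6)), ")")
  }
  if (g(lo) > 0) stop("half-repression point below bracketing floor")
  Kd <- uniroot(g, c(lo, hi), tol = tol)$root
  num <- Ks[1] * Kd + 2 * Ks[1] * Ks[2] * Kd^2 + 3 * Ks[1] * Ks[2] * Ks[3] * Kd^3
  den <- Ks[1] * Kd + Ks[1] * Ks[2] * Kd^2 + Ks[1] * Ks[2] * Ks[3] * Kd^3
  list(Kd_eff = Kd, nH_eff = num / den)
}

#' Export a regulation curve for plotting or inspection
#'
#' Evaluates a regulation specification on a concentration grid, returning both
#' the raw curve and its Hill-plot transform \eqn{\log_{10}[R/(1-R)]}.
#'
#' @param reg A `"regulation_spec"`.
#' @param c_grid Concentrations, molecules; defaults to a log grid around the
#'   half-repression point.
#' @return A data.frame with columns `c`, `R`, `log10_c`, `log10_R_ratio`.
#' @export
regulation_curve <- function(reg, c_grid = NULL) {
  stopifnot(inherits(reg, "regulation_spec"))
  if (is.null(c_grid)) {
    mid <- if (reg$form == "hill") reg$Kd else effective_hill(reg$Ks)$Kd_eff
    c_grid <- 10^seq(log10(mid) - 2, log10(mid) + 2, length.out = 200)
  }
  R <- regulatory_value(reg, c_grid)
  data.frame(c = c_grid, R = R,
             log10_c = log10(c_grid),
             log10_R_ratio = log10(R / (1 - R)))
}
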