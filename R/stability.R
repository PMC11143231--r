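#' Linearize a circuit model about its steady state
#'
#' Builds the instantaneous Jacobian `A` and, for discrete-delay variants, the
#' delayed Jacobians `B_j` with their lags, all by analytic differentiation of
#' the model right-hand side. The characteristic function is
#' \deqn{\chi(\lambda) = \det\left(\lambda I - A - \sum_j B_j
#'   e^{-\lambda \tau_j}\right),}
#' a polynomial of degree equal to the system dimension when no discrete lags
#' are present and a transcendental function otherwise. Erlang-kernel models
#' are expanded into their exact first-order chains first.
#'
#' @param model A [circuit_model()].
#' @return An object of class `"linearization"`: list with `fixed_point`,
#'   `A`, `B` (list of delayed Jacobians), `taus`, `chi` (vectorized
#'   characteristic function of a complex argument), and `dimension`.
#' @export
linearize <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  if (model$variant == "DDE_CRS" && model$delays[[1]]$kind == "erlang")
    model <- expand_chain(model)
  fp <- fixed_point(model)
  cs <- attr(fp, "c_star")
  syn <- model$synthesis
  k <- model$crs
  n <- model$dimension
  Rp <- regulatory_deriv(model$regulation, cs)
  B <- list(); taus <- numeric(0)

  A <- switch(model$variant,
    I = matrix(c(-syn$gamma_m, syn$alpha_m * Rp,
                 syn$alpha, -syn$gamma), 2, 2, byrow = TRUE),
    II = {
      M <- matrix(0, 4, 4)
      M[1, 1] <- -syn$beta1; M[1, 4] <- syn$alpha_m * Rp
      M[2, 1] <- syn$beta1; M[2, 2] <- -syn$gamma_m
      M[3, 2] <- syn$alpha; M[3, 3] <- -syn$beta2
      M[4, 3] <- syn$beta2; M[4, 4] <- -syn$gamma
      M
    },
    chain = {
      N <- syn$N; Mm <- syn$M
      M <- matrix(0, n, n)
      M[1, 1] <- -syn$r1; M[1, n] <- syn$alpha_m * Rp
      for (i in seq_len(N)) { M[i + 1, i] <- syn$r1; M[i + 1, i + 1] <- -syn$r1 }
      M[N + 2, N + 1] <- syn$r1; M[N + 2, N + 2] <- -syn$gamma_m
      M[N + 3, N + 2] <- syn$alpha; M[N + 3, N + 3] <- -syn$r2
      for (j in seq_len(Mm)) {
        M[N + 3 + j, N + 2 + j] <- syn$r2
        M[N + 3 + j, N + 3 + j] <- -syn$r2
      }
      M[n, n - 1] <- syn$r2; M[n, n] <- -syn$gamma
      M
    },
    III = {
      M <- matrix(0, 4, 4)
      M[1, 1] <- -syn$r1; M[1, 4] <- syn$alpha_m * Rp
      M[2, 2] <- -syn$gamma_m
      M[3, 2] <- syn$alpha; M[3, 3] <- -syn$r2
      M[4, 4] <- -syn$gamma
      B1 <- matrix(0, 4, 4); B1[2, 1] <- syn$r1
      B2 <- matrix(0, 4, 4); B2[4, 3] <- syn$r2
      B <- list(B1, B2); taus <- c(model$delays$tau_N, model$delays$tau_M)
      M
    },
    IV_full = {
      a <- fp[1:4]
      M <- matrix(0, 5, 5)
      M[1, ] <- c(-k$k01 * cs, k$k10, 0, 0, -k$k01 * a[1])
      M[2, ] <- c(k$k01 * cs, -k$k12 * cs - k$k10, k$k21, 0,
                  k$k01 * a[1] - k$k12 * a[2])
      M[3, ] <- c(0, k$k12 * cs, -k$k23 * cs - k$k21, k$k32,
                  k$k12 * a[2] - k$k23 * a[3])
      M[4, ] <- c(0, 0, k$k23 * cs, -k$k32, k$k23 * a[3])
      M[5, ] <- c(syn$alpha - cs * k$k01, k$k10 - cs * k$k12,
                  k$k21 - cs * k$k23, k$k32,
                  -syn$gamma - (k$k01 * a[1] + k$k12 * a[2] + k$k23 * a[3]))
      M
    },
    IV = {
      jb <- .crs_jacobian(k, cs, fp[1:3])
      M <- matrix(0, 4, 4)
      M[1:3, 1:3] <- jb$da; M[1:3, 4] <- jb$dc
      M[4, ] <- c(syn$alpha, 0, 0, -syn$gamma)
      M
    },
    QSS = matrix(syn$alpha * Rp - syn$gamma, 1, 1),
    V = {
      jb <- .crs_jacobian(k, cs, fp[1:3])
      M <- matrix(0, 5, 5)
      M[1:3, 1:3] <- jb$da; M[1:3, 5] <- jb$dc
      M[4, ] <- c(syn$alpha_m, 0, 0, -syn$gamma_m, 0)
      M[5, ] <- c(0, 0, 0, syn$alpha, -syn$gamma)
      M
    },
    DDE_CRS = {
      jb <- .crs_jacobian(k, cs, fp[1:3])
      M <- matrix(0, 4, 4)
      M[1:3, 1:3] <- jb$da
      M[4, ] <- c(syn$alpha_m * syn$alpha / syn$gamma, 0, 0, -syn$gamma_m)
      B1 <- matrix(0, 4, 4); B1[1:3, 4] <- jb$dc
      B <- list(B1); taus <- model$delays[[1]]$lag
      M
    },
    DDE_CRS_chain = {
      sh <- model$chain$shape; r <- model$chain$rate
      jb <- .crs_jacobian(k, cs, fp[1:3])
      M <- matrix(0, n, n)
      M[1:3, 1:3] <- jb$da; M[1:3, n] <- jb$dc   # promoter reads s_shape
      M[4, ] <- c(syn$alpha_m * syn$alpha / syn$gamma, 0, 0, -syn$gamma_m,
                  rep(0, sh))
      for (j in seq_len(sh)) {
        M[4 + j, 4 + j] <- -r
        M[4 + j, 3 + j] <- r     # stage j fed by mp (j = 1) or s_{j-1}
      }
      M
    })

  chi <- .make_chi(A, B, taus)
  structure(list(model = model, fixed_point = fp, A = A, B = B, taus = taus,
                 chi = chi, dimension = n),
            class = "linearization")
}

# Jacobian blocks of the 3-state promoter chain (with the k32(1 - sum a) term)
# wrt (a0, a1, a2) and wrt the concentration the promoter sees
.crs_jacobian <- function(k, cd, a) {
  da <- matrix(0, 3, 3)
  da[1, ] <- c(-k$k01 * cd, k$k10, 0)
  da[2, ] <- c(k$k01 * cd, -k$k12 * cd - k$k10, k$k21)
  da[3, ] <- c(-k$k32, k$k12 * cd - k$k32, -k$k23 * cd - k$k21 - k$k32)
  dc <- c(-k$k01 * a[1], k$k01 * a[1] - k$k12 * a[2], k$k12 * a[2] - k$k23 * a[3])
  list(da = da, dc = dc)
}

.make_chi <- function(A, B, taus) {
  force(A); force(B); force(taus)
  n <- nrow(A)
  one_chi <- function(l) {
    M <- diag(n) * l - A
    for (j in seq_along(B)) M <- M - B[[j]] * exp(-l * taus[j])
    if (any(!is.finite(Re(M))) || any(!is.finite(Im(M)))) return(NA_complex_)
    .cdet(M)
  }
  function(lambda) vapply(lambda, one_chi, complex(1))
}

# determinant of a (possibly complex) matrix via partial-pivot elimination
.cdet <- function(M) {
  n <- nrow(M)
  M <- M + 0i
  d <- 1 + 0i
  if (n == 1L) return(M[1, 1])
  for (j in seq_len(n - 1L)) {
    p <- which.max(Mod(M[j:n, j])) + j - 1L
    if (Mod(M[p, j]) == 0) return(0 + 0i)
    if (p != j) { M[c(j, p), ] <- M[c(p, j), ]; d <- -d }
    d <- d * M[j, j]
    rows <- (j + 1L):n
    M[rows, ] <- M[rows, ] - outer(M[rows, j] / M[j, j], M[j, ])
  }
  d * M[n, n]
}

#' Degree of the characteristic polynomial
#'
#' For models without discrete delays the characteristic function is a
#' polynomial whose degree equals the system dimension after Erlang chains are
#' expanded. Discrete-delay models have a transcendental characteristic
#' equation with infinitely many roots; asking for a degree is an error that
#' points to [rightmost_roots()].
#'
#' @param model A [circuit_model()].
#' @return Integer degree.
#' @export
char_poly_degree <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  if (has_discrete_delay(model))
    stop("discrete-delay models have a transcendental characteristic ",
         "equation; use rightmost_roots() on the linearization")
  if (model$variant == "DDE_CRS") model <- expand_chain(model)
  model$dimension
}

#' Rightmost characteristic roots
#'
#' Finds roots of the characteristic function \eqn{\chi(\lambda)} of a
#' [linearize()]d model by damped Newton iteration from a grid of complex
#' seeds in a search box, deduplicated and sorted by decreasing real part.
#' Only representatives with non-negative imaginary part are returned
#' (conjugates follow by symmetry of the real system). For delay-free models
#' the roots agree with the Jacobian eigenvalues.
#'
#' @param lin A `"linearization"`.
#' @param re_range,im_range Search box for `Re` and `Im` of the roots, 1/min.
#'   The default imaginary ceiling 60/min covers oscillation periods down to
#'   about 6 s.
#' @param n_seeds Seeds per axis of the starting grid.
#' @param extra_seeds Optional complex values added to the seed list (used to
#'   warm-start parameter scans).
#' @return Complex vector sorted by decreasing real part; empty (with a
#'   warning) if no seed converges.
#' @export
rightmost_roots <- function(lin, re_range = c(-20, 5), im_range = c(0, 60),
                            n_seeds = 25, extra_seeds = NULL) {
  stopifnot(inherits(lin, "linearization"))
  chi <- lin$chi
  seeds <- c(as.vector(outer(seq(re_range[1], re_range[2], length.out = n_seeds),
                             1i * seq(im_range[1], im_range[2],
                                      length.out = n_seeds), `+`)),
             extra_seeds)
  roots <- complex(0)
  for (s in seeds) {
    l <- s
    converged <- FALSE
    for (it in 1:80) {
      if (!is.finite(Mod(l)) || Mod(l) > 1e6) break
      h <- 1e-7 * max(1, Mod(l))
      v <- chi(l)
      dv <- (chi(l + h) - chi(l - h)) / (2 * h)
      if (is.na(v) || is.na(dv) || Mod(dv) < 1e-300) break
      step <- v / dv
      if (Mod(step) > 5) step <- step * 5 / Mod(step)   # damping far away
      l <- l - step
      if (Mod(step) < 1e-10 * max(1, Mod(l))) { converged <- TRUE; break }
    }
    if (converged &&
        Re(l) >= re_range[1] - 0.5 && Re(l) <= re_range[2] + 0.5 &&
        abs(Im(l)) <= im_range[2] + 0.5) {
      roots <- c(roots, complex(real = Re(l), imaginary = abs(Im(l))))
    }
  }
  if (!length(roots)) {
    warning("no characteristic root converged in the search box")
    return(complex(0))
  }
  key <- paste(round(Re(roots), 6), round(Im(roots), 6))
  roots <- roots[!duplicated(key)]
  roots[order(-Re(roots))]
}

#' Classify the steady state of a circuit model
#'
#' Root-based classification of the fixed point, cross-checked by a long
#' numerical integration from a perturbed start:
#' \itemize{
#'   \item `stable_node`: leading root real and negative;
#'   \item `stable_spiral`: leading complex pair with negative real part;
#'   \item `unstable_oscillatory`: leading pair with positive real part and
#'     nonzero imaginary part, and the simulation shows a bounded sustained
#'     oscillation;
#'   \item `unstable_other`: positive real leading root;
#'   \item `inconclusive`: the root-based and simulation-based views disagree
#'     (never silently resolved).
#' }
#' Delay-free variants use Jacobian eigenvalues directly; discrete-delay
#' variants use [rightmost_roots()]. Roots with `|Im| > 1e-8` count as a
#' complex pair; `|Re| < 1e-7` is treated as marginal and defers to the
#' simulation.
#'
#' @param model A [circuit_model()].
#' @param simulation_check Run the trajectory cross-check (default `TRUE`).
#' @param times Time grid for the cross-check integration.
#' @param perturbation Relative perturbation of the non-promoter states of the
#'   fixed point used as the starting condition.
#' @param n_seeds Passed to [rightmost_roots()] for delay variants.
#' @return An object of class `"stability_report"`.
#' @export
classify <- function(model, simulation_check = TRUE,
                     times = seq(0, 2000, 0.05), perturbation = 0.2,
                     n_seeds = 25) {
  stopifnot(inherits(model, "circuit_model"))
  lin <- linearize(model)
  if (length(lin$B)) {
    roots <- rightmost_roots(lin, n_seeds = n_seeds)
    method <- "dde_roots"
  } else {
    ev <- eigen(lin$A, only.values = TRUE)$values
    roots <- ev[Im(ev) >= 0]
    roots <- roots[order(-Re(roots))]
    method <- "eigen"
  }
  lead <- roots[1]
  oscillatory_lead <- any(abs(Re(roots) - Re(lead)) < 1e-7 &
                            abs(Im(roots)) > 1e-8)
  root_class <- if (abs(Re(lead)) < 1e-7) "marginal"
  else if (Re(lead) < 0) {
    if (oscillatory_lead) "stable_spiral" else "stable_node"
  } else {
    if (oscillatory_lead) "unstable_oscillatory" else "unstable_other"
  }

  sim <- NULL
  classification <- root_class
  if (simulation_check || root_class == "marginal") {
    fp <- lin$fixed_point
    init <- .perturb_fixed_point(model, fp, perturbation)
    traj <- integrate_model(model, times = times, init = init)
    var <- if ("c" %in% names(traj)) "c" else utils::tail(names(traj), 1)
    sim <- summarize_oscillation(traj, variable = var)
    end_dev <- abs(utils::tail(traj[[var]], 1) - attr(fp, "c_star"))
    start_dev <- abs(traj[[var]][1] - attr(fp, "c_star"))
    sim_converges <- !sim$sustained && end_dev < max(0.05 * start_dev, 1e-6)
    sim_class <- if (sim$sustained) "oscillatory" else if (sim_converges)
      "converging" else "undecided"
    if (root_class == "marginal") {
      classification <- switch(sim_class,
        oscillatory = "unstable_oscillatory",
        converging = if (oscillatory_lead) "stable_spiral" else "stable_node",
        "inconclusive")
    } else {
      root_osc <- root_class == "unstable_oscillatory"
      agree <- (root_osc && sim_class == "oscillatory") ||
        (!root_osc && root_class %in% c("stable_node", "stable_spiral") &&
           sim_class != "oscillatory") ||
        (root_class == "unstable_other" && sim_class != "converging")
      if (!agree) classification <- "inconclusive"
    }
  }
  structure(list(classification = classification,
                 leading_roots = utils::head(roots, 5),
                 fixed_point = lin$fixed_point, method = method,
                 simulation = sim),
            class = "stability_report")
}

.perturb_fixed_point <- function(model, fp, factor) {
  init <- as.numeric(fp)
  names(init) <- model$state_names
  mol <- !grepl("^a[0-9]$", names(init))   # perturb molecule counts only
  init[mol] <- init[mol] * (1 + factor)
  init
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Steady-state classification:", x$classification,
      sprintf("(%s)\n", x$method))
  cat(sprintf("  c* = %g molecules\n", attr(x$fixed_point, "c_star")))
  cat("  leading roots (1/min):\n")
  for (r in x$leading_roots)
    cat(sprintf("    %+.6f %+.6fi\n", Re(r), Im(r)))
  if (!is.null(x$simulation) && isTRUE(x$simulation$sustained))
    cat(sprintf("  simulation: sustained oscillation, period %.3f min\n",
                x$simulation$period))
  invisible(x)
}

#' Scan a parameter for the oscillation (Hopf) threshold
#'
#' Bisects on the sign of the leading characteristic-root real part across a
#' parameter range, returning the critical value at which the steady state
#' loses stability. Root searches at bisection midpoints are warm-started
#' from the roots found at the bracket endpoints, so only the two endpoint
#' evaluations pay for a full seed grid.
#'
#' @param make_model Function of one numeric parameter value returning a
#'   [circuit_model()].
#' @param range Length-2 numeric scan interval.
#' @param tol Absolute tolerance on the threshold parameter value.
#' @param n_seeds Seed-grid size for the endpoint root searches.
#' @return A list with `threshold` (`NA` if the classification does not change
#'   in range), `status`, and `trace` (data.frame of evaluated parameter
#'   values and leading real parts).
#' @examples
#' \donttest{
#' make <- function(nH) circuit_model("II",
#'   synthesis = list(alpha_m = 33, gamma_m = 0.23, alpha = 4.5, gamma = 0.23,
#'                    beta1 = 0.23, beta2 = 0.23),
#'   regulation = hill_regulation(40, nH))
#' hopf_scan(make, c(1, 10))$threshold  # ~ 4.13
#' }
#' @export
hopf_scan <- function(make_model, range, tol = 1e-4, n_seeds = 25) {
  stopifnot(length(range) == 2, range[1] < range[2])
  warm <- complex(0)
  lead_re <- function(value, full_grid) {
    lin <- linearize(make_model(value))
    if (!length(lin$B)) {
      ev <- eigen(lin$A, only.values = TRUE)$values
      return(max(Re(ev)))
    }
    roots <- if (full_grid) rightmost_roots(lin, n_seeds = n_seeds)
    else rightmost_roots(lin, n_seeds = 4, extra_seeds = warm)
    if (!length(roots)) return(NA_real_)
    warm <<- utils::head(c(roots, warm), 12)
    Re(roots[1])
  }
  lo <- range[1]; hi <- range[2]
  f_lo <- lead_re(lo, full_grid = TRUE)
  f_hi <- lead_re(hi, full_grid = TRUE)
  trace <- data.frame(value = c(lo, hi), leading_re = c(f_lo, f_hi))
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) {
    return(list(threshold = NA_real_, status = "no threshold in range",
                trace = trace))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- lead_re(mid, full_grid = FALSE)
    trace <- rbind(trace, data.frame(value = mid, leading_re = f_mid))
    if (is.na(f_mid)) return(list(threshold = NA_real_,
                                  status = "root search failed mid-scan",
                                  trace = trace))
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  list(threshold = if (f_lo < 0) hi else lo, status = "ok", trace = trace)
}
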