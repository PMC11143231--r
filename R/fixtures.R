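#' Sample synthetic cooperative-binding parameter sets
#'
#' Draws reproducible batches of CRS kinetic parameters spanning the
#' biologically plausible range: residence times `1/q` log-uniform over
#' 2–100 s (single-molecule tracking range for specific regulatory sites),
#' binding rate `p` log-uniform over 0.001–1 per minute, cooperativity
#' intensity `epsilon` log-uniform over 1–20, and alternating mechanisms.
#' Used to exercise every pipeline stage without external data.
#'
#' @param n Number of draws, `>= 1`.
#' @param seed Integer seed; the same seed always reproduces the same batch
#'   (generator fixed to Mersenne-Twister via [set.seed()]).
#' @return A data.frame of class `"fixture_batch"` with columns `mechanism`,
#'   `p`, `q`, `epsilon`, `residence_s`; attributes `seed` and
#'   `provenance = "synthetic"`.
#' @examples
#' batch <- sample_crs_params(5, seed = 1)
#' range(batch$residence_s)  # within [2, 100]
#' @export
sample_crs_params <- function(n, seed) {
  stopifnot(n >= 1, is.numeric(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  res_s <- exp(stats::runif(n, log(2), log(100)))       # residence time, s
  q <- 60 / res_s                                       # per minute
  p <- exp(stats::runif(n, log(0.001), log(1)))
  eps <- exp(stats::runif(n, log(1), log(20)))
  batch <- data.frame(mechanism = rep(c("RM", "SM"), length.out = n),
                      p = p, q = q, epsilon = eps, residence_s = res_s)
  structure(batch, seed = as.integer(seed), provenance = "synthetic",
            class = c("fixture_batch", "data.frame"))
}

#' Perturbed initial conditions around a steady state
#'
#' Multiplies each component of the model's fixed point by `(1 + u)` with `u`
#' uniform on `+/- relative_amplitude`. For the full promoter model the four
#' occupancy fractions are renormalized to sum to one afterwards, so the
#' conserved quantity keeps its physical value. For delay variants the
#' returned state doubles as a constant pre-history (the integrator's
#' default).
#'
#' @param model A [circuit_model()].
#' @param relative_amplitude Perturbation amplitude in `(0, 1)`; `0` returns
#'   the fixed point itself.
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric initial-state vector.
#' @export
perturbed_initials <- function(model, relative_amplitude, seed = NULL) {
  stopifnot(inherits(model, "circuit_model"),
            relative_amplitude >= 0, relative_amplitude < 1)
  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  fp <- fixed_point(model)
  if (relative_amplitude == 0) return(fp)
  for (try in 1:100) {
    u <- stats::runif(length(fp), -relative_amplitude, relative_amplitude)
    init <- as.numeric(fp) * (1 + u)
    if (all(init >= 0)) break
  }
  if (any(init < 0)) stop("could not draw a non-negative perturbed state")
  names(init) <- model$state_names
  if (model$variant == "IV_full") {
    a <- grepl("^a[0-9]$", names(init))
    init[a] <- init[a] / sum(init[a])
  }
  attr(init, "c_star") <- attr(fp, "c_star")
  init
}
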