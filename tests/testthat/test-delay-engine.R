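test_that("Erlang kernel density is normalized with the stated moments", {
  w <- delay_spec("erlang", shape = 1, rate = 4.6)
  tau <- c(0, 0.1, 0.5, 2)
  expect_equal(kernel_density(w, tau), 4.6 * exp(-4.6 * tau))

  for (spec in list(w, delay_spec("erlang", shape = 2, rate = 4),
                    delay_spec("erlang", shape = 6, rate = 0.5))) {
    mu <- kernel_mean(spec)
    norm <- integrate(function(x) kernel_density(spec, x), 0, 60 * mu,
                      rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
    m1 <- integrate(function(x) x * kernel_density(spec, x), 0, 60 * mu,
                    rel.tol = 1e-10)$value
    expect_equal(m1, spec$shape / spec$rate, tolerance = 1e-8)
  }
  expect_equal(kernel_mean(delay_spec("erlang", shape = 2, rate = 4)), 0.5)
  expect_error(kernel_density(w, -1), ">= 0")
})

test_that("chain expansion grows the dimension by the kernel shape", {
  md1 <- circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs(),
                       delays = delay_spec("erlang", shape = 1, rate = 4.6))
  md2 <- circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs(),
                       delays = delay_spec("erlang", shape = 2, rate = 4.6))
  expect_equal(expand_chain(md1)$dimension, 5L)
  expect_equal(expand_chain(md2)$dimension, 6L)
  mdd <- circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs(),
                       delays = delay_spec("discrete", lag = 3.5))
  expect_error(expand_chain(mdd), "cannot be\\s+expanded")
})

test_that("the weak-kernel model is model V in disguise", {
  # the shape-1 chain expansion must reproduce model V exactly under the
  # rescaling m' = (alpha/gamma) m, c = s1
  tt <- seq(0, 200, 0.01)
  trv <- integrate_model(circuit_model("V", fig5_syn, crs = fig5_crs()),
                         times = tt)
  trd <- integrate_model(circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs()),
                         times = tt)
  expect_lt(max(abs(trv$c - trd$c)), 1e-8)
  expect_lt(max(abs(trv$m * 4.5 / 4.6 - trd$mp)), 1e-8)
})

test_that("chain expansion equals the integro-differential form", {
  # linear feedback test problem: x' = 1 - D[x] - x with a weak kernel of
  # rate 1. Route A: exact chain expansion. Route B: trapezoid quadrature of
  # the distributed-delay integral over the stored past solution.
  tt <- seq(0, 30, 0.01)
  chain <- solve_delay_system(function(t, y, lagged)
    c(1 - y[2] - y[1], 1 * (y[1] - y[2])),
    init = c(0, 0), times = tt, atol = 1e-12, rtol = 1e-10)

  htau <- 0.02
  tau_grid <- seq(0, 20, htau)
  kern <- exp(-tau_grid)                 # shape-1, rate-1 Erlang density
  wts <- c(0.5, rep(1, length(tau_grid) - 2), 0.5) * htau
  rhs_int <- function(t, y, lagged) {
    past <- vapply(t - tau_grid, function(tp) {
      if (tp <= 0) 0 else if (tp >= t) y[1] else lagged(tp)[1]
    }, numeric(1))
    conv <- sum(wts * kern * past)
    1 - conv - y[1]
  }
  quad <- solve_delay_system(rhs_int, init = 0, times = tt, lags = 1,
                             atol = 1e-10, rtol = 1e-9)
  expect_lt(max(abs(chain[, 2] - quad[, 2])), 1e-4)
})

test_that("the method of steps reproduces the analytic cosine solution", {
  sol <- solve_delay_system(function(t, y, lagged) -lagged(t - pi / 2),
                            init = 1, times = seq(0, 20, 0.001), lags = pi / 2,
                            history = function(t) cos(t),
                            atol = 1e-10, rtol = 1e-10)
  expect_lt(max(abs(sol[, 2] - cos(sol[, 1]))), 1e-6)
})

test_that("a zero lag degenerates to the ordinary initial-value solve", {
  m0 <- circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs(),
                      delays = delay_spec("discrete", lag = 0))
  tt <- seq(0, 50, 0.01)
  tr0 <- integrate_model(m0, times = tt, atol = 1e-12, rtol = 1e-11)
  # independent path: the same equations hand-coded as a plain ODE
  k <- fig5_crs()
  pref <- 33 * 4.5 / 4.6
  ode_rhs <- function(t, y, p) {
    cd <- y[4]
    list(c(-k$k01 * y[1] * cd + k$k10 * y[2],
           -k$k12 * y[2] * cd + k$k21 * y[3] + k$k01 * y[1] * cd - k$k10 * y[2],
           -k$k23 * y[3] * cd + k$k32 * (1 - y[1] - y[2] - y[3]) +
             k$k12 * y[2] * cd - k$k21 * y[3],
           pref * y[1] - 0.23 * y[4]))
  }
  ref <- deSolve::ode(c(1, 0, 0, 0), tt, ode_rhs, NULL,
                      atol = 1e-12, rtol = 1e-11)
  expect_lt(max(abs(tr0$mp - ref[, 5])), 1e-8)
})

test_that("Erlang trajectories approach the discrete-delay limit monotonically", {
  mk <- function(d) circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs(),
                                  delays = d)
  res <- erlang_to_discrete_limit_check(mk, mean_lag = 1,
                                        shapes = c(1, 4, 16, 64),
                                        times = seq(0, 100, 0.02))
  expect_equal(res$shape, c(1L, 4L, 16L, 64L))
  # monotone non-increasing with 5% slack
  expect_true(all(diff(res$distance) <= 0.05 * res$distance[-nrow(res)]))
})

test_that("histories default to constant continuation of the start state", {
  m3 <- model_III()
  tr <- integrate_model(m3, times = seq(0, 5, 0.01))
  # during t < tau_M the delayed c0 term reads the zero history, so c stays 0
  expect_true(all(tr$c[tr$t_min < 2.8] == 0))
  # an explicit history changes that
  tr2 <- integrate_model(m3, times = seq(0, 5, 0.01),
                         history = function(t) c(1, 0, 2, 0))
  expect_true(any(tr2$c[tr2$t_min < 2.8] > 0))
})
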