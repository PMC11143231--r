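test_that("model dimensions match their variant", {
  expect_equal(model_I()$dimension, 2L)
  expect_equal(model_II()$dimension, 4L)
  expect_equal(model_III()$dimension, 4L)
  mch <- circuit_model("chain", c(lewis_syn, list(r1 = 2, r2 = 2, N = 3, M = 2)),
                       regulation = hill40())
  expect_equal(mch$dimension, 9L)  # 3 + 2 + 4
  expect_equal(circuit_model("V", fig5_syn, crs = fig5_crs())$dimension, 5L)
  expect_equal(circuit_model("IV_full", list(alpha = 4.5, gamma = 4.6),
                             crs = fig5_crs())$dimension, 5L)
  expect_equal(circuit_model("QSS", list(alpha = 4.5, gamma = 4.6),
                             crs = fig5_crs())$dimension, 1L)
})

test_that("inconsistent model specifications are rejected by name", {
  expect_error(circuit_model("I", list(alpha_m = 33), regulation = hill40()),
               "gamma_m")
  expect_error(circuit_model("IV", list(alpha = 4.5, gamma = 4.6),
                             regulation = hill40()),
               "explicit promoter")
  expect_error(circuit_model("I", lewis_syn, crs = fig5_crs()),
               "closed-form")
  expect_error(circuit_model("I", lewis_syn, regulation = hill40(),
                             delays = list(tau_N = 1)), "no delays")
  expect_error(circuit_model("II", lewis_syn, regulation = hill40()), "beta")
  expect_error(circuit_model("I",
    list(alpha_m = 33, gamma_m = -1, alpha = 4.5, gamma = 0.23),
    regulation = hill40()), "non-positive")
})

test_that("right-hand sides evaluate the model equations", {
  m1 <- model_I()
  expect_equal(model_rhs(m1, 0, c(0, 0)), c(33, 0))

  # the full promoter model conserves total promoter probability exactly
  m4f <- circuit_model("IV_full", list(alpha = 4.5, gamma = 4.6),
                       crs = fig5_crs())
  set.seed(7)
  for (i in 1:20) {
    a <- runif(4); a <- a / sum(a)
    st <- c(a, runif(1, 0, 100))
    expect_equal(sum(model_rhs(m4f, 0, st)[1:4]), 0, tolerance = 1e-12)
  }

  # model IV vanishes at its quasi-steady-state fixed point
  m4 <- circuit_model("IV", list(alpha = 4.5, gamma = 4.6), crs = fig5_crs())
  expect_lt(max(abs(model_rhs(m4, 0, fixed_point(m4)))), 1e-10)

  expect_error(model_rhs(m1, 0, c(1, 2, 3)), "length")
  expect_error(model_rhs(model_III(), 0, rep(0, 4)), "lagged")
})

test_that("the shared fixed point solves the scalar balance equation", {
  m1 <- model_I()
  fp <- fixed_point(m1)
  cs <- attr(fp, "c_star")
  # independent oracle: c* is the positive root of c^3 + Kd^2 c = Kd^2 * A
  A <- 33 * 4.5 / 0.23^2
  expect_equal(cs^3 + 40^2 * cs, 40^2 * A, tolerance = 1e-6)
  expect_equal(cs, 161.7602, tolerance = 1e-4)
  expect_equal(unname(fp["m"]), 33 * hill_regulatory(cs, 40, 2) / 0.23,
               tolerance = 1e-8)

  # description levels I, II, III share the fixed point
  expect_equal(attr(fixed_point(model_II()), "c_star"), cs, tolerance = 1e-9)
  expect_equal(attr(fixed_point(model_III()), "c_star"), cs, tolerance = 1e-9)

  # explicit-CRS family: V and its kernel reduction share the fixed point,
  # and match the reference value for the kernel-order comparison regime
  mv <- circuit_model("V", fig5_syn, crs = fig5_crs())
  md <- circuit_model("DDE_CRS", fig5_syn, crs = fig5_crs())
  cs5 <- attr(fixed_point(mv), "c_star")
  expect_equal(attr(fixed_point(md), "c_star"), cs5, tolerance = 1e-9)
  expect_equal(cs5, 20.2744, tolerance = 1e-4)

  # IV matches V when its aggregate expression rate is alpha_m*alpha/gamma_m
  m4 <- circuit_model("IV",
    list(alpha = 33 * 4.5 / 0.23, gamma = 4.6), crs = fig5_crs())
  expect_equal(attr(fixed_point(m4), "c_star"), cs5, tolerance = 1e-9)
})

test_that("promoter occupancies at the fixed point obey detailed balance", {
  m4 <- circuit_model("IV", list(alpha = 4.5, gamma = 4.6), crs = fig5_crs())
  fp <- fixed_point(m4)
  Ks <- as.numeric(equilibrium_constants(fig5_crs()))
  cs <- attr(fp, "c_star")
  expect_equal(unname(fp["a1"] / fp["a0"]), Ks[1] * cs, tolerance = 1e-10)
  expect_equal(unname(fp["a2"] / fp["a1"]), Ks[2] * cs, tolerance = 1e-10)
})

test_that("quasi-steady-state reduction preserves the fixed point", {
  m4 <- circuit_model("IV", list(alpha = 4.5, gamma = 4.6), crs = fig5_crs())
  mq <- qss_reduce(m4)
  expect_equal(mq$variant, "QSS")
  expect_equal(attr(fixed_point(mq), "c_star"), attr(fixed_point(m4), "c_star"),
               tolerance = 1e-9)

  mch <- circuit_model("chain", c(lewis_syn, list(r1 = 2, r2 = 2, N = 4, M = 3)),
                       regulation = hill40())
  mi <- qss_reduce(mch)
  expect_equal(mi$variant, "I")
  expect_equal(attr(fixed_point(mi), "c_star"),
               attr(fixed_point(mch), "c_star"), tolerance = 1e-9)
  expect_equal(qss_reduce(model_II())$variant, "I")
  mv <- circuit_model("V", fig5_syn, crs = fig5_crs())
  expect_error(qss_reduce(mv), "no quasi-steady-state reduction")
})

test_that("promoter probability is conserved along full-model trajectories", {
  m4f <- circuit_model("IV_full", list(alpha = 4.5, gamma = 4.6),
                       crs = fig5_crs())
  traj <- integrate_model(m4f, times = seq(0, 500, 0.1),
                          atol = 1e-12, rtol = 1e-10)
  asum <- rowSums(traj[c("a0", "a1", "a2", "a3")])
  expect_lt(max(abs(asum - 1)), 1e-9)

  # reduced promoter block stays inside the probability simplex
  m4 <- circuit_model("IV", list(alpha = 4.5, gamma = 4.6), crs = fig5_crs())
  tr <- integrate_model(m4, times = seq(0, 200, 0.05))
  s <- rowSums(tr[c("a0", "a1", "a2")])
  expect_true(all(s >= -1e-9 & s <= 1 + 1e-9))
})

test_that("dropping the sequestration flux changes little at high TF numbers", {
  t4 <- seq(0, 100, 0.01)
  trf <- integrate_model(circuit_model("IV_full",
    list(alpha = 4.5, gamma = 4.6), crs = fig5_crs()), times = t4)
  tr4 <- integrate_model(circuit_model("IV",
    list(alpha = 4.5, gamma = 4.6), crs = fig5_crs()), times = t4)
  expect_lt(max(abs(trf$c - tr4$c)) / max(tr4$c), 0.02)
})

test_that("the planar model cannot oscillate and contracts to its fixed point", {
  m1 <- model_I()
  # divergence of the vector field is -gamma_m - gamma everywhere
  L <- linearize(m1)
  expect_equal(sum(diag(L$A)), -0.23 - 0.23)
  traj <- integrate_model(m1, times = seq(0, 800, 0.1))
  cs <- attr(fixed_point(m1), "c_star")
  dev <- abs(traj$c - cs)
  expect_lt(tail(dev, 1), 1e-6 * cs)
  # distance envelope contracts over successive windows (windows chosen to
  # span at least one rotation and to end before the deviation reaches the
  # integrator noise floor)
  early <- traj$t_min <= 80
  win <- split(dev[early], cut(traj$t_min[early], 4))
  expect_true(all(diff(vapply(win, max, numeric(1))) < 0))
})
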