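test_that("cooperative rates follow the recruitment and stabilization rules", {
  rm_rates <- cooperative_rates(cooperativity_spec("RM", 0.1, 31.3, 5.5))
  expect_equal(unlist(rm_rates[c("k01", "k12", "k23")]),
               c(k01 = 0.3, k12 = 1.1, k23 = 3.025))
  expect_equal(unlist(rm_rates[c("k10", "k21", "k32")]),
               c(k10 = 31.3, k21 = 62.6, k32 = 93.9))

  sm_rates <- cooperative_rates(cooperativity_spec("SM", 0.1, 31.3, 5.5))
  expect_equal(unlist(sm_rates[c("k01", "k12", "k23")]),
               c(k01 = 0.3, k12 = 0.2, k23 = 0.1))
  expect_equal(unlist(sm_rates[c("k10", "k21", "k32")]),
               c(k10 = 31.3, k21 = 62.6 / 5.5, k32 = 93.9 / 5.5^2))

  # without cooperativity the two mechanisms coincide
  r1 <- cooperative_rates(cooperativity_spec("RM", 0.4, 7, 1))
  r2 <- cooperative_rates(cooperativity_spec("SM", 0.4, 7, 1))
  expect_equal(unclass(r1)[1:6], unclass(r2)[1:6])
})

test_that("invalid cooperativity parameters are rejected", {
  expect_error(cooperativity_spec("RM", -0.1, 31.3, 5.5), "positive")
  expect_error(cooperativity_spec("RM", 0.1, 0, 5.5), "positive")
  expect_error(cooperativity_spec("RM", 0.1, 31.3, 0.5), "epsilon")
  expect_error(cooperativity_spec("RM", 0.1, 31.3, 5.5, n_sites = 2), "three-site")
})

test_that("equilibrium constants are mechanism-independent rate ratios", {
  spec_rm <- cooperativity_spec("RM", 0.1, 31.3, 5.5)
  spec_sm <- cooperativity_spec("SM", 0.1, 31.3, 5.5)
  Ks_rm <- equilibrium_constants(cooperative_rates(spec_rm))
  Ks_sm <- equilibrium_constants(cooperative_rates(spec_sm))
  # closed forms K1 = 3p/q, K2 = eps*p/q, K3 = eps^2*p/(3q)
  expect_equal(as.numeric(Ks_rm),
               c(3 * 0.1 / 31.3, 5.5 * 0.1 / 31.3, 5.5^2 * 0.1 / (3 * 31.3)),
               tolerance = 1e-12)
  expect_equal(as.numeric(Ks_rm), as.numeric(Ks_sm), tolerance = 1e-14)

  Ks <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", 2, 2, 1)))
  expect_equal(as.numeric(Ks), c(3, 1, 1 / 3))

  bad <- list(k01 = 1, k12 = 1, k23 = 1, k10 = 0, k21 = 1, k32 = 1)
  expect_error(equilibrium_constants(bad), "positive")
})

test_that("the Adair function is a monotone repressor with R(0) = 1", {
  Ks <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", 0.1, 31.3, 5.5)))
  expect_identical(adair_regulatory(0, Ks), 1)
  expect_equal(adair_regulatory(40, Ks), 0.5, tolerance = 1e-3)
  expect_lt(adair_regulatory(1e6, Ks), 1e-6)
  cgrid <- seq(0, 500, 0.5)
  expect_true(all(diff(adair_regulatory(cgrid, Ks)) < 0))
  expect_true(all(adair_regulatory(cgrid, Ks) > 0 &
                    adair_regulatory(cgrid, Ks) <= 1))
  expect_error(adair_regulatory(-1, Ks), ">= 0")
})

test_that("RM and SM give identical Adair curves over a parameter grid", {
  cgrid <- c(0, 10^seq(-2, 4, length.out = 80))
  for (p in c(0.01, 0.1, 1)) for (q in c(0.6, 6, 30)) for (eps in c(1, 3, 15)) {
    Ks_rm <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", p, q, eps)))
    Ks_sm <- equilibrium_constants(cooperative_rates(cooperativity_spec("SM", p, q, eps)))
    expect_lt(max(abs(adair_regulatory(cgrid, Ks_rm) -
                        adair_regulatory(cgrid, Ks_sm))), 1e-12)
  }
})

test_that("the Hill function satisfies its defining identities", {
  expect_equal(hill_regulatory(40, 40, 2), 0.5)
  expect_equal(hill_regulatory(80, 40, 2), 0.2)
  expect_identical(hill_regulatory(0, 40, 2), 1)
  expect_error(hill_regulatory(1, -40, 2), "positive")
  expect_error(hill_regulatory(1, 40, 0), "positive")
})

test_that("effective Hill parameters reproduce the reference pairs", {
  pairs <- list(
    list(p = 0.1, q = 31.3, eps = 5.5, Kd = 40, nH = 1.96),
    list(p = 0.1, q = 43, eps = 8.5, Kd = 40.1, nH = 2.21),
    list(p = 0.1, q = 6.26, eps = 5.5, Kd = 8, nH = 1.96))
  for (pp in pairs) {
    Ks <- equilibrium_constants(cooperative_rates(
      cooperativity_spec("RM", pp$p, pp$q, pp$eps)))
    eff <- effective_hill(Ks)
    expect_equal(eff$Kd_eff, pp$Kd, tolerance = 0.01)
    expect_equal(eff$nH_eff, pp$nH, tolerance = 0.01)
  }
})

test_that("scaling q rescales Kd_eff and leaves nH_eff unchanged", {
  base <- effective_hill(equilibrium_constants(cooperative_rates(
    cooperativity_spec("RM", 0.1, 31.3, 5.5))))
  for (s in c(0.2, 0.5, 2, 5)) {
    scaled <- effective_hill(equilibrium_constants(cooperative_rates(
      cooperativity_spec("RM", 0.1, 31.3 * s, 5.5))))
    expect_equal(scaled$Kd_eff, base$Kd_eff * s, tolerance = 1e-8)
    expect_equal(scaled$nH_eff, base$nH_eff, tolerance = 1e-8)
  }
})

test_that("the effective Hill exponent is the Hill-plot slope at midpoint", {
  # independent slope oracle: central difference of log[R/(1-R)] in log c
  Ks <- equilibrium_constants(cooperative_rates(cooperativity_spec("RM", 0.1, 43, 8.5)))
  eff <- effective_hill(Ks)
  h <- 1e-5
  lr <- function(c) {
    R <- adair_regulatory(c, Ks)
    log(R / (1 - R))
  }
  slope <- (lr(eff$Kd_eff * exp(h)) - lr(eff$Kd_eff * exp(-h))) / (2 * h)
  expect_equal(eff$nH_eff, -slope, tolerance = 1e-6)
})

test_that("effective Hill exponent stays within the site-count bounds", {
  # degenerate single-site limit
  eff1 <- effective_hill(c(0.02, 1e-9, 1e-9))
  expect_equal(eff1$nH_eff, 1, tolerance = 1e-4)
  expect_equal(eff1$Kd_eff, 1 / 0.02, tolerance = 1e-4)
  for (eps in c(1, 2, 8, 20, 100)) {
    Ks <- equilibrium_constants(cooperative_rates(
      cooperativity_spec("SM", 0.05, 4, eps)))
    eff <- effective_hill(Ks)
    expect_gte(eff$nH_eff, 1)
    expect_lte(eff$nH_eff, 3)
  }
})

test_that("regulation curves export raw and Hill-plot columns", {
  reg <- hill_regulation(40, 2)
  cur <- regulation_curve(reg)
  expect_named(cur, c("c", "R", "log10_c", "log10_R_ratio"))
  # constant Hill-plot slope equal to -nH for a pure Hill curve
  slopes <- diff(cur$log10_R_ratio) / diff(cur$log10_c)
  expect_equal(slopes, rep(-2, length(slopes)), tolerance = 1e-8)
})
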