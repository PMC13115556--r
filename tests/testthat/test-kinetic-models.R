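p_ref <- pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)

test_that("parameter validation enforces the model's constraints", {
  expect_error(pk_params(ka = -1, kd = 0.5, v = 10, dose = 100), "positive")
  expect_error(pk_params(ka = 1, kd = 0.5, v = 10, dose = 100, f = 1.2),
               "apparent_f")
  expect_no_error(pk_params(ka = 1, kd = 0.5, v = 10, dose = 100, f = 1.2,
                            apparent_f = TRUE))
  expect_error(pk_params(ka = 1, kd = 0.5, v = 10, dose = 100, kgut = 0.5),
               "kgut")
})

test_that("extravascular amount vanishes at t = 0 and at large t", {
  expect_equal(amount_classic(p_ref, 0), 0)
  expect_equal(amount_corrected(p_ref, 0), 0)
  expect_lt(amount_classic(p_ref, 1e3), 1e-12)
  expect_error(amount_classic(p_ref, -1), "non-negative")
})

test_that("closed-form amount matches the two-ODE system integrated numerically", {
  library(deSolve)
  gut_sys <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      dgut <- -kgut * gut
      dsys <- ka * gut - kd * sys
      list(c(dgut, dsys))
    })
  }
  for (p in list(p_ref,
                 pk_params(ka = 2, kd = 0.3, v = 20, dose = 50, f = 0.8),
                 pk_params(ka = 1, kgut = 2, kd = 0.5, v = 10, dose = 100))) {
    tt <- c(0.5, 1, 2, 4, 8)
    # classic: the available dose leaves the gut at rate ka
    ode_classic <- ode(y = c(gut = p$f * p$dose, sys = 0), times = c(0, tt),
                       func = gut_sys,
                       parms = c(ka = p$ka, kgut = p$ka, kd = p$kd),
                       rtol = 1e-10, atol = 1e-12)
    expect_equal(amount_classic(p, tt), unname(ode_classic[-1, "sys"]),
                 tolerance = 1e-7)
    # corrected: the gut loses drug at the total rate kgut >= ka
    ode_corr <- ode(y = c(gut = p$f * p$dose, sys = 0), times = c(0, tt),
                    func = gut_sys,
                    parms = c(ka = p$ka, kgut = p$kgut, kd = p$kd),
                    rtol = 1e-10, atol = 1e-12)
    expect_equal(amount_corrected(p, tt), unname(ode_corr[-1, "sys"]),
                 tolerance = 1e-7)
  }
})

test_that("gut-loss correction reduces to the classic model when kgut = ka", {
  tt <- seq(0, 24, by = 0.5)
  expect_identical(amount_corrected(p_ref, tt), amount_classic(p_ref, tt))
  p2 <- pk_params(ka = 0.8, kd = 1.4, v = 30, dose = 250, f = 0.6)
  expect_equal(auc_closed_form(p2, "corrected"), auc_closed_form(p2, "classic"))
})

test_that("extra gut loss lowers the systemic amount at every time", {
  p_loss <- pk_params(ka = 1, kgut = 2, kd = 0.5, v = 10, dose = 100)
  tt <- seq(0.1, 48, by = 0.1)
  expect_true(all(amount_corrected(p_loss, tt) < amount_classic(p_loss, tt)))
})

test_that("the coincident-rate-constant limit is continuous", {
  p_near <- pk_params(ka = 0.5 * (1 + 1e-9), kd = 0.5, v = 10, dose = 100)
  p_at <- pk_params(ka = 0.5, kd = 0.5, v = 10, dose = 100)
  tt <- c(0.5, 2, 5)
  # limit form: ka * F * Dose * t * exp(-ka t)
  expect_equal(amount_classic(p_at, tt), 0.5 * 100 * tt * exp(-0.5 * tt),
               tolerance = 1e-12)
  expect_equal(amount_classic(p_near, tt), amount_classic(p_at, tt),
               tolerance = 1e-6)
})

test_that("concentration is amount over volume", {
  tt <- c(0, 1, 3)
  expect_equal(concentration_extravascular(p_ref, tt),
               amount_classic(p_ref, tt) / 10)
  p_v1 <- pk_params(ka = 1, kd = 0.5, v = 1, dose = 100)
  expect_equal(concentration_extravascular(p_v1, tt), amount_classic(p_v1, tt))
  p_v20 <- pk_params(ka = 1, kd = 0.5, v = 20, dose = 100)
  expect_equal(concentration_extravascular(p_v20, tt),
               concentration_extravascular(p_ref, tt) / 2)
})

test_that("closed-form AUC matches adaptive quadrature", {
  expect_equal(auc_closed_form(p_ref), 20)
  p_corr <- pk_params(ka = 1, kgut = 2, kd = 0.5, v = 10, dose = 100)
  expect_equal(auc_closed_form(p_corr, "corrected"), 10)
  for (model in c("classic", "corrected")) {
    q <- stats::integrate(function(t) concentration_extravascular(p_corr, t, model),
                          0, Inf, rel.tol = 1e-10)
    expect_equal(q$value, auc_closed_form(p_corr, model), tolerance = 1e-8)
  }
})

test_that("terminal slope of the oral curve is the slower rate constant", {
  # flip-flop: absorption slower than elimination governs the tail
  p_ff <- pk_params(ka = 0.05, kd = 1, v = 10, dose = 100)
  tt <- seq(60, 160, by = 1)
  slope <- -coef(lm(log(concentration_extravascular(p_ff, tt)) ~ tt))[[2]]
  expect_equal(slope, 0.05, tolerance = 1e-6)
  p_fast <- pk_params(ka = 5, kd = 0.4, v = 10, dose = 100)
  tt2 <- seq(10, 30, by = 0.5)
  slope2 <- -coef(lm(log(concentration_extravascular(p_fast, tt2)) ~ tt2))[[2]]
  expect_equal(slope2, 0.4, tolerance = 1e-6)
})

test_that("clearance identities follow the series law", {
  expect_equal(clearance_identities(p_ref)$cl_iv, 5)
  ci <- clearance_identities(p_ref, cl_gut = 5)
  expect_equal(ci$cl_after_oral_kirchhoff, 2.5)
  ci_big <- clearance_identities(p_ref, cl_gut = 1e12)
  expect_equal(ci_big$cl_after_oral_kirchhoff, ci_big$cl_iv, tolerance = 1e-9)
  # gut clearance via a gut volume of distribution
  ci_vg <- clearance_identities(p_ref, v_gut = 5)
  expect_equal(ci_vg$cl_gut, p_ref$kgut * 5)
})

test_that("simulated profiles are tidy and route-aware", {
  pr <- simulate_profile(p_ref, c(0.5, 1, 2), route = "iv_bolus")
  expect_equal(pr$conc_mg_per_L, 10 * exp(-0.5 * c(0.5, 1, 2)))
  expect_named(pr, c("subject_id", "route", "time_h", "conc_mg_per_L",
                     "dose_mg"))
  expect_error(simulate_profile(p_ref, c(2, 1)), "increasing")
})
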