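# modest dense grid so quadrature error stays well under the 1% recovery bound
recovery_grid <- dense_grid(96, dt_early = 0.05, dt_late = 0.5, t_switch = 12)

test_that("study designs validate their fields", {
  expect_error(study_design(routes = c("oral", "subq")), "iv_bolus")
  expect_error(study_design(doses = c(iv_bolus = 100)), "every route")
  expect_error(study_design(sampling_times = c(1, 1, 2)), "increasing")
  expect_error(study_design(renal_fraction = 1.5))
  d <- study_design(n_subjects = 3, seed = 9)
  expect_s3_class(d, "study_design")
  expect_equal(length(default_sampling_times()), 14)
})

test_that("simulation is a pure function of design and seed", {
  des <- study_design(n_subjects = 4, noise_cv = 0.2, seed = 5)
  s1 <- simulate_study(des, model = "series_clearance")
  s2 <- simulate_study(des, model = "series_clearance")
  expect_identical(s1$concentrations, s2$concentrations)
  expect_identical(s1$urine, s2$urine)
  des2 <- study_design(n_subjects = 4, noise_cv = 0.2, seed = 6)
  s3 <- simulate_study(des2, model = "series_clearance")
  expect_false(identical(s1$concentrations$conc_mg_per_L,
                         s3$concentrations$conc_mg_per_L))
  # simulation must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_study(des)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("mass balance holds at zero noise", {
  des <- study_design(n_subjects = 3, noise_cv = 0, seed = 8,
                      sampling_times = dense_grid(400, 0.5, 2, 24),
                      renal_fraction = 0.6)
  sim <- simulate_study(des, model = "classic")
  last_cum <- sim$urine |>
    dplyr::group_by(.data$subject_id, .data$route) |>
    dplyr::summarise(last = max(.data$cum_amount_mg),
                     u_inf = .data$u_inf_mg[1], .groups = "drop")
  expect_equal(last_cum$last, last_cum$u_inf, tolerance = 1e-6)
  oral_u <- last_cum$u_inf[last_cum$route == "oral"]
  expect_equal(oral_u, rep(0.6 * 0.7 * 100, 3))   # renal_fraction * F * dose
  iv_u <- last_cum$u_inf[last_cum$route == "iv_bolus"]
  expect_equal(iv_u, rep(0.6 * 100, 3))
})

test_that("classic-model studies show no input effect on measured clearance", {
  des <- study_design(n_subjects = 3, noise_cv = 0, seed = 2,
                      sampling_times = recovery_grid)
  sim <- simulate_study(des, model = "classic")
  rec <- recover_parameters(sim)
  expect_equal(rec$f_auc, rec$f_urine, tolerance = 5e-3)
  expect_equal(rec$clr_oral, rec$clr_iv, tolerance = 5e-3)
  expect_equal(rec$cl_after_oral_hat, rec$cl_iv_hat, tolerance = 5e-3)
  # the implied gut clearance is unidentifiable/infeasible at the boundary
  expect_true(all(!rec$feasible | rec$ratio_gut_over_iv_hat > 50))
})

test_that("series-clearance studies reproduce the exposure-inflation identities", {
  des <- study_design(n_subjects = 4, noise_cv = 0, seed = 4,
                      sampling_times = recovery_grid)
  sim <- simulate_study(des, model = "series_clearance")
  rec <- recover_parameters(sim)
  tr <- sim$truths
  expect_true(all(rec$feasible))
  expect_equal(rec$cl_gut_hat, tr$cl_gut, tolerance = 1e-2)
  expect_equal(rec$cl_iv_hat, tr$cl_iv, tolerance = 5e-3)
  # f_auc / f_urine equals the clearance inflation CLiv / CL_after_oral
  expect_equal(rec$f_auc / rec$f_urine, tr$cl_iv / tr$cl_after_oral,
               tolerance = 5e-3)
  # the renal-clearance diagnostic drops by the same factor
  expect_equal(rec$clr_oral / rec$clr_iv, tr$cl_after_oral / tr$cl_iv,
               tolerance = 5e-3)
  expect_true(all(rec$clr_oral < rec$clr_iv))
  # urinary bioavailability stays at true F while f_auc is inflated
  expect_equal(rec$f_urine, rep(0.7, 4), tolerance = 5e-3)
  expect_true(all(rec$f_auc > rec$f_urine))
})

test_that("equal gut and iv clearances double the dose-corrected AUC ratio", {
  des <- study_design(n_subjects = 2, noise_cv = 0, bsv_cv = 0, seed = 12,
                      sampling_times = recovery_grid)
  sim <- simulate_study(des, model = "series_clearance",
                        population = list(cl_iv = 40, cl_gut = 40, v = 100,
                                          ka = 1.2, f = 0.7))
  rec <- recover_parameters(sim)
  expect_equal(rec$f_auc, 2 * rec$f_urine, tolerance = 5e-3)
  expect_equal(rec$ratio_gut_over_iv_hat, rep(1, 2), tolerance = 1e-2)
})

test_that("the renal diagnostic survives realistic noise", {
  # cimetidine-like: gut clearance equal to iv, 15% residual CV
  des <- study_design(n_subjects = 100, noise_cv = 0.15, seed = 14)
  sim <- simulate_study(des, model = "series_clearance",
                        population = list(cl_iv = 48.5, cl_gut = 48.5,
                                          v = 100, ka = 1.2, f = 0.7))
  rec <- recover_parameters(sim)
  expect_gte(mean(rec$clr_oral < rec$clr_iv), 0.95)
})

test_that("study CSVs round-trip through the declared schema", {
  dir <- withr::local_tempdir()
  des <- study_design(n_subjects = 2, seed = 3)
  sim <- simulate_study(des)
  paths <- write_study_csv(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_named(back, c("subject_id", "route", "time_h", "conc_mg_per_L",
                       "dose_mg"))
  expect_equal(nrow(back), nrow(sim$concentrations))
})

test_that("JSON design configs reproduce study_design()", {
  cfg <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_subjects = 5, routes = c("iv_bolus", "oral"),
         doses = list(iv_bolus = 100, oral = 400),
         renal_fraction = 0.5, noise_cv = 0.1, seed = 77),
    cfg, auto_unbox = TRUE)
  des <- read_study_design(cfg)
  expect_equal(des$n_subjects, 5L)
  expect_equal(des$doses[["oral"]], 400)
  expect_equal(des$seed, 77L)
  expect_equal(des$sampling_times, default_sampling_times())
})
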