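test_that("zero noise reproduces the noise-free predictions exactly", {
  tr <- forestland_truth()
  obs <- generate_tracer_dataset(tr, noise = noise_model(0, 0), seed = 1)
  pred <- simulate_observables(tr$model, tr$params, tr$design,
                               n_lab0 = tr$n_lab0, step = 0.005)
  expect_equal(obs$conc_mean, pred$conc_mean, tolerance = 1e-12)
  expect_equal(obs$ape_mean, pred$ape_mean, tolerance = 1e-12)
  expect_equal(obs$conc_sd, rep(0, 16))
  expect_equal(obs$ape_sd, rep(0, 16))
})

test_that("a fixed seed reproduces the written CSV byte for byte", {
  tr <- cropland_truth()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_observations(generate_tracer_dataset(tr, seed = 9), f1)
  write_observations(generate_tracer_dataset(tr, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives different data
  f3 <- tempfile(fileext = ".csv")
  write_observations(generate_tracer_dataset(tr, seed = 10), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  unlink(c(f1, f2, f3))
})

test_that("replicate means concentrate on the noise-free predictions", {
  # central-limit check at 200 replicates: standardized deviations of the
  # replicate means should exceed 3 standard errors only rarely
  tr <- forestland_truth()
  d <- tr$design
  d$replicates <- 200
  noise <- noise_model()
  obs <- generate_tracer_dataset(tr, design = d, noise = noise, seed = 33)
  pred <- simulate_observables(tr$model, tr$params, d, n_lab0 = tr$n_lab0,
                               step = 0.005)
  se_conc <- noise$conc_cv * pred$conc_mean / sqrt(200)
  se_ape <- noise$ape_sd / sqrt(200)
  z <- c(abs(obs$conc_mean - pred$conc_mean) / se_conc,
         abs(obs$ape_mean - pred$ape_mean) / se_ape)
  expect_gte(mean(z <= 3), 0.95)
})

test_that("negative noise parameters are rejected", {
  expect_error(noise_model(conc_cv = -0.1), ">= 0")
  expect_error(noise_model(ape_sd = -1), ">= 0")
})

test_that("solve_params_for_rates hits its targets and is deterministic", {
  d <- test_design()
  targets <- c(M_Nlab = 2, M_Nrec = 1, I_NH4_Nlab = 3, I_NH4_Nrec = 1,
               A_NH4 = 0.2, R_NH4 = 0.15, O_NH4 = 2.5, O_Nrec = 0.05,
               D_NO3 = 0.1, I_NO3 = 0.5)
  s1 <- solve_params_for_rates(targets, d, n_lab0 = 60)
  s2 <- solve_params_for_rates(targets, d, n_lab0 = 60)
  expect_identical(s1$params$value, s2$params$value)
  expect_equal(unname(s1$achieved_rates), unname(targets), tolerance = 1e-6)
  # a zero target switches the flux off
  targets["D_NO3"] <- 0
  s3 <- solve_params_for_rates(targets, d, n_lab0 = 60)
  expect_equal(unname(s3$achieved_rates["D_NO3"]), 0)
  expect_error(solve_params_for_rates(c(O_NH4 = -1), d), ">= 0")
  expect_error(solve_params_for_rates(c(X_bogus = 1), d), "unknown process")
})

test_that("named truths realize the group-mean rate targets", {
  for (tr in list(forestland_truth(), cropland_truth())) {
    expect_equal(unname(tr$achieved_rates), unname(tr$target_rates),
                 tolerance = 1e-6)
    m_n <- sum(tr$achieved_rates[c("M_Nlab", "M_Nrec")])
    i_nh4 <- sum(tr$achieved_rates[c("I_NH4_Nlab", "I_NH4_Nrec")])
    if (tr$land_use == "forestland") {
      expect_equal(m_n, 3.95, tolerance = 1e-6)
      expect_equal(i_nh4, 6.67, tolerance = 1e-6)
      expect_equal(unname(tr$achieved_rates["O_NH4"]), 1.99,
                   tolerance = 1e-6)
    } else {
      expect_equal(m_n, 4.84, tolerance = 1e-6)
      expect_equal(i_nh4, 0.34, tolerance = 1e-6)
      expect_equal(unname(tr$achieved_rates["O_NH4"]), 14.54,
                   tolerance = 1e-6)
    }
  }
})

test_that("cohorts are deterministic and C/N is consistent by construction", {
  a <- generate_cohort(seed = 14)
  b <- generate_cohort(seed = 14)
  expect_identical(a, b)
  expect_equal(nrow(a), 19)
  expect_equal(sum(a$land_use == "forestland"), 11)
  expect_equal(sum(a$land_use == "cropland"), 8)
  expect_equal(a$cn, a$soc / a$tn, tolerance = 1e-9)
  expect_true(all(a[, c("pH", "soc", "tn", "nh4", "no3")] > 0))
  expect_true(all(a[, process_table()$process_id] >= 0))
  expect_equal(a$M_N, a$M_Nlab + a$M_Nrec, tolerance = 1e-12)
  expect_error(generate_cohort(n_forest = 1), ">= 2")
})

test_that("large cohorts centre on the generating group means", {
  co <- generate_cohort(n_forest = 1000, n_crop = 1000, seed = 6)
  fl <- co[co$land_use == "forestland", ]
  cl <- co[co$land_use == "cropland", ]
  # O_NH4 centres 1.99 (forest) and 14.54 (cropland), within 3 SE
  expect_lt(abs(mean(fl$O_NH4) - 1.99), 3 * sd(fl$O_NH4) / sqrt(1000) + 0.02)
  expect_lt(abs(mean(cl$O_NH4) - 14.54), 3 * sd(cl$O_NH4) / sqrt(1000) + 0.02)
  expect_lt(abs(mean(fl$I_NH4) - 6.67), 3 * sd(fl$I_NH4) / sqrt(1000) + 0.02)
  expect_lt(abs(mean(fl$soc) - 22.91), 3 * sd(fl$soc) / sqrt(1000))
  # built-in land-use contrasts point the documented way
  expect_gt(mean(cl$O_NH4), mean(fl$O_NH4))
  expect_gt(mean(fl$I_NH4), mean(cl$I_NH4))
  expect_gt(mean(fl$soc), mean(cl$soc))
  expect_gt(mean(fl$cn), mean(cl$cn))
  expect_gt(mean(cl$no3), mean(fl$no3))
  # no built-in difference: group centres agree within Monte Carlo error
  expect_lt(abs(mean(fl$I_NO3) - mean(cl$I_NO3)), 0.05)
  expect_lt(abs(mean(fl$D_NO3) - mean(cl$D_NO3)), 0.02)
})

test_that("cohort samples can be expanded into fittable truths", {
  co <- generate_cohort(n_forest = 2, n_crop = 2, seed = 2,
                        solve_params = TRUE)
  expect_true(is.list(co$params))
  p <- co$params[[1]]
  expect_s3_class(p, "data.frame")
  expect_true(all(p$value >= p$lower & p$value <= p$upper))
})
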