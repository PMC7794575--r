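test_that("process_rate implements the three kinetic laws", {
  expect_equal(process_rate("zero", list(k = 2), 5), 2)
  expect_equal(process_rate("first", list(k = 0.1), 20), 2)
  expect_equal(process_rate("michaelis_menten", list(vmax = 10, km = 20), 20),
               5) # half saturation
  # substrate exhaustion shuts every law off
  for (args in list(list("zero", list(k = 2)), list("first", list(k = 1)),
                    list("michaelis_menten", list(vmax = 3, km = 1))))
    expect_equal(process_rate(args[[1]], args[[2]], 0), 0)
  expect_error(process_rate("first", list(k = 0.1), -1), "nonnegative")
  expect_error(process_rate("first", list(k = -0.1), 1), ">= 0")
  expect_error(process_rate("michaelis_menten", list(vmax = 1), 1), "km")
})

test_that("derivatives do single-flux bookkeeping with source enrichment", {
  sp <- single_process_model("O_NH4", "first", O_NH4.k = 0.5)
  d <- derivatives(base_state(nh4 = 20, nh4_frac = 0.10), sp$model, sp$params)
  expect_equal(unname(d$d_total_n["nh4"]), -10)
  expect_equal(unname(d$d_total_n["no3"]), 10)
  expect_equal(unname(d$d_n15["nh4"]), -1)
  expect_equal(unname(d$d_n15["no3"]), 1)
  expect_equal(unname(d$flux["O_NH4"]), 10)
})

test_that("all-inactive model has zero derivatives", {
  m <- default_model_structure()
  m$active <- FALSE
  d <- derivatives(base_state(), m, default_parameters(m))
  expect_equal(unname(d$d_total_n), rep(0, 5))
  expect_equal(unname(d$d_n15), rep(0, 5))
})

test_that("derivative sums vanish for random active configurations", {
  # oracle: both conservation sums recomputed independently from the flux
  # list and the source/sink registry
  set.seed(421)
  reg <- process_table()
  for (rep in 1:25) {
    cfg <- random_configuration()
    d <- derivatives(cfg$state, cfg$model, cfg$params)
    expect_lt(abs(sum(d$d_total_n)), 1e-12)
    expect_lt(abs(sum(d$d_n15)), 1e-12)
    # independent reassembly from fluxes
    acc <- setNames(rep(0, 5), c("nh4", "no3", "n_lab", "n_rec", "nh4_ads"))
    for (i in seq_len(nrow(reg))) {
      acc[reg$source_pool[i]] <- acc[reg$source_pool[i]] - d$flux[i]
      acc[reg$sink_pool[i]] <- acc[reg$sink_pool[i]] + d$flux[i]
    }
    expect_equal(unname(d$d_total_n), unname(acc), tolerance = 1e-12)
  }
})

test_that("unknown process id is rejected", {
  m <- default_model_structure()
  m$process_id[7] <- "O_bogus"
  expect_error(validate_model_structure(m), "unknown process id")
})

test_that("single-process simulations match closed forms", {
  # first order: exponential decay of the source
  sp <- single_process_model("O_NH4", "first", O_NH4.k = 0.5)
  tr <- simulate_pools(sp$model, sp$params, base_state(nh4 = 20, no3 = 5),
                       c(0, 1, 2))
  expect_equal(unname(tr$states[3, "nh4"]), 20 * exp(-1), tolerance = 1e-6)
  expect_equal(unname(tr$states[3, "no3"]), 5 + 20 * (1 - exp(-1)),
               tolerance = 1e-6)
  # zero order: linear accumulation before exhaustion
  sp <- single_process_model("M_Nrec", "zero", M_Nrec.k = 3)
  tr <- simulate_pools(sp$model, sp$params, base_state(nh4 = 20), c(0, 1, 2))
  expect_equal(tr$states[, "nh4"], c(20, 23, 26), tolerance = 1e-8,
               ignore_attr = TRUE)
  # empty model: constant trajectory
  m <- default_model_structure()
  m$active <- FALSE
  tr <- simulate_pools(m, default_parameters(m), base_state(), c(0, 0.7, 2))
  expect_equal(tr$states[1, ], tr$states[3, ])
})

test_that("Michaelis-Menten limits recover zero- and first-order solutions", {
  s0 <- base_state(nh4 = 20, no3 = 5)
  # km -> 0: flux -> vmax (zero order with k = vmax)
  mm <- single_process_model("O_NH4", "michaelis_menten",
                             O_NH4.vmax = 3, O_NH4.km = 1e-3)
  tr <- simulate_pools(mm$model, mm$params, s0, c(0, 1))
  z <- single_process_model("O_NH4", "zero", O_NH4.k = 3)
  trz <- simulate_pools(z$model, z$params, s0, c(0, 1))
  expect_equal(unname(tr$states[2, "nh4"]), unname(trz$states[2, "nh4"]),
               tolerance = 1e-3)
  # km -> Inf at fixed vmax/km: flux -> (vmax/km) * S (first order)
  mm <- single_process_model("O_NH4", "michaelis_menten",
                             O_NH4.vmax = 50, O_NH4.km = 100)
  mm$params$upper[mm$params$name == "O_NH4.km"] <- 1e6
  mm$params <- set_param_values(mm$params,
                                c(O_NH4.vmax = 5000, O_NH4.km = 1e4))
  mm$params$upper[mm$params$name == "O_NH4.vmax"] <- 1e4
  f <- single_process_model("O_NH4", "first", O_NH4.k = 0.5)
  tr <- simulate_pools(mm$model, mm$params, s0, c(0, 2))
  trf <- simulate_pools(f$model, f$params, s0, c(0, 2))
  expect_equal(unname(tr$states[2, "nh4"]), unname(trf$states[2, "nh4"]),
               tolerance = 1e-2)
})

test_that("halving the integrator step leaves outputs unchanged to 1e-6", {
  set.seed(99)
  cfg <- random_configuration()
  t_out <- c(0.5 / 24, 0.5, 1, 2)
  a <- simulate_pools(cfg$model, cfg$params, cfg$state, t_out, step = 0.002)
  b <- simulate_pools(cfg$model, cfg$params, cfg$state, t_out, step = 0.001)
  expect_equal(a$states, b$states, tolerance = 1e-6)
})

test_that("conservation and enrichment bounds hold along trajectories", {
  set.seed(2024)
  for (rep in 1:10) {
    cfg <- random_configuration()
    tr <- simulate_pools(cfg$model, cfg$params, cfg$state,
                         c(0, 0.25, 0.5, 1, 2), step = 0.002)
    tot <- rowSums(tr$states[, 1:5])
    n15 <- rowSums(tr$states[, 6:10])
    expect_equal(tot, rep(tot[1], 5), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(n15, rep(n15[1], 5), tolerance = 1e-9, ignore_attr = TRUE)
    # mixing cannot create enrichment outside the initial range
    f0 <- tr$states[1, 6:10] / pmax(tr$states[1, 1:5], 1e-300)
    f0 <- f0[tr$states[1, 1:5] > 0]
    rng <- range(f0)
    for (i in 2:5) {
      tot_i <- tr$states[i, 1:5]
      frac <- tr$states[i, 6:10][tot_i > 1e-9] / tot_i[tot_i > 1e-9]
      expect_true(all(frac >= rng[1] - 1e-9 & frac <= rng[2] + 1e-9))
    }
  }
})

test_that("pools cannot be driven negative: zero-order source exhaustion", {
  # zero-order draw of 30/day from a 5 mg pool: must stop at 0, stay
  # nonnegative, and conserve total N throughout
  m <- default_model_structure()
  m$active <- m$process_id == "O_Nrec"
  p <- default_parameters(m, values = c(O_Nrec.k = 30))
  s0 <- soil_state(0, isotope_pool(1), isotope_pool(1), isotope_pool(1),
                   isotope_pool(5), isotope_pool(0))
  tr <- simulate_pools(m, p, s0, c(0, 0.1, 0.2, 1))
  expect_true(all(tr$states[, 1:5] >= 0))
  expect_equal(unname(tr$states[4, "n_rec"]), 0, tolerance = 1e-6)
  expect_equal(unname(tr$states[4, "no3"]), 6, tolerance = 1e-6)
  expect_equal(rowSums(tr$states[, 1:5]), rep(8, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("initial_state_from_design mixes label and background correctly", {
  d <- experiment_design(soil_nh4 = 2.46, soil_no3 = 13.60, soil_tn = 0.90)
  s <- initial_state_from_design(d, "NH4_labelled", n_lab0 = 40)
  expect_equal(s$nh4$total_n, 22.46)
  expect_equal(s$nh4$frac15 * 100 - d$natural_abundance, 20 * 9.44 / 22.46,
               tolerance = 1e-9) # ~8.406 APE
  # the unlabelled species sits at natural abundance
  expect_equal(s$no3$frac15 * 100, d$natural_abundance)
  expect_equal(s$nh4_ads$total_n, 0)
  expect_equal(s$n_rec$total_n, 900 - 40 - 2.46 - 13.60)
  # zero amendment: state equals soil background at natural abundance
  d0 <- experiment_design(soil_nh4 = 2.46, soil_no3 = 13.60, soil_tn = 0.90,
                          amendment_nh4 = 0, amendment_no3 = 0)
  s0 <- initial_state_from_design(d0, "NO3_labelled", n_lab0 = 40)
  expect_equal(s0$nh4$total_n, 2.46)
  expect_equal(s0$nh4$frac15 * 100, d0$natural_abundance)
  # missing background errors
  expect_error(experiment_design(soil_nh4 = NA, soil_no3 = 1, soil_tn = 1),
               "soil background")
})

test_that("predict_observables maps states to concentration and APE", {
  d <- test_design()
  m <- default_model_structure()
  m$active <- FALSE
  p <- default_parameters(m)
  times_d <- d$sampling_times_h / 24
  trs <- lapply(setNames(nm = c("NH4_labelled", "NO3_labelled")),
                function(trt)
                  simulate_pools(m, p,
                                 initial_state_from_design(d, trt, 50),
                                 times_d))
  pred <- predict_observables(trs, d)
  expect_equal(nrow(pred), 16) # 2 treatments x 4 times x 2 pools
  # pool at natural abundance has APE exactly 0
  expect_equal(pred$ape_mean[pred$treatment == "NH4_labelled" &
                               pred$pool == "NO3"], rep(0, 4))
  # frac15 -> APE unit identity
  fr <- (9.44 + d$natural_abundance) / 100
  st <- soil_state(0, isotope_pool(10, fr), isotope_pool(1), isotope_pool(1),
                   isotope_pool(1), isotope_pool(0))
  tr <- simulate_pools(m, p, st, times_d)
  pr <- predict_observables(tr, d, treatment = "NH4_labelled")
  expect_equal(pr$ape_mean[pr$pool == "NH4"], rep(9.44, 4), tolerance = 1e-9)
  # time outside the trajectory errors
  tr2 <- simulate_pools(m, p, st, c(1, 2))
  expect_error(predict_observables(tr2, d, "NH4_labelled"),
               "outside trajectory")
})

test_that("isotope pool and state invariants are enforced", {
  expect_error(isotope_pool(-1), ">= 0")
  expect_error(isotope_pool(1, 1.2), "frac15")
  expect_error(soil_state(-1, isotope_pool(1), isotope_pool(1),
                          isotope_pool(1), isotope_pool(1), isotope_pool(0)),
               "time")
  expect_error(experiment_design(soil_nh4 = 1, soil_no3 = 1, soil_tn = 1,
                                 sampling_times_h = c(2, 1)),
               "strictly increasing")
  expect_error(experiment_design(soil_nh4 = 1, soil_no3 = 1, soil_tn = 1,
                                 enrichment_nh4 = 0), "enrichments")
})
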