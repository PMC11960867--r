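test_that("per-cycle drug costs follow the dosing and vial arithmetic", {
  inputs <- econ_inputs()
  # under the trial's day-1/day-8 schedule: 125 mg/m2 x 1.84 m2 = 230 mg,
  # 3 vials of 100 mg each administration
  cfg2 <- model_config(nabpac_admin_per_cycle = 2)
  expect_equal(drug_cost_cycle("placebo", 0, inputs, cfg2),
               ceiling(230 / 100) * 1447.14 * 2)  # 8,682.84
  expect_equal(drug_cost_cycle("combo", 0, inputs, cfg2), 17574.87)
  expect_equal(drug_cost_cycle("combo", 40, inputs, cfg2), 0)  # beyond 2-year cap
  # without vial wastage the dose is priced pro rata
  cfg_nv <- model_config(nabpac_admin_per_cycle = 2, vial_rounding = FALSE)
  expect_equal(drug_cost_cycle("placebo", 0, inputs, cfg_nv), 2.3 * 1447.14 * 2)
  expect_error(drug_cost_cycle("chemo", 0, inputs, cfg2), "arm")
  expect_error(drug_cost_cycle("combo", 90, inputs, cfg2), "horizon")
})

test_that("first-cycle adverse-event burden is incidence-weighted", {
  cfg <- model_config()
  inputs <- econ_inputs()
  co <- ae_burden_first_cycle("combo", inputs, cfg)
  pl <- ae_burden_first_cycle("placebo", inputs, cfg)
  expect_equal(co$cost, 0.25 * 57.21 + 0.26 * 24376)  # 6,352.06
  expect_equal(pl$cost, 0.23 * 57.21 + 0.28 * 24376)  # 6,838.44
  expect_equal(co$qaly_loss, (0.25 * 0.09 + 0.26 * 0.10) * 21 / 365.25)
  zero <- econ_inputs(inc_leukopenia_combo = 0, inc_neutropenia_combo = 0)
  z <- ae_burden_first_cycle("combo", zero, cfg)
  expect_equal(c(z$cost, z$qaly_loss), c(0, 0))
})

test_that("discounting is continuous-in-cycles at the annual rate", {
  cfg <- model_config()
  expect_equal(discount_factor(0, cfg), 1)
  expect_equal(discount_factor(365.25 / 21, cfg), 1 / 1.05)
  expect_equal(discount_factor(87, cfg), 1.05^(-87 * 21 / 365.25))
  expect_equal(discount_factor(87, cfg), 0.7834, tolerance = 1e-4)
  expect_error(discount_factor(-1, cfg), ">= 0")
})

test_that("accrual of a two-cycle toy cohort matches a hand calculation", {
  u_m <- 21 / 30.4375
  cfg <- model_config(horizon_years = 2 * 21 / 365.25, discount_rate_annual = 0,
                      nabpac_admin_per_cycle = 2, counting = "start")
  expect_identical(cfg$n_cycles, 2L)
  # both curves exponential with S(u) = 1/2: alive 1, 0.5, 0.25; no PD state
  p <- surv_params("exponential", log(2) / u_m)
  tr <- run_trace(p, p, cfg)
  inputs <- econ_inputs()
  acc <- accrue(tr, "placebo", inputs, cfg)

  drug <- 8682.84 * (1 + 0.5)
  monitoring <- (16.36 + 152.62 + 105) * (1 + 0.5)
  terminal <- 85904 * 0.75
  ae <- 0.23 * 57.21 + 0.28 * 24376
  expect_equal(acc$total_cost, drug + monitoring + terminal + ae, tolerance = 1e-9)
  expect_equal(acc$ly, (1 + 0.5) * u_m / 12, tolerance = 1e-9)
  expect_equal(acc$qaly,
               0.76 * (1 + 0.5) * u_m / 12 -
                 (0.23 * 0.09 + 0.28 * 0.10) * 21 / 365.25,
               tolerance = 1e-9)
})

test_that("an immediately-absorbing cohort accrues only terminal care", {
  cfg <- model_config(counting = "end")
  steep <- surv_params("exponential", 1e4)
  tr <- run_trace(steep, steep, cfg)
  inputs <- econ_inputs(inc_leukopenia_placebo = 0, inc_neutropenia_placebo = 0)
  acc <- accrue(tr, "placebo", inputs, cfg)
  expect_equal(acc$total_cost, 85904, tolerance = 1e-6)
  expect_equal(acc$ly, 0, tolerance = 1e-12)
  expect_equal(acc$qaly, 0, tolerance = 1e-12)
})

test_that("utilities of 1 make QALYs equal life years", {
  inputs <- econ_inputs(u_pfs = 1, u_pd = 1,
                        disutil_leukopenia = 0, disutil_neutropenia = 0)
  acc <- run_arm("combo", inputs = inputs)
  expect_equal(acc$qaly, acc$ly, tolerance = 1e-12)
})

test_that("removing discounting increases both cost and QALYs", {
  s <- default_survival()
  r0 <- run_arm("placebo", s, econ_inputs(), model_config(discount_rate_annual = 0))
  r5 <- run_arm("placebo", s, econ_inputs(), model_config(discount_rate_annual = 0.05))
  expect_gt(r0$total_cost, r5$total_cost)
  expect_gt(r0$qaly, r5$qaly)
  expect_gt(r0$ly, r5$ly)
})

test_that("doubling the toripalimab price moves only the combo arm, linearly", {
  cfg <- model_config()
  s <- default_survival()
  base <- econ_inputs()
  doubled <- econ_inputs(cost_toripalimab_cycle = 2 * 8892.03)
  co1 <- run_arm("combo", s, base, cfg); co2 <- run_arm("combo", s, doubled, cfg)
  pl1 <- run_arm("placebo", s, base, cfg); pl2 <- run_arm("placebo", s, doubled, cfg)
  expect_equal(pl1$total_cost, pl2$total_cost)
  tr <- run_trace(s$combo$pfs, s$combo$os, cfg)
  n <- cfg$n_cycles; ci <- 0:(n - 1)
  on_trt <- ci * cfg$cycle_days < cfg$treatment_cap_years * 365.25
  occ <- sum(discount_factor(ci, cfg) * tr$pfs[1:n] * on_trt)
  expect_equal(co2$total_cost - co1$total_cost, occ * 8892.03, tolerance = 1e-9)
})

test_that("economic inputs are validated", {
  expect_error(econ_inputs(u_pfs = 1.3), "u_pfs")
  expect_error(econ_inputs(cost_lab = -5), "cost_lab")
  expect_error(econ_inputs(nonexistent = 1), "unknown parameter")
  expect_error(accrue(data.frame(), "combo", econ_inputs(), model_config()),
               "cohort_trace")
})

test_that("trace and config cycle counts must agree", {
  s <- default_survival()$combo
  tr <- run_trace(s$pfs, s$os, model_config())
  expect_error(accrue(tr, "combo", econ_inputs(),
                      model_config(horizon_years = 4)), "mismatch")
})
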