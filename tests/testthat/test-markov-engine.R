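test_that("model configuration derives 87 cycles over the 5-year horizon", {
  cfg <- model_config()
  expect_identical(cfg$n_cycles, 87L)
  expect_equal(cfg$cycle_months, 21 / 30.4375)
  expect_equal(cfg$horizon_months, 60)
})

test_that("transition probabilities follow the survivor-function ratio", {
  cfg <- model_config()
  u <- cfg$cycle_months
  # memorylessness: constant hazard gives a cycle-invariant probability
  ex <- surv_params("exponential", 0.1)
  p <- transition_probability(ex, 0:20, cfg)
  expect_equal(p, rep(1 - exp(-0.1 * u), 21))
  # composition against surv_prob for a shipped curve
  ll <- surv_params("loglogistic", 0.04349, 0.53309)
  expect_equal(transition_probability(ll, 0, cfg), 1 - surv_prob(ll, u))
  expect_equal(transition_probability(ll, 10, cfg),
               1 - surv_prob(ll, 11 * u) / surv_prob(ll, 10 * u))
  # absorbing tail once the survivor function has vanished numerically
  steep <- surv_params("exponential", 50)
  expect_equal(transition_probability(steep, 500, cfg), 1)
  expect_error(transition_probability(ll, -1, cfg), ">= 0")
})

test_that("cohort trace conserves mass and is monotone", {
  cfg <- model_config()
  surv <- default_survival()
  for (arm in c("combo", "placebo")) {
    tr <- run_trace(surv[[arm]]$pfs, surv[[arm]]$os, cfg)
    expect_equal(nrow(tr), 88L)
    expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= 0))
    expect_true(all(diff(tr$pfs) <= 0))
    expect_true(all(tr$pfs >= 0 & tr$pfs <= 1 & tr$pd >= 0 & tr$pd <= 1))
    expect_true(all(tr$new_prog >= 0))
    expect_lte(sum(tr$new_prog), 1)
    tun <- attr(tr, "tunnel")
    expect_true(all(abs(rowSums(tun) - tr$pd) < 1e-9))
    # terminal occupancy is the survivor function at exactly 60 months
    expect_equal(tr$dead[88], 1 - surv_prob(surv[[arm]]$os, 60))
    expect_equal(tr$time_months[88], 60)
  }
})

test_that("identical PFS and OS curves collapse to an alive/dead model", {
  cfg <- model_config()
  p <- surv_params("loglogistic", 0.04349, 0.53309)
  tr <- run_trace(p, p, cfg)
  expect_true(all(tr$pd == 0))
  expect_true(all(tr$new_prog == 0))
  expect_equal(tr$pfs, 1 - tr$dead)
})

test_that("curves crossing beyond tolerance raise an error naming the cycle", {
  cfg <- model_config()
  # a 'PFS' curve far above the 'OS' curve
  expect_error(
    run_trace(surv_params("loglogistic", 0.03223, 0.60082),
              surv_params("loglogistic", 0.14152, 0.53806), cfg),
    "cycle")
})

test_that("undiscounted life expectancy matches the OS integral and refines with cycle length", {
  surv <- default_survival()$placebo
  quad <- stats::integrate(function(t) surv_prob(surv$os, t), 0, 60,
                           rel.tol = 1e-10)$value # months
  ly_months <- function(cycle_days) {
    cfg <- model_config(cycle_days = cycle_days, discount_rate_annual = 0,
                        counting = "start")
    tr <- run_trace(surv$pfs, surv$os, cfg)
    n <- cfg$n_cycles
    alive <- 1 - tr$dead
    sum(alive[1:n] * diff(tr$time_months))
  }
  err21 <- abs(ly_months(21) - quad)
  err5 <- abs(ly_months(21 / 4) - quad)
  expect_lt(err21, 21 / 30.4375)  # within one cycle's area
  expect_lt(err5, err21 / 2)      # quadrature error shrinks with the step
})

test_that("trace CSV export has the documented columns", {
  cfg <- model_config()
  s <- default_survival()$combo
  tr <- run_trace(s$pfs, s$os, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("cycle", "pfs", "pd", "dead", "new_prog", "new_death"))
  expect_equal(back$pfs, tr$pfs)
})
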