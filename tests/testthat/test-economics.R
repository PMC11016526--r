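test_that("discounting is end-of-cycle with cycle 0 undiscounted", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 7), 1)
  expect_equal(discount_factor(0.03, 2), 1 / 1.0609, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 0:2), c(1, 1 / 1.03, 1 / 1.0609))
  expect_error(discount_factor(0.03, -1), "nonnegative")
  expect_error(discount_factor(-0.01, 1), "nonnegative")
})

test_that("a degenerate single-cycle run accrues one year in Resolved ACS", {
  p <- acs_parameters()
  cfg <- model_config(start_age = 30, max_age = 30)
  tr <- run_cohort(p, "LMIS", cfg)
  expect_identical(nrow(tr), 1L)
  r <- accumulate(tr, p, cfg = cfg)
  expect_equal(r$total_cost, 19728100 + 1474656)
  expect_equal(r$total_qaly, 0.78)
  h <- accumulate(run_cohort(p, "HIS", cfg), p, cfg = cfg)
  expect_equal(h$total_cost, 19728100 + 3908568)
})

test_that("accrual is linear in costs and utilities", {
  p <- acs_parameters()
  cfg <- model_config(max_age = 60)
  tr <- run_cohort(p, "LMIS", cfg)
  base <- accumulate(tr, p, cfg = cfg)

  doubled <- as.data.frame(p)
  doubled$mean[doubled$family == "cost"] <- 2 * doubled$mean[doubled$family == "cost"]
  r2 <- accumulate(tr, as_acs_parameters(doubled), cfg = cfg)
  expect_equal(r2$total_cost, 2 * base$total_cost, tolerance = 1e-12)
  expect_equal(r2$total_qaly, base$total_qaly)

  zeroed <- as.data.frame(p)
  zeroed$mean[zeroed$family == "utility"] <- 0
  expect_equal(accumulate(tr, as_acs_parameters(zeroed), cfg = cfg)$total_qaly, 0)

  # per-cycle breakdown is consistent with the totals
  expect_equal(base$total_cost, sum(base$per_cycle$disc_cost),
               tolerance = 1e-6)
  expect_equal(base$total_qaly, sum(base$per_cycle$disc_qaly),
               tolerance = 1e-6)
})

test_that("discounting never increases a nonnegative stream", {
  p <- acs_parameters()
  cfg0 <- model_config(discount_cost = 0, discount_outcome = 0)
  cfg3 <- model_config()
  tr <- run_cohort(p, "HIS", cfg3)
  undisc <- accumulate(tr, p, cfg = cfg0)
  disc <- accumulate(tr, p, cfg = cfg3)
  expect_lt(disc$total_cost, undisc$total_cost)
  expect_lt(disc$total_qaly, undisc$total_qaly)
})

test_that("incremental statistics classify the plane correctly", {
  mk <- function(strategy, cost, qaly)
    structure(list(strategy = strategy, total_cost = cost, total_qaly = qaly),
              class = "acs_result")
  r <- icer(mk("HIS", 150, 3), mk("LMIS", 50, 1))
  expect_equal(r$icer, 50)
  expect_identical(r$flag, "ratio")
  expect_identical(r$quadrant, "NE")
  expect_identical(icer(mk("HIS", 45, 1.1), mk("LMIS", 50, 1))$flag, "dominant")
  expect_identical(icer(mk("HIS", 60, 0.9), mk("LMIS", 50, 1))$flag, "dominated")
  und <- icer(mk("HIS", 60, 1), mk("LMIS", 50, 1))
  expect_identical(und$flag, "undefined")
  expect_true(is.na(und$icer))
})

test_that("the ICER is invariant to the reporting cohort scale", {
  fit <- acs_cua(max_age = 70)
  scale <- function(r, k) {
    r$total_cost <- r$total_cost * k
    r$total_qaly <- r$total_qaly * k
    r
  }
  big <- icer(scale(fit$results$HIS, 1000), scale(fit$results$LMIS, 1000))
  expect_equal(big$icer, fit$incremental$icer, tolerance = 1e-12)
})

test_that("net monetary benefit agrees with the ICER threshold rule", {
  fit <- acs_cua(max_age = 80)
  his <- fit$results$HIS; lmis <- fit$results$LMIS
  expect_equal(net_monetary_benefit(his, 0), -his$total_cost)
  inc <- fit$incremental
  expect_gt(inc$delta_qaly, 0)
  for (wtp in c(5e7, 1.5e8, 1.9e8, 2.5e8, 1e9)) {
    nmb_rule <- net_monetary_benefit(his, wtp) > net_monetary_benefit(lmis, wtp)
    icer_rule <- inc$icer < wtp
    expect_identical(nmb_rule, icer_rule)
  }
})
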