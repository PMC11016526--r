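test_that("sampling is seed-reproducible and degenerate at zero SE", {
  p <- acs_parameters()
  s1 <- acscua:::.with_seed(5, sample_parameters(p))
  s2 <- acscua:::.with_seed(5, sample_parameters(p))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  s3 <- acscua:::.with_seed(6, sample_parameters(p))
  expect_false(identical(s1$mean, s3$mean))
  # every draw passes validation
  expect_identical(nrow(validate_parameters(s1)), 0L)
  # zero SE collapses every distribution to its mean
  z <- acscua:::.with_seed(1, sample_parameters(zero_se_parameters()))
  expect_equal(z$mean, acs_parameters()$mean)
  # the Resolved-ACS row stays closed in every draw
  ra <- sum(s1$mean[s1$name %in% c("tpRA_RA", "tpRA_MI", "tpRA_CAr", "tpRA_Rv")])
  expect_equal(ra, 1, tolerance = 1e-12)
})

test_that("method-of-moments samplers recover tabulated means and SEs", {
  p <- acs_parameters()
  draws <- function(nm, n = 10000) {
    row <- p[p$name == nm, ]
    acscua:::.with_seed(2024, replicate(n, acscua:::.draw_param(
      row$mean, row$se, row$family)))
  }
  # beta (probability), gamma (cost), lognormal (hazard ratio)
  cases <- list(c("tpRA_MI", 0.012, 0.001),
                c("uMI", 0.65, 0.065),
                c("dmcRA", 19728100, 197281),
                c("cHIS", 3908568.00, 390856.80),
                c("HR_HIS_MI", 0.77, 0.07))
  for (cs in cases) {
    x <- draws(cs[1])
    m <- as.numeric(cs[2]); s <- as.numeric(cs[3])
    expect_lt(abs(mean(x) - m), 3 * s / sqrt(10000))
    expect_lt(abs(sd(x) - s) / s, 0.10)
  }
})

test_that("a zero-SE PSA reproduces the deterministic result exactly", {
  p <- zero_se_parameters()
  cfg <- model_config(max_age = 70)
  det <- acs_cua(params = p, config = cfg)
  psa <- run_psa(p, cfg, n = 5, seed = 3)
  expect_equal(psa$cost_HIS, rep(det$results$HIS$total_cost, 5))
  expect_equal(psa$qaly_LMIS, rep(det$results$LMIS$total_qaly, 5))
  expect_equal(psa$delta_cost / psa$delta_qaly,
               rep(det$incremental$icer, 5))
})

test_that("PSA runs are reproducible and iteration-indexed", {
  p <- acs_parameters()
  cfg <- model_config(max_age = 60)
  a <- run_psa(p, cfg, n = 10, seed = 11)
  b <- run_psa(p, cfg, n = 10, seed = 11)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c2 <- run_psa(p, cfg, n = 10, seed = 12)
  expect_false(identical(a$delta_cost, c2$delta_cost))
  expect_identical(a$iteration, 1:10)
  expect_false(anyDuplicated(a$iteration) > 0)
})

test_that("acceptability curves count positive incremental NMB", {
  p <- acs_parameters()
  # full horizon: the QALY gain of HIS is positive in essentially every draw
  cfg <- model_config()
  psa <- run_psa(p, cfg, n = 50, seed = 7)
  expect_true(all(psa$delta_cost > 0))  # added drug cost dominates here
  expect_equal(ceac(psa, 0)$probability, 0)
  expect_true(all(psa$delta_qaly > 0))
  expect_equal(ceac(psa, 1e15)$probability, 1)
  # monotone non-decreasing in WTP when every iteration gains QALYs
  grid <- ceac(psa, seq(0, 5e8, length.out = 21))
  expect_true(all(diff(grid$probability) >= 0))
  # hand-computed fraction at one threshold
  wtp <- 2e8
  expect_equal(ceac(psa, wtp)$probability,
               mean(wtp * psa$delta_qaly - psa$delta_cost > 0))
  expect_error(ceac(psa[0, ], 1e8), "empty")
})

test_that("quadrant labels and NMB ranking agree on every iteration", {
  psa <- run_psa(acs_parameters(), model_config(max_age = 60),
                 n = 200, seed = 13)
  for (wtp in c(1e8, 2e8)) {
    pos <- wtp * psa$delta_qaly - psa$delta_cost > 0
    # NE iterations are cost-effective iff the ratio clears the threshold
    ne <- psa$delta_cost >= 0 & psa$delta_qaly > 0
    expect_identical(pos[ne],
                     (psa$delta_cost / psa$delta_qaly)[ne] < wtp)
    # SE iterations (cheaper and better) are always cost-effective
    se <- psa$delta_cost < 0 & psa$delta_qaly > 0
    if (any(se)) expect_true(all(pos[se]))
  }
})

test_that("the CE-plane table is one row per iteration with thresholds attached", {
  psa <- run_psa(acs_parameters(), model_config(max_age = 60),
                 n = 40, seed = 21)
  cp <- ce_plane(psa)
  expect_identical(nrow(cp), 40L)
  expect_identical(names(cp), c("iteration", "delta_qaly", "delta_cost"))
  expect_equal(attr(cp, "wtp"), c(192514839, 206319831.79))
  expect_equal(cp$delta_cost, psa$delta_cost)
})

test_that("simulate() on a fitted analysis is the PSA", {
  fit <- acs_cua(max_age = 60)
  s <- simulate(fit, nsim = 8, seed = 4)
  expect_s3_class(s, "acs_psa")
  expect_identical(nrow(s), 8L)
  direct <- run_psa(fit$params, fit$config, n = 8, seed = 4)
  expect_equal(as.data.frame(s), as.data.frame(direct))
})
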