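test_that("age bands cover the model's age range", {
  expect_identical(age_band_for(30), "30-34")
  expect_identical(age_band_for(34), "30-34")
  expect_identical(age_band_for(62), "60-64")
  expect_identical(age_band_for(84), "80-84")
  expect_identical(age_band_for(92), "80-84")
  expect_identical(age_band_for(92, "hold_last_band"), "80-84")
  expect_error(age_band_for(29), "age")
  expect_error(age_band_for(85, "truncate"), "band")
  expect_identical(age_band_for(c(30, 47, 100)), c("30-34", "45-49", "80-84"))
})

test_that("hazard-ratio transforms act as stated on probabilities", {
  expect_equal(apply_hazard_ratio(0.012, 1, "multiplicative"), 0.012)
  expect_equal(apply_hazard_ratio(0.012, 1, "rate_based"), 0.012)
  expect_equal(apply_hazard_ratio(0.012, 0.77, "multiplicative"), 0.00924)
  expect_equal(apply_hazard_ratio(0.012, 0.77, "rate_based"),
               1 - 0.988^0.77, tolerance = 1e-12)
  expect_equal(apply_hazard_ratio(0.9, 2, "multiplicative"), 1)  # capped
  expect_lt(apply_hazard_ratio(0.9, 2, "rate_based"), 1)
  expect_error(apply_hazard_ratio(1.2, 0.5), "\\[0, 1\\]")
  expect_error(apply_hazard_ratio(0.5, -1), "positive")
})

test_that("transition matrices carry the tabulated rows", {
  p <- acs_parameters()
  M <- transition_matrix(p, "LMIS", age = 40)
  expect_equal(unname(M["RA", ]), c(0.952, 0.012, 0.001, 0.035, 0))
  expect_equal(unname(transition_matrix(p, "LMIS", 62)["MI", "D"]), 0.084)
  # high-intensity arm: hazard ratios on the event entries, residual closes
  H <- transition_matrix(p, "HIS", age = 40)
  expect_equal(unname(H["RA", "MI"]), 0.77 * 0.012)
  expect_equal(unname(H["RA", "CAr"]), 1.07 * 0.001)
  expect_equal(unname(H["RA", "Rv"]), 0.73 * 0.035)
  expect_equal(unname(H["RA", "RA"]),
               1 - (0.77 * 0.012 + 1.07 * 0.001 + 0.73 * 0.035))
  # all_inbound also transforms the recurrent transitions
  expect_equal(unname(H["Rv", "MI"]), 0.77 * 0.396)
  cfg_ra <- model_config(hr_scope = "from_RA_only")
  expect_equal(unname(transition_matrix(p, "HIS", 40, cfg_ra)["Rv", "MI"]),
               0.396)
  # residual conventions
  expect_equal(unname(M["CAr", "RA"]), 1 - 0.008)
  M_stay <- transition_matrix(p, "LMIS", 40, model_config(residual_rule = "stay"))
  expect_equal(unname(M_stay["CAr", "CAr"]), 1 - 0.008)
  expect_equal(unname(M_stay["CAr", "RA"]), 0)
  # death row absorbing
  expect_equal(unname(M["D", ]), c(0, 0, 0, 0, 1))
})

test_that("every matrix row is stochastic for fixture and synthetic tables", {
  cfgs <- list(model_config(),
               model_config(residual_rule = "stay",
                            hr_transform = "rate_based",
                            hr_scope = "from_RA_only"))
  tables <- c(list(acs_parameters()), lapply(1:20, random_parameters))
  for (p in tables) for (cfg in cfgs) for (s in c("HIS", "LMIS"))
    for (age in seq(30, 100, by = 5))
      expect_row_stochastic(transition_matrix(p, s, age, cfg))
})

test_that("infeasible rows are rescaled to stochasticity with a record", {
  q <- as.data.frame(acs_parameters())
  q$mean[q$name == "tpRv_MI"] <- 0.7  # 0.7 + 0.135 + 0.274 > 1 in last band
  p <- as_acs_parameters(q, check = FALSE)
  M <- transition_matrix(p, "LMIS", 84)
  expect_row_stochastic(M)
  expect_gte(attr(M, "rescaled"), 1L)
  expect_equal(unname(M["Rv", "RA"]), 0)  # no residual mass left
})

test_that("the cohort trace starts in Resolved ACS and loses mass only to death", {
  p <- acs_parameters()
  cfg <- model_config()
  tr <- run_cohort(p, "LMIS", cfg)
  expect_identical(nrow(tr), cfg$max_age - cfg$start_age + 1L)
  expect_equal(unname(unlist(tr[1, c("RA", "MI", "CAr", "Rv", "D")])),
               c(1, 0, 0, 0, 0))
  # cycle 1 is the age-30 Resolved-ACS row
  expect_equal(unname(unlist(tr[2, c("RA", "MI", "CAr", "Rv", "D")])),
               unname(transition_matrix(p, "LMIS", 30)["RA", ]))
  occ <- as.matrix(tr[, c("RA", "MI", "CAr", "Rv", "D")])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_true(all(diff(tr$D) >= -1e-12))
  # truncate rule ends the trace at age 85
  tr85 <- run_cohort(p, "LMIS", model_config(over_84_rule = "truncate"))
  expect_identical(max(tr85$age), 85L)
})

test_that("unit hazard ratios make the strategies indistinguishable", {
  q <- as.data.frame(acs_parameters())
  q$mean[grepl("^HR_", q$name)] <- 1
  p <- as_acs_parameters(q, check = FALSE)
  states <- c("RA", "MI", "CAr", "Rv", "D")
  for (cfg in list(model_config(),
                   model_config(hr_transform = "rate_based"))) {
    a <- run_cohort(p, "HIS", cfg)
    b <- run_cohort(p, "LMIS", cfg)
    expect_equal(as.matrix(a[, states]), as.matrix(b[, states]),
                 tolerance = 1e-12)
  }
})

test_that("cohort trace matches a per-individual microsimulation", {
  # modest n here; the full 200k-patient check runs with the model-validation
  # properties in test-acceptance.R
  p <- acs_parameters()
  cfg <- model_config(max_age = 45)
  tr <- run_cohort(p, "HIS", cfg)
  occ <- as.matrix(tr[, c("RA", "MI", "CAr", "Rv", "D")])
  sim <- microsim_trace(p, "HIS", cfg, n = 50000, seed = 99)
  expect_lt(max(abs(occ - sim)), 0.01)
})
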