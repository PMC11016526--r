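test_that("packaged reference table reproduces every tabulated cell", {
  p <- acs_parameters()
  # exact equality against the shipped CSV, cell by cell
  ref <- utils::read.csv(system.file("extdata", "reference_table.csv",
                                     package = "acscua"),
                         stringsAsFactors = FALSE)
  expect_identical(nrow(p), 56L)
  expect_identical(p$name, ref$name)
  expect_identical(p$mean, ref$mean)
  expect_identical(p$se, ref$se)
  expect_identical(p$family, ref$family)

  g <- function(nm) p[p$name == nm, ]
  expect_equal(g("tpRA_MI")$mean, 0.012)
  expect_equal(g("tpRA_MI")$se, 0.001)
  expect_equal(g("HR_HIS_CAr")$mean, 1.07)
  expect_equal(g("dmcRv")$mean, 40024100)
  expect_equal(g("tpMI_D_60to64")$mean, 0.084)
  expect_equal(g("cNHIS")$se, 147465.60)
  expect_equal(g("uCAr")$mean, 0.68)
  # the Resolved-ACS row is exactly closed
  ra <- sum(p$mean[p$name %in% c("tpRA_RA", "tpRA_MI", "tpRA_CAr", "tpRA_Rv")])
  expect_equal(ra, 1, tolerance = 1e-12)
  expect_identical(nrow(validate_parameters(p)), 0L)
})

test_that("validation reports domain violations as data", {
  tweak <- function(nm, field, value) {
    q <- as.data.frame(acs_parameters())
    q[q$name == nm, field] <- value
    as_acs_parameters(q, check = FALSE)
  }
  v <- validate_parameters(tweak("uMI", "mean", -0.1))
  expect_identical(v$symbol, "uMI")
  expect_identical(v$constraint, "unit_interval")

  # beta-moment feasibility: 0.25 >= 0.012 * 0.988
  v <- validate_parameters(tweak("tpRA_MI", "se", 0.5))
  expect_true("beta_feasible" %in% v$constraint)
  expect_true("tpRA_MI" %in% v$symbol)

  v <- validate_parameters(tweak("tpRA_MI", "mean", 1.3))
  expect_true(any(v$symbol == "tpRA_MI" & v$constraint == "unit_interval"))
  # pushing a probability up also breaks the row closure
  expect_true("row_sum" %in% v$constraint)

  v <- validate_parameters(tweak("HR_HIS_MI", "mean", -2))
  expect_true(any(v$symbol == "HR_HIS_MI" & v$constraint == "positive"))
  v <- validate_parameters(tweak("dmcRA", "mean", -5))
  expect_true(any(v$symbol == "dmcRA" & v$constraint == "nonnegative"))
})

test_that("parameter tables round-trip through CSV and YAML", {
  p <- acs_parameters()
  for (fmt in c("csv", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_parameters(p, path)
    q <- read_parameters(path)
    expect_equal(as.data.frame(q), as.data.frame(p))
  }
})

test_that("loading rejects incomplete or unknown symbol sets by name", {
  p <- as.data.frame(acs_parameters())
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(p[p$name != "uCAr", ], path, row.names = FALSE)
  expect_error(read_parameters(path), "missing.*uCAr")

  extra <- rbind(p, within(p[1L, ], name <- "tpXX_bogus"))
  write.csv(extra, path, row.names = FALSE)
  expect_error(read_parameters(path), "unknown.*tpXX_bogus")

  bad <- p
  bad$mean[bad$name == "tpRA_MI"] <- 1.3
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_parameters(path), "tpRA_MI")
})

test_that("synthetic parameter tables are valid, deterministic, and runnable", {
  expect_identical(random_parameters(42), random_parameters(42))
  expect_false(identical(random_parameters(1), random_parameters(2)))

  # 1000 consecutive seeds, alternating difficulty, all valid
  ok <- vapply(1:1000, function(seed) {
    p <- random_parameters(seed,
                           difficulty = if (seed %% 2) "typical" else "extreme")
    nrow(validate_parameters(p)) == 0L
  }, TRUE)
  expect_true(all(ok))
  # mortality is non-decreasing in age within each from-state
  p <- random_parameters(7)
  for (st in c("MI", "CAr", "Rv")) {
    d <- p$mean[grepl(paste0("^tp", st, "_D_"), p$name)]
    expect_true(all(diff(d) >= -1e-12))
  }
  # the full pipeline runs on synthetic tables
  for (seed in c(3, 11, 58)) {
    fit <- acs_cua(params = random_parameters(seed))
    expect_true(is.finite(fit$results$HIS$total_cost))
    expect_true(fit$results$HIS$total_qaly >= 0)
  }
})
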