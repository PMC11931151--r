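test_that("inhibition percentage follows the control-relative formula", {
  expect_equal(inhibition_percent(0.80, 0.80), 0)
  expect_equal(inhibition_percent(0.80, 0.00), 100)
  expect_equal(inhibition_percent(1.00, 0.25), 75)
  # vectorized, and out-of-range values pass through unclipped
  expect_equal(inhibition_percent(c(0.5, 0.5), c(0.6, -0.1)), c(-20, 120))
  expect_equal(flag_inhibition(c(-20, 50, 120)),
               c("negative", "ok", "above_100"))
  expect_error(inhibition_percent(0, 0.1), "control")
  expect_error(inhibition_percent(-1, 0.1), "control")
})

test_that("IC50 is recovered from curves with a known crossing", {
  conc <- c(0.062, 0.125, 0.25, 0.5, 1)

  # exact 50% hit at 0.25
  hit <- tibble::tibble(
    concentration = conc,
    inhibition = c(20, 35, 50, 65, 80)
  )
  est <- estimate_ic50(hit)
  expect_equal(est$ic50, 0.25)
  expect_false(est$extrapolated)

  # log-linear generating law: both estimators invert it exactly
  line <- tibble::tibble(
    concentration = conc,
    inhibition = 50 + 30 * (log10(conc) - log10(0.25))
  )
  expect_equal(estimate_ic50(line, "interpolation")$ic50, 0.25,
               tolerance = 1e-12)
  expect_equal(estimate_ic50(line, "regression")$ic50, 0.25,
               tolerance = 1e-12)

  # two-point bracket: geometric mean of the concentrations when the
  # bracket is symmetric around 50%
  two <- tibble::tibble(concentration = c(0.125, 0.25),
                        inhibition = c(40, 60))
  expect_equal(estimate_ic50(two)$ic50, sqrt(0.125 * 0.25),
               tolerance = 1e-12)
})

test_that("IC50 scales exactly with concentration units (both methods)", {
  for (seed in 1:5) {
    d <- simulate_dose_response(
      true_ic50 = 0.08 + 0.1 * seed, slope = 25 + 5 * seed,
      noise_sd = 3, seed = seed
    )
    for (m in c("interpolation", "regression")) {
      base <- suppressWarnings(estimate_ic50(d, m))
      for (k in c(0.5, 3, 10)) {
        scaled <- dplyr::mutate(d, concentration = concentration * k)
        est <- suppressWarnings(estimate_ic50(scaled, m))
        expect_equal(est$ic50, k * base$ic50, tolerance = 1e-10)
      }
    }
  }
})

test_that("interpolation lands strictly inside the bracketing pair", {
  for (seed in 1:10) {
    d <- simulate_dose_response(true_ic50 = 0.2, slope = 40,
                                noise_sd = 4, seed = 100 + seed)
    d <- d[order(d$concentration), ]
    if (is.unsorted(d$inhibition, strictly = TRUE)) next
    est <- suppressWarnings(estimate_ic50(d))
    if (!est$extrapolated && !any(d$inhibition == 50)) {
      below <- max(d$concentration[d$inhibition < 50])
      above <- min(d$concentration[d$inhibition > 50])
      expect_gt(est$ic50, below)
      expect_lt(est$ic50, above)
    }
  }
})

test_that("curves never reaching 50% fall back to regression and are flagged", {
  d <- tibble::tibble(
    concentration = c(0.062, 0.125, 0.25, 0.5, 1),
    inhibition = c(5, 12, 20, 28, 35)
  )
  est <- estimate_ic50(d, "interpolation")
  expect_true(est$extrapolated)
  expect_equal(est$ic50, estimate_ic50(d, "regression")$ic50)
})

test_that("replicate series yield one estimate each, pooling is optional", {
  d <- simulate_dose_response(0.25, slope = 30, noise_sd = 0, replicates = 3)
  est <- estimate_ic50(d)
  expect_equal(nrow(est), 3)
  expect_equal(est$ic50, rep(0.25, 3), tolerance = 1e-12)
  expect_equal(mean(est$ic50), 0.25, tolerance = 1e-12)
  pooled <- estimate_ic50(d, pooled = TRUE)
  expect_equal(nrow(pooled), 1)
})

test_that("degenerate curves are rejected with informative errors", {
  expect_error(
    estimate_ic50(tibble::tibble(concentration = 0.25, inhibition = 50)),
    "At least 2"
  )
  expect_error(
    estimate_ic50(tibble::tibble(concentration = c(0.1, 0.2),
                                 inhibition = c(40, 40))),
    "constant"
  )
  expect_error(
    estimate_ic50(tibble::tibble(concentration = c(-0.1, 0.2),
                                 inhibition = c(40, 60))),
    "positive"
  )
})

test_that("absorbance-pair input is converted before estimation", {
  d <- tibble::tibble(
    concentration = c(0.125, 0.25, 0.5),
    a_control = 0.8,
    a_sample = c(0.56, 0.40, 0.24)  # 30, 50, 70 % inhibition
  )
  est <- estimate_ic50(d)
  expect_equal(est$ic50, 0.25)
})
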