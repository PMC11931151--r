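test_that("special-cubic expansion reproduces the term algebra", {
  expect_equal(drop(special_cubic_terms(c(1, 0, 0))),
               c("x1" = 1, "x2" = 0, "x3" = 0, "x1:x2" = 0, "x1:x3" = 0,
                 "x2:x3" = 0, "x1:x2:x3" = 0))
  expect_equal(unname(drop(special_cubic_terms(rep(1 / 3, 3)))),
               c(1 / 3, 1 / 3, 1 / 3, 1 / 9, 1 / 9, 1 / 9, 1 / 27))
  expect_equal(unname(drop(special_cubic_terms(c(0.5, 0.5, 0)))),
               c(0.5, 0.5, 0, 0.25, 0, 0, 0))
})

test_that("noiseless responses are refit to machine precision", {
  truth <- published_scheffe_coefficients("glucosidase")
  sim <- simulate_mixture_responses(truth, noise_sd = 0, seed = 1)
  fit <- fit_scheffe(sim, response_mean)
  expect_equal(fit$coefficients, truth, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("the fit agrees with a direct normal-equations solve", {
  blend <- blend_ic50_data()
  X <- special_cubic_terms(blend)
  for (resp in c("ic50_glucosidase", "ic50_amylase")) {
    fit <- fit_scheffe(blend, resp)
    oracle <- normal_equations_fit(X, blend[[resp]])
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-10)
  }
})

test_that("measured blend data reproduce the published coefficient tables", {
  blend <- blend_ic50_data()
  for (resp in c("glucosidase", "amylase")) {
    fit <- fit_scheffe(blend, paste0("ic50_", resp))
    gold <- golden_coefficients(resp)
    expect_equal(unname(fit$coefficients), gold$estimate, tolerance = 0.01)
    expect_equal(tidy(fit)$significant, gold$significant)
  }
  # spot p-values at reporting precision
  fa <- fit_scheffe(blend, ic50_amylase)
  expect_equal(unname(fa$p_values["x1:x3"]), 0.1362, tolerance = 1e-3)
  expect_equal(unname(fa$p_values["x2:x3"]), 0.6011, tolerance = 1e-3)
})

test_that("predictions follow the model algebra", {
  bg <- published_scheffe_coefficients("glucosidase")
  ba <- published_scheffe_coefficients("amylase")
  # vertex prediction is the linear coefficient, exactly
  expect_equal(predict_scheffe(bg, c(1, 0, 0)), unname(bg["x1"]))
  expect_equal(predict_scheffe(bg, c(0, 0, 1)), unname(bg["x3"]))
  # 50/50 binary blend: hand arithmetic, close to the measured 0.044
  expect_equal(predict_scheffe(bg, c(0.5, 0.5, 0)),
               0.5 * 0.069 + 0.5 * 0.077 + 0.25 * (-0.115))
  # centroid of the amylase model, via the independent hand evaluator
  expect_equal(predict_scheffe(ba, rep(1 / 3, 3)),
               eval_special_cubic(ba, rep(1 / 3, 3)))
  expect_equal(predict_scheffe(ba, rep(1 / 3, 3)), 0.1523, tolerance = 1e-4)
})

test_that("ANOVA decomposition is additive in SS and df, and matches a brute-force pure error", {
  blend <- blend_ic50_data()
  fits <- list(
    fit_scheffe(blend, ic50_glucosidase),
    fit_scheffe(blend, ic50_amylase),
    fit_scheffe(
      simulate_mixture_responses(published_scheffe_coefficients("amylase"),
                                 noise_sd = 0.005, seed = 3),
      response_mean
    )
  )
  for (fit in fits) {
    an <- scheffe_anova(fit)
    get <- function(src, col) an[[col]][an$source == src]
    expect_equal(get("total", "sumsq"),
                 get("regression", "sumsq") + get("residual", "sumsq"),
                 tolerance = 1e-12)
    expect_equal(get("residual", "sumsq"),
                 get("lack_of_fit", "sumsq") + get("pure_error", "sumsq"),
                 tolerance = 1e-12)
    expect_equal(get("total", "df"),
                 get("regression", "df") + get("residual", "df"))
    expect_equal(get("residual", "df"),
                 get("lack_of_fit", "df") + get("pure_error", "df"))
    y <- fit$fitted + fit$residuals
    brute <- pure_error_brute(fit$proportions, y)
    expect_equal(get("pure_error", "sumsq"), brute$ss, tolerance = 1e-15)
    expect_equal(get("pure_error", "df"), brute$df)
  }
})

test_that("responses exactly on the surface give zero residual and R2 = 1", {
  sim <- simulate_mixture_responses(
    c(0.1, 0.2, 0.05, -0.1, 0.03, -0.02, 0.5), noise_sd = 0, seed = 2
  )
  fit <- fit_scheffe(sim, response_mean)
  an <- scheffe_anova(fit)
  expect_equal(an$sumsq[an$source == "residual"], 0, tolerance = 1e-20)
  expect_equal(fit$r_squared, 1)
})

test_that("a design without replicates warns and omits the lack-of-fit split", {
  sim <- simulate_mixture_responses(
    published_scheffe_coefficients("glucosidase"), noise_sd = 0.002,
    seed = 4, design = simplex_centroid_design(centroid_runs = 1)
  )
  fit <- fit_scheffe(sim, response_mean)
  expect_warning(an <- scheffe_anova(fit), "pure error")
  expect_false(any(c("lack_of_fit", "pure_error") %in% an$source))
})

test_that("adding a constant shifts linear coefficients only", {
  blend <- blend_ic50_data()
  f0 <- fit_scheffe(blend, ic50_glucosidase)
  k <- 0.37
  shifted <- dplyr::mutate(blend, y2 = ic50_glucosidase + k)
  f1 <- fit_scheffe(shifted, y2)
  expect_equal(unname(f1$coefficients[1:3]),
               unname(f0$coefficients[1:3]) + k, tolerance = 1e-9)
  expect_equal(unname(f1$coefficients[4:7]),
               unname(f0$coefficients[4:7]), tolerance = 1e-9)
})

test_that("relabelling components permutes the fitted coefficients", {
  blend <- blend_ic50_data()
  f0 <- fit_scheffe(blend, ic50_amylase)
  # swap components 1 and 3
  swapped <- dplyr::rename(blend, x1 = x3, x3 = x1)
  f1 <- fit_scheffe(swapped, ic50_amylase)
  expect_equal(unname(f1$coefficients[c("x1", "x2", "x3")]),
               unname(f0$coefficients[c("x3", "x2", "x1")]),
               tolerance = 1e-12)
  expect_equal(unname(f1$coefficients["x1:x2"]),
               unname(f0$coefficients["x2:x3"]), tolerance = 1e-12)
  expect_equal(unname(f1$coefficients["x1:x2:x3"]),
               unname(f0$coefficients["x1:x2:x3"]), tolerance = 1e-12)
})

test_that("backward reduction drops only non-significant interactions", {
  blend <- blend_ic50_data()
  full <- fit_scheffe(blend, ic50_amylase)
  red <- reduce_scheffe(full)
  expect_setequal(attr(red, "dropped"), c("x1:x3", "x2:x3"))
  expect_equal(unname(red$coefficients[c("x1:x3", "x2:x3")]), c(0, 0))
  # retained coefficients equal an independent refit on the kept columns
  keep <- c("x1", "x2", "x3", "x1:x2", "x1:x2:x3")
  oracle <- normal_equations_fit(special_cubic_terms(blend)[, keep],
                                 blend$ic50_amylase)
  expect_equal(unname(red$coefficients[keep]), unname(oracle),
               tolerance = 1e-10)
  # the published reduced equation carries the FULL-model estimates with
  # the dropped terms simply deleted; those survive rounding in the full fit
  expect_equal(unname(full$coefficients[keep]),
               c(0.046, 0.068, 0.032, -0.14, 3.11), tolerance = 0.01)
  # glucosidase model keeps all terms
  fg <- fit_scheffe(blend, ic50_glucosidase)
  expect_identical(reduce_scheffe(fg), fg)
})

test_that("coefficient table renders p-values in reporting style", {
  fit <- fit_scheffe(blend_ic50_data(), ic50_glucosidase)
  ct <- coefficient_table(fit)
  expect_equal(ct$p_label[ct$p.value < 1e-4], rep("<0.0001", sum(ct$p.value < 1e-4)))
  expect_true(all(ct$signif[ct$p.value < 0.05] == "*"))
  expect_match(ct$p_label[ct$term == "x1:x2:x3"], "^0\\.0106$")
})

test_that("degenerate fitting problems raise clear errors", {
  blend <- blend_ic50_data()
  expect_error(fit_scheffe(blend[1:7, ], ic50_glucosidase), "At least 8")
  # collinear design: all runs on one edge make x3-bearing terms collinear
  edge <- tibble::tibble(
    x1 = seq(0, 1, length.out = 9), x2 = 1 - x1, x3 = 0,
    y = seq(0, 1, length.out = 9)
  )
  expect_error(fit_scheffe(edge, y), "rank deficient")
})

test_that("tidy/glance/augment expose the fit in broom conventions", {
  fit <- fit_scheffe(blend_ic50_data(), ic50_glucosidase)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "significant"))
  expect_equal(nrow(td), 7)
  gl <- glance(fit)
  expect_equal(gl$nobs, 12)
  expect_equal(gl$df.residual, 5)
  expect_equal(gl$r.squared, fit$r_squared)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$ic50_glucosidase,
               tolerance = 1e-12)
})
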