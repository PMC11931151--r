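#' Simulate mixture-design IC50 responses from a known surface
#'
#' Generates responses with the statistical structure of the blend assay:
#' the special-cubic surface defined by `true_coefficients` is evaluated at
#' every design point, `assay_replicates` replicate measurements are drawn
#' with additive Gaussian noise of standard deviation `noise_sd`, and each
#' run reports the replicate mean and SD — the same mean-plus-minus-SD form
#' as a measured response table. With `noise_sd = 0` the means equal the
#' surface exactly, so a refit recovers `true_coefficients` to machine
#' precision.
#'
#' Additive Gaussian noise mirrors the symmetric plus/minus SDs that enzyme
#' assays report at these IC50 scales; set `lognormal = TRUE` for
#' multiplicative noise that keeps simulated IC50s positive at high noise
#' levels.
#'
#' @param true_coefficients Numeric vector of 7 special-cubic coefficients
#'   (mg/mL), e.g. [published_scheffe_coefficients()].
#' @param noise_sd Replicate noise SD in mg/mL. Default 0.003, the centre
#'   of the 0.001-0.009 range seen in measured blend tables.
#' @param assay_replicates Replicate measurements per run (default 3).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param design The `mixture_design` to simulate on (default: the 12-run
#'   augmented simplex-centroid).
#' @param lognormal Use multiplicative log-normal noise instead of additive
#'   Gaussian.
#' @return The design tibble with columns `response_mean`, `response_sd`
#'   and `true_response` appended.
#' @examples
#' sim <- simulate_mixture_responses(
#'   published_scheffe_coefficients("glucosidase"),
#'   noise_sd = 0, seed = 1
#' )
#' @export
simulate_mixture_responses <- function(true_coefficients,
                                       noise_sd = 0.003,
                                       assay_replicates = 3,
                                       seed = NULL,
                                       design = simplex_centroid_design(),
                                       lognormal = FALSE) {
  beta <- as_scheffe_coefficients(true_coefficients)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (assay_replicates < 1) abort("`assay_replicates` must be >= 1.")
  truth <- predict_scheffe(beta, design)

  draw <- function() {
    reps <- purrr::map(truth, function(mu) {
      if (lognormal) {
        if (mu <= 0) abort("Log-normal noise requires a positive surface.")
        sdlog <- sqrt(log1p((noise_sd / mu)^2))
        stats::rlnorm(assay_replicates, log(mu) - sdlog^2 / 2, sdlog)
      } else {
        stats::rnorm(assay_replicates, mu, noise_sd)
      }
    })
    out <- as_tibble(design)
    out$response_mean <- purrr::map_dbl(reps, mean)
    out$response_sd <- if (assay_replicates > 1) {
      purrr::map_dbl(reps, sd)
    } else {
      NA_real_
    }
    out$true_response <- truth
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a five-point dose-inhibition curve with known IC50
#'
#' Inhibition follows the log-linear law
#' `50 + slope * (log10(c) - log10(true_ic50))` at the five standard assay
#' concentrations, plus optional Gaussian noise. With `noise_sd = 0`,
#' [estimate_ic50()] recovers `true_ic50` exactly (both estimators).
#'
#' @param true_ic50 Generating IC50 in mg/mL.
#' @param slope Curve slope in percent per log10 unit (> 0).
#' @param noise_sd SD of additive Gaussian noise on inhibition (percent).
#' @param seed Optional integer seed.
#' @param concentrations Assay concentrations in mg/mL (default the
#'   standard five-point series 0.062-1).
#' @param replicates Number of replicate curves (adds a `replicate` column
#'   when > 1).
#' @return A tibble with columns `concentration`, `inhibition` and
#'   optionally `replicate`.
#' @examples
#' simulate_dose_response(0.25, slope = 30, noise_sd = 0)
#' @export
simulate_dose_response <- function(true_ic50,
                                   slope = 30,
                                   noise_sd = 0,
                                   seed = NULL,
                                   concentrations = c(0.062, 0.125, 0.25, 0.5, 1),
                                   replicates = 1) {
  if (!is.numeric(true_ic50) || true_ic50 <= 0) abort("`true_ic50` must be > 0.")
  if (slope <= 0) abort("`slope` must be > 0 (inhibition rises with dose).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  mu <- 50 + slope * (log10(concentrations) - log10(true_ic50))

  draw <- function() {
    out <- tidyr::expand_grid(
      replicate = seq_len(replicates),
      concentration = concentrations
    )
    out$inhibition <- rep(mu, replicates) +
      stats::rnorm(nrow(out), 0, noise_sd)
    if (replicates == 1) out$replicate <- NULL
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Monte-Carlo parameter-recovery report for the Scheffe fit
#'
#' Repeatedly simulates the full design with [simulate_mixture_responses()],
#' refits the special-cubic model, and summarizes per-coefficient bias,
#' RMSE and empirical standard error across simulations. The analytic
#' standard error is `sqrt(diag(sigma^2 (X'X)^-1))` with
#' `sigma = noise_sd / sqrt(assay_replicates)` (each fitted response is a
#' replicate mean); OLS unbiasedness makes the bias shrink toward zero as
#' `n_sims` grows, and `empirical_se / analytic_se` should sit near 1.
#'
#' @inheritParams simulate_mixture_responses
#' @param n_sims Number of simulated datasets (>= 100 recommended).
#' @return A tibble with one row per coefficient: `term`, `true`, `bias`,
#'   `rmse`, `empirical_se`, `analytic_se`, `se_ratio`.
#' @examples
#' \donttest{
#' parameter_recovery(published_scheffe_coefficients("glucosidase"),
#'                    n_sims = 100, seed = 7)
#' }
#' @export
parameter_recovery <- function(true_coefficients,
                               noise_sd = 0.003,
                               assay_replicates = 3,
                               n_sims = 500,
                               seed = NULL,
                               design = simplex_centroid_design()) {
  beta <- as_scheffe_coefficients(true_coefficients)
  if (n_sims < 2) abort("`n_sims` must be at least 2.")

  run <- function() {
    est <- matrix(NA_real_, n_sims, 7,
                  dimnames = list(NULL, scheffe_term_names()))
    for (s in seq_len(n_sims)) {
      sim <- simulate_mixture_responses(
        beta, noise_sd = noise_sd, assay_replicates = assay_replicates,
        design = design
      )
      est[s, ] <- fit_scheffe(sim, "response_mean")$coefficients
    }
    est
  }
  est <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  X <- special_cubic_terms(design)
  sigma <- noise_sd / sqrt(assay_replicates)
  analytic <- sqrt(diag(chol2inv(qr.R(qr(X)))) * sigma^2)

  emp_se <- unname(apply(est, 2, sd))
  tibble(
    term = scheffe_term_names(),
    true = unname(beta),
    bias = unname(colMeans(est)) - unname(beta),
    rmse = unname(sqrt(colMeans((est - matrix(beta, n_sims, 7,
                                              byrow = TRUE))^2))),
    empirical_se = emp_se,
    analytic_se = unname(analytic),
    se_ratio = ifelse(analytic > 0, emp_se / unname(analytic), NA_real_)
  )
}
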