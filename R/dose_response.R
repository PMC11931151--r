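#' Enzyme inhibition percentage from paired absorbances
#'
#' Inhibition is the relative drop in absorbance caused by the inhibitor:
#' `100 * (a_control - a_sample) / a_control`. Values below 0 (apparent
#' activation) or above 100 are returned unchanged so the raw assay signal is
#' preserved; use [flag_inhibition()] to mark them for QC.
#'
#' @param a_control Absorbance of the uninhibited control reaction (> 0).
#' @param a_sample Absorbance in the presence of the test material.
#' @return Numeric vector of inhibition percentages.
#' @examples
#' inhibition_percent(0.80, 0.20)  # 75
#' @export
inhibition_percent <- function(a_control, a_sample) {
  if (!is.numeric(a_control) || !is.numeric(a_sample)) {
    abort("Absorbances must be numeric.")
  }
  if (any(!is.finite(a_control)) || any(a_control <= 0)) {
    abort("`a_control` must be finite and > 0: the control defines 100% activity.")
  }
  100 * (a_control - a_sample) / a_control
}

#' QC flag for inhibition values
#'
#' @param inhibition Numeric vector of inhibition percentages.
#' @return Character vector: `"ok"`, `"negative"` (apparent activation) or
#'   `"above_100"`.
#' @export
flag_inhibition <- function(inhibition) {
  dplyr::case_when(
    inhibition < 0 ~ "negative",
    inhibition > 100 ~ "above_100",
    .default = "ok"
  )
}

#' Estimate IC50 from a dose-inhibition curve
#'
#' The half-maximal inhibitory concentration is located on the
#' log10(concentration) scale, where enzyme-inhibition curves are close to
#' linear over the assayed range. Two estimators are provided:
#'
#' * `"interpolation"` (default): find the adjacent concentration pair whose
#'   inhibition values bracket 50% and interpolate linearly in
#'   log10(concentration) — the numerical equivalent of reading the crossing
#'   off a semi-log plot. If no pair brackets 50% the estimate falls back to
#'   the regression line and is flagged `extrapolated`.
#' * `"regression"`: ordinary least squares of inhibition on
#'   log10(concentration) over all points, solved for 50%.
#'
#' If `data` has a `replicate` column, one estimate is returned per replicate
#' series (set `pooled = TRUE` to fit all points as one curve instead);
#' summarize across replicates with `mean()`/`sd()` as usual.
#'
#' @param data A data frame with columns `concentration` (mg/mL, positive)
#'   and either `inhibition` (percent) or the absorbance pair
#'   `a_control`/`a_sample`, plus an optional `replicate` column.
#' @param method `"interpolation"` or `"regression"`.
#' @param pooled If `TRUE`, ignore the `replicate` column and fit a single
#'   pooled curve.
#' @return A tibble with one row per estimated curve: `replicate` (if any),
#'   `ic50` (mg/mL), `method`, `extrapolated` (logical), `slope` (percent per
#'   log10 unit, from the regression line), and `n_points`.
#' @examples
#' curve <- tibble::tibble(
#'   concentration = c(0.062, 0.125, 0.25, 0.5, 1),
#'   inhibition = 50 + 30 * (log10(concentration) - log10(0.25))
#' )
#' estimate_ic50(curve)
#' @export
estimate_ic50 <- function(data,
                          method = c("interpolation", "regression"),
                          pooled = FALSE) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (!"concentration" %in% names(data)) {
    abort("`data` must contain a `concentration` column (mg/mL).")
  }
  if (!"inhibition" %in% names(data)) {
    if (all(c("a_control", "a_sample") %in% names(data))) {
      data$inhibition <- inhibition_percent(data$a_control, data$a_sample)
    } else {
      abort("`data` must contain `inhibition` or both `a_control` and `a_sample`.")
    }
  }
  if (any(data$concentration <= 0)) {
    abort("Concentrations must be strictly positive (log scale).")
  }
  out_of_range <- flag_inhibition(data$inhibition)
  if (any(out_of_range != "ok")) {
    warn(sprintf(
      "%d inhibition value(s) outside [0, 100] retained unclipped.",
      sum(out_of_range != "ok")
    ))
  }

  has_rep <- "replicate" %in% names(data) && !pooled
  groups <- if (has_rep) split(data, data$replicate) else list(data)

  res <- purrr::imap(groups, function(d, key) {
    est <- ic50_single(d$concentration, d$inhibition, method)
    est$replicate <- if (has_rep) key else NA_character_
    est
  })
  out <- dplyr::bind_rows(res)
  if (has_rep) dplyr::relocate(out, "replicate") else
    dplyr::select(out, -"replicate")
}

# One curve, already validated. Ascending-concentration order is imposed here.
ic50_single <- function(conc, inh, method) {
  ord <- order(conc)
  conc <- conc[ord]
  inh <- inh[ord]
  if (length(conc) < 2) {
    abort("At least 2 concentration points are required to estimate an IC50.")
  }
  if (anyDuplicated(conc)) {
    # pooled replicate curves: average inhibition at each concentration
    u <- sort(unique(conc))
    inh <- vapply(u, function(cc) mean(inh[conc == cc]), numeric(1))
    conc <- u
  }
  if (length(unique(inh)) == 1) {
    abort("Inhibition is constant across concentrations; IC50 is undefined.")
  }
  lc <- log10(conc)
  fit <- lm(inh ~ lc)
  slope <- unname(coef(fit)[2])

  regression_ic50 <- function() {
    if (abs(slope) < .Machine$double.eps^0.5) {
      abort("Regression slope is zero: the curve never crosses 50%.")
    }
    10^((50 - unname(coef(fit)[1])) / slope)
  }

  inside <- min(inh) <= 50 && max(inh) >= 50
  if (method == "regression") {
    value <- regression_ic50()
    return(tibble(
      ic50 = value, method = "regression",
      extrapolated = !inside, slope = slope, n_points = length(conc)
    ))
  }

  # interpolation: exact hit first, then a sign change on adjacent pairs
  hit <- which(inh == 50)
  if (length(hit) > 0) {
    value <- conc[hit[1]]
    extrapolated <- FALSE
  } else {
    d <- inh - 50
    cross <- which(d[-length(d)] * d[-1] < 0)
    if (length(cross) > 0) {
      i <- cross[1]
      value <- 10^(lc[i] + (50 - inh[i]) * (lc[i + 1] - lc[i]) /
                     (inh[i + 1] - inh[i]))
      extrapolated <- FALSE
    } else {
      value <- regression_ic50()
      extrapolated <- TRUE
    }
  }
  tibble(
    ic50 = value, method = "interpolation",
    extrapolated = extrapolated, slope = slope, n_points = length(conc)
  )
}

#' Plot a dose-inhibition curve with its IC50 estimate
#'
#' @param data Data frame as accepted by [estimate_ic50()].
#' @param method Estimator passed on to [estimate_ic50()].
#' @return A ggplot: inhibition vs log10 concentration, the 50% reference
#'   line, and the estimated IC50(s).
#' @export
plot_dose_response <- function(data, method = "interpolation") {
  est <- suppressWarnings(estimate_ic50(data, method = method))
  data <- as_tibble(data)
  if (!"inhibition" %in% names(data)) {
    data$inhibition <- inhibition_percent(data$a_control, data$a_sample)
  }
  mapping <- if ("replicate" %in% names(data)) {
    ggplot2::aes(log10(.data$concentration), .data$inhibition,
                 colour = factor(.data$replicate))
  } else {
    ggplot2::aes(log10(.data$concentration), .data$inhibition)
  }
  ggplot2::ggplot(data, mapping) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log10(est$ic50), linetype = "dotted") +
    ggplot2::labs(
      x = "log10 concentration (mg/mL)", y = "Inhibition (%)",
      colour = "Replicate",
      title = sprintf("IC50 = %s mg/mL",
                      paste(signif(est$ic50, 3), collapse = ", "))
    )
}
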