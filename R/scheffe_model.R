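#' Special-cubic model terms for a three-component mixture
#'
#' Expands compositions into the seven Scheffe special-cubic regressors
#' `(x1, x2, x3, x1*x2, x1*x3, x2*x3, x1*x2*x3)`. Because the proportions sum
#' to one, the model carries no intercept: the linear coefficients are the
#' predicted responses of the pure components, the binary terms capture
#' blending synergy or antagonism along each edge, and the ternary term the
#' three-way blending effect.
#'
#' @param x A composition: numeric vector of length 3, a 3-column matrix, or
#'   a data frame with columns `x1`, `x2`, `x3`.
#' @return A numeric matrix with 7 named columns, one row per composition.
#' @examples
#' special_cubic_terms(c(1/3, 1/3, 1/3))
#' @export
special_cubic_terms <- function(x) {
  if (is.data.frame(x)) x <- proportion_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3) {
    abort("The special-cubic model is defined for exactly 3 components.")
  }
  out <- cbind(
    x[, 1], x[, 2], x[, 3],
    x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
    x[, 1] * x[, 2] * x[, 3]
  )
  colnames(out) <- scheffe_term_names()
  out
}

scheffe_term_names <- function() {
  c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3", "x1:x2:x3")
}

#' Fit the Scheffe special-cubic model to mixture responses
#'
#' Intercept-free ordinary least squares of a response on the seven
#' special-cubic terms of a three-component mixture design. Standard errors
#' use the unbiased residual variance on `n - 7` degrees of freedom;
#' coefficient p-values are two-sided Student-t. The reported R-squared uses
#' the corrected (mean-centred) total sum of squares, the convention of
#' mixture-design software, even though the model itself has no intercept.
#'
#' @param data A data frame holding the design proportions `x1, x2, x3` (for
#'   example a [simplex_centroid_design()] joined with measured responses)
#'   and the response column.
#' @param response The response column, as a bare name or string
#'   (tidy-evaluated). Typically a mean IC50 in mg/mL.
#' @return An object of class `scheffe_fit`: see [tidy()], [glance()],
#'   [augment()], [predict.scheffe_fit()], [scheffe_anova()].
#' @examples
#' blend <- blend_ic50_data()
#' fit <- fit_scheffe(blend, ic50_glucosidase)
#' tidy(fit)
#' glance(fit)
#' @export
fit_scheffe <- function(data, response) {
  data <- as_tibble(data)
  response_name <- resolve_column(data, rlang::enquo(response))
  y <- data[[response_name]]
  props <- proportion_matrix(data)
  if (ncol(props) != 3) {
    abort("`fit_scheffe()` requires a three-component design (columns x1, x2, x3).")
  }
  if (nrow(props) < 8) {
    abort("At least 8 runs are needed to fit 7 terms with residual df >= 1.")
  }
  if (!is.numeric(y) || any(!is.finite(y))) {
    abort("The response must be finite and numeric.")
  }

  X <- special_cubic_terms(props)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0(
      "Design matrix is rank deficient; collinear term(s): ",
      paste(dropped, collapse = ", "),
      ". The augmented simplex-centroid design avoids this."
    ))
  }

  df_fit <- as.data.frame(X)
  names(df_fit) <- paste0("t", seq_len(ncol(X)))  # syntactic names for lm
  df_fit$.y <- y
  lm_fit <- lm(.y ~ 0 + ., data = df_fit)
  beta <- setNames(coef(lm_fit), colnames(X))

  res <- unname(resid(lm_fit))
  n <- length(y)
  df_residual <- n - ncol(X)
  sigma2 <- sum(res^2) / df_residual
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_residual, lower.tail = FALSE)

  ss_total <- sum((y - mean(y))^2)
  ss_res <- sum(res^2)

  structure(
    list(
      coefficients = beta,
      std_errors = setNames(se, colnames(X)),
      t_values = setNames(tval, colnames(X)),
      p_values = setNames(pval, colnames(X)),
      residuals = res,
      fitted = unname(lm_fit$fitted.values),
      df_residual = df_residual,
      sigma2 = sigma2,
      r_squared = 1 - ss_res / ss_total,
      response = response_name,
      data = data,
      proportions = props,
      lm = lm_fit
    ),
    class = "scheffe_fit"
  )
}

# Resolve a column given as a bare name, a string literal, or a variable
# holding a string, to the column's name.
resolve_column <- function(data, quo) {
  if (rlang::quo_is_symbol(quo) && rlang::as_name(quo) %in% names(data)) {
    return(rlang::as_name(quo))
  }
  v <- try(rlang::eval_tidy(quo), silent = TRUE)
  if (is.character(v) && length(v) == 1 && v %in% names(data)) {
    return(v)
  }
  abort(sprintf("Response column `%s` not found in `data`.",
                rlang::as_label(quo)))
}

#' @export
print.scheffe_fit <- function(x, ...) {
  cat(sprintf(
    "Scheffe special-cubic fit: response `%s`, %d runs, residual df %d\n",
    x$response, length(x$residuals), x$df_residual
  ))
  cat(sprintf("R-squared (corrected total): %.4f\n\n", x$r_squared))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn fit_scheffe Coefficient table: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, and `significant` at the 5% level.
#' @param x,object A `scheffe_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scheffe_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$t_values),
    p.value = unname(x$p_values),
    significant = unname(x$p_values) < 0.05
  )
}

#' @describeIn fit_scheffe One-row model summary with the corrected-total
#'   R-squared and the regression F test.
#' @exportS3Method generics::glance
glance.scheffe_fit <- function(x, ...) {
  an <- scheffe_anova(x, quiet = TRUE)
  reg <- an[an$source == "regression", ]
  tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$sigma2),
    statistic = reg$statistic,
    p.value = reg$p.value,
    df = reg$df,
    df.residual = x$df_residual,
    nobs = length(x$residuals)
  )
}

#' @describeIn fit_scheffe The modelling data with `.fitted` and `.resid`
#'   columns appended.
#' @exportS3Method generics::augment
augment.scheffe_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  out
}

#' Predict blend responses from a fitted or published special-cubic model
#'
#' @param object A `scheffe_fit`, or (via [predict_scheffe()]) a named
#'   7-vector of coefficients in the canonical term order.
#' @param newdata Compositions: numeric vector of length 3, matrix, or data
#'   frame with `x1, x2, x3`. Defaults to the training design.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.scheffe_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_scheffe(object$coefficients, newdata)
}

#' @rdname predict.scheffe_fit
#' @param coefficients Numeric vector of 7 special-cubic coefficients.
#' @export
predict_scheffe <- function(coefficients, newdata) {
  coefficients <- as_scheffe_coefficients(coefficients)
  drop(special_cubic_terms(newdata) %*% coefficients)
}

# Accept a scheffe_fit, a named or unnamed length-7 vector.
as_scheffe_coefficients <- function(x) {
  if (inherits(x, "scheffe_fit")) return(x$coefficients)
  if (!is.numeric(x) || length(x) != 7) {
    abort("Expected a `scheffe_fit` or a numeric vector of 7 coefficients.")
  }
  if (is.null(names(x))) names(x) <- scheffe_term_names()
  x[scheffe_term_names()]
}

#' Mixture-model ANOVA with lack-of-fit / pure-error split
#'
#' Decomposes the corrected total sum of squares (`sum((y - mean(y))^2)`, on
#' `n - 1` df) into regression (6 df: seven terms less the one absorbed by
#' the mixture constraint) and residual. Replicated design points — detected
#' as exact duplicate compositions — split the residual into pure error
#' (within-replicate-group variation) and lack of fit. F tests: regression
#' mean square over residual mean square, and lack-of-fit mean square over
#' pure-error mean square (a large value signals model inadequacy beyond
#' replicate noise).
#'
#' @param fit A `scheffe_fit`.
#' @param quiet Suppress the warning issued when no replicated points exist.
#' @return A tibble of class `scheffe_anova` with columns `source`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`; the corrected R-squared is
#'   attached as attribute `r_squared`.
#' @examples
#' fit <- fit_scheffe(blend_ic50_data(), ic50_amylase)
#' scheffe_anova(fit)
#' @export
scheffe_anova <- function(fit, quiet = FALSE) {
  stopifnot(inherits(fit, "scheffe_fit"))
  y <- fit$fitted + fit$residuals
  n <- length(y)

  ss_total <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_reg <- ss_total - ss_res
  df_total <- n - 1
  df_reg <- 6L
  df_res <- fit$df_residual

  ms_reg <- ss_reg / df_reg
  ms_res <- ss_res / df_res
  f_reg <- ms_reg / ms_res
  p_reg <- pf(f_reg, df_reg, df_res, lower.tail = FALSE)

  groups <- replicate_groups(fit$proportions)
  rep_groups <- split(y, groups)
  rep_groups <- rep_groups[lengths(rep_groups) >= 2]

  rows <- tibble(
    source = c("regression", "residual"),
    df = c(df_reg, df_res),
    sumsq = c(ss_reg, ss_res),
    meansq = c(ms_reg, ms_res),
    statistic = c(f_reg, NA_real_),
    p.value = c(p_reg, NA_real_)
  )

  if (length(rep_groups) == 0) {
    if (!quiet) {
      warn(paste(
        "No replicated design points: pure error is undefined and the",
        "lack-of-fit split is omitted."
      ))
    }
  } else {
    ss_pe <- sum(purrr::map_dbl(rep_groups, ~ sum((.x - mean(.x))^2)))
    df_pe <- sum(lengths(rep_groups) - 1L)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    ms_lof <- ss_lof / df_lof
    f_lof <- ms_lof / ms_pe
    p_lof <- pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    rows <- dplyr::bind_rows(rows, tibble(
      source = c("lack_of_fit", "pure_error"),
      df = c(df_lof, df_pe),
      sumsq = c(ss_lof, ss_pe),
      meansq = c(ms_lof, ms_pe),
      statistic = c(f_lof, NA_real_),
      p.value = c(p_lof, NA_real_)
    ))
  }

  rows <- dplyr::bind_rows(rows, tibble(
    source = "total", df = df_total, sumsq = ss_total,
    meansq = NA_real_, statistic = NA_real_, p.value = NA_real_
  ))
  attr(rows, "r_squared") <- fit$r_squared
  class(rows) <- c("scheffe_anova", class(rows))
  rows
}

#' Coefficient significance table in reporting style
#'
#' Like [tidy()] but with p-values rendered the way formulation studies print
#' them: `"<0.0001"` below 1e-4, four decimals otherwise, and a `*` star for
#' terms significant at the 5% level. Exact p-values stay available from
#' [tidy()].
#'
#' @param fit A `scheffe_fit`.
#' @param alpha Significance level for the star (default 0.05).
#' @return A tibble: `term`, `estimate`, `p.value`, `p_label`, `signif`.
#' @export
coefficient_table <- function(fit, alpha = 0.05) {
  td <- tidy(fit)
  tibble(
    term = td$term,
    estimate = td$estimate,
    p.value = td$p.value,
    p_label = ifelse(td$p.value < 1e-4, "<0.0001", sprintf("%.4f", td$p.value)),
    signif = ifelse(td$p.value < alpha, "*", "")
  )
}

#' Drop non-significant interaction terms and refit
#'
#' Backward reduction of the special-cubic model: interaction terms with
#' p-values above `alpha` are removed (linear blending terms are always
#' kept, as required for a valid Scheffe polynomial) and the model is refit
#' once on the remaining terms. Coefficients of removed terms are reported
#' as zero.
#'
#' @param fit A full `scheffe_fit`.
#' @param alpha Retention threshold on the full-model p-values.
#' @return A `scheffe_fit` whose coefficient vector has zeros for dropped
#'   terms; the dropped term names are in attribute `dropped`.
#' @export
reduce_scheffe <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "scheffe_fit"))
  td <- tidy(fit)
  interactions <- grepl(":", td$term)
  drop <- td$term[interactions & td$p.value > alpha]
  if (length(drop) == 0) return(fit)

  keep <- setdiff(td$term, drop)
  X <- special_cubic_terms(fit$proportions)[, keep, drop = FALSE]
  y <- fit$fitted + fit$residuals
  qrX <- qr(X)
  beta_kept <- qr.coef(qrX, y)
  beta <- setNames(numeric(7), scheffe_term_names())
  beta[keep] <- beta_kept

  n <- length(y)
  df_residual <- n - length(keep)
  res <- y - drop(X %*% beta_kept)
  sigma2 <- sum(res^2) / df_residual
  XtX_inv <- chol2inv(qr.R(qrX))
  se_kept <- sqrt(sigma2 * diag(XtX_inv))
  se <- setNames(rep(NA_real_, 7), scheffe_term_names())
  se[keep] <- se_kept
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_residual, lower.tail = FALSE)

  out <- fit
  out$coefficients <- beta
  out$std_errors <- se
  out$t_values <- tval
  out$p_values <- pval
  out$residuals <- res
  out$fitted <- y - res
  out$df_residual <- df_residual
  out$sigma2 <- sigma2
  out$r_squared <- 1 - sum(res^2) / sum((y - mean(y))^2)
  attr(out, "dropped") <- drop
  out
}

#' Observed-versus-predicted plot for a Scheffe fit
#'
#' @param object A `scheffe_fit`.
#' @param ... Unused.
#' @return A ggplot comparing observed responses with model predictions; a
#'   tight diagonal indicates a good fit.
#' @exportS3Method ggplot2::autoplot
autoplot.scheffe_fit <- function(object, ...) {
  d <- tibble(
    observed = object$fitted + object$residuals,
    predicted = object$fitted
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Predicted %s", object$response),
      y = sprintf("Observed %s", object$response),
      title = sprintf("R² = %.3f", object$r_squared)
    )
}
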