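# Independent oracles kept deliberately naive: they must not share code
# paths with the implementation they check.

# Least squares by explicitly solving the normal equations.
normal_equations_fit <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Pure-error sum of squares by looping over replicate groups.
pure_error_brute <- function(props, y) {
  key <- apply(round(props, 9), 1, paste, collapse = "|")
  ss <- 0
  df <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) >= 2) {
      ss <- ss + sum((y[idx] - mean(y[idx]))^2)
      df <- df + length(idx) - 1L
    }
  }
  list(ss = ss, df = df)
}

# Hand evaluation of the special cubic at one composition.
eval_special_cubic <- function(b, p) {
  sum(b * c(p[1], p[2], p[3],
            p[1] * p[2], p[1] * p[3], p[2] * p[3],
            p[1] * p[2] * p[3]))
}

# Published 7-term coefficient estimates and significance pattern
# (3-decimal reporting precision) for the measured blend dataset.
golden_coefficients <- function(response) {
  if (response == "glucosidase") {
    list(
      estimate = c(0.069, 0.077, 0.045, -0.115, -0.052, -0.059, 0.200),
      significant = rep(TRUE, 7)
    )
  } else {
    list(
      estimate = c(0.046, 0.068, 0.032, -0.140, 0.052, -0.016, 3.110),
      significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
    )
  }
}
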