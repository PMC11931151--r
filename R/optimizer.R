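#' Derringer desirability score
#'
#' Maps a response value onto `[0, 1]` relative to a target and an
#' acceptability bound. For a `"minimize"` goal the score is 1 at or below
#' the target `target`, 0 at or above the bound `upper`, and
#' `((upper - y) / (upper - target))^weight` in between; `"maximize"` is the
#' mirror image with a lower bound `lower`; `"target"` ramps up to the target
#' from `lower` and back down to `upper`. Multi-response desirability is the
#' geometric mean of per-response scores ([overall_desirability()]).
#'
#' @param y Numeric response value(s).
#' @param goal `"minimize"`, `"maximize"` or `"target"`.
#' @param target Most desirable response value.
#' @param upper Upper acceptability bound (required for minimize/target).
#' @param lower Lower acceptability bound (required for maximize/target).
#' @param weight Positive exponent shaping the ramp (1 = linear).
#' @return Desirability score(s) in `[0, 1]`.
#' @examples
#' desirability(0.05, "minimize", target = 0.041, upper = 0.078)
#' @export
desirability <- function(y, goal = c("minimize", "maximize", "target"),
                         target, upper = NULL, lower = NULL, weight = 1) {
  goal <- match.arg(goal)
  if (!is.numeric(weight) || weight <= 0) abort("`weight` must be > 0.")
  ramp <- function(num, den) pmin(1, pmax(0, num / den))^weight
  switch(goal,
    minimize = {
      if (is.null(upper)) abort("`upper` is required for goal = \"minimize\".")
      if (upper <= target) abort("Need `target` < `upper` for a minimize goal.")
      ramp(upper - y, upper - target)
    },
    maximize = {
      if (is.null(lower)) abort("`lower` is required for goal = \"maximize\".")
      if (lower >= target) abort("Need `lower` < `target` for a maximize goal.")
      ramp(y - lower, target - lower)
    },
    target = {
      if (is.null(lower) || is.null(upper)) {
        abort("`lower` and `upper` are required for goal = \"target\".")
      }
      if (!(lower < target && target < upper)) {
        abort("Need `lower` < `target` < `upper` for a target goal.")
      }
      ifelse(y <= target, ramp(y - lower, target - lower),
             ramp(upper - y, upper - target))
    }
  )
}

#' Combine per-response desirabilities
#'
#' @param ... Numeric vectors of per-response desirability scores.
#' @return Their geometric mean (elementwise).
#' @export
overall_desirability <- function(...) {
  d <- cbind(...)
  if (any(d < 0 | d > 1, na.rm = TRUE)) {
    abort("Desirability scores must lie in [0, 1].")
  }
  exp(rowMeans(log(d)))
}

# All compositions on the q=3 simplex lattice with `n` subdivisions,
# ordered lexicographically by (x1, x2, x3) descending index so that
# which.min tie-breaks reproducibly; returns an (N x 3) matrix.
simplex_lattice <- function(n) {
  i <- rep.int(0:n, n + 1L - (0:n))
  j <- sequence(n + 1L - (0:n)) - 1L
  cbind(x1 = i / n, x2 = j / n, x3 = (n - i - j) / n)
}

#' Minimize a blend response over the mixture simplex
#'
#' Exhaustively evaluates the special-cubic model on a dense simplex lattice
#' (pitch `grid_step`, boundary included) and then polishes the best lattice
#' point by deterministic pairwise coordinate descent with step halving down
#' to 1e-6. The special cubic is a low-order polynomial over a compact
#' region, so the dense grid brackets the global minimum and the polish
#' refines it; ties are broken toward the lexicographically smallest
#' composition.
#'
#' @param object A `scheffe_fit` or a numeric vector of 7 special-cubic
#'   coefficients (for instance published model coefficients).
#' @param grid_step Lattice pitch (default 0.001; must be <= 0.01).
#' @param desirability_bounds Optional list with elements `target` and
#'   `upper` for the minimize-goal desirability of the optimum. Defaults:
#'   `target` = the minimum found, `upper` = the largest observed response
#'   (for a fit) or the largest lattice prediction (for raw coefficients),
#'   under which the optimum scores 1 by construction.
#' @return A one-row tibble: `x1, x2, x3`, `predicted` (response at the
#'   optimum), `desirability`, and `boundary` (comma-separated names of
#'   zero components, `""` for an interior optimum).
#' @examples
#' coefs <- published_scheffe_coefficients("glucosidase")
#' optimize_blend(coefs, grid_step = 0.005)
#' @export
optimize_blend <- function(object, grid_step = 0.001,
                           desirability_bounds = NULL) {
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.01) {
    abort("`grid_step` must be in (0, 0.01].")
  }
  beta <- as_scheffe_coefficients(object)
  n <- round(1 / grid_step)

  grid <- simplex_lattice(n)
  pred <- drop(special_cubic_terms(grid) %*% beta)

  best_val <- min(pred)
  ties <- which(pred == best_val)
  best <- grid[ties[lex_smallest(grid[ties, , drop = FALSE])], ]

  polished <- polish_simplex(best, beta, step0 = grid_step)
  # polish must never lose to the grid point
  if (polished$value > best_val) {
    polished <- list(x = best, value = best_val)
  }
  x <- unname(polished$x)
  value <- unname(polished$value)

  if (is.null(desirability_bounds)) {
    upper <- if (inherits(object, "scheffe_fit")) {
      max(object$fitted + object$residuals)
    } else {
      max(pred)
    }
    desirability_bounds <- list(target = value, upper = upper)
  }
  d <- desirability(value, "minimize",
                    target = desirability_bounds$target,
                    upper = desirability_bounds$upper)

  zero <- abs(x) < 1e-9
  tibble(
    x1 = x[1], x2 = x[2], x3 = x[3],
    predicted = value,
    desirability = d,
    boundary = paste(c("x1", "x2", "x3")[zero], collapse = ",")
  )
}

# Index of the lexicographically smallest row of a matrix.
lex_smallest <- function(m) {
  if (nrow(m) == 1) return(1L)
  ord <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                          list(decreasing = FALSE)))
  ord[1]
}

# Deterministic pairwise coordinate descent on the simplex: repeatedly try
# moving `step` of mass between every ordered component pair, halving the
# step when no move improves, down to 1e-6.
polish_simplex <- function(x, beta, step0, step_min = 1e-6) {
  value <- sum(special_cubic_terms(x) * beta)
  step <- step0
  pairs <- expand.grid(from = 1:3, to = 1:3)
  pairs <- pairs[pairs$from != pairs$to, ]
  while (step >= step_min) {
    improved <- FALSE
    for (k in seq_len(nrow(pairs))) {
      from <- pairs$from[k]; to <- pairs$to[k]
      if (x[from] < step) next
      cand <- x
      cand[from] <- cand[from] - step
      cand[to] <- cand[to] + step
      v <- sum(special_cubic_terms(cand) * beta)
      if (v < value) {
        x <- cand
        value <- v
        improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  list(x = x, value = value)
}

#' Ternary response-surface grid
#'
#' Evaluates a special-cubic model on a barycentric lattice with
#' `resolution` subdivisions per edge — `choose(resolution + 2, 2)` nodes —
#' for contour/surface display or export. Vertex nodes equal the linear
#' coefficients of the model.
#'
#' @param object A `scheffe_fit` or a numeric vector of 7 coefficients.
#' @param resolution Number of lattice subdivisions per edge (>= 10 for
#'   plotting; smaller values are allowed for inspection).
#' @return A tibble of class `blend_surface`: `x1, x2, x3, predicted`.
#' @examples
#' surf <- response_surface(published_scheffe_coefficients("amylase"), 50)
#' @export
response_surface <- function(object, resolution = 100) {
  if (!is.numeric(resolution) || resolution < 2 ||
      resolution != round(resolution)) {
    abort("`resolution` must be an integer >= 2.")
  }
  beta <- as_scheffe_coefficients(object)
  grid <- simplex_lattice(resolution)
  out <- as_tibble(grid)
  out$predicted <- drop(special_cubic_terms(grid) %*% beta)
  class(out) <- c("blend_surface", class(out))
  out
}

# Barycentric -> 2D cartesian (equilateral triangle, unit edge).
ternary_xy <- function(props) {
  tibble(
    tx = props[, 2] + props[, 3] / 2,
    ty = props[, 3] * sqrt(3) / 2
  )
}

#' Ternary contour plot of a blend response surface
#'
#' @param object A `blend_surface` from [response_surface()].
#' @param ... Unused.
#' @return A ggplot of the simplex coloured by predicted response (lower =
#'   stronger inhibition for IC50 responses).
#' @exportS3Method ggplot2::autoplot
autoplot.blend_surface <- function(object, ...) {
  props <- proportion_matrix(object)
  d <- dplyr::bind_cols(as_tibble(object), ternary_xy(props))
  tri <- tibble(tx = c(0, 1, 0.5, 0), ty = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(d, ggplot2::aes(.data$tx, .data$ty)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$predicted), size = 1) +
    ggplot2::geom_path(data = tri, linewidth = 0.3, colour = "black") +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Predicted",
                  title = "Blend response surface (x1 left, x2 right, x3 top)")
}

#' Design-point plot on the ternary simplex
#'
#' @param object A `mixture_design`.
#' @param ... Unused.
#' @return A ggplot showing the design points coloured by point type.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_design <- function(object, ...) {
  props <- proportion_matrix(object)
  d <- dplyr::bind_cols(as_tibble(object), ternary_xy(props))
  tri <- tibble(tx = c(0, 1, 0.5, 0), ty = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(d, ggplot2::aes(.data$tx, .data$ty)) +
    ggplot2::geom_path(data = tri, linewidth = 0.3, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$point_type), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Point type",
                  title = "Augmented simplex-centroid design")
}
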