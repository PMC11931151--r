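#' Augmented simplex-centroid mixture design
#'
#' Builds the standard augmented simplex-centroid design for a `q`-component
#' mixture: the `q` pure-component vertices, all `choose(q, 2)` binary edge
#' midpoints, the overall centroid (optionally replicated to provide pure
#' error), and `q` interior axial points. For the default three-oil blend
#' (`q = 3`, three centroid runs, axial fraction 1/6) this is the 12-run,
#' 10-unique-point layout used throughout the package.
#'
#' Proportions are computed from exact fractions (`1/3`, `1/6`, ...) so that
#' every run sums to one to machine precision; round only for display.
#'
#' @param q Number of mixture components (>= 3).
#' @param centroid_runs Total number of centroid rows, including replicates
#'   (>= 1). The replicated centroid supplies the pure-error degrees of
#'   freedom in [scheffe_anova()].
#' @param axial_fraction Proportion assigned to each *minor* component of an
#'   axial point; the major component gets `1 - (q - 1) * axial_fraction`.
#'   Must lie strictly between 0 and `1/q`. The default `1/6` places axial
#'   points halfway between the centroid and each vertex.
#' @param component_names Optional character vector of length `q` used as
#'   component labels (stored as an attribute; columns are always
#'   `x1 ... xq`).
#'
#' @return A tibble of class `mixture_design` with columns `run` (integer),
#'   `point_type` (`"vertex"`, `"edge_midpoint"`, `"centroid"`, `"axial"`),
#'   `replicate_group` (integer; equal values mark identical compositions)
#'   and the proportion columns `x1 ... xq`.
#'
#' @examples
#' design <- simplex_centroid_design()
#' design
#' nrow(design)                         # 12 runs
#' dplyr::n_distinct(design$replicate_group)  # 10 unique points
#' @export
simplex_centroid_design <- function(q = 3,
                                    centroid_runs = 3,
                                    axial_fraction = 1 / 6,
                                    component_names = NULL) {
  if (!is.numeric(q) || length(q) != 1 || q < 3 || q != round(q)) {
    abort("`q` must be a single integer >= 3.")
  }
  if (!is.numeric(centroid_runs) || length(centroid_runs) != 1 ||
      centroid_runs < 1 || centroid_runs != round(centroid_runs)) {
    abort("`centroid_runs` must be a single integer >= 1.")
  }
  if (!is.numeric(axial_fraction) || length(axial_fraction) != 1 ||
      axial_fraction <= 0 || axial_fraction >= 1 / q) {
    abort("`axial_fraction` must lie strictly between 0 and 1/q.")
  }
  if (!is.null(component_names) && length(component_names) != q) {
    abort("`component_names` must have length `q`.")
  }

  vertices <- diag(q)
  pairs <- combn(q, 2)
  edges <- t(apply(pairs, 2, function(ij) {
    v <- numeric(q)
    v[ij] <- 1 / 2
    v
  }))
  centroid <- matrix(rep(1 / q, q * centroid_runs),
                     nrow = centroid_runs, byrow = TRUE)
  axial <- matrix(axial_fraction, nrow = q, ncol = q)
  diag(axial) <- 1 - (q - 1) * axial_fraction

  props <- rbind(vertices, edges, centroid, axial)
  colnames(props) <- paste0("x", seq_len(q))
  point_type <- c(
    rep("vertex", q),
    rep("edge_midpoint", ncol(pairs)),
    rep("centroid", centroid_runs),
    rep("axial", q)
  )

  out <- tibble(
    run = seq_len(nrow(props)),
    point_type = point_type
  )
  out <- dplyr::bind_cols(out, as_tibble(props))
  out$replicate_group <- replicate_groups(props)
  out <- dplyr::relocate(out, "replicate_group", .after = "point_type")

  attr(out, "q") <- as.integer(q)
  attr(out, "component_names") <- component_names
  class(out) <- c("mixture_design", class(out))
  out
}

#' Assign replicate-group ids to a matrix of compositions
#'
#' Rows with identical proportion vectors (to 1e-9) share an id, in order of
#' first appearance. Replicate groups with two or more members provide the
#' pure-error split in the lack-of-fit ANOVA.
#' @param props Numeric matrix, one composition per row.
#' @return Integer vector of group ids.
#' @keywords internal
replicate_groups <- function(props) {
  keys <- apply(round(props, 9), 1, paste, collapse = "|")
  match(keys, unique(keys))
}

#' Validate (and optionally renormalize) a mixture composition
#'
#' A valid composition has non-negative entries summing to one. In strict
#' mode any departure of the sum from one beyond `tol` is an error; in
#' lenient mode the vector is rescaled to sum to one and a message is
#' emitted. Negative entries are always an error.
#'
#' @param x Numeric vector of proportions.
#' @param strict If `TRUE` (default) reject sums outside `1 +/- tol`;
#'   otherwise renormalize.
#' @param tol Tolerance on `|sum(x) - 1|` in strict mode.
#' @return The validated (possibly renormalized) numeric vector.
#' @examples
#' validate_composition(c(0.5, 0.5, 0))
#' validate_composition(c(0.4, 0.4, 0.4), strict = FALSE)  # rescaled
#' @export
validate_composition <- function(x, strict = TRUE, tol = 1e-6) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("A composition must be a numeric vector of length >= 2.")
  }
  if (any(!is.finite(x))) abort("Composition entries must be finite.")
  if (any(x < 0)) abort("Composition entries must be non-negative.")
  s <- sum(x)
  if (abs(s - 1) > tol) {
    if (strict) {
      abort(sprintf(
        "Proportions must sum to 1 (got %.6f). Use strict = FALSE to renormalize.",
        s
      ))
    }
    if (s <= 0) abort("Cannot renormalize a composition with zero sum.")
    inform(sprintf("Renormalizing composition: sum was %.6f.", s))
    x <- x / s
  }
  x
}

#' Randomize the run order of a mixture design
#'
#' Returns the design with rows shuffled (run ids are kept with their rows so
#' the original canonical position remains traceable). A seed makes the
#' shuffle reproducible.
#'
#' @param design A `mixture_design`.
#' @param seed Optional integer seed.
#' @return The permuted design.
#' @export
randomize_runs <- function(design, seed = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  perm <- if (is.null(seed)) {
    sample.int(nrow(design))
  } else {
    withr::with_seed(seed, sample.int(nrow(design)))
  }
  design[perm, , drop = FALSE]
}

#' Extract the proportion columns of a design as a matrix
#' @param data A data frame containing columns `x1 ... xq`.
#' @return Numeric matrix of proportions.
#' @keywords internal
proportion_matrix <- function(data) {
  cols <- grep("^x[0-9]+$", names(data), value = TRUE)
  if (length(cols) < 2) {
    abort("No proportion columns `x1`, `x2`, ... found.")
  }
  cols <- cols[order(as.integer(sub("^x", "", cols)))]
  as.matrix(data[cols])
}

#' @export
print.mixture_design <- function(x, ...) {
  q <- attr(x, "q")
  cat(sprintf(
    "Augmented simplex-centroid design: %d components, %d runs, %d unique points\n",
    q, nrow(x), length(unique(x$replicate_group))
  ))
  nms <- attr(x, "component_names")
  if (!is.null(nms)) {
    cat("Components:", paste(sprintf("x%d = %s", seq_along(nms), nms),
                             collapse = ", "), "\n")
  }
  NextMethod()
  invisible(x)
}
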