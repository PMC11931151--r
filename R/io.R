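#' Parse "mean ± sd" cells
#'
#' Splits strings such as `"0.044 ± 0.001"` (also accepted: `"0.044 +/-
#' 0.001"` or a bare number, giving `sd = NA`) into numeric mean and SD.
#'
#' @param x Character vector of cells.
#' @return A tibble with columns `mean` and `sd`.
#' @examples
#' parse_mean_sd(c("0.044 ± 0.001", "0.15"))
#' @export
parse_mean_sd <- function(x) {
  x <- trimws(as.character(x))
  parts <- strsplit(x, "±|\\+/-")
  parse_one <- function(p, raw) {
    p <- trimws(p)
    m <- suppressWarnings(as.numeric(p[1]))
    s <- if (length(p) > 1) suppressWarnings(as.numeric(p[2])) else NA_real_
    if (is.na(m) || (length(p) > 1 && is.na(s))) {
      abort(sprintf("Malformed numeric cell: \"%s\".", raw))
    }
    c(m, s)
  }
  vals <- purrr::map2(parts, x, parse_one)
  tibble(
    mean = purrr::map_dbl(vals, 1),
    sd = purrr::map_dbl(vals, 2)
  )
}

#' Read a blend response table from CSV
#'
#' Expects UTF-8 CSV with a header: a `run` column, proportion columns
#' `x1, x2, x3`, and one or more response columns whose cells are either
#' plain numbers or `"mean ± sd"` strings. Each response column `foo`
#' becomes numeric columns `foo` (mean) and `foo_sd`. Validation errors
#' cite the offending row.
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, reject rows whose proportions stray from
#'   sum-to-one by more than `tol`; if `FALSE`, renormalize them.
#' @param tol Sum-to-one tolerance in strict mode. The default 0.005
#'   accommodates printed 3-decimal proportions (0.333 + 0.333 + 0.333).
#' @return A tibble, one row per run.
#' @export
read_blend_responses <- function(path, strict = TRUE, tol = 5e-3) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  if (!"run" %in% names(raw)) abort("Missing required column `run`.")
  if (anyDuplicated(raw$run)) {
    abort(sprintf("Duplicated run id(s): %s.",
                  paste(unique(raw$run[duplicated(raw$run)]), collapse = ", ")))
  }
  props <- proportion_matrix(raw)
  sums <- rowSums(props)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf(
        "Row(s) %s: proportions sum to %s, not 1.",
        paste(bad, collapse = ", "),
        paste(sprintf("%.4f", sums[bad]), collapse = ", ")
      ))
    }
    props[bad, ] <- props[bad, ] / sums[bad]
    raw[, colnames(props)] <- as_tibble(props)
  }

  prop_cols <- colnames(props)
  resp_cols <- setdiff(names(raw), c("run", "point_type", prop_cols))
  for (col in resp_cols) {
    if (is.character(raw[[col]])) {
      parsed <- parse_mean_sd(raw[[col]])
      raw[[col]] <- parsed$mean
      raw[[paste0(col, "_sd")]] <- parsed$sd
    }
  }
  raw
}

#' The measured blend IC50 dataset
#'
#' The 12-run augmented simplex-centroid experiment on the three-oil blend
#' (x1 = *Pelargonium graveolens*, x2 = *Inula viscosa*, x3 = *Cymbopogon
#' citratus*), with mean and replicate-SD IC50 responses (mg/mL) for
#' intestinal alpha-glucosidase and pancreatic alpha-amylase inhibition.
#' Proportions are restored to the exact design fractions (1/3, 2/3, 1/6)
#' rather than their printed 3-decimal renderings, so replicate detection
#' and model fitting are exact.
#'
#' @return A tibble of 12 runs: `run`, `point_type`, `replicate_group`,
#'   `x1, x2, x3`, `ic50_glucosidase`, `ic50_glucosidase_sd`,
#'   `ic50_amylase`, `ic50_amylase_sd`.
#' @examples
#' blend_ic50_data()
#' @export
blend_ic50_data <- function() {
  path <- system.file("extdata", "blend_ic50_responses.csv",
                      package = "eoblend", mustWork = TRUE)
  raw <- read_blend_responses(path)
  design <- simplex_centroid_design(
    component_names = c("P. graveolens", "I. viscosa", "C. citratus")
  )
  # sanity: printed proportions are 3-decimal renderings of the design's
  stopifnot(max(abs(proportion_matrix(raw) - proportion_matrix(design))) < 5e-4)
  out <- dplyr::bind_cols(
    as_tibble(design)[c("run", "point_type", "replicate_group")],
    as_tibble(proportion_matrix(design)),
    raw[setdiff(names(raw), c("run", "x1", "x2", "x3"))]
  )
  out
}

#' Published special-cubic model coefficients for the blend study
#'
#' The 7-term coefficient vectors of the fitted IC50 models as reported for
#' the three-oil blend (3-decimal precision), usable directly with
#' [predict_scheffe()], [optimize_blend()] and [response_surface()], and as
#' ground truth for [simulate_mixture_responses()].
#'
#' @param response `"glucosidase"` or `"amylase"`.
#' @return Named numeric vector of 7 coefficients (mg/mL).
#' @examples
#' published_scheffe_coefficients("amylase")
#' @export
published_scheffe_coefficients <- function(response = c("glucosidase", "amylase")) {
  response <- match.arg(response)
  path <- system.file("extdata", "published_model_coefficients.json",
                      package = "eoblend", mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(all[[response]])[scheffe_term_names()]
}

#' Frontier-orbital energies of the main blend metabolites
#'
#' HOMO/LUMO energies (eV, GGA-PBE level) of the five most abundant
#' volatile metabolites across the three oils, together with the published
#' reactivity descriptors derived from them (used as golden values by the
#' test suite). Note the compound label "b-mercene" is preserved as
#' published (likely beta-myrcene).
#'
#' @return A tibble: `compound`, `e_homo`, `e_lumo`, plus published `ip`,
#'   `ea`, `gap`, `electronegativity`, `hardness`, `delta_n_max`.
#' @examples
#' reactivity_descriptors(frontier_orbitals()[1:3])
#' @export
frontier_orbitals <- function() {
  path <- system.file("extdata", "frontier_orbitals.csv",
                      package = "eoblend", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

# Published reference summary values used by reproduce_study() comparisons.
published_reference_values <- function() {
  path <- system.file("extdata", "published_reference_values.json",
                      package = "eoblend", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
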