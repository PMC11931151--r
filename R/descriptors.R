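#' Conceptual-DFT global reactivity descriptors from frontier orbitals
#'
#' Derives the standard global reactivity descriptors from HOMO/LUMO
#' energies under Koopmans-type approximations:
#' ionization potential `IP = -E_HOMO`, electron affinity `EA = -E_LUMO`,
#' gap `= E_LUMO - E_HOMO = IP - EA`, electronegativity `chi = (IP + EA)/2`,
#' chemical hardness `eta = gap/2`, chemical potential `mu =
#' (E_LUMO + E_HOMO)/2 = -chi`, and the maximal electron transfer
#' `delta_n_max = -mu/eta = chi/eta`. A positive `delta_n_max` marks an
#' electrophile (electron acceptor). All energies in eV; `delta_n_max` is
#' dimensionless.
#'
#' @param data A data frame with numeric columns `e_homo` and `e_lumo`
#'   (eV), e.g. from [frontier_orbitals()].
#' @return The input tibble with columns `ip`, `ea`, `gap`,
#'   `electronegativity`, `hardness`, `chemical_potential`, `delta_n_max`
#'   appended.
#' @examples
#' reactivity_descriptors(tibble::tibble(e_homo = -6.046, e_lumo = -0.653))
#' @export
reactivity_descriptors <- function(data) {
  data <- as_tibble(data)
  if (!all(c("e_homo", "e_lumo") %in% names(data))) {
    abort("`data` must contain columns `e_homo` and `e_lumo` (eV).")
  }
  eh <- data$e_homo
  el <- data$e_lumo
  if (any(!is.finite(eh)) || any(!is.finite(el))) {
    abort("Orbital energies must be finite.")
  }
  if (any(el < eh)) {
    abort("E_LUMO must not lie below E_HOMO (negative gap).")
  }
  gap <- el - eh
  if (any(gap == 0)) {
    abort("Zero HOMO-LUMO gap: hardness is 0 and delta_n_max is undefined.")
  }
  dplyr::mutate(data,
    ip = -eh,
    ea = -el,
    gap = gap,
    electronegativity = (.data$ip + .data$ea) / 2,
    hardness = gap / 2,
    chemical_potential = (el + eh) / 2,
    delta_n_max = -.data$chemical_potential / .data$hardness
  )
}

#' Kovats retention index from an n-alkane ladder
#'
#' Places a peak's retention time on the Kovats scale (100 x carbon number
#' of the bracketing n-alkanes). The default `"linear"` form interpolates
#' retention times directly, appropriate for temperature-programmed GC runs
#' with a linear ramp; `"isothermal"` interpolates log retention times (the
#' classical isothermal definition).
#'
#' @param rt Retention time(s) of the peak(s), same units as the ladder.
#' @param ladder A data frame with ascending columns `carbon` (integer
#'   alkane carbon numbers, consecutive or sparse) and `rt` (retention
#'   times).
#' @param method `"linear"` (default) or `"isothermal"`.
#' @return Numeric retention index (indices) on the Kovats scale.
#' @examples
#' ladder <- tibble::tibble(carbon = c(10, 11, 12), rt = c(5.0, 6.2, 7.5))
#' kovats_ri(5.6, ladder)  # 1050
#' @export
kovats_ri <- function(rt, ladder, method = c("linear", "isothermal")) {
  method <- match.arg(method)
  ladder <- as_tibble(ladder)
  if (!all(c("carbon", "rt") %in% names(ladder))) {
    abort("`ladder` must contain columns `carbon` and `rt`.")
  }
  cn <- ladder$carbon
  tn <- ladder$rt
  if (is.unsorted(cn, strictly = TRUE) || is.unsorted(tn, strictly = TRUE)) {
    abort("The alkane ladder must be strictly increasing in carbon number and time.")
  }
  purrr::map_dbl(rt, function(t_x) {
    if (t_x < tn[1] || t_x > tn[length(tn)]) {
      abort(sprintf(
        "Retention time %.4g lies outside the ladder range [%.4g, %.4g]; refusing to extrapolate.",
        t_x, tn[1], tn[length(tn)]
      ))
    }
    i <- findInterval(t_x, tn, rightmost.closed = TRUE)
    if (method == "linear") {
      frac <- (t_x - tn[i]) / (tn[i + 1] - tn[i])
    } else {
      frac <- (log(t_x) - log(tn[i])) / (log(tn[i + 1]) - log(tn[i]))
    }
    100 * (cn[i] + (cn[i + 1] - cn[i]) * frac)
  })
}
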