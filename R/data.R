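#' Published MsbA-KDL reference tables
#'
#' Reference tables for the ABC transporter MsbA binding the LPS-precursor
#' lipid KDL, as determined by variable-temperature native MS titrations and
#' shipped with the package as plain-text CSV:
#'
#' * `"kd_inward"`, `"kd_trapped"` — replicate-mean stepwise equilibrium
#'   dissociation constants (uM, mean +/- SD, n = 3) per variant and
#'   temperature for the inward-facing transporter and for the
#'   vanadate-trapped outward-facing state, with the poorest-replicate
#'   goodness of fit.
#' * `"thermo_inward"`, `"thermo_trapped"` — thermodynamic signatures
#'   (dG, dH, -TdS in kJ/mol and dCp in kJ/mol/K, mean +/- SD) per variant,
#'   binding event and temperature.
#' * `"ddx_inward"`, `"ddx_trapped"` — mutant-minus-background differences
#'   (ddG, ddH, d(-TdS), kJ/mol) per pair table; `background` identifies the
#'   parent variant of each block.
#'
#' @param which One of the table names above.
#' @return A tibble.
#' @examples
#' msba_kdl_table("kd_inward")
#' @export
msba_kdl_table <- function(which = c("kd_inward", "kd_trapped",
                                     "thermo_inward", "thermo_trapped",
                                     "ddx_inward", "ddx_trapped")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("msba_kdl_", which, ".csv"),
                      package = "lipidcycles", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Cycle couplings from a published difference table
#'
#' Computes the interaction terms of a double mutant cycle directly from a
#' table of mutant-minus-background differences (the `"ddx_*"` reference
#' tables or any table with the same columns), applying
#' \eqn{\Delta\Delta X_{int} = \Delta\Delta X_{PX} + \Delta\Delta X_{PY} -
#' \Delta\Delta X_{PXY}} per quantity with quadrature SDs.
#'
#' @param ddx Difference table with columns `background`, `variant`,
#'   `temperature_K`, `event`, and `ddG`/`ddH`/`ddmTdS` value and `_sd`
#'   columns.
#' @param px,py Single-mutation labels.
#' @param pxy Label of the double mutant row (defaults to `"px py"`).
#' @param background Parent background of the cycle block (default `"WT"`).
#' @param event Binding event (default 1).
#' @param temperature Temperature(s) in kelvin; default all shared.
#' @return A tibble with one row per temperature and quantity (`G`, `H`,
#'   `mTdS`): `dd_px`, `dd_py`, `dd_pxy`, `dd_int` and their SDs.
#' @examples
#' ddx <- msba_kdl_table("ddx_inward")
#' coupling_from_ddx(ddx, "R78A", "K299A", temperature = 298)
#' @export
coupling_from_ddx <- function(ddx, px, py, pxy = paste(px, py),
                              background = "WT", event = 1L,
                              temperature = NULL) {
  ddx <- dplyr::filter(tibble::as_tibble(ddx),
                       .data$background == !!background,
                       .data$event == !!event)
  pick <- function(v, tk) {
    row <- dplyr::filter(ddx, .data$variant == v, .data$temperature_K == tk)
    if (nrow(row) != 1L) {
      stop(sprintf("expected one row for variant '%s' at %g K in background '%s', found %d",
                   v, tk, background, nrow(row)), call. = FALSE)
    }
    row
  }
  if (is.null(temperature)) {
    temperature <- Reduce(intersect, lapply(c(px, py, pxy), function(v) {
      ddx$temperature_K[ddx$variant == v]
    }))
  }
  grid <- tidyr::expand_grid(temperature_K = sort(temperature),
                             quantity = c("G", "H", "mTdS"))
  res <- purrr::pmap(grid, function(temperature_K, quantity) {
    col <- switch(quantity, G = "ddG", H = "ddH", mTdS = "ddmTdS")
    sdc <- paste0(col, "_sd")
    rx <- pick(px, temperature_K)
    ry <- pick(py, temperature_K)
    rxy <- pick(pxy, temperature_K)
    int <- double_cycle_coupling(rx[[col]], ry[[col]], rxy[[col]],
                                 rx[[sdc]], ry[[sdc]], rxy[[sdc]])
    tibble::tibble(dd_px = rx[[col]], dd_px_sd = rx[[sdc]],
                   dd_py = ry[[col]], dd_py_sd = ry[[sdc]],
                   dd_pxy = rxy[[col]], dd_pxy_sd = rxy[[sdc]],
                   dd_int = int$value, dd_int_sd = int$sd)
  })
  dplyr::bind_cols(
    tibble::tibble(pair = paste(px, py, sep = "/"), background = background,
                   event = event),
    grid, purrr::list_rbind(res)
  )
}
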