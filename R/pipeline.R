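#' Run the full titration-to-couplings pipeline
#'
#' Chains the analysis stages: per-replicate sequential-binding fits of a
#' titration table (skipped when a K_D table is supplied directly), van't
#' Hoff extraction of thermodynamic signatures, and mutant-cycle coupling
#' analysis for the requested cycles.
#'
#' @param titrations Long-format titration table ([read_titration_csv()]
#'   schema), or `NULL` when `kd` is given.
#' @param kd Long K_D table (`variant`, `temperature_K`, optional
#'   `replicate`, `event`, `kd_uM`) to bypass the fitting stage.
#' @param n_events,auto_events Passed to [fit_binding()].
#' @param model,t0,exclude Passed to [thermo_signature()].
#' @param cycles Optional list of cycle definitions; each element a list
#'   with `px`, `py`, `pxy` and optionally `wild_type`, `event`,
#'   `temperature` — passed to [mutant_cycle()].
#' @param out_dir Optional directory; when given, the result tables are
#'   written there as `fits.csv`, `kd_summary.csv`, `thermo.csv`,
#'   `cycles.csv`.
#' @return A list with elements `fits` (per-replicate constants, `NULL` when
#'   `kd` was supplied), `kd` (long K_D table), `kd_summary` (wide mean +/-
#'   SD table), `thermo` (signature table) and `cycles` (coupling table or
#'   `NULL`).
#' @export
run_binding_pipeline <- function(titrations = NULL, kd = NULL,
                                 n_events = NULL, auto_events = FALSE,
                                 model = "auto", t0 = 298, exclude = NULL,
                                 cycles = NULL, out_dir = NULL) {
  if (is.null(titrations) && is.null(kd)) {
    stop("supply `titrations` or `kd`", call. = FALSE)
  }
  fits <- NULL
  if (is.null(kd)) {
    fits <- fit_binding(titrations, n_events = n_events,
                        auto_events = auto_events)
    kd <- fits[, c("variant", "temperature_K", "replicate", "event", "kd_uM")]
    kd_summary <- summarize_kd(fits)
  } else {
    kd <- tibble::as_tibble(kd)
    kd_summary <- NULL
  }
  thermo <- thermo_signature(kd, model = model, t0 = t0, exclude = exclude)
  cycle_tbl <- NULL
  if (!is.null(cycles)) {
    cycle_tbl <- purrr::list_rbind(purrr::map(cycles, function(cy) {
      mutant_cycle(thermo, px = cy$px, py = cy$py, pxy = cy$pxy,
                   wild_type = cy$wild_type %||% "WT",
                   event = cy$event %||% 1L,
                   temperature = cy$temperature)
    }))
  }
  res <- list(fits = fits, kd = kd, kd_summary = kd_summary,
              thermo = thermo, cycles = cycle_tbl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fits)) {
      readr::write_csv(fits, file.path(out_dir, "fits.csv"))
      readr::write_csv(kd_summary, file.path(out_dir, "kd_summary.csv"))
    }
    readr::write_csv(thermo, file.path(out_dir, "thermo.csv"))
    if (!is.null(cycle_tbl)) {
      readr::write_csv(cycle_tbl, file.path(out_dir, "cycles.csv"))
    }
  }
  res
}

#' Summarise a thermodynamic signature for plotting
#'
#' Returns the stacked-bar view of a signature table: one record per
#' variant, event and temperature with the three additive terms
#' (\eqn{\Delta G = \Delta H + (-T\Delta S)}) in long form.
#'
#' @param thermo Signature table from [thermo_signature()] (or the
#'   same-shaped reference tables).
#' @return A tibble with columns `variant`, `event`, `temperature_K`,
#'   `term` (one of `dG`, `dH`, `mTdS`), `value`, `sd`.
#' @export
summarize_signature <- function(thermo) {
  long <- tidyr::pivot_longer(
    thermo[, c("variant", "event", "temperature_K",
               "dG_kJmol", "dG_sd", "dH_kJmol", "dH_sd",
               "mTdS_kJmol", "mTdS_sd")],
    cols = -c("variant", "event", "temperature_K"),
    names_pattern = "(dG|dH|mTdS)_(kJmol|sd)",
    names_to = c("term", ".value")
  )
  dplyr::rename(long, value = "kJmol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
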