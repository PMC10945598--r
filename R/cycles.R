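#' Quadrature propagation of standard deviations
#'
#' Combines independent standard deviations as the square root of the sum of
#' squares, the convention used throughout for replicate mean +/- SD
#' arithmetic on thermodynamic quantities.
#'
#' @param sds Numeric vector of non-negative standard deviations.
#' @return Combined standard deviation.
#' @examples
#' propagate_sd(c(11.3, 6.1, 6.9))  # 14.6
#' @export
propagate_sd <- function(sds) {
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  }
  sqrt(sum(sds^2))
}

#' Mutant-minus-wild-type difference
#'
#' \eqn{\Delta\Delta X = X_{mutant} - X_{wild type}} for any thermodynamic
#' quantity X (free energy, enthalpy or entropic term), with the SD
#' propagated in quadrature. Positive \eqn{\Delta\Delta G} means the
#' mutation weakens binding.
#'
#' @param x_mutant,x_wild_type Values in kJ/mol.
#' @param sd_mutant,sd_wild_type Their standard deviations (default 0).
#' @return A one-row tibble with `value` and `sd`.
#' @export
delta_delta <- function(x_mutant, x_wild_type, sd_mutant = 0, sd_wild_type = 0) {
  tibble::tibble(value = x_mutant - x_wild_type,
                 sd = propagate_sd(c(sd_mutant, sd_wild_type)))
}

#' Double mutant-cycle coupling
#'
#' The interaction (coupling) term of a double mutant cycle,
#' \deqn{\Delta\Delta X_{int} = \Delta\Delta X_{PX} + \Delta\Delta X_{PY}
#'       - \Delta\Delta X_{PXY},}
#' i.e. the deviation of the double mutant from additivity of the two single
#' mutants. A positive coupling free energy means the two residues cooperate
#' to stabilise binding. SDs combine in quadrature.
#'
#' @param ddx_px,ddx_py,ddx_pxy Mutant-minus-parent differences (kJ/mol) for
#'   the two single mutants and the double mutant, all relative to the same
#'   parent background and for the same quantity, binding event and
#'   temperature.
#' @param sd_px,sd_py,sd_pxy Their standard deviations (default 0).
#' @return A one-row tibble with `value` and `sd`.
#' @examples
#' double_cycle_coupling(2.7, 2.8, 3.8)  # 1.7 kJ/mol
#' @export
double_cycle_coupling <- function(ddx_px, ddx_py, ddx_pxy,
                                  sd_px = 0, sd_py = 0, sd_pxy = 0) {
  tibble::tibble(value = ddx_px + ddx_py - ddx_pxy,
                 sd = propagate_sd(c(sd_px, sd_py, sd_pxy)))
}

#' Triple mutant-cycle (third-order) coupling
#'
#' The third-order coupling is the change of a pairwise coupling upon
#' mutating a third residue: the pairwise interaction term computed in the
#' wild-type background minus the same pairwise term computed in the
#' third-mutant background. SDs combine in quadrature.
#'
#' @param pair_int_wt Pairwise coupling (kJ/mol) in the wild-type background.
#' @param pair_int_bg The same pairwise coupling in the background carrying
#'   the third mutation.
#' @param sd_wt,sd_bg Their standard deviations (default 0).
#' @return A one-row tibble with `value` and `sd`.
#' @examples
#' triple_cycle_coupling(0.8, -2.6)  # 3.4 kJ/mol
#' @export
triple_cycle_coupling <- function(pair_int_wt, pair_int_bg,
                                  sd_wt = 0, sd_bg = 0) {
  tibble::tibble(value = pair_int_wt - pair_int_bg,
                 sd = propagate_sd(c(sd_wt, sd_bg)))
}

# pull (value, sd) for one corner of a cycle from a thermo signature table
corner_value <- function(data, variant, event, temperature, quantity) {
  col <- switch(quantity, G = "dG", H = "dH", mTdS = "mTdS")
  row <- dplyr::filter(data, .data$variant == !!variant,
                       .data$event == !!event,
                       .data$temperature_K == !!temperature)
  if (nrow(row) == 0L) {
    stop(sprintf("no thermodynamic signature for variant '%s', event %d, %g K",
                 variant, event, temperature), call. = FALSE)
  }
  if (nrow(row) > 1L) {
    stop(sprintf("multiple signature rows for variant '%s', event %d, %g K",
                 variant, event, temperature), call. = FALSE)
  }
  list(value = row[[paste0(col, "_kJmol")]], sd = row[[paste0(col, "_sd")]])
}

#' Double mutant-cycle analysis of a thermodynamic signature table
#'
#' Computes, for each requested quantity (free energy, enthalpy, entropic
#' term), the mutant-minus-wild-type differences for the two single mutants
#' and the double mutant, and the interaction term
#' \eqn{\Delta\Delta X_{int}}, with quadrature SDs.
#'
#' @param data Thermodynamic signature table from [thermo_signature()] (or a
#'   table with the same columns typed in from published values).
#' @param px,py,pxy Variant labels of the two single mutants and the double
#'   mutant.
#' @param wild_type Label of the parent background (default `"WT"`).
#' @param event Binding event index (default 1).
#' @param temperature Temperature(s) in kelvin; defaults to all temperatures
#'   shared by the four corners.
#' @param quantities Character subset of `c("G", "H", "mTdS")`.
#' @return A tibble with one row per temperature and quantity: `pair`,
#'   `background`, `temperature_K`, `event`, `quantity`, `dd_px`, `dd_px_sd`,
#'   `dd_py`, `dd_py_sd`, `dd_pxy`, `dd_pxy_sd`, `dd_int`, `dd_int_sd`.
#' @export
mutant_cycle <- function(data, px, py, pxy, wild_type = "WT", event = 1L,
                         temperature = NULL, quantities = c("G", "H", "mTdS")) {
  quantities <- match.arg(quantities, several.ok = TRUE)
  corners <- c(wild_type, px, py, pxy)
  missing_v <- setdiff(corners, unique(data$variant))
  if (length(missing_v)) {
    stop("cycle corner(s) absent from the signature table: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  if (is.null(temperature)) {
    temperature <- Reduce(intersect, lapply(corners, function(v) {
      data$temperature_K[data$variant == v & data$event == event]
    }))
    if (!length(temperature)) {
      stop("no temperature shared by all four cycle corners", call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(temperature_K = sort(temperature),
                             quantity = quantities)
  res <- purrr::pmap(grid, function(temperature_K, quantity) {
    p <- corner_value(data, wild_type, event, temperature_K, quantity)
    x <- corner_value(data, px, event, temperature_K, quantity)
    y <- corner_value(data, py, event, temperature_K, quantity)
    xy <- corner_value(data, pxy, event, temperature_K, quantity)
    dx <- delta_delta(x$value, p$value, x$sd, p$sd)
    dy <- delta_delta(y$value, p$value, y$sd, p$sd)
    dxy <- delta_delta(xy$value, p$value, xy$sd, p$sd)
    int <- double_cycle_coupling(dx$value, dy$value, dxy$value,
                                 dx$sd, dy$sd, dxy$sd)
    tibble::tibble(
      dd_px = dx$value, dd_px_sd = dx$sd,
      dd_py = dy$value, dd_py_sd = dy$sd,
      dd_pxy = dxy$value, dd_pxy_sd = dxy$sd,
      dd_int = int$value, dd_int_sd = int$sd
    )
  })
  out <- dplyr::bind_cols(
    tibble::tibble(pair = paste(px, py, sep = "/"), background = wild_type,
                   event = event),
    grid, purrr::list_rbind(res)
  )
  structure(out, class = c("mutant_cycle_tbl", class(out)))
}

#' Triple mutant-cycle analysis of a thermodynamic signature table
#'
#' Computes the third-order coupling among three mutated positions from the
#' full eight-variant panel (wild type, three singles, three doubles, one
#' triple), along all three routes: for each choice of "third" mutation Z,
#' the pairwise X/Y coupling is evaluated in the wild-type background and in
#' the Z background and differenced. On one consistent signature table the
#' three routes agree exactly; on independently rounded published tables
#' small route disagreements are reported, not failed.
#'
#' @inheritParams mutant_cycle
#' @param x,y,z Single-mutant variant labels.
#' @param xy,xz,yz,xyz Labels of the double and triple mutants.
#' @param tol Route-agreement tolerance (kJ/mol) above which a warning is
#'   issued (default 1e-6).
#' @return A tibble with one row per temperature, quantity and route:
#'   columns `route` (the background single mutant), `pair_int_wt`,
#'   `pair_int_bg`, `dd_int3`, `dd_int3_sd`.
#' @export
triple_mutant_cycle <- function(data, x, y, z, xy, xz, yz, xyz,
                                wild_type = "WT", event = 1L,
                                temperature = NULL,
                                quantities = c("G", "H", "mTdS"),
                                tol = 1e-6) {
  quantities <- match.arg(quantities, several.ok = TRUE)
  routes <- list(
    list(bg = z, pair = c(x, y), pair_wt = xy, bg_singles = c(xz, yz), bg_pair = xyz),
    list(bg = y, pair = c(x, z), pair_wt = xz, bg_singles = c(xy, yz), bg_pair = xyz),
    list(bg = x, pair = c(y, z), pair_wt = yz, bg_singles = c(xy, xz), bg_pair = xyz)
  )
  res <- purrr::list_rbind(purrr::map(routes, function(r) {
    wt_cycle <- mutant_cycle(data, r$pair[1], r$pair[2], r$pair_wt,
                             wild_type = wild_type, event = event,
                             temperature = temperature, quantities = quantities)
    bg_cycle <- mutant_cycle(data, r$bg_singles[1], r$bg_singles[2], r$bg_pair,
                             wild_type = r$bg, event = event,
                             temperature = unique(wt_cycle$temperature_K),
                             quantities = quantities)
    joined <- dplyr::left_join(
      wt_cycle[, c("temperature_K", "quantity", "dd_int", "dd_int_sd")],
      bg_cycle[, c("temperature_K", "quantity", "dd_int", "dd_int_sd")],
      by = c("temperature_K", "quantity"), suffix = c("_wt", "_bg")
    )
    dplyr::mutate(
      joined,
      route = paste0(r$pair[1], "/", r$pair[2], " | ", r$bg),
      dd_int3 = .data$dd_int_wt - .data$dd_int_bg,
      dd_int3_sd = sqrt(.data$dd_int_sd_wt^2 + .data$dd_int_sd_bg^2),
      .before = 1
    )
  }))
  spread <- dplyr::summarise(
    dplyr::group_by(res, .data$temperature_K, .data$quantity),
    spread = max(.data$dd_int3) - min(.data$dd_int3), .groups = "drop"
  )
  if (any(spread$spread > tol)) {
    warning(sprintf(paste0("triple-cycle routes disagree by up to %.3g kJ/mol ",
                           "(expected for independently rounded inputs)"),
                    max(spread$spread)), call. = FALSE)
  }
  dplyr::rename(res, pair_int_wt = "dd_int_wt", pair_int_wt_sd = "dd_int_sd_wt",
                pair_int_bg = "dd_int_bg", pair_int_bg_sd = "dd_int_sd_bg")
}

#' Thermodynamic consistency of a set of couplings
#'
#' For couplings of G, H and the entropic term computed on the same cycle,
#' the identity \eqn{\Delta\Delta G_{int} = \Delta\Delta H_{int} +
#' \Delta(-T\Delta S)_{int}} must hold (exactly on unrounded inputs; on
#' published rounded tables the residual reflects rounding only).
#'
#' @param cycle_tbl Output of [mutant_cycle()] containing all three
#'   quantities.
#' @return A tibble per temperature with `residual` = ddG_int - (ddH_int +
#'   ddmTdS_int) and `consistent` at tolerance 1e-9.
#' @export
cycle_consistency <- function(cycle_tbl) {
  wide <- tidyr::pivot_wider(
    cycle_tbl[, c("pair", "background", "event", "temperature_K", "quantity",
                  "dd_int")],
    names_from = "quantity", values_from = "dd_int"
  )
  need <- c("G", "H", "mTdS")
  if (!all(need %in% names(wide))) {
    stop("consistency check needs couplings for G, H and mTdS", call. = FALSE)
  }
  dplyr::mutate(wide,
                residual = .data$G - (.data$H + .data$mTdS),
                consistent = abs(.data$residual) <= 1e-9)
}
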