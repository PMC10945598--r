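# Gas constant, kJ/mol/K
R_GAS <- 8.314462618e-3

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln K_D} with \eqn{K_D} expressed in molar (1 M
#' standard state), so sub-molar dissociation constants give negative free
#' energies. R = 8.314462618e-3 kJ/mol/K.
#'
#' @param kd_uM Dissociation constant(s) in uM (> 0).
#' @param temperature Temperature(s) in kelvin (> 0).
#' @return Free energy in kJ/mol.
#' @examples
#' delta_g_from_kd(0.68, 298)  # -35.2 kJ/mol
#' @export
delta_g_from_kd <- function(kd_uM, temperature) {
  if (any(!is.finite(kd_uM)) || any(kd_uM <= 0)) {
    stop("`kd_uM` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be finite and > 0", call. = FALSE)
  }
  R_GAS * temperature * log(kd_uM * 1e-6)
}

#' Back-calculate the entropic term
#'
#' Given \eqn{\Delta G} and \eqn{\Delta H}, returns the entropic contribution
#' \eqn{-T\Delta S = \Delta G - \Delta H}.
#'
#' @param delta_g,delta_h Free energy and enthalpy in kJ/mol.
#' @return \eqn{-T\Delta S} in kJ/mol.
#' @examples
#' back_calc_entropy(-35.2, 45.0)  # -80.2
#' @export
back_calc_entropy <- function(delta_g, delta_h) {
  delta_g - delta_h
}

new_vanthoff_fit <- function(model, t0, dH_T0, dCp, lnK0, temperature, lnKA) {
  fitted <- vant_hoff_lnka(temperature, t0, dH_T0, dCp, lnK0)
  structure(list(
    model = model, t0 = t0, dH_T0 = dH_T0, dCp = dCp, lnK0 = lnK0,
    dG_T0 = -R_GAS * t0 * lnK0,
    temperature = temperature, lnKA = lnKA, fitted = fitted,
    ssr = sum((lnKA - fitted)^2)
  ), class = "vanthoff_fit")
}

# ln K_A(T) under the constant-dCp integrated van't Hoff model
vant_hoff_lnka <- function(temperature, t0, dH_T0, dCp, lnK0) {
  (dH_T0 - t0 * dCp) / R_GAS * (1 / t0 - 1 / temperature) +
    dCp / R_GAS * log(temperature / t0) + lnK0
}

#' Linear van't Hoff analysis
#'
#' Least-squares line of \eqn{\ln K_A} (1 M standard state) against
#' \eqn{1/T}: \eqn{\ln K_A = -\Delta H / R \cdot 1/T + \Delta S / R}. The
#' enthalpy is temperature independent under this model.
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct values).
#' @param ka_per_uM Association constants in 1/uM, same length.
#' @param t0 Reference temperature (kelvin) used only to report
#'   \eqn{\ln K_0} and \eqn{\Delta G(T_0)}; defaults to 298.
#' @return A `vanthoff_fit` object with elements `dH_T0` (kJ/mol), `dS`
#'   (kJ/mol/K), `dCp = 0`, `lnK0` and `dG_T0`.
#' @examples
#' kd <- c(0.51, 0.44, 0.38, 0.31)  # uM
#' vant_hoff_linear(c(293, 298, 303, 310), 1 / kd)
#' @export
vant_hoff_linear <- function(temperature, ka_per_uM, t0 = 298) {
  check_vant_hoff_input(temperature, ka_per_uM, min_n = 2L)
  lnKA <- log(ka_per_uM * 1e6)
  fit <- stats::lm(lnKA ~ I(1 / temperature))
  dH <- -R_GAS * stats::coef(fit)[[2]]
  dS <- R_GAS * stats::coef(fit)[[1]]
  lnK0 <- (-dH / t0 + dS) * t0 / (R_GAS * t0) # = (-dH/R)/t0 + dS/R
  out <- new_vanthoff_fit("linear", t0, dH, 0, lnK0, temperature, lnKA)
  out$dS <- dS
  out
}

#' Nonlinear van't Hoff analysis with heat capacity
#'
#' Fits the integrated van't Hoff model with a constant heat-capacity change,
#' \deqn{\ln K_A = \frac{\Delta H_{T_0} - T_0 \Delta C_p}{R}
#'   \left(\frac{1}{T_0} - \frac{1}{T}\right) +
#'   \frac{\Delta C_p}{R} \ln\frac{T}{T_0} + \ln K_0,}
#' by least squares. The model is linear in the three parameters
#' \eqn{(\Delta H_{T_0} - T_0\Delta C_p)/R}, \eqn{\Delta C_p / R} and
#' \eqn{\ln K_0}, so the least-squares solution is exact (no iterative
#' optimiser). With `fix_dcp_zero = TRUE` the fit reduces to the linear model
#' reparameterised about `t0`.
#'
#' @inheritParams vant_hoff_linear
#' @param t0 Reference temperature in kelvin; should lie within the fitted
#'   temperature range.
#' @param fix_dcp_zero Constrain \eqn{\Delta C_p = 0}.
#' @return A `vanthoff_fit` object with `dH_T0` (kJ/mol at `t0`), `dCp`
#'   (kJ/mol/K), `lnK0` and `dG_T0` (kJ/mol).
#' @examples
#' kd <- c(0.69, 0.75, 0.68, 0.43)  # uM
#' vant_hoff_nonlinear(c(288, 293, 298, 303), 1 / kd, t0 = 298)
#' @export
vant_hoff_nonlinear <- function(temperature, ka_per_uM, t0 = 298,
                                fix_dcp_zero = FALSE) {
  check_vant_hoff_input(temperature, ka_per_uM,
                        min_n = if (fix_dcp_zero) 2L else 3L)
  lnKA <- log(ka_per_uM * 1e6)
  x1 <- 1 / t0 - 1 / temperature
  x2 <- log(temperature / t0)
  if (fix_dcp_zero) {
    fit <- stats::lm(lnKA ~ x1)
    a <- stats::coef(fit)[[2]]
    b <- 0
    lnK0 <- stats::coef(fit)[[1]]
  } else {
    fit <- stats::lm(lnKA ~ x1 + x2)
    a <- stats::coef(fit)[[2]]
    b <- stats::coef(fit)[[3]]
    lnK0 <- stats::coef(fit)[[1]]
  }
  dCp <- R_GAS * b
  dH_T0 <- R_GAS * a + t0 * dCp
  new_vanthoff_fit(if (fix_dcp_zero) "linear" else "nonlinear",
                   t0, dH_T0, dCp, lnK0, temperature, lnKA)
}

check_vant_hoff_input <- function(temperature, ka_per_uM, min_n) {
  if (length(temperature) != length(ka_per_uM)) {
    stop("`temperature` and `ka_per_uM` must have equal length", call. = FALSE)
  }
  keep <- is.finite(temperature) & is.finite(ka_per_uM)
  if (length(unique(temperature[keep])) < min_n) {
    stop("van't Hoff fit needs at least ", min_n, " distinct temperatures",
         call. = FALSE)
  }
  if (any(ka_per_uM[keep] <= 0)) {
    stop("association constants must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Enthalpy at an arbitrary temperature
#'
#' Under the constant-\eqn{\Delta C_p} model,
#' \eqn{\Delta H(T) = \Delta H_{T_0} + \Delta C_p (T - T_0)}; a linear fit
#' returns its constant enthalpy for every temperature.
#'
#' @param fit A `vanthoff_fit`.
#' @param temperature Temperature(s) in kelvin.
#' @return Enthalpy in kJ/mol.
#' @export
enthalpy_at_temperature <- function(fit, temperature) {
  stopifnot(inherits(fit, "vanthoff_fit"))
  fit$dH_T0 + fit$dCp * (temperature - fit$t0)
}

#' Predicted ln K_A from a van't Hoff fit
#'
#' @inheritParams enthalpy_at_temperature
#' @return \eqn{\ln K_A} (1 M standard state) at the requested temperatures.
#' @export
predict_lnka <- function(fit, temperature) {
  stopifnot(inherits(fit, "vanthoff_fit"))
  vant_hoff_lnka(temperature, fit$t0, fit$dH_T0, fit$dCp, fit$lnK0)
}

#' @export
print.vanthoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (%s), T0 = %g K\n", x$model, x$t0))
  cat(sprintf("  dH(T0) = %.2f kJ/mol, dCp = %.3f kJ/mol/K, dG(T0) = %.2f kJ/mol\n",
              x$dH_T0, x$dCp, x$dG_T0))
  invisible(x)
}

#' Tidy a van't Hoff fit
#'
#' @param x A `vanthoff_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @export
tidy.vanthoff_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH_T0", "dCp", "lnK0", "dG_T0"),
    estimate = c(x$dH_T0, x$dCp, x$lnK0, x$dG_T0)
  )
}

#' @rdname tidy.vanthoff_fit
#' @export
glance.vanthoff_fit <- function(x, ...) {
  tibble::tibble(model = x$model, t0 = x$t0, n_temperatures = length(x$temperature),
                 ssr = x$ssr)
}

#' van't Hoff analysis across a K_D table
#'
#' Runs a van't Hoff fit per variant, binding event and (when present)
#' replicate across temperatures. With `model = "auto"`, both forms are fit
#' and the nonlinear one is kept only when it reduces the residual sum of
#' squares by more than 50% and at least four temperatures are available.
#'
#' @param data Long K_D table: `variant`, `temperature_K`, `event`, `kd_uM`,
#'   optional `replicate` (see [read_kd_csv()]).
#' @param model `"auto"`, `"linear"` or `"nonlinear"`; may also be a named
#'   character vector keyed by variant label.
#' @param t0 Reference temperature in kelvin.
#' @param exclude Optional data frame of (`variant`, `temperature_K`) pairs
#'   dropped before fitting (explicit outlier-temperature exclusions).
#' @return A tibble with one row per fit: grouping columns, `model`, `t0`,
#'   `dH_T0`, `dCp`, `lnK0`, `dG_T0`, `ssr` and a `fit` list-column holding
#'   the `vanthoff_fit` objects.
#' @export
vant_hoff <- function(data, model = c("auto", "linear", "nonlinear"),
                      t0 = 298, exclude = NULL) {
  if (!is.character(model)) stop("`model` must be character", call. = FALSE)
  if (length(model) > 1L && is.null(names(model))) model <- model[1]
  data <- tibble::as_tibble(data)
  if (!is.null(exclude)) {
    data <- dplyr::anti_join(data, tibble::as_tibble(exclude),
                             by = intersect(c("variant", "temperature_K"),
                                            names(exclude)))
  }
  keys <- intersect(c("variant", "event", "replicate"), names(data))
  groups <- dplyr::group_split(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  )
  purrr::list_rbind(purrr::map(groups, function(g) {
    m <- if (!is.null(names(model))) {
      mm <- model[[as.character(g$variant[1])]]
      if (is.null(mm) || is.na(mm)) "auto" else mm
    } else model
    m <- match.arg(m, c("auto", "linear", "nonlinear"))
    fit <- fit_vant_hoff_one(g$temperature_K, 1 / g$kd_uM, m, t0)
    dplyr::bind_cols(
      g[1, keys, drop = FALSE],
      tibble::tibble(model = fit$model, t0 = t0, dH_T0 = fit$dH_T0,
                     dCp = fit$dCp, lnK0 = fit$lnK0, dG_T0 = fit$dG_T0,
                     ssr = fit$ssr, fit = list(fit))
    )
  }))
}

fit_vant_hoff_one <- function(temperature, ka, model, t0) {
  n_temp <- length(unique(temperature))
  if (model == "linear") return(vant_hoff_linear(temperature, ka, t0))
  if (model == "nonlinear") return(vant_hoff_nonlinear(temperature, ka, t0))
  lin <- vant_hoff_linear(temperature, ka, t0)
  if (n_temp < 4L) return(lin)
  nl <- vant_hoff_nonlinear(temperature, ka, t0)
  if (nl$ssr < 0.5 * lin$ssr) nl else lin
}

#' Assemble thermodynamic signatures
#'
#' Builds the per-temperature thermodynamic signature for every variant and
#' binding event: \eqn{\Delta G} directly from the replicate K_D values,
#' \eqn{\Delta H(T)} from a per-replicate van't Hoff fit evaluated at each
#' temperature, \eqn{-T\Delta S} back-calculated as their difference, and
#' \eqn{\Delta C_p} from the fit. With replicated input, values are replicate
#' means with sample standard deviations; the identity
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds row-wise by construction.
#'
#' @inheritParams vant_hoff
#' @return A tibble with columns `variant`, `event`, `temperature_K`,
#'   `dG_kJmol`, `dG_sd`, `dH_kJmol`, `dH_sd`, `mTdS_kJmol`, `mTdS_sd`,
#'   `dCp_kJmolK`, `dCp_sd`, `model`, `n_replicates`.
#' @export
thermo_signature <- function(data, model = "auto", t0 = 298, exclude = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(exclude)) {
    data <- dplyr::anti_join(data, tibble::as_tibble(exclude),
                             by = intersect(c("variant", "temperature_K"),
                                            names(exclude)))
  }
  has_rep <- "replicate" %in% names(data)
  if (!has_rep) data$replicate <- 1L
  fits <- vant_hoff(data, model = model, t0 = t0)
  joined <- dplyr::left_join(
    data, fits,
    by = intersect(c("variant", "event", "replicate"), names(fits))
  )
  per_rep <- dplyr::mutate(
    joined,
    dG = delta_g_from_kd(.data$kd_uM, .data$temperature_K),
    dH = .data$dH_T0 + .data$dCp * (.data$temperature_K - .data$t0),
    mTdS = .data$dG - .data$dH
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$variant, .data$event, .data$temperature_K),
    dG_kJmol = mean(.data$dG),
    dG_sd = sd0(.data$dG),
    dH_kJmol = mean(.data$dH),
    dH_sd = sd0(.data$dH),
    mTdS_kJmol = mean(.data$mTdS),
    mTdS_sd = sd0(.data$mTdS),
    dCp_kJmolK = mean(.data$dCp),
    dCp_sd = sd0(.data$dCp),
    model = .data$model[1],
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$variant, .data$event, .data$temperature_K)
}

sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
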