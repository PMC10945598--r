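#' Fit stepwise association constants to one titration replicate
#'
#' Globally fits the sequential ligand-binding model to the mole fractions of
#' one titration (one variant, temperature and replicate) by minimising the
#' pseudo chi-square \eqn{\sum (F_{exp} - F_{calc})^2}, with the free-ligand
#' mass balance solved exactly at every objective evaluation. The fit is
#' performed in \eqn{\ln K_A} space so positivity holds by construction, with
#' a multistart over K_D guesses spanning 0.1, 1 and 10 uM per event; the
#' start reaching the lowest pseudo chi-square wins.
#'
#' @param data A data frame with columns `ligand_total_uM`, `n_bound`,
#'   `mole_fraction` and either a `protein_total_uM` column or the
#'   `protein_total` argument; one row per species per titration point.
#' @param n_events Number of sequential binding events to fit (1-3). Defaults
#'   to the largest `n_bound` present.
#' @param protein_total Total protein concentration in uM; overrides the
#'   column if given.
#' @param auto_events If `TRUE`, drop the highest binding event and refit
#'   whenever its predicted occupancy never exceeds 1% across the titration.
#' @return An object of class `binding_fit`: a list with elements `ka`
#'   (1/uM), `kd` (uM), `n_events`, `pseudo_chi2`, `r_squared`, `converged`,
#'   `n_data`, `protein_total`, `f_exp`, `f_calc` and `ligand_total`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
fit_titration <- function(data, n_events = NULL, protein_total = NULL,
                          auto_events = FALSE) {
  data <- validate_titration(data, require_meta = FALSE)
  if (is.null(protein_total)) {
    protein_total <- unique(data$protein_total_uM)
    if (length(protein_total) != 1L) {
      stop("`protein_total_uM` must be constant within one titration",
           call. = FALSE)
    }
  }
  wide <- tidyr::pivot_wider(
    data[, c("ligand_total_uM", "n_bound", "mole_fraction")],
    names_from = "n_bound", values_from = "mole_fraction",
    names_prefix = "PL", values_fill = 0
  )
  wide <- dplyr::arrange(wide, .data$ligand_total_uM)
  lig <- wide$ligand_total_uM
  f_exp <- as.matrix(wide[, -1, drop = FALSE])
  n_max <- max(data$n_bound)
  if (is.null(n_events)) n_events <- n_max
  if (!n_events %in% 1:3) stop("`n_events` must be 1, 2 or 3", call. = FALSE)
  if (length(lig) < n_events + 1L || all(lig == 0)) {
    stop("titration has too few informative points to fit ", n_events,
         " binding events", call. = FALSE)
  }
  if (ncol(f_exp) < n_events + 1L) {
    f_exp <- cbind(f_exp, matrix(0, nrow(f_exp), n_events + 1L - ncol(f_exp)))
  }
  f_exp <- f_exp[, seq_len(n_events + 1L), drop = FALSE]
  # renormalise after any species truncation
  f_exp <- f_exp / rowSums(f_exp)
  colnames(f_exp) <- paste0("PL", 0:n_events)

  objective <- function(log_ka) {
    pseudo_chi2(f_exp, predict_mole_fractions(exp(log_ka), protein_total, lig))
  }

  if (n_events == 1L) {
    # 1-D objective: a single bracketed Brent search is global here
    best <- stats::optim(log(1), objective, method = "Brent",
                         lower = log(1e-6), upper = log(1e6))
  } else {
    starts <- as.matrix(expand.grid(rep(list(log(1 / c(0.1, 1, 10))),
                                        n_events)))
    # rank the multistart grid by raw objective, run a coarse simplex from
    # the three most promising starts, then polish the winner
    ranked <- order(apply(starts, 1L, objective))
    coarse <- lapply(ranked[1:3], function(i) {
      stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-8))
    })
    best <- coarse[[which.min(vapply(coarse, `[[`, numeric(1), "value"))]]
    best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
  }
  ka <- exp(unname(best$par))
  f_calc <- predict_mole_fractions(ka, protein_total, lig)
  chi2 <- pseudo_chi2(f_exp, f_calc)
  r2 <- 1 - chi2 / sum((f_exp - mean(f_exp))^2)
  out <- structure(list(
    ka = ka, kd = 1 / ka, n_events = n_events,
    pseudo_chi2 = chi2, r_squared = r2,
    converged = best$convergence == 0L,
    n_data = length(f_exp), protein_total = protein_total,
    ligand_total = lig, f_exp = f_exp, f_calc = f_calc
  ), class = "binding_fit")
  if (auto_events && n_events > 1L &&
      max(f_calc[, n_events + 1L]) < 0.01) {
    return(fit_titration(data, n_events - 1L, protein_total, auto_events))
  }
  if (!out$converged) {
    warning("binding fit did not report convergence (pseudo-chi2 = ",
            signif(chi2, 3), ")", call. = FALSE)
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Sequential binding fit:", x$n_events, "event(s),",
      length(x$ligand_total), "titration points\n")
  cat("  K_D (uM):", paste(signif(x$kd, 3), collapse = ", "), "\n")
  cat(sprintf("  pseudo-chi2 = %.4g, R2 = %.4f\n", x$pseudo_chi2, x$r_squared))
  invisible(x)
}

#' Tidy a sequential binding fit
#'
#' @param x A `binding_fit` object.
#' @param ... Unused.
#' @return One row per binding event with `event`, `ka_per_uM`, `kd_uM`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(event = seq_len(x$n_events), ka_per_uM = x$ka, kd_uM = x$kd)
}

#' @rdname tidy.binding_fit
#' @return For `glance()`: a one-row tibble with fit diagnostics.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, pseudo_chi2 = x$pseudo_chi2,
                 r_squared = x$r_squared, converged = x$converged,
                 n_data = x$n_data)
}

#' Fit binding constants across a titration table
#'
#' Fits every (variant, temperature, replicate) titration in a long-format
#' table independently with [fit_titration()] and returns the stepwise
#' constants in long form. Replicates are fit independently and later
#' summarised as mean and sample standard deviation by [summarize_kd()].
#'
#' @param data Long-format titration table (see [read_titration_csv()] for
#'   the schema).
#' @param n_events `NULL` (use the largest `n_bound` per group), a single
#'   integer, or a named vector/list mapping variant labels to event counts.
#' @param auto_events Passed to [fit_titration()].
#' @return A tibble with one row per variant, temperature, replicate and
#'   binding event: columns `variant`, `temperature_K`, `replicate`, `event`,
#'   `ka_per_uM`, `kd_uM`, `pseudo_chi2`, `r_squared`, `converged`.
#' @export
fit_binding <- function(data, n_events = NULL, auto_events = FALSE) {
  data <- validate_titration(data, require_meta = TRUE)
  groups <- dplyr::group_split(
    dplyr::group_by(data, .data$variant, .data$temperature_K, .data$replicate)
  )
  purrr::list_rbind(purrr::map(groups, function(g) {
    ne <- n_events
    if (!is.null(ne) && length(ne) > 1L) {
      ne <- ne[[as.character(g$variant[1])]]
      if (is.null(ne)) stop("no `n_events` entry for variant ",
                            g$variant[1], call. = FALSE)
    }
    fit <- fit_titration(g, n_events = ne, auto_events = auto_events)
    dplyr::bind_cols(
      tibble::tibble(variant = g$variant[1],
                     temperature_K = g$temperature_K[1],
                     replicate = g$replicate[1]),
      tidy(fit),
      tibble::tibble(pseudo_chi2 = fit$pseudo_chi2,
                     r_squared = fit$r_squared,
                     converged = fit$converged)
    )
  }))
}

#' Summarise replicate binding fits as mean and SD
#'
#' Collapses the per-replicate output of [fit_binding()] to replicate mean
#' and sample standard deviation per variant, temperature and event, plus
#' the poorest-replicate goodness of fit, mirroring the conventional
#' published K_D table layout.
#'
#' @param fits Output of [fit_binding()].
#' @param wide If `TRUE` (default), one row per variant and temperature with
#'   `KD<n>_uM`/`KD<n>_sd` columns plus `R2_worst` and `chi2_worst`;
#'   otherwise a long table with one row per event.
#' @return A tibble.
#' @export
summarize_kd <- function(fits, wide = TRUE) {
  long <- dplyr::summarise(
    dplyr::group_by(fits, .data$variant, .data$temperature_K, .data$event),
    kd_sd = if (dplyr::n() > 1L) stats::sd(.data$kd_uM) else 0,
    kd_uM = mean(.data$kd_uM),
    n_replicates = dplyr::n(),
    R2_worst = min(.data$r_squared),
    chi2_worst = max(.data$pseudo_chi2),
    .groups = "drop"
  )
  if (!wide) return(long)
  wide_kd <- tidyr::pivot_wider(
    long, id_cols = c("variant", "temperature_K"),
    names_from = "event", values_from = c("kd_uM", "kd_sd"),
    names_glue = "KD{event}_{ifelse(.value == 'kd_uM', 'uM', 'sd')}"
  )
  gof <- dplyr::summarise(
    dplyr::group_by(long, .data$variant, .data$temperature_K),
    R2_worst = min(.data$R2_worst), chi2_worst = max(.data$chi2_worst),
    .groups = "drop"
  )
  dplyr::left_join(wide_kd, gof, by = c("variant", "temperature_K"))
}
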