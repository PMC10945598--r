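#' Plot a titration and its sequential-binding fit
#'
#' Mole fractions of each ligand-bound species against total titrant, with
#' the fitted model drawn as smooth curves.
#'
#' @param fit A `binding_fit` from [fit_titration()].
#' @param n_curve Number of points for the fitted curves.
#' @return A ggplot object.
#' @export
plot_titration_fit <- function(fit, n_curve = 100) {
  stopifnot(inherits(fit, "binding_fit"))
  mk_long <- function(m, lig) {
    tibble::tibble(
      ligand_total_uM = rep(lig, times = ncol(m)),
      species = factor(rep(colnames(m), each = length(lig)),
                       levels = colnames(m)),
      mole_fraction = as.vector(m)
    )
  }
  obs <- mk_long(fit$f_exp, fit$ligand_total)
  grid <- seq(min(fit$ligand_total), max(fit$ligand_total),
              length.out = n_curve)
  pred <- mk_long(predict_mole_fractions(fit$ka, fit$protein_total, grid),
                  grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$ligand_total_uM,
                                    y = .data$mole_fraction,
                                    colour = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "total titrant (uM)", y = "mole fraction",
                  colour = "species") +
    ggplot2::theme_classic()
}

#' van't Hoff plot
#'
#' \eqn{\ln K_A} against \eqn{1/T} with the fitted (linear or
#' constant-\eqn{\Delta C_p}) model curve.
#'
#' @param fit A `vanthoff_fit`.
#' @param n_curve Number of points for the fitted curve.
#' @return A ggplot object.
#' @export
plot_vant_hoff <- function(fit, n_curve = 100) {
  stopifnot(inherits(fit, "vanthoff_fit"))
  obs <- tibble::tibble(inv_T = 1 / fit$temperature, lnKA = fit$lnKA)
  tgrid <- seq(min(fit$temperature), max(fit$temperature),
               length.out = n_curve)
  pred <- tibble::tibble(inv_T = 1 / tgrid, lnKA = predict_lnka(fit, tgrid))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$inv_T, y = .data$lnKA)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "1/T (1/K)", y = "ln K_A") +
    ggplot2::theme_classic()
}

#' Thermodynamic signature bars
#'
#' The classic signature plot: grouped bars of \eqn{\Delta G},
#' \eqn{\Delta H} and \eqn{-T\Delta S} per variant, faceted by temperature
#' when several are present.
#'
#' @param thermo Signature table from [thermo_signature()].
#' @param event Binding event to display (default 1).
#' @return A ggplot object.
#' @export
plot_thermo_signature <- function(thermo, event = 1L) {
  long <- summarize_signature(thermo[thermo$event == event, , drop = FALSE])
  long$term <- factor(long$term, levels = c("dG", "dH", "mTdS"),
                      labels = c("ΔG", "ΔH", "-TΔS"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$variant,
                                          y = .data$value,
                                          fill = .data$term)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "kJ/mol", fill = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(long$temperature_K)) > 1L) {
    p <- p + ggplot2::facet_wrap(~temperature_K)
  }
  p
}
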