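#' Association constant from thermodynamic ground truth
#'
#' Forward-evaluates the integrated constant-\eqn{\Delta C_p} van't Hoff
#' model: given \eqn{\Delta G(T_0)} (which fixes \eqn{\ln K_0}),
#' \eqn{\Delta H_{T_0}} and \eqn{\Delta C_p}, returns the stepwise
#' association constant at any temperature, in 1/uM.
#'
#' @param dG_T0,dH_T0 Free energy and enthalpy at the reference temperature,
#'   kJ/mol.
#' @param dCp Heat-capacity change, kJ/mol/K.
#' @param temperature Temperature(s) in kelvin.
#' @param t0 Reference temperature in kelvin.
#' @return Association constant(s) in 1/uM.
#' @examples
#' # dG(298) = -35.2 kJ/mol corresponds to K_D = 0.68 uM
#' 1 / ka_from_thermo(-35.2, 45, 8.9, temperature = 298, t0 = 298)
#' @export
ka_from_thermo <- function(dG_T0, dH_T0, dCp, temperature, t0 = 298) {
  lnK0 <- -dG_T0 / (R_GAS * t0)
  exp(vant_hoff_lnka(temperature, t0, dH_T0, dCp, lnK0)) / 1e6
}

#' Build a ground-truth panel for a mutant cycle
#'
#' Constructs per-variant thermodynamic parameters for a full mutant-cycle
#' panel: the wild-type baseline, single mutants obtained by additive shifts
#' of (\eqn{\Delta G}, \eqn{\Delta H}) at the reference temperature, multiple
#' mutants obtained as the sum of their single shifts *minus* the designed
#' interaction terms, and (for three mutations) a triple mutant carrying an
#' explicit third-order term. By construction, running the full analysis on
#' noiseless data generated from this truth returns exactly the designed
#' couplings; the entropic coupling follows as \eqn{c_G - c_H} so the
#' thermodynamic identity stays exact.
#'
#' @param baseline Data frame with columns `event`, `dG_T0`, `dH_T0`, `dCp`
#'   (kJ/mol, kJ/mol, kJ/mol/K) for the wild type.
#' @param shifts Named list: mutation label -> numeric vector with elements
#'   `dG` and `dH` (and optionally `dCp`), the additive shift applied to
#'   every binding event.
#' @param pair_couplings Named list keyed `"X:Y"` -> vector with `cG` and
#'   `cH` (kJ/mol), the designed pairwise interaction terms. Pairs not
#'   listed couple with 0.
#' @param triple_coupling Optional vector with `cG`, `cH`: the designed
#'   third-order term (requires exactly three mutations in `shifts`).
#' @param wild_type Label for the baseline variant.
#' @param t0 Reference temperature in kelvin.
#' @return A tibble with columns `variant`, `event`, `dG_T0`, `dH_T0`,
#'   `dCp`, `t0`; one row per variant and binding event. Multi-mutant
#'   variant labels join the mutation labels with a space, in `shifts`
#'   order.
#' @export
build_cycle_truth <- function(baseline, shifts, pair_couplings = NULL,
                              triple_coupling = NULL, wild_type = "WT",
                              t0 = 298) {
  baseline <- tibble::as_tibble(baseline)
  stopifnot(all(c("event", "dG_T0", "dH_T0", "dCp") %in% names(baseline)))
  muts <- names(shifts)
  if (length(muts) < 1L || length(muts) > 3L) {
    stop("`shifts` must name 1-3 mutations", call. = FALSE)
  }
  if (!is.null(triple_coupling) && length(muts) != 3L) {
    stop("a triple coupling requires exactly three mutations", call. = FALSE)
  }
  getc <- function(key) {
    if (is.null(pair_couplings)) return(c(cG = 0, cH = 0))
    hit <- pair_couplings[[key]]
    if (is.null(hit)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      hit <- pair_couplings[[paste(rev(parts), collapse = ":")]]
    }
    if (is.null(hit)) c(cG = 0, cH = 0) else c(cG = hit[["cG"]], cH = hit[["cH"]])
  }
  combos <- unlist(lapply(seq_along(muts), function(k) {
    utils::combn(muts, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map(c(list(character(0)), combos), function(set) {
    v <- baseline
    for (m in set) {
      s <- shifts[[m]]
      v$dG_T0 <- v$dG_T0 + s[["dG"]]
      v$dH_T0 <- v$dH_T0 + s[["dH"]]
      if ("dCp" %in% names(s)) v$dCp <- v$dCp + s[["dCp"]]
    }
    if (length(set) >= 2L) {
      for (pair in utils::combn(set, 2L, simplify = FALSE)) {
        cc <- getc(paste(pair, collapse = ":"))
        v$dG_T0 <- v$dG_T0 - cc[["cG"]]
        v$dH_T0 <- v$dH_T0 - cc[["cH"]]
      }
    }
    if (length(set) == 3L && !is.null(triple_coupling)) {
      v$dG_T0 <- v$dG_T0 + triple_coupling[["cG"]]
      v$dH_T0 <- v$dH_T0 + triple_coupling[["cH"]]
    }
    v$variant <- if (length(set)) paste(set, collapse = " ") else wild_type
    v
  })
  out <- purrr::list_rbind(rows)
  out$t0 <- t0
  out[, c("variant", "event", "dG_T0", "dH_T0", "dCp", "t0")]
}

# default titrant grid, uM
default_ligand_grid <- function() c(0, 0.25, 0.5, 1, 2, 3, 5, 7.5, 10)

#' Simulate a native MS titration
#'
#' Generates noisy mole-fraction titrations for one variant at one or more
#' temperatures from ground-truth thermodynamic parameters. Exact fractions
#' come from the sequential binding model with the free-ligand mass balance
#' solved exactly; Gaussian noise of SD `noise_sd` is then added to each
#' mole fraction, negative values are clipped to zero and each titration
#' point renormalised — emulating replicate scatter of deconvoluted,
#' normalised native MS peak intensities.
#'
#' @param truth Ground-truth tibble as built by [build_cycle_truth()] (or
#'   with the same columns).
#' @param variant Variant label to simulate (must appear in `truth`).
#' @param temperature Temperatures in kelvin.
#' @param ligand_total Total titrant grid in uM.
#' @param protein_total Total protein in uM (default 0.39, the study
#'   condition).
#' @param noise_sd Gaussian SD added to each mole fraction (default 0.01).
#' @param n_replicates Number of replicates (default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return A long-format titration tibble in the [read_titration_csv()]
#'   schema.
#' @export
simulate_titration <- function(truth, variant, temperature = 298,
                               ligand_total = default_ligand_grid(),
                               protein_total = 0.39, noise_sd = 0.01,
                               n_replicates = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- dplyr::arrange(
    dplyr::filter(tibble::as_tibble(truth), .data$variant == !!variant),
    .data$event
  )
  if (nrow(rows) == 0L) {
    stop("variant '", variant, "' not present in `truth`", call. = FALSE)
  }
  purrr::list_rbind(purrr::map(temperature, function(tk) {
    ka <- ka_from_thermo(rows$dG_T0, rows$dH_T0, rows$dCp, tk, rows$t0[1])
    f_true <- predict_mole_fractions(ka, protein_total, ligand_total)
    purrr::list_rbind(purrr::map(seq_len(n_replicates), function(rep_i) {
      f_obs <- f_true
      if (noise_sd > 0) {
        f_obs <- f_obs + stats::rnorm(length(f_obs), sd = noise_sd)
        f_obs <- pmax(f_obs, 0)
        f_obs <- f_obs / rowSums(f_obs)
      }
      tibble::tibble(
        variant = variant, temperature_K = tk, replicate = rep_i,
        protein_total_uM = protein_total,
        ligand_total_uM = rep(ligand_total, times = ncol(f_obs)),
        n_bound = rep(0:(ncol(f_obs) - 1L), each = length(ligand_total)),
        mole_fraction = as.vector(f_obs)
      )
    }))
  }))
}

#' Simulate a full mutant-cycle panel
#'
#' Generates titrations for every variant in a ground-truth panel at every
#' requested temperature, sharing one random-number stream so a single seed
#' makes the whole panel reproducible.
#'
#' @inheritParams simulate_titration
#' @param temperatures Temperatures in kelvin (default the study's 288, 293,
#'   298 and 303 K).
#' @return A long-format titration tibble covering all variants.
#' @export
simulate_panel <- function(truth, temperatures = c(288, 293, 298, 303),
                           ligand_total = default_ligand_grid(),
                           protein_total = 0.39, noise_sd = 0.01,
                           n_replicates = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variants <- unique(tibble::as_tibble(truth)$variant)
  purrr::list_rbind(purrr::map(variants, function(v) {
    simulate_titration(truth, v, temperatures, ligand_total, protein_total,
                       noise_sd, n_replicates, seed = NULL)
  }))
}
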