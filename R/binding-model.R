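#' Sequential binding model: species mole fractions
#'
#' For a protein P binding up to `n` ligands sequentially
#' (\eqn{PL_{n-1} + L \rightleftharpoons PL_n}, stepwise association constant
#' \eqn{K_{A,n}}), the mole fraction of the species with `n` ligands bound is
#' \deqn{F_{PL_n} = \frac{L^n \prod_{j \le n} K_{A,j}}
#'                       {1 + \sum_i L^i \prod_{j \le i} K_{A,j}}}
#' where `L` is the *free* ligand concentration. This is the binding
#' polynomial evaluated at the free-ligand activity.
#'
#' @param ka Numeric vector of stepwise association constants
#'   \eqn{K_{A,1} \dots K_{A,n}} in 1/uM. All must be strictly positive.
#' @param l_free Free ligand concentration in uM (scalar, >= 0).
#' @return Numeric vector of length `length(ka) + 1` with the mole fractions
#'   of the 0-, 1-, ..., n-bound species. Sums to 1.
#' @examples
#' species_fractions(ka = 1 / c(0.68, 2.53, 6.01), l_free = 0.68)
#' @export
species_fractions <- function(ka, l_free) {
  stopifnot(is.numeric(ka), length(ka) >= 1L, is.numeric(l_free),
            length(l_free) == 1L)
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    stop("all association constants `ka` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(l_free) || l_free < 0) {
    stop("`l_free` must be finite and >= 0", call. = FALSE)
  }
  # weights 1, L*K1, L^2*K1*K2, ... via a cumulative product
  w <- cumprod(c(1, ka * l_free))
  w / sum(w)
}

#' Solve the free-ligand mass balance
#'
#' The free ligand concentration satisfies
#' \deqn{L_{free} = L_{total} - P_{total} \sum_i i \, F_{PL_i}(L_{free}),}
#' i.e. total ligand minus ligand sequestered on the protein. The residual of
#' this balance is strictly increasing in \eqn{L_{free}}, so the root is
#' bracketed on \eqn{[0, L_{total}]} and found by Brent's method, then
#' polished by Newton steps to a relative mass-balance error below 1e-10.
#'
#' @inheritParams species_fractions
#' @param protein_total Total protein concentration in uM (>= 0).
#' @param ligand_total Total ligand concentration in uM (>= 0).
#' @return Free ligand concentration in uM, in `[0, ligand_total]`.
#' @examples
#' solve_free_ligand(1 / c(0.68, 2.53, 6.01), protein_total = 0.39,
#'                   ligand_total = 0.6)
#' @export
solve_free_ligand <- function(ka, protein_total, ligand_total) {
  stopifnot(is.numeric(protein_total), length(protein_total) == 1L,
            is.numeric(ligand_total), length(ligand_total) == 1L)
  if (!is.finite(protein_total) || protein_total < 0) {
    stop("`protein_total` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(ligand_total) || ligand_total < 0) {
    stop("`ligand_total` must be finite and >= 0", call. = FALSE)
  }
  if (ligand_total == 0) return(0)
  if (protein_total == 0) return(ligand_total)

  n <- length(ka)
  bound <- function(l) sum(seq_len(n) * species_fractions(ka, l)[-1])
  resid <- function(l) l + protein_total * bound(l) - ligand_total

  # resid(0) = -ligand_total < 0, resid(ligand_total) >= 0: root is bracketed.
  # A loose bracketing solve is enough: the Newton polish below converges
  # quadratically to the 1e-12 target.
  root <- stats::uniroot(resid, lower = 0, upper = ligand_total,
                         f.lower = -ligand_total,
                         tol = 1e-4 * max(ligand_total, 1))$root

  # Newton polish; d(bound)/dL from the variance identity of the bound-count
  # distribution: occupancy variance / L.
  for (i in 1:12) {
    f <- species_fractions(ka, root)
    occ <- sum(0:n * f)
    r <- root + protein_total * occ - ligand_total
    if (abs(r) <= 1e-12 * max(ligand_total, 1)) break
    var_occ <- sum((0:n)^2 * f) - occ^2
    dr <- 1 + protein_total * var_occ / max(root, .Machine$double.xmin)
    step <- r / dr
    root <- min(max(root - step, 0), ligand_total)
  }
  rel <- abs(resid(root)) / max(ligand_total, 1e-12)
  if (rel > 1e-10) {
    stop(sprintf("free-ligand solver did not reach tolerance (relative residual %.3e)",
                 rel), call. = FALSE)
  }
  root
}

#' Predicted mole fractions along a titration
#'
#' Composes [solve_free_ligand()] and [species_fractions()] across a series of
#' total ligand concentrations at fixed total protein.
#'
#' @inheritParams solve_free_ligand
#' @param ligand_total_series Numeric vector of total ligand concentrations
#'   (uM), non-negative and non-decreasing.
#' @return A numeric matrix with one row per titration point and
#'   `length(ka) + 1` columns (species `PL0 ... PLn`); each row sums to 1.
#' @export
predict_mole_fractions <- function(ka, protein_total, ligand_total_series) {
  stopifnot(is.numeric(ligand_total_series), length(ligand_total_series) >= 1L)
  if (any(diff(ligand_total_series) < 0)) {
    stop("`ligand_total_series` must be non-decreasing", call. = FALSE)
  }
  out <- t(vapply(ligand_total_series, function(lt) {
    species_fractions(ka, solve_free_ligand(ka, protein_total, lt))
  }, numeric(length(ka) + 1L)))
  colnames(out) <- paste0("PL", 0:length(ka))
  out
}

#' Pseudo chi-square of a titration fit
#'
#' Sum of squared residuals between experimental and calculated mole
#' fractions over all species and titration points:
#' \eqn{\chi^2 = \sum_j \sum_k (F_{exp} - F_{calc})^2}.
#'
#' @param f_exp,f_calc Numeric matrices of identical shape (points x species).
#' @return Non-negative scalar; 0 iff the matrices are equal.
#' @export
pseudo_chi2 <- function(f_exp, f_calc) {
  f_exp <- as.matrix(f_exp)
  f_calc <- as.matrix(f_calc)
  if (!identical(dim(f_exp), dim(f_calc))) {
    stop("`f_exp` and `f_calc` must have identical dimensions", call. = FALSE)
  }
  sum((f_exp - f_calc)^2)
}

#' Convert between stepwise K_A and K_D
#'
#' Stepwise dissociation constants are the reciprocals of the stepwise
#' association constants: \eqn{K_{D,n} = 1 / K_{A,n}}.
#'
#' @param ka Association constants in 1/uM.
#' @param kd Dissociation constants in uM.
#' @return The reciprocal constants (uM for `kd_from_ka`, 1/uM for
#'   `ka_from_kd`).
#' @export
kd_from_ka <- function(ka) {
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    stop("association constants must be finite and > 0", call. = FALSE)
  }
  1 / ka
}

#' @rdname kd_from_ka
#' @export
ka_from_kd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("dissociation constants must be finite and > 0", call. = FALSE)
  }
  1 / kd
}
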