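# Shared synthetic ground truths and independent oracles.

# WT-like three-event baseline at 298 K (K_D about 0.68 / 2.5 / 6 uM)
wt_like_baseline <- function(n_events = 2L) {
  tibble::tibble(
    event = seq_len(n_events),
    dG_T0 = c(-35.2, -32.0, -29.8)[seq_len(n_events)],
    dH_T0 = c(45, 60, 59)[seq_len(n_events)],
    dCp = c(8.9, 11.7, 10.7)[seq_len(n_events)]
  )
}

# one-event double-mutant-cycle truth with a designed coupling
one_event_cycle_truth <- function(cG = 2.0, cH = -26) {
  build_cycle_truth(
    baseline = wt_like_baseline(1L),
    shifts = list(X = c(dG = 2.7, dH = -60), Y = c(dG = 2.8, dH = -2)),
    pair_couplings = list("X:Y" = c(cG = cG, cH = cH))
  )
}

# independent free-ligand oracle: coarse grid bracketing + plain bisection,
# shares no code path with solve_free_ligand's uniroot/Newton solve
brute_free_ligand <- function(ka, protein_total, ligand_total,
                              n_grid = 200L, n_bisect = 60L) {
  resid <- function(l) {
    f <- species_fractions(ka, l)
    l + protein_total * sum(seq_along(ka) * f[-1]) - ligand_total
  }
  if (ligand_total == 0) return(0)
  grid <- seq(0, ligand_total, length.out = n_grid)
  vals <- vapply(grid, resid, numeric(1))
  i <- which(vals[-1] >= 0 & vals[-n_grid] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1L]
  for (k in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    if (resid(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
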