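test_that("quadrature SD propagation matches the published tables", {
  expect_equal(propagate_sd(c(0, 0, 0)), 0)
  expect_equal(propagate_sd(c(0.2, 0.2, 0.2)), 0.3464, tolerance = 1e-4)
  expect_equal(propagate_sd(c(11.3, 6.1, 6.9)), 14.578, tolerance = 1e-3)
  expect_error(propagate_sd(c(0.1, -0.2)), ">= 0")
})

test_that("mutant-minus-wild-type differences reproduce printed rows", {
  expect_equal(delta_delta(-30.4, -30.4)$value, 0)
  # R238A vs WT first-event free energy at 298 K
  dd <- delta_delta(-30.4, -35.2, 0.1, 0.2)
  expect_equal(dd$value, 4.8)
  expect_equal(dd$sd, sqrt(0.05), tolerance = 1e-12)
  expect_equal(delta_delta(0, 0, 0.1, 0.2)$sd, 0.2236, tolerance = 1e-4)
})

test_that("double-cycle couplings reproduce the headline values", {
  # additive mutants: zero coupling
  expect_equal(double_cycle_coupling(1.2, 2.3, 3.5)$value, 0)
  # interior-site pair R78A/K299A at 298 K
  expect_equal(double_cycle_coupling(2.7, 2.8, 3.8)$value, 1.7)
  # interior/exterior pair R188A/K299A at 298 K: negative coupling
  expect_equal(double_cycle_coupling(2.7, 2.8, 6.6)$value, -1.1)
  expect_equal(double_cycle_coupling(0, 0, 0, 0.2, 0.2, 0.2)$sd,
               0.3464, tolerance = 1e-4)
})

test_that("triple-cycle coupling is the background difference of pair couplings", {
  expect_equal(triple_cycle_coupling(1.4, 1.4)$value, 0)
  # exterior-site triple at 298 K: R238A/K243A pair in WT vs R188A background
  expect_equal(triple_cycle_coupling(0.8, -2.6)$value, 3.4)
  # same route for the coupling enthalpy
  expect_equal(triple_cycle_coupling(37.7, -62.4)$value, 100.1)
  expect_equal(triple_cycle_coupling(0, 0, 0.4, 0.2)$sd, sqrt(0.2))
})

test_that("cycle analysis of a signature table is antisymmetric and consistent", {
  truth <- one_event_cycle_truth(cG = 1.7, cH = -26)
  temps <- c(288, 293, 298, 303)
  kd <- tidyr::expand_grid(
    variant = unique(truth$variant), temperature_K = temps, event = 1L
  )
  kd$kd_uM <- purrr::pmap_dbl(kd, function(variant, temperature_K, event) {
    row <- truth[truth$variant == variant, ]
    1 / ka_from_thermo(row$dG_T0, row$dH_T0, row$dCp, temperature_K)
  })
  sig <- thermo_signature(kd, model = "nonlinear", t0 = 298)
  cyc <- mutant_cycle(sig, "X", "Y", "X Y")
  expect_equal(nrow(cyc), length(temps) * 3L)
  g298 <- cyc[cyc$quantity == "G" & cyc$temperature_K == 298, ]
  expect_equal(g298$dd_int, 1.7, tolerance = 1e-9)
  h298 <- cyc[cyc$quantity == "H" & cyc$temperature_K == 298, ]
  expect_equal(h298$dd_int, -26, tolerance = 1e-7)
  # swapping the two single mutants leaves the coupling unchanged
  cyc_swap <- mutant_cycle(sig, "Y", "X", "X Y")
  expect_equal(cyc_swap$dd_int, cyc$dd_int, tolerance = 1e-12)
  # thermodynamic identity at every temperature, exactly
  cons <- cycle_consistency(cyc)
  expect_true(all(cons$consistent))
  expect_error(mutant_cycle(sig, "X", "Z", "X Y"), "absent")
})

test_that("consistency residuals on printed rows reflect rounding only", {
  # R78A/K299A 298 K: 1.7 vs (-25.8 + 27.5)
  tbl <- tibble::tibble(
    pair = "a/b", background = "WT", event = 1L, temperature_K = 298,
    quantity = c("G", "H", "mTdS"),
    dd_int = c(1.7, -25.8, 27.5)
  )
  expect_equal(cycle_consistency(tbl)$residual, 0)
  # R188A/K243A 298 K: 3.2 vs (19.1 - 16.0)
  tbl$dd_int <- c(3.2, 19.1, -16.0)
  expect_equal(cycle_consistency(tbl)$residual, 0.1)
})

test_that("triple cycles are route-independent on exact tables", {
  base <- wt_like_baseline(1L)
  truth <- build_cycle_truth(
    baseline = base,
    shifts = list(X = c(dG = 2.7, dH = -3), Y = c(dG = 4.8, dH = -63),
                  Z = c(dG = 1.6, dH = 7)),
    pair_couplings = list("X:Y" = c(cG = 0.1, cH = -9),
                          "X:Z" = c(cG = 3.2, cH = 19),
                          "Y:Z" = c(cG = 0.8, cH = 38)),
    triple_coupling = c(cG = 3.4, cH = 100)
  )
  kd <- tidyr::expand_grid(variant = unique(truth$variant),
                           temperature_K = c(293, 298, 303), event = 1L)
  kd$kd_uM <- purrr::pmap_dbl(kd, function(variant, temperature_K, event) {
    row <- truth[truth$variant == variant, ]
    1 / ka_from_thermo(row$dG_T0, row$dH_T0, row$dCp, temperature_K)
  })
  sig <- thermo_signature(kd, model = "nonlinear", t0 = 298)
  tc <- triple_mutant_cycle(sig, "X", "Y", "Z", xy = "X Y", xz = "X Z",
                            yz = "Y Z", xyz = "X Y Z")
  # all three background routes agree exactly at every temperature
  for (tk in c(293, 298, 303)) {
    for (q in c("G", "H", "mTdS")) {
      vals <- tc$dd_int3[tc$quantity == q & tc$temperature_K == tk]
      expect_equal(length(vals), 3L)
      expect_lt(max(vals) - min(vals), 1e-8)
    }
  }
  # designed values drop out at the reference temperature
  g298 <- tc[tc$quantity == "G" & tc$temperature_K == 298, ]
  expect_equal(g298$dd_int3, rep(3.4, 3), tolerance = 1e-8)
  h <- tc[tc$quantity == "H", ]
  # enthalpy coupling is temperature-independent when the dCp terms cancel
  expect_equal(h$dd_int3, rep(100, 9), tolerance = 1e-7)
  s298 <- tc[tc$quantity == "mTdS" & tc$temperature_K == 298, ]
  expect_equal(s298$dd_int3, rep(3.4 - 100, 3), tolerance = 1e-7)
  # away from T0 the free-energy coupling evolves as cH(1 - T/T0) + cG T/T0
  g293 <- tc$dd_int3[tc$quantity == "G" & tc$temperature_K == 293]
  expect_equal(g293, rep(100 * (1 - 293 / 298) + 3.4 * 293 / 298, 3),
               tolerance = 1e-8)
})

test_that("published difference tables give the printed couplings", {
  ddx <- msba_kdl_table("ddx_inward")
  rk <- coupling_from_ddx(ddx, "R78A", "K299A", temperature = 298)
  expect_equal(rk$dd_int[rk$quantity == "G"], 1.7, tolerance = 0.051)
  expect_equal(rk$dd_int[rk$quantity == "H"], -25.9, tolerance = 0.2)
  expect_equal(rk$dd_int_sd[rk$quantity == "G"], 0.346, tolerance = 0.06)
  # exterior pair in the R188A background (printed block of the triple table)
  bg <- coupling_from_ddx(ddx, "R238A", "K243A", background = "R188A",
                          temperature = 298)
  expect_equal(bg$dd_int[bg$quantity == "G"], -2.6, tolerance = 0.051)
})
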