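test_that("free energy from K_D uses the 1 M standard state", {
  expect_equal(delta_g_from_kd(1e6, 298), 0)
  expect_equal(delta_g_from_kd(0.68, 298), -35.2, tolerance = 0.002)
  expect_equal(delta_g_from_kd(0.44, 298), -36.3, tolerance = 0.002)
  expect_error(delta_g_from_kd(-1, 298), "> 0")
  expect_error(delta_g_from_kd(1, 0), "> 0")
})

test_that("entropic term back-calculation is dG - dH", {
  expect_equal(back_calc_entropy(-12.3, -12.3), 0)
  expect_equal(back_calc_entropy(-35.2, 45.0), -80.2)
  expect_equal(back_calc_entropy(-36.3, 21.9), -58.2)
})

test_that("linear van't Hoff recovers exact lines and the trapped-WT slope", {
  # noiseless synthetic line: dH = -30, dS such that dG(298) = -35
  R <- 8.314462618e-3
  dH <- -30; dS <- (dH + 35) / 298
  temps <- c(288, 293, 298, 303)
  ka <- exp((-dH / R) / temps + dS / R) / 1e6
  fit <- vant_hoff_linear(temps, ka)
  expect_equal(fit$dH_T0, dH, tolerance = 1e-9)
  expect_equal(fit$dS, dS, tolerance = 1e-12)
  expect_equal(fit$dG_T0, -35, tolerance = 1e-9)

  # vanadate-trapped WT first event: published K_D1 means
  kd <- c(0.51, 0.44, 0.38, 0.31)
  fit2 <- vant_hoff_linear(c(293, 298, 303, 310), 1 / kd)
  expect_equal(fit2$dH_T0, 21.9, tolerance = 1.5)

  # two points define the line with zero residual
  fit3 <- vant_hoff_linear(c(293, 303), 1 / kd[c(1, 3)])
  expect_lt(fit3$ssr, 1e-20)
  expect_error(vant_hoff_linear(298, 2), "at least 2")
})

test_that("nonlinear van't Hoff is exact on self-generated data", {
  temps <- c(288, 293, 298, 303)
  ka <- ka_from_thermo(-35.2, 45, 8.9, temps, t0 = 298)
  fit <- vant_hoff_nonlinear(temps, ka, t0 = 298)
  expect_equal(fit$dH_T0, 45, tolerance = 1e-8)
  expect_equal(fit$dCp, 8.9, tolerance = 1e-8)
  expect_equal(fit$dG_T0, -35.2, tolerance = 1e-8)
  expect_error(vant_hoff_nonlinear(c(288, 298), 1 / c(0.7, 0.6)), "at least 3")
})

test_that("nonlinear fit nests the linear model", {
  temps <- c(288, 293, 298, 303)
  kd <- c(0.69, 0.75, 0.68, 0.43)
  lin <- vant_hoff_linear(temps, 1 / kd, t0 = 298)
  con <- vant_hoff_nonlinear(temps, 1 / kd, t0 = 298, fix_dcp_zero = TRUE)
  expect_equal(con$dH_T0, lin$dH_T0, tolerance = 1e-9)
  expect_equal(con$dG_T0, lin$dG_T0, tolerance = 1e-9)
  # data generated with dCp = 0 gives dCp about 0 and the linear enthalpy
  ka0 <- ka_from_thermo(-34, -20, 0, temps)
  nl <- vant_hoff_nonlinear(temps, ka0, t0 = 298)
  expect_equal(nl$dCp, 0, tolerance = 1e-8)
  expect_equal(nl$dH_T0, -20, tolerance = 1e-7)
})

test_that("the fitted curve is invariant to the reference temperature", {
  temps <- c(288, 293, 298, 303)
  kd <- c(0.69, 0.75, 0.68, 0.43)
  f298 <- vant_hoff_nonlinear(temps, 1 / kd, t0 = 298)
  f293 <- vant_hoff_nonlinear(temps, 1 / kd, t0 = 293)
  expect_equal(f293$dCp, f298$dCp, tolerance = 1e-8)
  grid <- seq(288, 303, by = 0.5)
  expect_equal(predict_lnka(f293, grid), predict_lnka(f298, grid),
               tolerance = 1e-8)
  # enthalpy extrapolation follows dH(T) = dH_T0 + dCp (T - T0)
  expect_equal(enthalpy_at_temperature(f298, 298), f298$dH_T0)
  expect_equal(enthalpy_at_temperature(f298, 288),
               f298$dH_T0 - 10 * f298$dCp)
  lin <- vant_hoff_linear(temps, 1 / kd)
  expect_equal(enthalpy_at_temperature(lin, c(250, 298, 340)),
               rep(lin$dH_T0, 3))
})

test_that("grouped van't Hoff honours model choice and exclusions", {
  kd_long <- kd_table_to_long(msba_kdl_table("kd_inward"))
  fits <- vant_hoff(kd_long[kd_long$variant %in% c("WT", "R78A"), ],
                    model = "nonlinear", t0 = 298)
  expect_equal(nrow(fits), 5L)  # WT 3 events + R78A 2 events
  wt1 <- fits[fits$variant == "WT" & fits$event == 1, ]
  expect_equal(wt1$dH_T0, 42.92, tolerance = 0.01)
  # R78A fitted over 288-298 K only once 303 K is excluded
  ex <- vant_hoff(kd_long[kd_long$variant == "R78A", ], model = "nonlinear",
                  exclude = tibble::tibble(variant = "R78A",
                                           temperature_K = 303))
  expect_equal(length(ex$fit[[1]]$temperature), 3L)
})

test_that("thermo signatures satisfy the additive identity row-wise", {
  kd_long <- kd_table_to_long(msba_kdl_table("kd_inward"))
  sig <- thermo_signature(kd_long[kd_long$variant == "WT", ],
                          model = "nonlinear", t0 = 298)
  expect_equal(nrow(sig), 12L)  # 3 events x 4 temperatures
  expect_equal(sig$dG_kJmol, sig$dH_kJmol + sig$mTdS_kJmol, tolerance = 1e-9)
  expect_true(all(sig$dG_sd == 0))  # single replicate-mean input
  wt298 <- sig[sig$event == 1 & sig$temperature_K == 298, ]
  expect_equal(wt298$dG_kJmol, -35.2, tolerance = 0.01)
  expect_equal(wt298$dH_kJmol, 45.0, tolerance = 5.8)
})

test_that("replicated signatures report sample SDs and drop excluded rows", {
  truth <- tibble::tibble(variant = "WT", wt_like_baseline(1L), t0 = 298)
  tt <- simulate_titration(truth, "WT", c(288, 293, 298, 303),
                           noise_sd = 0.01, n_replicates = 3, seed = 3)
  fits <- fit_binding(tt)
  kd <- fits[, c("variant", "temperature_K", "replicate", "event", "kd_uM")]
  sig <- thermo_signature(kd, model = "nonlinear", t0 = 298)
  expect_equal(sig$n_replicates, rep(3L, 4))
  expect_true(all(sig$dG_sd > 0))
  expect_equal(sig$dG_kJmol, sig$dH_kJmol + sig$mTdS_kJmol, tolerance = 1e-9)
  sig2 <- thermo_signature(kd, model = "nonlinear", t0 = 298,
                           exclude = tibble::tibble(variant = "WT",
                                                    temperature_K = 303))
  expect_equal(nrow(sig2), 3L)
})
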