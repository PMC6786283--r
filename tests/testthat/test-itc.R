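test_that("simulate_isotherm matches the quadratic mass-balance oracle", {
  withr::local_seed(202)
  for (i in 1:100) {
    des <- itc_design(cell_volume_uL = runif(1, 150, 1400),
                      n_injections = sample(10:30, 1),
                      injection_volume_uL = runif(1, 1, 10),
                      cell_conc_uM = runif(1, 2, 50),
                      syringe_conc_uM = runif(1, 20, 500),
                      temperature_K = runif(1, 278, 318))
    th <- binding_thermo(n = runif(1, 0.5, 2), K_d = 10^runif(1, -9, -5),
                         dH = runif(1, -12, 8), q_dil = runif(1, -0.2, 0.5),
                         T_K = des$temperature_K)
    got <- simulate_isotherm(th, des)
    want <- oracle_itc_normalized_heats(th$n, th$K_d, th$dH, th$q_dil, des)
    expect_rel_equal(got, want, 1e-10)
  }
})

test_that("limiting isotherms behave physically", {
  des <- itc_design()
  # zero enthalpy and offset: no heat at all
  th0 <- binding_thermo(K_d = 1e-7, dH = 0, q_dil = 0)
  expect_equal(simulate_isotherm(th0, des), rep(0, 20))
  # stoichiometric titration: total heat equals moles of protein times dH;
  # a large cell keeps overflow losses of unreacted protein below the 1%
  # tolerance (the loss scales with injection volume over cell volume)
  des_fast <- itc_design(cell_volume_uL = 1400, syringe_conc_uM = 500)
  tight <- binding_thermo(n = 1, K_d = 1e-12, dH = -5, q_dil = 0)
  q_total_kcal <- sum(simulate_heats_ucal(tight, des_fast)) * 1e-9
  mol_M <- des_fast$cell_conc_uM * 1e-6 * des_fast$cell_volume_uL * 1e-6
  expect_lt(abs(q_total_kcal - (-5 * mol_M)) / abs(5 * mol_M), 0.01)
  # saturation: late incremental normalized heats approach the offset
  sat <- binding_thermo(n = 1, K_d = 1e-12, dH = -5, q_dil = 0.5)
  des_long <- itc_design(cell_volume_uL = 1400, syringe_conc_uM = 500,
                         n_injections = 40)
  expect_equal(utils::tail(simulate_isotherm(sat, des_long), 1), 0.5,
               tolerance = 1e-3)
})

test_that("energy bookkeeping closes against the mass balance", {
  des <- itc_design(n_injections = 25)
  th <- binding_thermo(n = 1.1, K_d = 3e-8, dH = -7, q_dil = 0)
  q_sum <- sum(simulate_heats_ucal(th, des)) * 1e-9          # kcal
  conc <- isophys:::itc_concentrations(des)
  MX <- isophys:::bound_complex(th$n, th$K_d, conc$Mt_uM * 1e-6,
                                conc$Xt_uM * 1e-6)
  V0 <- des$cell_volume_uL * 1e-6
  v <- des$injection_volume_uL * 1e-6
  displaced <- sum(MX[-length(MX)] * v[-1] / V0)
  expect_rel_equal(q_sum, V0 * th$dH * (MX[length(MX)] + displaced), 1e-9)
})

test_that("derive_thermo honors the standard-state identities", {
  expect_equal(derive_thermo(1, -5, 298.15)$dG, 0)
  d <- derive_thermo(1e-6, -5, 298.15)
  expect_equal(d$dG, -8.185, tolerance = 1e-3)
  for (kd in 10^seq(-9, -3)) {
    d <- derive_thermo(kd, -4.2, 310)
    expect_equal(d$dG, -4.2 + d$mTdS + 0)      # dG = dH + (-TdS)
    expect_equal(d$dG, R_KCAL * 310 * log(kd))
  }
})

test_that("noiseless single-site fits round-trip all four parameters", {
  des <- itc_design()
  th <- binding_thermo(n = 1.05, K_d = 1e-7, dH = -5, q_dil = 0.4)
  fit <- fit_single_site(itc_experiment(des, simulate_heats_ucal(th, des)))
  expect_true(attr(fit, "converged"))
  expect_rel_equal(fit$n, 1.05, 1e-6)
  expect_rel_equal(fit$K_d, 1e-7, 1e-5)
  expect_rel_equal(fit$dH, -5, 1e-6)
  expect_rel_equal(fit$q_dil, 0.4, 1e-4)
  # identities propagate to the derived quantities
  expect_equal(fit$dG, R_KCAL * fit$T_K * log(fit$K_d))
  expect_equal(fit$dG, fit$dH + fit$mTdS)
})

test_that("fits at the study's design recover n and K_d under noise", {
  # 3-5 uM protein cell, 50 uM titrant, 2 uL injections; c around 50
  des <- itc_design(cell_conc_uM = 5, syringe_conc_uM = 50,
                    injection_volume_uL = 2, n_injections = 20)
  th <- binding_thermo(n = 1, K_d = 1e-7, dH = -5, q_dil = 0.5)
  kds <- ns <- numeric(50)
  for (s in seq_len(50)) {
    e <- generate_itc_series(th, list(des), noise_spec(0.05, s))[[1]]
    f <- fit_single_site(e)
    kds[s] <- f$K_d; ns[s] <- f$n
  }
  expect_lt(abs(median(kds) - 1e-7) / 1e-7, 0.10)
  expect_true(median(ns) > 0.9 && median(ns) < 1.1)
})

test_that("degenerate or flagged titrations are reported, not silent", {
  des <- itc_design()
  expect_error(fit_single_site(itc_experiment(des, rep(0, 20))),
               "degenerate")
  short <- itc_design(n_injections = 6)
  expect_error(fit_single_site(itc_experiment(short, rep(1, 6))),
               "at least 6 usable")
  # c-value far out of range raises a warning flag on the result
  loose <- binding_thermo(n = 1, K_d = 1e-4, dH = -5, q_dil = 0)
  e <- itc_experiment(des, simulate_heats_ucal(loose, des))
  f <- fit_single_site(e)
  expect_true(any(grepl("c-value", attr(f, "warnings"))))
})

test_that("linkage and heat-capacity regressions recover their lines", {
  l <- linkage_regression(c(-2, -5), c(0, 10))
  expect_equal(l$dH0, -2)
  expect_equal(l$n_H, -0.3)
  expect_equal(linkage_regression(c(-4, -4, -4), c(0, 5, 10))$n_H, 0)
  expect_error(linkage_regression(c(-2, -5), c(3, 3)), "singular")
  h <- heat_capacity_regression(c(293.15, 303.15), c(-5, -8))
  expect_equal(h$dCp, -0.3)
  expect_equal(heat_capacity_regression(c(290, 300, 310), c(-6, -6, -6))$dCp, 0)
  expect_error(heat_capacity_regression(c(298, 298), c(-5, -6)), "singular")
})

test_that("affinity folds are ratios of dissociation constants", {
  a <- binding_thermo(K_d = 9e-7, dH = -5)
  b <- binding_thermo(K_d = 1e-7, dH = -5)
  expect_equal(compare_affinity(a, b), 9)
  expect_equal(compare_affinity(a, a), 1)
  expect_equal(compare_affinity(a, b) * compare_affinity(b, a), 1)
})
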