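test_that("generators are deterministic under a fixed seed", {
  p <- two_state_params(328.15, 50, baseline_folded = c(10, -0.01),
                        baseline_unfolded = c(4, -0.005))
  ns <- noise_spec(0.05, seed = 42)
  expect_identical(generate_melt_curve(p, 298, 358, 0.5, ns),
                   generate_melt_curve(p, 298, 358, 0.5, ns))
  th <- binding_thermo(K_d = 1e-7, dH = -5, q_dil = 0.5)
  des <- list(itc_design(), itc_design(buffer_dH_ion = 10))
  expect_identical(generate_itc_series(th, des, ns),
                   generate_itc_series(th, des, ns))
  expect_identical(generate_decay_series(4, c(0, 2, 4, 8), ns),
                   generate_decay_series(4, c(0, 2, 4, 8), ns))
  expect_identical(generate_frap_trace(7, 0.8, 0.8, seq(0, 30, 0.5), ns),
                   generate_frap_trace(7, 0.8, 0.8, seq(0, 30, 0.5), ns))
  expect_identical(generate_peptide_table(5, 10, 5, seed = 7),
                   generate_peptide_table(5, 10, 5, seed = 7))
  # earlier streams survive list extension (child-seed counter scheme)
  e3 <- generate_itc_series(th, c(des, list(itc_design(temperature_K = 303))), ns)
  expect_identical(e3[1:2], generate_itc_series(th, des, ns))
})

test_that("noiseless melt generation matches the closed-form model, midpoint at Tm", {
  p <- two_state_params(328.15, 50, baseline_folded = c(10, -0.01),
                        baseline_unfolded = c(4, -0.005))
  cv <- generate_melt_curve(p, 298.15, 358.15, 0.1)
  expect_rel_equal(cv$signal, two_state_signal(p, cv$temperature_K), 1e-12)
  # at Tm the signal is exactly midway between the two baselines
  bf <- 10 - 0.01 * 328.15
  bu <- 4 - 0.005 * 328.15
  i <- which(cv$temperature_K == 328.15)
  expect_equal(cv$signal[i], (bf + bu) / 2)
  expect_error(generate_melt_curve(p, 298, 358, step = -1), "invalid grid")
})

test_that("generated noise matches the requested magnitude", {
  p <- two_state_params(328.15, 50, baseline_folded = c(10, 0),
                        baseline_unfolded = c(4, 0))
  cv <- generate_melt_curve(p, 280, 380, 0.01, noise_spec(sd = 0.01, seed = 11))
  res <- cv$signal - two_state_signal(p, cv$temperature_K)
  n <- length(res)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(res)), 3 * 0.01 / sqrt(n))
  expect_lt(abs(sd(res) - 0.01) / 0.01, 0.05)
})

test_that("itc series obey the proton-linkage arithmetic", {
  # no linkage: identical heats across buffers
  th0 <- binding_thermo(K_d = 1e-7, dH = -3, dH0 = -3, n_H = 0, dCp = 0,
                        q_dil = 0)
  des <- lapply(c(0, 5, 10), function(h) itc_design(buffer_dH_ion = h))
  exps <- generate_itc_series(th0, des)
  expect_equal(exps[[1]]$normalized_heats, exps[[2]]$normalized_heats)
  expect_equal(exps[[1]]$normalized_heats, exps[[3]]$normalized_heats)
  # dH0 = -2, n_H = -0.3, ionization 0 and 10 -> apparent -2 and -5
  th <- binding_thermo(K_d = 1e-7, dH = -2, dH0 = -2, n_H = -0.3, q_dil = 0)
  expect_equal(apparent_dH(th, itc_design(buffer_dH_ion = 0)), -2)
  expect_equal(apparent_dH(th, itc_design(buffer_dH_ion = 10)), -5)
  # zero enthalpy: every normalized heat equals the dilution offset
  thz <- binding_thermo(K_d = 1e-7, dH = 0, dH0 = 0, n_H = 0, q_dil = 0.5)
  ez <- generate_itc_series(thz, list(itc_design()))[[1]]
  expect_equal(ez$normalized_heats, rep(0.5, 20))
  expect_error(generate_itc_series(th0, list()), "empty design list")
})

test_that("decay generator hits the closed-form first-order values", {
  expect_equal(generate_decay_series(4, c(0, 4))$value, c(1, 0.5))
  expect_equal(generate_decay_series(2, c(0, 6))$value[2], 0.125)
  expect_equal(generate_decay_series(Inf, c(0, 5, 10))$value, rep(1, 3))
  expect_equal(generate_decay_series(3, c(0, 1, 7))$value[1], 1)
  expect_error(generate_decay_series(4, c(-1, 0, 2)), "negative timepoint")
})

test_that("frap generator respects floor, plateau and half-recovery", {
  tp <- sort(c(6.93, seq(0, 90, 0.5)))
  full <- generate_frap_trace(6.93, 1, 0.8, tp)
  expect_equal(max(full$intensity[full$phase == "post"]),
               1, tolerance = 1e-3)
  immobile <- generate_frap_trace(6.93, 0, 0.8, tp)
  expect_equal(unname(immobile$intensity[immobile$phase == "post"]),
               rep(0.2, length(tp)))
  tr <- generate_frap_trace(6.93, 0.75, 0.8, tp)
  # one half-life after the bleach the signal sits midway to the plateau:
  # F0 = 0.2, Finf = 0.2 + 0.75*0.8 = 0.8, midpoint 0.5
  i <- which(tr$phase == "post")[which(tp == 6.93)]
  expect_equal(tr$intensity[i], 0.5, tolerance = 1e-4)
  expect_error(generate_frap_trace(6.93, 1.2, 0.8, tp), "mobile_fraction")
})

test_that("peptide tables plant recoverable truth", {
  pt0 <- generate_peptide_table(0, 10, 5, seed = 1)
  expect_length(filter_interactors(pt0), 0)
  pt5 <- generate_peptide_table(5, 0, 0, seed = 1)
  expect_setequal(as.character(filter_interactors(pt5)),
                  attr(pt5, "true_interactors"))
  pt <- generate_peptide_table(10, 50, 10, seed = 99)
  expect_true(all(pt$counts >= 0))
  expect_setequal(as.character(filter_interactors(pt)),
                  attr(pt, "true_interactors"))
})
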