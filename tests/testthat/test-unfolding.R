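base_params <- function(T_m = 318, dH_m = 40)
  two_state_params(T_m, dH_m, baseline_folded = c(12, -0.012),
                   baseline_unfolded = c(5, -0.006))

test_that("fraction_unfolded follows the Gibbs-Helmholtz closed form", {
  p <- two_state_params(328.15, 50)
  expect_identical(fraction_unfolded(p, 328.15), 0.5)
  # frozen from the closed form: dG = 50*(1-298.15/328.15), K = exp(-dG/RT)
  expect_equal(fraction_unfolded(p, 298.15), 4.458349e-4, tolerance = 1e-6)
  # f(Tm) = 0.5 exactly for any valid parameter set, including dCp != 0
  for (tm in c(310, 328.15, 345)) {
    for (dcp in c(0, 0.5)) {
      expect_identical(
        fraction_unfolded(two_state_params(tm, 60, dcp), tm), 0.5)
    }
  }
  # strictly increasing in T for a cooperative transition
  Tv <- seq(300, 350, 0.5)
  expect_true(all(diff(fraction_unfolded(p, Tv)) > 0))
})

test_that("noiseless melt fits round-trip the generating parameters", {
  p <- base_params()
  fit <- fit_two_state(generate_melt_curve(p, 288, 348, 0.5))
  expect_true(fit$converged)
  expect_rel_equal(fit$params$T_m, 318, 1e-6)
  expect_rel_equal(fit$params$dH_m, 40, 1e-6)
  expect_lt(fit$residual_sd, 1e-8)
  # free-dCp mode round-trips a curve generated with dCp > 0
  p2 <- two_state_params(318, 60, 0.4, c(12, -0.012), c(5, -0.006))
  fit2 <- fit_two_state(generate_melt_curve(p2, 288, 348, 0.25), fix_dCp = FALSE)
  expect_rel_equal(fit2$params$T_m, 318, 1e-5)
  expect_rel_equal(fit2$params$dCp_unf, 0.4, 1e-3)
})

test_that("a 1 K stability difference is resolved at 1% noise", {
  sig_range <- abs(diff(range(two_state_signal(base_params(), c(288, 348)))))
  d <- replicate(60, NA_real_)
  for (s in seq_along(d)) {
    f1 <- fit_two_state(generate_melt_curve(base_params(318), 288, 348, 0.5,
                                            noise_spec(0.01 * sig_range, s)))
    f2 <- fit_two_state(generate_melt_curve(base_params(319), 288, 348, 0.5,
                                            noise_spec(0.01 * sig_range, s + 1000)))
    d[s] <- f1$params$T_m - f2$params$T_m
  }
  expect_lt(abs(median(d) - (-1)), 0.1)
})

test_that("ligand-stabilized curves keep their Tm ordering under noise", {
  # emulates DNA-bound vs apo melts: higher true Tm must fit higher
  sig_range <- abs(diff(range(two_state_signal(base_params(), c(288, 348)))))
  ok <- logical(100)
  for (s in seq_len(100)) {
    apo <- fit_two_state(generate_melt_curve(base_params(316), 288, 348, 0.5,
                                             noise_spec(0.01 * sig_range, s)))
    holo <- fit_two_state(generate_melt_curve(base_params(320), 288, 348, 0.5,
                                              noise_spec(0.01 * sig_range, s + 5000)))
    ok[s] <- holo$params$T_m > apo$params$T_m
  }
  expect_gte(sum(ok), 95)
})

test_that("degenerate melts are rejected, unit convention is invariant", {
  flat <- melt_curve(seq(288, 348, 1), rep(5, 61))
  expect_error(fit_two_state(flat), "no detectable transition")
  # Celsius I/O round-trip: writing and re-reading changes nothing
  p <- base_params()
  cv <- generate_melt_curve(p, 288, 348, 0.5, noise_spec(0.02, 3))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_experiment_table(cv, tmp)
  fit_disk <- fit_two_state(read_experiment_table(tmp, "melt"))
  fit_mem <- fit_two_state(cv)
  expect_equal(fit_disk$params$T_m, fit_mem$params$T_m, tolerance = 1e-9)
})
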