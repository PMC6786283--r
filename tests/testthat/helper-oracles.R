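# Independent oracles, deliberately implemented along different routes than
# the package code they check.

# ITC heats by numeric root-finding on the 1:1 mass balance (package code
# uses the closed-form quadratic root). Returns normalized heats, kcal/mol.
oracle_itc_normalized_heats <- function(n, K_d, dH, q_dil, design) {
  V0 <- design$cell_volume_uL
  dV <- cumsum(design$injection_volume_uL)
  Mt <- design$cell_conc_uM * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)) * 1e-6
  Xt <- design$syringe_conc_uM * (dV / V0) / (1 + dV / (2 * V0)) * 1e-6
  MX <- vapply(seq_along(Mt), function(i) {
    f <- function(mx) (n * Mt[i] - mx) * (Xt[i] - mx) - K_d * mx
    fp <- function(mx) -(Xt[i] - mx) - (n * Mt[i] - mx) - K_d
    upper <- min(n * Mt[i], Xt[i])
    if (upper <= 0) return(0)
    r <- stats::uniroot(f, c(0, upper), tol = .Machine$double.eps)$root
    for (it in 1:50) {                 # Newton polish to the noise floor
      step <- f(r) / fp(r)
      r <- min(upper, max(0, r - step))
      if (abs(step) <= 1e-15 * r) break
    }
    r
  }, numeric(1))
  V0_L <- V0 * 1e-6
  v_L <- design$injection_volume_uL * 1e-6
  MX_prev <- c(0, MX[-length(MX)])
  q_kcal <- V0_L * dH * (MX - MX_prev * (1 - v_L / V0_L))
  mol <- design$syringe_conc_uM * 1e-6 * v_L
  q_kcal / mol + q_dil
}

# Exact two-sided Mann-Whitney p by direct enumeration over the observed
# data (the package enumerates rank assignments; this walks label subsets).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("relative difference %.3g within %.3g",
                              max(abs(object - expected) / pmax(abs(expected), 1e-300)),
                              tol))
}
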