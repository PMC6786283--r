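#' Design of a single calorimetric titration
#'
#' Cell/syringe concentrations and the injection schedule of an overflow-cell
#' titration calorimeter. The macromolecule (protein) sits in the cell and the
#' titrant (DNA duplex) in the syringe, so the isotherm's molar-ratio axis is
#' titrant over macromolecule.
#'
#' @param cell_volume_uL active cell volume V0, uL
#' @param n_injections number of injections (>= 2)
#' @param injection_volume_uL volume per injection, uL (recycled to
#'   `n_injections`)
#' @param cell_conc_uM macromolecule concentration in the cell, uM
#' @param syringe_conc_uM titrant concentration in the syringe, uM
#' @param temperature_K experiment temperature, K
#' @param buffer_dH_ion buffer ionization enthalpy, kcal/mol
#' @param buffer optional buffer name label
#' @return an object of class `itc_design`
#' @export
itc_design <- function(cell_volume_uL = 200, n_injections = 20,
                       injection_volume_uL = 2, cell_conc_uM = 5,
                       syringe_conc_uM = 50, temperature_K = 298.15,
                       buffer_dH_ion = 0, buffer = NA_character_) {
  stopifnot(cell_volume_uL > 0, n_injections >= 2, all(injection_volume_uL > 0),
            cell_conc_uM > 0, syringe_conc_uM > 0, temperature_K > 0)
  structure(list(cell_volume_uL = cell_volume_uL,
                 n_injections = as.integer(n_injections),
                 injection_volume_uL = rep_len(injection_volume_uL, n_injections),
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 temperature_K = temperature_K,
                 buffer_dH_ion = buffer_dH_ion,
                 buffer = buffer),
            class = "itc_design")
}

#' Binding thermodynamics of a 1:1 protein-ligand interaction
#'
#' Holds fitted or ground-truth binding quantities. `dG` and `mTdS` are
#' derived so the identities `dG = RT ln(K_d)` (K_d in molar) and
#' `dG = dH + mTdS` hold exactly. The linkage layer adds the
#' buffer-independent enthalpy `dH0`, protons exchanged `n_H` (positive =
#' taken up from buffer, negative = released) and the binding heat capacity
#' `dCp` referenced to `T_ref`.
#'
#' @param n stoichiometry (sites per macromolecule)
#' @param K_d dissociation constant, M (> 0)
#' @param dH apparent binding enthalpy, kcal/mol (exothermic < 0)
#' @param T_K temperature at which `dG`/`mTdS` are evaluated, K
#' @param q_dil heat-of-dilution offset, kcal per mol of injectant
#' @param dH0 buffer-independent binding enthalpy, kcal/mol
#' @param n_H protons exchanged per complex (signed)
#' @param dCp binding heat capacity, kcal/(mol K)
#' @param T_ref reference temperature for `dCp`, K
#' @return an object of class `binding_thermo`
#' @export
binding_thermo <- function(n = 1, K_d, dH, T_K = 298.15, q_dil = 0,
                           dH0 = NA_real_, n_H = NA_real_, dCp = NA_real_,
                           T_ref = 298.15) {
  stopifnot(K_d > 0, is.finite(K_d), n > 0, T_K > 0)
  d <- derive_thermo(K_d, dH, T_K)
  structure(list(n = n, K_d = K_d, dH = dH, dG = d$dG, mTdS = d$mTdS,
                 T_K = T_K, q_dil = q_dil, dH0 = dH0, n_H = n_H,
                 dCp = dCp, T_ref = T_ref),
            class = "binding_thermo")
}

#' Gibbs energy and entropic term from K_d and dH
#'
#' `dG = RT ln(K_d)` with `K_d` in molar (so `K_d = 1 M` gives the
#' standard-state reference `dG = 0`), and `mTdS = dG - dH` so the
#' decomposition `dG = dH + mTdS` is exact.
#'
#' @param K_d dissociation constant, M
#' @param dH binding enthalpy, kcal/mol
#' @param T temperature, K
#' @return list with `dG` and `mTdS`, kcal/mol
#' @export
derive_thermo <- function(K_d, dH, T = 298.15) {
  stopifnot(K_d > 0, T > 0)
  dG <- R_KCAL * T * log(K_d)
  list(dG = dG, mTdS = dG - dH)
}

# per-injection cell concentrations under the overflow-cell dilution model.
# dV_i is the cumulative injected volume AFTER injection i.
itc_concentrations <- function(design) {
  V0 <- design$cell_volume_uL
  dV <- cumsum(design$injection_volume_uL)
  Mt <- design$cell_conc_uM * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  Xt <- design$syringe_conc_uM * (dV / V0) / (1 + dV / (2 * V0))
  list(Mt_uM = Mt, Xt_uM = Xt)
}

# bound-complex concentration (M) from the 1:1 quadratic mass balance;
# the rationalized root avoids catastrophic cancellation far from saturation
bound_complex <- function(n, K_d, Mt, Xt) {
  b <- n * Mt + Xt + K_d
  disc <- b^2 - 4 * n * Mt * Xt
  disc[disc < 0] <- 0
  2 * n * Mt * Xt / (b + sqrt(disc))
}

#' Simulate a noiseless single-site binding isotherm
#'
#' Forward model of the normalized injection heats of a 1:1 titration with
#' overflow-cell dilution. For injection i with cumulative injected volume
#' \eqn{\Delta V_i}, the cell macromolecule and titrant concentrations are
#' \deqn{M_i = M_0 \frac{1 - \Delta V_i/2V_0}{1 + \Delta V_i/2V_0}, \quad
#'       X_i = X_0 \frac{\Delta V_i/V_0}{1 + \Delta V_i/2V_0}}
#' the bound complex is the stable root of the quadratic mass balance, and
#' the heat of injection i is
#' \deqn{q_i = V_0 \Delta H ([MX]_i - [MX]_{i-1}(1 - v_i/V_0)) +
#'       q_{dil} \cdot n_{inj,i}}
#' At saturation incremental heats converge to the dilution offset.
#'
#' @param thermo a `binding_thermo` (uses `n`, `K_d`, `dH`, `q_dil`)
#' @param design an `itc_design`
#' @return numeric vector of normalized heats, kcal per mol of injectant
#' @export
simulate_isotherm <- function(thermo, design) {
  stopifnot(inherits(thermo, "binding_thermo"), inherits(design, "itc_design"))
  conc <- itc_concentrations(design)
  Mt <- conc$Mt_uM * 1e-6
  Xt <- conc$Xt_uM * 1e-6
  Kd <- thermo$K_d
  MX <- bound_complex(thermo$n, Kd, Mt, Xt)        # M
  V0_L <- design$cell_volume_uL * 1e-6
  v_L <- design$injection_volume_uL * 1e-6
  MX_prev <- c(0, MX[-length(MX)])
  q_bind_kcal <- V0_L * thermo$dH * (MX - MX_prev * (1 - v_L / V0_L))
  mol_inj <- design$syringe_conc_uM * 1e-6 * v_L
  (q_bind_kcal + thermo$q_dil * mol_inj) / mol_inj
}

#' Per-injection raw heats (ucal) for a design and truth
#'
#' Same model as [simulate_isotherm()], returned as instrument-style raw
#' heats in microcalories per injection.
#' @inheritParams simulate_isotherm
#' @return numeric vector, ucal
#' @export
simulate_heats_ucal <- function(thermo, design) {
  ndh <- simulate_isotherm(thermo, design)
  mol_inj <- design$syringe_conc_uM * 1e-6 * design$injection_volume_uL * 1e-6
  ndh * mol_inj * 1e9
}

#' Bundle raw injection heats with their design
#'
#' @param design an `itc_design`
#' @param heats_ucal per-injection heats, ucal (length `n_injections`)
#' @param condition optional condition label (variant, methylation state, pH)
#' @return an object of class `itc_experiment` with derived
#'   `normalized_heats` in kcal/mol injectant
#' @export
itc_experiment <- function(design, heats_ucal, condition = NA_character_) {
  stopifnot(inherits(design, "itc_design"),
            length(heats_ucal) == design$n_injections)
  mol_inj <- design$syringe_conc_uM * 1e-6 * design$injection_volume_uL * 1e-6
  structure(list(design = design,
                 heats_ucal = as.numeric(heats_ucal),
                 normalized_heats = heats_ucal * 1e-9 / mol_inj,
                 condition = condition),
            class = "itc_experiment")
}

#' Fit the single-binding-site model to a titration
#'
#' Levenberg-Marquardt least squares on normalized heats for
#' `(n, K_d, dH, q_dil)`, with `K_d` parameterized on the log scale. The
#' first injection is discarded by default (instrument convention: syringe
#' diffusion artifacts). The Wiseman c-value `n * [M]_cell / K_d` controls
#' identifiability; a warning flag is set when c < 1 or c > 1000, and when
#' the titration does not cross molar ratio 1.
#'
#' For low-c titrations (c below about 10) the stoichiometry is poorly
#' separable from `K_d` and `dH`; the standard rescue is to pin `n` at a
#' known value via `fix_n` and fit only `(K_d, dH, q_dil)`.
#'
#' @param exp an `itc_experiment`
#' @param discard_first drop injection 1 before fitting (default `TRUE`)
#' @param fix_n `NULL` (default) to fit the stoichiometry, or a number to
#'   hold it fixed (low-c convention)
#' @return a `binding_thermo` with fitted `n`, `K_d`, `dH`, `q_dil`, derived
#'   `dG`/`mTdS`, plus attributes: `se` (standard errors on n, log10_Kd, dH,
#'   q_dil), `converged`, `warnings` (character), `residual_sd`
#' @export
fit_single_site <- function(exp, discard_first = TRUE, fix_n = NULL) {
  stopifnot(inherits(exp, "itc_experiment"))
  design <- exp$design
  ndh <- exp$normalized_heats
  keep <- if (discard_first) -1L else seq_along(ndh)
  idx <- seq_along(ndh)[keep]
  y <- ndh[idx]
  if (length(y) < 6) stop("need at least 6 usable injections")
  if (all(y == 0)) stop("degenerate titration: all heats zero")

  conc <- itc_concentrations(design)
  ratio <- conc$Xt_uM / conc$Mt_uM
  warn <- character()
  if (max(ratio) < 1) warn <- c(warn, "titration does not cross molar ratio 1; K_d poorly determined")

  model_ndh <- function(n, log10Kd, dH, q_dil) {
    th <- binding_thermo(n = n, K_d = 10^log10Kd, dH = dH,
                         T_K = design$temperature_K, q_dil = q_dil)
    simulate_isotherm(th, design)[idx]
  }

  # deterministic data-driven starts; grid over log10 Kd picks the best SSR
  q_dil0 <- mean(utils::tail(y, 3))
  dH_tot <- y[1] - q_dil0
  n0 <- {
    half <- q_dil0 + dH_tot / 2
    cross <- which.min(abs(y - half))
    max(0.2, min(5, ratio[idx][cross]))
  }
  if (!is.null(fix_n)) n0 <- fix_n
  starts <- lapply(seq(-9, -4, by = 0.5), function(lk)
    list(n = n0, log10Kd = lk, dH = dH_tot, q_dil = q_dil0))
  ssr <- vapply(starts, function(s)
    sum((y - do.call(model_ndh, s))^2), numeric(1))
  start <- starts[[which.min(ssr)]]

  fit <- tryCatch(
    if (is.null(fix_n)) {
      minpack.lm::nlsLM(
        y ~ model_ndh(n, log10Kd, dH, q_dil),
        start = start,
        lower = c(0.05, -13, -Inf, -Inf), upper = c(10, -1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12))
    } else {
      minpack.lm::nlsLM(
        y ~ model_ndh(fix_n, log10Kd, dH, q_dil),
        start = start[c("log10Kd", "dH", "q_dil")],
        lower = c(-13, -Inf, -Inf), upper = c(-1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- binding_thermo(n = start$n, K_d = 10^start$log10Kd, dH = start$dH,
                          T_K = design$temperature_K, q_dil = start$q_dil)
    attr(res, "converged") <- FALSE
    attr(res, "warnings") <- c(warn, conditionMessage(fit))
    return(res)
  }

  co <- stats::coef(fit)
  if (!is.null(fix_n)) co <- c(n = fix_n, co)
  Kd <- 10^co[["log10Kd"]]
  cval <- co[["n"]] * design$cell_conc_uM * 1e-6 / Kd
  if (cval < 1) warn <- c(warn, sprintf("low c-value (%.2g): K_d weakly identified", cval))
  if (cval > 1000) warn <- c(warn, sprintf("high c-value (%.3g): K_d weakly identified", cval))

  res <- binding_thermo(n = co[["n"]], K_d = Kd, dH = co[["dH"]],
                        T_K = design$temperature_K, q_dil = co[["q_dil"]])
  rs <- stats::resid(fit)
  attr(res, "se") <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                              error = function(e) rep(NA_real_, 4))
  attr(res, "residual_sd") <- sqrt(sum(rs^2) / max(1, length(y) - 4))
  attr(res, "converged") <- isTRUE(fit$convInfo$isConv) ||
    isTRUE(fit$convInfo$stopCode %in% 1:3)
  attr(res, "warnings") <- warn
  attr(res, "c_value") <- cval
  res
}

#' Proton-linkage regression across buffers
#'
#' When complex formation exchanges protons with the buffer, the apparent
#' binding enthalpy depends linearly on the buffer ionization enthalpy:
#' \deqn{\Delta H_{app} = \Delta H_0 + n_H \, \Delta H_{ion}}
#' Ordinary least squares over titrations in buffers of different ionization
#' enthalpy returns the buffer-independent enthalpy (intercept) and the
#' number of protons exchanged (slope; negative = released to buffer under
#' this sign convention).
#'
#' When per-point measurement errors are supplied (the standard errors of
#' the fitted apparent enthalpies), the line is estimated by weighted least
#' squares and the reported parameter uncertainties combine, in quadrature,
#' the error propagated from the measurements with the residual-scatter
#' estimate — a deliberately conservative convention for the short series
#' (3-4 buffers) typical of linkage experiments.
#'
#' @param dH_apparent apparent enthalpies, kcal/mol
#' @param buffer_dH_ion buffer ionization enthalpies, kcal/mol (>= 2
#'   distinct values)
#' @param dH_se optional per-point standard errors of `dH_apparent`
#' @return list with `dH0`, `n_H`, their standard errors `dH0_se`, `n_H_se`,
#'   and the underlying `lm` fit
#' @export
linkage_regression <- function(dH_apparent, buffer_dH_ion, dH_se = NULL) {
  stopifnot(length(dH_apparent) == length(buffer_dH_ion),
            length(dH_apparent) >= 2)
  if (length(unique(buffer_dH_ion)) < 2)
    stop("singular design: all buffer ionization enthalpies equal")
  wls <- wls_line(buffer_dH_ion, dH_apparent, dH_se)
  list(dH0 = wls$intercept, n_H = wls$slope,
       dH0_se = wls$intercept_se, n_H_se = wls$slope_se,
       fit = wls$fit)
}

# straight line by (weighted) least squares; with known per-point sigma the
# parameter SEs combine the known-variance propagation and the residual
# estimate in quadrature
wls_line <- function(x, y, se = NULL) {
  if (is.null(se)) {
    fit <- stats::lm(y ~ x)
    co <- suppressWarnings(summary(fit))$coefficients
    return(list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
                intercept_se = unname(co[1, 2]), slope_se = unname(co[2, 2]),
                fit = fit))
  }
  stopifnot(length(se) == length(y), all(se > 0))
  w <- 1 / se^2
  fit <- stats::lm(y ~ x, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  # known-variance (z-type) covariance: (X' W X)^-1 with W = diag(1/se^2)
  X <- cbind(1, x)
  cov_known <- solve(t(X) %*% (w * X))
  se_known <- sqrt(diag(cov_known))
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       intercept_se = sqrt(se_known[1]^2 + unname(co[1, 2])^2),
       slope_se = sqrt(se_known[2]^2 + unname(co[2, 2])^2),
       fit = fit)
}

#' Binding heat capacity from the temperature dependence of dH
#'
#' OLS slope of apparent binding enthalpy against temperature:
#' \eqn{\Delta C_P = d\Delta H/dT}.
#'
#' @param T_K temperatures, K (>= 2 distinct)
#' @param dH apparent enthalpies, kcal/mol
#' @param dH_se optional per-point standard errors (same conservative
#'   weighting convention as [linkage_regression()])
#' @return list with `dCp` kcal/(mol K), `dCp_se`, and the `lm` fit
#' @export
heat_capacity_regression <- function(T_K, dH, dH_se = NULL) {
  stopifnot(length(T_K) == length(dH), length(T_K) >= 2)
  if (length(unique(T_K)) < 2)
    stop("singular design: need titrations at >= 2 temperatures")
  wls <- wls_line(T_K, dH, dH_se)
  list(dCp = wls$slope, dCp_se = wls$slope_se, fit = wls$fit)
}

#' Fold difference in affinity between two binding results
#'
#' `K_d(a) / K_d(b)`: values > 1 mean `a` binds more weakly (higher
#' dissociation constant) than `b`.
#'
#' @param a,b `binding_thermo` objects
#' @return unitless fold ratio
#' @export
compare_affinity <- function(a, b) {
  stopifnot(inherits(a, "binding_thermo"), inherits(b, "binding_thermo"),
            a$K_d > 0, b$K_d > 0)
  a$K_d / b$K_d
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat(sprintf("1:1 binding: n = %.3f, K_d = %.3g M (%.3g uM)\n",
              x$n, x$K_d, x$K_d * 1e6))
  cat(sprintf("  dG = %.2f, dH = %.2f, -TdS = %.2f kcal/mol at %.2f K\n",
              x$dG, x$dH, x$mTdS, x$T_K))
  if (!is.na(x$n_H) || !is.na(x$dCp))
    cat(sprintf("  linkage: dH0 = %.2f kcal/mol, n_H = %.3f, dCp = %.3f kcal/(mol K)\n",
                x$dH0, x$n_H, x$dCp))
  invisible(x)
}
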