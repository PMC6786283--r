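#' Parameters of the two-state thermal unfolding model
#'
#' Describes a cooperative folded/unfolded equilibrium followed by an optical
#' signal with linear pre- and post-transition baselines. The Gibbs energy of
#' unfolding at temperature T is
#' \deqn{\Delta G(T) = \Delta H_m (1 - T/T_m) -
#'   \Delta C_p [(T_m - T) + T \ln(T/T_m)]}
#' so that \eqn{\Delta G(T_m) = 0} and the unfolded fraction at `T_m` is 1/2.
#'
#' @param T_m mid-transition temperature, K
#' @param dH_m van't Hoff unfolding enthalpy at `T_m`, kcal/mol (> 0 for a
#'   cooperative transition)
#' @param dCp_unf unfolding heat capacity, kcal/(mol K); default 0 (short
#'   transition window)
#' @param baseline_folded numeric length-2, `c(intercept, slope)` of the
#'   folded-state signal (signal units, signal units per K)
#' @param baseline_unfolded numeric length-2 for the unfolded-state signal
#' @return an object of class `two_state_params`
#' @export
two_state_params <- function(T_m, dH_m, dCp_unf = 0,
                             baseline_folded = c(1, 0),
                             baseline_unfolded = c(0, 0)) {
  stopifnot(T_m > 0, is.finite(dH_m),
            length(baseline_folded) == 2, length(baseline_unfolded) == 2)
  structure(list(T_m = T_m, dH_m = dH_m, dCp_unf = dCp_unf,
                 baseline_folded = as.numeric(baseline_folded),
                 baseline_unfolded = as.numeric(baseline_unfolded)),
            class = "two_state_params")
}

#' Unfolded fraction of a two-state protein at temperature T
#'
#' Returns \eqn{K_U/(1+K_U)} with \eqn{K_U = \exp(-\Delta G(T)/(RT))} and the
#' Gibbs-Helmholtz \eqn{\Delta G(T)} of [two_state_params()]. Exactly 0.5 at
#' `T = T_m`, and strictly increasing in T when `dH_m > 0`.
#'
#' @param params a `two_state_params` object
#' @param T temperature(s), K; must be > 0
#' @return unfolded fraction(s) in (0, 1)
#' @export
fraction_unfolded <- function(params, T) {
  stopifnot(inherits(params, "two_state_params"), all(T > 0))
  dG <- params$dH_m * (1 - T / params$T_m) -
    params$dCp_unf * ((params$T_m - T) + T * log(T / params$T_m))
  if (any(!is.finite(dG))) stop("non-finite unfolding free energy")
  # logistic form avoids overflow of exp() far from the transition
  stats::plogis(-dG / (R_KCAL * T))
}

#' Noiseless two-state melt signal
#'
#' Baseline-weighted signal: `(1-f)*baseline_folded(T) + f*baseline_unfolded(T)`
#' with f from [fraction_unfolded()].
#'
#' @inheritParams fraction_unfolded
#' @return signal values, arbitrary fluorescence units
#' @export
two_state_signal <- function(params, T) {
  f <- fraction_unfolded(params, T)
  bf <- params$baseline_folded[1] + params$baseline_folded[2] * T
  bu <- params$baseline_unfolded[1] + params$baseline_unfolded[2] * T
  (1 - f) * bf + f * bu
}

#' Construct a melt curve
#'
#' @param temperature_K strictly increasing temperatures, K (>= 10 points)
#' @param signal fluorescence signal, arbitrary units
#' @param condition optional condition label (variant, ligand state, pH)
#' @return a data.frame of class `melt_curve` with columns `temperature_K`,
#'   `signal` and a `condition` attribute
#' @export
melt_curve <- function(temperature_K, signal, condition = NA_character_) {
  stopifnot(length(temperature_K) == length(signal),
            length(temperature_K) >= 10,
            all(diff(temperature_K) > 0))
  out <- data.frame(temperature_K = temperature_K, signal = signal)
  attr(out, "condition") <- condition
  class(out) <- c("melt_curve", "data.frame")
  out
}

# locate the transition midpoint from the extremum of a smoothed dS/dT;
# errors if no interior extremum exists (flat or truncated transitions)
locate_transition <- function(Tv, S) {
  if (diff(range(S)) == 0) stop("no detectable transition: constant signal")
  dS <- diff(S) / diff(Tv)
  Tmid <- (Tv[-1] + Tv[-length(Tv)]) / 2
  k <- max(3, min(11, floor(length(dS) / 5)))
  if (k %% 2 == 0) k <- k + 1
  sm <- stats::filter(dS, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  idx <- which.max(abs(sm))
  edge <- max(2, ceiling(0.02 * length(sm)))
  if (idx <= edge || idx > length(sm) - edge) {
    # tolerate a second, larger interior extremum before giving up
    interior <- abs(sm)
    interior[seq_len(edge)] <- 0
    interior[seq(length(sm) - edge + 1, length(sm))] <- 0
    if (max(interior) <= 0.25 * abs(sm[idx]))
      stop("no detectable transition: derivative extremum at grid edge")
    idx <- which.max(interior)
  }
  list(T_mid = Tmid[idx], slope = sm[idx])
}

#' Fit a two-state unfolding model to a melt curve
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) for
#' `(T_m, dH_m, baselines[, dCp_unf])`. Starting values are deterministic and
#' data-driven: `T_m` from the extremum of a smoothed signal derivative,
#' baselines from the outer 15% of points at each end, `dH_m` from the
#' transition slope at the midpoint via
#' \eqn{df/dT|_{T_m} = \Delta H_m / (4 R T_m^2)}.
#'
#' @param curve a `melt_curve`
#' @param fix_dCp if `TRUE` (default) the unfolding heat capacity is fixed at
#'   0; set `FALSE` to fit it (wide scans only)
#' @return an object of class `two_state_fit`: `params` (a
#'   `two_state_params`), `se` (named standard errors), `residual_sd`,
#'   `converged`
#' @export
fit_two_state <- function(curve, fix_dCp = TRUE) {
  stopifnot(inherits(curve, "melt_curve"))
  Tv <- curve$temperature_K
  S <- curve$signal
  tr <- locate_transition(Tv, S)
  Tm0 <- tr$T_mid

  n <- length(Tv)
  n_edge <- max(3, floor(0.15 * n))
  lo <- seq_len(n_edge)
  hi <- seq(n - n_edge + 1, n)
  bf <- stats::coef(stats::lm(S[lo] ~ Tv[lo]))
  bu <- stats::coef(stats::lm(S[hi] ~ Tv[hi]))

  d_sig <- (bu[1] + bu[2] * Tm0) - (bf[1] + bf[2] * Tm0)
  if (abs(d_sig) < .Machine$double.eps * max(abs(S)))
    stop("no detectable transition: baselines coincide")
  df_dT <- (tr$slope - (bf[2] + bu[2]) / 2) / d_sig
  dH0 <- 4 * R_KCAL * Tm0^2 * df_dT
  if (!is.finite(dH0) || dH0 <= 0) dH0 <- 50

  model <- function(T_m, dH_m, bf1, bf2, bu1, bu2, dCp) {
    p <- two_state_params(T_m, dH_m, dCp, c(bf1, bf2), c(bu1, bu2))
    two_state_signal(p, Tv)
  }
  start <- lapply(list(T_m = Tm0, dH_m = dH0, bf1 = bf[1], bf2 = bf[2],
                       bu1 = bu[1], bu2 = bu[2]), function(v) unname(as.numeric(v)))
  if (!fix_dCp) start$dCp <- 0

  fit <- if (fix_dCp) {
    minpack.lm::nlsLM(
      S ~ model(T_m, dH_m, bf1, bf2, bu1, bu2, 0),
      start = start,
      lower = c(min(Tv) - 50, 1e-3, rep(-Inf, 4)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
  } else {
    minpack.lm::nlsLM(
      S ~ model(T_m, dH_m, bf1, bf2, bu1, bu2, dCp),
      start = start,
      lower = c(min(Tv) - 50, 1e-3, rep(-Inf, 5)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
  }

  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  res <- stats::resid(fit)
  dof <- max(1, n - length(co))
  info <- fit$convInfo
  structure(list(
    params = two_state_params(co[["T_m"]], co[["dH_m"]],
                              if (fix_dCp) 0 else co[["dCp"]],
                              c(co[["bf1"]], co[["bf2"]]),
                              c(co[["bu1"]], co[["bu2"]])),
    se = se,
    residual_sd = sqrt(sum(res^2) / dof),
    converged = isTRUE(info$isConv) || isTRUE(info$stopCode %in% 1:3)
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Two-state unfolding fit: Tm = %.2f K (%.2f C), dHm = %.1f kcal/mol\n",
              p$T_m, kelvin_to_celsius(p$T_m), p$dH_m))
  cat(sprintf("  residual sd = %.4g; converged: %s\n",
              x$residual_sd, x$converged))
  invisible(x)
}
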