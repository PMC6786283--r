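#' First-order decay series (cycloheximide chase)
#'
#' @param time_h sampling times, h; non-negative and including 0
#' @param value normalized band intensity (1 at t = 0 by construction)
#' @param condition optional condition label
#' @return data.frame of class `decay_series`
#' @export
decay_series <- function(time_h, value, condition = NA_character_) {
  stopifnot(length(time_h) == length(value), all(time_h >= 0),
            any(time_h == 0), all(value > 0))
  out <- data.frame(time_h = time_h, value = value)
  attr(out, "condition") <- condition
  class(out) <- c("decay_series", "data.frame")
  out
}

#' FRAP recovery trace
#'
#' @param time_s frame times relative to the bleach, s; pre-bleach frames
#'   have negative times
#' @param intensity normalized intensity (pre-bleach plateau near 1)
#' @param condition optional label
#' @return data.frame of class `frap_trace` with `phase` column
#'   (`"pre"`/`"post"`)
#' @export
frap_trace <- function(time_s, intensity, condition = NA_character_) {
  stopifnot(length(time_s) == length(intensity))
  phase <- ifelse(time_s < 0, "pre", "post")
  if (!any(phase == "pre")) stop("normalization error: no pre-bleach frames")
  if (sum(phase == "post") < 10) stop("need >= 10 post-bleach frames")
  if (mean(intensity[phase == "pre"]) <= min(intensity[phase == "post"]))
    stop("invalid trace: pre-bleach mean not above post-bleach minimum")
  out <- data.frame(time_s = time_s, intensity = intensity, phase = phase)
  attr(out, "condition") <- condition
  class(out) <- c("frap_trace", "data.frame")
  out
}

kinetic_fit <- function(k, mobile_fraction = NA_real_, plateau = NA_real_,
                        floor = NA_real_, amplitude = NA_real_,
                        se = NULL, converged = TRUE, boundary = FALSE) {
  structure(list(k = k,
                 t_half = if (k > 0) log(2) / k else Inf,
                 mobile_fraction = mobile_fraction,
                 plateau = plateau, floor = floor, amplitude = amplitude,
                 se = se, converged = converged, boundary = boundary),
            class = "kinetic_fit")
}

#' Fit a first-order decay to a chase series
#'
#' Least squares on the linear scale for `A * exp(-k t)` with `A` free by
#' default (`pin_A = TRUE` fixes A = 1). `k >= 0` is enforced; a series with
#' no net decay returns a boundary fit with `k = 0` and infinite half-life,
#' flagged via `boundary = TRUE`.
#'
#' @param series a `decay_series` (>= 3 timepoints)
#' @param pin_A fix the amplitude at 1
#' @return a `kinetic_fit` with `k` (1/h), `t_half` (h), `amplitude`,
#'   standard errors, `converged` and `boundary` flags
#' @export
fit_decay <- function(series, pin_A = FALSE) {
  stopifnot(inherits(series, "decay_series"), nrow(series) >= 3)
  t <- series$time_h
  y <- series$value
  # slope-sign screen: a non-decreasing series pins k at the 0 boundary
  slope <- stats::coef(stats::lm(y ~ t))[2]
  if (slope >= 0 || diff(range(y)) == 0) {
    return(kinetic_fit(k = 0, amplitude = mean(y), boundary = TRUE,
                       converged = TRUE))
  }
  y_pos <- pmax(y, .Machine$double.eps)
  k0 <- if (pin_A) {
    max(1e-6, -stats::coef(stats::lm(log(y_pos) ~ t + 0))[1])
  } else {
    max(1e-6, -stats::coef(stats::lm(log(y_pos) ~ t))[2])
  }
  fit <- if (pin_A) {
    minpack.lm::nlsLM(y ~ exp(-k * t), start = list(k = k0), lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-12, ptol = 1e-12))
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-k * t), start = list(A = y[t == 0][1], k = k0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-12, ptol = 1e-12))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  kinetic_fit(k = unname(co[["k"]]),
              amplitude = if (pin_A) 1 else unname(co[["A"]]),
              se = se,
              converged = isTRUE(fit$convInfo$isConv) ||
                isTRUE(fit$convInfo$stopCode %in% 1:3),
              boundary = co[["k"]] <= 0)
}

#' Fit a single-exponential FRAP recovery
#'
#' Double normalization (divide by the pre-bleach mean), then least squares
#' for \eqn{F(t) = F_0 + (F_\infty - F_0)(1 - e^{-kt})} with t = 0 at the
#' first post-bleach frame. The mobile fraction is
#' \eqn{(F_\infty - F_0)/(1 - F_0)} and `t_half = ln 2 / k`, so the fitted
#' curve passes through \eqn{(F_0+F_\infty)/2} at one half-life.
#'
#' @param trace a `frap_trace`
#' @return a `kinetic_fit` with `k` (1/s), `t_half` (s), `mobile_fraction`,
#'   `plateau` (F-infinity), `floor` (F0)
#' @export
fit_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace$intensity[trace$phase == "pre"]
  if (length(pre) == 0) stop("normalization error: no pre-bleach frames")
  y <- trace$intensity[trace$phase == "post"] / mean(pre)
  t <- trace$time_s[trace$phase == "post"]
  t <- t - t[1]                       # t = 0 at first post-bleach frame

  F0_0 <- y[1]
  Finf_0 <- mean(utils::tail(y, max(3, floor(length(y) / 10))))
  if (diff(range(y)) == 0 || Finf_0 <= F0_0 + 1e-12) {
    # no recovery: flat post-bleach trace pins the rate at its boundary
    if (Finf_0 < F0_0 - 0.05) stop("invalid recovery: plateau below bleach floor")
    return(kinetic_fit(k = 0, mobile_fraction = 0, plateau = F0_0,
                       floor = F0_0, boundary = TRUE, converged = TRUE))
  }
  thalf0 <- {
    half <- (F0_0 + Finf_0) / 2
    i <- which(y >= half)[1]
    if (is.na(i) || t[i] <= 0) max(t) / 5 else t[i]
  }
  fit <- minpack.lm::nlsLM(
    y ~ F0 + (Finf - F0) * (1 - exp(-k * t)),
    start = list(F0 = F0_0, Finf = Finf_0, k = log(2) / thalf0),
    lower = c(-Inf, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  co <- stats::coef(fit)
  if (co[["Finf"]] < co[["F0"]])
    stop("invalid recovery: fitted plateau below bleach floor")
  mf <- (co[["Finf"]] - co[["F0"]]) / (1 - co[["F0"]])
  mf <- min(1, max(0, mf))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kinetic_fit(k = unname(co[["k"]]),
              mobile_fraction = unname(mf),
              plateau = unname(co[["Finf"]]), floor = unname(co[["F0"]]),
              se = se,
              converged = isTRUE(fit$convInfo$isConv) ||
                isTRUE(fit$convInfo$stopCode %in% 1:3),
              boundary = FALSE)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("First-order fit: k = %.4g, t_half = %.4g\n", x$k, x$t_half))
  if (!is.na(x$mobile_fraction))
    cat(sprintf("  mobile fraction = %.3f (floor %.3f, plateau %.3f)\n",
                x$mobile_fraction, x$floor, x$plateau))
  if (x$boundary) cat("  boundary fit (no detectable decay/recovery)\n")
  invisible(x)
}
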