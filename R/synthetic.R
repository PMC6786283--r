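#' Synthetic fluorescence melt curve
#'
#' Evaluates the two-state model of [two_state_signal()] on a monotone
#' temperature grid and adds i.i.d. Gaussian noise. With `noise$sd = 0` the
#' curve is pointwise equal to the closed-form model.
#'
#' @param params a `two_state_params` ground truth
#' @param t_start,t_end grid limits, K (`t_start < t_end`)
#' @param step grid step, K (> 0)
#' @param noise a [noise_spec()]
#' @param condition optional label
#' @return a `melt_curve`
#' @export
generate_melt_curve <- function(params, t_start, t_end, step = 0.25,
                                noise = noise_spec(0), condition = NA_character_) {
  if (step <= 0) stop("invalid grid: step must be > 0")
  stopifnot(t_start < t_end)
  Tv <- seq(t_start, t_end, by = step)
  mu <- two_state_signal(params, Tv)
  sig <- if (noise$sd > 0) {
    mu + with_seed(noise$seed, stats::rnorm(length(Tv), sd = noise$sd))
  } else mu
  melt_curve(Tv, sig, condition = condition)
}

#' Apparent binding enthalpy under proton linkage and heat capacity
#'
#' `dH_app = dH0 + n_H * buffer_dH_ion + dCp * (T - T_ref)`; missing linkage
#' fields in `truth` are treated as zero contribution.
#'
#' @param truth a `binding_thermo` with `dH0`, `n_H`, `dCp`, `T_ref` set
#'   (NA fields contribute 0)
#' @param design an `itc_design`
#' @return apparent enthalpy, kcal/mol
#' @export
apparent_dH <- function(truth, design) {
  dH0 <- if (is.na(truth$dH0)) truth$dH else truth$dH0
  nh <- if (is.na(truth$n_H)) 0 else truth$n_H
  dcp <- if (is.na(truth$dCp)) 0 else truth$dCp
  dH0 + nh * design$buffer_dH_ion + dcp * (design$temperature_K - truth$T_ref)
}

#' Synthetic calorimetric titration series
#'
#' One experiment per design. The apparent enthalpy of each experiment
#' follows the linkage relation of [apparent_dH()]; heats come from
#' [simulate_isotherm()] (which includes the heat-of-dilution offset in
#' `truth$q_dil`) with Gaussian noise of `noise$sd` microcalories added per
#' injection. Each experiment draws from its own child seed
#' ([child_seed()] of `noise$seed` with the experiment index), so extending
#' the design list never perturbs earlier experiments.
#'
#' @param truth a `binding_thermo` ground truth (linkage fields optional)
#' @param designs non-empty list of `itc_design`
#' @param noise a [noise_spec()]; `sd` in ucal per injection
#' @return list of `itc_experiment`
#' @export
generate_itc_series <- function(truth, designs, noise = noise_spec(0)) {
  stopifnot(inherits(truth, "binding_thermo"))
  if (length(designs) == 0) stop("empty design list")
  lapply(seq_along(designs), function(i) {
    design <- designs[[i]]
    stopifnot(inherits(design, "itc_design"))
    th <- binding_thermo(n = truth$n, K_d = truth$K_d,
                         dH = apparent_dH(truth, design),
                         T_K = design$temperature_K, q_dil = truth$q_dil)
    q <- simulate_heats_ucal(th, design)
    if (noise$sd > 0) {
      q <- q + with_seed(child_seed(noise$seed, i),
                         stats::rnorm(length(q), sd = noise$sd))
    }
    itc_experiment(design, q)
  })
}

#' Synthetic first-order decay series
#'
#' Noiseless value at time t is `exp(-t ln2 / t_half)`; `t_half = Inf` gives
#' the constant-1 (no turnover) limit. Noisy values are clipped to stay
#' positive (band intensities cannot be negative).
#'
#' @param t_half half-life, h (> 0; `Inf` allowed)
#' @param timepoints sampling times, h; non-negative, must include 0
#' @param noise a [noise_spec()]
#' @param condition optional label
#' @return a `decay_series`
#' @export
generate_decay_series <- function(t_half, timepoints, noise = noise_spec(0),
                                  condition = NA_character_) {
  if (any(timepoints < 0)) stop("negative timepoint")
  stopifnot(t_half > 0, any(timepoints == 0))
  mu <- if (is.finite(t_half)) exp(-timepoints * log(2) / t_half) else
    rep(1, length(timepoints))
  v <- if (noise$sd > 0) {
    pmax(mu + with_seed(noise$seed,
                        stats::rnorm(length(mu), sd = noise$sd)),
         1e-6)
  } else mu
  decay_series(timepoints, v, condition = condition)
}

#' Synthetic FRAP recovery trace
#'
#' Pre-bleach plateau at 1; the bleach drops the signal to
#' `F0 = 1 - bleach_depth`; recovery approaches the plateau
#' `Finf = F0 + mobile_fraction * (1 - F0)` as a single exponential with rate
#' `ln2 / t_half`.
#'
#' @param t_half half-maximal recovery time, s
#' @param mobile_fraction recoverable share of the bleached signal, in 0..1
#' @param bleach_depth fraction of signal removed by the bleach, in (0, 1]
#' @param timepoints post-bleach frame times, s (>= 10 frames, starting at 0)
#' @param noise a [noise_spec()]
#' @param n_prebleach number of pre-bleach frames (default 10)
#' @param condition optional label
#' @return a `frap_trace`
#' @export
generate_frap_trace <- function(t_half, mobile_fraction, bleach_depth,
                                timepoints, noise = noise_spec(0),
                                n_prebleach = 10, condition = NA_character_) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction outside [0, 1]")
  stopifnot(bleach_depth > 0, bleach_depth <= 1, t_half > 0,
            n_prebleach >= 1, all(timepoints >= 0))
  F0 <- 1 - bleach_depth
  Finf <- F0 + mobile_fraction * (1 - F0)
  mu_post <- F0 + (Finf - F0) * (1 - exp(-timepoints * log(2) / t_half))
  dt <- if (length(timepoints) > 1) stats::median(diff(timepoints)) else 1
  t_pre <- -rev(seq_len(n_prebleach)) * dt
  mu <- c(rep(1, n_prebleach), mu_post)
  v <- if (noise$sd > 0) {
    mu + with_seed(noise$seed, stats::rnorm(length(mu), sd = noise$sd))
  } else mu
  frap_trace(c(t_pre, timepoints), v, condition = condition)
}

#' Synthetic co-IP peptide-count table with planted interactors
#'
#' Plants `n_true` true interactors (at least 2 IP peptides, zero in both
#' controls), `n_background` background proteins (0-1 IP peptides, zero in
#' controls) and `n_contaminant` contaminants (at least 1 peptide in at least
#' one negative control). The planted truth is recorded in the
#' `true_interactors` attribute so recovery can be checked exactly.
#'
#' @param n_true,n_background,n_contaminant protein counts (>= 0)
#' @param seed integer seed
#' @param n_ip number of IP replicate columns (default 2)
#' @return a `peptide_table` with attribute `true_interactors`
#' @export
generate_peptide_table <- function(n_true, n_background, n_contaminant,
                                   seed = 1L, n_ip = 2) {
  stopifnot(n_true >= 0, n_background >= 0, n_contaminant >= 0, n_ip >= 1)
  roles <- c(rep("IP", n_ip), "blocked_control", "IgG_control")
  n_prot <- n_true + n_background + n_contaminant
  ids <- sprintf("PROT%04d", seq_len(max(1, n_prot)))[seq_len(n_prot)]
  counts <- matrix(0L, nrow = n_prot, ncol = length(roles),
                   dimnames = list(ids, paste0(roles, "_", seq_along(roles))))
  truth <- character(0)
  if (n_prot > 0) {
    with_seed(seed, {
      row <- 0L
      for (i in seq_len(n_true)) {
        row <- row + 1L
        # every true interactor carries >= 2 peptides in at least one IP
        counts[row, seq_len(n_ip)] <- c(sample(2:12, 1),
                                        sample(0:12, n_ip - 1, replace = TRUE))
      }
      truth <- ids[seq_len(n_true)]
      for (i in seq_len(n_background)) {
        row <- row + 1L
        counts[row, seq_len(n_ip)] <- sample(0:1, n_ip, replace = TRUE)
      }
      for (i in seq_len(n_contaminant)) {
        row <- row + 1L
        counts[row, seq_len(n_ip)] <- sample(0:8, n_ip, replace = TRUE)
        ctrl <- sample(c(n_ip + 1L, n_ip + 2L), 1)
        counts[row, ctrl] <- sample(1:6, 1)
        # the other control may or may not see the contaminant
        counts[row, setdiff(c(n_ip + 1L, n_ip + 2L), ctrl)] <-
          sample(0:3, 1)
      }
    })
    truth <- ids[seq_len(n_true)]
  }
  out <- peptide_table(counts, roles)
  attr(out, "true_interactors") <- truth
  out
}
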