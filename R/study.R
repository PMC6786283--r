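#' Affinity-fold recovery simulation for two isoform variants
#'
#' Drives the full ITC chain for the isoform comparison: per seed, one
#' titration is generated for each variant at its true dissociation constant,
#' both are fitted with [fit_single_site()], and the fitted affinity fold
#' `K_d(a) / K_d(b)` is recorded. Variant `a` is the weak binder (higher
#' `K_d`), so folds above 1 reproduce the weaker-affinity phenotype.
#'
#' @param kd_a,kd_b true dissociation constants, M
#' @param dH_a,dH_b true apparent binding enthalpies, kcal/mol
#' @param design an [itc_design()] shared by both variants
#' @param noise_sd per-injection heat noise, ucal
#' @param n_seeds number of simulated experiment pairs
#' @param seed global seed; seed pairs are expanded with [child_seed()]
#' @param q_dil heat-of-dilution offset, kcal/mol injectant
#' @param fix_n stoichiometry pinned during fitting (default 1: the
#'   constructs bind 1:1 and the weak variant sits at low c, where freeing n
#'   destroys K_d identifiability); `NULL` fits n
#' @return list with `folds` (per-seed fitted folds), `median_fold`,
#'   `true_fold`
#' @export
recover_affinity_fold <- function(kd_a, kd_b, dH_a, dH_b,
                                  design = itc_design(),
                                  noise_sd = 0.02, n_seeds = 50, seed = 1,
                                  q_dil = 0.5, fix_n = 1) {
  th_a <- binding_thermo(n = 1, K_d = kd_a, dH = dH_a,
                         T_K = design$temperature_K, q_dil = q_dil)
  th_b <- binding_thermo(n = 1, K_d = kd_b, dH = dH_b,
                         T_K = design$temperature_K, q_dil = q_dil)
  folds <- vapply(seq_len(n_seeds), function(s) {
    e_a <- generate_itc_series(th_a, list(design),
                               noise_spec(noise_sd, child_seed(seed, 2 * s)))[[1]]
    e_b <- generate_itc_series(th_b, list(design),
                               noise_spec(noise_sd, child_seed(seed, 2 * s + 1)))[[1]]
    compare_affinity(fit_single_site(e_a, fix_n = fix_n),
                     fit_single_site(e_b, fix_n = fix_n))
  }, numeric(1))
  list(folds = folds, median_fold = stats::median(folds),
       true_fold = kd_a / kd_b)
}

#' Linkage-chain recovery simulation
#'
#' Per seed: generate one titration per buffer (and optionally per
#' temperature) from a linkage-aware ground truth, fit each with
#' [fit_single_site()], then regress the fitted apparent enthalpies with
#' [linkage_regression()] and [heat_capacity_regression()] using the fits'
#' enthalpy standard errors as weights.
#'
#' @param truth a [binding_thermo()] with `dH0`, `n_H`, `dCp`, `T_ref` set
#' @param buffer_dH_ion buffer ionization enthalpies for the buffer series,
#'   kcal/mol
#' @param temperatures_K temperatures for the heat-capacity series, K
#' @param design base [itc_design()] (buffer/temperature fields overridden)
#' @param noise_sd per-injection heat noise, ucal
#' @param seed integer seed
#' @param n_replicates titrations per buffer/temperature condition
#'   (default 2; every replicate contributes a point to the regression)
#' @return list with `linkage` (from [linkage_regression()]) and `heat_cap`
#'   (from [heat_capacity_regression()]), each carrying estimates and SEs
#' @export
recover_linkage_chain <- function(truth, buffer_dH_ion, temperatures_K,
                                  design = itc_design(), noise_sd = 0.02,
                                  seed = 1, n_replicates = 2) {
  fit_one <- function(des, stream) {
    e <- generate_itc_series(truth, list(des),
                             noise_spec(noise_sd, child_seed(seed, stream)))[[1]]
    f <- fit_single_site(e)
    se <- attr(f, "se")
    list(dH = f$dH, dH_se = if (is.null(se)) NA_real_ else unname(se[["dH"]]))
  }
  expand <- function(values, alter, offset) {
    idx <- rep(seq_along(values), each = n_replicates)
    fits <- lapply(seq_along(idx), function(j) {
      des <- alter(design, values[idx[j]])
      fit_one(des, offset + j)
    })
    list(x = values[idx],
         dH = vapply(fits, `[[`, 0, "dH"),
         se = vapply(fits, `[[`, 0, "dH_se"))
  }
  buf <- expand(buffer_dH_ion,
                function(d, v) { d$buffer_dH_ion <- v; d }, 0)
  tmp <- expand(temperatures_K,
                function(d, v) { d$temperature_K <- v; d }, 1000)
  usable <- function(se) if (all(is.finite(se)) && all(se > 0)) se else NULL
  list(
    linkage = linkage_regression(buf$dH, buf$x, dH_se = usable(buf$se)),
    heat_cap = heat_capacity_regression(tmp$x, tmp$dH,
                                        dH_se = usable(tmp$se)))
}
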