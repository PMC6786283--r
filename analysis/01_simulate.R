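#!/usr/bin/env Rscript
# Generate one synthetic dataset per instrument type, in the CSV dialects
# the fitting stages read. These stand in for the study's raw exports:
# fluorescence melts for the two isoform fragments (apo and DNA-bound),
# calorimetric titrations across buffers, chase decays, FRAP traces and a
# co-IP peptide table with planted interactors.

suppressMessages(library(isophys))
seed <- 20260925
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# melts: E1-like fragment slightly less stable than E2-like; DNA binding
# stabilizes both
melts <- list(
  E1_apo  = 316, E2_apo  = 317.2,
  E1_mCpG = 319, E2_mCpG = 321
)
for (nm in names(melts)) {
  p <- two_state_params(melts[[nm]], 40,
                        baseline_folded = c(12, -0.012),
                        baseline_unfolded = c(5, -0.006))
  cv <- generate_melt_curve(p, 288, 348, 0.5,
                            noise_spec(0.07, child_seed(seed, match(nm, names(melts)))),
                            condition = nm)
  write_experiment_table(cv, file.path(out, paste0("melt_", nm, ".csv")))
}

# titrations: weak enthalpy-driven binder (E1-like) vs tight entropy-driven
# binder (E2-like), four buffers of distinct ionization enthalpy
buffers <- c(phosphate = 0.86, pipes = 2.74, hepes = 4.88, tris = 11.35)
des <- itc_design(cell_conc_uM = 5, syringe_conc_uM = 50,
                  injection_volume_uL = 2, n_injections = 35)
truths <- list(
  E1 = binding_thermo(n = 1, K_d = 9e-7, dH = -8, q_dil = 0.5,
                      dH0 = -8, n_H = -0.5, dCp = -0.3),
  E2 = binding_thermo(n = 1, K_d = 1e-7, dH = -3, q_dil = 0.5,
                      dH0 = -3, n_H = -0.2, dCp = -0.1)
)
for (iso in names(truths)) {
  designs <- lapply(unname(buffers), function(h) {
    d <- des; d$buffer_dH_ion <- h; d
  })
  exps <- generate_itc_series(truths[[iso]], designs,
                              noise_spec(0.02, child_seed(seed, 10 + match(iso, names(truths)))))
  for (i in seq_along(exps)) {
    exps[[i]]$design$buffer <- names(buffers)[i]
    exps[[i]]$condition <- iso
    write_experiment_table(exps[[i]],
                           file.path(out, sprintf("itc_%s_%s.csv", iso, names(buffers)[i])))
  }
}

# chase decays: E1-like turns over faster than E2-like
chase <- c(E1 = 3, E2 = 6)
for (iso in names(chase)) {
  d <- generate_decay_series(chase[[iso]], c(0, 2, 4, 8),
                             noise_spec(0.05, child_seed(seed, 20 + match(iso, names(chase)))),
                             condition = iso)
  write_experiment_table(d, file.path(out, paste0("chase_", iso, ".csv")))
}

# FRAP traces: similar recovery parameters for both isoforms
frap <- list(E1 = c(t_half = 6.0, mf = 0.78), E2 = c(t_half = 7.5, mf = 0.74))
for (iso in names(frap)) {
  tr <- generate_frap_trace(frap[[iso]]["t_half"], frap[[iso]]["mf"], 0.8,
                            seq(0, 60, 0.4),
                            noise_spec(0.01, child_seed(seed, 30 + match(iso, names(frap)))),
                            condition = iso)
  write_experiment_table(tr, file.path(out, paste0("frap_", iso, ".csv")))
}

# co-IP peptide table with planted interactors
pt <- generate_peptide_table(n_true = 10, n_background = 50,
                             n_contaminant = 10, seed = child_seed(seed, 40))
long <- data.frame(
  protein = rep(rownames(pt$counts), times = ncol(pt$counts)),
  sample = rep(colnames(pt$counts), each = nrow(pt$counts)),
  role = rep(pt$roles, each = nrow(pt$counts)),
  peptides = as.vector(pt$counts))
write.csv(long, file.path(out, "coip_peptides.csv"), row.names = FALSE,
          quote = FALSE)
writeLines(attr(pt, "true_interactors"), file.path(out, "coip_truth.txt"))

cat("wrote", length(list.files(out)), "files to", out, "\n")
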