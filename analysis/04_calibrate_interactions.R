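#!/usr/bin/env Rscript
# Two-step model <-> measurement matching. Step 1: invert the computed
# thickness-vs-cohesion curve at the measured NTR-free film thickness to
# obtain eps_pp. Step 2: scan the NTR-FG attraction eps_pc and minimize the
# squared log-difference between model and measured binding isotherms over
# 0.025-10 uM. Runs the full pipeline on the synthetic study measurement
# and, separately, round-trip recoveries at the published reference
# parameters (see reference_interactions()).

library(fgfilm)

dir.create("results", showWarnings = FALSE)
geom <- cylinder_geometry(height = 90, dz = 0.75, radially_uniform = TRUE)
conc_set <- 10^seq(log10(0.025), 1, length.out = 9L)
scan <- read.csv("results/thickness_scan.csv")

rows <- list()

# -- full pipeline on the synthetic study measurement (Nsp1-like film,
#    pristine thickness 30 nm, Hill isotherm gamma_max 2, K 1, alpha 0.71)
cal_pp <- calibrate_epp(30 / 600, scan[scan$fg_domain == "Nsp1", ],
                        measured_err = 0.002)
exp_iso <- generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.71,
                                     noise_cv = 0, d0 = 30, seed = 7)
cal_pc <- calibrate_epc(exp_iso, fit_hill(exp_iso), eps_pp = cal_pp$eps_pp,
                        conc_set = conc_set, geom = geom)
message(sprintf("pipeline best match: eps_pp %.4f kBT, eps_pc %.3f kBT",
                cal_pp$eps_pp, cal_pc$eps_pc))
rows$pipeline <- data.frame(system = "Nsp1/NTF2 (synthetic study)",
                            eps_pp = cal_pp$eps_pp, eps_pc = cal_pc$eps_pc,
                            mode = "pipeline")

# -- round-trip recoveries at the published reference parameters
ref <- reference_interactions()
for (dom in c("Nsp1", "Nup98-glyco")) {
  meas <- synthetic_thickness_measurement(dom, geom = geom)
  pp <- calibrate_epp(meas$per_aa, scan[scan$fg_domain == dom, ],
                      measured_err = meas$per_aa_err)
  message(sprintf("recovered eps_pp(%s) = %.4f (reference %.3f)",
                  dom, pp$eps_pp, meas$eps_pp_true))
  rows[[paste0("pp_", dom)]] <- data.frame(
    system = paste0(dom, " (thickness recovery)"), eps_pp = pp$eps_pp,
    eps_pc = NA_real_, mode = "recovery")
}
for (sys in list(c("Nsp1", "NTF2"), c("Nup98-glyco", "NTF2"),
                 c("reg-FSFG", "NTF2"))) {
  meas <- synthetic_isotherm_measurement(sys[1], sys[2], conc = conc_set,
                                         geom = geom)
  curve <- approxfun(meas$curve$c_NTR, meas$curve$gamma_NTR, rule = 2)
  pc <- calibrate_epc(exp_curve = curve,
                      eps_pp = ref$eps_pp[ref$fg_domain == sys[1]],
                      conc_set = conc_set, geom = geom,
                      fg_domain = sys[1], ntr = sys[2])
  message(sprintf("recovered eps_pc(%s on %s) = %.3f (reference %.2f)",
                  sys[2], sys[1], pc$eps_pc, meas$eps_pc_true))
  rows[[paste(sys, collapse = "_")]] <- data.frame(
    system = paste0(sys[2], "/", sys[1], " (isotherm recovery)"),
    eps_pp = ref$eps_pp[ref$fg_domain == sys[1]], eps_pc = pc$eps_pc,
    mode = "recovery")
}

# Impb: published point lies below the 6 nm colloid's binding onset in this
# functional; calibrate against a synthetic experimental isotherm instead
imp <- generate_isotherm_dataset(fg_domain = "Nsp1", ntr = "Impb",
                                 gamma_max = 1.2, K_05 = 1.5, alpha = 0.71,
                                 noise_cv = 0, seed = 11)
cal_imp <- calibrate_epc(imp, fit_hill(imp),
                         eps_pp = ref$eps_pp[ref$fg_domain == "Nsp1"],
                         eps_pc_grid = seq(0.3, 0.6, by = 0.02),
                         conc_set = conc_set, geom = geom,
                         fg_domain = "Nsp1", ntr = "Impb")
message(sprintf("pipeline eps_pc(Impb on Nsp1) = %.3f", cal_imp$eps_pc))
rows$impb <- data.frame(system = "Impb/Nsp1 (pipeline)",
                        eps_pp = ref$eps_pp[ref$fg_domain == "Nsp1"],
                        eps_pc = cal_imp$eps_pc, mode = "pipeline")

tab <- do.call(rbind, rows)
write.csv(tab, "results/interaction_parameters.csv", row.names = FALSE)
message("wrote results/interaction_parameters.csv")
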