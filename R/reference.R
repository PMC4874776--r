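#' Reference interaction parameters for NPC-like FG-domain films
#'
#' Published best-match contact energies (kBT) for the three FG-domain
#' constructs and the two NTRs studied with this model: the FG-FG
#' cohesiveness `eps_pp` determined from NTR-free film thickness, and the
#' NTR-FG attraction `eps_pc` determined from binding isotherms. These
#' values serve as the ground truth when constructing synthetic
#' pseudo-measurements for calibration round-trip checks (the original
#' titration source tables are not redistributed with the package).
#'
#' @return data.frame with columns `fg_domain`, `eps_pp`, `eps_pp_err`,
#'   `eps_pc_NTF2`, `eps_pc_NTF2_err`, `eps_pc_Impb`, `eps_pc_Impb_err`
#'   (NA where no isotherm was measured).
#' @export
reference_interactions <- function() {
  data.frame(
    fg_domain = c("Nsp1", "Nup98-glyco", "reg-FSFG"),
    eps_pp = c(0.024, 0.030, 0.030),
    eps_pp_err = c(0.001, 0.002, 0.005),
    eps_pc_NTF2 = c(0.34, 0.36, 0.40),
    eps_pc_NTF2_err = c(0.02, 0.02, 0.02),
    eps_pc_Impb = c(0.40, NA, NA),
    eps_pc_Impb_err = c(0.02, NA, NA)
  )
}

#' Synthetic pseudo-measurements for calibration round-trips
#'
#' Generates "measured" film observables from the model itself at the
#' reference interaction parameters of [reference_interactions()]:
#' `synthetic_thickness_measurement()` returns the NTR-free
#' thickness-per-amino-acid a film with the reference `eps_pp` would show,
#' and `synthetic_isotherm_measurement()` the binding isotherm a film with
#' the reference (`eps_pp`, `eps_pc`) pair would show. Feeding these back
#' into [calibrate_epp()] / [calibrate_epc()] checks that the calibration
#' machinery recovers known parameters; the data are synthetic, not
#' experimental.
#'
#' @param fg_domain,ntr system selection.
#' @param geom,grafting_density,control as in [solve_film()].
#' @param conc concentrations for the isotherm, uM.
#' @return `synthetic_thickness_measurement()`: list with `per_aa`,
#'   `per_aa_err` (propagated from the reference `eps_pp_err`) and
#'   `eps_pp_true`. `synthetic_isotherm_measurement()`: list with `curve`
#'   (data.frame `c_NTR`, `gamma_NTR`), `eps_pp_true`, `eps_pc_true`.
#' @export
synthetic_thickness_measurement <- function(fg_domain = "Nsp1",
                                            geom = cylinder_geometry(radially_uniform = TRUE),
                                            grafting_density = 5.5,
                                            control = film_control()) {
  ref <- reference_interactions()
  row <- ref[ref$fg_domain == fg_domain, ]
  polymer <- fg_polymer_spec(fg_domain, grafting_density)
  per_aa_at <- function(e) {
    f <- solve_film(geom, polymer, params = interaction_params(eps_pp = e),
                    control = control)
    film_thickness(f, thresholds = 0.05,
                   n_amino_acids = polymer$n_amino_acids)$d_per_aa[[1L]]
  }
  val <- per_aa_at(row$eps_pp)
  lo <- per_aa_at(row$eps_pp + row$eps_pp_err)
  hi <- per_aa_at(row$eps_pp - row$eps_pp_err)
  list(per_aa = val, per_aa_err = (hi - lo) / 2,
       eps_pp_true = row$eps_pp, fg_domain = fg_domain)
}

#' @rdname synthetic_thickness_measurement
#' @export
synthetic_isotherm_measurement <- function(fg_domain = "Nsp1", ntr = "NTF2",
                                           conc = 10^seq(log10(0.025), 1,
                                                         length.out = 13L),
                                           geom = cylinder_geometry(radially_uniform = TRUE),
                                           grafting_density = 5.5,
                                           control = film_control()) {
  ref <- reference_interactions()
  row <- ref[ref$fg_domain == fg_domain, ]
  eps_pc <- if (ntr == "NTF2") row$eps_pc_NTF2 else row$eps_pc_Impb
  if (is.na(eps_pc))
    stop("no reference eps_pc for ", ntr, " on ", fg_domain, call. = FALSE)
  iso <- model_isotherm(fg_domain = fg_domain, ntr = ntr,
                        eps_pp = row$eps_pp, eps_pc = eps_pc, conc = conc,
                        geom = geom, grafting_density = grafting_density,
                        control = control)
  list(curve = iso, eps_pp_true = row$eps_pp, eps_pc_true = eps_pc,
       fg_domain = fg_domain, ntr = ntr)
}
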