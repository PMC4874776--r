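#' Unit conversions for areal densities and solution concentrations
#'
#' Grafted-film experiments report areal molar densities \eqn{\Gamma} in
#' pmol/cm2, while molecular models count molecules per area. With Avogadro's
#' number, 1 pmol/cm2 corresponds to 0.602 molecules per 100 nm2 (commonly
#' quoted as 0.6).
#'
#' @param x areal density in pmol/cm2 (or molecules per 100 nm2 for the
#'   inverse direction). Must be finite and non-negative.
#' @return the converted value, same length as `x`.
#' @examples
#' pmol_to_molecules(1)    # ~0.6 molecules per 100 nm2
#' pmol_to_molecules(5.5)  # ~3.3 molecules per 100 nm2
#' molecules_to_pmol(pmol_to_molecules(2.7))
#' @export
pmol_to_molecules <- function(x) {
  check_nonneg(x, "x")
  # 1 pmol/cm2 = 1e-12 mol/cm2 * N_A / 1e14 nm2/cm2 * 100 nm2
  x * (.N_A * 1e-24)
}

#' @rdname pmol_to_molecules
#' @export
molecules_to_pmol <- function(x) {
  check_nonneg(x, "x")
  x / (.N_A * 1e-24)
}

#' Convert a molar solution concentration to a number density
#'
#' Maps a micromolar concentration to molecules per nm3, the scale on which
#' the film model's colloid reservoir activity is set.
#'
#' @param c_uM concentration in micromol/L; finite and non-negative.
#' @return number density in nm^-3.
#' @examples
#' molar_to_number_density(1)  # 6.022e-7 nm^-3
#' @export
molar_to_number_density <- function(c_uM) {
  check_nonneg(c_uM, "c_uM")
  # 1 uM = 1e-6 mol/L * N_A / 1e24 nm3/L
  c_uM * (.N_A * 1e-30)
}

#' Estimate the FG-domain grafting density of a nuclear pore channel
#'
#' Treats the NPC central channel as a cylinder and spreads the FG domains
#' over its lateral wall area \eqn{\pi D L}. The count per 100 nm2 is
#' converted to pmol/cm2 with the conventional factor 0.6 molecules per
#' 100 nm2 per pmol/cm2, and the result rounded to one decimal, matching how
#' such estimates are usually quoted.
#'
#' @param n_domains number of FG domains anchored in the channel (e.g. ~136
#'   for the yeast NPC).
#' @param diameter,length channel dimensions in nm; both must be positive.
#' @return grafting density in pmol/cm2, rounded to 1 decimal place.
#' @examples
#' npc_grafting_density(136, diameter = 40, length = 35)  # 5.2
#' npc_grafting_density(136, diameter = 35, length = 30)  # 6.9
#' @export
npc_grafting_density <- function(n_domains, diameter, length) {
  if (any(!is.finite(c(n_domains, diameter, length))) ||
      any(c(n_domains, diameter, length) <= 0))
    stop("`n_domains`, `diameter` and `length` must be positive and finite",
         call. = FALSE)
  per_100nm2 <- 100 * n_domains / (pi * diameter * length)
  round(per_100nm2 / 0.6, 1)
}

#' Areal mass and molar density from ellipsometric film parameters
#'
#' de Feijter's relation converts an optical film thickness and refractive
#' index contrast into an areal mass density,
#' \eqn{\Gamma = d_{SE} \Delta n / (dn/dc)}, and with the molar mass into an
#' areal molar density. A value of dn/dc = 0.18 cm3/g is the standard
#' refractive index increment for protein films.
#'
#' @param d_se optical film thickness, nm (>= 0).
#' @param delta_n refractive index difference between film and buffer
#'   (dimensionless).
#' @param mw molar mass of the film species, g/mol (> 0).
#' @param dndc refractive index increment, cm3/g (> 0).
#' @return list with `mass_ng_cm2` (areal mass density, ng/cm2) and
#'   `gamma_pmol_cm2` (areal molar density, pmol/cm2).
#' @examples
#' de_feijter_density(d_se = 10, delta_n = 0.018, mw = 64100)
#' @export
de_feijter_density <- function(d_se, delta_n, mw, dndc = 0.18) {
  if (!is.finite(dndc) || dndc <= 0)
    stop("`dndc` must be positive", call. = FALSE)
  if (!is.finite(mw) || mw <= 0)
    stop("`mw` must be positive", call. = FALSE)
  check_nonneg(d_se, "d_se")
  # d [nm] * dn / (dn/dc [cm3/g]) = 1e-7 cm * g/cm3 = 1e2 ng/cm2
  mass <- 100 * d_se * delta_n / dndc
  list(mass_ng_cm2 = mass, gamma_pmol_cm2 = 1e3 * mass / mw)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}
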