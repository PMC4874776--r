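#' Iso-density film thickness
#'
#' The local film thickness at radius r is the largest height at which the
#' polymer packing fraction still reaches a defined fraction (1%, 5% or 10%)
#' of its maximum within the film; the reported thickness is the
#' 2-pi-r-weighted average of these local values across the cylinder. The 5%
#' threshold is the default working definition; the three thresholds always
#' satisfy d(1%) >= d(5%) >= d(10%).
#'
#' @param fields a `density_fields` object.
#' @param thresholds iso-density fractions of the maximal packing.
#' @param n_amino_acids when given, per-amino-acid thicknesses are reported
#'   as well (thickness divided by the number of represented amino acids).
#' @return list with `d` (named vector, nm), optionally `d_per_aa` (nm per
#'   amino acid), `local` (matrix of local thickness per radius and
#'   threshold) and `phi_max`.
#' @export
film_thickness <- function(fields, thresholds = c(0.01, 0.05, 0.10),
                           n_amino_acids = NULL) {
  phi <- fields$phi_p
  phi_max <- max(phi)
  if (phi_max <= 0)
    stop("polymer field is identically zero; thickness undefined",
         call. = FALSE)
  nr <- nrow(phi)
  wts <- if (fields$radially_uniform) rep(1, nr) else fields$r
  wts <- wts / sum(wts)
  local <- sapply(thresholds, function(th) {
    lim <- th * phi_max
    vapply(seq_len(nr), function(i) {
      idx <- which(phi[i, ] >= lim)
      if (!length(idx)) 0 else fields$z[max(idx)] + fields$dz / 2
    }, numeric(1L))
  })
  local <- matrix(local, nrow = nr)
  d <- colSums(local * wts)
  names(d) <- sprintf("d_%gpct", thresholds * 100)
  out <- list(d = d, local = local, thresholds = thresholds,
              phi_max = phi_max)
  if (!is.null(n_amino_acids)) out$d_per_aa <- d / n_amino_acids
  out
}

#' Areal density of film-bound colloids
#'
#' Integrates the colloid excess over the reservoir density along z and
#' averages radially (with the 2-pi-r weight) either over the full cylinder
#' cross-section or over its central part of half the diameter; comparing
#' the two quantifies side-wall artifacts. The excess is converted to
#' pmol/cm2.
#'
#' @param fields a `density_fields` object carrying a colloid field.
#' @param region `"full"` or `"central50"` (central half-diameter).
#' @return list with `gamma` (pmol/cm2), the `excess` number per nm2, and
#'   the region used.
#' @export
bound_colloid_density <- function(fields, region = c("full", "central50")) {
  region <- match.arg(region)
  if (is.null(fields$phi_c))
    stop("fields carry no colloid density", call. = FALSE)
  v_c <- pi / 6 * fields$colloid_diameter^3
  rho <- fields$phi_c / v_c
  excess_z <- colSums_weighted(rho - fields$bulk_colloid_density, fields,
                               region) * fields$dz
  excess <- sum(excess_z)
  list(gamma = excess / 6.02214076e-3, excess_per_nm2 = excess,
       region = region)
}

# 2-pi-r-weighted radial average per z slice, restricted to a region
colSums_weighted <- function(mat, fields, region = "full") {
  nr <- nrow(mat)
  wts <- if (fields$radially_uniform) rep(1, nr) else fields$r
  keep <- rep(TRUE, nr)
  if (region == "central50") {
    if (!fields$radially_uniform) keep <- fields$r <= fields$radius / 2
    if (!any(keep)) stop("region is narrower than one grid cell",
                         call. = FALSE)
  } else if (region != "full") stop("unknown region", call. = FALSE)
  w <- wts * keep
  colSums(mat * (w / sum(w)))
}

#' Axial packing-fraction profiles
#'
#' Radially averaged (2-pi-r weighted) polymer and colloid packing fractions
#' as a function of the distance from the grafting surface.
#'
#' @param fields a `density_fields` object.
#' @return data.frame with `z`, `phi_p`, `phi_c` (NA without colloids), plus
#'   attribute `phi_p_max` (the maximum of the radially averaged polymer
#'   profile).
#' @export
axial_profiles <- function(fields) {
  phi_p_z <- colSums_weighted(fields$phi_p, fields)
  phi_c_z <- if (!is.null(fields$phi_c))
    colSums_weighted(fields$phi_c, fields) else rep(NA_real_, length(fields$z))
  out <- data.frame(z = fields$z, phi_p = phi_p_z, phi_c = phi_c_z)
  attr(out, "phi_p_max") <- max(phi_p_z)
  out
}

#' Fraction of film material below the iso-density thickness
#'
#' @param fields a `density_fields` object.
#' @param threshold iso-density fraction defining the thickness.
#' @return fraction of the total polymer material lying below the local
#'   iso-density thickness.
#' @export
material_fraction_below <- function(fields, threshold = 0.05) {
  th <- film_thickness(fields, thresholds = threshold)
  vol <- field_cell_volumes(fields)
  below <- outer(th$local[, 1L], fields$z, ">=")
  sum(fields$phi_p * below * vol) / sum(fields$phi_p * vol)
}

#' Order-of-magnitude contact count and binding energy of an embedded colloid
#'
#' Estimates how many polymer beads touch a colloid surrounded by polymer at
#' a given packing fraction: beads whose centres lie within half a bead
#' diameter of the hard-contact distance count as contacts, i.e. the bead
#' density times the volume of the shell [R_c, R_c + bead radius] around the
#' colloid, with R_c = (colloid + bead diameter)/2. The binding energy is
#' `n_contacts * eps_pc`. This is a deliberately rough, order-of-magnitude
#' estimate.
#'
#' @param colloid a [colloid_spec()] (or a diameter in nm).
#' @param packing local polymer packing fraction (0 to 0.74).
#' @param eps_pc polymer-colloid contact energy, kBT.
#' @param bead_diameter bead diameter, nm.
#' @return list with `n_contacts` and `binding_energy` (kBT).
#' @examples
#' contact_energy_estimate(colloid_spec("NTF2"), packing = 0.2, eps_pc = 0.34)
#' @export
contact_energy_estimate <- function(colloid, packing, eps_pc = 0,
                                    bead_diameter = 0.76) {
  dia <- if (inherits(colloid, "colloid_spec")) colloid$diameter else colloid
  stopifnot(packing >= 0, packing <= 0.74)
  r_in <- (dia + bead_diameter) / 2
  r_out <- r_in + bead_diameter / 2
  shell_vol <- 4 / 3 * pi * (r_out^3 - r_in^3)
  v_bead <- pi / 6 * bead_diameter^3
  n <- packing / v_bead * shell_vol
  list(n_contacts = n, binding_energy = n * eps_pc,
       shell = c(r_in = r_in, r_out = r_out))
}
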