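#' The 12-step up-titration concentration grid
#'
#' Standard concentration series (uM) used for the NTR titrations emulated by
#' the generator.
#'
#' @return numeric vector of 12 concentrations, 0.0025 to 10 uM.
#' @export
titration_grid <- function() {
  c(0.0025, 0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 3, 5, 7.5, 10)
}

#' Generate one synthetic titration dataset
#'
#' Emulates a measured NTR binding isotherm: bound areal densities follow a
#' Hill law on the titration grid, multiplied by lognormal noise with unit
#' mean and coefficient of variation `noise_cv` (spectroscopic areal
#' densities carry an approximately constant relative error). The concomitant
#' film thickness follows `d0 * (1 + s * Gamma/gamma_max)`, reproducing the
#' observed moderate (5--35%) thickness increase at saturating NTR
#' concentrations. Output is deterministic for a fixed seed.
#'
#' @param fg_domain,ntr,gamma_FG film metadata (see [isotherm_dataset()]).
#' @param gamma_max,K_05,alpha Hill parameters of the underlying isotherm
#'   (pmol/cm2, uM, dimensionless).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param d0 thickness of the pristine film, nm.
#' @param thickness_rise fractional thickness increase at saturation.
#' @param conc concentration grid, uM; strictly increasing.
#' @param full_range mark the dataset as covering the full fitting window;
#'   inferred from `conc` when `NULL`.
#' @param seed RNG seed (required; the generator never touches the global
#'   RNG state).
#' @return an [isotherm_dataset()].
#' @export
generate_isotherm_dataset <- function(fg_domain = "Nsp1", ntr = "NTF2",
                                      gamma_FG = 5.5, gamma_max = 2,
                                      K_05 = 1, alpha = 0.71,
                                      noise_cv = 0.05, d0 = 30,
                                      thickness_rise = 0.2,
                                      conc = titration_grid(),
                                      full_range = NULL, seed) {
  stopifnot(noise_cv >= 0, alpha > 0, gamma_max > 0, K_05 > 0,
            all(diff(conc) > 0))
  with_seed(seed, {
    hill <- gamma_max * conc^alpha / (K_05^alpha + conc^alpha)
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log1p(noise_cv^2))
      rlnorm(length(conc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(conc))
    gamma <- hill * noise
    thickness <- d0 * (1 + thickness_rise * gamma / gamma_max)
    isotherm_dataset(fg_domain = fg_domain, ntr = ntr, gamma_FG = gamma_FG,
                     c_NTR = conc, gamma_NTR = gamma, thickness = thickness,
                     full_range = full_range)
  })
}

#' Generate a family of synthetic isotherms sharing one Hill coefficient
#'
#' Produces `n_datasets` titration curves with a common Hill coefficient and
#' per-dataset `gamma_max` and `K_05` drawn log-uniformly from the given
#' ranges, mimicking the spread seen across FG-domain types and grafting
#' densities. A fixed fraction of the family (by default 3 of 10) is
#' truncated below 0.2 uM and flagged as not covering the full fitting
#' window, mirroring titrations that missed the low-concentration regime.
#'
#' @param n_datasets number of curves.
#' @param alpha common Hill coefficient.
#' @param gamma_max_range,K_05_range sampling ranges (pmol/cm2, uM).
#' @param n_partial how many curves to truncate below 0.2 uM.
#' @param noise_cv,conc,seed as in [generate_isotherm_dataset()].
#' @return list of [isotherm_dataset()] objects.
#' @export
generate_dataset_family <- function(n_datasets = 10L, alpha = 0.71,
                                    gamma_max_range = c(0.5, 5),
                                    K_05_range = c(0.3, 3),
                                    n_partial = max(0L, round(n_datasets * 0.3)),
                                    noise_cv = 0.05,
                                    conc = titration_grid(), seed) {
  stopifnot(n_partial <= n_datasets)
  combos <- expand.grid(ntr = ntr_names(), fg_domain = fg_domain_names(),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    pars <- data.frame(
      gamma_max = exp(runif(n_datasets, log(gamma_max_range[1L]),
                            log(gamma_max_range[2L]))),
      K_05 = exp(runif(n_datasets, log(K_05_range[1L]), log(K_05_range[2L]))),
      gamma_FG = runif(n_datasets, 4, 11)
    )
    seeds <- sample.int(.Machine$integer.max, n_datasets)
    partial <- if (n_partial > 0L)
      seq(n_datasets - n_partial + 1L, n_datasets) else integer()
    lapply(seq_len(n_datasets), function(i) {
      cmb <- combos[(i - 1L) %% nrow(combos) + 1L, ]
      grid_i <- if (i %in% partial) conc[conc >= 0.2] else conc
      generate_isotherm_dataset(
        fg_domain = cmb$fg_domain, ntr = cmb$ntr, gamma_FG = pars$gamma_FG[i],
        gamma_max = pars$gamma_max[i], K_05 = pars$K_05[i], alpha = alpha,
        noise_cv = noise_cv, conc = grid_i,
        full_range = !(i %in% partial), seed = seeds[i])
    })
  })
}

#' Analytic density-field fixtures for testing the observables
#'
#' Builds a `density_fields` object from a closed-form axial profile so that
#' film thickness and excess integrals are known exactly: a uniform slab of
#' height `h`, a linear ramp vanishing at `h`, or a slab with a Gaussian
#' interface of width `w` centred at `h`. Optionally adds a uniform colloid
#' excess slab of height `h_c` and excess number density `excess_c` on top of
#' a uniform bulk density.
#'
#' @param profile profile shape for the polymer packing fraction.
#' @param phi0 plateau packing fraction.
#' @param h characteristic height, nm.
#' @param w Gaussian interface width, nm.
#' @param radius,height,dr,dz grid geometry, nm.
#' @param bulk_c bulk colloid number density, nm^-3.
#' @param excess_c uniform excess colloid number density inside `z <= h_c`.
#' @param h_c height of the colloid excess slab, nm.
#' @param colloid_diameter colloid diameter, nm (for packing fractions).
#' @return a `density_fields` object (see [solve_film()]).
#' @export
generate_slab_fixture <- function(profile = c("uniform", "ramp", "gaussian"),
                                  phi0 = 0.2, h = 30, w = 2,
                                  radius = 20, height = 60, dr = 2, dz = 0.5,
                                  bulk_c = 0, excess_c = 0, h_c = h,
                                  colloid_diameter = 4) {
  profile <- match.arg(profile)
  nr <- max(1L, round(radius / dr))
  nz <- round(height / dz)
  z <- (seq_len(nz) - 0.5) * dz
  phi_z <- switch(profile,
    uniform = ifelse(z <= h, phi0, 0),
    ramp = pmax(0, phi0 * (1 - z / h)),
    gaussian = phi0 * stats::pnorm(h, mean = z, sd = w))
  phi_p <- matrix(rep(phi_z, each = nr), nrow = nr)
  v_c <- pi / 6 * colloid_diameter^3
  rho_c_z <- bulk_c + ifelse(z <= h_c, excess_c, 0)
  phi_c <- matrix(rep(rho_c_z * v_c, each = nr), nrow = nr)
  new_density_fields(
    phi_p = phi_p, phi_c = if (bulk_c > 0 || excess_c > 0) phi_c else NULL,
    radius = nr * dr, height = height, dr = dr, dz = dz,
    radially_uniform = FALSE,
    bead_diameter = 0.76, colloid_diameter = colloid_diameter,
    n_beads_total = NA_real_, bulk_colloid_density = bulk_c,
    convergence = list(converged = TRUE, iterations = 0L, residual = 0),
    source = sprintf("slab fixture (%s)", profile))
}
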