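#' Model components: geometry, polymer, colloid and interaction parameters
#'
#' The film model represents FG domains as freely-jointed chains of beads of
#' 0.76 nm diameter and bond length (a Kuhn length of twice the contour
#' length of an amino acid, giving a persistence length of 0.38 nm that
#' mirrors unfolded polypeptides), end-grafted to the bottom of a cylinder of
#' 100 nm diameter and 120 nm height. NTRs are hard spheres (4.0 nm for the
#' NTF2 homodimer, 6.0 nm for Importin beta) exchanging with a bulk
#' reservoir. Attractions are exponential tails with a 1 nm decay length;
#' `eps_pp` and `eps_pc` are the polymer-polymer and polymer-colloid contact
#' energies in kBT (colloid-colloid attraction is zero).
#'
#' `cylinder_geometry()` defines the numerical cell. With
#' `radially_uniform = TRUE` the film is treated as laterally infinite
#' (single radial cell, no side walls) — the fast configuration used for
#' isotherm scans; otherwise zero-density boundary conditions apply at the
#' side walls, polymers see hard walls at top and bottom, and colloids are
#' periodic in z.
#'
#' @param radius,height cylinder radius and height, nm.
#' @param dr,dz grid spacings, nm; `dz` must not exceed the bead diameter.
#' @param radially_uniform collapse the radial direction (laterally infinite
#'   film)?
#' @return object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(radius = 50, height = 120, dr = 2.5, dz = 0.5,
                              radially_uniform = FALSE) {
  stopifnot(radius > 0, height > 0, dr > 0, dz > 0)
  if (dz > 0.76 + 1e-9)
    stop("`dz` must not exceed the bead diameter (0.76 nm)", call. = FALSE)
  nr <- if (radially_uniform) 1L else max(2L, as.integer(round(radius / dr)))
  nz <- as.integer(round(height / dz))
  structure(list(radius = radius, height = height,
                 dr = if (radially_uniform) radius else radius / nr,
                 dz = height / nz, nr = nr, nz = nz,
                 radially_uniform = radially_uniform),
            class = "cylinder_geometry")
}

#' @rdname cylinder_geometry
#' @param fg_domain FG-domain construct; sets the chain length: 300 beads
#'   (Nsp1), 260 (Nup98-glyco), 155 (reg-FSFG), each bead representing two
#'   amino acids.
#' @param grafting_density chains per area, pmol/cm2.
#' @export
fg_polymer_spec <- function(fg_domain = "Nsp1", grafting_density = 5.5) {
  fg_domain <- match.arg(fg_domain, fg_domain_names())
  stopifnot(grafting_density > 0)
  n_beads <- c(Nsp1 = 300L, `Nup98-glyco` = 260L, `reg-FSFG` = 155L)[[fg_domain]]
  structure(list(fg_domain = fg_domain, n_beads = n_beads,
                 bead_diameter = 0.76, bond_length = 0.76,
                 n_amino_acids = 2L * n_beads,
                 grafting_density = grafting_density),
            class = "fg_polymer_spec")
}

#' @rdname cylinder_geometry
#' @param ntr NTR type (`"NTF2"` 4.0 nm, `"Impb"` 6.0 nm) or `NULL` when
#'   giving `diameter` directly.
#' @param diameter colloid diameter, nm.
#' @param bulk_concentration reservoir concentration, uM.
#' @export
colloid_spec <- function(ntr = NULL, diameter = NULL, bulk_concentration = 1) {
  if (is.null(diameter)) {
    ntr <- match.arg(ntr, ntr_names())
    diameter <- c(NTF2 = 4.0, Impb = 6.0)[[ntr]]
  }
  stopifnot(diameter > 0, bulk_concentration >= 0)
  structure(list(ntr = ntr, diameter = diameter,
                 bulk_concentration = bulk_concentration),
            class = "colloid_spec")
}

#' @rdname cylinder_geometry
#' @param eps_pp,eps_pc contact energies, kBT (>= 0).
#' @param decay_length tail decay length, nm.
#' @export
interaction_params <- function(eps_pp = 0, eps_pc = 0, decay_length = 1) {
  stopifnot(eps_pp >= 0, eps_pc >= 0, decay_length > 0)
  structure(list(eps_pp = eps_pp, eps_pc = eps_pc, eps_cc = 0,
                 decay_length = decay_length),
            class = "interaction_params")
}

#' Hard-core plus exponential-tail pair potential
#'
#' The generic attraction used throughout the model: infinitely repulsive
#' inside the contact distance, and \eqn{-\epsilon \exp(-(r - r_c)/\lambda)}
#' beyond it, so that `eps` is the energy gained on bringing the pair from
#' infinite separation to hard contact.
#'
#' @param r centre-centre distances, nm (>= 0).
#' @param eps contact energy, kBT.
#' @param contact_distance hard-core contact distance, nm.
#' @param decay_length tail decay length, nm.
#' @return potential energies in kBT (`Inf` inside the core).
#' @examples
#' pair_potential(0.76, eps = 0.3, contact_distance = 0.76)  # -0.3
#' @export
pair_potential <- function(r, eps, contact_distance, decay_length = 1) {
  check_nonneg(r, "r")
  ifelse(r < contact_distance, Inf,
         -eps * exp(-(r - contact_distance) / decay_length))
}

#' Solver control settings
#'
#' @param tol convergence tolerance on the maximum change of the species
#'   potentials between Picard iterations, kBT.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   carrying the residual history.
#' @param mix,mix_min,mix_max initial and bounding values of the adaptive
#'   Picard mixing parameter.
#' @param phi_cap packing fraction at which the hard-sphere free energy is
#'   capped.
#' @param on_fail `"error"` or `"warn"` on non-convergence.
#' @export
film_control <- function(tol = 1e-6, max_iter = 4000L, mix = 0.05,
                         mix_min = 1e-3, mix_max = 0.25, phi_cap = 0.65,
                         on_fail = c("error", "warn")) {
  list(tol = tol, max_iter = as.integer(max_iter), mix = mix,
       mix_min = mix_min, mix_max = mix_max, phi_cap = phi_cap,
       on_fail = match.arg(on_fail))
}

# exact z-projection of the uniform spherical bond shell onto grid offsets
shell_weights_1d <- function(b, dz) {
  kmax <- ceiling((b + 0.5 * dz) / dz)
  k <- seq(-kmax, kmax)
  lo <- pmax((k - 0.5) * dz, -b)
  hi <- pmin((k + 0.5) * dz, b)
  w <- pmax(0, hi - lo) / (2 * b)
  keep <- w > 0
  list(k = k[keep], w = w[keep])
}

# bond-shell kernel as interpolation triplets (receiver r, source r, z
# offset, weight); weight lost at the side wall implements the zero-density
# boundary condition
make_shell_kernel <- function(geom, b, n_delta = 24L, n_phi = 16L) {
  key <- paste("shell", geom$nr, geom$nz, signif(geom$dr, 10),
               signif(geom$dz, 10), signif(b, 10), signif(geom$radius, 10),
               sep = "|")
  memoize(key, function() build_shell_kernel(geom, b, n_delta, n_phi))
}

build_shell_kernel <- function(geom, b, n_delta = 24L, n_phi = 16L) {
  dz <- geom$dz
  if (geom$nr == 1L) {
    w1 <- shell_weights_1d(b, dz)
    return(list(rec = rep(0L, length(w1$k)), src = rep(0L, length(w1$k)),
                dz = as.integer(w1$k), w = w1$w))
  }
  dr <- geom$dr
  nr <- geom$nr
  r_cent <- (seq_len(nr) - 0.5) * dr
  deltas <- (seq_len(n_delta) - 0.5) / n_delta * 2 * b - b
  phis <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  acc <- new.env(parent = emptyenv())
  add <- function(rec, src, dzo, w) {
    key <- paste(rec, src, dzo, sep = ",")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
  }
  for (i in seq_len(nr)) {
    ri <- r_cent[i]
    for (d in deltas) {
      s <- sqrt(max(0, b^2 - d^2))
      zf <- d / dz
      z0 <- floor(zf)
      wz1 <- zf - z0
      for (ph in phis) {
        rp <- sqrt(ri^2 + s^2 + 2 * ri * s * cos(ph))
        if (rp > geom$radius) next  # beyond the side wall: density is zero
        fr <- rp / dr + 0.5
        i0 <- floor(fr)
        wr1 <- fr - i0
        base_w <- 1 / (n_delta * n_phi)
        for (rz in list(c(z0, 1 - wz1), c(z0 + 1, wz1))) {
          if (rz[2] <= 0) next
          for (rr in list(c(i0, 1 - wr1), c(i0 + 1, wr1))) {
            if (rr[2] <= 0) next
            src <- min(max(rr[1], 1), nr)  # clamp to axis / last ring centre
            if (rr[1] > nr) next           # outside the wall
            add(i - 1L, as.integer(src) - 1L, as.integer(rz[1]),
                base_w * rz[2] * rr[2])
          }
        }
      }
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  list(rec = as.integer(parts[, 1L]), src = as.integer(parts[, 2L]),
       dz = as.integer(parts[, 3L]),
       w = vapply(keys, function(k) acc[[k]], numeric(1L), USE.NAMES = FALSE))
}

# laterally integrated mean-field attraction for the radially uniform cell.
# In the mean-field convolution the attraction is continued at -eps through
# the core region (van der Waals convention): a local-density treatment with
# g(r) = 1 would otherwise underweight the contact-shell attraction.
# Closed form of the in-plane integral of -eps exp(-(max(d, sig) - sig)/lambda).
lateral_tail_integral <- function(dzv, eps, sig, lambda) {
  a <- pmax(sig, abs(dzv))
  tail_part <- -eps * 2 * pi * lambda * (a + lambda) * exp(-(a - sig) / lambda)
  core_part <- ifelse(abs(dzv) < sig, -eps * pi * (sig^2 - dzv^2), 0)
  tail_part + core_part
}

# kernels depend only on geometry and contact distances, not on the contact
# energies (the tail is linear in eps); memoize the expensive unit kernels
.kernel_memo <- new.env(parent = emptyenv())

memoize <- function(key, build) {
  if (is.null(.kernel_memo[[key]])) .kernel_memo[[key]] <- build()
  .kernel_memo[[key]]
}

# mean-field attraction kernel K[rec, src, k]: ring-integrated tail times the
# source cell volume, so that U = K * rho is in kBT
make_attraction_kernel <- function(geom, eps, sig, lambda = 1,
                                   n_phi = 24L, n_sub = 3L) {
  key <- paste("attr", geom$nr, geom$nz, signif(geom$dr, 10),
               signif(geom$dz, 10), signif(sig, 10), signif(lambda, 10),
               sep = "|")
  unit <- memoize(key, function()
    build_attraction_kernel(geom, 1, sig, lambda, n_phi, n_sub))
  list(K = unit$K * eps, knz = unit$knz)
}

build_attraction_kernel <- function(geom, eps, sig, lambda = 1,
                                    n_phi = 24L, n_sub = 3L) {
  dz <- geom$dz
  kcut <- as.integer(ceiling((sig + 8 * lambda) / dz))
  ks <- seq(-kcut, kcut)
  if (geom$nr == 1L) {
    K <- array(lateral_tail_integral(ks * dz, eps, sig, lambda) * dz,
               dim = c(1L, 1L, length(ks)))
    return(list(K = K, knz = length(ks)))
  }
  nr <- geom$nr
  dr <- geom$dr
  r_cent <- (seq_len(nr) - 0.5) * dr
  r_edges <- seq(0, nr) * dr
  vol <- pi * diff(r_edges^2) * dz
  phis <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  sub <- (seq_len(n_sub) - 0.5) / n_sub - 0.5
  K <- array(0, dim = c(nr, nr, length(ks)))
  for (k in seq_along(ks)) {
    zd <- ks[k] * dz
    for (j in seq_len(nr)) {
      rs <- r_cent[j] + sub * dr
      for (i in seq_len(nr)) {
        d <- sqrt(outer(r_cent[i]^2 + rs^2 + zd^2, rep(1, n_phi)) -
                    2 * r_cent[i] * outer(rs, cos(phis)))
        u <- -eps * exp(-(pmax(d, sig) - sig) / lambda)
        K[i, j, k] <- mean(u) * vol[j]
      }
    }
  }
  list(K = K, knz = length(ks))
}

#' Solve for the equilibrium polymer and colloid density fields
#'
#' Self-consistent mean-field solution for end-grafted cohesive bead-chains
#' with (optionally) grand-canonical absorbing colloids. Chain connectivity
#' uses the exact freely-jointed-chain propagator; hard cores enter through a
#' local hard-sphere-mixture (BMCSL) excess free energy; attractions are
#' mean-field convolutions of the exponential tails. The colloid reservoir
#' activity is the bulk number density of the given molar concentration
#' (ideal reservoir; at micromolar concentrations bulk crowding is
#' negligible). The solver is deterministic for fixed grid and tolerances.
#'
#' @param geom a [cylinder_geometry()].
#' @param polymer an [fg_polymer_spec()].
#' @param colloid a [colloid_spec()], or `NULL` for an NTR-free film.
#' @param params an [interaction_params()].
#' @param control a [film_control()].
#' @param init a previous `density_fields` solution used as warm start (same
#'   geometry), or `NULL`.
#' @param kernels optional precomputed kernel set from [film_kernels()] to
#'   amortize setup across repeated solves.
#' @return an object of class `density_fields`: packing-fraction matrices
#'   `phi_p`, `phi_c` (nr x nz), grid vectors `r`, `z`, and a `convergence`
#'   report.
#' @export
solve_film <- function(geom, polymer, colloid = NULL,
                       params = interaction_params(),
                       control = film_control(), init = NULL,
                       kernels = NULL) {
  stopifnot(inherits(geom, "cylinder_geometry"),
            inherits(polymer, "fg_polymer_spec"))
  if (!is.null(colloid)) stopifnot(inherits(colloid, "colloid_spec"))
  if (is.null(kernels))
    kernels <- film_kernels(geom, polymer, colloid, params)
  nr <- geom$nr; nz <- geom$nz
  r_edges <- seq(0, nr) * geom$dr
  vol <- if (geom$radially_uniform) geom$dz else pi * diff(r_edges^2) * geom$dz
  area <- if (geom$radially_uniform) 1 else pi * geom$radius^2
  sigma_nm2 <- polymer$grafting_density * 6.02214076e-3  # pmol/cm2 -> nm^-2
  n_chains <- sigma_nm2 * area
  has_col <- !is.null(colloid) && colloid$bulk_concentration > 0
  z_act <- if (has_col) molar_to_number_density(colloid$bulk_concentration) else 0
  d_c <- if (!is.null(colloid)) colloid$diameter else 1
  cmask <- rep(1L, nr)
  if (!geom$radially_uniform && !is.null(colloid)) {
    r_cent <- (seq_len(nr) - 0.5) * geom$dr
    cmask <- as.integer(r_cent <= geom$radius - d_c / 2)
  }
  wp0 <- matrix(0, nr, nz); wc0 <- matrix(0, nr, nz)
  if (!is.null(init)) {
    stopifnot(ncol(init$wp) == nz)
    if (nrow(init$wp) == nr) {
      wp0 <- init$wp
      if (!is.null(init$wc)) wc0 <- init$wc
    } else if (nrow(init$wp) == 1L) {
      # broadcast a radially uniform solution across the cylinder radius
      wp0 <- matrix(init$wp[1L, ], nr, nz, byrow = TRUE)
      if (!is.null(init$wc))
        wc0 <- matrix(init$wc[1L, ], nr, nz, byrow = TRUE)
    } else stop("warm start has incompatible grid", call. = FALSE)
  }
  sol <- .scf_solve(nr, nz, vol, cmask,
                    kernels$shell$rec, kernels$shell$src, kernels$shell$dz,
                    kernels$shell$w,
                    kernels$Kpp$K, kernels$Kpp$knz,
                    kernels$Kpc$K, kernels$Kpc$knz,
                    polymer$n_beads, n_chains,
                    has_col, z_act,
                    polymer$bead_diameter, d_c,
                    control$phi_cap, 100,
                    wp0, wc0,
                    control$tol, control$max_iter,
                    control$mix, control$mix_min, control$mix_max)
  if (!sol$converged) {
    msg <- sprintf(
      "film solver did not converge in %d iterations (residual %.3g)",
      sol$iterations, sol$residual)
    if (control$on_fail == "error") {
      cond <- simpleError(msg)
      cond$res_hist <- sol$res_hist
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  v_p <- pi / 6 * polymer$bead_diameter^3
  v_c <- pi / 6 * d_c^3
  new_density_fields(
    phi_p = sol$rho_p * v_p,
    phi_c = if (has_col) sol$rho_c * v_c else NULL,
    radius = geom$radius, height = geom$height, dr = geom$dr, dz = geom$dz,
    radially_uniform = geom$radially_uniform,
    bead_diameter = polymer$bead_diameter, colloid_diameter = d_c,
    n_beads_total = n_chains * polymer$n_beads,
    bulk_colloid_density = z_act,
    convergence = list(converged = sol$converged,
                       iterations = sol$iterations,
                       residual = sol$residual,
                       res_hist = tail(sol$res_hist, 50L)),
    source = "mean-field solver",
    wp = sol$wp, wc = if (has_col) sol$wc else NULL,
    polymer = polymer, colloid = colloid, params = params)
}

#' @rdname solve_film
#' @export
film_kernels <- function(geom, polymer, colloid = NULL,
                         params = interaction_params()) {
  b <- polymer$bond_length
  shell <- make_shell_kernel(geom, b)
  Kpp <- make_attraction_kernel(geom, params$eps_pp, polymer$bead_diameter,
                                params$decay_length)
  sig_pc <- (polymer$bead_diameter +
               (if (!is.null(colloid)) colloid$diameter else 1)) / 2
  Kpc <- make_attraction_kernel(geom, params$eps_pc, sig_pc,
                                params$decay_length)
  list(shell = shell, Kpp = Kpp, Kpc = Kpc)
}

new_density_fields <- function(phi_p, phi_c, radius, height, dr, dz,
                               radially_uniform, bead_diameter,
                               colloid_diameter, n_beads_total,
                               bulk_colloid_density, convergence, source,
                               wp = NULL, wc = NULL, polymer = NULL,
                               colloid = NULL, params = NULL) {
  nr <- nrow(phi_p); nz <- ncol(phi_p)
  structure(list(
    phi_p = phi_p, phi_c = phi_c,
    r = (seq_len(nr) - 0.5) * dr, z = (seq_len(nz) - 0.5) * dz,
    radius = radius, height = height, dr = dr, dz = dz,
    radially_uniform = radially_uniform,
    bead_diameter = bead_diameter, colloid_diameter = colloid_diameter,
    n_beads_total = n_beads_total,
    bulk_colloid_density = bulk_colloid_density,
    convergence = convergence, source = source,
    wp = wp, wc = wc, polymer = polymer, colloid = colloid, params = params
  ), class = "density_fields")
}

#' @export
print.density_fields <- function(x, ...) {
  cat(sprintf(
    "<density_fields> %d x %d grid (dr %.3g, dz %.3g nm), %s\n  max phi_p %.4g%s\n",
    nrow(x$phi_p), ncol(x$phi_p), x$dr, x$dz, x$source, max(x$phi_p),
    if (!is.null(x$phi_c)) sprintf(", max phi_c %.4g", max(x$phi_c)) else ""))
  invisible(x)
}

# radial cell volumes (nm^3) for a density_fields object
field_cell_volumes <- function(f) {
  nr <- nrow(f$phi_p)
  if (f$radially_uniform) return(rep(f$dz, nr))
  r_edges <- seq(0, nr) * f$dr
  pi * diff(r_edges^2) * f$dz
}
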