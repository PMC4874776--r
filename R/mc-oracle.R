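#' Monte Carlo oracle for small grafted-film systems
#'
#' Samples the same physical model as [solve_film()] — freely-jointed
#' hard-sphere bead chains end-grafted in a cylinder, plus grand-canonical
#' hard-sphere colloids with exponential-tail attractions — by Metropolis
#' Monte Carlo, and histograms the bead and colloid densities on the same
#' (r,z) grid. Intended as an independent cross-check of the mean-field
#' solver on small systems (at most 20 chains of at most 60 beads); it is
#' not a production sampler.
#'
#' Chain moves are crankshaft rotations for interior beads and sphere
#' resampling for the free end; the first bead stays at its (seeded, random)
#' anchor point just above the grafting surface. Colloids undergo
#' translations and insertion/deletion at the reservoir activity, with
#' periodic boundaries in z. With `phantom = TRUE` all interactions and
#' walls are switched off (ideal freely-jointed chains), which gives the
#' closed-form mean-squared anchor-to-end distance (n_beads - 1) b^2.
#'
#' @param geom a [cylinder_geometry()] (small; also sets the histogram
#'   grid).
#' @param polymer an [fg_polymer_spec()]-like list; `n_beads` must be <= 60
#'   and the implied chain count <= 20.
#' @param colloid a [colloid_spec()] or `NULL`.
#' @param params an [interaction_params()].
#' @param seed RNG seed (required).
#' @param n_sweeps sampling sweeps; `n_equil` equilibration sweeps are run
#'   first.
#' @param n_equil,sample_every sampling schedule.
#' @param phantom switch off all interactions and walls.
#' @param n_chains override the chain count implied by the grafting density.
#' @return a `density_fields` object (source `"mc oracle"`) with extra
#'   elements `r2_mean`, `r2_se`, `ncol_mean`, `ncol_se` and `acceptance`.
#' @export
mc_oracle <- function(geom, polymer, colloid = NULL,
                      params = interaction_params(), seed,
                      n_sweeps = 4000L, n_equil = max(500L, n_sweeps %/% 4L),
                      sample_every = 5L, phantom = FALSE, n_chains = NULL) {
  stopifnot(inherits(geom, "cylinder_geometry"))
  if (missing(seed)) stop("`seed` is required for the MC oracle",
                          call. = FALSE)
  area <- pi * geom$radius^2
  if (is.null(n_chains)) {
    sigma_nm2 <- polymer$grafting_density * 6.02214076e-3
    n_chains <- max(1L, round(sigma_nm2 * area))
  }
  if (n_chains > 20L || polymer$n_beads > 60L)
    stop("MC oracle is restricted to small systems (<= 20 chains, <= 60 beads)",
         call. = FALSE)
  has_col <- !is.null(colloid) && colloid$bulk_concentration > 0
  z_act <- if (has_col) molar_to_number_density(colloid$bulk_concentration) else 0
  d_c <- if (!is.null(colloid)) colloid$diameter else 1
  res <- with_seed(seed, {
    anchors <- matrix(0, n_chains, 2L)
    if (!phantom) {
      # rejection-sample non-overlapping anchor points in the disc
      placed <- 0L
      while (placed < n_chains) {
        rr <- (geom$radius - polymer$bead_diameter) * sqrt(runif(1))
        ph <- runif(1, 0, 2 * pi)
        cand <- c(rr * cos(ph), rr * sin(ph))
        if (placed == 0L || all((anchors[seq_len(placed), 1L] - cand[1L])^2 +
                                (anchors[seq_len(placed), 2L] - cand[2L])^2 >
                                polymer$bead_diameter^2)) {
          placed <- placed + 1L
          anchors[placed, ] <- cand
        }
      }
    }
    .mc_run(n_chains, polymer$n_beads, polymer$bond_length, d_c,
            params$eps_pp, params$eps_pc, params$decay_length,
            if (phantom) -1 else geom$radius, geom$height,
            TRUE, !phantom, phantom, anchors,
            has_col, z_act,
            as.integer(n_equil), as.integer(n_sweeps),
            as.integer(sample_every),
            geom$nr, geom$dr, geom$nz, geom$dz)
  })
  acc <- c(bead = res$acc_bead, colloid = res$acc_colloid,
           exchange = res$acc_exchange)
  ok <- acc[!is.na(acc)]
  if (length(ok) && any(ok < 0.05 | ok > 0.98))
    warning("MC acceptance rate outside the usual range: ",
            paste(sprintf("%s=%.2f", names(ok), ok), collapse = ", "),
            call. = FALSE)
  vol <- rep(pi * diff((seq(0, geom$nr) * geom$dr)^2) * geom$dz,
             length.out = geom$nr)
  v_p <- pi / 6 * polymer$bead_diameter^3
  v_c <- pi / 6 * d_c^3
  phi_p <- sweep(res$count_p, 1L, vol, "/") * v_p
  phi_c <- if (has_col) sweep(res$count_c, 1L, vol, "/") * v_c else NULL
  # batch-means standard error (samples along a chain are autocorrelated)
  se <- function(x, nb = 16L) {
    if (length(x) < 2L * nb) return(if (length(x) > 1L)
      sd(x) / sqrt(length(x)) else NA_real_)
    bm <- tapply(x, cut(seq_along(x), nb), mean)
    sd(bm) / sqrt(nb)
  }
  out <- new_density_fields(
    phi_p = phi_p, phi_c = phi_c,
    radius = geom$radius, height = geom$height, dr = geom$dr, dz = geom$dz,
    radially_uniform = FALSE,
    bead_diameter = polymer$bead_diameter, colloid_diameter = d_c,
    n_beads_total = n_chains * polymer$n_beads,
    bulk_colloid_density = z_act,
    convergence = list(converged = TRUE, iterations = n_sweeps,
                       residual = NA_real_),
    source = "mc oracle")
  out$r2_mean <- mean(res$r2_samples)
  out$r2_se <- se(res$r2_samples)
  out$ncol_mean <- mean(res$ncol_samples)
  out$ncol_se <- se(res$ncol_samples)
  out$acceptance <- acc
  out$colloid_volume <- res$colloid_volume
  out$n_chains <- n_chains
  out
}
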