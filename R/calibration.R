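#' Model thickness as a function of the FG-domain cohesiveness
#'
#' Solves the NTR-free film for each value of `eps_pp` on a grid and records
#' the iso-density thicknesses, both absolute and per represented amino
#' acid. This is the computational side of the cohesiveness calibration.
#'
#' @param fg_domain FG-domain construct.
#' @param eps_pp_grid cohesion energies to compute, kBT.
#' @param geom a [cylinder_geometry()]; the default radially-uniform cell is
#'   the fast configuration appropriate for laterally averaged thickness.
#' @param grafting_density chains per area, pmol/cm2.
#' @param control a [film_control()].
#' @return data.frame with one row per `eps_pp`: `d_1pct`, `d_5pct`,
#'   `d_10pct` and the matching `*_per_aa` columns.
#' @export
thickness_scan <- function(fg_domain = "Nsp1",
                           eps_pp_grid = default_eps_pp_grid(),
                           geom = cylinder_geometry(radially_uniform = TRUE),
                           grafting_density = 5.5,
                           control = film_control()) {
  polymer <- fg_polymer_spec(fg_domain, grafting_density)
  init <- NULL
  rows <- lapply(sort(eps_pp_grid), function(e) {
    f <- solve_film(geom, polymer, params = interaction_params(eps_pp = e),
                    control = control, init = init)
    init <<- f
    th <- film_thickness(f, n_amino_acids = polymer$n_amino_acids)
    data.frame(eps_pp = e,
               d_1pct = th$d[["d_1pct"]], d_5pct = th$d[["d_5pct"]],
               d_10pct = th$d[["d_10pct"]],
               d_1pct_per_aa = th$d_per_aa[["d_1pct"]],
               d_5pct_per_aa = th$d_per_aa[["d_5pct"]],
               d_10pct_per_aa = th$d_per_aa[["d_10pct"]])
  })
  do.call(rbind, rows)
}

#' @rdname thickness_scan
#' @export
default_eps_pp_grid <- function() c(0, 0.01, 0.02, 0.025, 0.03, 0.035, 0.04,
                                    0.05)

#' Calibrate the FG-domain cohesiveness from a measured film thickness
#'
#' Inverts a cubic interpolation of the computed thickness-per-amino-acid
#' versus `eps_pp` curve at the measured value. Thickness decreases
#' monotonically with cohesion, so larger measured thickness maps to smaller
#' `eps_pp`. The uncertainty is propagated from the measured band by
#' inverting at `measured +/- measured_err`.
#'
#' @param measured_per_aa measured film thickness per amino acid, nm/aa.
#' @param scan a [thickness_scan()] result (at least 4 grid points must
#'   bracket the measurement).
#' @param threshold which iso-density threshold to match: `"d_5pct"`
#'   (default), `"d_1pct"` or `"d_10pct"`.
#' @param measured_err half-width of the measured band, nm/aa.
#' @return list with `eps_pp`, `eps_pp_lo`, `eps_pp_hi`, the `threshold`
#'   used and the interpolation grid.
#' @export
calibrate_epp <- function(measured_per_aa, scan, threshold = "d_5pct",
                          measured_err = 0) {
  col <- paste0(threshold, "_per_aa")
  if (!col %in% names(scan)) stop("unknown threshold column: ", col,
                                  call. = FALSE)
  x <- scan$eps_pp
  y <- scan[[col]]
  if (length(x) < 4L)
    stop("need at least 4 eps_pp grid points", call. = FALSE)
  if (measured_per_aa > max(y) || measured_per_aa < min(y))
    stop(sprintf(
      "measured thickness %.4g nm/aa lies outside the computed range [%.4g, %.4g]",
      measured_per_aa, min(y), max(y)), call. = FALSE)
  fun <- splinefun(x, y, method = "natural")
  invert <- function(target) {
    if (target >= max(y)) return(x[which.max(y)])
    if (target <= min(y)) return(x[which.min(y)])
    uniroot(function(e) fun(e) - target, range(x), tol = 1e-10)$root
  }
  est <- invert(measured_per_aa)
  lo <- invert(measured_per_aa + measured_err)  # thicker film, weaker cohesion
  hi <- invert(measured_per_aa - measured_err)
  list(eps_pp = est, eps_pp_lo = min(lo, hi), eps_pp_hi = max(lo, hi),
       threshold = threshold, grid = data.frame(eps_pp = x, per_aa = y))
}

#' Model binding isotherm at fixed interaction parameters
#'
#' Solves the film with colloids over a ladder of bulk concentrations (warm
#' starting each solve from the previous one) and reports the bound areal
#' density at each concentration.
#'
#' @param fg_domain,ntr system selection.
#' @param eps_pp,eps_pc interaction parameters, kBT.
#' @param conc concentration ladder, uM (solved in increasing order).
#' @param geom a [cylinder_geometry()].
#' @param grafting_density chains per area, pmol/cm2.
#' @param control a [film_control()].
#' @param region averaging region for the bound amount.
#' @return data.frame with `c_NTR` (uM) and `gamma_NTR` (pmol/cm2).
#' @export
model_isotherm <- function(fg_domain = "Nsp1", ntr = "NTF2",
                           eps_pp, eps_pc,
                           conc = titration_grid(),
                           geom = cylinder_geometry(radially_uniform = TRUE),
                           grafting_density = 5.5,
                           control = film_control(),
                           region = "full", polymer = NULL) {
  if (is.null(polymer)) polymer <- fg_polymer_spec(fg_domain, grafting_density)
  params <- interaction_params(eps_pp = eps_pp, eps_pc = eps_pc)
  ord <- order(conc)
  init <- NULL
  gam <- numeric(length(conc))
  for (i in ord) {
    col <- colloid_spec(ntr, bulk_concentration = conc[i])
    f <- tryCatch(
      solve_film(geom, polymer, col, params, control = control, init = init),
      error = function(e) NULL)
    if (is.null(f)) {
      # strong-coupling points converge only with gentler damping
      gentle <- control
      gentle$mix <- min(control$mix, 0.01)
      gentle$mix_max <- min(control$mix_max, 0.04)
      gentle$max_iter <- 4L * control$max_iter
      f <- solve_film(geom, polymer, col, params, control = gentle,
                      init = init)
    }
    init <- f
    gam[i] <- bound_colloid_density(f, region)$gamma
  }
  data.frame(c_NTR = conc, gamma_NTR = gam)
}

#' Calibrate the NTR-FG attraction from a binding isotherm
#'
#' Finds the `eps_pc` whose model isotherm best matches an experimental
#' curve, by minimizing the sum of squared differences of
#' \eqn{\log \Gamma_{NTR}} over a log-spaced concentration set in
#' [0.025, 10] uM. The experimental curve is represented the way the
#' measured data are interpolated/extrapolated in practice: a linear fit
#' through the origin below 0.05 uM and the Hill fit above. The grid search
#' (default step 0.02 kBT, refined to 0.01 near the optimum) is followed by
#' a quadratic interpolation of the objective around its minimum; the quoted
#' uncertainty is half the fine grid step.
#'
#' @param ds an [isotherm_dataset()]; together with `hill` and `pc_slope` it
#'   defines the experimental curve. Alternatively supply `exp_curve` as a
#'   function of concentration.
#' @param hill a `hill_fit` for the dataset (fitted if missing).
#' @param eps_pp the FG-domain cohesion fixed beforehand (thickness
#'   calibration).
#' @param eps_pc_grid coarse search grid, kBT.
#' @param conc_set objective concentrations, uM; default 13 log-spaced
#'   points in [0.025, 10].
#' @param exp_curve optional function c -> Gamma replacing the
#'   dataset-derived curve.
#' @param refine_step fine grid step near the optimum, kBT.
#' @param ... passed to [model_isotherm()] (geometry, control, grafting
#'   density, `fg_domain`, `ntr`).
#' @return list with `eps_pc`, `eps_pc_err`, the searched `objective`
#'   (data.frame), and `bracket` isotherms at `eps_pc +/- 0.01` kBT.
#' @export
calibrate_epc <- function(ds = NULL, hill = NULL, eps_pp,
                          eps_pc_grid = seq(0.1, 0.5, by = 0.02),
                          conc_set = 10^seq(log10(0.025), 1,
                                            length.out = 13L),
                          exp_curve = NULL, refine_step = 0.01, ...) {
  if (length(eps_pc_grid) < 3L)
    stop("need at least 3 eps_pc grid points", call. = FALSE)
  if (is.null(exp_curve)) {
    stopifnot(inherits(ds, "isotherm_dataset"))
    if (is.null(hill)) hill <- fit_hill(ds)
    low <- ds$records[ds$records$c_NTR > 0 & ds$records$c_NTR <= 0.05, ,
                      drop = FALSE]
    slope <- if (nrow(low) >= 2L)
      sum(low$c_NTR * low$gamma_NTR) / sum(low$c_NTR^2)
    else predict_isotherm(hill, 0.05) / 0.05
    exp_curve <- function(c_NTR)
      ifelse(c_NTR < 0.05, slope * c_NTR, predict_isotherm(hill, c_NTR))
  }
  g_exp <- exp_curve(conc_set)
  if (any(g_exp <= 0))
    stop("experimental curve must be positive on the objective set",
         call. = FALSE)
  # grid points where the model film shows no uptake (or the solver fails to
  # converge) are infinitely bad rather than fatal
  objective_of <- function(e) {
    iso <- tryCatch(
      model_isotherm(eps_pp = eps_pp, eps_pc = e, conc = conc_set, ...),
      error = function(err) NULL)
    if (is.null(iso) || all(iso$gamma_NTR <= 0)) return(Inf)
    sum((log(pmax(iso$gamma_NTR, 1e-12)) - log(g_exp))^2)
  }
  evals <- data.frame(eps_pc = numeric(), objective = numeric())
  eval_memo <- function(e) {
    hit <- which(abs(evals$eps_pc - e) < 1e-12)
    if (length(hit)) return(evals$objective[hit[1L]])
    o <- objective_of(e)
    evals[nrow(evals) + 1L, ] <<- c(e, o)
    o
  }
  # coarse bracketing on a thinned grid, then walk the full grid near the
  # minimum, then refine at half step
  grid <- sort(eps_pc_grid)
  coarse <- grid[unique(round(seq(1, length(grid), length.out = 6L)))]
  for (e in coarse) eval_memo(e)
  repeat {
    best <- evals$eps_pc[which.min(evals$objective)]
    cand <- c(grid[which.min(abs(grid - best)) + c(-1L, 1L)],
              best - refine_step, best + refine_step)
    cand <- cand[!is.na(cand) & cand >= min(grid) & cand <= max(grid)]
    new <- cand[vapply(cand, function(e)
      !any(abs(evals$eps_pc - e) < 1e-12), logical(1L))]
    if (!length(new)) break
    for (e in new) eval_memo(e)
  }
  evals <- evals[order(evals$eps_pc), ]
  i <- which.min(evals$objective)
  if (!is.finite(evals$objective[i]))
    stop("model shows no colloid uptake anywhere on the eps_pc grid; ",
         "objective degenerate", call. = FALSE)
  est <- evals$eps_pc[i]
  # quadratic interpolation through the minimum and its neighbours
  if (i > 1L && i < nrow(evals) &&
      all(is.finite(evals$objective[(i - 1L):(i + 1L)]))) {
    x <- evals$eps_pc[(i - 1L):(i + 1L)]
    y <- evals$objective[(i - 1L):(i + 1L)]
    denom <- (x[1L] - x[2L]) * (x[1L] - x[3L]) * (x[2L] - x[3L])
    a <- (x[3L] * (y[2L] - y[1L]) + x[2L] * (y[1L] - y[3L]) +
            x[1L] * (y[3L] - y[2L])) / denom
    bq <- (x[3L]^2 * (y[1L] - y[2L]) + x[2L]^2 * (y[3L] - y[1L]) +
             x[1L]^2 * (y[2L] - y[3L])) / denom
    if (a > 0) {
      v <- -bq / (2 * a)
      if (v >= x[1L] && v <= x[3L]) est <- v
    }
  }
  list(eps_pc = est, eps_pc_err = refine_step / 2,
       eps_pc_grid_best = evals$eps_pc[i], objective = evals,
       eps_pp = eps_pp)
}

#' Sensitivity of colloid binding and distribution to the interactions
#'
#' Three scans around a baseline parameter set:
#' `"epc25"` reduces `eps_pc` by 25% at a fixed concentration (default
#' 1.4 uM) and reports the fold-reduction in the bound amount;
#' `"epc001"` brackets the isotherm with `eps_pc +/- 0.01` kBT;
#' `"epp33"` increases `eps_pp` by 33% and reports an
#' absorption-vs-adsorption indicator: the ratio of the mean colloid excess
#' inside the film (z below the 5% thickness) to the peak colloid excess in
#' the interfacial band just above it (one colloid diameter wide). An
#' indicator above 1 means the colloids are enriched inside the film, below
#' 1 on top of it.
#'
#' @param fg_domain,ntr system selection.
#' @param eps_pp,eps_pc baseline interaction parameters, kBT.
#' @param mode which scan to run.
#' @param c_eval concentration for the scan, uM.
#' @param geom,grafting_density,control passed to [solve_film()].
#' @return a list; see details per mode.
#' @export
sensitivity_scan <- function(fg_domain = "Nsp1", ntr = "NTF2",
                             eps_pp, eps_pc,
                             mode = c("epc25", "epc001", "epp33"),
                             c_eval = 1.4,
                             geom = cylinder_geometry(radially_uniform = TRUE),
                             grafting_density = 5.5,
                             control = film_control(), polymer = NULL) {
  mode <- match.arg(mode)
  if (is.null(polymer)) polymer <- fg_polymer_spec(fg_domain, grafting_density)
  col <- colloid_spec(ntr, bulk_concentration = c_eval)
  solve_at <- function(epp, epc, init = NULL) {
    par <- interaction_params(eps_pp = epp, eps_pc = epc)
    tryCatch(
      solve_film(geom, polymer, col, par, control = control, init = init),
      error = function(e) {
        # strong-coupling points need much gentler damping
        gentle <- control
        gentle$mix <- min(control$mix, 0.005)
        gentle$mix_max <- min(control$mix_max, 0.02)
        gentle$max_iter <- 8L * control$max_iter
        solve_film(geom, polymer, col, par, control = gentle, init = init)
      })
  }
  base <- solve_at(eps_pp, eps_pc)
  g_base <- bound_colloid_density(base)$gamma
  if (mode == "epc25") {
    red <- solve_at(eps_pp, 0.75 * eps_pc)
    g_red <- bound_colloid_density(red)$gamma
    return(list(mode = mode, c_eval = c_eval, gamma_baseline = g_base,
                gamma_reduced = g_red,
                fold_reduction = g_base / max(g_red, 1e-12)))
  }
  if (mode == "epc001") {
    lo <- solve_at(eps_pp, eps_pc - 0.01, init = base)
    hi <- solve_at(eps_pp, eps_pc + 0.01, init = base)
    return(list(mode = mode, c_eval = c_eval, gamma_baseline = g_base,
                gamma_minus = bound_colloid_density(lo)$gamma,
                gamma_plus = bound_colloid_density(hi)$gamma))
  }
  up <- solve_at(eps_pp * 4 / 3, eps_pc, init = base)
  list(mode = mode, c_eval = c_eval,
       indicator_baseline = absorption_indicator(base),
       indicator_raised = absorption_indicator(up),
       gamma_baseline = g_base, gamma_raised = bound_colloid_density(up)$gamma)
}

# mean in-film colloid excess over the peak interfacial excess; > 1 means
# absorption into the film, < 1 adsorption on top of it
absorption_indicator <- function(fields, threshold = 0.05) {
  d5 <- film_thickness(fields, thresholds = threshold)$d[[1L]]
  prof <- axial_profiles(fields)
  v_c <- pi / 6 * fields$colloid_diameter^3
  excess <- prof$phi_c / v_c - fields$bulk_colloid_density
  inside <- prof$z <= d5
  band <- prof$z > d5 & prof$z <= d5 + fields$colloid_diameter
  if (!any(inside) || !any(band)) return(NA_real_)
  mean(excess[inside]) / max(excess[band])
}
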