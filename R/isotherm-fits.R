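#' Langmuir and Hill fits of NTR binding isotherms
#'
#' `fit_langmuir()` fits the one-to-one binding isotherm
#' \eqn{\Gamma = \Gamma_{max} c / (K_{0.5} + c)}. `fit_hill()` fits the Hill
#' isotherm \eqn{\Gamma = \Gamma_{max} c^\alpha / (K_{0.5}^\alpha +
#' c^\alpha)}; a Hill coefficient \eqn{\alpha < 1} signals negative
#' cooperativity (the average binding strength decreases as the film fills).
#' Fits are unweighted nonlinear least squares on the linear \eqn{\Gamma}
#' scale by default; `weighting = "log"` fits on \eqn{\log\Gamma} instead.
#' Duplicate concentrations are averaged before fitting.
#'
#' @param ds an [isotherm_dataset()].
#' @param window concentration window (uM) used for fitting; the default for
#'   the Hill fit, 0.05--10 uM, excludes the independent-binding regime at
#'   lower concentrations.
#' @param alpha when non-`NULL`, the Hill coefficient is held fixed at this
#'   value and only \eqn{\Gamma_{max}} and \eqn{K_{0.5}} are adjusted.
#' @param weighting `"linear"` (unweighted on \eqn{\Gamma}) or `"log"`.
#' @return an object of class `hill_fit` (or `langmuir_fit`) with elements
#'   `gamma_max`, `K_05`, `alpha`, `alpha_fixed`, standard errors `se`,
#'   `window`, residual sum of squares `rss` and `residuals`.
#' @examples
#' ds <- generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.7,
#'                                 noise_cv = 0, seed = 1)
#' fit_hill(ds)
#' @export
fit_hill <- function(ds, window = c(0.05, 10), alpha = NULL,
                     weighting = c("linear", "log")) {
  weighting <- match.arg(weighting)
  dat <- window_records(ds, window)
  fixed <- !is.null(alpha)
  need <- if (fixed) 3L else 4L
  if (nrow(dat) < need)
    stop(sprintf("need at least %d records in the fitting window, got %d",
                 need, nrow(dat)), call. = FALSE)
  start <- list(gamma_max = max(dat$gamma_NTR) * 1.2,
                K_05 = stats::median(dat$c_NTR))
  if (!fixed) start$alpha <- 0.8
  hill <- function(c, gamma_max, K_05, alpha)
    gamma_max * c^alpha / (K_05^alpha + c^alpha)
  fml <- if (weighting == "linear") {
    if (fixed) gamma_NTR ~ hill(c_NTR, gamma_max, K_05, alpha)
    else gamma_NTR ~ hill(c_NTR, gamma_max, K_05, alpha)
  } else {
    if (any(dat$gamma_NTR <= 0))
      stop("log weighting requires strictly positive gamma_NTR",
           call. = FALSE)
    log(gamma_NTR) ~ log(hill(c_NTR, gamma_max, K_05, alpha))
  }
  env <- list2env(list(hill = hill), parent = environment())
  dat_fit <- dat
  if (fixed) dat_fit$alpha <- alpha
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat_fit, start = start,
                      lower = c(1e-12, 1e-9, if (!fixed) 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  pred <- hill(dat$c_NTR, cf[["gamma_max"]], cf[["K_05"]],
               if (fixed) alpha else cf[["alpha"]])
  res <- dat$gamma_NTR - pred
  structure(list(
    gamma_max = unname(cf[["gamma_max"]]), K_05 = unname(cf[["K_05"]]),
    alpha = if (fixed) alpha else unname(cf[["alpha"]]),
    alpha_fixed = fixed,
    se = list(gamma_max = unname(se[["gamma_max"]]),
              K_05 = unname(se[["K_05"]]),
              alpha = if (fixed) NA_real_ else unname(se[["alpha"]])),
    window = window, weighting = weighting,
    rss = sum(res^2), residuals = res, n = nrow(dat),
    dataset = dataset_label(ds)
  ), class = "hill_fit")
}

#' @rdname fit_hill
#' @export
fit_langmuir <- function(ds, window = c(0, Inf),
                         weighting = c("linear", "log")) {
  weighting <- match.arg(weighting)
  dat <- window_records(ds, window)
  if (nrow(dat) < 3L)
    stop("need at least 3 records in the fitting window", call. = FALSE)
  hf <- fit_hill(structure(list(fg_domain = ds$fg_domain, ntr = ds$ntr,
                                gamma_FG = ds$gamma_FG,
                                records = dat, full_range = ds$full_range),
                           class = "isotherm_dataset"),
                 window = window, alpha = 1, weighting = weighting)
  structure(list(
    gamma_max = hf$gamma_max, K_05 = hf$K_05,
    se = hf$se[c("gamma_max", "K_05")],
    window = window, weighting = weighting,
    rss = hf$rss, residuals = hf$residuals, n = hf$n,
    dataset = dataset_label(ds)
  ), class = "langmuir_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> %s: gamma_max = %.4g pmol/cm2, K_05 = %.4g uM, alpha = %.3g%s\n",
    x$dataset, x$gamma_max, x$K_05, x$alpha,
    if (x$alpha_fixed) " (fixed)" else ""))
  invisible(x)
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("<langmuir_fit> %s: gamma_max = %.4g pmol/cm2, K_05 = %.4g uM\n",
              x$dataset, x$gamma_max, x$K_05))
  invisible(x)
}

#' Evaluate a fitted isotherm
#'
#' @param fit a `hill_fit` or `langmuir_fit`.
#' @param c_NTR concentrations, uM.
#' @return predicted bound areal densities, pmol/cm2.
#' @export
predict_isotherm <- function(fit, c_NTR) {
  a <- if (inherits(fit, "langmuir_fit")) 1 else fit$alpha
  fit$gamma_max * c_NTR^a / (fit$K_05^a + c_NTR^a)
}

#' Two-stage Hill analysis of a set of isotherms
#'
#' Stage 1 fits the Hill equation with a free Hill coefficient to every
#' dataset covering the full 0.05--10 uM window and averages the fitted
#' coefficients. Stage 2 refits the remaining (truncated) datasets with the
#' coefficient held fixed at the stage-1 mean (rounded to two decimals),
#' which prevents parameter scatter that would only reflect the limited
#' concentration coverage.
#'
#' @param datasets list of [isotherm_dataset()] objects; at least one must be
#'   flagged full-range.
#' @inheritParams fit_hill
#' @return list with `fits` (one `hill_fit` per dataset, in input order),
#'   `mean_alpha`, `sd_alpha`, `alpha_fixed_at`, and the indices
#'   `stage1`/`stage2`.
#' @export
two_stage_hill_fit <- function(datasets, window = c(0.05, 10),
                               weighting = c("linear", "log")) {
  weighting <- match.arg(weighting)
  full <- vapply(datasets, function(d) isTRUE(d$full_range), logical(1L))
  if (!any(full))
    stop("two-stage procedure requires at least one full-range dataset",
         call. = FALSE)
  fits <- vector("list", length(datasets))
  fits[full] <- lapply(datasets[full], fit_hill, window = window,
                       weighting = weighting)
  alphas <- vapply(fits[full], `[[`, numeric(1L), "alpha")
  mean_alpha <- mean(alphas)
  alpha_fixed_at <- round(mean_alpha, 2L)
  fits[!full] <- lapply(datasets[!full], fit_hill, window = window,
                        alpha = alpha_fixed_at, weighting = weighting)
  list(fits = fits, mean_alpha = mean_alpha,
       sd_alpha = if (length(alphas) > 1L) sd(alphas) else NA_real_,
       alpha_fixed_at = alpha_fixed_at,
       stage1 = which(full), stage2 = which(!full))
}

#' Partition coefficient from the independent-binding regime
#'
#' At low concentrations NTRs bind independently and the bound amount rises
#' linearly with concentration: \eqn{\Gamma/c = PC \times d}. The slope of a
#' linear fit through the origin over `c_NTR <= c_max`, divided by the film
#' thickness, gives the dimensionless in-film/bulk partition coefficient.
#'
#' @param ds an [isotherm_dataset()].
#' @param d_ref reference film thickness, nm. Defaults to the mean recorded
#'   thickness over the low-concentration window.
#' @param c_max upper edge of the linear window, uM.
#' @return list with `PC`, `slope` (pmol/cm2 per uM), `d_ref`, `window` and
#'   the number of points used.
#' @export
partition_coefficient <- function(ds, d_ref = NULL, c_max = 0.05) {
  dat <- ds$records[ds$records$c_NTR <= c_max & ds$records$c_NTR > 0, ,
                    drop = FALSE]
  if (nrow(dat) < 2L)
    stop("need at least 2 records with 0 < c_NTR <= c_max", call. = FALSE)
  if (is.null(d_ref)) {
    d_ref <- mean(dat$thickness, na.rm = TRUE)
    if (!is.finite(d_ref))
      stop("no thickness data in the window; supply `d_ref`", call. = FALSE)
  }
  if (!is.finite(d_ref) || d_ref <= 0)
    stop("`d_ref` must be positive", call. = FALSE)
  slope <- sum(dat$c_NTR * dat$gamma_NTR) / sum(dat$c_NTR^2)
  # Gamma/d in pmol/cm2/nm equals 1e4 uM; PC is dimensionless
  list(PC = 1e4 * slope / d_ref, slope = slope, d_ref = d_ref,
       window = c(0, c_max), n = nrow(dat))
}

#' Master-curve collapse of normalized isotherms
#'
#' Normalizing each isotherm by its fitted \eqn{\Gamma_{max}} and
#' \eqn{K_{0.5}} maps all curves onto a single master curve when they share a
#' common Hill coefficient. The collapse quality is quantified as the RMS,
#' over logarithmic \eqn{c/K_{0.5}} bins populated by at least two datasets,
#' of the across-dataset standard deviation of the normalized bound amount.
#'
#' @param fits list of `hill_fit` objects, one per dataset.
#' @param datasets list of matching [isotherm_dataset()] objects.
#' @param n_bins number of logarithmic bins spanning the pooled
#'   \eqn{c/K_{0.5}} range.
#' @return list with `points` (data.frame `dataset`, `c_norm`, `gamma_norm`)
#'   and `dispersion`.
#' @export
master_curve_collapse <- function(fits, datasets, n_bins = 12L) {
  stopifnot(length(fits) == length(datasets))
  pts <- do.call(rbind, lapply(seq_along(fits), function(i) {
    rec <- datasets[[i]]$records
    rec <- rec[rec$c_NTR > 0, , drop = FALSE]
    data.frame(dataset = i, c_norm = rec$c_NTR / fits[[i]]$K_05,
               gamma_norm = rec$gamma_NTR / fits[[i]]$gamma_max)
  }))
  if (length(unique(pts$dataset)) < 2L)
    return(list(points = pts, dispersion = 0))
  lx <- log10(pts$c_norm)
  br <- seq(min(lx), max(lx), length.out = n_bins + 1L)
  bin <- findInterval(lx, br, rightmost.closed = TRUE)
  sds <- vapply(split(pts, bin), function(g) {
    m <- tapply(g$gamma_norm, g$dataset, mean)
    if (length(m) < 2L) NA_real_ else sd(m)
  }, numeric(1L))
  sds <- sds[is.finite(sds)]
  list(points = pts,
       dispersion = if (length(sds)) sqrt(mean(sds^2)) else 0)
}

#' FG-motif stoichiometry of bound NTRs
#'
#' Relates the number of FG motifs present in the film to the number of bound
#' NTRs at a reference concentration: with \eqn{\Gamma_{FG}} the grafting
#' density and m motifs per FG domain, `motifs_per_bound_NTR =
#' gamma_FG * m / gamma_NTR(c_eval)`. Given the number of FG-binding sites on
#' the NTR (2 for the NTF2 dimer, up to 9 for Importin beta), the maximal
#' fraction of motifs that can be simultaneously engaged is
#' `sites_per_ntr / motifs_per_bound_NTR`.
#'
#' @param ds an [isotherm_dataset()].
#' @param fit optional `hill_fit` used to extrapolate the bound amount when
#'   `c_eval` was not measured directly.
#' @param c_eval evaluation concentration, uM.
#' @param sites_per_ntr FG-binding sites per NTR; defaults to 2 for NTF2 and
#'   9 for Importin beta.
#' @return list with `motifs_per_domain`, `gamma_NTR_eval`,
#'   `motifs_per_bound_NTR`, `max_occupied_fraction` and `extrapolated`.
#' @export
motif_stoichiometry <- function(ds, fit = NULL, c_eval = 10,
                                sites_per_ntr = NULL) {
  motifs <- fg_motifs_per_domain(ds$fg_domain)
  if (is.null(sites_per_ntr))
    sites_per_ntr <- switch(ds$ntr, NTF2 = 2, Impb = 9)
  hit <- which(abs(ds$records$c_NTR - c_eval) <= 1e-9 * max(c_eval, 1))
  if (length(hit)) {
    g <- mean(ds$records$gamma_NTR[hit])
    extrap <- FALSE
  } else {
    if (is.null(fit)) fit <- fit_hill(ds)
    g <- predict_isotherm(fit, c_eval)
    extrap <- TRUE
  }
  total_motifs <- ds$gamma_FG * motifs
  mpn <- if (g > 0) total_motifs / g else Inf
  list(motifs_per_domain = motifs, gamma_NTR_eval = g,
       motifs_per_bound_NTR = mpn,
       max_occupied_fraction = if (is.finite(mpn)) sites_per_ntr / mpn else 0,
       sites_per_ntr = sites_per_ntr, c_eval = c_eval, extrapolated = extrap)
}

#' FG motifs per domain for the constructs studied here
#'
#' @param fg_domain FG-domain name.
#' @return motif count: 33 (Nsp1), 39 (Nup98-glyco), 16 (reg-FSFG).
#' @export
fg_motifs_per_domain <- function(fg_domain) {
  fg_domain <- match.arg(fg_domain, fg_domain_names())
  c(Nsp1 = 33, `Nup98-glyco` = 39, `reg-FSFG` = 16)[[fg_domain]]
}

window_records <- function(ds, window) {
  stopifnot(inherits(ds, "isotherm_dataset"))
  rec <- ds$records
  rec <- rec[rec$c_NTR >= window[1L] & rec$c_NTR <= window[2L], ,
             drop = FALSE]
  # duplicate concentrations are averaged before fitting
  if (anyDuplicated(rec$c_NTR)) {
    sp <- split(rec, rec$c_NTR)
    rec <- do.call(rbind, lapply(sp, function(g)
      data.frame(c_NTR = g$c_NTR[1L], gamma_NTR = mean(g$gamma_NTR),
                 gamma_err = mean(g$gamma_err), thickness = mean(g$thickness),
                 thickness_err = mean(g$thickness_err))))
    rec <- rec[order(rec$c_NTR), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

dataset_label <- function(ds)
  sprintf("%s/%s@%.3g", ds$ntr, ds$fg_domain, ds$gamma_FG)
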