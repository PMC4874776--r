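test_that("noiseless Hill data are recovered exactly", {
  ds <- noiseless_dataset(gamma_max = 1.5, K = 0.8, alpha = 0.7)
  fit <- fit_hill(ds)
  expect_equal(fit$gamma_max, 1.5, tolerance = 1e-6)
  expect_equal(fit$K_05, 0.8, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-6)
  # Hill identity: Gamma at K_05 is half the plateau, for any alpha
  expect_equal(predict_isotherm(fit, fit$K_05), fit$gamma_max / 2)
})

test_that("noiseless Langmuir data are recovered and Hill(alpha=1) agrees", {
  ds <- noiseless_dataset(gamma_max = 2, K = 1, alpha = 1)
  lg <- fit_langmuir(ds)
  expect_equal(lg$gamma_max, 2, tolerance = 1e-6)
  expect_equal(lg$K_05, 1, tolerance = 1e-6)
  hl <- fit_hill(ds, window = c(0, Inf), alpha = 1)
  expect_equal(hl$gamma_max, lg$gamma_max, tolerance = 1e-9)
  expect_equal(hl$K_05, lg$K_05, tolerance = 1e-9)
  # low-concentration log-log slope of Langmuir data is one
  low <- ds$records[ds$records$c_NTR <= 0.05, ]
  slope <- coef(lm(log(gamma_NTR) ~ log(c_NTR), data = low))[[2]]
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("Langmuir systematically misfits negatively cooperative data", {
  ds <- noiseless_dataset(gamma_max = 2, K = 1, alpha = 0.7)
  lg <- fit_langmuir(ds, window = c(0.05, 10))
  hl <- fit_hill(ds)
  expect_gt(lg$rss, 10 * hl$rss)
  # residuals show a systematic sign pattern (runs, not noise)
  expect_lt(length(rle(sign(lg$residuals))$lengths), length(lg$residuals) - 2)
})

test_that("Hill fit is scale-equivariant in the bound amount", {
  ds <- generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.71,
                                  noise_cv = 0.05, seed = 5)
  k <- 3.7
  ds2 <- ds
  ds2$records$gamma_NTR <- k * ds$records$gamma_NTR
  f1 <- fit_hill(ds); f2 <- fit_hill(ds2)
  expect_equal(f2$gamma_max, k * f1$gamma_max, tolerance = 1e-6)
  expect_equal(f2$K_05, f1$K_05, tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
})

test_that("fits demand enough records and report window membership", {
  ds <- noiseless_dataset(conc = c(0.1, 1, 10))
  expect_error(fit_hill(ds), "at least 4")
  expect_s3_class(fit_hill(ds, alpha = 0.71), "hill_fit")
  expect_error(fit_langmuir(noiseless_dataset(conc = c(1, 2))), "at least 3")
})

test_that("two-stage procedure fixes alpha at the stage-1 mean", {
  fam <- generate_dataset_family(n_datasets = 10L, alpha = 0.71,
                                 noise_cv = 0.05, seed = 31)
  res <- two_stage_hill_fit(fam)
  expect_length(res$stage2, 3L)
  expect_equal(res$mean_alpha, 0.71, tolerance = 0.05)
  expect_equal(res$alpha_fixed_at, round(res$mean_alpha, 2))
  for (i in res$stage2) {
    expect_true(res$fits[[i]]$alpha_fixed)
    expect_equal(res$fits[[i]]$alpha, res$alpha_fixed_at)
    expect_true(is.na(res$fits[[i]]$se$alpha))
  }
  for (i in res$stage1) expect_false(res$fits[[i]]$alpha_fixed)
  # all-full-range family leaves stage 2 empty
  fam2 <- generate_dataset_family(n_datasets = 4L, n_partial = 0L, seed = 8)
  expect_length(two_stage_hill_fit(fam2)$stage2, 0L)
  # no full-range dataset at all is a procedure error
  fam3 <- lapply(fam[1:3], function(d) { d$full_range <- FALSE; d })
  expect_error(two_stage_hill_fit(fam3), "full-range")
})

test_that("stage-2 parameters are recovered accurately with fixed alpha", {
  true <- list(gamma_max = 1.8, K = 1.2)
  part <- generate_isotherm_dataset(gamma_max = true$gamma_max,
                                    K_05 = true$K, alpha = 0.71,
                                    noise_cv = 0.0,
                                    conc = titration_grid()[titration_grid() >= 0.2],
                                    full_range = FALSE, seed = 3)
  full <- lapply(1:2, function(i)
    generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.71,
                              noise_cv = 0, seed = i))
  res <- two_stage_hill_fit(c(full, list(part)))
  f <- res$fits[[3]]
  expect_equal(f$gamma_max, true$gamma_max, tolerance = 0.02)
  expect_equal(f$K_05, true$K, tolerance = 0.02)
})

test_that("partition coefficient has the right units and limits", {
  # Gamma = 0.01 pmol/cm2 at c = 0.01 uM with d = 10 nm gives PC = 1000
  ds <- isotherm_dataset("Nsp1", "NTF2", 5,
                         c_NTR = c(0.005, 0.01, 1),
                         gamma_NTR = c(0.005, 0.01, 1))
  pc <- partition_coefficient(ds, d_ref = 10)
  expect_equal(pc$PC, 1000, tolerance = 1e-9)
  # zero binding gives PC 0
  ds0 <- isotherm_dataset("Nsp1", "NTF2", 5, c_NTR = c(0.01, 0.02),
                          gamma_NTR = c(0, 0))
  expect_equal(partition_coefficient(ds0, d_ref = 10)$PC, 0)
  expect_error(partition_coefficient(
    isotherm_dataset("Nsp1", "NTF2", 5, 1, 1), d_ref = 10), "at least 2")
  expect_error(partition_coefficient(ds, d_ref = -1), "positive")
})

test_that("synthetic study-like datasets give partition coefficients in the
           expected range", {
  fam <- generate_dataset_family(n_datasets = 10L, seed = 77)
  pcs <- vapply(fam[1:7], function(d)
    partition_coefficient(d)$PC, numeric(1L))
  # every synthetic film shows strong enrichment; the typical value sits in
  # the 1e3..1e5 window reported for measured films (the generator samples a
  # slightly wider parameter box than the measured set)
  expect_true(all(pcs > 3e2 & pcs < 1e6))
  expect_true(median(pcs) > 1e3 && median(pcs) < 1e5)
})

test_that("master curve collapses families with a common Hill coefficient", {
  fam <- generate_dataset_family(n_datasets = 6L, alpha = 0.71,
                                 noise_cv = 0.05, n_partial = 0L, seed = 12)
  fits <- lapply(fam, fit_hill)
  mc <- master_curve_collapse(fits, fam)
  expect_lt(mc$dispersion, 0.05)
  # normalized value at c = K_05 is one half for every curve
  for (f in fits)
    expect_equal(predict_isotherm(f, f$K_05) / f$gamma_max, 0.5)
  # single dataset: zero dispersion by construction
  expect_equal(master_curve_collapse(fits[1], fam[1])$dispersion, 0)
  # mixed-alpha family disperses more than the common-alpha family
  fam2 <- c(generate_dataset_family(3L, alpha = 0.55, noise_cv = 0.05,
                                    n_partial = 0L, seed = 13),
            generate_dataset_family(3L, alpha = 0.9, noise_cv = 0.05,
                                    n_partial = 0L, seed = 14))
  fits2 <- lapply(fam2, fit_hill)
  expect_gt(master_curve_collapse(fits2, fam2)$dispersion, mc$dispersion)
})

test_that("motif stoichiometry arithmetic and occupancy bounds", {
  # 5 pmol/cm2 Nsp1 film (33 motifs/domain) with 16.5 pmol/cm2 bound NTR
  ds <- isotherm_dataset("Nsp1", "NTF2", 5, c_NTR = 10, gamma_NTR = 16.5)
  st <- motif_stoichiometry(ds, c_eval = 10)
  expect_equal(st$motifs_per_bound_NTR, 10)
  expect_equal(st$max_occupied_fraction, 0.2)  # 2 sites per NTF2 dimer
  expect_false(st$extrapolated)
  # extrapolation through the Hill fit when 10 uM was not measured
  ds2 <- noiseless_dataset(gamma_max = 2, K = 1, alpha = 0.71,
                           conc = titration_grid()[titration_grid() < 10])
  fit <- fit_hill(ds2, alpha = 0.71)
  st2 <- motif_stoichiometry(ds2, fit = fit, c_eval = 10)
  expect_true(st2$extrapolated)
  expect_equal(st2$gamma_NTR_eval, hill_gamma(10, 2, 1, 0.71),
               tolerance = 1e-6)
  # vanishing binding: infinite motif ratio, zero occupancy
  ds0 <- isotherm_dataset("Nsp1", "NTF2", 5, c_NTR = 10, gamma_NTR = 0)
  st0 <- motif_stoichiometry(ds0, c_eval = 10)
  expect_true(is.infinite(st0$motifs_per_bound_NTR))
  expect_equal(st0$max_occupied_fraction, 0)
})

test_that("motif counts per FG domain are looked up correctly", {
  expect_equal(fg_motifs_per_domain("Nsp1"), 33)
  expect_equal(fg_motifs_per_domain("Nup98-glyco"), 39)
  expect_equal(fg_motifs_per_domain("reg-FSFG"), 16)
  expect_error(fg_motifs_per_domain("Nup153"))
})
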