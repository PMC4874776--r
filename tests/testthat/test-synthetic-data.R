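test_that("generator is deterministic and leaves the global RNG alone", {
  a <- generate_isotherm_dataset(seed = 123)
  set.seed(999); before <- runif(1)
  b <- generate_isotherm_dataset(seed = 123)
  expect_identical(a, b)
  set.seed(999)
  expect_identical(runif(1), before)
  fam1 <- generate_dataset_family(5L, seed = 4)
  fam2 <- generate_dataset_family(5L, seed = 4)
  expect_identical(fam1, fam2)
  # byte-identical CSV across runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_isotherm_tables(fam1, p1); write_isotherm_tables(fam2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noise-free generation reproduces the Hill law exactly", {
  ds <- noiseless_dataset(gamma_max = 2, K = 1, alpha = 0.71)
  expect_equal(ds$records$gamma_NTR,
               hill_gamma(titration_grid(), 2, 1, 0.71))
  # thickness rises with the bound amount from its baseline
  ds2 <- generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.71,
                                   noise_cv = 0, d0 = 30,
                                   thickness_rise = 0.2, seed = 1)
  th <- ds2$records$thickness
  expect_equal(th[1], 30, tolerance = 0.01)
  expect_equal(max(th) / 30 - 1, 0.2 * max(ds2$records$gamma_NTR) / 2,
               tolerance = 1e-9)
})

test_that("multiplicative noise has unit mean at the stated cv", {
  cv <- 0.05
  ratios <- unlist(lapply(1:500, function(i) {
    ds <- generate_isotherm_dataset(noise_cv = cv, seed = 1e4 + i)
    ds$records$gamma_NTR / hill_gamma(titration_grid(), 2, 1, 0.71)
  }))
  se <- cv / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se)
  expect_equal(sd(ratios), cv, tolerance = 0.1)
})

test_that("family truncation marks partial-range curves", {
  fam <- generate_dataset_family(10L, seed = 21)
  partial <- vapply(fam, function(d) !d$full_range, logical(1L))
  expect_equal(sum(partial), 3L)
  for (d in fam[partial]) expect_gte(min(d$records$c_NTR), 0.2)
  for (d in fam[!partial]) expect_equal(min(d$records$c_NTR), 0.0025)
  expect_length(generate_dataset_family(1L, n_partial = 0L, seed = 2), 1L)
})

test_that("alpha recovery from noisy synthetic data is essentially unbiased", {
  alphas <- vapply(1:100, function(i) {
    ds <- generate_isotherm_dataset(gamma_max = 2, K_05 = 1, alpha = 0.71,
                                    noise_cv = 0.05, seed = 2e4 + i)
    fit_hill(ds)$alpha
  }, numeric(1L))
  expect_lt(abs(mean(alphas) - 0.71), 0.02)
  expect_lt(median(abs(alphas - 0.71)), 0.05)
})

test_that("slab fixtures have the advertised closed-form properties", {
  f <- generate_slab_fixture("uniform", phi0 = 0.2, h = 30)
  th <- film_thickness(f)
  expect_equal(unname(th$d), rep(30, 3))
  # ramp: thresholds cut at the stated fractions of the ramp height
  fr <- generate_slab_fixture("ramp", phi0 = 0.3, h = 40, dz = 0.25,
                              height = 60)
  thr <- film_thickness(fr)
  expect_equal(thr$d[["d_10pct"]] / 40, 0.9, tolerance = 0.02)
  expect_equal(thr$d[["d_5pct"]] / 40, 0.95, tolerance = 0.02)
  # gaussian interface: material fraction below d_5pct from the erf integral
  fgx <- generate_slab_fixture("gaussian", phi0 = 0.2, h = 30, w = 2,
                               height = 60, dz = 0.25)
  got <- material_fraction_below(fgx, 0.05)
  z <- seq(0.125, 60, by = 0.25)
  phi <- 0.2 * pnorm(30, z, 2)
  d5 <- max(z[phi >= 0.05 * max(phi)]) + 0.125
  expect_equal(got, sum(phi[z <= d5]) / sum(phi), tolerance = 1e-6)
  # zero field: undefined thickness
  f0 <- generate_slab_fixture("uniform", phi0 = 0)
  expect_error(film_thickness(f0), "zero")
})
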