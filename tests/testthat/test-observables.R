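test_that("thickness thresholds are ordered on every field", {
  for (pf in c("uniform", "ramp", "gaussian")) {
    f <- generate_slab_fixture(pf, phi0 = 0.25, h = 25)
    d <- film_thickness(f)$d
    expect_true(d[["d_1pct"]] >= d[["d_5pct"]])
    expect_true(d[["d_5pct"]] >= d[["d_10pct"]])
  }
  g <- small_geom()
  f <- solve_film(g, short_polymer(30L),
                  params = interaction_params(eps_pp = 0.03))
  d <- film_thickness(f)$d
  expect_true(d[["d_1pct"]] >= d[["d_5pct"]] && d[["d_5pct"]] >= d[["d_10pct"]])
})

test_that("bound-colloid densities integrate uniform excess slabs exactly", {
  bulk <- molar_to_number_density(1)
  f <- generate_slab_fixture("uniform", phi0 = 0.1, h = 20, bulk_c = bulk,
                             excess_c = 5e-5, h_c = 12)
  b <- bound_colloid_density(f)
  expect_equal(b$excess_per_nm2, 5e-5 * 12, tolerance = 1e-9)
  expect_equal(b$gamma, 5e-5 * 12 / 6.02214076e-3, tolerance = 1e-6)
  # pure bulk means zero excess
  f0 <- generate_slab_fixture("uniform", phi0 = 0.1, h = 20, bulk_c = bulk)
  expect_equal(bound_colloid_density(f0)$gamma, 0, tolerance = 1e-12)
  # radially uniform fields: full and central averages coincide
  expect_equal(bound_colloid_density(f, "central50")$gamma, b$gamma,
               tolerance = 1e-12)
})

test_that("axial profiles average radially and conserve material", {
  f <- generate_slab_fixture("ramp", phi0 = 0.3, h = 30)
  prof <- axial_profiles(f)
  # radially uniform field: profile equals any single-radius slice
  expect_equal(prof$phi_p, unname(f$phi_p[1, ]))
  # integral of the profile recovers the slab material
  v_b <- pi / 6 * 0.76^3
  area <- pi * f$radius^2
  total <- sum(prof$phi_p / v_b * area * f$dz)
  expect_equal(total, sum(f$phi_p / v_b *
                            fgfilm:::field_cell_volumes(f)), tolerance = 1e-9)
})

test_that("uniform slabs put all material below every threshold", {
  f <- generate_slab_fixture("uniform", phi0 = 0.2, h = 30)
  expect_equal(material_fraction_below(f, 0.05), 1)
})

test_that("contact estimate matches shell volume and scales with colloid size", {
  c4 <- contact_energy_estimate(colloid_spec("NTF2"), packing = 0.2,
                                eps_pc = 0.34)
  c6 <- contact_energy_estimate(colloid_spec("Impb"), packing = 0.2,
                                eps_pc = 0.40)
  # a 4 nm colloid at 20% packing touches a few tens of beads; the 6 nm
  # colloid roughly twice as many
  expect_gt(c4$n_contacts, 13); expect_lt(c4$n_contacts, 52)
  expect_equal(c6$n_contacts / c4$n_contacts, 2, tolerance = 0.08)
  expect_equal(c4$binding_energy, c4$n_contacts * 0.34)
  expect_equal(contact_energy_estimate(4, packing = 0)$n_contacts, 0)
  expect_error(contact_energy_estimate(4, packing = 0.9), "packing")
})

test_that("shell-volume contact count agrees with brute-force packing", {
  # random sequential insertion of beads around a colloid at phi ~ 0.2
  set.seed(4)
  sig_b <- 0.76; R_col <- 2.0
  L <- 11
  target <- round(0.2 * L^3 / (pi / 6 * sig_b^3))
  centers <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(centers) < target && tries < 2e5) {
    tries <- tries + 1L
    cand <- runif(3, -L / 2, L / 2)
    rc <- sqrt(sum(cand^2))
    if (rc < R_col + sig_b / 2) next  # overlaps the central colloid
    if (nrow(centers)) {
      d2 <- colSums((t(centers) - cand)^2)
      if (any(d2 < sig_b^2)) next
    }
    centers <- rbind(centers, cand)
  }
  phi_eff <- nrow(centers) * (pi / 6 * sig_b^3) /
    (L^3 - 4 / 3 * pi * (R_col + sig_b / 2)^3)
  rr <- sqrt(rowSums(centers^2))
  est <- contact_energy_estimate(2 * R_col, packing = phi_eff)
  brute <- sum(rr >= est$shell[["r_in"]] & rr < est$shell[["r_out"]])
  expect_equal(brute, est$n_contacts, tolerance = 0.2)
})
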