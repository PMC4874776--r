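test_that("pair potential is a hard core with an exponential tail", {
  expect_equal(pair_potential(0.76, 0.3, 0.76), -0.3)
  expect_equal(pair_potential(1.76, 0.3, 0.76), -0.3 / exp(1))
  expect_equal(pair_potential(50, 0.3, 0.76), 0, tolerance = 1e-12)
  expect_identical(pair_potential(0.5, 0.3, 0.76), Inf)
  expect_error(pair_potential(-1, 0.3, 0.76), "non-negative")
})

test_that("polymer specs encode the construct sizes", {
  expect_equal(fg_polymer_spec("Nsp1")$n_beads, 300L)
  expect_equal(fg_polymer_spec("Nup98-glyco")$n_beads, 260L)
  p <- fg_polymer_spec("reg-FSFG")
  expect_equal(p$n_beads, 155L)
  expect_equal(p$bead_diameter, 0.76)
  expect_equal(p$bond_length, p$bead_diameter)
  # two amino acids per bead approximates the construct length within 5%
  expect_lt(abs(2 * 300 - 615) / 615, 0.05)
  expect_error(fg_polymer_spec("Nup214"))
})

test_that("hard-sphere mixture chemical potential reduces to known limits", {
  eta <- c(0.05, 0.15, 0.3)
  rho <- eta / (pi / 6 * 0.76^3)
  mu <- fgfilm:::.bmcsl_mu(rho, rep(0, 3), 0.76, 4)[, 1]
  mu_cs <- (8 * eta - 9 * eta^2 + 3 * eta^3) / (1 - eta)^3
  expect_equal(mu, mu_cs, tolerance = 1e-12)
  # dilute big-sphere insertion cost approaches the excluded-volume virial
  rho0 <- 0.01 / (pi / 6 * 0.76^3)
  mu_c <- fgfilm:::.bmcsl_mu(rho0, 0, 0.76, 4)[, 2]
  v_excl <- 4 / 3 * pi * ((0.76 + 4) / 2)^3
  expect_equal(mu_c, v_excl * rho0, tolerance = 0.05)
})

test_that("NTR-free film conserves polymer mass and responds to cohesion", {
  g <- small_geom()
  p <- short_polymer(40L)
  v_b <- pi / 6 * 0.76^3
  d5 <- vapply(c(0, 0.02, 0.04), function(e) {
    f <- solve_film(g, p, params = interaction_params(eps_pp = e))
    beads <- sum(f$phi_p / v_b * fgfilm:::field_cell_volumes(f))
    expect_equal(beads, f$n_beads_total, tolerance = 1e-3)
    film_thickness(f)$d[["d_5pct"]]
  }, numeric(1L))
  # thickness decreases monotonically with increasing cohesiveness
  expect_true(all(diff(d5) < 0))
})

test_that("normalized thickness is chain-length invariant at equal cohesion", {
  g <- small_geom(height = 60)
  d_per_aa <- vapply(c(60L, 52L), function(n) {
    p <- short_polymer(n)
    f <- solve_film(g, p, params = interaction_params(eps_pp = 0.02))
    film_thickness(f, n_amino_acids = 2 * n)$d_per_aa[["d_5pct"]]
  }, numeric(1L))
  expect_equal(d_per_aa[1], d_per_aa[2], tolerance = 0.05)
})

test_that("purely repulsive films exclude colloids; binding grows with eps_pc", {
  g <- small_geom()
  p <- short_polymer(40L)
  col <- colloid_spec("NTF2", bulk_concentration = 2)
  f0 <- solve_film(g, p, col, interaction_params(eps_pp = 0.02, eps_pc = 0))
  # far from the film the colloid density equals its bulk value within 1%
  rho_far <- f0$phi_c[1, ncol(f0$phi_c)] / (pi / 6 * 4^3)
  expect_equal(rho_far, f0$bulk_colloid_density, tolerance = 0.01)
  # inside a purely repulsive film the colloid density cannot exceed bulk
  expect_lte(max(f0$phi_c), (1 + 1e-9) * f0$bulk_colloid_density * pi / 6 * 4^3)
  expect_lt(bound_colloid_density(f0)$gamma, 0)
  # bound amount is non-decreasing in eps_pc
  gam <- vapply(c(0.2, 0.35, 0.45), function(e) {
    f <- solve_film(g, p, col, interaction_params(0.02, e))
    bound_colloid_density(f)$gamma
  }, numeric(1L))
  expect_true(all(diff(gam) > 0))
})

test_that("doubling the reservoir concentration doubles the far-field density", {
  g <- small_geom()
  p <- short_polymer(30L)
  f1 <- solve_film(g, p, colloid_spec("NTF2", bulk_concentration = 1),
                   interaction_params(0.02, 0.1))
  f2 <- solve_film(g, p, colloid_spec("NTF2", bulk_concentration = 2),
                   interaction_params(0.02, 0.1))
  top <- ncol(f1$phi_c)
  expect_equal(f2$phi_c[1, top] / f1$phi_c[1, top], 2, tolerance = 1e-3)
})

test_that("solver is deterministic and reports convergence", {
  g <- small_geom()
  p <- short_polymer(30L)
  f1 <- solve_film(g, p, params = interaction_params(eps_pp = 0.02))
  f2 <- solve_film(g, p, params = interaction_params(eps_pp = 0.02))
  expect_identical(f1$phi_p, f2$phi_p)
  expect_true(f1$convergence$converged)
  expect_lt(f1$convergence$residual, 1e-6)
  # non-convergence raises an error carrying the residual history
  err <- tryCatch(
    solve_film(g, p, params = interaction_params(eps_pp = 0.02),
               control = film_control(max_iter = 3L)),
    error = function(e) e)
  expect_match(conditionMessage(err), "did not converge")
  expect_true(length(err$res_hist) > 0)
})

test_that("fields are stable under grid refinement", {
  p <- short_polymer(60L)
  f1 <- solve_film(small_geom(dz = 0.5), p,
                   params = interaction_params(eps_pp = 0.02))
  f2 <- solve_film(small_geom(dz = 0.25), p,
                   params = interaction_params(eps_pp = 0.02))
  d1 <- film_thickness(f1)$d
  d2 <- film_thickness(f2)$d
  # iso-density heights are resolved to about one coarse cell
  expect_true(all(abs(d1 - d2) <= 0.8))
  expect_equal(max(f1$phi_p), max(f2$phi_p), tolerance = 0.05)
})

test_that("2D cylinder fields are radially symmetric by construction and
           deplete at the side wall", {
  g <- cylinder_geometry(radius = 15, height = 30, dr = 1.25, dz = 0.5)
  p <- short_polymer(25L)
  f <- solve_film(g, p, params = interaction_params(eps_pp = 0.01),
                  control = film_control(max_iter = 6000))
  v_b <- pi / 6 * 0.76^3
  beads <- sum(sweep(f$phi_p / v_b, 1, fgfilm:::field_cell_volumes(f), "*"))
  expect_equal(beads, f$n_beads_total, tolerance = 1e-3)
  # zero-density boundary at the side wall: outermost ring is depleted
  inner <- mean(f$phi_p[1:2, 1:20])
  outer <- mean(f$phi_p[nrow(f$phi_p), 1:20])
  expect_lt(outer, 0.5 * inner)
})
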