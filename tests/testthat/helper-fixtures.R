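# small shared fixtures built in code

hill_gamma <- function(c, gamma_max, K, alpha)
  gamma_max * c^alpha / (K^alpha + c^alpha)

noiseless_dataset <- function(gamma_max = 2, K = 1, alpha = 0.7,
                              conc = titration_grid(), ...) {
  generate_isotherm_dataset(gamma_max = gamma_max, K_05 = K, alpha = alpha,
                            noise_cv = 0, conc = conc, seed = 1, ...)
}

# small fast geometry for solver tests
small_geom <- function(height = 40, dz = 0.5)
  cylinder_geometry(height = height, dz = dz, radially_uniform = TRUE)

short_polymer <- function(n_beads = 40L, grafting_density = 5.5) {
  p <- fg_polymer_spec("Nsp1", grafting_density)
  p$n_beads <- as.integer(n_beads)
  p$n_amino_acids <- 2L * p$n_beads
  p
}
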