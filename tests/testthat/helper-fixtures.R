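# Shared fixtures: small synthetic populations and ad-hoc configurations.
# Everything is generated in code under fixed seeds.

small_population <- function(n = 6, groups = 1, seed = 42, ...) {
  npg <- stats::setNames(rep(n, groups), LETTERS[seq_len(groups)])
  simulate_population(simulation_spec(n_per_group = npg, seed = seed, ...))
}

# a deterministic asymmetric 41x3 configuration in the midsagittal frame
asym_test_config <- function(seed = 7, scale = 1) {
  set.seed(seed)
  geo <- make_palate_geometry(simulation_spec(n_per_group = c(A = 2)))
  tpl <- geo$template
  tpl + scale * matrix(stats::rnorm(123, sd = 0.3), 41, 3)
}

rigid_motion <- function(coords, angle = 0.7, axis = c(0, 0, 1),
                         translation = c(3, -2, 5), scale = 1) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  scale * coords %*% R + matrix(translation, nrow(coords), 3, byrow = TRUE)
}
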