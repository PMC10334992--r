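# Shared fixtures: all built in code at test time.

# internal helpers used across tests
deg2rad <- qpli:::deg2rad
rad2deg <- qpli:::rad2deg
wrap_axial <- qpli:::wrap_axial
validate_config <- qpli:::validate_config

# A perfectly aligned noise-free single-retarder phantom: every pixel is a
# retarder with the given fast axis and retardance.
uniform_scene <- function(mode = "transmission", fast_axis_deg = 20,
                          retardance_rad = pi / 2, shape = c(64, 64),
                          seed = 0, ...) {
  generate_scene("aligned", mode, shape = shape, seed = seed,
                 kappa = 1e6, mu_deg = fast_axis_deg,
                 retardance_rad = retardance_rad, ...)
}

# Full mosaic-to-Stokes run of a scene
pipeline_stokes <- function(scene, handedness = "right", noise = FALSE,
                            seed = NULL, method = "bilinear") {
  m <- render_mosaic(scene, input_handedness = handedness,
                     noise = noise, seed = seed)
  compute_stokes(demosaic(m, method))
}

# Random physical Stokes vector (uniform over the Poincare ball)
random_physical_state <- function() {
  p <- stats::runif(1)^(1 / 3)
  v <- stats::rnorm(3)
  v <- p * v / sqrt(sum(v^2))
  s0 <- stats::runif(1, 0.1, 2)
  stokes_vector(s0, s0 * v[1], s0 * v[2], s0 * v[3])
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

random_element <- function() {
  kind <- sample(c("retarder", "polarizer", "depolarizer", "attenuator",
                   "mirror"), 1)
  switch(kind,
    retarder = make_element("retarder",
                            fast_axis_deg = stats::runif(1, -90, 90),
                            retardance_rad = stats::runif(1, 0, 2 * pi - 1e-6)),
    polarizer = make_element("polarizer", axis_deg = stats::runif(1, -90, 90)),
    depolarizer = make_element("depolarizer",
                               depol_linear = stats::runif(1),
                               depol_circular = stats::runif(1)),
    attenuator = make_element("attenuator", transmissivity = stats::runif(1)),
    mirror = make_element("mirror"))
}
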