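# Shared fixtures, built once per test run (generation is deterministic).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

fig3 <- function() fixture("fig3", function() make_fig3_fixture())

# spherical lattice used by the recovery and cleaning suites
sphere_truth <- function() {
  fixture("sphere", function() make_spherical_lattice(40, 8, coverage = 1,
                                                      seed = 1))
}

sphere_volume <- function(noise_sigma = 0, rng_seed = 42) {
  key <- sprintf("sphere_vol_%g_%d", noise_sigma, rng_seed)
  fixture(key, function() {
    truth <- sphere_truth()
    shape <- rep(ceiling(2 * (40 + 1.5 * 8)), 3L)
    render_tomogram(truth, make_template(12), shape,
                    noise_sigma = noise_sigma, rng_seed = rng_seed)
  })
}

sphere_params <- function(...) {
  # box 10 exactly contains the reach-4 template support and the mask
  # support (radius 3.5 + soft 0.5); a larger box only adds zero-weight
  # voxels to every correlation
  defaults <- list(angular_ranges = c(12, 72, 12), angular_steps = 4,
                   translational_range = 3, translational_step = 1,
                   transition_list = hex_transitions(8), box_size = 10,
                   spacing = 8, cc_threshold = 0.5, max_iterations = 60,
                   d_min = 4)
  do.call(expansion_params, utils::modifyList(defaults, list(...)))
}

# seed the sphere at the site nearest the spin-axis equator, where the frame
# field twist is minimal
sphere_seed <- function() {
  truth <- sphere_truth()
  U <- sweep(truth$positions, 2L, attr(truth, "center"), "-")
  U <- U / sqrt(rowSums(U^2))
  i <- which.min(abs(U %*% attr(truth, "spin_axis")))
  particle_set(truth$positions[i, , drop = FALSE],
               truth$angles[i, , drop = FALSE],
               status = "seed", tomo_name = "sphere")
}

# nearest-truth-site matching: distances n_truth x n_particles
truth_particle_distances <- function(truth, set) {
  tp <- truth$positions
  fp <- particle_positions(set)
  D <- matrix(0, nrow(tp), nrow(fp))
  for (k in 1:3) D <- D + outer(tp[, k], fp[, k], "-")^2
  sqrt(D)
}

# largest per-axis component (degrees) of the rotation from a to b
max_axis_error <- function(a, b) {
  max(abs(rotation_vector(crossprod(as_rot(a), as_rot(b)))))
}

as_rot <- function(o) if (is.matrix(o)) o else euler_to_matrix(o)

pairwise_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

plane_set <- function(n1 = 7, n2 = 7, spacing = 8) {
  truth <- make_planar_lattice(n1, n2, spacing, origin = c(20, 20, 24))
  particle_set(truth$positions, truth$angles, status = "accepted",
               tomo_name = "plane")
}

random_rotation <- function() {
  euler_to_matrix(c(stats::runif(1, -180, 180), stats::runif(1, 0, 180),
                    stats::runif(1, -180, 180)))
}
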