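# oracle: axial hexagon enumeration with the radius predicate
axial_hex_oracle <- function(radius) {
  g <- expand.grid(q = -radius:radius, r = -radius:radius)
  g[pmax(abs(g$q), abs(g$r), abs(g$q + g$r)) <= radius, ]
}

test_that("the two-patch fixture reproduces its designed geometry", {
  fx <- fig3()
  # patch A: radius-4 hexagon (61 sites by enumeration) minus site (3,1)
  expect_equal(nrow(axial_hex_oracle(4)), 61)
  expect_equal(sum(fx$truth$patch_id == 1), 60)
  expect_equal(sum(fx$truth$patch_id == 2), 7)
  expect_equal(nrow(fx$seeds), 3)
  # the two patches are at least four lattice constants apart
  A <- fx$truth$positions[fx$truth$patch_id == 1, ]
  B <- fx$truth$positions[fx$truth$patch_id == 2, ]
  expect_gte(min(pairwise_dist(A, B)), 4 * fx$truth$spacing)
  # every site frame maps local Y onto tomogram +Z
  for (i in seq_len(nrow(fx$truth$positions))) {
    y <- orient_vector(fx$truth$angles[i, ], c(0, 1, 0))
    expect_lt(max(abs(y - c(0, 0, 1))), 1e-9)
  }
})

test_that("fixture seeds have the designed neighbor counts", {
  # neighbor enumeration oracle on axial coordinates
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  patchA <- axial_hex_oracle(4)
  patchA <- patchA[!(patchA$q == 3 & patchA$r == 1), ]
  n_in_patch <- function(q, r) {
    sum(apply(offs, 1, function(o)
      any(patchA$q == q + o[1] & patchA$r == r + o[2])))
  }
  expect_equal(n_in_patch(4, 0), 2)
  expect_equal(n_in_patch(0, 0), 6)
  expect_equal(n_in_patch(-3, 0), 6)
})

test_that("fixture sizing errors name the minimal shape", {
  expect_error(make_fig3_fixture(8, c(40, 40, 40)), "need at least")
  expect_error(make_fig3_fixture(4), "spacing")
})

test_that("spherical lattice respects radius, spacing and frames", {
  truth <- sphere_truth()
  ctr <- attr(truth, "center")
  R <- attr(truth, "radius")
  d <- truth$spacing
  U <- sweep(truth$positions, 2, ctr, "-")
  rad <- sqrt(rowSums(U^2))
  expect_lt(max(abs(rad - R)), 0.5)
  # site count within 15% of the flat hexagonal-packing estimate
  est <- 4 * pi * R^2 / (sqrt(3) / 2 * d^2)
  expect_lt(abs(nrow(U) - est) / est, 0.15)
  # nearest same-patch neighbor at spacing within 1%
  D <- as.matrix(dist(truth$positions))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_lt(max(abs(nn / d - 1)), 0.01)
  # local Y along the outward radial direction
  for (i in seq_len(nrow(U))) {
    y <- orient_vector(truth$angles[i, ], c(0, 1, 0))
    expect_gt(sum(y * U[i, ]) / rad[i], 0.99)
  }
})

test_that("spherical coverage cap keeps a contiguous fraction", {
  cap <- make_spherical_lattice(40, 8, coverage = 0.4, seed = 3,
                                n_pass = 300)
  full <- 4 * pi * 40^2 / (sqrt(3) / 2 * 64)
  expect_lt(nrow(cap$positions), 0.55 * full)
  expect_gt(nrow(cap$positions), 0.25 * full)
  expect_error(make_spherical_lattice(40, 8, coverage = 0), "coverage")
  expect_error(make_spherical_lattice(6, 8), "radius")
})

test_that("filament lattice follows the arc geometry", {
  # straight line: collinear, exact spacing
  fil <- make_filament_lattice(9, 8, curvature = 0, origin = c(5, 5, 5))
  p <- fil$positions
  expect_equal(unique(p[, 2]), 5)
  expect_equal(unique(p[, 3]), 5)
  expect_equal(diff(p[, 1]), rep(8, 8))
  # curved: total turn angle = curvature * spacing * (n - 1)
  kappa <- 1 / 60
  filc <- make_filament_lattice(9, 8, curvature = kappa)
  f1 <- euler_to_matrix(filc$angles[1, ])
  f9 <- euler_to_matrix(filc$angles[9, ])
  turn <- angular_distance(f1, f9) * pi / 180
  expect_equal(turn, kappa * 8 * 8, tolerance = 1e-6)
  # consecutive arc-length spacing: chord = 2 R sin(d kappa / 2)
  chords <- sqrt(rowSums((filc$positions[-1, ] - filc$positions[-9, ])^2))
  expect_equal(chords, rep(2 / kappa * sin(8 * kappa / 2), 8),
               tolerance = 1e-9)
  # local Y is normal to the chain, in-chain axis is local X
  for (i in c(1, 5, 9)) {
    Fm <- euler_to_matrix(filc$angles[i, ])
    tangent <- if (i < 9) filc$positions[i + 1, ] - filc$positions[i, ] else
      filc$positions[i, ] - filc$positions[i - 1, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    expect_lt(abs(sum(Fm[, 2] * tangent)), 0.1)  # Y ~ normal
    expect_gt(sum(Fm[, 1] * tangent), 0.99 * cos(8 * kappa / 2))
  }
  expect_error(make_filament_lattice(9, 8, curvature = 0.2), "curvature")
  expect_error(make_filament_lattice(1, 8), "n_repeats")
})

test_that("render_tomogram is deterministic and respects its contract", {
  truth <- make_filament_lattice(3, 8, origin = c(12, 16, 16))
  tpl <- make_template(12)
  v1 <- render_tomogram(truth, tpl, c(48, 32, 32), noise_sigma = 0.2,
                        rng_seed = 7)
  v2 <- render_tomogram(truth, tpl, c(48, 32, 32), noise_sigma = 0.2,
                        rng_seed = 7)
  expect_identical(v1, v2)
  # noise standard deviation in an empty corner within 5% of the request
  corner <- v1[40:48, 24:32, 24:32]
  expect_lt(abs(sd(corner) / 0.2 - 1), 0.05)
  # single isolated site: voxel-wise maximum near the site approximates the
  # template maximum (interpolation tolerance)
  # a half-integer site center samples the template grid exactly (the
  # template center sits at (box-1)/2 = 5.5)
  one <- lattice_truth(matrix(c(16.5, 16.5, 16.5), 1), matrix(0, 1, 3),
                       spacing = 8)
  v <- render_tomogram(one, tpl, c(32, 32, 32), noise_sigma = 0)
  expect_equal(max(v), max(tpl), tolerance = 1e-3)
  # out-of-bounds sites are reported by index
  bad <- lattice_truth(matrix(c(100, 16, 16), 1), matrix(0, 1, 3),
                       spacing = 8)
  expect_error(render_tomogram(bad, tpl, c(32, 32, 32)), "out of bounds")
  # template side must stay under twice the spacing
  expect_error(render_tomogram(one, array(0, c(17, 17, 17)), c(32, 32, 32)),
               "twice the lattice spacing")
})

test_that("the template has no density beyond its reach", {
  tpl <- make_template(12, reach = 4)
  c0 <- (12 - 1) / 2
  ax <- seq_len(12) - 1 - c0
  g <- expand.grid(x = ax, y = ax, z = ax)
  outside <- sqrt(g$x^2 + g$y^2 + g$z^2) > 4
  expect_true(all(abs(as.numeric(tpl)[outside]) < 1e-12))
  expect_gt(max(tpl), 0.5)
})
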