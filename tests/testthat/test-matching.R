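# brute-force masked Pearson oracle via elementwise sums
cc_oracle <- function(a, b, w) {
  a <- as.numeric(a); b <- as.numeric(b); w <- as.numeric(w)
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  sum(w * (a - ma) * (b - mb)) /
    sqrt(sum(w * (a - ma)^2) * sum(w * (b - mb)^2))
}

test_that("masked_cc matches the brute-force oracle and its identities", {
  set.seed(5)
  for (i in 1:10) {
    a <- array(rnorm(125), c(5, 5, 5))
    b <- array(rnorm(125), c(5, 5, 5))
    m <- array(rbinom(125, 1, 0.6), c(5, 5, 5))
    if (sum(m) < 3) next
    expect_equal(masked_cc(a, b, m), cc_oracle(a, b, m), tolerance = 1e-9)
    # symmetry and affine-intensity invariance
    expect_equal(masked_cc(a, b, m), masked_cc(b, a, m), tolerance = 1e-12)
    expect_equal(masked_cc(2.5 * a + 3, b, m), masked_cc(a, b, m),
                 tolerance = 1e-9)
  }
  v <- array(rnorm(27), c(3, 3, 3))
  expect_equal(masked_cc(v, v), 1, tolerance = 1e-9)
  expect_equal(masked_cc(v, -v), -1, tolerance = 1e-9)
  # degenerate variance returns 0
  expect_equal(masked_cc(array(1, c(3, 3, 3)), v), 0)
  expect_error(masked_cc(v, array(0, c(4, 4, 4))), "shape")
})

test_that("search grids always contain the zero offset", {
  for (p in list(expansion_params(),
                 expansion_params(angular_ranges = c(10, 0, 6),
                                  angular_steps = 4),
                 expansion_params(translational_range = 0))) {
    g <- search_grid(p)
    expect_false(is.na(g$izero_rot))
    expect_false(is.na(g$izero_shift))
    expect_equal(unname(g$rot_offsets[g$izero_rot, ]), c(0, 0, 0))
    expect_equal(unname(g$shifts[g$izero_shift, ]), c(0, 0, 0))
  }
})

test_that("constrained_align degenerates to the prior pose at zero ranges", {
  fx <- fig3()
  p0 <- expansion_params(angular_ranges = c(0, 0, 0), angular_steps = 4,
                         translational_range = 0, box_size = 16,
                         spacing = 8, transition_list = hex_transitions(8))
  pos <- c(fx$seeds$x[1], fx$seeds$y[1], fx$seeds$z[1])
  ori <- c(fx$seeds$rot[1], fx$seeds$tilt[1], fx$seeds$psi[1])
  res <- constrained_align(fx$volume, pos, ori, fx$reference, fx$mask, p0)
  expect_equal(res$position, pos, tolerance = 1e-9)
  expect_equal(angular_distance(res$orientation, ori), 0, tolerance = 1e-6)
  expect_equal(res$cc, res$cc_prior)
})

test_that("constrained_align recovers a known pose offset", {
  # a single site rendered at a known pose; prior displaced by 2 voxels and
  # 8 degrees about local Y; grid step 1 voxel / 4 degrees
  tpl <- make_template(12)
  truthR <- euler_to_matrix(c(25, 40, -10))
  pos <- c(24, 25.4, 23.7)
  truth <- lattice_truth(matrix(pos, 1), matrix(matrix_to_euler(truthR), 1),
                         spacing = 8)
  vol <- render_tomogram(truth, tpl, c(48, 48, 48), noise_sigma = 0)
  params <- expansion_params(angular_ranges = c(8, 8, 8), angular_steps = 4,
                             translational_range = 2, translational_step = 1,
                             box_size = 12, spacing = 8,
                             transition_list = hex_transitions(8),
                             refine_subgrid = FALSE)
  mask <- make_default_mask(12, radius = 3.5, soft = 0.5)
  priorR <- truthR %*% euler_to_matrix(c(0, 8, 0))  # 8 deg about local Y
  res <- constrained_align(vol, pos + c(2, 0, 0), priorR, tpl, mask, params)
  expect_gt(res$cc, 0.9)
  expect_lt(sqrt(sum((res$position - pos)^2)), 1.1)      # within a grid step
  expect_lt(angular_distance(res$orientation, truthR), 4.1)
  # cc never drops below the prior pose's cc
  expect_gte(res$cc, res$cc_prior)
  # an empty region has no variance: cc 0
  res0 <- constrained_align(vol, c(10, 10, 38), priorR, tpl, mask, params)
  expect_equal(res0$cc, 0)
  # out-of-bounds box names the particle
  expect_error(constrained_align(vol, c(2, 2, 2), priorR, tpl, mask, params,
                                 label = "p7"), "p7")
})

test_that("sub-grid polish stays within the searched neighborhood", {
  tpl <- make_template(12)
  truthR <- euler_to_matrix(c(25, 40, -10))
  pos <- c(24, 25.4, 23.7)
  truth <- lattice_truth(matrix(pos, 1), matrix(matrix_to_euler(truthR), 1),
                         spacing = 8)
  vol <- render_tomogram(truth, tpl, c(48, 48, 48), noise_sigma = 0)
  params <- expansion_params(angular_ranges = c(8, 8, 8), angular_steps = 4,
                             translational_range = 2, translational_step = 1,
                             box_size = 12, spacing = 8,
                             transition_list = hex_transitions(8),
                             refine_subgrid = TRUE)
  mask <- make_default_mask(12, radius = 3.5, soft = 0.5)
  res <- constrained_align(vol, pos + c(1.3, -0.8, 0.4), truthR, tpl, mask,
                           params)
  # polished pose lands essentially on the rendered pose
  expect_lt(sqrt(sum((res$position - pos)^2)), 0.3)
  expect_lt(angular_distance(res$orientation, truthR), 1.5)
  expect_gt(res$cc, 0.99)
})

test_that("on-site and off-site candidates separate on the fixture", {
  fx <- fig3()
  p1 <- fx$params
  p1$max_iterations <- 1L
  p1$refine_subgrid <- FALSE # raw grid scores, the selection criterion
  run <- run_expansion(fx$volume, fx$seeds, fx$reference, fx$mask, p1)
  cc <- sort(run$records[[1]]$aligned$cc)
  expect_equal(length(cc), 18)
  expect_lt(cc[4], 0.2)   # all four off-site candidates
  expect_gt(cc[5], 0.9)   # all fourteen on-site candidates
})
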