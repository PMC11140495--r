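random_set <- function(n = 8, seed = 19) {
  set.seed(seed)
  particle_set(matrix(runif(3 * n, 20, 60), n),
               cbind(runif(n, -180, 180), runif(n, 0, 180),
                     runif(n, -180, 180)),
               cc = runif(n), status = "accepted", tomo_name = "t1")
}

test_that("recenter shifts by the rotated local offset", {
  set <- random_set()
  expect_equal(as.data.frame(recenter(set, c(0, 0, 0))), as.data.frame(set))
  # identity orientations: a plain translation
  flat <- particle_set(matrix(1:6, 2), matrix(0, 2, 3))
  out <- recenter(flat, c(0, 0, 5))
  expect_equal(out$z, flat$z + 5)
  expect_equal(out$x, flat$x)
  # rotated particles against an explicit matrix-multiply oracle
  out2 <- recenter(set, c(1, -2, 3))
  mats <- particle_matrices(set)
  for (i in seq_len(nrow(set))) {
    expected <- c(set$x[i], set$y[i], set$z[i]) +
      drop(mats[[i]] %*% c(1, -2, 3))
    expect_lt(max(abs(c(out2$x[i], out2$y[i], out2$z[i]) - expected)), 1e-9)
  }
  # recenter with the negated offset is the identity
  back <- recenter(out2, -c(1, -2, 3))
  expect_equal(back$x, set$x, tolerance = 1e-9)
  expect_equal(back$y, set$y, tolerance = 1e-9)
  expect_equal(back$z, set$z, tolerance = 1e-9)
})

test_that("yaxis_to_z maps the old Y image onto the new Z image", {
  set <- random_set()
  conv <- yaxis_to_z(set)
  expect_equal(conv$x, set$x)
  expect_equal(conv$y, set$y)
  expect_equal(conv$z, set$z)
  m_old <- particle_matrices(set)
  m_new <- particle_matrices(conv)
  for (i in seq_len(nrow(set))) {
    expect_lt(max(abs(m_new[[i]] %*% c(0, 0, 1) - m_old[[i]] %*% c(0, 1, 0))),
              1e-9)
    # explicit frame-change oracle: right-composition with Rx(-90)
    expect_lt(max(abs(m_new[[i]] -
                        m_old[[i]] %*% latticepick:::rot_x(-90))), 1e-9)
  }
  # a particle whose local Y maps to tomogram +Z ends with local Z there
  up <- particle_set(matrix(c(1, 2, 3), 1),
                     matrix(matrix_to_euler(latticepick:::rot_x(90)), 1))
  upc <- yaxis_to_z(up)
  expect_lt(max(abs(orient_vector(c(upc$rot, upc$tilt, upc$psi),
                                  c(0, 0, 1)) - c(0, 0, 1))), 1e-9)
})

test_that("yaxis_to_z preserves the cleaning geometry", {
  truth <- sphere_truth()
  set <- particle_set(truth$positions, truth$angles, status = "accepted")
  sub <- set[1:40, ]
  s1 <- neighbor_stats(sub, 12)
  conv <- yaxis_to_z(sub)
  # after conversion the lattice normal is the local Z axis
  axes_z <- t(vapply(particle_matrices(conv), function(R) R[, 3], numeric(3)))
  axes_y <- t(vapply(particle_matrices(sub), function(R) R[, 2], numeric(3)))
  expect_lt(max(abs(axes_z - axes_y)), 1e-9)
})

test_that("export_placeback writes markers and a cleaned STAR", {
  set <- plane_set()
  stats <- neighbor_stats(set, 12)
  bad <- classify_bad(stats, 3, 30)
  prefix <- file.path(withr::local_tempdir(), "pb")
  paths <- export_placeback(set, stats, prefix, cmm = TRUE)
  mk <- read_placeback_markers(paste0(prefix, "_markers.txt"))
  expect_equal(nrow(mk), sum(!bad))
  keep <- which(!bad)
  expect_equal(mk$x, set$x[keep], tolerance = 1e-6)
  expect_equal(mk$curvature, stats$curvature_proxy[keep], tolerance = 1e-6)
  # flat plane: every curvature value is zero
  expect_true(all(abs(mk$curvature) < 1e-6))
  clean <- read_star_particles(paste0(prefix, "_clean.star"))
  expect_equal(nrow(clean), sum(!bad))
  expect_true(file.exists(paste0(prefix, ".cmm")))
  # no particle flagged: row count preserved
  paths2 <- export_placeback(set, stats, prefix, bad = rep(FALSE, nrow(set)))
  expect_equal(nrow(read_star_particles(paste0(prefix, "_clean.star"))),
               nrow(set))
  expect_error(export_placeback(set, stats[1:3, ], prefix), "mismatch")
})

test_that("assemble disambiguates tomogram names and dedups within them", {
  a <- particle_set(rbind(c(1, 1, 1), c(9, 9, 9)), matrix(0, 2, 3),
                    tomo_name = "t")
  b <- particle_set(rbind(c(1.5, 1, 1), c(40, 40, 40)), matrix(0, 2, 3),
                    tomo_name = "t")
  out <- assemble_particle_sets(list(a, b), d_min = 2)
  expect_equal(length(unique(out$tomo_name)), 2)
  expect_equal(nrow(out), 4) # different tomograms: near-duplicates kept
  b2 <- b; b2$tomo_name <- NULL # same name, same tomogram
  out2 <- assemble_particle_sets(list(a, a), d_min = 2)
  expect_equal(nrow(out2), 4) # renamed second set, no cross-tomo dedup
  merged <- assemble_particle_sets(
    list(particle_set(rbind(c(1, 1, 1), c(1.5, 1, 1), c(9, 9, 9)),
                      matrix(0, 3, 3), tomo_name = "t")), d_min = 2)
  expect_equal(nrow(merged), 2) # within-tomogram duplicate removed
})
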