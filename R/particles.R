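#' Construct a particle set
#'
#' A particle set is an ordered table of picked particles bound to one
#' tomogram: continuous 0-based voxel positions, ZYZ Euler orientations in
#' degrees, a cross-correlation score, a status flag and the iteration at
#' which the particle entered the set. It is a `data.frame` subclass so the
#' usual subsetting and inspection idioms apply.
#'
#' @param position Numeric matrix `n x 3` of voxel coordinates `(x, y, z)`,
#'   0-based, continuous.
#' @param angles Numeric matrix `n x 3` of Euler angles `(rot, tilt, psi)` in
#'   degrees. Defaults to identity orientations.
#' @param cc Correlation coefficients in `[-1, 1]`; `NA` for seeds not yet
#'   aligned.
#' @param status Character vector; each of `"seed"`, `"accepted"` or
#'   `"rejected"`.
#' @param iteration_added Integer iteration index (0 for seeds).
#' @param tomo_name Tomogram identifier (recycled).
#' @param voxel_size Optional voxel size in Angstrom per voxel, kept as
#'   metadata.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(position = matrix(numeric(), 0L, 3L),
                         angles = NULL, cc = NA_real_, status = "seed",
                         iteration_added = 0L, tomo_name = "tomo",
                         voxel_size = NULL) {
  position <- matrix(as.numeric(position), ncol = 3L)
  n <- nrow(position)
  if (is.null(angles)) angles <- matrix(0, n, 3L)
  angles <- matrix(as.numeric(angles), ncol = 3L)
  stopifnot(nrow(angles) == n)
  cc <- rep_len(as.numeric(cc), n)
  ok <- is.na(cc) | (cc >= -1 & cc <= 1)
  if (!all(ok)) stop("cc out of [-1, 1] for particle(s) ",
                     paste(which(!ok), collapse = ", "))
  status <- rep_len(as.character(status), n)
  bad <- setdiff(unique(status), c("seed", "accepted", "rejected",
                                   "candidate"))
  if (length(bad)) stop("unknown particle status: ", paste(bad, collapse = ", "))
  df <- data.frame(
    tomo_name = rep_len(as.character(tomo_name), n),
    x = position[, 1L], y = position[, 2L], z = position[, 3L],
    rot = angles[, 1L], tilt = angles[, 2L], psi = angles[, 3L],
    cc = cc, status = status,
    iteration_added = rep_len(as.integer(iteration_added), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("particle_set", "data.frame")
  attr(df, "voxel_size") <- voxel_size
  df
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d particles (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$status)), table(x$status)),
                    collapse = ", ")))
  if (!is.null(attr(x, "voxel_size")))
    cat(sprintf("voxel size: %g A/voxel\n", attr(x, "voxel_size")))
  NextMethod()
}

as_particle_set <- function(df, voxel_size = NULL) {
  need <- c("tomo_name", "x", "y", "z", "rot", "tilt", "psi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing particle column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$cc)) df$cc <- NA_real_
  if (is.null(df$status)) df$status <- "accepted"
  if (is.null(df$iteration_added)) df$iteration_added <- 0L
  df <- df[, c(need, "cc", "status", "iteration_added")]
  rownames(df) <- NULL
  class(df) <- c("particle_set", "data.frame")
  attr(df, "voxel_size") <- voxel_size
  df
}

#' Particle positions as a matrix
#'
#' @param set A `particle_set`.
#' @return Numeric `n x 3` matrix of voxel coordinates.
#' @export
particle_positions <- function(set) {
  cbind(x = set$x, y = set$y, z = set$z)
}

#' Particle orientations as rotation matrices
#'
#' @param set A `particle_set`.
#' @return A list of 3x3 rotation matrices, one per particle.
#' @export
particle_matrices <- function(set) {
  lapply(seq_len(nrow(set)), function(i)
    euler_to_matrix(set$rot[i], set$tilt[i], set$psi[i]))
}

# n x 9 matrix of column-major flattened rotation matrices (for the C++ side)
particle_matrices_flat <- function(set) {
  if (nrow(set) == 0L) return(matrix(numeric(), 0L, 9L))
  t(vapply(particle_matrices(set), as.numeric, numeric(9L)))
}

rbind_particle_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, nrow, 0L) > 0L | vapply(sets, nrow, 0L) == 0L]
  out <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)))
  as_particle_set(out, voxel_size = attr(sets[[1L]], "voxel_size"))
}

# Minimum pairwise distance, Inf for fewer than 2 particles.
min_pair_distance <- function(set) {
  if (nrow(set) < 2L) return(Inf)
  min(stats::dist(particle_positions(set)))
}
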