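#' Neighbor-graph statistics for geometric particle cleaning
#'
#' For each particle, counts the neighbors within `radius` (Euclidean,
#' excluding the particle itself) and averages the tilt angle between the
#' particle's lattice-normal axis (the tomogram-frame image of local Y) and
#' each neighbor's. On a flat lattice the mean tilt is 0; on a sphere of
#' radius `R` with spacing `d` it approximates `degrees(d / R)` — a local
#' surface-curvature proxy.
#'
#' @param set A [particle_set].
#' @param radius Neighborhood radius, voxels (`> 0`). A practical default is
#'   1.5 times the lattice spacing.
#' @param fold_axes If `TRUE`, axes are treated as undirected and angles are
#'   folded into `[0, 90]`. The default `FALSE` uses directed axes in
#'   `[0, 180]`, so inside-out flipped particles stand out.
#' @return A `data.frame` with one row per particle: `neighbor_count`,
#'   `mean_tilt` (degrees; `NA` when there are no neighbors) and
#'   `curvature_proxy` (alias of `mean_tilt`, exported for coloring).
#' @export
neighbor_stats <- function(set, radius, fold_axes = FALSE) {
  if (radius <= 0) stop("radius must be > 0")
  n <- nrow(set)
  pos <- particle_positions(set)
  axes <- t(vapply(particle_matrices(set), function(R) R[, 2L], numeric(3L)))
  count <- integer(n)
  mt <- rep(NA_real_, n)
  if (n > 1L) {
    D <- as.matrix(stats::dist(pos))
    diag(D) <- Inf
    for (i in seq_len(n)) {
      nb <- which(D[i, ] <= radius)
      count[i] <- length(nb)
      if (!length(nb)) next
      cosang <- pmin(1, pmax(-1, axes[nb, , drop = FALSE] %*% axes[i, ]))
      ang <- acos(cosang) * 180 / pi
      if (fold_axes) ang <- pmin(ang, 180 - ang)
      mt[i] <- mean(ang)
    }
  }
  data.frame(neighbor_count = count, mean_tilt = mt, curvature_proxy = mt)
}

#' Flag geometric outliers ("bad" particles)
#'
#' A particle is bad when it has too few neighbors or tilts too far from its
#' neighborhood: `neighbor_count < min_neighbors` or `mean_tilt > max_tilt`.
#' Particles without neighbors (mean tilt undefined) can only fail the count
#' rule.
#'
#' @param stats Output of [neighbor_stats()].
#' @param min_neighbors Minimum acceptable neighbor count.
#' @param max_tilt Maximum acceptable mean tilt, degrees.
#' @return Logical vector, `TRUE` for bad particles.
#' @export
classify_bad <- function(stats, min_neighbors = 3, max_tilt = 30) {
  bad_count <- stats$neighbor_count < min_neighbors
  bad_tilt <- !is.na(stats$mean_tilt) & stats$mean_tilt > max_tilt
  bad_count | bad_tilt
}

#' Write a per-particle cleaning table
#'
#' Tab-separated table with neighbor count, mean tilt and the bad flag,
#' deterministic field formatting.
#'
#' @param stats Output of [neighbor_stats()].
#' @param bad Logical vector from [classify_bad()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_table <- function(stats, bad, path) {
  stopifnot(nrow(stats) == length(bad))
  df <- data.frame(index = seq_len(nrow(stats)),
                   neighbor_count = stats$neighbor_count,
                   mean_tilt = ifelse(is.na(stats$mean_tilt), "NA",
                                      sprintf("%.6f", stats$mean_tilt)),
                   bad = as.integer(bad))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
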