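#' Read a two-point seed-pair file
#'
#' Plain-text stalkInit-style picks: six whitespace-separated numbers per
#' line, `x1 y1 z1 x2 y2 z2`, one particle per line. The two points define
#' the particle's local Y axis; the center sits between them. Blank lines
#' and `#` comments are ignored.
#'
#' @param path Path to the point file.
#' @return A list with matrices `p1` and `p2` (`n x 3` each).
#' @export
read_seed_pairs <- function(path) {
  if (!file.exists(path)) stop("seed-pair file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(list(p1 = matrix(numeric(), 0L, 3L),
                                  p2 = matrix(numeric(), 0L, 3L)))
  vals <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1L]]))
    if (length(v) != 6L || anyNA(v))
      stop(sprintf("line %d: expected six numbers (x1 y1 z1 x2 y2 z2)", i))
    v
  })
  m <- do.call(rbind, vals)
  list(p1 = m[, 1:3, drop = FALSE], p2 = m[, 4:6, drop = FALSE])
}

#' Seed particles from two-point picks
#'
#' Each pair becomes one seed: position at the midpoint `(p1 + p2) / 2`,
#' orientation the minimal rotation carrying local +Y onto the unit vector
#' from `p1` to `p2` (no spin about the axis — the restricted angular search
#' absorbs the unresolvable in-plane spin).
#'
#' @param pairs Output of [read_seed_pairs()] (list with `p1`, `p2`).
#' @param tomo_name Tomogram identifier.
#' @param voxel_size Optional voxel size metadata.
#' @return A [particle_set] with status `"seed"`.
#' @export
seeds_from_pairs <- function(pairs, tomo_name = "tomo", voxel_size = NULL) {
  p1 <- matrix(as.numeric(pairs$p1), ncol = 3L)
  p2 <- matrix(as.numeric(pairs$p2), ncol = 3L)
  stopifnot(nrow(p1) == nrow(p2))
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12))
    stop("coincident points in pair(s): ",
         paste(which(len < 1e-12), collapse = ", "))
  ang <- t(vapply(seq_len(nrow(p1)), function(i) {
    u <- d[i, ] / len[i]
    matrix_to_euler(geodesic_rotation(c(0, 1, 0), u))
  }, numeric(3L)))
  particle_set((p1 + p2) / 2, ang, status = "seed", tomo_name = tomo_name,
               voxel_size = voxel_size)
}
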