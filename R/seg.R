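#' Binary cube labels from particle coordinates
#'
#' Builds the training-target volume for segmentation-based picking: an
#' axis-aligned cube of side `cube_side` centered at each rounded coordinate
#' is set to 1 (union over particles), clipped at the volume borders.
#'
#' @param coords Numeric `n x 3` matrix of 0-based voxel coordinates.
#' @param cube_side Odd cube side `>= 1`. A practical default is
#'   `max(3, nearest odd to 0.25 * spacing)`, small enough not to bridge
#'   adjacent lattice sites.
#' @param shape Integer vector of length 3.
#' @return A binary array of dimension `shape` (values 0/1).
#' @export
labels_from_coords <- function(coords, cube_side, shape) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  shape <- as.integer(shape)
  if (cube_side < 1 || cube_side %% 2 != 1)
    stop("cube_side must be odd and >= 1")
  out <- array(0L, dim = shape)
  bad <- which(coords[, 1L] < 0 | coords[, 2L] < 0 | coords[, 3L] < 0 |
                 coords[, 1L] > shape[1L] - 1 | coords[, 2L] > shape[2L] - 1 |
                 coords[, 3L] > shape[3L] - 1)
  if (length(bad))
    stop("coordinate(s) outside the volume: ", paste(bad, collapse = ", "))
  h <- (cube_side - 1L) / 2L
  ctr <- round(coords)
  for (i in seq_len(nrow(coords))) {
    xr <- max(0L, ctr[i, 1L] - h):min(shape[1L] - 1L, ctr[i, 1L] + h)
    yr <- max(0L, ctr[i, 2L] - h):min(shape[2L] - 1L, ctr[i, 2L] + h)
    zr <- max(0L, ctr[i, 3L] - h):min(shape[3L] - 1L, ctr[i, 3L] + h)
    out[xr + 1L, yr + 1L, zr + 1L] <- 1L
  }
  out
}

#' Particle coordinates from a segmentation map
#'
#' Thresholds a binary label volume or probability map, clusters the lit
#' voxels by single-linkage agglomerative clustering with the given distance
#' cutoff, discards clusters smaller than `min_voxels`, and returns each
#' surviving cluster's voxel centroid. For large maps the clustering is
#' applied per 26-connected component, which is identical to global
#' single-linkage whenever `linkage_cutoff >= sqrt(3)` (adjacent voxels are
#' then always linked); below that the global algorithm is used.
#'
#' @param vol Numeric 3D array (binary labels or probabilities).
#' @param binarize_at Threshold applied to `vol` (default 0.5).
#' @param linkage_cutoff Single-linkage distance cutoff, voxels (`> 0`).
#' @param min_voxels Minimum cluster size retained.
#' @param max_direct Lit-voxel count up to which plain `hclust` is used.
#' @return Numeric `k x 3` matrix of 0-based centroid coordinates (0 rows if
#'   the map is empty).
#' @export
coords_from_labels <- function(vol, binarize_at = 0.5, linkage_cutoff,
                               min_voxels = 1L, max_direct = 3000L) {
  if (linkage_cutoff <= 0) stop("linkage_cutoff must be > 0")
  lit <- which(vol >= binarize_at)
  if (!length(lit)) return(matrix(numeric(), 0L, 3L))
  idx <- arrayInd(lit, dim(vol)) - 1L # 0-based voxel coords
  if (length(lit) <= max_direct || linkage_cutoff < sqrt(3)) {
    cl <- single_linkage_clusters(idx, linkage_cutoff)
  } else {
    # decompose into 26-connected components, then merge components whose
    # minimum inter-component distance is within the cutoff
    comp <- cc_label_cpp(vol >= binarize_at, dim(vol))[lit]
    cl <- merge_components(idx, comp, linkage_cutoff)
  }
  keep <- as.integer(names(which(table(cl) >= min_voxels)))
  out <- t(vapply(keep, function(k) colMeans(idx[cl == k, , drop = FALSE]),
                  numeric(3L)))
  if (!nrow(out)) matrix(numeric(), 0L, 3L) else out
}

single_linkage_clusters <- function(idx, cutoff) {
  if (nrow(idx) == 1L) return(1L)
  hc <- stats::hclust(stats::dist(idx), method = "single")
  stats::cutree(hc, h = cutoff)
}

merge_components <- function(idx, comp, cutoff) {
  ids <- sort(unique(comp))
  k <- length(ids)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) {
    vox <- lapply(ids, function(id) idx[comp == id, , drop = FALSE])
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      if (find(a) == find(b)) next
      # cheap bounding-box rejection before the exact minimum distance
      gap <- pmax(0, pmax(apply(vox[[a]], 2L, min) - apply(vox[[b]], 2L, max),
                          apply(vox[[b]], 2L, min) - apply(vox[[a]], 2L, max)))
      if (sqrt(sum(gap^2)) > cutoff) next
      dmin <- min(proxy_cross_dist(vox[[a]], vox[[b]]))
      if (dmin <= cutoff) parent[find(b)] <- find(a)
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  match(roots[match(comp, ids)], unique(roots))
}

proxy_cross_dist <- function(a, b) {
  # pairwise Euclidean distances between two coordinate sets
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

#' Write coordinates as plain three-column text
#'
#' @param coords Numeric `n x 3` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coords_text <- function(coords, path) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  lines <- apply(coords, 1L, function(p) sprintf("%.6f %.6f %.6f",
                                                 p[1L], p[2L], p[3L]))
  writeLines(lines, path)
  invisible(path)
}
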