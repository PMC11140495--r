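#' Shift particle centers by a local-frame offset
#'
#' Moves every particle by `R(orientation) %*% offset_local` (e.g. to reset
#' the center to a symmetry center found in the average). Orientations are
#' unchanged.
#'
#' @param set A [particle_set].
#' @param offset_local Numeric length-3 local-frame offset, voxels.
#' @return The recentered [particle_set].
#' @export
recenter <- function(set, offset_local) {
  stopifnot(length(offset_local) == 3L)
  mats <- particle_matrices(set)
  for (i in seq_len(nrow(set))) {
    p <- c(set$x[i], set$y[i], set$z[i]) + drop(mats[[i]] %*% offset_local)
    set$x[i] <- p[1L]; set$y[i] <- p[2L]; set$z[i] <- p[3L]
  }
  set
}

#' Convert Y-axis particle frames to the Relion Z-axis convention
#'
#' Right-composes every orientation with the fixed frame change that maps
#' local Y onto local Z: afterwards the image of local Z equals the previous
#' image of local Y (the stalkInit axis ends up on the Relion rotation
#' axis). Positions are unchanged.
#'
#' @param set A [particle_set].
#' @return The converted [particle_set].
#' @export
yaxis_to_z <- function(set) {
  C <- rot_x(-90)
  for (i in seq_len(nrow(set))) {
    R <- euler_to_matrix(set$rot[i], set$tilt[i], set$psi[i]) %*% C
    e <- matrix_to_euler(R)
    set$rot[i] <- e[1L]; set$tilt[i] <- e[2L]; set$psi[i] <- e[3L]
  }
  set
}

#' Export a place-back marker file and a cleaned STAR
#'
#' Writes (a) a plain-text transform/marker file with one line per kept
#' particle — position, the tomogram-frame images of the three local axes
#' and the curvature proxy (mean neighbor tilt) — suitable for placing the
#' averaged structure back into the tomogram, and (b) a STAR file containing
#' only the particles not flagged bad. Optionally also writes ChimeraX
#' marker XML (`.cmm`).
#'
#' @param set A [particle_set].
#' @param stats Output of [neighbor_stats()] computed on `set`.
#' @param prefix Output path prefix; writes `<prefix>_markers.txt` and
#'   `<prefix>_clean.star` (and `<prefix>.cmm` when requested).
#' @param bad Logical vector of bad flags; defaults to
#'   `classify_bad(stats)`.
#' @param cmm Also write ChimeraX markers.
#' @return Character vector of written paths, invisibly.
#' @export
export_placeback <- function(set, stats, prefix, bad = NULL, cmm = FALSE) {
  if (nrow(stats) != nrow(set))
    stop("stats/set length mismatch")
  if (is.null(bad)) bad <- classify_bad(stats)
  if (length(bad) != nrow(set)) stop("stats/set length mismatch")
  keep <- which(!bad)
  mats <- particle_matrices(set)
  marker_path <- paste0(prefix, "_markers.txt")
  hdr <- paste("# index x y z ax_x ax_y ax_z ay_x ay_y ay_z az_x az_y az_z",
               "curvature")
  lines <- vapply(keep, function(i) {
    R <- mats[[i]]
    cv <- stats$curvature_proxy[i]
    sprintf("%d %.6f %.6f %.6f %s %s %s %s", i, set$x[i], set$y[i], set$z[i],
            paste(sprintf("%.6f", R[, 1L]), collapse = " "),
            paste(sprintf("%.6f", R[, 2L]), collapse = " "),
            paste(sprintf("%.6f", R[, 3L]), collapse = " "),
            if (is.na(cv)) "NA" else sprintf("%.6f", cv))
  }, character(1L))
  writeLines(c(hdr, lines), marker_path)
  star_path <- paste0(prefix, "_clean.star")
  write_star_particles(set[keep, , drop = FALSE], star_path)
  paths <- c(marker_path, star_path)
  if (cmm) {
    cmm_path <- paste0(prefix, ".cmm")
    ml <- vapply(keep, function(i)
      sprintf(paste0('<marker id="%d" x="%.3f" y="%.3f" z="%.3f"',
                     ' radius="2" r="0.2" g="0.8" b="0.2"/>'),
              i, set$x[i], set$y[i], set$z[i]), character(1L))
    writeLines(c('<marker_set name="latticepick">', ml, "</marker_set>"),
               cmm_path)
    paths <- c(paths, cmm_path)
  }
  invisible(paths)
}

#' Parse a place-back marker file
#'
#' @param path Marker file written by [export_placeback()].
#' @return A `data.frame` with the particle index, position, axis images and
#'   curvature.
#' @export
read_placeback_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("index", "x", "y", "z",
                                         "ax_x", "ax_y", "ax_z",
                                         "ay_x", "ay_y", "ay_z",
                                         "az_x", "az_y", "az_z",
                                         "curvature"),
                           na.strings = "NA")
  tab
}

#' Assemble per-tomogram particle tables into one set
#'
#' Concatenates particle sets, disambiguating duplicate tomogram names, and
#' runs a duplicate check at `d_min` within each tomogram (earlier sets take
#' precedence).
#'
#' @param sets A list of [particle_set] objects.
#' @param d_min Duplicate distance, voxels; `NULL` disables the check.
#' @return A single [particle_set].
#' @export
assemble_particle_sets <- function(sets, d_min = NULL) {
  stopifnot(length(sets) > 0L)
  seen <- character()
  for (i in seq_along(sets)) {
    nm <- unique(sets[[i]]$tomo_name)
    nm <- if (length(nm)) nm[1L] else sprintf("tomo%03d", i)
    if (nm %in% seen) nm <- sprintf("%s_%d", nm, i)
    if (nrow(sets[[i]])) sets[[i]]$tomo_name <- nm
    seen <- c(seen, nm)
  }
  out <- do.call(rbind_particle_sets, sets)
  if (!is.null(d_min) && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (nm in unique(out$tomo_name)) {
      ii <- which(out$tomo_name == nm)
      if (length(ii) < 2L) next
      D <- as.matrix(stats::dist(particle_positions(out[ii, , drop = FALSE])))
      for (a in seq_along(ii)) {
        if (!keep[ii[a]]) next
        dup <- which(D[a, ] < d_min)
        dup <- dup[dup > a]
        keep[ii[dup]] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  as_particle_set(as.data.frame(out), voxel_size = attr(sets[[1L]],
                                                        "voxel_size"))
}
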