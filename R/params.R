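#' Expansion control parameters
#'
#' The JSON-serializable control block for auto expansion: pose-search ranges
#' and steps, the transition list encoding the lattice topology, the box used
#' for alignment, the lattice spacing, the correlation acceptance threshold
#' and termination caps.
#'
#' Angular offsets are searched on a grid of intrinsic rotations about the
#' particle's local Z (`rot`), Y (`tilt`) and X (`psi`) axes, composed after
#' the prior orientation; this parametrization spans all three rotational
#' degrees of freedom at first order (see the package vignette).
#'
#' @param angular_ranges Half-ranges `(rot, tilt, psi)` in degrees.
#' @param angular_steps Step(s) in degrees (recycled to length 3). Must be
#'   positive wherever the matching range is positive.
#' @param translational_range Half-range of the shift search, voxels.
#' @param translational_step Shift step, voxels.
#' @param transition_list Numeric `k x 3` matrix of local-frame displacement
#'   vectors (voxels) from a particle to its expected neighbors.
#' @param box_size Side of the cubic alignment box, voxels.
#' @param spacing Expected neighbor distance, voxels.
#' @param cc_threshold Acceptance threshold in `(-1, 1]`.
#' @param max_iterations Iteration cap (`>= 0`); 0 means regather-only.
#' @param d_min Duplicate-merging distance, voxels. Defaults to
#'   `0.5 * spacing`.
#' @param max_attempts Cap on alignment attempts per spatial cell of side
#'   `d_min`, guaranteeing termination when rejected positions are
#'   re-proposed.
#' @param refine_subgrid Polish the grid argmax by a bounded continuous
#'   optimization confined to half a grid step in every pose parameter.
#'   Removes the orientation bias that integer shift grids alias out of
#'   sub-voxel lattice positions; never leaves the winning grid cell.
#' @return An object of class `expansion_params`.
#' @export
expansion_params <- function(angular_ranges = c(8, 8, 8), angular_steps = 4,
                             translational_range = 2, translational_step = 1,
                             transition_list = hex_transitions(8),
                             box_size = 16, spacing = 8, cc_threshold = 0.5,
                             max_iterations = 20, d_min = 0.5 * spacing,
                             max_attempts = 3, refine_subgrid = TRUE) {
  angular_ranges <- rep_len(as.numeric(angular_ranges), 3L)
  angular_steps <- rep_len(as.numeric(angular_steps), 3L)
  transition_list <- matrix(as.numeric(transition_list), ncol = 3L)
  if (nrow(transition_list) == 0L) stop("transition list must be non-empty")
  len <- sqrt(rowSums(transition_list^2))
  if (any(len == 0)) stop("transition list contains a zero-length vector")
  if (any(angular_ranges > 0 & angular_steps <= 0))
    stop("angular step must be > 0 where the range is > 0")
  if (translational_range > 0 && translational_step <= 0)
    stop("translational step must be > 0 where the range is > 0")
  if (!(cc_threshold > -1 && cc_threshold <= 1))
    stop("cc_threshold must lie in (-1, 1]")
  if (d_min <= 0) stop("d_min must be > 0")
  if (max_iterations < 0) stop("max_iterations must be >= 0")
  structure(list(
    angular_ranges = angular_ranges, angular_steps = angular_steps,
    translational_range = as.numeric(translational_range),
    translational_step = as.numeric(translational_step),
    transition_list = transition_list, box_size = as.integer(box_size),
    spacing = as.numeric(spacing), cc_threshold = as.numeric(cc_threshold),
    max_iterations = as.integer(max_iterations), d_min = as.numeric(d_min),
    max_attempts = as.integer(max_attempts),
    refine_subgrid = isTRUE(refine_subgrid)
  ), class = "expansion_params")
}

#' @export
print.expansion_params <- function(x, ...) {
  cat("expansion_params:\n")
  cat(sprintf("  angular half-ranges %s deg, steps %s deg\n",
              paste(x$angular_ranges, collapse = "/"),
              paste(x$angular_steps, collapse = "/")))
  cat(sprintf("  translational range %g voxels, step %g\n",
              x$translational_range, x$translational_step))
  cat(sprintf("  %d transitions, box %d, spacing %g, cc >= %g\n",
              nrow(x$transition_list), x$box_size, x$spacing, x$cc_threshold))
  cat(sprintf("  max %d iterations, d_min %g, max %d attempts/cell\n",
              x$max_iterations, x$d_min, x$max_attempts))
  invisible(x)
}

#' Six-neighbor hexagonal transition list
#'
#' In-plane displacement vectors of one lattice constant at 60-degree
#' increments, in the local X-Z plane (the plane normal to the particle's
#' local Y axis).
#'
#' @param spacing Lattice constant in voxels.
#' @return A `6 x 3` numeric matrix.
#' @export
hex_transitions <- function(spacing) {
  k <- 0:5
  cbind(spacing * cos(k * pi / 3), 0, spacing * sin(k * pi / 3))
}

#' Read or write expansion parameters as JSON
#'
#' The JSON schema mirrors the fields of [expansion_params()] key for key;
#' `transition_list` is a list of `[sx, sy, sz]` triples in voxels.
#'
#' @param params An `expansion_params` object.
#' @param path File path.
#' @return `read_expansion_params` returns an `expansion_params` object;
#'   `write_expansion_params` returns `path` invisibly.
#' @export
write_expansion_params <- function(params, path) {
  stopifnot(inherits(params, "expansion_params"))
  x <- unclass(params)
  x$transition_list <- lapply(seq_len(nrow(params$transition_list)),
                              function(i) params$transition_list[i, ])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_expansion_params
#' @export
read_expansion_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tl <- x$transition_list
  if (is.list(tl)) tl <- do.call(rbind, tl)
  expansion_params(
    angular_ranges = x$angular_ranges, angular_steps = x$angular_steps,
    translational_range = x$translational_range,
    translational_step = x$translational_step,
    transition_list = tl, box_size = x$box_size, spacing = x$spacing,
    cc_threshold = x$cc_threshold, max_iterations = x$max_iterations,
    d_min = if (is.null(x$d_min)) 0.5 * x$spacing else x$d_min,
    max_attempts = if (is.null(x$max_attempts)) 3L else x$max_attempts,
    refine_subgrid = if (is.null(x$refine_subgrid)) TRUE else x$refine_subgrid
  )
}
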