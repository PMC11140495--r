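#' Masked normalized cross-correlation
#'
#' Pearson correlation of two equally shaped volumes under non-negative mask
#' weights: both volumes are mean-centered and variance-normalized with the
#' mask as weights. Returns 0 when either masked variance falls below 1e-12
#' (e.g. a constant or empty region).
#'
#' @param a,b Numeric arrays of identical shape.
#' @param mask Optional weight array of the same shape with values in
#'   `[0, 1]` and positive sum; `NULL` means all ones.
#' @return A correlation coefficient in `[-1, 1]`.
#' @export
masked_cc <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between the two volumes")
  if (is.null(mask)) {
    w <- rep(1, length(a))
  } else {
    if (!identical(dim(a), dim(mask)))
      stop("shape mismatch between volume and mask")
    w <- as.numeric(mask)
    if (any(w < 0) || any(w > 1) || sum(w) <= 0)
      stop("mask values must lie in [0, 1] with positive sum")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  sw <- sum(w)
  ma <- sum(w * a) / sw
  mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2)
  vb <- sum(w * (b - mb)^2)
  if (va < 1e-12 || vb < 1e-12) return(0)
  sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
}

#' Pose search grid from expansion parameters
#'
#' Enumerates the rotation offsets (intrinsic rotations about the local Z, Y
#' and X axes by the `rot`, `tilt` and `psi` offsets respectively, composed
#' as `Rz %*% Ry %*% Rx`) and the shift offsets. Both grids always contain
#' the zero offset.
#'
#' @param params An [expansion_params].
#' @return A list with `rot_offsets` (`n x 3` matrix of offset angles,
#'   degrees), `rot_mats` (list of offset matrices), `shifts` (`m x 3`
#'   matrix, voxels) and the indices of the zero offsets.
#' @export
search_grid <- function(params) {
  axis_seq <- function(range, step) {
    if (range <= 0) return(0)
    k <- floor(range / step + 1e-9)
    seq(-k, k) * step
  }
  aa <- axis_seq(params$angular_ranges[1L], params$angular_steps[1L])
  bb <- axis_seq(params$angular_ranges[2L], params$angular_steps[2L])
  cc <- axis_seq(params$angular_ranges[3L], params$angular_steps[3L])
  rot_offsets <- as.matrix(expand.grid(rot = aa, tilt = bb, psi = cc,
                                       KEEP.OUT.ATTRS = FALSE))
  rot_mats <- lapply(seq_len(nrow(rot_offsets)), function(i)
    rot_z(rot_offsets[i, 1L]) %*% rot_y(rot_offsets[i, 2L]) %*%
      rot_x(rot_offsets[i, 3L]))
  ss <- axis_seq(params$translational_range, params$translational_step)
  shifts <- as.matrix(expand.grid(x = ss, y = ss, z = ss,
                                  KEEP.OUT.ATTRS = FALSE))
  list(rot_offsets = rot_offsets, rot_mats = rot_mats, shifts = shifts,
       izero_rot = which(rowSums(abs(rot_offsets)) == 0)[1L],
       izero_shift = which(rowSums(abs(shifts)) == 0)[1L])
}

#' Constrained rigid alignment of a subvolume to a reference
#'
#' Exhaustively evaluates the masked cross-correlation between the subvolume
#' extracted around each shifted position and the reference rotated by
#' `prior` composed with each rotation offset, and returns the best pose.
#' Ties are broken by smallest shift norm, then smallest angular offset norm,
#' then enumeration order. The zero offset is always in the grid, so the
#' returned cc is never below the prior pose's cc.
#'
#' @param tomo Tomogram volume (3D array).
#' @param prior_position Numeric length-3, 0-based voxel coordinates.
#' @param prior_orientation Euler angles `c(rot, tilt, psi)` in degrees or a
#'   3x3 matrix.
#' @param reference Reference volume; a cube of side `params$box_size`.
#' @param mask Mask volume of the same shape as `reference` (or `NULL`).
#'   Applied in the extraction frame (not rotated); use a spherical mask
#'   unless you know better.
#' @param params An [expansion_params].
#' @param label Identifier used in error messages.
#' @return A list with `position`, `orientation` (Euler degrees), `cc`,
#'   `cc_prior`, `rot_offset` and `shift`.
#' @export
constrained_align <- function(tomo, prior_position, prior_orientation,
                              reference, mask = NULL, params,
                              label = "particle") {
  box <- params$box_size
  if (!all(dim(reference) == box))
    stop("reference must be a cube of side box_size")
  if (is.null(mask)) mask <- array(1, dim(reference))
  if (!identical(dim(mask), dim(reference)))
    stop("mask/reference shape mismatch")
  half <- (box - 1) / 2
  reach <- half + params$translational_range
  dims <- dim(tomo)
  if (any(prior_position - reach < 0) ||
      any(prior_position + reach > dims - 1))
    stop(sprintf("alignment box out of bounds for %s at (%.1f, %.1f, %.1f)",
                 label, prior_position[1L], prior_position[2L],
                 prior_position[3L]))
  g <- search_grid(params)
  priorR <- as_rotmat(prior_orientation)
  rots <- vapply(g$rot_mats, function(m) as.numeric(priorR %*% m), numeric(9L))
  res <- grid_align_cpp(as.numeric(tomo), dims, as.numeric(prior_position),
                        rots, sqrt(rowSums(g$rot_offsets^2)),
                        g$shifts, sqrt(rowSums(g$shifts^2)),
                        as.numeric(reference), dim(reference),
                        as.numeric(mask),
                        g$izero_rot - 1L, g$izero_shift - 1L)
  bestR <- matrix(rots[, res$irot], 3L, 3L)
  out <- list(position = unname(as.numeric(prior_position) +
                                  g$shifts[res$ishift, ]),
              orientation = matrix_to_euler(bestR),
              cc = res$cc, cc_prior = res$cc_prior,
              rot_offset = unname(g$rot_offsets[res$irot, ]),
              shift = unname(g$shifts[res$ishift, ]))
  if (isTRUE(params$refine_subgrid)) {
    # integer shift grids alias sub-voxel lattice positions into orientation
    # error along the position-orientation ridge of the cc surface, which can
    # demote the true basin's grid sample below a secondary basin; polishing
    # the few best rotation candidates and keeping the best polished result
    # makes the refinement robust to that aliasing
    k <- min(3L, nrow(g$rot_offsets))
    sep <- 1.5 * max(params$angular_steps)
    ord <- order(res$rot_best_cc, decreasing = TRUE)
    top <- res$irot
    for (ir in ord) {
      if (length(top) >= k) break
      dmin <- min(sqrt(rowSums((g$rot_offsets[top, , drop = FALSE] -
                                  matrix(g$rot_offsets[ir, ], length(top),
                                         3L, byrow = TRUE))^2)))
      if (dmin >= sep) top <- c(top, ir)
    }
    best <- NULL
    for (ir in top) {
      is_ <- res$rot_best_shift[ir]
      cand <- list(position = unname(as.numeric(prior_position) +
                                       g$shifts[is_, ]),
                   orientation = matrix_to_euler(matrix(rots[, ir], 3L, 3L)),
                   cc = res$rot_best_cc[ir])
      cand <- polish_pose(tomo, dims, cand, reference, mask, params)
      if (is.null(best) || cand$cc > best$cc) best <- cand
    }
    # the prior pose itself seeds one more polish: with sub-voxel lattice
    # positions the integer grid often scores the true basin below a
    # compensating one, while the prior sits within polish reach of it
    pr <- polish_pose(tomo, dims,
                      list(position = as.numeric(prior_position),
                           orientation = matrix_to_euler(priorR),
                           cc = res$cc_prior),
                      reference, mask, params,
                      shift_bound = max(params$translational_range,
                                        1.5 * params$translational_step))
    if (pr$cc > best$cc) best <- pr
    # with the position pinned (sub-voxel accurate after polishing), a
    # rotation-only rescan of the full grid is free of the ridge confound;
    # alternate rescan and polish until stable
    tv <- as.numeric(tomo); rv <- as.numeric(reference)
    mv <- as.numeric(mask); rdim <- dim(reference)
    Qs <- vapply(g$rot_mats, function(m) as.numeric(priorR %*% m),
                 numeric(9L))
    for (round in 1:3) {
      ccs <- cc_at_poses_cpp(tv, dims, best$position, Qs, rv, rdim, mv)
      ir <- which.max(ccs)
      cand <- list(position = best$position,
                   orientation = matrix_to_euler(priorR %*% g$rot_mats[[ir]]),
                   cc = ccs[ir])
      cand <- polish_pose(tomo, dims, cand, reference, mask, params)
      if (cand$cc > best$cc) best <- cand else break
    }
    if (best$cc >= out$cc) {
      out$position <- best$position
      out$orientation <- best$orientation
      out$cc <- best$cc
    }
  }
  out
}

# Bounded sub-grid polish of the grid argmax: cyclic golden-section descent
# over the six pose parameters around the winning grid point. An integer
# shift grid aliases sub-voxel lattice positions into compensating
# orientation error (the position-orientation ridge of the cc surface), and
# the aliasing can push the discrete argmax a cell or two along the ridge;
# the polish follows the ridge back to its crest. Bounds: one shift step and
# two angular steps per axis, so the result stays local to the grid optimum,
# and only strict cc improvements are accepted (the returned cc can never
# drop below the grid argmax, hence never below the prior pose).
polish_pose <- function(tomo, dims, res, reference, mask, params,
                        shift_bound = NULL, ang_bound = NULL) {
  hs <- if (is.null(shift_bound)) 1.5 * params$translational_step else
    shift_bound
  ha <- if (is.null(ang_bound)) 5 * params$angular_steps else ang_bound
  ha <- rep_len(ha, 3L)
  if (params$translational_range <= 0) hs <- 0
  ha[params$angular_ranges <= 0] <- 0
  tv <- as.numeric(tomo); rv <- as.numeric(reference); mv <- as.numeric(mask)
  rdim <- dim(reference)
  p0 <- res$position
  R <- euler_to_matrix(res$orientation)
  p <- p0
  ccf <- function(pos, Q) cc_at_pose_cpp(tv, dims, pos, as.numeric(Q), rv,
                                         rdim, mv)
  best <- ccf(p, R)
  axrot <- list(rot_z, rot_y, rot_x)
  for (rep_ in 1:2) {
    rep_start <- best
    # rotation: exhaustive 1-degree scans about each local axis with the
    # position held fixed -- immune to the position-orientation ridge
    for (pass in 1:2) for (k in c(2L, 1L, 3L)) {
      if (ha[k] <= 0) next
      ts <- seq(-ha[k], ha[k], by = 1)
      ccs <- vapply(ts, function(t_) ccf(p, R %*% axrot[[k]](t_)), numeric(1L))
      i <- which.max(ccs)
      if (ccs[i] > best) { best <- ccs[i]; R <- R %*% axrot[[k]](ts[i]) }
    }
    # position: bounded Nelder-Mead at the current orientation
    if (hs > 0) {
      obj <- function(q) -ccf(p0 + pmin(hs, pmax(-hs, q)), R)
      o <- stats::optim(p - p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 150, reltol = 1e-10,
                                       parscale = rep(3, 3L)))
      if (-o$value > best) {
        best <- -o$value
        p <- p0 + pmin(hs, pmax(-hs, o$par))
      }
    }
    if (best - rep_start < 1e-7) break # converged, skip the second sweep
  }
  # final joint sub-degree / sub-voxel refinement
  free <- c(if (hs > 0) 1:3, 3L + which(ha > 0))
  if (length(free)) {
    obj <- function(q) {
      par <- numeric(6L)
      par[free] <- q
      pos <- p0 + pmin(hs, pmax(-hs, (p - p0) + par[1:3]))
      Q <- R %*% rot_z(par[4L]) %*% rot_y(par[5L]) %*% rot_x(par[6L])
      -ccf(pos, Q)
    }
    o <- stats::optim(numeric(length(free)), obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10,
                                     parscale = c(2, 2, 2, 8, 8, 8)[free]))
    if (-o$value > best) {
      best <- -o$value
      par <- numeric(6L)
      par[free] <- o$par
      p <- p0 + pmin(hs, pmax(-hs, (p - p0) + par[1:3]))
      R <- R %*% rot_z(par[4L]) %*% rot_y(par[5L]) %*% rot_x(par[6L])
    }
  }
  if (best > res$cc) {
    res$position <- p
    res$orientation <- matrix_to_euler(R)
    res$cc <- best
  }
  res
}
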