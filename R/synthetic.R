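#' Ground-truth lattice container
#'
#' Holds the generator output every downstream stage is scored against: site
#' positions (0-based voxel coordinates), site frames (ZYZ Euler degrees,
#' local frame to tomogram), a patch identifier per site and the lattice
#' constant.
#'
#' @param positions Numeric `n x 3` matrix.
#' @param angles Numeric `n x 3` matrix of Euler angles in degrees.
#' @param patch_id Integer vector (recycled).
#' @param spacing Lattice constant, voxels.
#' @return An object of class `lattice_truth`.
#' @export
lattice_truth <- function(positions, angles, patch_id = 1L, spacing) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  angles <- matrix(as.numeric(angles), ncol = 3L)
  stopifnot(nrow(positions) == nrow(angles))
  structure(list(positions = positions, angles = angles,
                 patch_id = rep_len(as.integer(patch_id), nrow(positions)),
                 spacing = as.numeric(spacing)),
            class = "lattice_truth")
}

#' @export
print.lattice_truth <- function(x, ...) {
  cat(sprintf("lattice_truth: %d sites in %d patch(es), spacing %g voxels\n",
              nrow(x$positions), length(unique(x$patch_id)), x$spacing))
  invisible(x)
}

truth_matrices <- function(truth) {
  lapply(seq_len(nrow(truth$positions)), function(i)
    euler_to_matrix(truth$angles[i, ]))
}

truth_matrices_flat <- function(truth) {
  t(vapply(truth_matrices(truth), as.numeric, numeric(9L)))
}

#' Synthetic particle template
#'
#' A compact density made of four non-coplanar Gaussian blobs of distinct
#' amplitude, so that no rotation maps the template onto itself and full
#' orientation recovery is well-posed. The blob along local +Y marks the
#' lattice-normal axis; the two off-axis blobs put roughly half of the
#' template energy into in-plane features, which is what makes the in-plane
#' spin sharply recoverable by correlation. (Two blobs, the minimal
#' asymmetric choice, would leave a continuous spin degeneracy about the
#' axis through their centers.)
#'
#' @param box_size Cube side in voxels.
#' @param blobs Optional `data.frame` with columns `x, y, z, sigma, amp`
#'   (local offsets in voxels) overriding the default four-blob layout.
#' @param reach Support radius in voxels: every blob is smoothly truncated
#'   (`max(0, g - g(cut))`) so the whole template vanishes beyond `reach`
#'   from the center. With `reach` at half the lattice spacing, neighboring
#'   copies on a lattice contribute exactly zero inside an alignment mask of
#'   the same support, which keeps the correlation optimum free of
#'   neighbor-density bias.
#' @return A `box_size^3` numeric array with values in roughly `[0, 1]`.
#' @export
make_template <- function(box_size = 12, blobs = NULL, reach = 4) {
  if (is.null(blobs))
    blobs <- data.frame(x = c(0, 0, 1.7, -0.7), y = c(0, 1.7, 0.4, -0.4),
                        z = c(0, 0, 0, 1.4),
                        sigma = c(1.4, 1.0, 1.2, 0.9),
                        amp = c(0.6, 0.9, 1.0, 0.8))
  c0 <- (box_size - 1) / 2
  ax <- seq_len(box_size) - 1 - c0
  g <- expand.grid(x = ax, y = ax, z = ax)
  v <- numeric(nrow(g))
  for (i in seq_len(nrow(blobs))) {
    r2 <- (g$x - blobs$x[i])^2 + (g$y - blobs$y[i])^2 + (g$z - blobs$z[i])^2
    cut <- reach - sqrt(blobs$x[i]^2 + blobs$y[i]^2 + blobs$z[i]^2)
    if (cut <= 0) stop("blob offset exceeds the template reach")
    floor_ <- exp(-cut^2 / (2 * blobs$sigma[i]^2))
    v <- v + blobs$amp[i] * pmax(0, exp(-r2 / (2 * blobs$sigma[i]^2)) -
                                      floor_)
  }
  array(v, dim = rep(box_size, 3L))
}

#' Soft spherical alignment mask
#'
#' @param box_size Cube side in voxels.
#' @param radius Radius of the flat core, voxels.
#' @param soft Width of the cosine falloff, voxels.
#' @return A `box_size^3` array with values in `[0, 1]`.
#' @export
make_default_mask <- function(box_size, radius = 0.35 * box_size, soft = 1) {
  c0 <- (box_size - 1) / 2
  ax <- seq_len(box_size) - 1 - c0
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  v <- ifelse(r <= radius, 1,
              ifelse(r >= radius + soft, 0,
                     0.5 * (1 + cos(pi * (r - radius) / soft))))
  array(v, dim = rep(box_size, 3L))
}

# frame with local Y along tomogram +Z (the flat-lattice convention):
# columns X, Y, Z = (+x, +z, -y)
flat_frame <- function() rot_x(90)

# axial hexagon coordinates with max(|q|,|r|,|q+r|) <= radius
hex_axial_sites <- function(radius) {
  g <- expand.grid(q = -radius:radius, r = -radius:radius)
  g[pmax(abs(g$q), abs(g$r), abs(g$q + g$r)) <= radius, , drop = FALSE]
}

axial_to_cart <- function(q, r, spacing, origin = c(0, 0, 0)) {
  cbind(origin[1L] + spacing * (q + r / 2),
        origin[2L] + spacing * r * sqrt(3) / 2,
        origin[3L])
}

#' Flat hexagonal lattice patch
#'
#' A rhombic patch of a hexagonal lattice in a plane of constant z, with every
#' site frame mapping local Y onto tomogram +Z. Used by the cleaning tests
#' and as a building block for larger fixtures.
#'
#' @param n1,n2 Number of sites along the two lattice directions.
#' @param spacing Lattice constant, voxels.
#' @param origin Position of the first site.
#' @return A [lattice_truth].
#' @export
make_planar_lattice <- function(n1, n2, spacing, origin = c(0, 0, 0)) {
  g <- expand.grid(q = seq_len(n1) - 1L, r = seq_len(n2) - 1L)
  pos <- axial_to_cart(g$q, g$r, spacing, origin)
  ang <- matrix(rep(matrix_to_euler(flat_frame()), each = nrow(pos)),
                ncol = 3L)
  lattice_truth(pos, ang, 1L, spacing)
}

#' The two-patch hexagonal worked-example fixture
#'
#' Constructs the geometry behind the package's worked expansion example: a
#' hexagonal patch of axial radius 4 (61 sites) with site `(3, 1)` removed
#' (60 sites), a disjoint radius-1 patch of 7 sites at least four lattice
#' constants away, three seed particles at axial `(4, 0)`, `(0, 0)` and
#' `(-3, 0)`, the six-neighbor transition list, and a noise-free rendering of
#' one oriented template copy per site. By construction the three seeds
#' generate exactly 18 distinct candidate positions of which 14 coincide with
#' density-bearing sites.
#'
#' @param spacing Lattice constant, voxels (must be `>= 6`).
#' @param volume_shape Integer vector of length 3. Must be large enough to
#'   hold both patches plus an alignment margin; if not, the error names the
#'   minimal shape.
#' @return A list with elements `truth`, `seeds` (a [particle_set]),
#'   `volume`, `template`, `reference`, `mask`, `transition_list` and
#'   `params` (an [expansion_params] matching the worked example's search
#'   settings).
#' @export
make_fig3_fixture <- function(spacing = 8, volume_shape = c(160, 80, 48)) {
  if (spacing < 6) stop("spacing must be >= 6 voxels")
  volume_shape <- as.integer(volume_shape)

  axA <- hex_axial_sites(4L)
  axA <- axA[!(axA$q == 3L & axA$r == 1L), , drop = FALSE]
  cA <- c(7 * spacing, 5 * spacing, volume_shape[3L] / 2)
  posA <- axial_to_cart(axA$q, axA$r, spacing, cA)

  axB <- hex_axial_sites(1L)
  cB <- cA + c(9.5 * spacing, 0, 0)
  posB <- axial_to_cart(axB$q, axB$r, spacing, cB)

  pos <- rbind(posA, posB)
  ang <- matrix(rep(matrix_to_euler(flat_frame()), each = nrow(pos)),
                ncol = 3L)
  truth <- lattice_truth(pos, ang, rep(c(1L, 2L), c(nrow(posA), nrow(posB))),
                         spacing)

  margin <- spacing + 4
  need <- ceiling(apply(pos, 2L, max) + margin)
  lowok <- all(pos - margin >= 0)
  if (!lowok || any(need > volume_shape))
    stop(sprintf("volume_shape too small; need at least c(%s)",
                 paste(pmax(need, ceiling(2 * margin)), collapse = ", ")))

  seed_ax <- cbind(q = c(4L, 0L, -3L), r = c(0L, 0L, 0L))
  seed_pos <- axial_to_cart(seed_ax[, 1L], seed_ax[, 2L], spacing, cA)
  seeds <- particle_set(seed_pos,
                        angles = matrix(rep(matrix_to_euler(flat_frame()),
                                            each = 3L), ncol = 3L),
                        status = "seed", tomo_name = "fig3")

  template <- make_template(12)
  box <- 2L * as.integer(spacing)
  reference <- make_template(box)
  mask <- make_default_mask(box, radius = 0.44 * spacing, soft = 0.5)
  params <- expansion_params(
    angular_ranges = c(8, 8, 8), angular_steps = 4,
    translational_range = 2, translational_step = 1,
    transition_list = hex_transitions(spacing), box_size = box,
    spacing = spacing, cc_threshold = 0.5, max_iterations = 20,
    d_min = spacing / 2
  )
  volume <- render_tomogram(truth, template, volume_shape, noise_sigma = 0)
  list(truth = truth, seeds = seeds, volume = volume, template = template,
       reference = reference, mask = mask,
       transition_list = params$transition_list, params = params)
}

#' Near-hexagonal lattice on a sphere
#'
#' Generates an approximately hexagonal packing on a sphere: a Fibonacci
#' point set relaxed so that every site's nearest neighbor lies within 1% of
#' the requested spacing (the site count is set to 93% of the flat-packing
#' estimate `4*pi*R^2 / (sqrt(3)/2 * d^2)`, the density at which that band is
#' attainable despite the packing's unavoidable disclinations). Each site
#' frame has local Y along the outward radial direction; the in-plane spin
#' follows the azimuthal direction around a reference axis placed through
#' lattice face centers, so the two frame-field vortices that the hairy-ball
#' theorem forces onto any sphere sit maximally far from the sites. Adjacent
#' frames then differ by the geodesic tilt (`spacing / radius`) plus a spin
#' twist that grows toward the two vortex points — the reason the tracer
#' searches a wide spin range on spherical lattices.
#'
#' @param radius Sphere radius, voxels (`> spacing`).
#' @param spacing Target nearest-neighbor distance, voxels.
#' @param coverage Fraction of the sphere retained as one contiguous cap, in
#'   `(0, 1]`. Note the cap rim keeps the full-sphere geometry, so rim sites
#'   may lose their nearest neighbor to the cut.
#' @param seed Integer seed controlling cap placement.
#' @param center Sphere center in voxel coordinates; defaults to
#'   `rep(radius + 1.5 * spacing, 3)` so the lattice fits a cube of side
#'   `ceiling(2 * (radius + 1.5 * spacing))`.
#' @param n_pass Relaxation passes.
#' @return A [lattice_truth]; also carries the sphere `center` and `radius`
#'   as attributes.
#' @export
make_spherical_lattice <- function(radius, spacing, coverage = 1, seed = 1,
                                   center = NULL, n_pass = 1200) {
  if (radius <= spacing) stop("infeasible: radius must exceed spacing")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (is.null(center)) center <- rep(radius + 1.5 * spacing, 3L)
  d <- spacing
  n <- round(0.93 * 4 * pi * radius^2 / (sqrt(3) / 2 * d^2))
  if (n < 4) stop("infeasible: spacing too large for this radius")

  # Fibonacci start
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  P <- radius * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))

  # band relaxation: all pairs kept above 0.992 d, every site's nearest
  # neighbor pulled below 1.008 d
  lo <- 0.992 * d; hi <- 1.008 * d
  for (pass in seq_len(n_pass)) {
    Dm <- as.matrix(stats::dist(P)); diag(Dm) <- Inf
    dP <- matrix(0, n, 3L)
    ov <- which(Dm < lo & upper.tri(Dm), arr.ind = TRUE)
    if (nrow(ov)) {
      v <- P[ov[, 2L], , drop = FALSE] - P[ov[, 1L], , drop = FALSE]
      len <- Dm[ov]
      corr <- 0.45 * (len - lo) / len * v
      for (k in 1:3) {
        dP[, k] <- dP[, k] +
          unname(tapply(corr[, k], factor(ov[, 1L], levels = 1:n), sum,
                        default = 0)) -
          unname(tapply(corr[, k], factor(ov[, 2L], levels = 1:n), sum,
                        default = 0))
      }
    }
    nnj <- apply(Dm, 1L, which.min)
    nnd <- Dm[cbind(1:n, nnj)]
    far <- which(nnd > hi)
    if (length(far)) {
      v <- P[nnj[far], , drop = FALSE] - P[far, , drop = FALSE]
      dP[far, ] <- dP[far, ] + 0.4 * (nnd[far] - hi) / nnd[far] * v
    }
    dP[is.na(dP)] <- 0
    P <- P + dP
    P <- P * (radius / sqrt(rowSums(P^2)))
  }

  # contiguous cap
  set.seed(seed)
  if (coverage < 1) {
    a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
    cosmin <- 1 - 2 * coverage
    keep <- which((P %*% a) / radius >= cosmin)
    # root the frame propagation at the site closest to the cap center
    root <- keep[which.max((P[keep, , drop = FALSE] %*% a))]
    keep <- c(root, setdiff(keep, root))
    P <- P[keep, , drop = FALSE]
    n <- nrow(P)
  }

  # frames: local Y radial; in-plane spin follows the azimuthal direction
  # around a reference axis. Any tangent frame field on a sphere must carry
  # two vortices (hairy-ball theorem); the axis is chosen through lattice
  # face centers so both vortices sit maximally far from the sites.
  U <- P / radius
  Dm <- as.matrix(stats::dist(P)); diag(Dm) <- Inf
  axis <- pick_spin_axis(U, Dm < 1.35 * d)
  frames <- lapply(seq_len(n), function(i) {
    X <- cross3(axis, U[i, ])
    nx <- sqrt(sum(X^2))
    if (nx < 1e-6) { # site exactly on the axis: any tangent direction
      e <- if (abs(U[i, 1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
      X <- e - sum(e * U[i, ]) * U[i, ]
      nx <- sqrt(sum(X^2))
    }
    X <- X / nx
    cbind(X, U[i, ], cross3(X, U[i, ]))
  })

  # snap each spin to the local lattice azimuth (circular mean modulo the
  # 60-degree hexagonal symmetry): transition fans then point at actual
  # neighbors, and the residual inter-site spin mismatch is the smooth
  # lattice-orientation gradient plus exact 60-degree jumps at the
  # disclination scars
  for (i in seq_len(n)) {
    nb <- which(Dm[i, ] < 1.35 * d)
    if (!length(nb)) next
    va <- t(frames[[i]]) %*% t(P[nb, , drop = FALSE] - matrix(P[i, ],
                                                              length(nb), 3L,
                                                              byrow = TRUE))
    alpha <- atan2(va[3L, ], va[1L, ]) # in-plane azimuth, radians
    delta <- atan2(sum(sin(6 * alpha)), sum(cos(6 * alpha))) / 6
    frames[[i]] <- frames[[i]] %*% rot_y(-delta * 180 / pi)
  }

  ang <- t(vapply(frames, matrix_to_euler, numeric(3L)))
  pos <- sweep(P, 2L, center, "+")
  out <- lattice_truth(pos, ang, 1L, spacing)
  attr(out, "center") <- center
  attr(out, "radius") <- radius
  attr(out, "spin_axis") <- axis
  out
}

# choose the spin-reference axis: among centroids of mutually-adjacent site
# triangles, take the direction whose two poles are farthest from any site
pick_spin_axis <- function(U, adj) {
  n <- nrow(U)
  best <- c(0, 0, 1); bestscore <- -Inf
  for (i in seq_len(n - 2L)) {
    nbi <- which(adj[i, ] & seq_len(n) > i)
    for (j in nbi) for (k in nbi[nbi > j]) {
      if (!adj[j, k]) next
      a <- U[i, ] + U[j, ] + U[k, ]
      a <- a / sqrt(sum(a^2))
      ang <- acos(pmin(1, abs(U %*% a))) # angle to nearer pole
      score <- min(ang)
      if (score > bestscore) { bestscore <- score; best <- a }
    }
  }
  best
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# minimal rotation carrying unit vector u onto unit vector v
geodesic_rotation <- function(u, v) {
  cuv <- sum(u * v)
  if (cuv > 1 - 1e-12) return(diag(3))
  ax <- cross3(u, v)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) { # antipodal: rotate 180 about any perpendicular axis
    e <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    ax <- e - sum(e * u) * u
    return(rodrigues(ax / sqrt(sum(ax^2)), pi))
  }
  rodrigues(ax / s, atan2(s, cuv))
}

rodrigues <- function(axis, angle) {
  K <- matrix(c(0, axis[3L], -axis[2L], -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' 1D filament lattice along a circular arc
#'
#' Repeats along an arc of the given curvature (0 means a straight line along
#' +X), with consecutive arc-length spacing equal to `spacing`. Local Y is
#' the outward arc normal and local X the tangent, so the in-chain transition
#' axis is local X.
#'
#' @param n_repeats Number of repeats (`>= 2`).
#' @param spacing Arc-length repeat distance, voxels.
#' @param curvature Arc curvature in 1/voxels; `curvature * spacing` must not
#'   exceed 1.
#' @param origin Position of the first repeat.
#' @return A [lattice_truth].
#' @export
make_filament_lattice <- function(n_repeats, spacing, curvature = 0,
                                  origin = c(0, 0, 0)) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (curvature * spacing > 1)
    stop("geometry error: curvature * spacing exceeds 1")
  i <- seq_len(n_repeats) - 1
  if (curvature == 0) {
    pos <- cbind(origin[1L] + i * spacing, origin[2L], origin[3L])
    frames <- rep(list(diag(3)), n_repeats)
  } else {
    Rc <- 1 / curvature
    th <- i * spacing * curvature
    ctr <- origin + c(0, Rc, 0)
    pos <- cbind(ctr[1L] + Rc * sin(th), ctr[2L] - Rc * cos(th), ctr[3L])
    frames <- lapply(th, function(t_)
      cbind(c(cos(t_), sin(t_), 0), c(sin(t_), -cos(t_), 0), c(0, 0, -1)))
  }
  ang <- t(vapply(frames, matrix_to_euler, numeric(3L)))
  lattice_truth(pos, ang, 1L, spacing)
}

#' Render a synthetic tomogram from a lattice truth
#'
#' Sums one rotated-and-shifted copy of the template per site (trilinear
#' interpolation, zero padding) and adds i.i.d. Gaussian noise. Identical
#' `rng_seed` gives a bit-identical volume; the caller's RNG state is left
#' untouched.
#'
#' @param truth A [lattice_truth].
#' @param template Density template (3D array). Its largest side must be
#'   smaller than twice the lattice spacing to limit overlap.
#' @param volume_shape Integer vector of length 3.
#' @param noise_sigma Gaussian noise standard deviation in density units.
#' @param rng_seed Integer seed for the noise.
#' @return A numeric array of dimension `volume_shape`.
#' @export
render_tomogram <- function(truth, template, volume_shape, noise_sigma = 0,
                            rng_seed = 1) {
  stopifnot(inherits(truth, "lattice_truth"))
  volume_shape <- as.integer(volume_shape)
  if (max(dim(template)) >= 2 * truth$spacing)
    stop("template side must be smaller than twice the lattice spacing")
  pos <- truth$positions
  inside <- pos[, 1L] >= 0 & pos[, 2L] >= 0 & pos[, 3L] >= 0 &
    pos[, 1L] <= volume_shape[1L] - 1 & pos[, 2L] <= volume_shape[2L] - 1 &
    pos[, 3L] <= volume_shape[3L] - 1
  if (!all(inside))
    stop("site(s) out of bounds: ",
         paste(which(!inside), collapse = ", "))
  v <- render_sites_cpp(volume_shape, pos, truth_matrices_flat(truth),
                        as.numeric(template), dim(template))
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(rng_seed)
    v <- v + stats::rnorm(length(v), 0, noise_sigma)
  }
  array(v, dim = volume_shape)
}
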