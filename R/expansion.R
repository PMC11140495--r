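#' Generate candidate particles from seeds via the transition list
#'
#' For every seed `s` and transition `t` a candidate is proposed at
#' `position(s) + R(s) %*% t` carrying the seed's orientation as its prior.
#' Candidates falling within `d_min` of an already-picked particle, or of an
#' earlier candidate generated in the same call, are dropped (first
#' occurrence kept; enumeration order is seed order, then transition order).
#' Out-of-volume positions are kept here; they fail alignment later.
#'
#' @param seeds A [particle_set] with defined orientations.
#' @param transitions Numeric `k x 3` matrix of local-frame displacements
#'   (voxels).
#' @param picked A [particle_set] (or `n x 3` position matrix) of positions
#'   already in the particle set.
#' @param d_min Deduplication distance, voxels.
#' @return A [particle_set] of candidates (status `"candidate"`) with
#'   attributes `seed_index` and `transition_index`.
#' @export
generate_candidates <- function(seeds, transitions, picked, d_min) {
  stopifnot(nrow(seeds) > 0L)
  transitions <- matrix(as.numeric(transitions), ncol = 3L)
  pickpos <- if (is.matrix(picked)) picked else particle_positions(picked)
  mats <- particle_matrices(seeds)
  pos <- matrix(numeric(), 0L, 3L)
  ang <- matrix(numeric(), 0L, 3L)
  si <- integer(); ti <- integer()
  for (i in seq_len(nrow(seeds))) {
    offs <- transitions %*% t(mats[[i]]) # k x 3, rows R %*% t
    for (j in seq_len(nrow(transitions))) {
      p <- c(seeds$x[i], seeds$y[i], seeds$z[i]) + offs[j, ]
      near_picked <- nrow(pickpos) > 0L &&
        min(sqrt(rowSums((pickpos - matrix(p, nrow(pickpos), 3L,
                                           byrow = TRUE))^2))) < d_min
      near_cand <- nrow(pos) > 0L &&
        min(sqrt(rowSums((pos - matrix(p, nrow(pos), 3L,
                                       byrow = TRUE))^2))) < d_min
      if (near_picked || near_cand) next
      pos <- rbind(pos, p)
      ang <- rbind(ang, c(seeds$rot[i], seeds$tilt[i], seeds$psi[i]))
      si <- c(si, i); ti <- c(ti, j)
    }
  }
  out <- particle_set(pos, ang, cc = NA_real_, status = "candidate",
                      iteration_added = NA_integer_,
                      tomo_name = if (nrow(seeds)) seeds$tomo_name[1L] else
                        "tomo")
  attr(out, "seed_index") <- si
  attr(out, "transition_index") <- ti
  out
}

#' Run the iterative auto-expansion lattice tracer
#'
#' Each iteration proposes candidates adjacent to the current seeds via the
#' transition list, aligns each candidate to the reference on the constrained
#' pose grid, splits them at the correlation threshold, and promotes the
#' accepted particles (with refined poses) to be the next iteration's seeds.
#' All iteration-0 seeds and every accepted particle enter the final set,
#' which is kept duplicate-free at distance `d_min` with earlier particles
#' taking precedence. The run stops when no candidates remain or after
#' `params$max_iterations` iterations. Rejected positions may be re-proposed
#' from a different seed later, capped at `params$max_attempts` alignment
#' attempts per spatial cell of side `d_min`.
#'
#' @param tomo Tomogram volume (3D array).
#' @param seeds Non-empty [particle_set] of seed particles.
#' @param reference Reference volume, cube of side `params$box_size`.
#' @param mask Optional mask (same shape as `reference`).
#' @param params An [expansion_params].
#' @param run_dir Optional directory; when given, the run writes the
#'   three-directory layout `<tomo>`, `<tomo>_cache` (one JSON record per
#'   iteration) and `<tomo>_final` (final particle STAR) underneath it, plus
#'   a per-iteration count log.
#' @param verbose Log per-iteration counts to the console.
#' @return An object of class `expansion_run`: list with `records`, `final`
#'   (a [particle_set]), `stop_reason` and `params`.
#' @export
run_expansion <- function(tomo, seeds, reference, mask = NULL, params,
                          run_dir = NULL, verbose = FALSE) {
  if (!inherits(seeds, "particle_set") || nrow(seeds) == 0L)
    stop("empty seed set")
  if (!all(dim(reference) == params$box_size))
    stop("reference shape does not match box_size")
  if (!is.null(mask) && !identical(dim(mask), dim(reference)))
    stop("mask shape does not match the reference")
  tomo_name <- seeds$tomo_name[1L]

  dirs <- NULL
  if (!is.null(run_dir)) {
    dirs <- file.path(run_dir, paste0(tomo_name, c("", "_cache", "_final")))
    for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  logline <- function(...) {
    msg <- sprintf(...)
    if (verbose) message(msg)
    if (!is.null(dirs))
      cat(msg, "\n", sep = "", file = file.path(dirs[1L], "run.log"),
          append = TRUE)
  }

  seeds$status <- "seed"
  seeds$iteration_added <- 0L
  final <- seeds
  picked <- particle_positions(seeds)
  attempts <- new.env(parent = emptyenv())
  cellkey <- function(p) paste(floor(p / params$d_min), collapse = "_")
  cur <- seeds
  records <- list()
  stop_reason <- "max_iterations"

  it <- 0L
  while (it < params$max_iterations) {
    cand <- generate_candidates(cur, params$transition_list, picked,
                                params$d_min)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      k <- cellkey(c(cand$x[i], cand$y[i], cand$z[i]))
      n <- if (is.null(attempts[[k]])) 0L else attempts[[k]]
      n < params$max_attempts
    }, logical(1L))
    att <- cand[keep, , drop = FALSE]
    if (nrow(att) == 0L) { stop_reason <- "no_candidates"; break }

    aligned <- data.frame(
      prior_x = att$x, prior_y = att$y, prior_z = att$z,
      prior_rot = att$rot, prior_tilt = att$tilt, prior_psi = att$psi,
      x = NA_real_, y = NA_real_, z = NA_real_,
      rot = NA_real_, tilt = NA_real_, psi = NA_real_, cc = NA_real_
    )
    for (i in seq_len(nrow(att))) {
      k <- cellkey(c(att$x[i], att$y[i], att$z[i]))
      attempts[[k]] <- (if (is.null(attempts[[k]])) 0L else attempts[[k]]) + 1L
      res <- tryCatch(
        constrained_align(tomo, c(att$x[i], att$y[i], att$z[i]),
                          c(att$rot[i], att$tilt[i], att$psi[i]),
                          reference, mask, params,
                          label = sprintf("candidate %d (iteration %d)", i,
                                          it)),
        error = function(e) {
          if (!grepl("out of bounds", conditionMessage(e))) stop(e)
          NULL
        })
      if (is.null(res)) next # out of bounds: no computable cc, rejected
      aligned[i, c("x", "y", "z")] <- res$position
      aligned[i, c("rot", "tilt", "psi")] <- res$orientation
      aligned$cc[i] <- res$cc
    }
    aligned$accepted <- !is.na(aligned$cc) & aligned$cc >= params$cc_threshold

    # merge accepted into the final set; refined poses may collide with
    # already-picked positions, earlier particles take precedence
    aligned$kept <- FALSE
    nxt_idx <- integer()
    for (i in which(aligned$accepted)) {
      p <- c(aligned$x[i], aligned$y[i], aligned$z[i])
      dmin <- min(sqrt(rowSums((picked - matrix(p, nrow(picked), 3L,
                                                byrow = TRUE))^2)))
      if (dmin >= params$d_min) {
        picked <- rbind(picked, p)
        aligned$kept[i] <- TRUE
        nxt_idx <- c(nxt_idx, i)
      }
    }
    kept <- aligned[nxt_idx, , drop = FALSE]
    newpart <- particle_set(cbind(kept$x, kept$y, kept$z),
                            cbind(kept$rot, kept$tilt, kept$psi),
                            cc = kept$cc, status = "accepted",
                            iteration_added = it, tomo_name = tomo_name)
    final <- rbind_particle_sets(final, newpart)

    rec <- list(iteration = it, seeds_in = as.data.frame(cur),
                aligned = aligned, cc_threshold = params$cc_threshold,
                d_min = params$d_min,
                n_candidates = nrow(att), n_accepted = sum(aligned$accepted),
                n_rejected = sum(!aligned$accepted))
    records[[length(records) + 1L]] <- rec
    if (!is.null(dirs)) write_cache_record(rec, dirs[2L])
    logline("iteration %d: seeds=%d candidates=%d accepted=%d rejected=%d",
            it, nrow(cur), rec$n_candidates, rec$n_accepted, rec$n_rejected)

    cur <- newpart
    it <- it + 1L
    if (nrow(cur) == 0L) { stop_reason <- "no_candidates"; break }
  }
  logline("stop: %s; final particles: %d", stop_reason, nrow(final))
  if (!is.null(dirs))
    write_star_particles(final, file.path(dirs[3L], "particles.star"))
  structure(list(records = records, final = final, stop_reason = stop_reason,
                 params = params, tomo_name = tomo_name),
            class = "expansion_run")
}

#' @export
print.expansion_run <- function(x, ...) {
  cat(sprintf("expansion_run (%s): %d iteration(s), stop: %s\n", x$tomo_name,
              length(x$records), x$stop_reason))
  for (r in x$records)
    cat(sprintf("  iteration %d: seeds=%d candidates=%d accepted=%d rejected=%d\n",
                r$iteration, nrow(r$seeds_in), r$n_candidates, r$n_accepted,
                r$n_rejected))
  cat(sprintf("final: %d particles\n", nrow(x$final)))
  invisible(x)
}

write_cache_record <- function(rec, dir) {
  path <- file.path(dir, sprintf("iteration_%03d.json", rec$iteration))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read an auto-expansion cache directory
#'
#' @param dir A `<tomo>_cache` directory written by [run_expansion()].
#' @return A list of iteration records, sorted by iteration.
#' @export
read_cache <- function(dir) {
  files <- sort(list.files(dir, pattern = "^iteration_\\d+\\.json$",
                           full.names = TRUE))
  recs <- lapply(files, function(f) {
    x <- jsonlite::read_json(f, simplifyVector = TRUE)
    x$aligned <- as.data.frame(x$aligned)
    x$seeds_in <- as.data.frame(x$seeds_in)
    x
  })
  recs[order(vapply(recs, `[[`, 0L, "iteration"))]
}

#' Regather a final particle set from cached iteration records
#'
#' Re-applies a (possibly different) correlation threshold to every cached
#' aligned candidate and rebuilds the final set without any new alignment:
#' seeds plus re-accepted particles, deduplicated at `d_min` with
#' earlier-iteration particles taking precedence. This is the
#' iteration-number-0 mode used to change the threshold after an expensive
#' run.
#'
#' @param cache List of iteration records ([read_cache()] output or
#'   `expansion_run$records`).
#' @param new_threshold Correlation threshold to re-apply.
#' @param seeds The original seed [particle_set].
#' @param d_min Deduplication distance; defaults to the value stored in the
#'   cache.
#' @return A [particle_set].
#' @export
regather <- function(cache, new_threshold, seeds, d_min = NULL) {
  if (length(cache) == 0L) stop("nothing to regather: empty cache")
  if (is.null(d_min)) d_min <- cache[[1L]]$d_min
  seeds$status <- "seed"
  seeds$iteration_added <- 0L
  final <- seeds
  picked <- particle_positions(seeds)
  for (rec in cache) {
    al <- rec$aligned
    for (i in seq_len(nrow(al))) {
      if (is.na(al$cc[i]) || al$cc[i] < new_threshold) next
      p <- c(al$x[i], al$y[i], al$z[i])
      dmin <- min(sqrt(rowSums((picked - matrix(p, nrow(picked), 3L,
                                                byrow = TRUE))^2)))
      if (dmin < d_min) next
      picked <- rbind(picked, p)
      final <- rbind_particle_sets(
        final,
        particle_set(matrix(p, 1L), matrix(c(al$rot[i], al$tilt[i],
                                             al$psi[i]), 1L),
                     cc = al$cc[i], status = "accepted",
                     iteration_added = rec$iteration,
                     tomo_name = seeds$tomo_name[1L]))
    }
  }
  final
}
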