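#' Write a particle set as a STAR file
#'
#' Emits the Relion-4 tomogram convention: a `data_particles` block whose
#' loop carries the tomogram name, voxel coordinates, ZYZ Euler angles in
#' degrees and the correlation score as the auto-pick figure of merit.
#' Package-specific bookkeeping (status, iteration added, optional voxel
#' size) travels in `_lp*` columns, which Relion ignores. The writer is
#' deterministic: identical input gives a byte-identical file.
#'
#' @param set A [particle_set] (may be empty; the header is still written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_particles <- function(set, path) {
  cols <- c("_rlnTomoName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnCoordinateZ", "_rlnAngleRot", "_rlnAngleTilt",
            "_rlnAnglePsi", "_rlnAutopickFigureOfMerit", "_lpStatus",
            "_lpIterationAdded")
  vs <- attr(set, "voxel_size")
  if (!is.null(vs)) cols <- c(cols, "_lpVoxelSize")
  lines <- c("# version 30001", "", "data_particles", "", "loop_",
             sprintf("%s #%d", cols, seq_along(cols)))
  if (nrow(set) > 0L) {
    num <- function(x) sprintf("%.6f", x)
    body <- paste(set$tomo_name, num(set$x), num(set$y), num(set$z),
                  num(set$rot), num(set$tilt), num(set$psi),
                  ifelse(is.na(set$cc), "NaN", num(set$cc)),
                  set$status, as.integer(set$iteration_added))
    if (!is.null(vs)) body <- paste(body, num(vs))
    lines <- c(lines, body)
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

#' Read a particle STAR file
#'
#' Tolerant Relion STAR reader: finds the particles loop (any block name),
#' accepts arbitrary column order and extra columns, and requires the
#' tomogram-convention mandatory columns. Coordinates are interpreted as
#' voxels, angles as ZYZ degrees.
#'
#' @param path Path to a STAR file.
#' @return A [particle_set].
#' @export
read_star_particles <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!grepl("^#", lines)]
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block found in ", path)
  cols <- character()
  i <- li[1L] + 1L
  while (i <= length(lines) && grepl("^_", lines[i])) {
    cols <- c(cols, sub("\\s+#.*$", "", lines[i]))
    i <- i + 1L
  }
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !grepl("^(data_|loop_)", lines[i])) {
    rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1L]]
    i <- i + 1L
  }
  need <- c("_rlnTomoName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnCoordinateZ", "_rlnAngleRot", "_rlnAngleTilt",
            "_rlnAnglePsi")
  miss <- setdiff(need, cols)
  if (length(miss))
    stop("mandatory STAR column(s) missing: ", paste(miss, collapse = ", "))
  if (!length(rows)) return(particle_set(tomo_name = character()))
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- cols
  getn <- function(col, default = NA_real_) {
    if (col %in% cols) suppressWarnings(as.numeric(tab[[col]])) else
      rep(default, nrow(tab))
  }
  set <- particle_set(
    cbind(getn("_rlnCoordinateX"), getn("_rlnCoordinateY"),
          getn("_rlnCoordinateZ")),
    cbind(getn("_rlnAngleRot"), getn("_rlnAngleTilt"), getn("_rlnAnglePsi")),
    cc = getn("_rlnAutopickFigureOfMerit"),
    status = if ("_lpStatus" %in% cols) tab[["_lpStatus"]] else "accepted",
    iteration_added = if ("_lpIterationAdded" %in% cols)
      as.integer(tab[["_lpIterationAdded"]]) else 0L,
    tomo_name = tab[["_rlnTomoName"]]
  )
  set$cc[is.nan(set$cc)] <- NA_real_
  if ("_lpVoxelSize" %in% cols)
    attr(set, "voxel_size") <- getn("_lpVoxelSize")[1L]
  set
}
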