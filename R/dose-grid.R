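#' 3D voxelized dose grid
#'
#' A regular 3D lattice of dose values in Gy. `origin` is the *corner* of the
#' first voxel (cm); voxel `[i, j, k]` (1-based) occupies the half-open box
#' `[origin + (idx-1)*spacing, origin + idx*spacing)` and its center sits at
#' `origin + (idx - 0.5) * spacing`. An optional scalar `rel_uncertainty_pct`
#' carries the Type-A statistical uncertainty of the grid in percent.
#'
#' @param origin Numeric length-3, grid corner in cm.
#' @param spacing Numeric length-3 (or scalar), voxel size in cm, `> 0`.
#' @param values 3D numeric array of non-negative finite doses (Gy).
#' @param rel_uncertainty_pct Optional scalar Type-A uncertainty in percent.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(origin, spacing, values, rel_uncertainty_pct = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  check_finite(origin, "origin"); check_finite(spacing, "spacing")
  if (length(origin) != 3L || length(spacing) != 3L)
    stop_imrtqa("origin and spacing must have length 3")
  if (any(spacing <= 0)) stop_imrtqa("spacing must be > 0 on every axis")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_imrtqa("values must be a 3D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop_imrtqa("dose values must be finite and >= 0")
  if (!is.null(rel_uncertainty_pct)) {
    check_finite(rel_uncertainty_pct, "rel_uncertainty_pct")
    stopifnot(length(rel_uncertainty_pct) == 1L, rel_uncertainty_pct >= 0)
  }
  structure(
    list(origin = as.numeric(origin), spacing = as.numeric(spacing),
         dims = dim(values), values = values,
         rel_uncertainty_pct = rel_uncertainty_pct),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("dose_grid: ", paste(x$dims, collapse = " x "), " voxels, spacing ",
      paste(format(x$spacing), collapse = " x "), " cm\n", sep = "")
  cat("  dose range [Gy]:", format(min(x$values), digits = 4), "-",
      format(max(x$values), digits = 4),
      if (!is.null(x$rel_uncertainty_pct))
        paste0(" | Type-A uncertainty ", format(x$rel_uncertainty_pct), "%"),
      "\n")
  invisible(x)
}

# Voxel-center coordinates along one axis.
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$spacing[axis]
}

same_lattice <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

#' Boolean structure mask on a dose-grid lattice
#'
#' @param name Structure name.
#' @param voxels Logical 3D array on the grid lattice.
#' @param grid The [dose_grid()] the mask lives on (supplies the lattice).
#' @return An object of class `structure_mask` with derived `volume_cc`.
#' @export
structure_mask <- function(name, voxels, grid) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!is.logical(voxels) || !identical(dim(voxels), as.integer(grid$dims)))
    stop_imrtqa("voxels must be a logical array matching the grid dims")
  structure(
    list(name = name, voxels = voxels,
         origin = grid$origin, spacing = grid$spacing, dims = grid$dims,
         volume_cc = sum(voxels) * prod(grid$spacing)),
    class = "structure_mask")
}

#' Cylindrical and spherical masks for the chamber geometry
#'
#' `cylinder_mask()` marks voxels whose centers lie inside a cylinder with
#' axis parallel to y (the chamber sits perpendicular to the beam plane);
#' `sphere_mask()` marks voxels inside a sphere. Both take the shape center
#' in cm in grid coordinates.
#'
#' @param grid A [dose_grid()].
#' @param center Length-3 center (cm).
#' @param radius Radius (cm).
#' @param length Cylinder length along y (cm).
#' @param name Structure name.
#' @return A [structure_mask()].
#' @export
cylinder_mask <- function(grid, center, radius, length,
                          name = "chamber") {
  cx <- axis_centers(grid, 1L) - center[1L]
  cy <- axis_centers(grid, 2L) - center[2L]
  cz <- axis_centers(grid, 3L) - center[3L]
  r2 <- outer(cx^2, cz^2, `+`)                      # nx x nz radial distance
  inside_r <- r2 <= radius^2
  inside_y <- abs(cy) <= length / 2
  vox <- array(FALSE, grid$dims)
  for (j in which(inside_y)) vox[, j, ] <- inside_r
  structure_mask(name, vox, grid)
}

#' @rdname cylinder_mask
#' @export
sphere_mask <- function(grid, center, radius, name = "water_sphere") {
  cx <- axis_centers(grid, 1L) - center[1L]
  cy <- axis_centers(grid, 2L) - center[2L]
  cz <- axis_centers(grid, 3L) - center[3L]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  structure_mask(name, d2 <= radius^2, grid)
}

#' Expand a mask by a Euclidean margin (morphological dilation)
#'
#' Marks every voxel whose center lies within `margin_cm` of the center of
#' any voxel already in the mask; the original mask is always included. Used
#' to build the 1.5 cm shell around the chamber for the conformity index.
#'
#' @param mask A [structure_mask()].
#' @param margin_cm Non-negative margin in cm.
#' @return The dilated [structure_mask()].
#' @export
expand_mask <- function(mask, margin_cm) {
  stopifnot(inherits(mask, "structure_mask"), margin_cm >= 0)
  if (margin_cm == 0 || !any(mask$voxels)) return(mask)
  sp <- mask$spacing
  nr <- pmin(floor(margin_cm / sp), mask$dims - 1L)
  offs <- expand.grid(dx = -nr[1L]:nr[1L], dy = -nr[2L]:nr[2L],
                      dz = -nr[3L]:nr[3L])
  dist <- sqrt((offs$dx * sp[1L])^2 + (offs$dy * sp[2L])^2 +
               (offs$dz * sp[3L])^2)
  offs <- offs[dist <= margin_cm, , drop = FALSE]
  idx <- which(mask$voxels, arr.ind = TRUE)
  out <- array(FALSE, mask$dims)
  # shift the true-voxel index set by every in-ball offset
  for (o in seq_len(nrow(offs))) {
    i <- idx[, 1L] + offs$dx[o]
    j <- idx[, 2L] + offs$dy[o]
    k <- idx[, 3L] + offs$dz[o]
    ok <- i >= 1L & i <= mask$dims[1L] & j >= 1L & j <= mask$dims[2L] &
          k >= 1L & k <= mask$dims[3L]
    out[cbind(i[ok], j[ok], k[ok])] <- TRUE
  }
  m <- mask
  m$voxels <- out
  m$volume_cc <- sum(out) * prod(sp)
  m
}

#' Sum per-beam dose grids voxelwise
#'
#' @param beam_doses Non-empty list of [dose_grid()]s on one lattice.
#' @return A [dose_grid()] holding the voxelwise sum (total plan dose).
#' @export
sum_beam_doses <- function(beam_doses) {
  if (!is.list(beam_doses) || length(beam_doses) < 1L ||
      !all(vapply(beam_doses, inherits, logical(1), "dose_grid")))
    stop_imrtqa("beam_doses must be a non-empty list of dose_grid objects")
  ref <- beam_doses[[1L]]
  total <- ref$values
  for (g in beam_doses[-1L]) {
    if (!same_lattice(ref, g))
      stop_imrtqa("beam dose grids are on different lattices")
    total <- total + g$values
  }
  dose_grid(ref$origin, ref$spacing, total)
}

#' Read and write the plain-text raster fixture format
#'
#' A minimal detached-header raster format for dose grids and masks: three
#' header lines `dims: nx ny nz`, `spacing: sx sy sz`, `origin: ox oy oz`,
#' followed by one value per line in column-major (x fastest) order. Masks
#' are stored as 0/1 rasters.
#'
#' @param path File path.
#' @return `read_dose_raster` returns a [dose_grid()]; `read_mask_raster` a
#'   [structure_mask()]; the writers invisibly return `path`.
#' @export
read_dose_raster <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    m <- grep(paste0("^", key, ":"), lines[1:3], value = TRUE)
    if (length(m) != 1L) stop_imrtqa("raster header missing '", key, ":'")
    as.numeric(strsplit(trimws(sub(".*:", "", m)), "[[:space:]]+")[[1L]])
  }
  dims <- as.integer(hdr("dims")); spacing <- hdr("spacing")
  origin <- hdr("origin")
  vals <- as.numeric(lines[-(1:3)])
  if (length(vals) != prod(dims))
    stop_imrtqa("raster payload has ", length(vals), " values, expected ",
                prod(dims))
  dose_grid(origin, spacing, array(vals, dim = dims))
}

#' @rdname read_dose_raster
#' @param grid A [dose_grid()] to write.
#' @export
write_dose_raster <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("dims:", paste(grid$dims, collapse = " ")),
               paste("spacing:", paste(format(grid$spacing, digits = 17),
                                       collapse = " ")),
               paste("origin:", paste(format(grid$origin, digits = 17),
                                      collapse = " "))), con)
  writeLines(format(as.vector(grid$values), digits = 17, trim = TRUE,
                    scientific = NA), con)
  invisible(path)
}

#' @rdname read_dose_raster
#' @param name Structure name for the mask.
#' @export
read_mask_raster <- function(path, name = "chamber") {
  g <- read_dose_raster(path)
  structure_mask(name, g$values > 0.5, g)
}

#' @rdname read_dose_raster
#' @param mask A [structure_mask()] to write.
#' @export
write_mask_raster <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  g <- dose_grid(mask$origin, mask$spacing,
                 array(as.numeric(mask$voxels), dim = mask$dims))
  write_dose_raster(g, path)
}
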