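#' Voxelized scalar grid
#'
#' A 3D scalar field (density relative to water, or dose in Gy) on a
#' regular grid. Axes follow a fixed right-handed patient-like convention:
#' x and y span the axial plane, z the cranio-caudal axis; gantry rotation
#' is about z. Indices are 1-based; the center of voxel (i, j, k) sits at
#' \code{origin + (c(i, j, k) - 0.5) * spacing} (mm), i.e. \code{origin} is
#' the corner of the first voxel.
#'
#' @param values Numeric 3D array.
#' @param spacing Voxel size in mm per axis, length 3, positive.
#' @param origin Corner of voxel (1,1,1) in mm, length 3.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %dx%dx%d voxels, %.3gx%.3gx%.3g mm, values in [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Structure labelmaps sharing one grid geometry
#'
#' Holds one logical mask per structure, all congruent with a companion
#' \code{\link{voxel_grid}}. Multi-label coverage (e.g. an OAR overlapping
#' the PTV) is represented naturally by overlapping masks.
#'
#' @param masks Named list of logical 3D arrays of identical dimension.
#' @param spacing,origin Grid geometry as in \code{\link{voxel_grid}}.
#' @return An object of class \code{structure_set}.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0)) {
  if (length(masks) == 0L || is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a non-empty named list")
  if (anyDuplicated(names(masks))) stop("structure labels must be unique")
  dims <- lapply(masks, dim)
  if (any(vapply(dims, length, integer(1)) != 3L) ||
      length(unique(lapply(dims, identity))) != 1L)
    stop("all masks must be 3D arrays of identical dimension")
  masks <- lapply(masks, function(m) array(as.logical(m), dim = dim(m)))
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<structure_set> %d structures on %dx%dx%d grid: %s\n",
              length(x$masks), d[1], d[2], d[3],
              paste(sprintf("%s (%d vox)", names(x$masks),
                            vapply(x$masks, sum, numeric(1))), collapse = ", ")))
  invisible(x)
}

## Cartesian voxel-center coordinates (mm) of linear indices into a grid
voxel_centers <- function(idx, dim3, spacing, origin) {
  ijk <- arrayInd(idx, dim3)
  sweep(sweep(ijk - 0.5, 2, spacing, "*"), 2, origin, "+")
}

#' Labels covering each voxel of a structure set
#'
#' @param structures A \code{\link{structure_set}}.
#' @param idx Linear voxel index.
#' @return Character vector of covering structure labels (possibly empty).
#' @export
voxel_labels <- function(structures, idx) {
  names(structures$masks)[vapply(structures$masks, function(m) m[idx], logical(1))]
}

#' Halve the in-plane resolution of a grid
#'
#' Doubles the voxel dimensions in x and y (merging 2x2 in-plane blocks by
#' arithmetic mean), leaving z untouched — the standard speed/resolution
#' trade used before microbeam dose calculation. Odd trailing rows/columns
#' are truncated with a warning.
#'
#' @param grid A \code{\link{voxel_grid}}.
#' @return A \code{\link{voxel_grid}} with doubled in-plane spacing.
#' @export
resample_double_xy <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  nx <- d[1] %/% 2L; ny <- d[2] %/% 2L
  if (nx < 1L || ny < 1L) stop("grid too small to downsample in-plane")
  if (d[1] %% 2L || d[2] %% 2L)
    warning("odd in-plane extent; trailing row/column truncated")
  v <- grid$values[seq_len(2L * nx), seq_len(2L * ny), , drop = FALSE]
  out <- (v[seq(1, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
          v[seq(2, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
          v[seq(1, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE] +
          v[seq(2, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE]) / 4
  voxel_grid(out, grid$spacing * c(2, 2, 1), grid$origin)
}

#' Halve the in-plane resolution of a structure set
#'
#' Companion of \code{\link{resample_double_xy}} for labelmaps: each merged
#' 2x2 block votes by majority, with ties resolved toward "inside" so that
#' downsampling never erodes a structure through tie-breaking.
#'
#' @param structures A \code{\link{structure_set}}.
#' @return A \code{\link{structure_set}} on the downsampled geometry.
#' @export
resample_double_xy_labels <- function(structures) {
  stopifnot(inherits(structures, "structure_set"))
  d <- dim(structures$masks[[1]])
  nx <- d[1] %/% 2L; ny <- d[2] %/% 2L
  if (d[1] %% 2L || d[2] %% 2L)
    warning("odd in-plane extent; trailing row/column truncated")
  masks <- lapply(structures$masks, function(m) {
    v <- m[seq_len(2L * nx), seq_len(2L * ny), , drop = FALSE] * 1
    s <- v[seq(1, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
         v[seq(2, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
         v[seq(1, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE] +
         v[seq(2, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE]
    s >= 2
  })
  structure_set(masks, structures$spacing * c(2, 2, 1), structures$origin)
}

## Beam axes for a coplanar gantry angle (degrees, rotation about z).
## At 0 deg the beam travels along -y; u is the in-plane lateral axis
## (microbeam lattice axis), v is z.
beam_axes <- function(gantry_angle) {
  th <- gantry_angle * pi / 180
  list(dir = c(sin(th), -cos(th), 0), lat = c(cos(th), sin(th), 0))
}

#' Conformal field aperture in the beam's-eye plane
#'
#' A 2D boolean aperture on a regular (u, v) pixel raster at the isocenter
#' plane: u is the in-plane lateral coordinate perpendicular to the beam,
#' v the cranio-caudal coordinate (both mm, relative to the isocenter).
#'
#' @param pixels Logical matrix (u rows, v columns).
#' @param pitch Pixel pitch in mm, length 2.
#' @param u0,v0 Coordinates (mm) of the corner of pixel (1,1).
#' @return An object of class \code{field_mask}.
#' @export
field_mask <- function(pixels, pitch, u0, v0) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, pitch = as.numeric(pitch),
                 u0 = as.numeric(u0), v0 = as.numeric(v0)),
            class = "field_mask")
}

#' Test beam's-eye coordinates against an aperture
#'
#' @param u,v Coordinates in mm relative to the isocenter (vectorized).
#' @param mask A \code{\link{field_mask}} or \code{NULL} (open field).
#' @return Logical vector: inside the aperture.
#' @export
in_aperture <- function(u, v, mask) {
  if (is.null(mask)) return(rep(TRUE, length(u)))
  i <- floor((u - mask$u0) / mask$pitch[1]) + 1L
  j <- floor((v - mask$v0) / mask$pitch[2]) + 1L
  ok <- i >= 1L & i <= nrow(mask$pixels) & j >= 1L & j <= ncol(mask$pixels)
  out <- rep(FALSE, length(u))
  out[ok] <- mask$pixels[cbind(i[ok], j[ok])]
  out
}

#' Project a target volume onto the beam's-eye plane
#'
#' Builds the binary shadow of a structure along a coplanar beam axis: the
#' center of every target voxel is projected to (u, v) coordinates and the
#' covered aperture pixels are marked. The raster pitch defaults to half
#' the smallest voxel dimension so that the undilated silhouette covers
#' every projected voxel center; the 1-2 voxel dilation applied afterwards
#' absorbs voxel-footprint edge effects.
#'
#' @param mask Logical 3D array (the structure).
#' @param spacing,origin Grid geometry (mm).
#' @param gantry_angle Gantry angle in degrees (rotation about z).
#' @param isocenter Isocenter in mm; defaults to the structure centroid.
#' @param pitch Aperture pixel pitch in mm (scalar or length 2).
#' @return A \code{\link{field_mask}}.
#' @export
project_target <- function(mask, spacing, origin, gantry_angle,
                           isocenter = NULL, pitch = min(spacing) / 2) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("cannot project an empty structure")
  ctr <- voxel_centers(idx, dim(mask), spacing, origin)
  if (is.null(isocenter)) isocenter <- colMeans(ctr)
  ax <- beam_axes(gantry_angle)
  rel <- sweep(ctr, 2, isocenter)
  u <- rel %*% ax$lat
  v <- rel[, 3]
  pitch <- rep(as.numeric(pitch), length.out = 2L)
  # half-pixel margin so extreme centers fall strictly inside the raster
  u0 <- min(u) - pitch[1]; v0 <- min(v) - pitch[2]
  nu <- ceiling((max(u) - u0) / pitch[1]) + 1L
  nv <- ceiling((max(v) - v0) / pitch[2]) + 1L
  px <- matrix(FALSE, nu, nv)
  iu <- floor((u - u0) / pitch[1]) + 1L
  iv <- floor((v - v0) / pitch[2]) + 1L
  px[cbind(iu, iv)] <- TRUE
  field_mask(px, pitch, u0, v0)
}

#' Dilate a conformal aperture
#'
#' Binary morphological dilation with a square structuring element of the
#' given pixel radius — the margin that turns the raw target silhouette
#' into a field with full target coverage. Radii outside {0, 1, 2} are
#' accepted with a warning.
#'
#' @param mask A \code{\link{field_mask}}.
#' @param radius_px Dilation radius in aperture pixels.
#' @return A dilated \code{\link{field_mask}} (same raster, grown by
#'   \code{radius_px} pixels of padding).
#' @export
dilate_mask <- function(mask, radius_px = 1L) {
  stopifnot(inherits(mask, "field_mask"))
  r <- as.integer(radius_px)
  if (r < 0L) stop("dilation radius must be >= 0")
  if (r > 2L) warning("dilation radius beyond the usual 1-2 pixels")
  if (r == 0L) return(mask)
  p <- mask$pixels
  padded <- matrix(FALSE, nrow(p) + 2L * r, ncol(p) + 2L * r)
  out <- padded
  padded[r + seq_len(nrow(p)), r + seq_len(ncol(p))] <- p
  for (di in -r:r) for (dj in -r:r)
    out <- out | shift_matrix(padded, di, dj)
  field_mask(out, mask$pitch,
             mask$u0 - r * mask$pitch[1], mask$v0 - r * mask$pitch[2])
}

## shift a logical matrix by (di, dj), filling with FALSE
shift_matrix <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  si <- seq_len(n) - di; sj <- seq_len(p) - dj
  ok_i <- si >= 1L & si <= n; ok_j <- sj >= 1L & sj <= p
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

#' Arrange cross-firing conformal microbeam fields
#'
#' Creates one \code{\link{beam_spec}} per gantry angle, all sharing the
#' microbeam lattice parameters, each with its own conformal aperture built
#' by projecting the target and dilating it. Duplicate angles are allowed
#' but warned about (they double-weight a field).
#'
#' @param angles Gantry angles in degrees (coplanar, rotation about z).
#' @param target Logical 3D array: the planning target volume.
#' @param spacing,origin Grid geometry in mm.
#' @param entrance_peak_dose Peak entrance dose per field in Gy (recycled).
#' @param dilation_px Aperture dilation radius in pixels (1 or 2).
#' @param isocenter Isocenter in mm; defaults to the target centroid.
#' @param ... Lattice parameters passed to \code{\link{beam_spec}}
#'   (peak_width_um, center_to_center_um, valley_fraction, effective_mu,
#'   penumbra_sigma_um, scatter_fraction).
#' @return List of \code{\link{beam_spec}}, one per angle.
#' @export
arrange_beams <- function(angles, target, spacing, origin,
                          entrance_peak_dose = 1, dilation_px = 1L,
                          isocenter = NULL, ...) {
  if (length(angles) == 0L) stop("empty beam-angle list")
  if (anyDuplicated(angles))
    warning("duplicate gantry angles: coincident fields are double-weighted")
  if (is.null(isocenter)) {
    idx <- which(target)
    if (length(idx) == 0L) stop("cannot plan on an empty target")
    isocenter <- colMeans(voxel_centers(idx, dim(target), spacing, origin))
  }
  entrance_peak_dose <- rep(entrance_peak_dose, length.out = length(angles))
  lapply(seq_along(angles), function(i) {
    fm <- dilate_mask(project_target(target, spacing, origin, angles[i],
                                     isocenter = isocenter), dilation_px)
    beam_spec(gantry_angle = angles[i],
              entrance_peak_dose = entrance_peak_dose[i],
              field_mask = fm, isocenter = isocenter, ...)
  })
}
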