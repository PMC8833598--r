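#' Synthetic phantom specification
#'
#' Declares a body-like voxel phantom: a water-equivalent cylindrical (or
#' slab) body surrounded by air, a spherical/ellipsoidal target volume, a
#' set of labelled spherical organs at risk (which may overlap the target —
#' the configuration that exercises tissue-parameter priority), and an
#' optional low-density lung-like compartment. Structure labels should
#' match tissue-registry rows so that radiobiology parameters resolve by
#' name.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param spacing Voxel size in mm (length 3).
#' @param body List: \code{type} ("cylinder" about z, or "slab"),
#'   \code{radius} in mm (cylinder), \code{density} (default 1).
#' @param target List: \code{label}, \code{center} (mm), \code{diameter}
#'   (mm), optional \code{semiaxes} (mm, length 3) for an ellipsoid.
#' @param oars List of lists like \code{target} (possibly empty).
#' @param lung Optional list: \code{center}, \code{diameter}, \code{density}
#'   (default 0.26) — a low-density compartment without its own label.
#' @param air_density Density outside the body (default 0.001).
#' @param noise_sd Relative s.d. of multiplicative density noise inside the
#'   body; 0 (default) keeps the phantom strictly deterministic.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 8L), spacing = c(2, 2, 2),
                         body = list(type = "cylinder", radius = 30, density = 1),
                         target = list(label = "ptv", center = c(40, 24, 8),
                                       diameter = 15),
                         oars = list(), lung = NULL,
                         air_density = 0.001, noise_sd = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  labels <- c(target$label, vapply(oars, `[[`, character(1), "label"))
  if (anyDuplicated(labels)) stop("structure labels must be unique")
  structure(list(shape = shape, spacing = as.numeric(spacing), body = body,
                 target = target, oars = oars, lung = lung,
                 air_density = air_density, noise_sd = noise_sd),
            class = "phantom_spec")
}

## logical mask of a sphere/ellipsoid on the phantom grid
rasterize_blob <- function(blob, shape, spacing) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 0.5) * spacing[a]))
  semi <- if (!is.null(blob$semiaxes)) blob$semiaxes else rep(blob$diameter / 2, 3)
  dx2 <- outer(((ax[[1]] - blob$center[1]) / semi[1])^2,
               ((ax[[2]] - blob$center[2]) / semi[2])^2, "+")
  arr <- array(0, shape)
  for (k in seq_len(shape[3]))
    arr[, , k] <- dx2 + ((ax[[3]][k] - blob$center[3]) / semi[3])^2
  arr <= 1
}

#' Generate a deterministic phantom from a specification
#'
#' Rasterizes the body, target and OAR geometry onto the voxel grid and
#' returns the density grid plus the structure labelmaps. Identical
#' spec and seed always give identical grids; the seed only feeds the
#' optional density-noise term.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param seed Integer seed for the optional noise term.
#' @return List with \code{density} (\code{\link{voxel_grid}}),
#'   \code{structures} (\code{\link{structure_set}}), and \code{body}
#'   (logical body mask).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; sp <- spec$spacing
  extent <- shape * sp
  body_density <- if (is.null(spec$body$density)) 1 else spec$body$density
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 0.5) * sp[a]))
  body <- array(FALSE, shape)
  if (identical(spec$body$type, "cylinder")) {
    cxy <- extent[1:2] / 2
    r2 <- outer((ax[[1]] - cxy[1])^2, (ax[[2]] - cxy[2])^2, "+")
    inside <- r2 <= spec$body$radius^2
    for (k in seq_len(shape[3])) body[, , k] <- inside
  } else if (identical(spec$body$type, "slab")) {
    body[] <- TRUE
  } else stop("unknown body type '", spec$body$type, "'")
  dens <- array(spec$air_density, shape)
  dens[body] <- body_density
  if (!is.null(spec$lung)) {
    lmask <- rasterize_blob(spec$lung, shape, sp)
    if (any(lmask & !body)) stop("lung compartment extends outside the body")
    dens[lmask] <- if (is.null(spec$lung$density)) 0.26 else spec$lung$density
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    n <- sum(body)
    dens[body] <- dens[body] * pmax(0.05, 1 + stats::rnorm(n, 0, spec$noise_sd))
  }
  blobs <- c(list(spec$target), spec$oars)
  masks <- lapply(blobs, rasterize_blob, shape = shape, spacing = sp)
  names(masks) <- vapply(blobs, `[[`, character(1), "label")
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) stop("structure '", nm, "' rasterizes to no voxels")
    if (any(masks[[nm]] & !body))
      stop("structure '", nm, "' extends outside the body")
  }
  list(density = voxel_grid(dens, sp),
       structures = structure_set(masks, sp),
       body = body)
}

#' The packaged default phantom
#'
#' A head-like water cylinder with a 15 mm diameter target whose edge is
#' overlapped by a brain-stem-like OAR (so that tissue-priority resolution
#' is exercised) and a small cochlea-like OAR nearby — the geometry of the
#' resection-cavity scenario at desk scale.
#'
#' @param shape,spacing Grid geometry (defaults 32 x 32 x 8 at 2 mm).
#' @return A \code{\link{phantom_spec}}.
#' @export
default_phantom_spec <- function(shape = c(32L, 32L, 8L), spacing = c(2, 2, 2)) {
  phantom_spec(
    shape = shape, spacing = spacing,
    body = list(type = "cylinder", radius = 30, density = 1),
    target = list(label = "ptv_gbm_cavity", center = c(40, 26, 8), diameter = 15),
    oars = list(
      list(label = "brain_stem", center = c(33, 32, 8), diameter = 10),
      list(label = "cochlea", center = c(44, 38, 8), diameter = 5)))
}
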