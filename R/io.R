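#' Write a voxel grid to NIfTI
#'
#' Stores values and voxel spacing (mm) via the RNifti package; the grid
#' origin is carried in the qform offset. Requires the suggested RNifti
#' package.
#'
#' @param grid A \code{\link{voxel_grid}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("grid I/O needs the RNifti package")
  img <- RNifti::asNifti(grid$values)
  # qform maps 0-based voxel indices to mm; our voxel centers sit at
  # origin + (index - 0.5) * spacing
  m <- rbind(cbind(diag(grid$spacing), grid$origin + 0.5 * grid$spacing),
             c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel grid from NIfTI
#'
#' @param path NIfTI file path.
#' @return A \code{\link{voxel_grid}}.
#' @export
read_grid <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("grid I/O needs the RNifti package")
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  org <- RNifti::xform(img)[1:3, 4] - 0.5 * spacing
  voxel_grid(array(as.numeric(img), dim(img)[1:3]), spacing, org)
}

#' Export a dose histogram to CSV
#'
#' Two columns, \code{dose} (Gy) and \code{weight}.
#'
#' @param hist A \code{\link{dose_histogram}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "dose_histogram"))
  utils::write.csv(data.frame(dose = hist$bin_doses, weight = hist$bin_weights),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a DVH curve to CSV
#'
#' @param curve A \code{dvh_curve} from \code{\link{dvh}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dvh_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility run log
#'
#' Records inputs, parameters, seed and package version alongside a run's
#' outputs, as JSON when jsonlite is available and as \code{dput} text
#' otherwise.
#'
#' @param path Output path.
#' @param ... Named fields to record.
#' @return \code{path}, invisibly.
#' @export
write_run_log <- function(path, ...) {
  log <- c(list(package = "mrtdose",
                version = as.character(utils::packageVersion("mrtdose")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(...))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(log, file = path)
  }
  invisible(path)
}
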