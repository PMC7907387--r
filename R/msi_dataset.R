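#' Construct an MSI dataset
#'
#' The central container of the package: a `w` x `h` pixel grid in which a
#' subset of pixels (the *spectral pixels*) carries a mass spectrum over a
#' common m/z axis. Intensities are held as a dense `|p+| x d` matrix whose
#' row order matches `coords`; pixels not listed in `coords` are implicitly
#' all-zero.
#'
#' @param width number of grid columns (positive integer).
#' @param height number of grid rows (positive integer).
#' @param mz strictly increasing numeric vector of d mass-to-charge values
#'   (Da).
#' @param coords integer matrix with columns `i` (column index, 1..width) and
#'   `j` (row index, 1..height), one row per spectral pixel. Rows must be
#'   unique.
#' @param intensities non-negative numeric matrix, `nrow(coords)` x
#'   `length(mz)`; row k is the spectrum of pixel `coords[k, ]`.
#' @param dataset_id short identifier string used as the group name in the
#'   HDF5 store.
#' @return An object of class `msi_dataset`.
#' @export
#' @examples
#' ds <- msi_dataset(2, 2, mz = c(100, 200),
#'                   coords = cbind(i = c(1, 2), j = c(1, 1)),
#'                   intensities = rbind(c(0, 2), c(2, 0)))
#' mean_spectrum(ds)$mu
msi_dataset <- function(width, height, mz, coords, intensities,
                        dataset_id = "dataset") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("i", "j")
  intensities <- as.matrix(intensities)
  ds <- structure(
    list(width = as.integer(width), height = as.integer(height),
         mz = as.numeric(mz), coords = coords,
         intensities = intensities, dataset_id = as.character(dataset_id)),
    class = "msi_dataset")
  validate_msi_dataset(ds)
  ds
}

#' Validate an MSI dataset's invariants
#'
#' Checks grid bounds, coordinate uniqueness, a strictly increasing m/z
#' axis, matching matrix dimensions and non-negative intensities. Called by
#' the constructor and after destructive operations.
#'
#' @param ds an `msi_dataset`.
#' @return `ds`, invisibly; stops with an informative error on violation.
#' @export
validate_msi_dataset <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (ds$width < 1L || ds$height < 1L)
    stop("grid dimensions must be positive")
  if (nrow(ds$coords) < 1L)
    stop("no spectral pixels")
  if (any(ds$coords[, 1] < 1L) || any(ds$coords[, 1] > ds$width) ||
      any(ds$coords[, 2] < 1L) || any(ds$coords[, 2] > ds$height))
    stop("pixel coordinates outside the ", ds$width, "x", ds$height, " grid")
  if (anyDuplicated(ds$coords))
    stop("duplicate pixel coordinates")
  d <- length(ds$mz)
  if (d < 1L) stop("empty m/z axis")
  if (d > 1L && any(diff(ds$mz) <= 0))
    stop("m/z axis must be strictly increasing")
  if (nrow(ds$intensities) != nrow(ds$coords) ||
      ncol(ds$intensities) != d)
    stop("intensity matrix must be |p+| x d (",
         nrow(ds$coords), " x ", d, ")")
  if (any(ds$intensities < 0))
    stop("negative intensities")
  invisible(ds)
}

#' @exportS3Method base::print
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset '%s'> %d x %d grid, %d spectral pixels, %d m/z channels (%.4f-%.4f Da)\n",
              x$dataset_id, x$width, x$height, nrow(x$coords),
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Number of spectral pixels
#' @param ds an `msi_dataset`.
#' @return integer count of spectral pixels `|p+|`.
#' @export
n_pixels <- function(ds) nrow(ds$coords)

#' Mean spectrum over spectral pixels
#'
#' Per-channel arithmetic mean of the intensities of the spectral pixels
#' only (non-spectral pixels do not contribute). This is the spectrum on
#' which peak picking operates.
#'
#' @param ds an `msi_dataset`.
#' @return A `mean_spectrum`: list with `mz` and non-negative `mu`, both of
#'   length d.
#' @export
mean_spectrum <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  structure(list(mz = ds$mz, mu = colMeans(ds$intensities)),
            class = "mean_spectrum")
}

#' @exportS3Method base::print
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> %d channels, max %.4g at %.4f Da\n",
              length(x$mz), max(x$mu), x$mz[which.max(x$mu)]))
  invisible(x)
}

#' Single mass-channel image
#'
#' Extracts channel k as a height x width matrix (row j, column i);
#' non-spectral pixels are 0.
#'
#' @param ds an `msi_dataset`.
#' @param k channel index, 1..d.
#' @return An `intensity_image`: list with `width`, `height` and a
#'   `height x width` matrix `values`.
#' @export
channel_image <- function(ds, k) {
  stopifnot(inherits(ds, "msi_dataset"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(ds$mz))
    stop("channel index k out of range 1..", length(ds$mz))
  values <- matrix(0, nrow = ds$height, ncol = ds$width)
  values[cbind(ds$coords[, 2], ds$coords[, 1])] <- ds$intensities[, k]
  structure(list(width = ds$width, height = ds$height, values = values),
            class = "intensity_image")
}

#' Restrict a dataset to an m/z window
#'
#' Keeps the channels with `lo <= mz <= hi` (closed interval). Typical use
#' is harmonizing the mass range across datasets before comparison, e.g.
#' trimming everything to 100-1150 Da.
#'
#' @param ds an `msi_dataset`.
#' @param lo,hi window bounds in Da, `lo < hi`.
#' @return The cropped `msi_dataset`.
#' @export
crop_mz <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (!(lo < hi)) stop("require lo < hi")
  keep <- which(ds$mz >= lo & ds$mz <= hi)
  if (length(keep) == 0L)
    stop("no m/z channels inside [", lo, ", ", hi, "]")
  ds$mz <- ds$mz[keep]
  ds$intensities <- ds$intensities[, keep, drop = FALSE]
  validate_msi_dataset(ds)
}

# Row index of the spectral pixel at grid position (i, j); NA if the pixel
# carries no spectrum.
pixel_index <- function(ds, i, j) {
  hit <- which(ds$coords[, 1] == i & ds$coords[, 2] == j)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Rounding used throughout the rendering path: half away from zero, so that
# results do not depend on the platform's banker's rounding. All inputs on
# this path are non-negative.
round_half_away <- function(x) floor(x + 0.5)
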