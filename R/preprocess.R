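# Spectrum alignment to a common m/z axis and intensity normalization.
#
# MSI spectra carry a strong per-spectrum multiplicative intensity
# variation (ionization efficiency, matrix crystal size, detector drift).
# Normalization divides every spectrum by a scaling factor so that spectra
# become comparable within a dataset (intra) and across datasets (inter).
# Three factor estimators are provided: mean and median of the nonzero
# intensities, and median fold change (mfc, the default) against a
# reference spectrum. Nonzero-only statistics are used because MSI spectra
# are sparse and the zeros would dominate plain means/medians.

#' Build a common m/z axis across datasets
#'
#' Pools every channel m/z of the given datasets, smooths them with a
#' Gaussian kernel density of the given bandwidth and places one common
#' channel at each local maximum of the density. Each maximum is snapped to
#' the nearest observed pooled m/z value, so the common axis consists of
#' measured masses. Channels of the same ion species recorded at slightly
#' different masses therefore collapse onto one common channel.
#'
#' @param ds_list list of [msi_dataset()] objects (at least one).
#' @param kernel_bandwidth Gaussian kernel bandwidth in Da; channels closer
#'   than roughly the bandwidth merge into one density mode.
#' @return sorted numeric vector, the common m/z axis.
#' @export
build_common_mz <- function(ds_list, kernel_bandwidth) {
  if (length(ds_list) == 0L) stop("need at least one dataset")
  if (!is.numeric(kernel_bandwidth) || kernel_bandwidth <= 0)
    stop("kernel_bandwidth must be > 0")
  pooled <- sort(unlist(lapply(ds_list, `[[`, "mz")))
  if (length(unique(pooled)) == 1L) return(unique(pooled))
  # grid fine enough to resolve modes separated by ~bandwidth
  span <- diff(range(pooled)) + 6 * kernel_bandwidth
  n_grid <- min(2^19, max(1024L, ceiling(span / (kernel_bandwidth / 20))))
  dens <- stats::density(pooled, bw = kernel_bandwidth, n = n_grid,
                         from = min(pooled) - 3 * kernel_bandwidth,
                         to = max(pooled) + 3 * kernel_bandwidth)
  y <- dens$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  # drop numerical ghost maxima from the underflowing tails; any real
  # mode backed by >= 1 channel has density >= max/|pool| >> this floor
  is_max <- is_max & y > max(y) * 1e-8
  peaks_x <- dens$x[is_max]
  peaks_y <- y[is_max]
  if (length(peaks_x) == 0L) {
    peaks_x <- dens$x[which.max(y)]
    peaks_y <- max(y)
  }
  # modes closer than the kernel bandwidth are not resolvable: merge
  # them, keeping the densest (guards against grid-level ripples on
  # flat-topped modes)
  ord <- order(peaks_x)
  peaks_x <- peaks_x[ord]; peaks_y <- peaks_y[ord]
  grp <- cumsum(c(1, diff(peaks_x) > kernel_bandwidth))
  keep <- vapply(split(seq_along(grp), grp), function(ix)
    ix[which.max(peaks_y[ix])], integer(1))
  peaks_x <- peaks_x[keep]
  # snap each density mode to the nearest observed mass
  snapped <- vapply(peaks_x, function(x)
    pooled[which.min(abs(pooled - x))], numeric(1))
  sort(unique(snapped))
}

#' Align a dataset onto a common m/z axis
#'
#' Each original channel's intensity column is added onto the nearest
#' common channel within `tol`; channels with no common channel within
#' `tol` are dropped. When several original channels map to the same
#' common channel their intensities are summed, so total ion current is
#' conserved whenever `tol` captures every channel.
#'
#' @param ds an [msi_dataset()].
#' @param common_mz sorted numeric vector (e.g. from [build_common_mz()]).
#' @param tol maximum distance in Da for a channel to be assigned.
#' @return The aligned [msi_dataset()] with `d = length(common_mz)`.
#' @export
align_mz <- function(ds, common_mz, tol) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (is.unsorted(common_mz, strictly = TRUE))
    stop("common_mz must be sorted strictly increasing")
  target <- vapply(ds$mz, function(x) {
    k <- which.min(abs(common_mz - x))
    if (abs(common_mz[k] - x) <= tol) k else NA_integer_
  }, integer(1))
  out <- matrix(0, nrow = nrow(ds$intensities), ncol = length(common_mz))
  for (src in which(!is.na(target)))
    out[, target[src]] <- out[, target[src]] + ds$intensities[, src]
  ds$mz <- as.numeric(common_mz)
  ds$intensities <- out
  validate_msi_dataset(ds)
}

norm_factor <- function(s, method, ref = NULL) {
  nz <- s[s > 0]
  switch(method,
    mean = if (length(nz)) mean(nz) else NA_real_,
    median = if (length(nz)) stats::median(nz) else NA_real_,
    mfc = {
      ok <- s > 0 & ref > 0
      if (any(ok)) stats::median(s[ok] / ref[ok]) else NA_real_
    },
    stop("unknown normalization method '", method, "'"))
}

#' Intra-sample normalization
#'
#' Divides each spectrum by its own scaling factor. `mean`/`median` use the
#' mean/median of the spectrum's nonzero intensities; `mfc` (default) uses
#' the median, over channels nonzero in both, of the fold change against
#' the dataset's per-channel median spectrum. Spectra for which no factor
#' can be computed (all-zero, or no channel shared with the reference) are
#' left unchanged with a warning and a reported factor of 1.
#'
#' @param ds an [msi_dataset()].
#' @param method one of `"mfc"`, `"mean"`, `"median"`.
#' @return list with `dataset` (normalized) and `report`, a
#'   `normalization_report` holding `method`, per-spectrum `scale_factors`
#'   and the `reference` spectrum used by mfc (empty otherwise).
#' @export
intra_normalize <- function(ds, method = c("mfc", "mean", "median")) {
  stopifnot(inherits(ds, "msi_dataset"))
  method <- match.arg(method)
  ref <- if (method == "mfc") apply(ds$intensities, 2, stats::median)
         else numeric(0)
  factors <- apply(ds$intensities, 1, norm_factor, method = method,
                   ref = ref)
  bad <- !is.finite(factors) | factors <= 0
  if (any(bad)) {
    warning(sum(bad), " spectra have no usable normalization factor; ",
            "left unchanged")
    factors[bad] <- 1
  }
  ds$intensities <- ds$intensities / factors
  report <- structure(list(method = method, scale_factors = factors,
                           reference = ref),
                      class = "normalization_report")
  list(dataset = validate_msi_dataset(ds), report = report)
}

#' @exportS3Method base::print
print.normalization_report <- function(x, ...) {
  cat(sprintf("<normalization_report> method=%s, %d spectra, factors %.4g-%.4g\n",
              x$method, length(x$scale_factors),
              min(x$scale_factors), max(x$scale_factors)))
  invisible(x)
}

#' Write a normalization report as CSV
#' @param report a `normalization_report`.
#' @param path output path; one row per spectrum.
#' @return `path`, invisibly.
#' @export
write_normalization_csv <- function(report, path) {
  utils::write.csv(data.frame(spectrum = seq_along(report$scale_factors),
                              scale_factor = report$scale_factors),
                   path, row.names = FALSE)
  invisible(path)
}

#' Inter-sample normalization
#'
#' Computes one scaling factor per dataset from its mean spectrum against a
#' cross-dataset reference spectrum, then divides every spectrum of the
#' dataset by that factor. The reference is the per-channel lower median of
#' the dataset mean spectra, so for identical datasets all factors are 1.
#' All datasets must share the same m/z axis.
#'
#' @param ds_list list of at least two [msi_dataset()] objects.
#' @param method as in [intra_normalize()].
#' @return list with `datasets` (normalized, same order) and `factors`.
#' @export
inter_normalize <- function(ds_list, method = c("mfc", "mean", "median")) {
  method <- match.arg(method)
  if (length(ds_list) < 2L) stop("need at least two datasets")
  d <- length(ds_list[[1]]$mz)
  for (ds in ds_list)
    if (length(ds$mz) != d || any(ds$mz != ds_list[[1]]$mz))
      stop("datasets must share the same m/z axis; align first")
  means <- t(vapply(ds_list, function(ds) mean_spectrum(ds)$mu, numeric(d)))
  # lower median: the floor((n+1)/2)-th sorted value per channel
  lo_med <- apply(means, 2, function(col)
    sort(col)[floor((length(col) + 1) / 2)])
  factors <- vapply(seq_along(ds_list), function(k) {
    m <- means[k, ]
    f <- switch(method,
      mean = norm_factor(m, "mean") / norm_factor(lo_med, "mean"),
      median = norm_factor(m, "median") / norm_factor(lo_med, "median"),
      mfc = norm_factor(m, "mfc", ref = lo_med))
    if (!is.finite(f) || f <= 0) {
      warning("dataset ", k, " has no usable inter-sample factor")
      f <- 1
    }
    f
  }, numeric(1))
  out <- lapply(seq_along(ds_list), function(k) {
    ds <- ds_list[[k]]
    ds$intensities <- ds$intensities / factors[k]
    validate_msi_dataset(ds)
  })
  list(datasets = out, factors = factors)
}
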