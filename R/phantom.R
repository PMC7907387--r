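# Synthetic MSI phantom with ground truth.
#
# The phantom emulates the structure the rest of the package assumes about
# MALDI MSI data: a pixel grid whose border band carries pure matrix
# spectra, interior tissue regions with region-specific peak sets (each
# peak with isotope satellites at +1.00335 Da steps), a ubiquitous matrix
# signal added to every pixel (the matrix is sprayed over the whole
# section), isolated artifact hotspot pixels with strong spikes at random
# channels, a per-spectrum log-normal intensity scale and additive noise.
# It does not emulate MALDI physics (mass drift, laser ablation patterns,
# detector saturation).

# Layout (artifact positions) comes from a fixed internal stream so that
# different user seeds vary only noise, never the truth geometry.
PHANTOM_STRUCT_SEED <- 7919L

#' Specification of a synthetic phantom
#'
#' Defaults describe the standard validation phantom: a 64 x 64 grid, 500
#' channels over 100-600 Da, a 6-pixel matrix border band, two circular
#' tissue regions plus a background-tissue region, a dominant matrix
#' signal on every pixel, 40 artifact hotspots, two isotope satellites per
#' peak at ratio 0.5, 20% log-normal per-spectrum scale spread and
#' additive noise of sigma 0.02 (2% of the sample peak height).
#'
#' @param width,height grid size.
#' @param d number of m/z channels.
#' @param mz_lo,mz_hi mass range in Da (channels evenly spaced).
#' @param matrix_border width in pixels of the pure-matrix border band.
#' @param regions list of disk regions, each
#'   `list(cx, cy, radius, channels, height)`; `NULL` uses two default
#'   disks with disjoint 8-channel peak sets.
#' @param background_channels peak channels of the background tissue that
#'   fills the interior outside the disk regions.
#' @param background_height peak height of the background tissue.
#' @param matrix_channels channels of the matrix signal.
#' @param matrix_intensity matrix peak height (dominant by default).
#' @param sample_height peak height of the disk regions.
#' @param artifact_count number of isolated hotspot pixels.
#' @param artifact_multiplier spike height in units of `sample_height`.
#' @param artifact_channels spiked channels per artifact type.
#' @param artifact_types number of distinct hotspot spectral types;
#'   hotspots of one type share their spike channels (as hotspots from one
#'   physical cause, e.g. matrix crystals, share spectral character),
#'   while pixels of different types do not.
#' @param iso_ratio satellite/parent intensity ratio per +1.00335 Da step.
#' @param n_satellites satellites per peak.
#' @param peak_sigma Gaussian peak width in channels.
#' @param sigma_scale sd of the log-normal per-spectrum scale (0 = none).
#' @param sigma_noise sd of the additive Gaussian noise (clamped at 0).
#' @param seed RNG seed (mandatory).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 64L, height = 64L, d = 500L,
                         mz_lo = 100, mz_hi = 600,
                         matrix_border = 6L,
                         regions = NULL,
                         background_channels = c(450L, 462L, 474L, 486L),
                         background_height = 0.8,
                         matrix_channels = c(20L, 30L, 40L, 50L, 410L, 430L),
                         matrix_intensity = 4,
                         sample_height = 1,
                         artifact_count = 40L,
                         artifact_multiplier = 10,
                         artifact_channels = 5L,
                         artifact_types = 4L,
                         iso_ratio = 0.5,
                         n_satellites = 2L,
                         peak_sigma = 1.0,
                         sigma_scale = 0.2,
                         sigma_noise = 0.02,
                         seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  if (is.null(regions))
    regions <- list(
      list(cx = 22, cy = 22, radius = 10,
           channels = seq(60L, by = 45L, length.out = 8L),
           height = sample_height),
      list(cx = 43, cy = 43, radius = 10,
           channels = seq(80L, by = 45L, length.out = 8L),
           height = sample_height))
  spec <- list(width = as.integer(width), height = as.integer(height),
               d = as.integer(d), mz_lo = mz_lo, mz_hi = mz_hi,
               matrix_border = as.integer(matrix_border),
               regions = regions,
               background_channels = as.integer(background_channels),
               background_height = background_height,
               matrix_channels = as.integer(matrix_channels),
               matrix_intensity = matrix_intensity,
               sample_height = sample_height,
               artifact_count = as.integer(artifact_count),
               artifact_multiplier = artifact_multiplier,
               artifact_channels = as.integer(artifact_channels),
               artifact_types = as.integer(artifact_types),
               iso_ratio = iso_ratio,
               n_satellites = as.integer(n_satellites),
               peak_sigma = peak_sigma,
               sigma_scale = sigma_scale, sigma_noise = sigma_noise,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Gaussian peak plus isotope satellites on the channel axis; satellite
# positions are the channels nearest to mz + n * 1.00335.
add_peaks <- function(base, mz, channels, height, spec) {
  for (ch in channels) {
    targets <- ch
    heights <- height
    for (n in seq_len(spec$n_satellites)) {
      sat_mz <- mz[ch] + n * 1.00335
      sat_ch <- which.min(abs(mz - sat_mz))
      targets <- c(targets, sat_ch)
      heights <- c(heights, height * spec$iso_ratio^n)
    }
    for (t in seq_along(targets)) {
      c0 <- targets[t]
      win <- max(1L, c0 - 4L):min(length(mz), c0 + 4L)
      base[win] <- base[win] +
        heights[t] * exp(-(win - c0)^2 / (2 * spec$peak_sigma^2))
    }
  }
  base
}

#' Generate a synthetic phantom with ground truth
#'
#' Builds the dataset described by a [phantom_spec()] together with its
#' ground truth. Matrix peaks are present on every pixel; the border band
#' carries only matrix signal; artifact pixels get strong spikes at random
#' channels on top of their location's spectrum. Bit-identical for a fixed
#' seed; different seeds change noise, per-spectrum scales and artifact
#' spike channels but not the truth geometry.
#'
#' @param spec a [phantom_spec()].
#' @return list with `dataset` (an [msi_dataset()]) and `truth`, a
#'   `phantom_truth` holding per-pixel `labels`
#'   (sample/matrix/artifact) and `region` ids (0 = background tissue, NA
#'   for the matrix band), `region_peaks` (per-region main peak channels),
#'   and `matrix_mean` (the noiseless matrix base spectrum).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width; h <- spec$height; d <- spec$d
  mz <- seq(spec$mz_lo, spec$mz_hi, length.out = d)
  b <- spec$matrix_border
  grid <- expand.grid(i = seq_len(w), j = seq_len(h))
  coords <- as.matrix(grid)
  n <- nrow(coords)

  in_matrix <- coords[, 1] <= b | coords[, 1] > w - b |
               coords[, 2] <= b | coords[, 2] > h - b

  region <- ifelse(in_matrix, NA_integer_, 0L)
  for (k in seq_along(spec$regions)) {
    rg <- spec$regions[[k]]
    inside <- (coords[, 1] - rg$cx)^2 + (coords[, 2] - rg$cy)^2 <=
      rg$radius^2
    if (any(inside & in_matrix))
      stop("region ", k, " overlaps the matrix border band")
    region[inside] <- k
  }

  matrix_base <- add_peaks(numeric(d), mz, spec$matrix_channels,
                           spec$matrix_intensity, spec)
  background_base <- add_peaks(numeric(d), mz, spec$background_channels,
                               spec$background_height, spec)
  region_bases <- lapply(spec$regions, function(rg)
    add_peaks(numeric(d), mz, rg$channels, rg$height, spec))

  signal <- matrix(rep(matrix_base, each = n), nrow = n)
  bg_rows <- which(!is.na(region) & region == 0L)
  signal[bg_rows, ] <- signal[bg_rows, ] +
    rep(background_base, each = length(bg_rows))
  for (k in seq_along(spec$regions)) {
    rows <- which(!is.na(region) & region == k)
    signal[rows, ] <- signal[rows, ] +
      rep(region_bases[[k]], each = length(rows))
  }

  labels <- ifelse(in_matrix, "matrix", "sample")

  # layout stream: artifact positions are part of the truth geometry
  set.seed(PHANTOM_STRUCT_SEED)
  art_rows <- if (spec$artifact_count > 0L)
    sample.int(n, spec$artifact_count) else integer(0)

  # noise stream: everything that may vary between seeds
  set.seed(spec$seed)
  if (length(art_rows) > 0L) {
    n_types <- max(1L, min(spec$artifact_types, length(art_rows)))
    type_channels <- lapply(seq_len(n_types), function(t)
      sample.int(d, spec$artifact_channels))
    type_of <- rep_len(seq_len(n_types), length(art_rows))
    for (a in seq_along(art_rows)) {
      row <- art_rows[a]
      spike_ch <- type_channels[[type_of[a]]]
      signal[row, spike_ch] <- signal[row, spike_ch] +
        spec$artifact_multiplier * spec$sample_height
      labels[row] <- "artifact"
    }
  }
  scales <- if (spec$sigma_scale > 0)
    exp(stats::rnorm(n, 0, spec$sigma_scale)) else rep(1, n)
  intens <- signal * scales
  if (spec$sigma_noise > 0)
    intens <- intens + matrix(stats::rnorm(n * d, 0, spec$sigma_noise),
                              nrow = n)
  intens[intens < 0] <- 0

  ds <- msi_dataset(w, h, mz, coords, intens, dataset_id = "phantom")
  truth <- structure(
    list(labels = factor(labels,
                         levels = c("sample", "matrix", "artifact")),
         region = region,
         region_peaks = c(list(`0` = spec$background_channels),
                          stats::setNames(
                            lapply(spec$regions, `[[`, "channels"),
                            seq_along(spec$regions))),
         matrix_mean = matrix_base),
    class = "phantom_truth")
  list(dataset = ds, truth = truth)
}

#' @exportS3Method base::print
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s\n",
              paste(names(table(x$labels)), table(x$labels), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Write phantom ground truth as CSV and label mask
#' @param ds the phantom's [msi_dataset()].
#' @param truth its `phantom_truth`.
#' @param prefix output prefix; writes `<prefix>_truth.csv` and a PNG
#'   label mask `<prefix>_truth.png` (sample=0, matrix=1, artifact=2).
#' @return `prefix`, invisibly.
#' @export
write_phantom_truth <- function(ds, truth, prefix) {
  utils::write.csv(
    data.frame(i = ds$coords[, 1], j = ds$coords[, 2],
               label = as.character(truth$labels),
               region = truth$region),
    paste0(prefix, "_truth.csv"), row.names = FALSE)
  code <- c(sample = 0L, matrix = 1L, artifact = 2L)
  mask <- matrix(255L, nrow = ds$height, ncol = ds$width)
  mask[cbind(ds$coords[, 2], ds$coords[, 1])] <-
    code[as.character(truth$labels)]
  png::writePNG(mask / 255, paste0(prefix, "_truth.png"))
  invisible(prefix)
}
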