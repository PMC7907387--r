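# Spectral-similarity pseudocoloring.
#
# Rendering works on an 8-bit byte representation of the spectra: each
# spectrum is scaled by 255/max and rounded, which bounds the per-spectrum
# intensity resolution at 256 distinct values. Because the similarity
# measure is angular (scale-free per vector), the per-spectrum scaling
# cannot distort Similarity mode. Three scalar fields can be rendered:
#   similarity: inverse angular distance to a reference pixel's spectrum,
#               c' = [255 * (1 - 2/pi * arccos(cos(p', p'_ref)))]
#   browsing:   one mass channel, c' = p'[, k]
#   grouping:   mean over a set of channels, c' = [mean_k p'[, k]]
# The raw field c' is min-max normalized over the spectral pixels to c''
# in [0, 255] and then mapped through a color lookup table.

#' 8-bit byte representation of a dataset
#'
#' Per spectrum s: `bytes = [255 * s / max(s)]` with half-away-from-zero
#' rounding; an all-zero spectrum stays all-zero.
#'
#' @param ds an [msi_dataset()].
#' @return A `byte_dataset`: like the input but with an integer `bytes`
#'   matrix in 0..255 instead of `intensities`.
#' @export
to_bytes <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  mx <- apply(ds$intensities, 1, max)
  scale <- ifelse(mx > 0, 255 / mx, 0)
  bytes <- round_half_away(ds$intensities * scale)
  storage.mode(bytes) <- "integer"
  structure(list(width = ds$width, height = ds$height, mz = ds$mz,
                 coords = ds$coords, bytes = bytes,
                 dataset_id = ds$dataset_id),
            class = "byte_dataset")
}

#' @exportS3Method base::print
print.byte_dataset <- function(x, ...) {
  cat(sprintf("<byte_dataset '%s'> %d x %d grid, %d spectral pixels, %d channels\n",
              x$dataset_id, x$width, x$height, nrow(x$coords),
              length(x$mz)))
  invisible(x)
}

new_field <- function(width, height, coords, values_at_coords) {
  values <- matrix(0, nrow = height, ncol = width)
  values[cbind(coords[, 2], coords[, 1])] <- values_at_coords
  structure(list(width = width, height = height, coords = coords,
                 values = values),
            class = "msi_field")
}

field_values <- function(field)
  field$values[cbind(field$coords[, 2], field$coords[, 1])]

#' @exportS3Method base::print
print.msi_field <- function(x, ...) {
  v <- field_values(x)
  cat(sprintf("<msi_field> %d x %d, %d spectral pixels, range %.4g-%.4g\n",
              x$width, x$height, nrow(x$coords), min(v), max(v)))
  invisible(x)
}

# Inverse-angular-distance similarity of every row of M against ref,
# on the 0..255 scale. Zero-norm rows map to 0 (maximally dissimilar),
# matching the black-background convention.
inverse_angle_values <- function(M, ref) {
  refn <- sqrt(sum(ref^2))
  rown <- sqrt(rowSums(M^2))
  cosv <- as.numeric(M %*% ref) / (rown * refn)
  cosv[!is.finite(cosv)] <- NA
  cosv <- pmin(pmax(cosv, -1), 1)
  out <- round_half_away(255 * (1 - (2 / pi) * acos(cosv)))
  out[rown == 0] <- 0
  out
}

#' Similarity field against a reference pixel
#'
#' The raw field value at (i, j) is the inverse angular distance between
#' that pixel's spectrum and the reference pixel's spectrum, mapped to
#' 0..255: identical direction gives 255, orthogonal spectra give 0.
#' Zero-norm and non-spectral pixels render as 0. Works on a
#' `byte_dataset` (the rendering path) and, for fidelity checks, directly
#' on an `msi_dataset` with full-precision intensities.
#'
#' @param x a `byte_dataset` from [to_bytes()], or an [msi_dataset()].
#' @param q,r grid coordinates of the reference pixel (column, row); must
#'   address a spectral pixel with a nonzero spectrum.
#' @return An `msi_field` with the raw values c'.
#' @export
similarity_field <- function(x, q, r) UseMethod("similarity_field")

#' @export
similarity_field.byte_dataset <- function(x, q, r) {
  idx <- ref_pixel_index(x, q, r)
  new_field(x$width, x$height, x$coords,
            inverse_angle_values(x$bytes, x$bytes[idx, ]))
}

#' @export
similarity_field.msi_dataset <- function(x, q, r) {
  idx <- ref_pixel_index(x, q, r)
  M <- x$intensities
  new_field(x$width, x$height, x$coords,
            inverse_angle_values(M, M[idx, ]))
}

ref_pixel_index <- function(x, q, r) {
  hit <- which(x$coords[, 1] == q & x$coords[, 2] == r)
  if (length(hit) == 0L)
    stop("reference pixel (", q, ", ", r, ") is not a spectral pixel")
  M <- if (inherits(x, "byte_dataset")) x$bytes else x$intensities
  if (all(M[hit[1L], ] == 0))
    stop("reference pixel (", q, ", ", r, ") has an all-zero spectrum")
  hit[1L]
}

#' Browsing field: one mass channel
#'
#' @param bds a `byte_dataset`.
#' @param k channel index 1..d.
#' @return An `msi_field` with `c' = bytes[, k]`.
#' @export
browsing_field <- function(bds, k) {
  stopifnot(inherits(bds, "byte_dataset"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(bds$mz))
    stop("channel index k out of range 1..", length(bds$mz))
  new_field(bds$width, bds$height, bds$coords, bds$bytes[, k])
}

#' Grouping field: mean over a channel set
#'
#' `c'` is the rounded mean of the byte values over the selected channels,
#' so a single-channel set reduces exactly to [browsing_field()].
#'
#' @param bds a `byte_dataset`.
#' @param channels nonempty vector of channel indices.
#' @return An `msi_field`.
#' @export
grouping_field <- function(bds, channels) {
  stopifnot(inherits(bds, "byte_dataset"))
  channels <- as.integer(channels)
  if (length(channels) == 0L) stop("empty channel set")
  if (any(is.na(channels)) || any(channels < 1L) ||
      any(channels > length(bds$mz)))
    stop("channel indices out of range 1..", length(bds$mz))
  vals <- round_half_away(
    rowMeans(bds$bytes[, channels, drop = FALSE]))
  new_field(bds$width, bds$height, bds$coords, vals)
}

#' Min-max normalize a raw field to 0..255
#'
#' `c'' = 255 * (c' - min) / (max - min)`, with min/max taken over the
#' spectral pixels only. A constant field maps to all zeros.
#'
#' @param field an `msi_field` of raw values.
#' @return An `msi_field` of normalized values in `[0, 255]`.
#' @export
normalize_field <- function(field) {
  stopifnot(inherits(field, "msi_field"))
  v <- field_values(field)
  mn <- min(v); mx <- max(v)
  nv <- if (mx > mn) 255 * (v - mn) / (mx - mn) else rep(0, length(v))
  new_field(field$width, field$height, field$coords, nv)
}

# 256-entry RGB lookup tables (values 0..255 per channel)
colormap_lut <- function(scale_name) {
  x <- 0:255
  switch(scale_name,
    gray = cbind(r = x, g = x, b = x),
    fire = {
      # black -> red -> yellow -> white, linear in RGB between the stops
      stops <- c(0, 96, 192, 255)
      rr <- c(0, 255, 255, 255); gg <- c(0, 0, 255, 255)
      bb <- c(0, 0, 0, 255)
      cbind(r = stats::approx(stops, rr, xout = x)$y,
            g = stats::approx(stops, gg, xout = x)$y,
            b = stats::approx(stops, bb, xout = x)$y)
    },
    stop("unknown color scale '", scale_name, "'"))
}

#' Apply a color scale to a normalized field
#'
#' Values are rounded to integers, clamped to 0..255 and looked up in a
#' 256-entry LUT. `"fire"` runs black, red, yellow, white; `"gray"` is the
#' identity on the value channel.
#'
#' @param field an `msi_field` with values in `[0, 255]` (typically from
#'   [normalize_field()]).
#' @param scale `"fire"` (default) or `"gray"`.
#' @return height x width x 3 array of RGB values in 0..255.
#' @export
apply_colormap <- function(field, scale = "fire") {
  stopifnot(inherits(field, "msi_field"))
  lut <- colormap_lut(scale)
  idx <- pmin(pmax(round_half_away(field$values), 0), 255) + 1
  array(c(lut[idx, 1], lut[idx, 2], lut[idx, 3]),
        dim = c(field$height, field$width, 3))
}

field_histogram <- function(field) {
  v <- field_values(field)
  bins <- pmin(floor(v), 255)
  tabulate(bins + 1L, nbins = 256L)
}

#' Render a pseudocolor map
#'
#' Computes the raw field for the requested mode, normalizes it, colors it
#' and (optionally) writes a PNG of the image, a CSV of the normalized
#' values per spectral pixel and a CSV of the 256-bin histogram next to
#' `out_prefix`. Non-spectral pixels render as the color of value 0.
#'
#' @param bds a `byte_dataset`.
#' @param mode `"similarity"`, `"browsing"` or `"grouping"`.
#' @param ref length-2 vector `c(q, r)` for similarity mode.
#' @param channel channel index for browsing mode.
#' @param channels channel set for grouping mode.
#' @param scale color scale name, see [apply_colormap()].
#' @param out_prefix if non-NULL, files `<prefix>.png`, `<prefix>_field.csv`
#'   and `<prefix>_histogram.csv` are written.
#' @return A `rendered_map`: list with `raw`, `normalized` (both
#'   `msi_field`), `image` (RGB array), `histogram` (256 counts summing to
#'   `|p+|`), `mode` and `reference`.
#' @export
render_map <- function(bds, mode = c("similarity", "browsing", "grouping"),
                       ref = NULL, channel = NULL, channels = NULL,
                       scale = "fire", out_prefix = NULL) {
  stopifnot(inherits(bds, "byte_dataset"))
  mode <- match.arg(mode)
  raw <- switch(mode,
    similarity = {
      if (is.null(ref) || length(ref) != 2L)
        stop("similarity mode needs ref = c(q, r)")
      similarity_field(bds, ref[1], ref[2])
    },
    browsing = {
      if (is.null(channel)) stop("browsing mode needs a channel")
      browsing_field(bds, channel)
    },
    grouping = {
      if (is.null(channels)) stop("grouping mode needs a channel set")
      grouping_field(bds, channels)
    })
  normalized <- normalize_field(raw)
  image <- apply_colormap(normalized, scale)
  histogram <- field_histogram(normalized)
  reference <- switch(mode, similarity = ref, browsing = channel,
                      grouping = channels)
  out <- structure(list(raw = raw, normalized = normalized, image = image,
                        histogram = histogram, mode = mode,
                        reference = reference),
                   class = "rendered_map")
  if (!is.null(out_prefix)) {
    png::writePNG(image / 255, paste0(out_prefix, ".png"))
    v <- field_values(normalized)
    utils::write.csv(data.frame(i = bds$coords[, 1], j = bds$coords[, 2],
                                value = v),
                     paste0(out_prefix, "_field.csv"), row.names = FALSE)
    utils::write.csv(data.frame(bin = 0:255, count = histogram),
                     paste0(out_prefix, "_histogram.csv"),
                     row.names = FALSE)
  }
  out
}

#' @exportS3Method base::print
print.rendered_map <- function(x, ...) {
  cat(sprintf("<rendered_map> mode=%s, %d x %d, histogram n=%d\n",
              x$mode, ncol(x$raw$values), nrow(x$raw$values),
              sum(x$histogram)))
  invisible(x)
}

#' Byte spectrum shown for a reference position
#'
#' Returns the byte spectrum at (q, r) if that pixel is spectral, and the
#' byte mean spectrum of the dataset otherwise (the viewer's fallback when
#' no reference is selected).
#'
#' @param bds a `byte_dataset`.
#' @param q,r grid coordinates.
#' @return numeric vector of length d.
#' @export
reference_spectrum <- function(bds, q, r) {
  stopifnot(inherits(bds, "byte_dataset"))
  hit <- which(bds$coords[, 1] == q & bds$coords[, 2] == r)
  if (length(hit) > 0L) as.numeric(bds$bytes[hit[1L], ])
  else colMeans(bds$bytes)
}
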