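# Peak picking on the mean spectrum.
#
# Peaks are picked on the dataset mean spectrum only, never on individual
# pixel spectra. A peak is a local maximum of the mean spectrum whose apex
# intensity exceeds a threshold z_t; its extent [l, r] is the contiguous
# run of channels around the apex with intensity >= 50% of the apex height
# (an FWHM-style reading), and its representative channel v is the integer
# median of {l, ..., r} (lower middle for even runs). The per-pixel peak
# intensity is the plain sum of intensities over l..r.

#' Winsorize the mean spectrum from above
#'
#' Caps every value at omega, the `z_w`-th highest value of the spectrum
#' (rank on the sorted-descending multiset, so ties at the rank share the
#' cap). Used to clip a few towering channels so that a picking threshold
#' can be judged against the bulk of the spectrum. `z_w = 1` caps at the
#' maximum, i.e. changes nothing.
#'
#' @param mu a `mean_spectrum` (see [mean_spectrum()]).
#' @param z_w positive integer rank, 1..d.
#' @return the winsorized `mean_spectrum`.
#' @export
winsorize_mean <- function(mu, z_w) {
  stopifnot(inherits(mu, "mean_spectrum"))
  z_w <- as.integer(z_w)
  d <- length(mu$mu)
  if (length(z_w) != 1L || is.na(z_w) || z_w < 1L || z_w > d)
    stop("z_w must be an integer in 1..", d)
  omega <- sort(mu$mu, decreasing = TRUE)[z_w]
  mu$mu <- pmin(mu$mu, omega)
  mu
}

# Leftmost channel of every maximal plateau that is a local maximum.
# A plateau run is a maximum when each existing neighbor run is strictly
# lower; runs touching the spectrum boundary only need the inner neighbor
# to be lower.
local_maxima_apexes <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  left_ok <- c(TRUE, r$values[-1] > r$values[-k])
  right_ok <- c(r$values[-k] > r$values[-1], TRUE)
  starts[left_ok & right_ok]
}

#' Peak extent at half height
#'
#' From a local-maximum apex, walks left and right through the contiguous
#' run of channels whose intensity is at least 50% of the apex height;
#' `l` and `r` are the outermost channels of that run and `v` the integer
#' median of `{l, ..., r}` (lower middle channel when the run has even
#' length).
#'
#' @param mu a `mean_spectrum`.
#' @param apex channel index of a local maximum.
#' @return list with integer `l`, `v`, `r`.
#' @export
peak_extent <- function(mu, apex) {
  stopifnot(inherits(mu, "mean_spectrum"))
  y <- mu$mu
  half <- 0.5 * y[apex]
  l <- apex
  while (l > 1L && y[l - 1L] >= half) l <- l - 1L
  r <- apex
  while (r < length(y) && y[r + 1L] >= half) r <- r + 1L
  list(l = l, v = l + (r - l) %/% 2L, r = r)
}

#' Detect peaks on the mean spectrum
#'
#' Local maxima (leftmost channel of a flat apex run) with intensity
#' strictly above `z_t` become peaks; extents come from [peak_extent()].
#' Where the extents of adjacent peaks would overlap, both are truncated at
#' the valley minimum between the two apexes (the valley channel goes to
#' the left peak), so peak intervals never overlap.
#'
#' @param mu a `mean_spectrum`, optionally winsorized first.
#' @param z_t minimum apex intensity, >= 0. In absolute `mu` units by
#'   default; with `relative = TRUE` it is a fraction of the maximum of
#'   `mu`, the scale on which thresholds like 0.019 are usually quoted.
#'   A relative threshold is also what makes matrix subtraction pay off
#'   at picking time: removing a dominant matrix signal lowers the
#'   maximum, so formerly buried tissue peaks clear the same `z_t`.
#' @param z_w winsorize rank actually applied to `mu` beforehand, recorded
#'   in the result for provenance only; `NA` if none.
#' @param relative interpret `z_t` as a fraction of `max(mu)`.
#' @return A `peak_set`: data.frame with columns `l`, `v`, `r`, `mz_v`,
#'   `height`, sorted by `mz_v`, plus attributes `z_t` and `z_w`.
#' @export
detect_peaks <- function(mu, z_t, z_w = NA_integer_, relative = FALSE) {
  stopifnot(inherits(mu, "mean_spectrum"))
  if (z_t < 0) stop("z_t must be >= 0")
  y <- mu$mu
  threshold <- if (relative) z_t * max(y) else z_t
  apexes <- local_maxima_apexes(y)
  apexes <- apexes[y[apexes] > threshold]
  if (length(apexes) == 0L)
    return(empty_peak_set(z_t, z_w))
  ext <- lapply(apexes, function(a) peak_extent(mu, a))
  l <- vapply(ext, `[[`, integer(1), "l")
  r <- vapply(ext, `[[`, integer(1), "r")
  if (length(apexes) > 1L) {
    for (k in seq_len(length(apexes) - 1L)) {
      if (r[k] >= l[k + 1L]) {
        between <- (apexes[k] + 1L):(apexes[k + 1L] - 1L)
        valley <- between[which.min(y[between])]
        r[k] <- min(r[k], valley)
        l[k + 1L] <- max(l[k + 1L], valley + 1L)
      }
    }
  }
  v <- l + (r - l) %/% 2L
  peaks <- data.frame(l = l, v = v, r = r, mz_v = mu$mz[v],
                      height = y[apexes])
  peaks <- peaks[order(peaks$mz_v), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, z_t = z_t, z_w = z_w, class = c("peak_set", "data.frame"))
}

empty_peak_set <- function(z_t = NA_real_, z_w = NA_integer_) {
  structure(data.frame(l = integer(0), v = integer(0), r = integer(0),
                       mz_v = numeric(0), height = numeric(0)),
            z_t = z_t, z_w = z_w, class = c("peak_set", "data.frame"))
}

#' @exportS3Method base::print
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (z_t=%.4g, z_w=%s)\n", nrow(x),
              attr(x, "z_t"),
              ifelse(is.na(attr(x, "z_w")), "none", attr(x, "z_w"))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Summed intensity of one peak in one spectrum
#'
#' @param spectrum numeric vector over the full channel axis.
#' @param peak one row of a `peak_set` (list/row with `l` and `r`).
#' @return sum of the spectrum over channels `l..r` inclusive.
#' @export
peak_intensity <- function(spectrum, peak) {
  sum(spectrum[peak$l:peak$r])
}

#' Reduce a dataset to its peaks
#'
#' Replaces the channel axis by the picked peaks: output channel k of each
#' pixel is the summed intensity of peak k over its extent, and the m/z
#' axis becomes the peaks' `mz_v` values. This is the dimensionality
#' reduction step that makes interactive rendering of high-resolution data
#' practical.
#'
#' @param ds an [msi_dataset()].
#' @param ps a nonempty `peak_set` picked on this dataset's mean spectrum.
#' @return The reduced [msi_dataset()] with `d = nrow(ps)`.
#' @export
reduce_to_peaks <- function(ds, ps) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(ps, "peak_set"))
  if (nrow(ps) == 0L) stop("empty peak set")
  out <- vapply(seq_len(nrow(ps)), function(k)
    rowSums(ds$intensities[, ps$l[k]:ps$r[k], drop = FALSE]),
    numeric(nrow(ds$intensities)))
  if (nrow(ds$intensities) == 1L) out <- matrix(out, nrow = 1L)
  ds$mz <- ps$mz_v
  ds$intensities <- out
  validate_msi_dataset(ds)
}

#' Remove isotope satellite peaks
#'
#' Greedy deisotoping assuming singly charged ions: peaks are visited in
#' order of descending height (ties: lower mass first); each kept peak at
#' mass m removes any not-yet-kept peak within `tol` of `m + n * spacing`
#' for `n = 1..max_iso`.
#'
#' @param ps a `peak_set` sorted by `mz_v`.
#' @param tol mass tolerance in Da for matching a satellite position.
#' @param max_iso number of satellite positions checked per peak.
#' @param spacing isotope spacing in Da; default 1.00335 (13C-12C mass
#'   difference, charge 1).
#' @return the filtered `peak_set`.
#' @export
deisotope <- function(ps, tol, max_iso = 3L, spacing = 1.00335) {
  stopifnot(inherits(ps, "peak_set"))
  n <- nrow(ps)
  if (n < 2L) return(ps)
  ord <- order(-ps$height, ps$mz_v)
  state <- rep("open", n)            # open | kept | removed
  for (k in ord) {
    if (state[k] != "open") next
    state[k] <- "kept"
    for (iso in seq_len(max_iso)) {
      sat <- ps$mz_v[k] + iso * spacing
      hit <- which(state == "open" & abs(ps$mz_v - sat) <= tol)
      state[hit] <- "removed"
    }
  }
  out <- ps[state == "kept", , drop = FALSE]
  rownames(out) <- NULL
  structure(out, z_t = attr(ps, "z_t"), z_w = attr(ps, "z_w"),
            class = c("peak_set", "data.frame"))
}

#' Write a peak list as CSV
#' @param ps a `peak_set`.
#' @param path output path (columns `mz_v`, `l`, `v`, `r`, `height`).
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(ps, path) {
  utils::write.csv(as.data.frame(ps)[, c("mz_v", "l", "v", "r", "height")],
                   path, row.names = FALSE)
  invisible(path)
}
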