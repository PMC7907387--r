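# Brute-force peak-picking oracle, independent of the package's
# implementation: every channel is tested by direct scans of its
# neighborhood, extents by exhaustive all()-checks over candidate runs,
# and the non-overlap truncation by a literal rescan of the valley.

oracle_peak_table <- function(y, z_t) {
  d <- length(y)
  apexes <- integer(0)
  for (k in seq_len(d)) {
    if (k > 1L && y[k - 1L] == y[k]) next      # not leftmost of plateau
    e <- k
    while (e < d && y[e + 1L] == y[k]) e <- e + 1L
    left_ok <- (k == 1L) || (y[k - 1L] < y[k])
    right_ok <- (e == d) || (y[e + 1L] < y[k])
    if (left_ok && right_ok && y[k] > z_t) apexes <- c(apexes, k)
  }
  if (length(apexes) == 0L)
    return(data.frame(l = integer(0), v = integer(0), r = integer(0),
                      height = numeric(0)))
  l <- r <- integer(length(apexes))
  for (t in seq_along(apexes)) {
    a <- apexes[t]
    half <- y[a] / 2
    cand_l <- a
    for (m in a:1) if (all(y[m:a] >= half)) cand_l <- m else break
    cand_r <- a
    for (m in a:d) if (all(y[a:m] >= half)) cand_r <- m else break
    l[t] <- cand_l; r[t] <- cand_r
  }
  if (length(apexes) > 1L) {
    for (t in seq_len(length(apexes) - 1L)) {
      if (r[t] >= l[t + 1L]) {
        seg <- (apexes[t] + 1L):(apexes[t + 1L] - 1L)
        valley <- seg[which.min(y[seg])]
        if (r[t] > valley) r[t] <- valley
        if (l[t + 1L] < valley + 1L) l[t + 1L] <- valley + 1L
      }
    }
  }
  v <- vapply(seq_along(apexes), function(t)
    (l[t]:r[t])[ceiling((r[t] - l[t] + 1L) / 2)], integer(1))
  data.frame(l = l, v = v, r = r, height = y[apexes])
}

# random spiky test spectra: sparse Gaussian bumps on a noise floor
random_spectrum <- function(d, n_bumps = 8) {
  y <- abs(stats::rnorm(d, 0, 0.05))
  centers <- sample.int(d, n_bumps)
  heights <- stats::runif(n_bumps, 0.5, 5)
  widths <- stats::runif(n_bumps, 0.8, 3)
  for (b in seq_len(n_bumps)) {
    win <- max(1, centers[b] - 8):min(d, centers[b] + 8)
    y[win] <- y[win] +
      heights[b] * exp(-(win - centers[b])^2 / (2 * widths[b]^2))
  }
  y
}

as_mean_spectrum <- function(y, mz = seq_along(y)) {
  structure(list(mz = as.numeric(mz), mu = as.numeric(y)),
            class = "mean_spectrum")
}
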