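# Embedding-based matrix and artifact detection and subtraction.
#
# Spectral pixels fall into three categories: sample (tissue) signals,
# matrix signals (the sprayed MALDI matrix, e.g. DHB, physically located in
# the border area around the tissue) and artifacts (isolated intensity
# hotspots scattered over the grid). The pixel spectra are embedded into
# 2-D (truncated SVD first when the channel count exceeds 1000, then UMAP),
# clustered there, and the clusters are mapped to categories by two spatial
# heuristics: artifact clusters are spatially scattered or tiny, and the
# matrix cluster is the one most concentrated on the image border frame.
# The mean spectrum of the matrix (or artifact) pixels is then subtracted
# from every pixel spectrum, clamped at zero.

#' Embed pixel spectra into 2-D
#'
#' When the number of channels d exceeds 1000, a truncated SVD to
#' `tsvd_components` dimensions is applied first and UMAP runs on the
#' reduced representation; otherwise UMAP runs on the spectra directly.
#' Duplicate spectra are collapsed before UMAP and share one embedding
#' point, so identical pixels land at exactly the same 2-D position. The
#' result is deterministic for a fixed seed (single-threaded UMAP).
#'
#' @param ds an [msi_dataset()] with at least 10 spectral pixels.
#' @param seed integer RNG seed (mandatory; recorded in the result).
#' @param tsvd_components dimensionality of the SVD pre-step, default 100.
#' @return An `embedding2d`: list with `coords2d` (`|p+| x 2`),
#'   `method_chain` (`"tsvd","umap"` or `"umap"`) and `seed`.
#' @export
embed_pixels <- function(ds, seed, tsvd_components = 100L) {
  stopifnot(inherits(ds, "msi_dataset"))
  n <- nrow(ds$intensities)
  if (n < 10L) stop("need at least 10 spectral pixels to embed")
  d <- length(ds$mz)
  X <- ds$intensities
  chain <- "umap"
  if (d > 1000L) {
    set.seed(seed)
    k <- min(tsvd_components, min(dim(X)) - 1L)
    sv <- irlba::irlba(X, nv = k)
    X <- sv$u %*% diag(sv$d, nrow = k)
    chain <- c("tsvd", "umap")
  }
  dup <- duplicated(X)
  Xu <- X[!dup, , drop = FALSE]
  nu <- nrow(Xu)
  if (nu < 4L) {
    # degenerate input: too few distinct spectra for a neighbor graph;
    # place each distinct spectrum at a fixed point
    coords_u <- cbind(seq_len(nu) - 1, rep(0, nu))
  } else {
    set.seed(seed)
    coords_u <- uwot::umap(Xu, n_neighbors = min(15L, nu - 1L),
                           n_threads = 1, n_sgd_threads = 1)
  }
  key <- apply(X, 1, function(row) paste(row, collapse = "\r"))
  key_u <- key[!dup]
  coords2d <- coords_u[match(key, key_u), , drop = FALSE]
  structure(list(coords2d = coords2d, method_chain = chain,
                 seed = as.integer(seed)),
            class = "embedding2d")
}

#' @exportS3Method base::print
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d pixels, chain %s, seed %d\n",
              nrow(x$coords2d), paste(x$method_chain, collapse = "+"),
              x$seed))
  invisible(x)
}

# Classic DBSCAN on a small 2-D point set. Returns integer labels,
# 0 = noise. O(n^2) distance evaluations, vectorized per point.
dbscan2d <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  neighbors_of <- function(k) {
    dx <- pts[, 1] - pts[k, 1]
    dy <- pts[, 2] - pts[k, 2]
    which(dx * dx + dy * dy <= eps * eps)
  }
  cluster <- 0L
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- neighbors_of(p)
    if (length(nb) < min_pts) next         # noise unless claimed later
    cluster <- cluster + 1L
    labels[p] <- cluster
    queue <- setdiff(nb, p)
    while (length(queue) > 0L) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- neighbors_of(q)
        if (length(nbq) >= min_pts)
          queue <- c(queue, nbq[!visited[nbq] & labels[nbq] == 0L])
      }
      if (labels[q] == 0L) labels[q] <- cluster
    }
  }
  labels
}

#' Default parameters for automatic classification
#'
#' @param eps DBSCAN radius in embedding units; `NULL` (default) uses
#'   `eps_frac` times the embedding span. UMAP packs points of one
#'   cluster densely while separating clusters by distances on the order
#'   of the span, so a span-relative radius is stable across datasets.
#' @param eps_frac fraction of the larger embedding extent used for the
#'   automatic `eps`.
#' @param min_pts DBSCAN core-point neighbor count.
#' @param min_matrix_frac clusters smaller than this fraction of `|p+|`
#'   are artifacts.
#' @param hotspot_dist clusters whose pixels have a mean spatial
#'   nearest-neighbor distance (grid units) above this are artifacts.
#' @param hotspot_cos per-pixel hotspot rule: a pixel whose spectrum has
#'   an angular distance (1 - cosine) above this value to the median
#'   spectrum of its 8 spatial neighbors is an artifact. 0.15
#'   corresponds to a spectral angle of about 32 degrees, far beyond
#'   what tissue boundaries produce.
#' @param border_px width of the border frame used to locate the matrix
#'   clusters.
#' @param min_border_frac minimum border-frame pixel fraction for a
#'   cluster to be accepted as matrix.
#' @return named list of parameters.
#' @export
clean_params <- function(eps = NULL, eps_frac = 0.05, min_pts = 10L,
                         min_matrix_frac = 0.01,
                         hotspot_dist = 3.0, hotspot_cos = 0.15,
                         border_px = 2L, min_border_frac = 0.1) {
  list(eps = eps, eps_frac = eps_frac, min_pts = as.integer(min_pts),
       min_matrix_frac = min_matrix_frac, hotspot_dist = hotspot_dist,
       hotspot_cos = hotspot_cos,
       border_px = as.integer(border_px), min_border_frac = min_border_frac)
}

# Angular distance (1 - cosine) of each pixel spectrum to the median
# spectrum of its up-to-8 spatial neighbors; NA where a pixel has no
# spectral neighbor or a zero-norm spectrum is involved.
neighborhood_angle <- function(ds) {
  n <- nrow(ds$coords)
  d <- length(ds$mz)
  idx <- matrix(NA_integer_, ds$height + 2L, ds$width + 2L)
  idx[cbind(ds$coords[, 2] + 1L, ds$coords[, 1] + 1L)] <- seq_len(n)
  M <- ds$intensities
  offsets <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  # (n*d) x 8 table of neighbor intensities, NA where absent
  nb_vals <- matrix(NA_real_, n * d, 8L)
  for (k in 1:8) {
    nbi <- idx[cbind(ds$coords[, 2] + 1L + offsets[k, 2],
                     ds$coords[, 1] + 1L + offsets[k, 1])]
    nb_vals[, k] <- as.vector(M[nbi, , drop = FALSE])
  }
  ref <- matrix(matrixStats::rowMedians(nb_vals, na.rm = TRUE), n, d)
  ref[!is.finite(ref)] <- NA_real_
  has_nb <- rowSums(!is.na(ref)) == d
  ref[is.na(ref)] <- 0
  den <- sqrt(rowSums(M^2) * rowSums(ref^2))
  out <- ifelse(has_nb & den > 0, 1 - rowSums(M * ref) / den, NA_real_)
  out
}

new_classification <- function(labels, provenance) {
  structure(list(labels = factor(labels,
                                 levels = c("sample", "matrix", "artifact")),
                 provenance = provenance),
            class = "pixel_classification")
}

#' @exportS3Method base::print
print.pixel_classification <- function(x, ...) {
  cat(sprintf("<pixel_classification> (%s) %s\n", x$provenance,
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# mean spatial nearest-neighbor distance among a set of (i, j) positions
mean_spatial_nn <- function(ij) {
  m <- nrow(ij)
  if (m < 2L) return(Inf)
  nn <- vapply(seq_len(m), function(p) {
    d2 <- (ij[, 1] - ij[p, 1])^2 + (ij[, 2] - ij[p, 2])^2
    sqrt(min(d2[-p]))
  }, numeric(1))
  mean(nn)
}

#' Automatic pixel classification
#'
#' Clusters the 2-D embedding with DBSCAN and maps clusters to categories
#' with three heuristics mirroring the physical description of the
#' classes:
#'
#' 1. *Hotspot rule* (per pixel): a pixel whose spectrum points in a
#'    grossly different direction than the median spectrum of its 8
#'    spatial neighbors (angular distance above `hotspot_cos`) is an
#'    isolated intensity hotspot, hence artifact. This also catches
#'    hotspots that the embedding placed inside a larger cluster.
#' 2. *Cluster rules*: DBSCAN noise points, clusters spatially scattered
#'    over the grid (mean spatial nearest-neighbor distance above
#'    `hotspot_dist`) and tiny clusters (below `min_matrix_frac * |p+|`)
#'    are artifacts.
#' 3. *Border rule*: among the remaining clusters, every cluster with at
#'    least `min_border_frac` of its pixels on the image border frame
#'    (width `border_px`) is matrix -- the matrix band is where no tissue
#'    lies. Everything else is sample.
#'
#' If clustering finds fewer than two clusters the cluster and border
#' rules cannot separate anything: everything (minus hotspots) is sample
#' and a warning is raised.
#'
#' @param ds an [msi_dataset()].
#' @param emb an `embedding2d` computed from `ds` (see [embed_pixels()]).
#' @param params see [clean_params()].
#' @return A `pixel_classification` with per-pixel labels in
#'   sample/matrix/artifact and provenance `"auto"`.
#' @export
auto_classify <- function(ds, emb, params = clean_params()) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(emb, "embedding2d"))
  n <- nrow(ds$coords)
  if (nrow(emb$coords2d) != n)
    stop("embedding does not match the dataset")
  pts <- emb$coords2d
  eps <- params$eps
  if (is.null(eps)) {
    span <- max(apply(pts, 2, function(col) diff(range(col))))
    eps <- params$eps_frac * span
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
  }
  ang <- neighborhood_angle(ds)
  hotspot <- !is.na(ang) & ang > params$hotspot_cos
  cl <- dbscan2d(pts, eps, params$min_pts)
  ids <- setdiff(unique(cl), 0L)
  if (length(ids) < 2L) {
    warning("fewer than two embedding clusters found; ",
            "all non-hotspot pixels labeled sample")
    labels <- ifelse(hotspot, "artifact", "sample")
    return(new_classification(labels, "auto"))
  }
  labels <- rep("sample", n)
  labels[cl == 0L] <- "artifact"
  remaining <- integer(0)
  for (id in ids) {
    members <- which(cl == id)
    tiny <- length(members) < params$min_matrix_frac * n
    scattered <- mean_spatial_nn(ds$coords[members, , drop = FALSE]) >
      params$hotspot_dist
    if (tiny || scattered) labels[members] <- "artifact"
    else remaining <- c(remaining, id)
  }
  if (length(remaining) > 0L) {
    b <- params$border_px
    on_border <- ds$coords[, 1] <= b | ds$coords[, 1] > ds$width - b |
                 ds$coords[, 2] <= b | ds$coords[, 2] > ds$height - b
    fracs <- vapply(remaining, function(id)
      mean(on_border[cl == id]), numeric(1))
    for (id in remaining[fracs >= params$min_border_frac])
      labels[cl == id] <- "matrix"
  }
  labels[hotspot] <- "artifact"
  new_classification(labels, "auto")
}

# even-odd rule point-in-polygon; poly is an m x 2 matrix of vertices
points_in_polygon <- function(pts, poly) {
  m <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- m
  for (k in seq_len(m)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- k
  }
  inside
}

#' Classification by explicit selection
#'
#' Headless stand-in for interactive selection: label the pixels inside a
#' polygon drawn in embedding space (even-odd rule), or an explicit list
#' of grid coordinates. Unselected pixels keep their prior label (or
#' sample if no prior classification is given).
#'
#' @param ds an [msi_dataset()].
#' @param emb an `embedding2d` (required for polygon selections).
#' @param selection either a list `list(polygon = <m x 2 matrix>)` with
#'   vertices in embedding space, or `list(coords = <m x 2 matrix>)` of
#'   (i, j) grid positions.
#' @param label `"sample"`, `"matrix"` or `"artifact"`.
#' @param prior optional `pixel_classification` to update.
#' @return A `pixel_classification` with provenance `"manual"`.
#' @export
classify_by_selection <- function(ds, emb = NULL, selection, label,
                                  prior = NULL) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (!label %in% c("sample", "matrix", "artifact"))
    stop("label must be one of sample, matrix, artifact")
  n <- nrow(ds$coords)
  labels <- if (is.null(prior)) rep("sample", n)
            else as.character(prior$labels)
  if (!is.null(selection$polygon)) {
    poly <- as.matrix(selection$polygon)
    if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
    if (is.null(emb)) stop("polygon selection requires an embedding")
    hit <- points_in_polygon(emb$coords2d, poly)
  } else if (!is.null(selection$coords)) {
    sel <- as.matrix(selection$coords)
    if (nrow(sel) == 0L) stop("empty coordinate selection")
    key <- paste(ds$coords[, 1], ds$coords[, 2])
    hit <- key %in% paste(sel[, 1], sel[, 2])
  } else {
    stop("selection must contain $polygon or $coords")
  }
  if (!any(hit)) stop("selection matches no spectral pixel")
  labels[hit] <- label
  new_classification(labels, "manual")
}

#' Subtract the mean spectrum of a pixel class
#'
#' The mean spectrum of the pixels carrying the given label is subtracted
#' channel-wise from every spectral pixel of the dataset; negative results
#' are clamped to zero. This removes e.g. the ubiquitous matrix signal
#' from tissue spectra rather than merely excluding matrix pixels.
#'
#' @param ds an [msi_dataset()].
#' @param cls a `pixel_classification` for `ds`.
#' @param which `"matrix"` or `"artifact"`.
#' @return The cleaned [msi_dataset()].
#' @export
subtract_class_mean <- function(ds, cls, which = c("matrix", "artifact")) {
  stopifnot(inherits(ds, "msi_dataset"),
            inherits(cls, "pixel_classification"))
  which <- match.arg(which)
  members <- cls$labels == which
  if (!any(members)) stop("no pixels labeled '", which, "'")
  m <- colMeans(ds$intensities[members, , drop = FALSE])
  out <- sweep(ds$intensities, 2, m, `-`)
  out[out < 0] <- 0
  ds$intensities <- out
  validate_msi_dataset(ds)
}

#' Remove the pixels of a class from the dataset
#'
#' Labeled pixels are dropped from the spectral-pixel set; the grid
#' dimensions are unchanged (removed positions become non-spectral).
#'
#' @inheritParams subtract_class_mean
#' @return The reduced [msi_dataset()].
#' @export
remove_pixels <- function(ds, cls, which = c("matrix", "artifact")) {
  stopifnot(inherits(ds, "msi_dataset"),
            inherits(cls, "pixel_classification"))
  which <- match.arg(which)
  drop <- cls$labels == which
  if (all(drop)) stop("removing '", which, "' would empty the dataset")
  ds$coords <- ds$coords[!drop, , drop = FALSE]
  ds$intensities <- ds$intensities[!drop, , drop = FALSE]
  validate_msi_dataset(ds)
}

#' Iterative artifact-first cleaning
#'
#' Strong artifacts can dominate the embedding and blur the
#' sample/matrix separation. This runs two passes: (1) embed, classify and
#' remove artifact pixels; (2) re-embed the remaining pixels, classify
#' again and subtract the matrix mean spectrum. With no artifacts detected
#' in pass 1, the result equals the single-pass pipeline.
#'
#' @param ds an [msi_dataset()].
#' @param seed RNG seed used for both embeddings.
#' @param params see [clean_params()].
#' @param emb optional precomputed pass-1 `embedding2d` for `ds` (same
#'   seed); saves one UMAP run when an embedding already exists.
#' @return list with `dataset` (cleaned), `classification` and `embedding`
#'   (both from the final pass) and `first_pass` (the pass-1
#'   classification).
#' @export
iterative_clean <- function(ds, seed, params = clean_params(),
                            emb = NULL) {
  e1 <- if (is.null(emb)) embed_pixels(ds, seed) else emb
  c1 <- auto_classify(ds, e1, params)
  if (any(c1$labels == "artifact")) {
    ds2 <- remove_pixels(ds, c1, "artifact")
    e2 <- embed_pixels(ds2, seed)
  } else {
    ds2 <- ds
    e2 <- e1
  }
  c2 <- auto_classify(ds2, e2, params)
  if (any(c2$labels == "matrix")) {
    ds3 <- subtract_class_mean(ds2, c2, "matrix")
  } else {
    warning("no matrix pixels detected in the final pass; ",
            "nothing subtracted")
    ds3 <- ds2
  }
  list(dataset = ds3, classification = c2, embedding = e2,
       first_pass = c1)
}

#' Write classification labels as CSV and PNG mask
#'
#' The PNG mask encodes sample=0, matrix=1, artifact=2 in the red channel
#' (values 0, 1, 2 out of 255); non-spectral pixels are 255.
#'
#' @param ds an [msi_dataset()].
#' @param cls a `pixel_classification`.
#' @param prefix output prefix; writes `<prefix>.csv` and `<prefix>.png`.
#' @return `prefix`, invisibly.
#' @export
write_classification <- function(ds, cls, prefix) {
  code <- c(sample = 0L, matrix = 1L, artifact = 2L)
  utils::write.csv(data.frame(i = ds$coords[, 1], j = ds$coords[, 2],
                              label = as.character(cls$labels)),
                   paste0(prefix, ".csv"), row.names = FALSE)
  mask <- matrix(255L, nrow = ds$height, ncol = ds$width)
  mask[cbind(ds$coords[, 2], ds$coords[, 1])] <-
    code[as.character(cls$labels)]
  png::writePNG(mask / 255, paste0(prefix, ".png"))
  invisible(prefix)
}

#' Read a PNG label mask back into a classification
#' @param ds an [msi_dataset()] the mask belongs to.
#' @param path PNG path written by [write_classification()].
#' @return A `pixel_classification` with provenance `"manual"`.
#' @export
read_classification_mask <- function(ds, path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  code <- round(img * 255)
  vals <- code[cbind(ds$coords[, 2], ds$coords[, 1])]
  labels <- c("sample", "matrix", "artifact")[vals + 1L]
  if (anyNA(labels)) stop("mask contains values other than 0/1/2 at spectral pixels")
  new_classification(labels, "manual")
}
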