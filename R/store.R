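# HDF5 pixel-table store.
#
# Layout (schema version 1):
#   /                      attribute "msimaps_schema" = "1"
#   /<dataset_id>/mz            float64[d]
#   /<dataset_id>/coords        int32[|p+| x 2]   (columns i, j)
#   /<dataset_id>/intensities   float32[|p+| x d]
#   /<dataset_id>               attributes "width", "height"
# Several datasets can live in one file, keyed by dataset_id.

STORE_SCHEMA_VERSION <- "1"

#' Save a dataset into an HDF5 store
#'
#' Creates the file if needed; a group with the same `dataset_id` is
#' replaced. Intensities are stored as 32-bit floats, the m/z axis as
#' 64-bit floats.
#'
#' @param ds an [msi_dataset()].
#' @param path store file path (`.h5`).
#' @return `path`, invisibly.
#' @export
save_store <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  rhdf5::h5closeAll()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!file.exists(path)) {
    rhdf5::h5createFile(path)
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(STORE_SCHEMA_VERSION, fid, "msimaps_schema")
    rhdf5::H5Fclose(fid)
  } else {
    check_store_schema(path)
  }
  gname <- ds$dataset_id
  existing <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (gname %in% existing) rhdf5::h5delete(path, gname)
  rhdf5::h5createGroup(path, gname)
  rhdf5::h5write(ds$mz, path, paste0(gname, "/mz"))
  rhdf5::h5write(ds$coords, path, paste0(gname, "/coords"))
  rhdf5::h5createDataset(path, paste0(gname, "/intensities"),
                         dims = dim(ds$intensities),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(ds$intensities, path, paste0(gname, "/intensities"))
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, gname)
  rhdf5::h5writeAttribute(ds$width, gid, "width")
  rhdf5::h5writeAttribute(ds$height, gid, "height")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

check_store_schema <- function(path) {
  ver <- tryCatch(
    as.character(rhdf5::h5readAttributes(path, "/")$msimaps_schema),
    error = function(e) NA_character_)
  if (is.na(ver) || length(ver) == 0L)
    stop("'", path, "' is not a readable msimaps store (missing schema tag)")
  if (!identical(ver, STORE_SCHEMA_VERSION))
    stop("store schema version mismatch: file has '", ver,
         "', this package reads '", STORE_SCHEMA_VERSION, "'")
  invisible(ver)
}

#' List dataset ids in a store
#' @param path store file path.
#' @return character vector of dataset ids.
#' @export
list_store <- function(path) {
  rhdf5::h5closeAll()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  check_store_schema(path)
  rhdf5::h5ls(path, recursive = FALSE)$name
}

#' Load a dataset from an HDF5 store
#'
#' @param path store file path.
#' @param dataset_id id of the dataset to load; may be omitted when the
#'   store holds exactly one.
#' @return An [msi_dataset()].
#' @export
load_store <- function(path, dataset_id = NULL) {
  rhdf5::h5closeAll()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  check_store_schema(path)
  ids <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (is.null(dataset_id)) {
    if (length(ids) != 1L)
      stop("store holds ", length(ids),
           " datasets; pass dataset_id (one of: ",
           paste(ids, collapse = ", "), ")")
    dataset_id <- ids
  }
  if (!dataset_id %in% ids)
    stop("dataset '", dataset_id, "' not in store")
  mz <- as.numeric(rhdf5::h5read(path, paste0(dataset_id, "/mz")))
  coords <- rhdf5::h5read(path, paste0(dataset_id, "/coords"))
  intens <- rhdf5::h5read(path, paste0(dataset_id, "/intensities"))
  at <- rhdf5::h5readAttributes(path, dataset_id)
  msi_dataset(at$width, at$height, mz, coords, intens,
              dataset_id = dataset_id)
}

#' Export the mean spectrum as CSV
#' @param ds an [msi_dataset()].
#' @param path output CSV path (columns `mz`, `mu`).
#' @return `path`, invisibly.
#' @export
write_mean_spectrum_csv <- function(ds, path) {
  mu <- mean_spectrum(ds)
  utils::write.csv(data.frame(mz = mu$mz, mu = mu$mu), path,
                   row.names = FALSE)
  invisible(path)
}
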