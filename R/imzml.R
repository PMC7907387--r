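# imzML 1.1 input/output.
#
# imzML splits a dataset into an XML part (.imzML: metadata, pixel
# positions, byte offsets) and a binary part (.ibd: a 16-byte UUID followed
# by the raw m/z and intensity arrays). Two layouts exist: "continuous"
# (one shared m/z array, one intensity array per pixel) and "processed"
# (per-pixel m/z and intensity arrays). Only the controlled-vocabulary
# terms needed for these layouts are handled here.

IMZML_ACC <- list(
  continuous = "IMS:1000030", processed = "IMS:1000031",
  uuid = "IMS:1000080",
  pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  ext_offset = "IMS:1000102", ext_len = "IMS:1000103",
  ext_enc_len = "IMS:1000104",
  mz_array = "MS:1000514", int_array = "MS:1000515",
  f64 = "MS:1000523", f32 = "MS:1000521")

ibd_path_for <- function(path) {
  base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  paste0(base, ".ibd")
}

#' Read an imzML/ibd pair
#'
#' Supports continuous and processed mode. Processed-mode spectra are
#' unified onto a common axis: the union of all per-pixel m/z values,
#' optionally merged when neighboring values lie within `tol` of each other
#' (merged channels take the mean m/z; intensities falling on the same
#' merged channel are summed). Channels absent in a pixel are 0.
#'
#' @param path path to the `.imzML` file; the companion `.ibd` must sit
#'   next to it with the same base name.
#' @param tol tolerance in Da for merging the union axis of processed-mode
#'   files; default 0 (exact-value union).
#' @param dataset_id identifier for the returned dataset; defaults to the
#'   file base name.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, tol = 0, dataset_id = NULL) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd))
    stop("companion .ibd file not found: ", ibd)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("failed to parse imzML XML in '", path, "': ",
         conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.imzml$", "", basename(path), ignore.case = TRUE)

  acc_here <- function(node, accession)
    length(xml2::xml_find_all(
      node, sprintf(".//cvParam[@accession='%s']", accession))) > 0
  continuous <- acc_here(doc, IMZML_ACC$continuous)
  processed <- acc_here(doc, IMZML_ACC$processed)
  if (!continuous && !processed)
    stop("imzML file declares neither continuous nor processed mode")

  # referenceableParamGroup id -> vector of accessions, so arrays that only
  # carry a group reference can still be typed
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_acc <- lapply(groups, function(g)
    xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession"))
  names(group_acc) <- xml2::xml_attr(groups, "id")

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  n <- length(spectra)
  if (n == 0L) stop("imzML file contains no spectra")

  param_value <- function(node, accession) {
    p <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    xml2::xml_attr(p, "value")
  }
  array_info <- function(bda) {
    accs <- xml2::xml_attr(xml2::xml_find_all(bda, "./cvParam"), "accession")
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
    if (!is.na(ref) && ref %in% names(group_acc))
      accs <- c(accs, group_acc[[ref]])
    kind <- if (IMZML_ACC$mz_array %in% accs) "mz"
            else if (IMZML_ACC$int_array %in% accs) "intensity"
            else NA_character_
    size <- if (IMZML_ACC$f64 %in% accs) 8L
            else if (IMZML_ACC$f32 %in% accs) 4L
            else stop("unsupported binary data type (only 32/64-bit float)")
    list(kind = kind,
         size = size,
         offset = as.numeric(param_value(bda, IMZML_ACC$ext_offset)),
         len = as.integer(param_value(bda, IMZML_ACC$ext_len)))
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_array <- function(info) {
    seek(con, where = info$offset, origin = "start")
    readBin(con, what = "double", n = info$len, size = info$size,
            endian = "little")
  }

  coords <- matrix(0L, nrow = n, ncol = 2,
                   dimnames = list(NULL, c("i", "j")))
  mz_list <- vector("list", n)
  int_list <- vector("list", n)
  shared_mz <- NULL
  for (s in seq_len(n)) {
    sp <- spectra[[s]]
    scan <- xml2::xml_find_first(sp, ".//scan")
    coords[s, ] <- c(as.integer(param_value(scan, IMZML_ACC$pos_x)),
                     as.integer(param_value(scan, IMZML_ACC$pos_y)))
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    infos <- lapply(bdas, array_info)
    kinds <- vapply(infos, `[[`, "", "kind")
    mzi <- infos[[match("mz", kinds)]]
    ini <- infos[[match("intensity", kinds)]]
    if (continuous) {
      if (is.null(shared_mz)) shared_mz <- read_array(mzi)
      int_list[[s]] <- read_array(ini)
    } else {
      mz_list[[s]] <- read_array(mzi)
      int_list[[s]] <- read_array(ini)
    }
  }

  if (continuous) {
    d <- length(shared_mz)
    intens <- do.call(rbind, int_list)
    if (ncol(intens) != d) stop("inconsistent spectrum lengths")
    mz <- shared_mz
  } else {
    merged <- merge_mz_union(unlist(mz_list), tol)
    mz <- merged$mz
    intens <- matrix(0, nrow = n, ncol = length(mz))
    for (s in seq_len(n)) {
      idx <- map_to_axis(mz_list[[s]], merged)
      # sum, not assign: several source channels may merge onto one target
      for (u in seq_along(idx))
        intens[s, idx[u]] <- intens[s, idx[u]] + int_list[[s]][u]
    }
  }
  intens[intens < 0] <- 0
  grid_w <- max(coords[, 1])
  grid_h <- max(coords[, 2])
  msi_dataset(grid_w, grid_h, mz, coords, intens, dataset_id = dataset_id)
}

# Union axis for processed-mode files: sorted unique values, then clusters
# of consecutive values closer than tol collapse to their mean.
merge_mz_union <- function(values, tol = 0) {
  u <- sort(unique(values))
  if (tol <= 0 || length(u) < 2L)
    return(list(mz = u, breaks = u, cluster = seq_along(u), sorted = u))
  cluster <- cumsum(c(1, diff(u) > tol))
  mz <- as.numeric(tapply(u, cluster, mean))
  list(mz = mz, cluster = cluster, sorted = u)
}

map_to_axis <- function(values, merged) {
  pos <- match(values, merged$sorted)
  if (anyNA(pos)) stop("internal: m/z value missing from union axis")
  if (is.null(merged$cluster)) pos else merged$cluster[pos]
}

#' Write a continuous-mode imzML/ibd pair
#'
#' The m/z axis is stored once as 64-bit floats; intensities are stored as
#' 32-bit floats (one array per spectral pixel). A fresh UUID is written to
#' both the XML and the .ibd header.
#'
#' @param ds an [msi_dataset()].
#' @param path output `.imzML` path; the `.ibd` is written next to it.
#' @return the `.imzML` path, invisibly.
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (nrow(ds$coords) == 0L) stop("no spectral pixels")
  ibd <- ibd_path_for(path)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_str <- paste(sprintf("%02X", as.integer(uuid)), collapse = "")

  d <- length(ds$mz)
  n <- nrow(ds$coords)
  mz_offset <- 16
  int_offsets <- mz_offset + 8 * d + 4 * d * (seq_len(n) - 1)

  con <- file(ibd, "wb")
  writeBin(uuid, con)
  writeBin(as.numeric(ds$mz), con, size = 8, endian = "little")
  for (s in seq_len(n))
    writeBin(as.numeric(ds$intensities[s, ]), con, size = 4,
             endian = "little")
  close(con)

  spectra_xml <- vapply(seq_len(n), function(s) {
    imzml_spectrum_xml(s, ds$coords[s, 1], ds$coords[s, 2], d,
                       mz_offset, 8 * d, d, int_offsets[s], 4 * d)
  }, character(1))
  xml <- imzml_document_xml("continuous", uuid_str, ds$width, ds$height,
                            spectra_xml)
  writeLines(xml, path)
  invisible(path)
}

# Processed-mode writer used to build test fixtures with per-pixel axes.
# coords: n x 2; mz_list/int_list: per-pixel numeric vectors.
write_imzml_processed <- function(path, coords, mz_list, int_list,
                                  width = max(coords[, 1]),
                                  height = max(coords[, 2])) {
  ibd <- ibd_path_for(path)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_str <- paste(sprintf("%02X", as.integer(uuid)), collapse = "")
  n <- nrow(coords)

  con <- file(ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  spectra_xml <- character(n)
  for (s in seq_len(n)) {
    mzv <- as.numeric(mz_list[[s]])
    iv <- as.numeric(int_list[[s]])
    stopifnot(length(mzv) == length(iv))
    writeBin(mzv, con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + 8 * length(mzv)
    writeBin(iv, con, size = 4, endian = "little")
    int_off <- offset; offset <- offset + 4 * length(iv)
    spectra_xml[s] <- imzml_spectrum_xml(
      s, coords[s, 1], coords[s, 2], length(mzv),
      mz_off, 8 * length(mzv), length(iv), int_off, 4 * length(iv))
  }
  close(con)
  xml <- imzml_document_xml("processed", uuid_str, width, height,
                            spectra_xml)
  writeLines(xml, path)
  invisible(path)
}

imzml_spectrum_xml <- function(index, i, j, mz_len, mz_off, mz_bytes,
                               int_len, int_off, int_bytes) {
  sprintf(
'      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
    index, index - 1L, mz_len, i, j, mz_len, mz_bytes, mz_off,
    int_len, int_bytes, int_off)
}

imzml_document_xml <- function(mode, uuid_str, width, height, spectra_xml) {
  mode_acc <- if (mode == "continuous") IMZML_ACC$continuous
              else IMZML_ACC$processed
  paste0(
'<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="IMS" accession="', mode_acc, '" name="', mode, '"/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{', uuid_str, '}"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="msimaps" version="0.1.0"/>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', width, '"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', height, '"/>
    </scanSettings>
  </scanSettingsList>
  <run id="run1">
    <spectrumList count="', length(spectra_xml), '">
', paste(spectra_xml, collapse = "\n"), '
    </spectrumList>
  </run>
</mzML>')
}
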