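# imzML input/output and tabular exports.
#
# imzML stores an XML index (.imzML) next to a binary blob (.ibd) that
# starts with the 16-byte UUID echoed in the XML. In continuous mode the
# m/z axis is written once and every spectrum appends its intensity array;
# in processed mode each spectrum carries its own m/z array. Per-spectrum
# x/y/z grid positions are 1-based in the file and mapped to the package's
# 0-based image convention on read. Intensities default to 32-bit floats,
# the m/z axis to 64-bit.

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

random_uuid_raw <- function() {
  as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
}

uuid_to_string <- function(u) {
  h <- paste0(format(u), collapse = "")
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

#' Write sections to an imzML/ibd file pair (continuous mode)
#'
#' All sections must share one m/z axis; each section's pixels are written
#' with its `z_index` as the third grid position so that a whole
#' (timepoint, segment) stack round-trips through one file.
#'
#' @param sections An [msi_section], a list of them, or an [msi_study].
#' @param path Output path (with or without the `.imzML` extension).
#' @param intensity_bytes 4 (32-bit float, default) or 8 (64-bit).
#' @return The `.imzML` path, invisibly.
#' @export
write_imzml <- function(sections, path, intensity_bytes = 4L) {
  if (inherits(sections, "msi_study")) sections <- sections$sections
  if (inherits(sections, "msi_section")) sections <- list(sections)
  stopifnot(length(sections) >= 1L, intensity_bytes %in% c(4L, 8L))
  mz <- sections[[1L]]$mz
  for (s in sections) {
    if (!isTRUE(all.equal(s$mz, mz))) {
      msi_stop("write_imzml needs a shared m/z axis across sections")
    }
  }
  p <- imzml_paths(path)
  uuid <- random_uuid_raw()
  con <- file(p$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  mz_offset <- 16L
  writeBin(as.numeric(mz), con, size = 8L, endian = "little")
  offset <- mz_offset + 8 * length(mz)
  rows <- character(0)
  idx <- 0L
  total <- sum(vapply(sections, function(s) nrow(s$intensities), numeric(1)))
  spectra <- character(total)
  for (s in sections) {
    for (pix in seq_len(nrow(s$intensities))) {
      idx <- idx + 1L
      writeBin(as.numeric(s$intensities[pix, ]), con,
               size = intensity_bytes, endian = "little")
      enc_len <- intensity_bytes * length(mz)
      spectra[idx] <- sprintf(
        paste0(
          '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
          '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>',
          '<scan><cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000052" name="position z" value="%d"/>',
          '</scan></scanList>',
          '<binaryDataArrayList count="2">',
          '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
          '<binary/></binaryDataArray>',
          '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
          '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
          '<binary/></binaryDataArray>',
          '</binaryDataArrayList></spectrum>'
        ),
        idx - 1L, idx, length(mz),
        s$coords$x[pix] + 1L, s$coords$y[pix] + 1L, s$meta$z_index,
        length(mz), mz_offset, 8L * length(mz),
        length(mz), offset, enc_len
      )
      offset <- offset + enc_len
    }
  }
  int_bits_acc <- if (intensity_bytes == 4L) "MS:1000521" else "MS:1000523"
  int_bits_name <- if (intensity_bytes == 4L) "32-bit float" else "64-bit float"
  max_x <- max(vapply(sections, function(s) max(s$coords$x), numeric(1))) + 1L
  max_y <- max(vapply(sections, function(s) max(s$coords$y), numeric(1))) + 1L
  header <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="%s" name="%s"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>',
    '</scanSettings></scanSettingsList>\n',
    '<softwareList count="1"><software id="msi3d" version="0.1.0"/></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="msi3d">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n'),
    uuid_to_string(uuid), int_bits_acc, int_bits_name, max_x, max_y,
    sections[[1L]]$pixel_size, total)
  xml <- c(header, spectra, "</spectrumList>\n</run>\n</mzML>")
  writeLines(paste0(xml, collapse = "\n"), p$xml)
  invisible(p$xml)
}

# pull one attribute from a cvParam accession under a node set, vectorized
cv_values <- function(doc, xpath) {
  nodes <- xml2::xml_find_all(doc, xpath)
  xml2::xml_attr(nodes, "value")
}

#' Read an imzML file into MSI sections
#'
#' Continuous files keep their shared axis; processed files are resampled
#' (linear interpolation) onto a common uniform axis spanning the union of
#' all per-pixel axes. Pixels are grouped into sections by their z
#' position; 1-based file coordinates become 0-based grid coordinates.
#'
#' @param path `.imzML` path (the `.ibd` must sit next to it).
#' @param bin_width Bin width for resampling processed-mode data; default =
#'   the median spacing of the first spectrum's axis.
#' @return List of [msi_section] objects (one per z position).
#' @export
read_imzml <- function(path, bin_width = NULL) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) msi_stop("file not found: ", p$xml)
  if (!file.exists(p$ibd)) {
    msi_stop("missing binary file: ", p$ibd, class = "msi3d_format_error")
  }
  doc <- xml2::read_xml(p$xml)
  xml2::xml_ns_strip(doc)
  mode_cont <- length(xml2::xml_find_all(
    doc, "//cvParam[@accession='IMS:1000030']")) > 0L
  mode_proc <- length(xml2::xml_find_all(
    doc, "//cvParam[@accession='IMS:1000031']")) > 0L
  if (!mode_cont && !mode_proc) {
    msi_stop("imzML file declares neither continuous nor processed mode ",
             "(fileContent cvParam missing)", class = "msi3d_format_error")
  }
  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(spectra)) {
    msi_stop("imzML file contains no spectra", class = "msi3d_format_error")
  }
  gx <- as.integer(cv_values(doc, "//spectrum//cvParam[@accession='IMS:1000050']"))
  gy <- as.integer(cv_values(doc, "//spectrum//cvParam[@accession='IMS:1000051']"))
  gz <- cv_values(doc, "//spectrum//cvParam[@accession='IMS:1000052']")
  gz <- if (length(gz)) as.integer(gz) else rep(1L, length(gx))
  if (length(gx) != length(spectra) || length(gy) != length(spectra)) {
    msi_stop("spectrum scan positions missing (IMS:1000050/51)",
             class = "msi3d_format_error")
  }
  # per-spectrum external offsets: mz array first, intensity second, by
  # referenceableParamGroupRef
  grp_prec <- function(group_id) {
    acc <- xml2::xml_attr(xml2::xml_find_all(doc, sprintf(
      "//referenceableParamGroup[@id='%s']/cvParam[@accession='MS:1000523' or @accession='MS:1000521']",
      group_id)), "accession")
    if (!length(acc)) "MS:1000523" else acc[1L]
  }
  bytes_of <- function(acc) if (acc == "MS:1000521") 4L else 8L
  arr_info <- function(group_id) {
    base <- sprintf(
      "//spectrum//binaryDataArray[referenceableParamGroupRef/@ref='%s']",
      group_id)
    list(
      offset = as.numeric(cv_values(
        doc, paste0(base, "/cvParam[@accession='IMS:1000102']"))),
      length = as.integer(cv_values(
        doc, paste0(base, "/cvParam[@accession='IMS:1000103']"))),
      bytes = bytes_of(grp_prec(group_id))
    )
  }
  mzs <- arr_info("mzArray")
  ints <- arr_info("intensityArray")
  if (length(ints$offset) != length(spectra)) {
    msi_stop("binary data array index incomplete",
             class = "msi3d_format_error")
  }
  ibd <- file(p$ibd, "rb")
  on.exit(close(ibd), add = TRUE)
  read_arr <- function(offset, n, bytes) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, "numeric", n = n, size = bytes, endian = "little")
  }
  ns <- length(spectra)
  if (mode_cont) {
    mz <- read_arr(mzs$offset[1L], mzs$length[1L], mzs$bytes)
    if (is.unsorted(mz, strictly = TRUE)) {
      msi_stop("m/z axis is not strictly increasing",
               class = "msi3d_format_error")
    }
    X <- matrix(0, ns, length(mz))
    for (i in seq_len(ns)) {
      X[i, ] <- read_arr(ints$offset[i], ints$length[i], ints$bytes)
    }
  } else {
    mz_list <- lapply(seq_len(ns), function(i)
      read_arr(mzs$offset[i], mzs$length[i], mzs$bytes))
    int_list <- lapply(seq_len(ns), function(i)
      read_arr(ints$offset[i], ints$length[i], ints$bytes))
    if (is.null(bin_width)) bin_width <- stats::median(diff(mz_list[[1L]]))
    rng <- range(unlist(mz_list))
    mz <- seq(rng[1L], rng[2L], by = bin_width)
    X <- matrix(0, ns, length(mz))
    for (i in seq_len(ns)) {
      X[i, ] <- stats::approx(mz_list[[i]], int_list[[i]], xout = mz,
                              yleft = 0, yright = 0, rule = 1)$y
      X[i, is.na(X[i, ])] <- 0
    }
  }
  X[X < 0] <- 0
  pix <- data.frame(x = gx - 1L, y = gy - 1L, z = gz)
  secs <- lapply(sort(unique(pix$z)), function(z) {
    rows <- which(pix$z == z)
    msi_section(mz, X[rows, , drop = FALSE],
                pix[rows, c("x", "y")], z_index = z,
                z_position_um = NA_real_)
  })
  secs
}

#' Export a feature matrix as CSV
#'
#' One row per pixel with its (section, x, y) key; columns are the m/z
#' interval centers.
#'
#' @param features A [feature_matrix].
#' @param path Output CSV path.
#' @export
export_feature_matrix <- function(features, path) {
  df <- cbind(features$keys, as.data.frame(features$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix back from CSV
#' @param path CSV path written by [export_feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  keycols <- c("section", "x", "y")
  vals <- as.matrix(df[, setdiff(names(df), keycols), drop = FALSE])
  centers <- as.numeric(sub("^mz_", "", colnames(vals)))
  feature_matrix(vals, df[, keycols], centers)
}

#' Export a peak list as CSV
#' @param peaks A [peaklist].
#' @param path Output CSV path.
#' @export
export_peaklist <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
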