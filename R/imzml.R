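# Minimal processed-mode imzML writer/reader.
#
# imzML stores metadata in an XML file (<name>.imzML) and the numeric arrays
# in a binary sidecar (<name>.ibd) whose first 16 bytes are a UUID echoed in
# the XML. In processed mode every spectrum carries its own m/z array. m/z
# values are written as 64-bit floats, intensities as 32-bit floats.

.imzml_uuid <- function(seed) {
  set.seed(seed)
  as.raw(sample(0:255, 16, replace = TRUE))
}

#' Write a peak table as processed-mode imzML
#'
#' Writes one spectrum per row of the peak table at the given 1-based integer
#' pixel coordinates. Zero-intensity entries are kept so that every pixel
#' shares the centroid list (the file is still declared processed mode, since
#' per-section centroid lists differ in general).
#'
#' @param table a `peak_table`.
#' @param coordinates data.frame or matrix with columns `x`, `y` (1-based
#'   integers), one row per table row.
#' @param path output path; `".imzML"` is appended when missing, and the
#'   binary sidecar uses the same stem with `".ibd"`.
#' @return Invisibly, the path of the XML file.
#' @seealso [read_imzml()]
#' @export
write_imzml <- function(table, coordinates, path) {
  stopifnot(inherits(table, "peak_table"))
  coordinates <- as.data.frame(coordinates)
  if (!all(c("x", "y") %in% names(coordinates)))
    stop("`coordinates` needs columns x and y", call. = FALSE)
  n <- nrow(table$intensity)
  if (nrow(coordinates) != n)
    stop("coordinate/row-count mismatch: ", nrow(coordinates), " vs ", n,
         call. = FALSE)
  if (any(coordinates$x < 1) || any(coordinates$y < 1) ||
      any(coordinates$x != round(coordinates$x)) ||
      any(coordinates$y != round(coordinates$y)))
    stop("coordinates must be 1-based integers", call. = FALSE)

  path <- sub("\\.imzML$", "", path)
  xml_path <- paste0(path, ".imzML")
  ibd_path <- paste0(path, ".ibd")

  uuid <- .imzml_uuid(sum(utf8ToInt(basename(path))) + n)
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    mz <- as.numeric(table$mz)
    inten <- as.numeric(table$intensity[i, ])
    writeBin(mz, con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + 8 * length(mz)
    writeBin(inten, con, size = 4, endian = "little")
    int_off <- offset; offset <- offset + 4 * length(inten)
    meta[[i]] <- list(mz_off = mz_off, int_off = int_off,
                      len = length(mz))
  }

  uuid_str <- paste0("{", paste0(format(as.hexmode(as.integer(uuid)),
                                        width = 2), collapse = ""), "}")
  spectra_xml <- vapply(seq_len(n), function(i) {
    m <- meta[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, m$len,
      coordinates$x[i], coordinates$y[i],
      m$mz_off, m$len, 8L * m$len,
      m$int_off, m$len, 4L * m$len)
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>',
            uuid_str),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="meister" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            max(coordinates$x)),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            max(coordinates$y)),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="meister">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run0" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="export">', n),
    paste0(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, xml_path)
  invisible(xml_path)
}

#' Read a processed-mode imzML file
#'
#' Parses the XML index, reads the external binary arrays from the `.ibd`
#' sidecar, and reassembles a peak table. When the per-pixel m/z lists are
#' identical the table uses them directly; otherwise the peak lists are
#' aligned with [ppm_bin()].
#'
#' @param path path to the `.imzML` file.
#' @param width_ppm bin width used when per-pixel m/z lists differ.
#' @return list with `table` (a `peak_table`) and `coordinates` (data.frame
#'   `x`, `y`).
#' @export
read_imzml <- function(path, width_ppm = 3) {
  doc <- xml2::read_xml(path)
  ns <- c(d = "http://psi.hupo.org/ms/mzml")
  ibd_path <- paste0(sub("\\.imzML$", "", path), ".ibd")
  if (!file.exists(ibd_path))
    stop("missing binary sidecar: ", ibd_path, call. = FALSE)
  spectra <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  if (!length(spectra)) stop("no spectra in imzML file", call. = FALSE)
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)
  ibd_size <- file.size(ibd_path)

  get_param <- function(node, accession) {
    p <- xml2::xml_find_first(
      node, sprintf(".//d:cvParam[@accession='%s']", accession), ns)
    if (inherits(p, "xml_missing")) NA_character_
    else xml2::xml_attr(p, "value")
  }
  peaklists <- vector("list", length(spectra))
  coords <- data.frame(x = integer(length(spectra)),
                       y = integer(length(spectra)))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    coords$x[i] <- as.integer(get_param(sp, "IMS:1000050"))
    coords$y[i] <- as.integer(get_param(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//d:binaryDataArray", ns)
    if (length(arrays) < 2)
      stop("spectrum ", i, ": missing binary data arrays", call. = FALSE)
    vals <- list()
    for (arr in arrays) {
      off <- as.numeric(get_param(arr, "IMS:1000102"))
      len <- as.integer(get_param(arr, "IMS:1000103"))
      ref <- xml2::xml_attr(xml2::xml_find_first(
        arr, ".//d:referenceableParamGroupRef", ns), "ref")
      is_mz <- identical(ref, "mzArray") ||
        !inherits(xml2::xml_find_first(
          arr, ".//d:cvParam[@accession='MS:1000514']", ns), "xml_missing")
      size <- if (is_mz) 8L else 4L
      if (is.na(off) || is.na(len) || off + size * len > ibd_size)
        stop("spectrum ", i,
             ": binary data out of range or missing in .ibd", call. = FALSE)
      seek(ibd, off)
      v <- readBin(ibd, "double", n = len, size = size, endian = "little")
      vals[[if (is_mz) "mz" else "intensity"]] <- v
    }
    if (is.null(vals$mz) || is.null(vals$intensity))
      stop("spectrum ", i, ": incomplete arrays", call. = FALSE)
    peaklists[[i]] <- data.frame(mz = vals$mz, intensity = vals$intensity)
  }
  shared_axis <- all(vapply(peaklists, function(p)
    isTRUE(all.equal(p$mz, peaklists[[1]]$mz)), TRUE))
  table <- if (shared_axis) {
    structure(list(mz = peaklists[[1]]$mz,
                   intensity = do.call(rbind, lapply(peaklists,
                                                     `[[`, "intensity")),
                   ppm = width_ppm),
              class = "peak_table")
  } else ppm_bin(peaklists, width_ppm)
  list(table = table, coordinates = coords)
}
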