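# Minimal GIFTI (.gii) support: surface geometry (POINTSET + TRIANGLE) and
# per-vertex scalar arrays. Writes GZipBase64Binary little-endian; reads
# ASCII, Base64Binary and GZipBase64Binary in either byte order.

gifti_dtype <- function(name) {
  switch(name,
    "NIFTI_TYPE_FLOAT32" = list(what = "numeric", size = 4),
    "NIFTI_TYPE_FLOAT64" = list(what = "numeric", size = 8),
    "NIFTI_TYPE_INT32"   = list(what = "integer", size = 4),
    "NIFTI_TYPE_UINT8"   = list(what = "integer", size = 1),
    stop_arg("unsupported GIFTI DataType: %s", name))
}

decode_gifti_array <- function(da) {
  enc <- xml2::xml_attr(da, "Encoding")
  dt <- gifti_dtype(xml2::xml_attr(da, "DataType"))
  ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(i)
    as.integer(xml2::xml_attr(da, paste0("Dim", i))), integer(1))
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  endian <- if (identical(xml2::xml_attr(da, "Endian"), "BigEndian"))
    "big" else "little"
  node <- xml2::xml_find_first(da, ".//Data")
  if (inherits(node, "xml_missing")) stop_arg("GIFTI DataArray lacks <Data>")
  txt <- xml2::xml_text(node)
  n <- prod(dims)
  vals <- switch(enc,
    "ASCII" = as.numeric(strsplit(trimws(txt), "\\s+")[[1]]),
    "Base64Binary" = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                             dt$what, n = n, size = dt$size, endian = endian),
    "GZipBase64Binary" = readBin(
      memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)), type = "gzip"),
      dt$what, n = n, size = dt$size, endian = endian),
    stop_arg("unsupported GIFTI Encoding: %s", enc))
  if (length(vals) != n)
    stop_arg("GIFTI Data length %d does not match Dim attributes (%d)",
             length(vals), n)
  if (length(dims) == 2L) {
    if (identical(order, "ColumnMajorOrder")) matrix(vals, dims[1], dims[2])
    else matrix(vals, dims[1], dims[2], byrow = TRUE)
  } else vals
}

gifti_arrays <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_arg("cannot parse GIFTI XML: %s", path))
  xml2::xml_find_all(doc, ".//DataArray")
}

read_gifti_surface <- function(path) {
  das <- gifti_arrays(path)
  intents <- vapply(das, function(d) xml2::xml_attr(d, "Intent"), character(1))
  pi <- which(intents == "NIFTI_INTENT_POINTSET")
  ti <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(pi) || !length(ti))
    stop_arg("GIFTI file lacks POINTSET/TRIANGLE arrays: %s", path)
  v <- decode_gifti_array(das[[pi[1]]])
  f <- decode_gifti_array(das[[ti[1]]])
  surface_mesh(v, f + 1L)
}

read_gifti_scalar <- function(path) {
  das <- gifti_arrays(path)
  if (!length(das)) stop_arg("GIFTI file has no DataArray: %s", path)
  as.numeric(decode_gifti_array(das[[1]]))
}

encode_gzb64 <- function(raw_bytes) {
  jsonlite::base64_enc(memCompress(raw_bytes, type = "gzip"))
}

gifti_da_xml <- function(values, dims, intent, dtype) {
  dt <- gifti_dtype(dtype)
  raw_bytes <- writeBin(if (dt$what == "integer") as.integer(values)
                        else as.numeric(values),
                        raw(), size = dt$size, endian = "little")
  dimattrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                    collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="GZipBase64Binary" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
    intent, dtype, length(dims), dimattrs, encode_gzb64(raw_bytes))
}

write_gifti <- function(path, arrays) {
  body <- paste(arrays, collapse = "\n")
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="%d">\n%s\n</GIFTI>\n'),
    length(arrays), body)
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

write_gifti_surface <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  write_gifti(path, c(
    gifti_da_xml(as.numeric(t(v)), dim(v), "NIFTI_INTENT_POINTSET",
                 "NIFTI_TYPE_FLOAT32"),
    gifti_da_xml(as.integer(t(f)), dim(f), "NIFTI_INTENT_TRIANGLE",
                 "NIFTI_TYPE_INT32")))
}

write_gifti_scalar <- function(values, path) {
  write_gifti(path, gifti_da_xml(as.numeric(values), length(values),
                                 "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32"))
}
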