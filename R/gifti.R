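# Minimal GIFTI (.gii) reader/writer covering the arrays this package
# exchanges: POINTSET/TRIANGLE pairs for surfaces and single-column metric
# arrays for per-vertex maps. Encodings handled: ASCII, Base64Binary and
# GZipBase64Binary; data types FLOAT32/FLOAT64/INT32/UINT8. Data written by
# the package uses Base64Binary FLOAT64 (metrics, coordinates) and INT32
# (triangles, 0-based per the GIFTI standard) so that round trips are
# bit-identical.

.gifti_dtypes <- list(
  NIFTI_TYPE_UINT8   = list(what = "integer", size = 1L, signed = FALSE),
  NIFTI_TYPE_INT32   = list(what = "integer", size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT32 = list(what = "double",  size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT64 = list(what = "double",  size = 8L, signed = TRUE)
)

.read_gifti_data_array <- function(node, path) {
  at <- xml2::xml_attrs(node)
  need <- function(name) {
    if (is.na(at[name])) {
      abort(sprintf("malformed GIFTI '%s': DataArray missing attribute '%s'.", path, name))
    }
    at[[name]]
  }
  intent <- need("Intent")
  dtype <- need("DataType")
  enc <- need("Encoding")
  dims <- integer(0)
  dimensionality <- as.integer(need("Dimensionality"))
  for (k in seq_len(dimensionality)) {
    dims <- c(dims, as.integer(need(paste0("Dim", k - 1L))))
  }
  order <- if (!is.na(at["ArrayIndexingOrder"])) at[["ArrayIndexingOrder"]] else "RowMajorOrder"
  spec <- .gifti_dtypes[[dtype]]
  if (is.null(spec)) {
    abort(sprintf("malformed GIFTI '%s': unsupported DataType '%s'.", path, dtype))
  }
  data_node <- xml2::xml_find_first(node, "./Data")
  if (inherits(data_node, "xml_missing")) {
    abort(sprintf("malformed GIFTI '%s': DataArray has no <Data> element.", path))
  }
  txt <- xml2::xml_text(data_node)
  n <- prod(dims)
  vals <- switch(enc,
    ASCII = {
      v <- scan(text = txt, what = double(), quiet = TRUE)
      if (spec$what == "integer") as.integer(v) else v
    },
    Base64Binary = ,
    GZipBase64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      endian <- if (!is.na(at["Endian"]) && at[["Endian"]] == "BigEndian") "big" else "little"
      readBin(raw, what = spec$what, n = n, size = spec$size,
              signed = spec$signed, endian = endian)
    },
    abort(sprintf("malformed GIFTI '%s': unsupported Encoding '%s'.", path, enc))
  )
  if (length(vals) != n) {
    abort(sprintf(
      "malformed GIFTI '%s': DataArray holds %d values, dimensions promise %d.",
      path, length(vals), n
    ))
  }
  data <- if (length(dims) == 2L) {
    if (order == "RowMajorOrder") {
      matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
    } else {
      matrix(vals, nrow = dims[1L], ncol = dims[2L])
    }
  } else {
    vals
  }
  list(intent = intent, data = data)
}

.read_gifti <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed GIFTI '%s': %s", path, conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "GIFTI") {
    abort(sprintf("malformed GIFTI '%s': root element is <%s>, expected <GIFTI>.",
                  path, xml2::xml_name(doc)))
  }
  arrays <- xml2::xml_find_all(doc, "./DataArray")
  if (length(arrays) == 0L) {
    abort(sprintf("malformed GIFTI '%s': no DataArray elements.", path))
  }
  lapply(arrays, .read_gifti_data_array, path = path)
}

.gifti_encode <- function(values, dtype) {
  spec <- .gifti_dtypes[[dtype]]
  raw <- writeBin(
    if (spec$what == "integer") as.integer(values) else as.double(values),
    raw(), size = spec$size, endian = "little"
  )
  jsonlite::base64_enc(raw)
}

.gifti_data_array_xml <- function(values, intent, dtype, dims) {
  dim_attrs <- paste(
    sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
    collapse = " "
  )
  paste0(
    sprintf(
      paste0('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
             'Dimensionality="%d" %s Encoding="Base64Binary" Endian="LittleEndian" ',
             'ExternalFileName="" ExternalFileOffset="">'),
      intent, dtype, length(dims), dim_attrs
    ),
    "<Data>", .gifti_encode(values, dtype), "</Data></DataArray>"
  )
}

.write_gifti <- function(path, arrays_xml) {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays_xml), '">',
    paste(arrays_xml, collapse = ""),
    "</GIFTI>\n"
  )
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

.write_gifti_surface <- function(mesh, path) {
  coords <- t(mesh$vertices) # row-major serialisation of an n x 3 array
  tris <- t(mesh$triangles - 1L) # GIFTI triangles are 0-based
  .write_gifti(path, c(
    .gifti_data_array_xml(coords, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64",
                          c(mesh$vertex_count, 3L)),
    .gifti_data_array_xml(tris, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                          c(nrow(mesh$triangles), 3L))
  ))
}

.read_gifti_surface <- function(path) {
  arrays <- .read_gifti(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it)) {
    abort(sprintf(
      "malformed GIFTI surface '%s': needs POINTSET and TRIANGLE DataArrays (found: %s).",
      path, paste(intents, collapse = ", ")
    ))
  }
  surface_mesh(arrays[[ip]]$data, arrays[[it]]$data + 1L)
}

.write_gifti_metric <- function(values, path) {
  .write_gifti(path, .gifti_data_array_xml(
    values, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64", length(values)
  ))
}

.read_gifti_metric <- function(path) {
  arrays <- .read_gifti(path)
  v <- arrays[[1L]]$data
  if (is.matrix(v)) v <- as.vector(t(v))
  as.double(v)
}
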