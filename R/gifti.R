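# Minimal GIFTI-1.0 I/O (ASCII encoding), enough for per-vertex functional
# maps (.func.gii) and integer label maps (.label.gii). Arrays are written as
# 1-D ASCII DataArrays, one per map.

write_gifti <- function(path, arrays, intent = "NIFTI_INTENT_NONE",
                        datatype = "NIFTI_TYPE_FLOAT32", labels = NULL) {
  stopifnot(is.list(arrays), length(arrays) >= 1L)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  if (!is.null(labels)) {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (i in seq_along(labels)) {
      lab <- xml2::xml_add_child(lt, "Label", Key = as.character(i))
      xml2::xml_set_text(lab, labels[[i]])
    }
  }
  for (a in arrays) {
    da <- xml2::xml_add_child(doc, "DataArray",
                              Intent = intent,
                              DataType = datatype,
                              ArrayIndexingOrder = "RowMajorOrder",
                              Dimensionality = "1",
                              Dim0 = as.character(length(a)),
                              Encoding = "ASCII",
                              Endian = "LittleEndian")
    txt <- if (datatype == "NIFTI_TYPE_INT32") {
      paste(as.integer(a), collapse = " ")
    } else {
      paste(format(as.numeric(a), digits = 9, trim = TRUE, scientific = TRUE),
            collapse = " ")
    }
    dat <- xml2::xml_add_child(da, "Data")
    xml2::xml_set_text(dat, txt)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0L) stop("no DataArray elements in ", path)
  arrays <- lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("unsupported GIFTI encoding: ", enc)
    txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1L]])
    n <- as.integer(xml2::xml_attr(da, "Dim0"))
    if (length(vals) != n)
      stop("GIFTI DataArray length ", length(vals), " != Dim0 ", n)
    vals
  })
  arrays
}
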