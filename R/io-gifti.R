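#' Read and write surface metric and label files (GIFTI)
#'
#' Minimal GIFTI (XML) support for the two file kinds the pipeline
#' exchanges: metric files (one float per vertex, e.g. thickness in mm)
#' and label files (one integer label per vertex plus a label table).
#' Data arrays are ASCII-encoded, so the files are plain text and
#' readable by standard neuroimaging libraries. Missing vertices are
#' stored as NaN in metric files.
#'
#' @param values Numeric vector of per-vertex values (`NA` allowed).
#' @param path File path (conventionally `*.func.gii` / `*.label.gii`).
#' @param name Optional map name stored in the array metadata.
#' @return Writers return `path` invisibly. `read_metric_gifti()` returns
#'   a numeric vector (NaN mapped back to `NA`); `read_label_gifti()`
#'   returns a list with `labels` (integer vector) and `label_table`
#'   (tibble `id`, `name`).
#' @export
write_metric_gifti <- function(values, path, name = "thickness_mm") {
  vals <- ifelse(is.na(values), "NaN", formatC(values, format = "g", digits = 9))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  da <- xml2::xml_add_child(
    doc, "DataArray",
    Intent = "NIFTI_INTENT_SHAPE", DataType = "NIFTI_TYPE_FLOAT32",
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(values)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "", ExternalFileOffset = ""
  )
  md <- xml2::xml_add_child(da, "MetaData")
  mdn <- xml2::xml_add_child(md, "MD")
  xml2::xml_add_child(mdn, "Name", "Name")
  xml2::xml_add_child(mdn, "Value", name)
  xml2::xml_add_child(da, "Data", paste(vals, collapse = " "))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_metric_gifti
#' @export
read_metric_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  stopifnot(xml2::xml_attr(da, "Encoding") == "ASCII")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  x <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  x[is.nan(x)] <- NA_real_
  n <- as.integer(xml2::xml_attr(da, "Dim0"))
  if (length(x) != n) stop("corrupt metric file: length mismatch", call. = FALSE)
  x
}

#' @rdname write_metric_gifti
#' @param labels Integer vector of per-vertex label ids (0 = unassigned).
#' @param label_table Tibble with `id` and `name` columns.
#' @export
write_label_gifti <- function(labels, label_table, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  n0 <- xml2::xml_add_child(lt, "Label", Key = "0",
                            Red = "0", Green = "0", Blue = "0", Alpha = "0")
  xml2::xml_text(n0) <- "???"
  for (i in seq_len(nrow(label_table))) {
    shade <- formatC(i / (nrow(label_table) + 1), format = "f", digits = 4)
    nd <- xml2::xml_add_child(lt, "Label", Key = as.character(label_table$id[i]),
                              Red = shade, Green = shade, Blue = shade,
                              Alpha = "1")
    xml2::xml_text(nd) <- label_table$name[i]
  }
  da <- xml2::xml_add_child(
    doc, "DataArray",
    Intent = "NIFTI_INTENT_LABEL", DataType = "NIFTI_TYPE_INT32",
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(labels)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "", ExternalFileOffset = ""
  )
  xml2::xml_add_child(da, "Data", paste(as.integer(labels), collapse = " "))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_metric_gifti
#' @export
read_label_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  labels <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])
  lab_nodes <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  tbl <- tibble::tibble(
    id = as.integer(xml2::xml_attr(lab_nodes, "Key")),
    name = xml2::xml_text(lab_nodes)
  )
  list(labels = labels, label_table = tbl[tbl$id != 0, , drop = FALSE])
}
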