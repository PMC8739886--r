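# Readers and writers for surface meshes, label maps and per-vertex metric
# data. Two interchange forms are supported: GIFTI (ASCII-encoded data
# arrays, the XML surface format used across surface-based neuroimaging)
# and plain-text tables that round-trip doubles exactly (printed with 17
# significant digits). File vertex indices are 0-based in both formats, as
# is conventional; in memory everything is 1-based.

is_gifti_path <- function(path) grepl("\\.gii$", path, ignore.case = TRUE)

#' Read / write a surface mesh
#'
#' GIFTI surfaces (`*.surf.gii`, ASCII encoding) or a plain two-table text
#' format: a header line `N M`, then N lines of x y z coordinates, then M
#' lines of 0-based face index triples.
#'
#' @param path file path; `.gii` selects GIFTI.
#' @param g a `surface_graph` (for the writer).
#' @return `read_surface` returns a `surface_graph`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is_gifti_path(path)) {
    arrays <- gifti_read_arrays(path)
    pts <- arrays[["NIFTI_INTENT_POINTSET"]]
    tri <- arrays[["NIFTI_INTENT_TRIANGLE"]]
    if (is.null(pts) || is.null(tri)) stop("GIFTI surface needs POINTSET and TRIANGLE arrays")
    return(surface_graph(pts$data, tri$data + 1L))
  }
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("empty surface file: %s", path))
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop(sprintf("malformed header (expected 'N M'): %s", lines[1]))
  n <- hdr[1]; m <- hdr[2]
  if (length(lines) < 1L + n + m) stop(sprintf("expected %d data lines, found %d", n + m, length(lines) - 1L))
  verts <- matrix(scan(text = lines[1L + seq_len(n)], what = double(), quiet = TRUE),
                  n, 3L, byrow = TRUE)
  faces <- matrix(scan(text = lines[1L + n + seq_len(m)], what = integer(), quiet = TRUE),
                  m, 3L, byrow = TRUE)
  if (any(faces < 0L) || any(faces >= n)) {
    stop(sprintf("face index %d outside [0, %d)", faces[faces < 0L | faces >= n][1L], n))
  }
  surface_graph(verts, faces + 1L)
}

#' @rdname read_surface
#' @export
write_surface <- function(g, path) {
  stopifnot(inherits(g, "surface_graph"))
  if (is_gifti_path(path)) {
    gifti_write(path, list(
      list(intent = "NIFTI_INTENT_POINTSET", data = g$vertices, type = "float"),
      list(intent = "NIFTI_INTENT_TRIANGLE", data = g$faces - 1L, type = "int")
    ))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", g$n_vertices, nrow(g$faces)), con)
  writeLines(apply(g$vertices, 1L, function(r) paste(fmt_full(r), collapse = " ")), con)
  writeLines(apply(g$faces - 1L, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read / write a label map
#'
#' GIFTI label files (`*.label.gii`, ASCII) or a text vector of one
#' non-negative integer code per line. The unlabeled code is preserved; C is
#' taken from metadata when present, otherwise inferred as the largest
#' positive code.
#'
#' @param path file path; `.gii` selects GIFTI.
#' @param lm a `label_map` (for the writer).
#' @param unlabeled_code unlabeled code assumed when reading (default 0).
#' @return `read_labels` returns a `label_map`.
#' @export
read_labels <- function(path, unlabeled_code = 0L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is_gifti_path(path)) {
    arrays <- gifti_read_arrays(path)
    arr <- arrays[["NIFTI_INTENT_LABEL"]] %||% arrays[[1L]]
    labels <- as.integer(arr$data)
    nc <- arr$meta[["num_classes"]]
    return(label_map(labels, num_classes = if (is.null(nc)) NULL else as.integer(nc),
                     unlabeled_code = unlabeled_code))
  }
  txt <- readLines(path)
  vals <- suppressWarnings(as.integer(txt))
  if (any(is.na(vals))) {
    stop(sprintf("non-integer label at line %d: '%s'", which(is.na(vals))[1L], txt[which(is.na(vals))[1L]]))
  }
  label_map(vals, unlabeled_code = unlabeled_code)
}

#' @rdname read_labels
#' @export
write_labels <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  if (is_gifti_path(path)) {
    gifti_write(path, list(list(intent = "NIFTI_INTENT_LABEL",
                                data = matrix(lm$labels, ncol = 1L), type = "int",
                                meta = list(num_classes = lm$num_classes))))
    return(invisible(path))
  }
  writeLines(as.character(lm$labels), path)
  invisible(path)
}

#' Read / write per-vertex metric data
#'
#' Column-named per-vertex vectors or matrices (time series, scalar maps,
#' features, probabilities). GIFTI metric files (`*.func.gii`, ASCII, one
#' data array per column) or tab-separated text with a header row. Doubles
#' round-trip exactly in the text form.
#'
#' @param path file path; `.gii` selects GIFTI.
#' @param x numeric matrix or vector (for the writer).
#' @param n_vertices optional expected N; a mismatch is an error.
#' @return `read_metric` returns a named matrix (a plain vector for a
#'   single-column metric).
#' @export
read_metric <- function(path, n_vertices = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is_gifti_path(path)) {
    arrays <- gifti_read_arrays(path)
    cols <- lapply(arrays, function(a) as.numeric(a$data))
    nm <- vapply(seq_along(arrays), function(i) {
      arrays[[i]]$meta[["Name"]] %||% paste0("V", i)
    }, character(1))
    mat <- do.call(cbind, cols)
    colnames(mat) <- nm
  } else {
    lines <- readLines(path)
    if (!length(lines)) stop(sprintf("empty metric file: %s", path))
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    widths <- lengths(body)
    if (length(unique(widths)) > 1L || (length(widths) && widths[1] != length(header))) {
      stop("ragged rows: metric rows disagree with the header width")
    }
    mat <- matrix(as.numeric(unlist(body)), ncol = length(header), byrow = TRUE)
    colnames(mat) <- header
  }
  if (!is.null(n_vertices) && nrow(mat) != n_vertices) {
    stop(sprintf("metric has %d rows but the mesh has %d vertices", nrow(mat), n_vertices))
  }
  if (ncol(mat) == 1L) {
    v <- mat[, 1L]
    names(v) <- NULL
    return(v)
  }
  mat
}

#' @rdname read_metric
#' @export
write_metric <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is_gifti_path(path)) {
    arrays <- lapply(seq_len(ncol(x)), function(i) {
      list(intent = "NIFTI_INTENT_NONE", data = x[, i, drop = FALSE],
           type = "float", meta = list(Name = colnames(x)[i]))
    })
    gifti_write(path, arrays)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  writeLines(apply(x, 1L, function(r) paste(fmt_full(r), collapse = "\t")), con)
  invisible(path)
}

# ---- minimal GIFTI (ASCII encoding) ----------------------------------------

gifti_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(nodes)) stop(sprintf("no DataArray elements in GIFTI file: %s", path))
  out <- list()
  for (nd in nodes) {
    enc <- xml2::xml_attr(nd, "Encoding")
    if (!identical(enc, "ASCII")) {
      stop(sprintf("unsupported GIFTI encoding '%s' (only ASCII is handled)", enc))
    }
    intent <- xml2::xml_attr(nd, "Intent")
    d0 <- as.integer(xml2::xml_attr(nd, "Dim0"))
    d1 <- xml2::xml_attr(nd, "Dim1")
    d1 <- if (is.na(d1)) 1L else as.integer(d1)
    txt <- xml2::xml_text(xml2::xml_find_first(nd, ".//Data"))
    vals <- scan(text = txt, what = double(), quiet = TRUE)
    if (length(vals) != d0 * d1) {
      stop(sprintf("GIFTI data length %d does not match Dim0*Dim1 = %d", length(vals), d0 * d1))
    }
    data <- matrix(vals, d0, d1, byrow = TRUE)
    meta <- list()
    for (md in xml2::xml_find_all(nd, ".//MetaData/MD")) {
      meta[[xml2::xml_text(xml2::xml_find_first(md, "./Name"))]] <-
        xml2::xml_text(xml2::xml_find_first(md, "./Value"))
    }
    entry <- list(intent = intent, data = data, meta = meta)
    if (!is.null(intent) && !is.na(intent) && is.null(out[[intent]])) {
      out[[intent]] <- entry
    } else {
      out[[length(out) + 1L]] <- entry
    }
  }
  out
}

gifti_write <- function(path, arrays) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  for (arr in arrays) {
    data <- as.matrix(arr$data)
    dtype <- if (identical(arr$type, "int")) "NIFTI_TYPE_INT32" else "NIFTI_TYPE_FLOAT64"
    nd <- xml2::xml_add_child(doc, "DataArray",
                              Intent = arr$intent,
                              DataType = dtype,
                              ArrayIndexingOrder = "RowMajorOrder",
                              Dimensionality = "2",
                              Dim0 = as.character(nrow(data)),
                              Dim1 = as.character(ncol(data)),
                              Encoding = "ASCII",
                              Endian = "LittleEndian")
    if (!is.null(arr$meta) && length(arr$meta)) {
      mdnode <- xml2::xml_add_child(nd, "MetaData")
      for (nm in names(arr$meta)) {
        md <- xml2::xml_add_child(mdnode, "MD")
        xml2::xml_add_child(md, "Name", nm)
        xml2::xml_add_child(md, "Value", as.character(arr$meta[[nm]]))
      }
    }
    txt <- if (identical(arr$type, "int")) {
      paste(apply(data, 1L, paste, collapse = " "), collapse = "\n")
    } else {
      paste(apply(data, 1L, function(r) paste(fmt_full(r), collapse = " ")), collapse = "\n")
    }
    xml2::xml_add_child(nd, "Data", txt)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
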