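# Minimal GIFTI (.gii) support: ASCII-encoded read/write, plus reading of
# Base64Binary / GZipBase64Binary arrays. Covers the metric (.func.gii /
# .shape.gii), label (.label.gii) and surface (.surf.gii) flavours used by
# the pipeline; no installed R package provides this format.

.giftiTypeInfo <- function(dataType) {
  switch(dataType,
    NIFTI_TYPE_FLOAT32 = list(what = "numeric", size = 4L),
    NIFTI_TYPE_FLOAT64 = list(what = "numeric", size = 8L),
    NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
    NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
    stop("unsupported GIFTI DataType: ", dataType))
}

.readGiftiArrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop("no DataArray elements in ", path)
  lapply(das, function(da) {
    at <- as.list(xml2::xml_attrs(da))
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    enc <- at$Encoding
    vals <- if (identical(enc, "ASCII")) {
      scan(text = txt, quiet = TRUE)
    } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (identical(enc, "GZipBase64Binary"))
        raw <- memDecompress(raw, type = "gzip")
      ti <- .giftiTypeInfo(at$DataType)
      readBin(raw, ti$what, n = length(raw) %/% ti$size, size = ti$size,
              endian = if (identical(at$Endian, "BigEndian")) "big"
                       else "little")
    } else stop("unsupported GIFTI encoding: ", enc)
    dims <- as.integer(at[grepl("^Dim[0-9]$", names(at))])
    if (length(dims) > 1L && prod(dims) == length(vals)) {
      byrow <- !identical(at$ArrayIndexingOrder, "ColumnMajorOrder")
      vals <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = byrow)
    }
    list(intent = at$Intent, dataType = at$DataType, values = vals,
         node = da)
  })
}

.writeGifti <- function(arrays, path) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<GIFTI Version=\"1.0\" NumberOfDataArrays=\"%d\">",
                     length(arrays)))
  for (a in arrays) {
    v <- a$values
    dims <- if (is.matrix(v)) dim(v) else length(v)
    dimAttrs <- paste(sprintf("Dim%d=\"%d\"", seq_along(dims) - 1L, dims),
                      collapse = " ")
    flat <- if (is.matrix(v)) as.vector(t(v)) else v  # RowMajor
    txt <- paste(formatC(flat, format = "g", digits = 17), collapse = " ")
    lines <- c(lines, sprintf(
      paste0("<DataArray Intent=\"%s\" DataType=\"%s\" ",
             "ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"%d\" ",
             "%s Encoding=\"ASCII\" Endian=\"LittleEndian\" ",
             "ExternalFileName=\"\" ExternalFileOffset=\"\">"),
      a$intent, a$dataType, length(dims), dimAttrs),
      if (!is.null(a$labelTable)) a$labelTable,
      "<Data>", txt, "</Data>", "</DataArray>")
  }
  writeLines(c(lines, "</GIFTI>"), path)
  invisible(path)
}

.extOf <- function(path) {
  if (grepl("\\.(func|shape)\\.gii$", path)) "metric.gii"
  else if (grepl("\\.label\\.gii$", path)) "label.gii"
  else if (grepl("\\.surf\\.gii$", path)) "surf.gii"
  else if (grepl("\\.(csv|tsv|txt)$", path)) "text"
  else "unknown"
}

#' Read / write a surface map
#'
#' Supported formats: GIFTI metric files (`.func.gii` / `.shape.gii`,
#' ASCII or Base64 encodings) and one-column delimited text with a header
#' line. Values are aligned to mesh vertex order and checked against the
#' mesh length.
#'
#' @param path input file.
#' @param mesh the [SphericalMesh-class] the map lives on.
#' @param name map label (default: file base name).
#' @return a [SurfaceMap-class].
#' @export
readSurfaceMap <- function(path, mesh, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .extOf(path)
  vals <- switch(ext,
    metric.gii = {
      arr <- .readGiftiArrays(path)
      as.numeric(arr[[1]]$values)
    },
    text = read.table(path, header = TRUE)[[1]],
    stop("unknown extension for a surface map: ", path,
         " (supported: .func.gii, .shape.gii, .csv, .tsv, .txt)"))
  if (length(vals) != nVertices(mesh))
    stop(sprintf("map has %d values but mesh has %d vertices",
                 length(vals), nVertices(mesh)))
  vals[!mesh@valid] <- 0
  if (is.null(name)) name <- sub("\\..*$", "", basename(path))
  new("SurfaceMap", values = as.numeric(vals), mesh = mesh, name = name)
}

#' @rdname readSurfaceMap
#' @param map a [SurfaceMap-class] to write.
#' @export
writeSurfaceMap <- function(map, path) {
  ext <- .extOf(path)
  if (ext == "metric.gii") {
    .writeGifti(list(list(intent = "NIFTI_INTENT_NONE",
                          dataType = "NIFTI_TYPE_FLOAT32",
                          values = map@values)), path)
  } else if (ext == "text") {
    write.table(data.frame(value = formatC(map@values, format = "g",
                                           digits = 17)),
                path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else stop("unknown extension for a surface map: ", path)
  invisible(path)
}

#' Read / write vertex labels
#'
#' GIFTI label files (`.label.gii`; the label table is preserved as
#' attribute `"labelTable"`) or one-column integer text with header.
#' Label 0 is reserved for unassigned / medial-wall vertices.
#'
#' @param path input file.
#' @param mesh the mesh the labels live on.
#' @return integer labels per vertex.
#' @export
readLabels <- function(path, mesh) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .extOf(path)
  if (ext == "label.gii") {
    arr <- .readGiftiArrays(path)
    vals <- as.integer(arr[[1]]$values)
    lt <- xml2::xml_find_first(xml2::read_xml(path), ".//LabelTable")
    out <- vals
    if (!inherits(lt, "xml_missing")) {
      labs <- xml2::xml_find_all(lt, ".//Label")
      attr(out, "labelTable") <- data.frame(
        key = as.integer(xml2::xml_attr(labs, "Key")),
        name = xml2::xml_text(labs))
    }
  } else if (ext == "text") {
    out <- as.integer(read.table(path, header = TRUE)[[1]])
  } else stop("unknown extension for labels: ", path,
              " (supported: .label.gii, .csv, .tsv, .txt)")
  if (length(out) != nVertices(mesh))
    stop(sprintf("labels have %d values but mesh has %d vertices",
                 length(out), nVertices(mesh)))
  out
}

#' @rdname readLabels
#' @param labels integer labels per vertex to write.
#' @param labelTable optional data.frame (key, name) written as the GIFTI
#'   label table.
#' @export
writeLabels <- function(labels, path, labelTable = NULL) {
  ext <- .extOf(path)
  if (ext == "label.gii") {
    lt <- NULL
    if (!is.null(labelTable))
      lt <- c("<LabelTable>",
              sprintf("<Label Key=\"%d\"><![CDATA[%s]]></Label>",
                      labelTable$key, labelTable$name),
              "</LabelTable>")
    .writeGifti(list(list(intent = "NIFTI_INTENT_LABEL",
                          dataType = "NIFTI_TYPE_INT32",
                          values = as.integer(labels),
                          labelTable = paste(lt, collapse = "\n"))), path)
  } else if (ext == "text") {
    write.table(data.frame(label = as.integer(labels)), path, sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else stop("unknown extension for labels: ", path)
  invisible(path)
}

#' Read / write a spherical mesh
#'
#' GIFTI surface files (`.surf.gii`: POINTSET + TRIANGLE arrays, triangle
#' indices 0-based in the file) or a documented text triple
#' `<base>_coords.tsv`, `<base>_triangles.tsv`, `<base>_valid.tsv`.
#'
#' @param path `.surf.gii` file or text-triple base path.
#' @param validLabels optional path of a label file; nonzero labels mark
#'   invalid (medial wall) vertices for `.surf.gii` input.
#' @return a [SphericalMesh-class].
#' @export
readMesh <- function(path, validLabels = NULL) {
  if (grepl("\\.surf\\.gii$", path)) {
    arrs <- .readGiftiArrays(path)
    ints <- vapply(arrs, function(a) a$intent, character(1))
    coords <- arrs[[match("NIFTI_INTENT_POINTSET", ints)]]$values
    tris <- arrs[[match("NIFTI_INTENT_TRIANGLE", ints)]]$values + 1L
    coords <- coords / sqrt(rowSums(coords^2))
    valid <- rep(TRUE, nrow(coords))
    if (!is.null(validLabels)) {
      m0 <- new("SphericalMesh", coords = coords,
                triangles = matrix(as.integer(tris), ncol = 3),
                valid = valid)
      valid <- readLabels(validLabels, m0) == 0L
    }
    new("SphericalMesh", coords = coords,
        triangles = matrix(as.integer(tris), ncol = 3), valid = valid)
  } else {
    fn <- paste0(path, c("_coords.tsv", "_triangles.tsv", "_valid.tsv"))
    if (!all(file.exists(fn)))
      stop("text mesh triple not found at base path: ", path)
    coords <- as.matrix(read.table(fn[1], header = TRUE))
    tris <- as.matrix(read.table(fn[2], header = TRUE))
    valid <- as.logical(read.table(fn[3], header = TRUE)[[1]])
    dimnames(coords) <- NULL
    dimnames(tris) <- NULL
    storage.mode(tris) <- "integer"
    new("SphericalMesh", coords = coords, triangles = tris, valid = valid)
  }
}

#' @rdname readMesh
#' @param mesh a [SphericalMesh-class] to write.
#' @param format "gifti" (requires a `.surf.gii` path) or "text" (path is
#'   the triple base).
#' @export
writeMesh <- function(mesh, path, format = c("text", "gifti")) {
  format <- match.arg(format)
  if (format == "gifti") {
    .writeGifti(list(
      list(intent = "NIFTI_INTENT_POINTSET",
           dataType = "NIFTI_TYPE_FLOAT64", values = mesh@coords),
      list(intent = "NIFTI_INTENT_TRIANGLE",
           dataType = "NIFTI_TYPE_INT32", values = mesh@triangles - 1L)),
      path)
  } else {
    write.table(as.data.frame(mesh@coords), paste0(path, "_coords.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(mesh@triangles),
                paste0(path, "_triangles.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(data.frame(valid = as.integer(mesh@valid)),
                paste0(path, "_valid.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' Read / write an image series as a delimited-text directory
#'
#' Layout: `<dir>/meta.json` (dimensions, pixel size), `<dir>/valid.tsv`
#' (0/1 matrix), and `<dir>/frames/frame_NNNN.tsv`, one matrix per frame.
#'
#' @param path series directory.
#' @return an [ImageSeries-class].
#' @export
readSeries <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a series directory (no meta.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  valid <- as.matrix(read.table(file.path(path, "valid.tsv")))
  dimnames(valid) <- NULL
  fr <- sort(list.files(file.path(path, "frames"), pattern = "^frame_",
                        full.names = TRUE))
  if (length(fr) != meta$T)
    stop(sprintf("meta.json declares %d frames but %d found", meta$T,
                 length(fr)))
  frames <- array(NA_real_, c(meta$T, meta$rows, meta$cols))
  for (t in seq_along(fr)) {
    m <- as.matrix(read.table(fr[t]))
    if (!identical(dim(m), as.integer(c(meta$rows, meta$cols))))
      stop("frame dimension mismatch in ", fr[t])
    frames[t, , ] <- m
  }
  new("ImageSeries", frames = frames, pixelValid = valid == 1,
      pixelSize = as.numeric(unlist(meta$pixelSize)))
}

#' @rdname readSeries
#' @param series an [ImageSeries-class] to write.
#' @export
writeSeries <- function(series, path) {
  dir.create(file.path(path, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  d <- dim(series@frames)
  jsonlite::write_json(list(T = d[1], rows = d[2], cols = d[3],
                            pixelSize = series@pixelSize),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(matrix(as.integer(series@pixelValid), d[2], d[3]),
              file.path(path, "valid.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  for (t in seq_len(d[1]))
    write.table(format(series@frames[t, , ], digits = 17),
                file.path(path, "frames", sprintf("frame_%04d.tsv", t)),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  invisible(path)
}

#' Save / load a surrogate ensemble as text + JSON
#'
#' @param ensemble a [SurrogateEnsemble-class].
#' @param path output directory.
#' @export
saveEnsemble <- function(ensemble, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.table(format(ensemble@maps, digits = 17),
              file.path(path, "maps.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(seed = ensemble@seed,
                              resample = ensemble@resample),
                         ensemble@meta),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
readEnsemble <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  maps <- as.matrix(read.table(file.path(path, "maps.tsv")))
  dimnames(maps) <- NULL
  new("SurrogateEnsemble", maps = maps, seed = meta$seed,
      resample = meta$resample,
      meta = meta[setdiff(names(meta), c("seed", "resample"))])
}
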