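#' Read a plain-text mesh
#'
#' Reads the package's plain-text mesh dialect: a header line `"N M"`, then N
#' vertex lines `"x y z curv label"`, then M face lines `"i j k"` with 0-based
#' vertex indices (converted to 1-based in memory).
#'
#' @param path file path.
#' @return a [tri_surface].
#' @export
read_mesh_txt <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed header: expected 'N M'")
  n <- hdr[1]; m <- hdr[2]
  if (length(lines) < 1L + n + m) stop("truncated mesh file: ", path)
  vparts <- strsplit(trimws(lines[2:(1 + n)]), "[[:space:]]+")
  vnum <- vapply(vparts, function(p) as.numeric(p[1:4]), numeric(4))
  labels <- vapply(vparts, function(p) paste(p[-(1:4)], collapse = " "),
                   character(1))
  fmat <- matrix(scan(text = paste(lines[(2 + n):(1 + n + m)], collapse = "\n"),
                      what = integer(), quiet = TRUE),
                 ncol = 3, byrow = TRUE)
  tri_surface(t(vnum[1:3, , drop = FALSE]), fmat + 1L,
              curvature = vnum[4, ], atlas_labels = labels)
}

#' Write a plain-text mesh
#'
#' Writer for the dialect read by [read_mesh_txt()]; face indices are written
#' 0-based. Missing curvature is written as 0, missing labels as `"other"`.
#'
#' @param surface a [tri_surface].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_txt <- function(surface, path) {
  n <- nrow(surface$vertices); m <- nrow(surface$faces)
  curv <- if (is.null(surface$curvature)) rep(0, n) else surface$curvature
  lab <- if (is.null(surface$atlas_labels)) rep("other", n) else
    surface$atlas_labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(n, m), con)
  writeLines(sprintf("%.9g %.9g %.9g %.9g %s", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3], curv, lab),
             con)
  writeLines(sprintf("%d %d %d", surface$faces[, 1] - 1L,
                     surface$faces[, 2] - 1L, surface$faces[, 3] - 1L), con)
  invisible(path)
}

# ---- FreeSurfer binary formats ---------------------------------------------

read_int24 <- function(con) {
  b <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

#' Read a FreeSurfer binary surface
#'
#' Reads the big-endian triangle surface format written by FreeSurfer
#' (`lh.pial` and friends): int24 magic 16777214, a comment line terminated by
#' "\\n\\n", vertex/face counts, float32 coordinates and int32 0-based faces.
#'
#' @param path file path.
#' @return a [tri_surface] (no curvature/labels/sphere attached).
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int24(con)
  if (magic != 16777214L)
    stop("not a FreeSurfer triangle surface (magic ", magic, ")")
  # comment: bytes until "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("unexpected end of file in header")
    if (prev == as.raw(10) && b == as.raw(10)) break
    # a single "\n" followed by a non-"\n" byte also ends the comment in
    # files written by some tools; treat strictly as "\n\n" (our writer)
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  tri_surface(matrix(v, ncol = 3, byrow = TRUE),
              matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary surface
#'
#' @param surface a [tri_surface].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fs_surface <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(charToRaw("created by tmsmap\n\n"), con)
  writeBin(as.integer(nrow(surface$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(surface$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(surface$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(surface$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer curvature file (new binary format)
#'
#' @param path file path.
#' @return numeric vector of per-vertex values.
#' @export
read_fs_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int24(con)
  if (magic != 16777215L)
    stop("not a new-format FreeSurfer curv file (magic ", magic, ")")
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  readBin(con, "integer", n = 2, size = 4, endian = "big") # nfaces, vals/vertex
  readBin(con, "numeric", n = nv, size = 4, endian = "big")
}

#' Write a FreeSurfer curvature file
#'
#' @param values numeric per-vertex values.
#' @param path output file path.
#' @param n_faces face count recorded in the header (informational).
#' @return `path`, invisibly.
#' @export
write_fs_curv <- function(values, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 255)), con)
  writeBin(as.integer(c(length(values), n_faces, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

# ---- GIFTI -----------------------------------------------------------------

gifti_decode_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  n <- prod(dims)
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, "gzip")
    size <- if (grepl("32", dtype)) 4L else 8L
    what <- if (grepl("FLOAT", dtype)) "numeric" else "integer"
    vals <- readBin(raw, what, n = n, size = size,
                    endian = if (identical(endian, "BigEndian")) "big" else
                      "little")
  }
  if (length(dims) == 2L) matrix(vals, ncol = dims[2], byrow = TRUE) else vals
}

#' Read a GIFTI surface
#'
#' Reads a GIFTI (`.surf.gii`) file containing a `NIFTI_INTENT_POINTSET` and a
#' `NIFTI_INTENT_TRIANGLE` data array (ASCII, Base64Binary or
#' GZipBase64Binary encodings; triangles 0-based on disk).
#'
#' @param path file path.
#' @return a [tri_surface].
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) == 0 || length(it) == 0)
    stop("GIFTI file lacks a POINTSET or TRIANGLE data array")
  v <- gifti_decode_array(arrays[[ip[1]]])
  f <- gifti_decode_array(arrays[[it[1]]])
  storage.mode(f) <- "integer"
  tri_surface(v, f + 1L)
}

#' Write a GIFTI surface (ASCII encoding)
#'
#' @param surface a [tri_surface].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(surface, path) {
  fmt_rows <- function(m) paste(apply(m, 1, paste, collapse = " "),
                                collapse = "\n")
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"2\">\n",
    "<DataArray Intent=\"NIFTI_INTENT_POINTSET\" DataType=\"NIFTI_TYPE_FLOAT32\"",
    " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\" Dim0=\"",
    nrow(surface$vertices), "\" Dim1=\"3\" Encoding=\"ASCII\"",
    " Endian=\"LittleEndian\">\n<Data>",
    fmt_rows(surface$vertices),
    "</Data>\n</DataArray>\n",
    "<DataArray Intent=\"NIFTI_INTENT_TRIANGLE\" DataType=\"NIFTI_TYPE_INT32\"",
    " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\" Dim0=\"",
    nrow(surface$faces), "\" Dim1=\"3\" Encoding=\"ASCII\"",
    " Endian=\"LittleEndian\">\n<Data>",
    fmt_rows(surface$faces - 1L),
    "</Data>\n</DataArray>\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Attach atlas labels from a CSV sidecar
#'
#' Reads a two-column CSV (`vertex_id` 0-based, `label`) and attaches the
#' labels to a surface; vertices absent from the sidecar get `default`.
#'
#' @param surface a [tri_surface].
#' @param path CSV path.
#' @param default label for vertices not listed.
#' @return the surface with `atlas_labels` set.
#' @export
attach_labels_csv <- function(surface, path, default = "other") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lab <- rep(default, nrow(surface$vertices))
  idx <- df$vertex_id + 1L
  if (any(idx < 1L | idx > length(lab))) stop("vertex_id out of range")
  lab[idx] <- df$label
  surface$atlas_labels <- lab
  surface
}
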