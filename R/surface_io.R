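## FreeSurfer binary formats.  Everything on disk is big-endian; surfaces and
## curv files carry a 3-byte magic number, annot files carry an embedded
## colortable.  Only the modern ("new") dialects are supported: the obsolete
## quad surface and old two-int curv layouts are rejected with a format error.

TRIANGLE_MAGIC <- 16777214L  # 0xFFFFFE
NEW_CURV_MAGIC <- 16777215L  # 0xFFFFFF

readInt24 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) return(NA_integer_)
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

writeInt24 <- function(con, value) {
  b <- as.raw(c(value %/% 65536L, (value %/% 256L) %% 256L, value %% 256L))
  writeBin(b, con)
}

readBigInt <- function(con, n = 1L) readBin(con, "integer", n = n, size = 4L, endian = "big")
readBigFloat <- function(con, n = 1L) readBin(con, "double", n = n, size = 4L, endian = "big")
writeBigInt <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "big")
writeBigFloat <- function(con, x) writeBin(as.numeric(x), con, size = 4L, endian = "big")

## Comment line in surface files: text terminated by "\n\n" (a single "\n"
## also occurs in the wild; the second byte is only consumed if it is "\n").
readCommentLine <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("corrupt surface file: unterminated comment")
    if (b == as.raw(10L)) break
    chars <- c(chars, b)
  }
  pos <- seek(con, where = NA)
  b <- readBin(con, "raw", n = 1L)
  if (length(b) == 1L && b != as.raw(10L)) seek(con, where = pos)
  rawToChar(chars)
}

#' Read a FreeSurfer binary triangle surface
#'
#' @param path path to a surface file (e.g. \code{lh.white}).
#' @return A \linkS4class{SurfaceMesh}; vertex order is preserved and face
#'   indices are converted from the file's 0-based convention to 1-based.
#' @export
readSurface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readInt24(con)
  if (is.na(magic) || magic != TRIANGLE_MAGIC)
    stop("unrecognized surface format (expected binary triangle magic)")
  readCommentLine(con)
  nv <- readBigInt(con)
  nf <- readBigInt(con)
  if (length(nv) < 1L || length(nf) < 1L || is.na(nv) || is.na(nf) ||
      nv < 3L || nf < 1L)
    stop("corrupt surface file: implausible vertex/face counts")
  coords <- readBigFloat(con, 3L * nv)
  faces <- readBigInt(con, 3L * nf)
  if (length(coords) < 3L * nv || length(faces) < 3L * nf)
    stop("corrupt surface file: truncated payload")
  vertices <- matrix(coords, ncol = 3L, byrow = TRUE)
  f <- matrix(faces, ncol = 3L, byrow = TRUE) + 1L
  SurfaceMesh(vertices, f)
}

#' Write a FreeSurfer binary triangle surface
#'
#' Writes are deterministic: the same mesh always produces identical bytes,
#' and geometry round-trips bit-compatibly through \code{\link{readSurface}}.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(mesh, path) {
  validObject(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeInt24(con, TRIANGLE_MAGIC)
  writeBin(charToRaw("created by cortexgcn\n\n"), con)
  writeBigInt(con, nVertices(mesh))
  writeBigInt(con, nFaces(mesh))
  writeBigFloat(con, as.numeric(t(mesh@vertices)))
  writeBigInt(con, as.integer(t(mesh@faces)) - 1L)
  invisible(path)
}

#' Read / write FreeSurfer curv (per-vertex scalar) files
#'
#' Only the new (magic-tagged, float32) curv dialect is supported; values
#' round-trip to float32 precision.
#'
#' @param path curv file path.
#' @param expectedN optional vertex count to validate against.
#' @return numeric vector of per-vertex values.
#' @export
readCurv <- function(path, expectedN = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readInt24(con)
  if (is.na(magic) || magic != NEW_CURV_MAGIC)
    stop("unrecognized curv format (expected new-format magic)")
  nv <- readBigInt(con)
  readBigInt(con)                       # face count, unused
  vpv <- readBigInt(con)
  if (is.na(nv) || nv < 1L || is.na(vpv) || vpv != 1L)
    stop("corrupt curv file: bad header")
  vals <- readBigFloat(con, nv)
  if (length(vals) < nv) stop("corrupt curv file: truncated payload")
  if (!is.null(expectedN) && nv != expectedN)
    stop(sprintf("curv length mismatch: file has %d values, expected %d", nv, expectedN))
  vals
}

#' @rdname readCurv
#' @param values numeric vector of per-vertex values (finite).
#' @param nFaces face count recorded in the header (informational).
#' @export
writeCurv <- function(values, path, nFaces = 0L) {
  if (!all(is.finite(values))) stop("curv values must be finite")
  con <- file(path, "wb")
  on.exit(close(con))
  writeInt24(con, NEW_CURV_MAGIC)
  writeBigInt(con, length(values))
  writeBigInt(con, nFaces)
  writeBigInt(con, 1L)
  writeBigFloat(con, values)
  invisible(path)
}

packRGB <- function(r, g, b) r + 256 * g + 65536 * b

readLengthString <- function(con) {
  len <- readBigInt(con)
  if (is.na(len) || len < 0L || len > 1e6) stop("corrupt annot file: bad string length")
  chars <- readBin(con, "raw", n = len)
  rawToChar(chars[chars != as.raw(0)])
}

#' Read a FreeSurfer annot (label) file
#'
#' Per-vertex packed RGB annotation values are matched against the embedded
#' colortable and remapped to contiguous class indices \code{0..K-1} in table
#' order; vertices whose annotation value matches no table entry get the
#' ignore sentinel \code{-1}.  Both the old (positive version) and new
#' (version 2) colortable layouts are read.
#'
#' @param path annot file path.
#' @return A \linkS4class{Parcellation}.
#' @export
readAnnot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.info(path)$size
  n <- readBigInt(con)
  if (length(n) < 1L || is.na(n) || n < 1L || fsize < 4 + 8 * as.numeric(n))
    stop("corrupt annot file: implausible vertex count")
  dat <- readBigInt(con, 2L * n)
  if (length(dat) < 2L * n) stop("corrupt annot file: truncated vertex data")
  ann <- dat[seq.int(2L, 2L * n, by = 2L)]
  tabFlag <- readBigInt(con)
  if (length(tabFlag) < 1L || is.na(tabFlag) || tabFlag == 0L)
    stop("annot without colortable unsupported")
  ver <- readBigInt(con)
  if (ver > 0L) {                       # old colortable layout
    k <- ver
    readLengthString(con)               # original table filename
    name <- character(k); rgb <- matrix(0L, k, 3L); sid <- seq_len(k) - 1L
    for (i in seq_len(k)) {
      name[i] <- readLengthString(con)
      rgb[i, ] <- readBigInt(con, 3L)
      readBigInt(con)                   # transparency flag
    }
  } else {
    if (-ver != 2L) stop(sprintf("unsupported annot colortable version %d", -ver))
    readBigInt(con)                     # max structure id, unused
    readLengthString(con)
    k <- readBigInt(con)
    name <- character(k); rgb <- matrix(0L, k, 3L); sid <- integer(k)
    for (i in seq_len(k)) {
      sid[i] <- readBigInt(con)
      name[i] <- readLengthString(con)
      rgb[i, ] <- readBigInt(con, 3L)
      readBigInt(con)
    }
  }
  packed <- packRGB(rgb[, 1L], rgb[, 2L], rgb[, 3L])
  labels <- match(ann, packed) - 1L
  labels[is.na(labels)] <- -1L
  tab <- data.frame(class = seq_len(k) - 1L, name = name,
                    red = rgb[, 1L], green = rgb[, 2L], blue = rgb[, 3L],
                    structureId = sid, stringsAsFactors = FALSE)
  new("Parcellation", labels = labels, ignoreIndex = -1L, labelTable = tab)
}

#' Write a FreeSurfer annot (label) file
#'
#' Labels are encoded as the packed RGB of their colortable entry (new-style
#' version-2 colortable); ignored vertices are written with annotation value
#' 0, which maps back to the ignore sentinel on re-read provided no region is
#' pure black.
#'
#' @param parc a \linkS4class{Parcellation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnot <- function(parc, path) {
  validObject(parc)
  tab <- parc@labelTable
  packed <- packRGB(tab$red, tab$green, tab$blue)
  if (anyDuplicated(packed)) stop("label table colours must be distinct")
  lab <- parc@labels
  ann <- integer(length(lab))
  keep <- lab != parc@ignoreIndex
  ann[keep] <- packed[match(lab[keep], tab$class)]
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(lab)
  writeBigInt(con, n)
  inter <- integer(2L * n)
  inter[seq.int(1L, 2L * n, by = 2L)] <- seq_len(n) - 1L
  inter[seq.int(2L, 2L * n, by = 2L)] <- ann
  writeBigInt(con, inter)
  writeBigInt(con, 1L)                  # colortable present
  writeBigInt(con, -2L)                 # new-format version 2
  writeBigInt(con, max(tab$structureId) + 1L)
  orig <- charToRaw("synthetic.ctab")
  writeBigInt(con, length(orig)); writeBin(orig, con)
  writeBigInt(con, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    writeBigInt(con, tab$structureId[i])
    nm <- c(charToRaw(tab$name[i]), as.raw(0L))
    writeBigInt(con, length(nm)); writeBin(nm, con)
    writeBigInt(con, c(tab$red[i], tab$green[i], tab$blue[i], 0L))
  }
  invisible(path)
}
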