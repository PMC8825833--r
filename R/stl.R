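# STL read/write (binary and ASCII). Binary STL stores float32 coordinates;
# ASCII is written with enough digits to round-trip double precision.

#' Write a mesh to an STL file
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL (`TRUE`) or binary (`FALSE`, default).
#'   Binary STL stores 32-bit floats, so coordinates are quantised to float32
#'   precision; ASCII preserves doubles to ~1e-9 relative.
#' @return `path`, invisibly.
#' @export
save_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  nt <- nrow(a)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    solid <- gsub("[^A-Za-z0-9_.-]", "_", mesh$name)
    writeLines(paste("solid", solid), con)
    fmt <- function(x) sprintf("%.9g", x)
    for (i in seq_len(nt)) {
      writeLines(c(
        sprintf("  facet normal %s %s %s", fmt(n[i, 1]), fmt(n[i, 2]), fmt(n[i, 3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(a[i, 1]), fmt(a[i, 2]), fmt(a[i, 3])),
        sprintf("      vertex %s %s %s", fmt(b[i, 1]), fmt(b[i, 2]), fmt(b[i, 3])),
        sprintf("      vertex %s %s %s", fmt(c_[i, 1]), fmt(c_[i, 2]), fmt(c_[i, 3])),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste("endsolid", solid), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC(mesh$name, width = -80))
    length(header) <- 80L
    header[is.na(header)] <- as.raw(0)
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    tri <- matrix(0, nrow = 12L, ncol = nt)
    tri[1:3, ] <- t(n)
    tri[4:6, ] <- t(a)
    tri[7:9, ] <- t(b)
    tri[10:12, ] <- t(c_)
    for (i in seq_len(nt)) {
      writeBin(tri[, i], con, size = 4L, endian = "little")
      writeBin(as.integer(0), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

stl_parse_error <- function(path, offset, what) {
  stop(sprintf("malformed STL '%s' at byte offset %d: %s", path, offset, what),
       call. = FALSE)
}

#' Read a mesh from an STL file
#'
#' Detects binary vs ASCII automatically, merges exactly-coincident vertices
#' so that shared topology (and hence watertightness checks) is recovered,
#' and reports parse errors with the byte offset at which reading failed.
#'
#' @param path STL file path.
#' @param name label for the mesh; defaults to the file's solid name.
#' @return a [tri_mesh()].
#' @export
load_stl <- function(path, name = NULL) {
  info <- file.info(path)
  if (is.na(info$size)) stop(sprintf("file '%s' not found", path))
  if (info$size == 0) stl_parse_error(path, 0L, "empty file")
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(info$size, 512L))
  close(con)
  is_ascii <- identical(rawToChar(head[1:min(5, length(head))]), "solid") &&
    !any(head == as.raw(0)) &&
    grepl("facet", rawToChar(head), fixed = TRUE)
  # a short file starting with "solid" but no facets: decide by size check below
  if (identical(rawToChar(head[1:min(5, length(head))]), "solid") &&
      !any(head == as.raw(0)) && !is_ascii && info$size < 84) {
    is_ascii <- TRUE
  }
  if (is_ascii) load_stl_ascii(path, name) else load_stl_binary(path, name)
}

load_stl_binary <- function(path, name) {
  size <- file.info(path)$size
  if (size < 84) stl_parse_error(path, as.integer(size), "truncated header")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nt < 0) stl_parse_error(path, 80L, "invalid triangle count")
  expected <- 84 + 50 * as.numeric(nt)
  if (size < expected) {
    stl_parse_error(path, as.integer(size),
                    sprintf("expected %d triangles (%.0f bytes)", nt, expected))
  }
  raw <- readBin(con, "raw", n = 50L * nt)
  m <- matrix(raw, nrow = 50L)
  floats <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", size = 4L,
                    n = 12L * nt, endian = "little")
  tri <- matrix(floats, nrow = 12L)
  verts <- rbind(t(tri[4:6, , drop = FALSE]), t(tri[7:9, , drop = FALSE]),
                 t(tri[10:12, , drop = FALSE]))
  order_idx <- as.vector(t(matrix(seq_len(3L * nt), ncol = 3L)))
  verts <- verts[order_idx, , drop = FALSE]
  if (is.null(name)) {
    name <- trimws(rawToChar(header[header != as.raw(0)]))
    if (name == "") name <- "stl"
  }
  stl_weld(verts, name, path)
}

load_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  offs <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))
  trimmed <- trimws(lines)
  if (!grepl("^solid", trimmed[1])) stl_parse_error(path, 0L, "missing 'solid'")
  vidx <- grep("^vertex\\b", trimmed)
  lidx <- grep("^outer loop$", trimmed)
  eidx <- grep("^endloop$", trimmed)
  if (length(lidx) != length(eidx)) {
    stl_parse_error(path, offs[length(offs) - 1L], "unbalanced loop markers")
  }
  if (length(vidx) == 0L) {
    stl_parse_error(path, offs[length(offs) - 1L], "no vertices found")
  }
  # every loop must contain exactly 3 vertices (triangles only)
  loop_of <- findInterval(vidx, lidx)
  counts <- tabulate(loop_of, nbins = length(lidx))
  if (any(counts != 3L)) {
    bad <- which(counts != 3L)[1]
    stl_parse_error(path, offs[lidx[bad]],
                    sprintf("facet with %d vertices; STL requires triangles",
                            counts[bad]))
  }
  toks <- strsplit(trimmed[vidx], "\\s+")
  bad_tok <- which(lengths(toks) != 4L)
  if (length(bad_tok) > 0L) {
    stl_parse_error(path, offs[vidx[bad_tok[1]]], "vertex needs 3 coordinates")
  }
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L, byrow = TRUE))
  if (anyNA(coords)) {
    bad <- which(apply(is.na(coords), 1, any))[1]
    stl_parse_error(path, offs[vidx[bad]], "non-numeric coordinate")
  }
  if (is.null(name)) {
    name <- sub("^solid\\s*", "", trimmed[1])
    if (name == "") name <- "stl"
  }
  stl_weld(coords, name, path)
}

# merge exactly-equal vertices; faces are consecutive vertex triples
stl_weld <- function(verts, name, path) {
  nt <- nrow(verts) / 3L
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, key)
  keep <- !duplicated(uid)
  remap <- cumsum(keep)[uid]
  faces <- matrix(remap, ncol = 3L, byrow = TRUE)
  degenerate <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  tri_mesh(verts[keep, , drop = FALSE], faces[!degenerate, , drop = FALSE],
           name = name)
}
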