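# Mesh input/output: ASCII/binary STL, OBJ, ASCII PLY.

#' Load a triangulated surface from file
#'
#' Supported formats (chosen by file extension): STL (ASCII or binary), OBJ
#' and PLY (ASCII). Vertex coordinates are multiplied by `units_scale`, so a
#' mesh authored in metres is loaded with `units_scale = 1000` to obtain mm.
#' Degenerate faces are removed with a warning by the [tri_surface()]
#' constructor.
#'
#' @param path file path.
#' @param units_scale positive scalar applied to all coordinates.
#' @return a [tri_surface()].
#' @export
load_surface <- function(path, units_scale = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(is.numeric(units_scale), units_scale > 0)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = .read_stl(path),
    obj = .read_obj(path),
    ply = .read_ply(path),
    stop(sprintf("unsupported mesh format: '%s' (use STL, OBJ or PLY)", ext))
  )
  tri_surface(mesh$vertices * units_scale, mesh$faces)
}

#' Write a triangulated surface to file
#'
#' Format chosen by extension: `.stl` (ASCII), `.obj`, `.ply` (ASCII).
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "tri_surface"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .write_stl(surface, path),
    obj = .write_obj(surface, path),
    ply = .write_ply(surface, path),
    stop(sprintf("unsupported mesh format: '%s'", ext))
  )
  invisible(path)
}

.read_stl <- function(path) {
  # ASCII STL starts with "solid" and contains "facet"; binary may also start
  # with "solid", so check the body.
  head <- readBin(path, "raw", n = 512L)
  printable <- head >= as.raw(0x20) & head <= as.raw(0x7e) |
    head == as.raw(0x0a) | head == as.raw(0x0d) | head == as.raw(0x09)
  txt <- rawToChar(head[printable])
  if (grepl("^\\s*solid", txt, useBytes = TRUE) &&
      grepl("facet", txt, useBytes = TRUE)) {
    .read_stl_ascii(path)
  } else {
    .read_stl_binary(path)
  }
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop(sprintf("malformed ASCII STL: %s", path))
  }
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  nf <- nrow(v) / 3L
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = faces)
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf <= 0L) stop(sprintf("malformed binary STL: %s", path))
  body <- readBin(con, "raw", n = 50L * nf)
  if (length(body) < 50L * nf) stop(sprintf("truncated binary STL: %s", path))
  # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
  float_idx <- as.vector(outer(1:48, (0:(nf - 1L)) * 50L, "+"))
  floats <- readBin(body[float_idx], "numeric", n = 12L * nf, size = 4L,
                    endian = "little")
  rec <- matrix(floats, nrow = 12L)
  v <- matrix(as.numeric(rec[4:12, ]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = faces)
}

.write_stl <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  n <- surface$normals
  con <- file(path, "w")
  on.exit(close(con))
  fmt_v <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3])
  writeLines("solid edem", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                 "    outer loop",
                 fmt_v(v[f[i, 1], ]), fmt_v(v[f[i, 2], ]), fmt_v(v[f[i, 3], ]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid edem", con)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop(sprintf("malformed OBJ (no vertices or faces): %s", path))
  }
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  parse_face <- function(x) {
    idx <- as.integer(vapply(strsplit(x[-1], "/", fixed = TRUE),
                             function(p) p[1], character(1)))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    idx
  }
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), parse_face))
  list(vertices = v, faces = f)
}

.write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface$faces[, 1], surface$faces[, 2],
                     surface$faces[, 3]), con)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop(sprintf("not a PLY file: %s", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop(sprintf("malformed PLY header: %s", path))
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format\\s+binary", header))) {
    stop(sprintf("binary PLY is not supported: %s", path))
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", header, value = TRUE)))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", header, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L) {
    stop(sprintf("malformed PLY header: %s", path))
  }
  body <- trimws(lines[(end + 1L):length(lines)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop(sprintf("truncated PLY body: %s", path))
  v <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(body[nv + seq_len(nf)], "\\s+"),
                             function(x) {
                               n <- as.integer(x[1])
                               if (n != 3L) stop("only triangular PLY faces are supported")
                               as.integer(x[2:4]) + 1L
                             }))
  list(vertices = v, faces = f)
}

.write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(surface$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(surface$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", surface$faces[, 1] - 1L,
                     surface$faces[, 2] - 1L, surface$faces[, 3] - 1L), con)
}
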