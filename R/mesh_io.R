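#' Read a triangle mesh from file
#'
#' Supported formats: OFF, ASCII PLY, and a plain vertex/face text
#' dialect (first line `"m k"`, then `m` coordinate lines, then `k`
#' 0-based index triples).  Vertex order is preserved.  Malformed
#' headers, out-of-range face indices and non-triangle faces raise
#' errors naming the offending line.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"off"`, `"ply"`, `"txt"`.  `"auto"`
#'   dispatches on the file extension, falling back to the first line.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("off", "ply")) ext
    else if (length(lines) && grepl("^\\s*OFF\\s*$", lines[1])) "off"
    else if (length(lines) && grepl("^\\s*ply\\s*$", lines[1])) "ply"
    else "txt"
  }
  switch(format,
         off = .read_off(lines, path),
         ply = .read_ply(lines, path),
         txt = .read_plain(lines, path))
}

#' Write a triangle mesh to file
#'
#' Coordinates are written with 17 significant digits so that a
#' write/read round trip reproduces the vertex array bit for bit.
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param format one of `"off"`, `"ply"`, `"txt"` (see [read_mesh()]).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("off", "ply", "txt")) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- match.arg(format)
  if (nrow(mesh$vertices) == 0L)
    stop("empty mesh")
  v <- apply(mesh$vertices, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  f0 <- mesh$triangles - 1L  # file formats are 0-based
  out <- switch(
    format,
    off = c("OFF",
            sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
            v,
            sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(mesh$vertices)),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", nrow(mesh$triangles)),
            "property list uchar int vertex_indices",
            "end_header",
            v,
            sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L])),
    txt = c(sprintf("%d %d", nrow(mesh$vertices), nrow(mesh$triangles)),
            v,
            sprintf("%d %d %d", f0[, 1L], f0[, 2L], f0[, 3L])))
  writeLines(out, path)
  invisible(path)
}

.parse_nums <- function(line, lineno, path, n = NULL) {
  x <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(x) || (!is.null(n) && length(x) < n))
    stop(sprintf("%s: parse error at line %d: '%s'", path, lineno, line))
  x
}

.strip_off_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.build_from_arrays <- function(verts, faces, path, face_lineno) {
  m <- nrow(verts)
  bad <- faces < 0L | faces >= m
  if (any(bad)) {
    r <- which(rowSums(bad) > 0L)[1L]
    stop(sprintf("%s: face index out of range at line %d", path,
                 face_lineno[r]))
  }
  trimesh(verts, faces + 1L)
}

.read_off <- function(lines, path) {
  s <- .strip_off_comments(lines)
  if (length(s$lines) < 2L || !grepl("^\\s*OFF\\s*$", s$lines[1]))
    stop(path, ": malformed header: expected 'OFF' on line 1")
  cnt <- .parse_nums(s$lines[2], s$lineno[2], path, 2)
  m <- as.integer(cnt[1]); k <- as.integer(cnt[2])
  if (length(s$lines) < 2L + m + k)
    stop(path, ": truncated file: header promises ", m, " vertices and ",
         k, " faces")
  verts <- t(vapply(seq_len(m), function(i)
    .parse_nums(s$lines[2L + i], s$lineno[2L + i], path, 3)[1:3],
    numeric(3)))
  face_rows <- seq_len(k) + 2L + m
  faces <- t(vapply(face_rows, function(i) {
    x <- .parse_nums(s$lines[i], s$lineno[i], path)
    if (x[1] != 3)
      stop(sprintf("%s: non-triangle face (%d vertices) at line %d",
                   path, as.integer(x[1]), s$lineno[i]))
    as.integer(x[2:4])
  }, integer(3)))
  .build_from_arrays(verts, faces, path, s$lineno[face_rows])
}

.read_ply <- function(lines, path) {
  if (!length(lines) || !grepl("^\\s*ply\\s*$", lines[1]))
    stop(path, ": malformed header: expected 'ply' on line 1")
  hdr_end <- which(grepl("^\\s*end_header\\s*$", lines))[1]
  if (is.na(hdr_end))
    stop(path, ": malformed header: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^\\s*format\\s+ascii", hdr)))
    stop(path, ": only ASCII PLY is supported")
  ev <- grep("^\\s*element\\s+vertex\\s+\\d+", hdr, value = TRUE)
  ef <- grep("^\\s*element\\s+face\\s+\\d+", hdr, value = TRUE)
  if (!length(ev) || !length(ef))
    stop(path, ": malformed header: missing element vertex/face")
  m <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1", ev[1]))
  k <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1", ef[1]))
  body <- lines[-seq_len(hdr_end)]
  body_lineno <- seq_along(body) + hdr_end
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_lineno <- body_lineno[keep]
  if (length(body) < m + k)
    stop(path, ": truncated file: header promises ", m, " vertices and ",
         k, " faces")
  verts <- t(vapply(seq_len(m), function(i)
    .parse_nums(body[i], body_lineno[i], path, 3)[1:3], numeric(3)))
  face_rows <- seq_len(k) + m
  faces <- t(vapply(face_rows, function(i) {
    x <- .parse_nums(body[i], body_lineno[i], path)
    if (x[1] != 3)
      stop(sprintf("%s: non-triangle face (%d vertices) at line %d",
                   path, as.integer(x[1]), body_lineno[i]))
    as.integer(x[2:4])
  }, integer(3)))
  .build_from_arrays(verts, faces, path, body_lineno[face_rows])
}

.read_plain <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  lines2 <- lines[keep]; lineno <- which(keep)
  if (!length(lines2))
    stop(path, ": empty file, no header")
  cnt <- .parse_nums(lines2[1], lineno[1], path, 2)
  m <- as.integer(cnt[1]); k <- as.integer(cnt[2])
  if (length(lines2) < 1L + m + k)
    stop(path, ": truncated file: header promises ", m, " vertices and ",
         k, " faces")
  verts <- t(vapply(seq_len(m), function(i)
    .parse_nums(lines2[1L + i], lineno[1L + i], path, 3)[1:3], numeric(3)))
  face_rows <- seq_len(k) + 1L + m
  faces <- t(vapply(face_rows, function(i) {
    as.integer(.parse_nums(lines2[i], lineno[i], path, 3)[1:3])
  }, integer(3)))
  .build_from_arrays(verts, faces, path, lineno[face_rows])
}
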