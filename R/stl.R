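# STL triangle-mesh plumbing for phantom cavity files.  Both dialects are
# supported: ASCII ("solid ... facet normal ... vertex ...") and binary
# (80-byte header, uint32 triangle count, 50-byte little-endian facet
# records: 12 float32 + uint16 attribute).

#' Read an STL file
#'
#' Parses an STL cavity file (binary or ASCII, auto-detected) and returns a
#' summary: triangle count, bounding box in the file's units (mm by
#' convention here), dialect, and a watertightness heuristic (every edge
#' shared by exactly two triangles). The triangle coordinates are kept in
#' the result for round-tripping.
#'
#' @param path Path to an `.stl` file.
#' @return An object of class `"stl_summary"` with elements `n_triangles`,
#'   `bbox` (3x2 matrix, rows x/y/z), `format` (`"ascii"` or `"binary"`),
#'   `watertight` and `triangles` (`n x 3 x 3` array: triangle, vertex,
#'   coordinate).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) abort(sprintf("STL file not found: %s", path))
  size <- file.info(path)$size
  if (size == 0) abort(sprintf("STL format error in %s: empty file", path))
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(size, 512))
  is_ascii <- looks_ascii_stl(head_raw, size)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  summarize_stl(tri, if (is_ascii) "ascii" else "binary")
}

looks_ascii_stl <- function(head_raw, size) {
  # keep printable ASCII plus whitespace so binary headers cannot produce
  # invalid multibyte strings
  keep <- (head_raw >= as.raw(0x20) & head_raw <= as.raw(0x7e)) |
    head_raw %in% as.raw(c(0x09, 0x0a, 0x0d))
  txt <- rawToChar(head_raw[keep])
  starts_solid <- grepl("^\\s*solid", txt)
  # binary files may also start with "solid": require the ascii keyword
  starts_solid && grepl("facet", txt, fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  n_facets <- sum(grepl("^facet\\s+normal", lines))
  vlines <- lines[grepl("^vertex\\s", lines)]
  if (n_facets == 0 || length(vlines) != 3 * n_facets) {
    abort(sprintf(
      "STL format error in %s: %d facet(s) but %d vertex line(s)",
      path, n_facets, length(vlines)))
  }
  coords <- vapply(strsplit(sub("^vertex\\s+", "", vlines), "\\s+"),
                   function(v) as.numeric(v[1:3]), numeric(3))
  if (anyNA(coords)) abort(sprintf("STL format error in %s: non-numeric vertex", path))
  tri <- array(NA_real_, c(n_facets, 3, 3))
  for (i in seq_len(n_facets)) {
    tri[i, , ] <- t(coords[, (3 * i - 2):(3 * i)])
  }
  tri
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < 84) {
    abort(sprintf("STL format error in %s: binary file truncated at byte %d (need 84-byte header)",
                  path, size))
  }
  invisible(readBin(con, "raw", n = 80))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  if (expected != size) {
    abort(sprintf(
      "STL format error in %s: declared %d triangles need %d bytes, file has %d (payload mismatch at byte offset 84)",
      path, n, expected, size))
  }
  tri <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", n = 2))
    tri[i, , ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

summarize_stl <- function(tri, format) {
  n <- dim(tri)[1]
  pts <- matrix(aperm(tri, c(2, 1, 3)), ncol = 3)
  bbox <- t(apply(pts, 2, range))
  rownames(bbox) <- c("x", "y", "z")
  colnames(bbox) <- c("min", "max")
  if (!all(is.finite(bbox))) abort("STL geometry has non-finite coordinates.")
  structure(
    list(n_triangles = n, bbox = bbox, format = format,
         watertight = stl_watertight(tri), triangles = tri),
    class = "stl_summary"
  )
}

# heuristic: mesh is watertight iff every undirected edge occurs exactly twice
stl_watertight <- function(tri) {
  n <- dim(tri)[1]
  pts <- matrix(aperm(tri, c(2, 1, 3)), ncol = 3)
  key <- apply(signif(pts, 9), 1, paste, collapse = ",")
  vid <- match(key, unique(key))
  vid <- matrix(vid, nrow = 3)  # vertices per triangle in columns
  edges <- character(0)
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    a <- pmin(vid[e[1], ], vid[e[2], ])
    b <- pmax(vid[e[1], ], vid[e[2], ])
    edges <- c(edges, paste(a, b, sep = "-"))
  }
  all(table(edges) == 2)
}

#' @export
print.stl_summary <- function(x, ...) {
  cat(sprintf("<stl_summary> %d triangle(s), %s dialect, watertight: %s\n",
              x$n_triangles, x$format, x$watertight))
  cat("  bounding box (mm):\n")
  print(round(x$bbox, 3))
  invisible(x)
}

#' Write triangles to an STL file
#'
#' Writes a triangle soup to either STL dialect. Facet normals are computed
#' from the right-hand vertex order.
#'
#' @param triangles An `n x 3 x 3` array (triangle, vertex, coordinate) or
#'   an `"stl_summary"` object.
#' @param path Output path.
#' @param format `"ascii"` or `"binary"`.
#' @param name Solid name used in the ASCII dialect.
#' @return `path`, invisibly.
#' @export
write_stl <- function(triangles, path, format = c("ascii", "binary"),
                      name = "phantomix") {
  format <- match.arg(format)
  if (inherits(triangles, "stl_summary")) triangles <- triangles$triangles
  n <- dim(triangles)[1]
  normal <- function(v) {
    nrm <- c(
      (v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
      (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
      (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1])
    )
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm / len else c(0, 0, 0)
  }
  if (format == "ascii") {
    out <- c(sprintf("solid %s", name))
    for (i in seq_len(n)) {
      v <- triangles[i, , ]
      nr <- normal(v)
      out <- c(out,
        sprintf("  facet normal %.9g %.9g %.9g", nr[1], nr[2], nr[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
        "    endloop",
        "  endfacet")
    }
    writeLines(c(out, sprintf("endsolid %s", name)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("phantomix binary STL:", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    for (i in seq_len(n)) {
      v <- triangles[i, , ]
      writeBin(as.numeric(c(normal(v), t(v))), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
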