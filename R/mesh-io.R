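#' Read a triangle mesh from OBJ or PLY
#'
#' Indices are normalized to the package's internal 1-based convention at the
#' I/O boundary: OBJ files are already 1-based, PLY files are 0-based and get
#' shifted on read. Per-vertex colors are loaded when present (OBJ vertex-color
#' extension: six numbers on a `v` record; PLY `red/green/blue` properties,
#' 8-bit channels rescaled to `[0, 1]`).
#'
#' @param path file path.
#' @param format `"obj"` or `"ply"`; inferred from the file extension when
#'   omitted.
#' @return a validated [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- infer_mesh_format(path)
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  mesh <- switch(format, obj = read_obj(path), ply = read_ply(path))
  validate_mesh(mesh)
  mesh
}

infer_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply"))
    stop("cannot infer mesh format from extension '", ext, "' (use format=)")
  ext
}

#' Write a triangle mesh to OBJ or PLY
#'
#' PLY vertex coordinates are written as 32-bit `float` properties (the common
#' dialect); colors as 8-bit `uchar`, so a color round-trip is exact to within
#' 1/255 per channel. OBJ colors use the widespread six-number `v` record
#' extension; set `obj_colors = FALSE` to target strict OBJ readers, in which
#' case color is dropped with a warning.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"obj"` or `"ply"` (inferred from extension when omitted).
#' @param ply_format `"binary_little_endian"` (default) or `"ascii"`.
#' @param obj_colors write vertex colors on OBJ `v` records when present.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"),
                       ply_format = c("binary_little_endian", "ascii"),
                       obj_colors = TRUE) {
  format <- match.arg(format)
  ply_format <- match.arg(ply_format)
  if (format == "auto") format <- infer_mesh_format(path)
  validate_mesh(mesh)
  switch(format,
         obj = write_obj(mesh, path, obj_colors),
         ply = write_ply(mesh, path, ply_format))
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v[[:space:]]", lines)
  fl <- grep("^f[[:space:]]", lines)
  if (!length(vl)) stop("OBJ parse error: no vertex records in ", path)
  vtok <- strsplit(trimws(sub("^v", "", lines[vl])), "[[:space:]]+")
  nfield <- lengths(vtok)
  if (any(nfield < 3L))
    stop("OBJ parse error at line ", vl[which(nfield < 3L)[1L]],
         ": vertex record with fewer than 3 coordinates")
  vnum <- suppressWarnings(lapply(vtok, as.numeric))
  if (any(vapply(vnum, anyNA, logical(1L))))
    stop("OBJ parse error at line ", vl[which(vapply(vnum, anyNA, logical(1L)))[1L]],
         ": non-numeric vertex field")
  pts <- t(vapply(vnum, function(v) v[1:3], numeric(3L)))
  colors <- NULL
  if (all(nfield >= 6L)) {
    colors <- t(vapply(vnum, function(v) v[4:6], numeric(3L)))
    if (min(colors) < 0 || max(colors) > 1) colors <- NULL  # not a color extension
  }
  tri <- NULL
  if (length(fl)) {
    ftok <- strsplit(trimws(sub("^f", "", lines[fl])), "[[:space:]]+")
    bad <- which(lengths(ftok) != 3L)
    if (length(bad))
      stop("OBJ parse error at line ", fl[bad[1L]],
           ": only triangular faces are supported")
    idx <- suppressWarnings(
      vapply(ftok, function(f) as.integer(sub("/.*$", "", f)), integer(3L)))
    if (anyNA(idx))
      stop("OBJ parse error: non-integer face index near line ", fl[1L])
    tri <- t(idx)
  } else {
    tri <- matrix(integer(0L), 0L, 3L)
  }
  triangle_mesh(pts, tri, colors = colors, validate = FALSE)
}

write_obj <- function(mesh, path, obj_colors) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- mesh$points
  if (!is.null(mesh$colors) && obj_colors) {
    writeLines(sprintf("v %.17g %.17g %.17g %.9g %.9g %.9g",
                       p[, 1L], p[, 2L], p[, 3L],
                       mesh$colors[, 1L], mesh$colors[, 2L], mesh$colors[, 3L]),
               con)
  } else {
    if (!is.null(mesh$colors) && !obj_colors)
      warning("OBJ dialect without vertex-color support: colors dropped")
    writeLines(sprintf("v %.17g %.17g %.17g", p[, 1L], p[, 2L], p[, 3L]), con)
  }
  t <- mesh$trilist
  if (nrow(t))
    writeLines(sprintf("f %d %d %d", t[, 1L], t[, 2L], t[, 3L]), con)
}

## ---- PLY ----

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size[[type]]
  bytes <- raw[(off + 1L):(off + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", size = 1L, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", size = 4L, endian = "little"),
    float = , float32 = readBin(bytes, "numeric", size = 4L, endian = "little"),
    double = , float64 = readBin(bytes, "numeric", size = 8L, endian = "little"))
  list(value = as.numeric(val), off = off + sz)
}

parse_ply_header <- function(lines) {
  if (length(lines) < 2L || trimws(lines[1L]) != "ply")
    stop("PLY parse error: missing 'ply' magic line")
  fmt_line <- grep("^format", lines, value = TRUE)[1L]
  if (is.na(fmt_line)) stop("PLY parse error: missing format line")
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY parse error: unsupported format '", fmt, "'")
  elements <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (!length(tok)) next
    if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L],
               item_type = tok[4L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      return(list(format = fmt, elements = elements, header_lines = i))
    }
  }
  stop("PLY parse error: missing end_header")
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate the end of the (always-ascii) header at the byte level: the body
  # of a binary file may contain nul bytes that rawToChar cannot pass over
  pat <- charToRaw("end_header")
  limit <- min(length(raw), 65536L)
  hits <- which(raw[seq_len(limit)] == pat[1L])
  marker <- NA_integer_
  for (h in hits) {
    if (h + length(pat) - 1L <= limit &&
        identical(raw[h:(h + length(pat) - 1L)], pat)) {
      marker <- h
      break
    }
  }
  if (is.na(marker)) stop("PLY parse error: missing end_header")
  # byte offset just past the end_header line's newline
  body_off <- marker + length(pat) - 1L
  while (body_off < length(raw) && raw[body_off + 1L] != as.raw(10L))
    body_off <- body_off + 1L
  body_off <- body_off + 1L
  hdr_lines <- strsplit(rawToChar(raw[seq_len(body_off)]), "\r?\n")[[1L]]
  hdr <- parse_ply_header(hdr_lines)
  vert <- hdr$elements[["vertex"]]
  face <- hdr$elements[["face"]]
  if (is.null(vert)) stop("PLY parse error: no vertex element")
  if (hdr$format == "ascii") {
    body <- strsplit(trimws(rawToChar(raw[(body_off + 1L):length(raw)])),
                     "\r?\n")[[1L]]
    body <- body[nzchar(trimws(body))]
    read_ply_ascii(hdr, body, vert, face)
  } else {
    read_ply_binary(hdr, raw, body_off, vert, face)
  }
}

# TRUE when the red/green/blue vertex properties are 8-bit integer types.
ply_colors_are_uchar <- function(vert) {
  pn <- vapply(vert$props, `[[`, "", "name")
  j <- match("red", pn)
  if (is.na(j)) return(FALSE)
  vert$props[[j]]$type %in% c("uchar", "uint8", "char", "int8")
}

read_ply_ascii <- function(hdr, body, vert, face) {
  need <- vert$count + if (!is.null(face)) face$count else 0L
  if (length(body) < need)
    stop("PLY parse error: expected ", need, " body lines, found ", length(body))
  vtok <- strsplit(trimws(body[seq_len(vert$count)]), "[[:space:]]+")
  pnames <- vapply(vert$props, `[[`, "", "name")
  vmat <- t(vapply(vtok, function(tk) suppressWarnings(as.numeric(tk)),
                   numeric(length(pnames))))
  if (anyNA(vmat)) stop("PLY parse error: non-numeric vertex field")
  colnames(vmat) <- pnames
  tri <- matrix(integer(0L), 0L, 3L)
  if (!is.null(face) && face$count > 0L) {
    ftok <- strsplit(trimws(body[vert$count + seq_len(face$count)]),
                     "[[:space:]]+")
    tri <- t(vapply(seq_along(ftok), function(i) {
      tk <- as.integer(ftok[[i]])
      if (tk[1L] != 3L)
        stop("PLY parse error: face ", i, " has ", tk[1L],
             " vertices; only triangles supported")
      tk[2:4] + 1L
    }, integer(3L)))
  }
  ply_assemble(vmat, tri, ply_colors_are_uchar(vert))
}

read_ply_binary <- function(hdr, raw, off, vert, face) {
  pnames <- vapply(vert$props, `[[`, "", "name")
  sizes <- vapply(vert$props, function(p) ply_type_size[[p$type]], integer(1L))
  stride <- sum(sizes)
  # fast path: read each property as a strided column
  vmat <- matrix(0, vert$count, length(pnames))
  block <- raw[(off + 1L):(off + stride * vert$count)]
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  for (j in seq_along(pnames)) {
    tp <- vert$props[[j]]$type
    sz <- sizes[j]
    sel <- as.vector(outer(seq_len(sz), (seq_len(vert$count) - 1L) * stride +
                             starts[j], "+"))
    col_raw <- block[sel]
    vmat[, j] <- switch(tp,
      char = , int8 = readBin(col_raw, "integer", n = vert$count, size = 1L,
                              signed = TRUE),
      uchar = , uint8 = readBin(col_raw, "integer", n = vert$count, size = 1L,
                                signed = FALSE),
      short = , int16 = readBin(col_raw, "integer", n = vert$count, size = 2L,
                                signed = TRUE, endian = "little"),
      ushort = , uint16 = readBin(col_raw, "integer", n = vert$count, size = 2L,
                                  signed = FALSE, endian = "little"),
      int = , int32 = , uint = , uint32 =
        readBin(col_raw, "integer", n = vert$count, size = 4L, endian = "little"),
      float = , float32 = readBin(col_raw, "numeric", n = vert$count, size = 4L,
                                  endian = "little"),
      double = , float64 = readBin(col_raw, "numeric", n = vert$count, size = 8L,
                                   endian = "little"))
  }
  colnames(vmat) <- pnames
  off <- off + stride * vert$count
  tri <- matrix(integer(0L), 0L, 3L)
  if (!is.null(face) && face$count > 0L) {
    lp <- face$props[[1L]]
    if (!lp$list) stop("PLY parse error: face element without list property")
    csz <- ply_type_size[[lp$count_type]]
    isz <- ply_type_size[[lp$item_type]]
    tri <- matrix(0L, face$count, 3L)
    for (i in seq_len(face$count)) {
      cnt <- ply_read_scalar(raw, off, lp$count_type)
      if (cnt$value != 3)
        stop("PLY parse error: face ", i, " has ", cnt$value,
             " vertices; only triangles supported")
      off <- cnt$off
      for (k in 1:3) {
        v <- ply_read_scalar(raw, off, lp$item_type)
        tri[i, k] <- as.integer(v$value) + 1L
        off <- v$off
      }
    }
  }
  ply_assemble(vmat, tri, ply_colors_are_uchar(vert))
}

ply_assemble <- function(vmat, tri, colors_uchar = FALSE) {
  pn <- colnames(vmat)
  for (ax in c("x", "y", "z"))
    if (!ax %in% pn) stop("PLY parse error: missing vertex property '", ax, "'")
  pts <- vmat[, c("x", "y", "z"), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% pn)) {
    colors <- vmat[, c("red", "green", "blue"), drop = FALSE]
    if (colors_uchar) colors <- colors / 255
    colors[] <- pmin(pmax(colors, 0), 1)
  }
  triangle_mesh(pts, tri, colors = colors, validate = FALSE)
}

write_ply <- function(mesh, path, ply_format) {
  has_col <- !is.null(mesh$colors)
  hdr <- c("ply",
           paste("format", ply_format, "1.0"),
           "comment written by morphable3d",
           paste("element vertex", nrow(mesh$points)),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           paste("element face", nrow(mesh$trilist)),
           "property list uchar int vertex_indices",
           "end_header")
  col8 <- if (has_col) round(mesh$colors * 255) else NULL
  if (ply_format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    p <- mesh$points
    if (has_col) {
      writeLines(sprintf("%.9g %.9g %.9g %d %d %d", p[, 1L], p[, 2L], p[, 3L],
                         col8[, 1L], col8[, 2L], col8[, 3L]), con)
    } else {
      writeLines(sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L]), con)
    }
    t0 <- mesh$trilist - 1L
    if (nrow(t0))
      writeLines(sprintf("3 %d %d %d", t0[, 1L], t0[, 2L], t0[, 3L]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    n <- nrow(mesh$points)
    if (has_col) {
      for (i in seq_len(n)) {
        writeBin(mesh$points[i, ], con, size = 4L, endian = "little")
        writeBin(as.integer(col8[i, ]), con, size = 1L)
      }
    } else {
      writeBin(as.numeric(t(mesh$points)), con, size = 4L, endian = "little")
    }
    t0 <- mesh$trilist - 1L
    for (i in seq_len(nrow(t0))) {
      writeBin(3L, con, size = 1L)
      writeBin(as.integer(t0[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
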