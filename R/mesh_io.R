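#' Read a surface mesh from PLY or OBJ
#'
#' PLY is the reference dialect: ASCII and binary little-endian files are
#' accepted, with optional per-vertex `red`/`green`/`blue` (and ignored
#' `alpha`) uchar color properties. OBJ is read with the common vertex-color
#' extension (`v x y z r g b`). Only triangular faces are accepted; a face
#' with more (or fewer) than three vertices is an error, never silently
#' triangulated. Coordinates are taken to be millimetres; no unit metadata is
#' read.
#'
#' @param path file path.
#' @param format `"auto"` (from the file extension), `"ply"` or `"obj"`.
#' @return a [triangle_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension: ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, ply = read_ply(path), obj = read_obj(path))
}

#' Write a surface mesh to PLY or OBJ
#'
#' PLY is written as ASCII with uchar color properties when the mesh has
#' colors (quantized to 1/255); OBJ uses the vertex-color extension.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"auto"`, `"ply"` or `"obj"`.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension: ", path))
  }
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  switch(format, ply = write_ply(mesh, path), obj = write_obj(mesh, path))
  invisible(path)
}

# -- PLY ----------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, "integer", 1, size = 1, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", 1, size = 1, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", 1, size = 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", 1, size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", 1, size = 4, endian = "little"),
    float = , float32 = readBin(con, "double", 1, size = 4, endian = "little"),
    double = , float64 = readBin(con, "double", 1, size = 8, endian = "little"),
    stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop("malformed PLY (missing 'ply' magic) at line 1: ", path)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(name,type,list_count_type))
  cur <- NULL
  lineno <- 1L
  repeat {
    line <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(line) == 0L) stop("malformed PLY header (no end_header): ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' at line ", lineno)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before element at line ", lineno)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list_count_type = NULL)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else stop("unrecognized PLY header line ", lineno, ": ", line)
  }
  if (is.null(elements$vertex)) stop("PLY without vertex element: ", path)

  parse_elements <- function(get_scalar, get_list) {
    out <- list()
    for (el in elements) {
      scalar_names <- vapply(el$props, function(p) p$name, "")
      is_list <- vapply(el$props, function(p) !is.null(p$list_count_type), TRUE)
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- vector("list", length(el$props))
        for (j in seq_along(el$props)) {
          p <- el$props[[j]]
          vals[[j]] <- if (is_list[j]) get_list(p) else get_scalar(p)
        }
        names(vals) <- scalar_names
        rows[[i]] <- vals
      }
      out[[el$name]] <- rows
    }
    out
  }

  if (fmt == "ascii") {
    rest <- readLines(con)
    nums <- as.numeric(unlist(strsplit(trimws(rest[nzchar(trimws(rest))]),
                                       "\\s+")))
    if (anyNA(nums)) stop("malformed numeric record in PLY body: ", path)
    pos <- 0L
    take <- function(n) {
      if (pos + n > length(nums)) stop("truncated PLY body: ", path)
      v <- nums[(pos + 1L):(pos + n)]
      pos <<- pos + n
      v
    }
    data <- parse_elements(
      get_scalar = function(p) take(1L),
      get_list = function(p) {
        cnt <- take(1L)
        take(cnt)
      })
  } else {
    data <- parse_elements(
      get_scalar = function(p) ply_read_scalar(con, p$type),
      get_list = function(p) {
        cnt <- ply_read_scalar(con, p$list_count_type)
        vapply(seq_len(cnt), function(k) ply_read_scalar(con, p$type), 0)
      })
  }

  vrows <- data$vertex
  getcol <- function(nm) vapply(vrows, function(r) as.numeric(r[[nm]]), 0)
  vnames <- names(vrows[[1]])
  if (!all(c("x", "y", "z") %in% vnames))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  vertices <- cbind(getcol("x"), getcol("y"), getcol("z"))
  colors <- NULL
  if (all(c("red", "green", "blue") %in% vnames)) {
    colors <- cbind(getcol("red"), getcol("green"), getcol("blue")) / 255
  }
  frows <- if (!is.null(data$face)) data$face else list()
  if (length(frows)) {
    idx_name <- intersect(c("vertex_indices", "vertex_index"),
                          names(frows[[1]]))[1]
    if (is.na(idx_name)) stop("PLY face element lacks vertex_indices: ", path)
    lens <- vapply(frows, function(r) length(r[[idx_name]]), 0L)
    bad <- which(lens != 3L)
    if (length(bad))
      stop("non-triangular face (record ", bad[1], ", ", lens[bad[1]],
           " vertices) in ", path)
    triangles <- t(vapply(frows, function(r) as.integer(r[[idx_name]]) + 1L,
                          integer(3)))
  } else triangles <- matrix(integer(0), 0, 3)
  triangle_mesh(vertices, triangles, colors)
}

write_ply <- function(mesh, path) {
  has_col <- !is.null(mesh$colors)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n_vertices(mesh)),
    "property float x", "property float y", "property float z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    sprintf("element face %d", n_triangles(mesh)),
    "property list uchar int vertex_indices",
    "end_header")
  v <- mesh$vertices
  if (has_col) {
    rgb <- round(mesh$colors * 255)
    vlines <- sprintf("%.6f %.6f %.6f %d %d %d",
                      v[, 1], v[, 2], v[, 3], rgb[, 1], rgb[, 2], rgb[, 3])
  } else {
    vlines <- sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$triangles - 1L
  flines <- if (nrow(f)) sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
            else character(0)
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(c(header, vlines, flines), con)
}

# -- OBJ ----------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path)
  vt <- list()
  ft <- list()
  col <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "v") {
      vals <- suppressWarnings(as.numeric(tok[-1]))
      if (anyNA(vals) || !(length(vals) %in% c(3L, 6L)))
        stop("malformed OBJ vertex at line ", i, ": ", line)
      vt[[length(vt) + 1L]] <- vals[1:3]
      col[[length(col) + 1L]] <- if (length(vals) == 6L) vals[4:6] else NULL
    } else if (tok[1] == "f") {
      refs <- tok[-1]
      if (length(refs) != 3L)
        stop("non-triangular face (", length(refs), " vertices) at line ",
             i, ": ", line)
      idx <- suppressWarnings(as.integer(vapply(
        strsplit(refs, "/"), `[`, "", 1L)))
      if (anyNA(idx)) stop("malformed OBJ face at line ", i, ": ", line)
      ft[[length(ft) + 1L]] <- idx
    }
    # vn/vt/usemtl etc. ignored
  }
  if (!length(vt)) stop("OBJ without vertices: ", path)
  vertices <- do.call(rbind, vt)
  has_col <- !vapply(col, is.null, TRUE)
  colors <- NULL
  if (all(has_col)) colors <- do.call(rbind, col)
  else if (any(has_col))
    stop("OBJ mixes vertices with and without colors: ", path)
  triangles <- if (length(ft)) do.call(rbind, ft) else matrix(integer(0), 0, 3)
  triangle_mesh(vertices, triangles, colors)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  if (!is.null(mesh$colors)) {
    c3 <- mesh$colors
    vlines <- sprintf("v %.6f %.6f %.6f %.6f %.6f %.6f",
                      v[, 1], v[, 2], v[, 3], c3[, 1], c3[, 2], c3[, 3])
  } else {
    vlines <- sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  }
  f <- mesh$triangles
  flines <- if (nrow(f)) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
            else character(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(vlines, flines), con)
}
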