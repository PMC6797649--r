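#' Read a triangulated surface from PLY or STL
#'
#' Supports ASCII and binary-little-endian PLY (float32/float64 vertex
#' properties) and ASCII and binary STL. Coordinates are taken as millimetres.
#' STL stores each facet's vertices independently; duplicates are merged by
#' exact coordinate match, which recovers shared vertices because STL writers
#' emit identical floats for them.
#'
#' @param path file path.
#' @param format `"ply"` or `"stl"`; guessed from the extension when `NULL`.
#' @return a `triangle_mesh`.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format, c("ply", "stl"))
  if (format == "ply") read_ply(path) else read_stl(path)
}

#' Write a mesh to PLY or STL
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param format `"ply"` or `"stl"`; guessed from the extension when `NULL`.
#' @param binary write the binary flavour (little-endian) instead of ASCII.
#' @param displacement optional n x 3 matrix written as extra per-vertex
#'   properties `ux, uy, uz` (PLY only), carrying a displacement field.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = NULL, binary = FALSE,
                      displacement = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "stl"))
  if (format == "ply") {
    write_ply(mesh, path, binary = binary, displacement = displacement)
  } else {
    if (!is.null(displacement))
      stop("displacement properties are only supported for PLY output")
    write_stl(mesh, path, binary = binary)
  }
  invisible(path)
}

# ---- PLY ---------------------------------------------------------------

#' Read a displacement field stored as ux/uy/uz PLY vertex properties
#'
#' Companion to the `displacement` argument of [save_mesh()].
#'
#' @param path PLY file written with per-vertex `ux, uy, uz` properties.
#' @return numeric matrix (n x 3).
#' @export
load_displacement <- function(path) {
  dat <- read_ply(path, raw = TRUE)
  need <- c("ux", "uy", "uz")
  if (!all(need %in% colnames(dat$vertex)))
    stop("PLY file carries no ux/uy/uz displacement properties: ", path)
  unname(dat$vertex[, need, drop = FALSE])
}

read_ply <- function(path, raw = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000L) stop("PLY header too long; not a PLY file?")
  }
  if (trimws(header[1L]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  if (length(fmt_line) != 1L) stop("malformed PLY: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse element/property declarations
  elements <- list(); cur <- NULL
  for (line in trimws(header)) {
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        elements[[cur]]$props[[tok[5L]]] <-
          list(list = TRUE, count_type = tok[3L], type = tok[4L])
      } else {
        elements[[cur]]$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
      }
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY must declare vertex and face elements")

  if (fmt == "ascii") {
    dat <- read_ply_ascii(con, elements)
  } else {
    dat <- read_ply_binary(con, elements)
  }
  if (raw) return(dat)
  v <- dat$vertex[, c("x", "y", "z"), drop = FALSE]
  triangle_mesh(v, dat$faces)
}

ply_type_info <- function(type) {
  switch(type,
    "char" = , "int8" = list(what = integer(), size = 1L, signed = TRUE),
    "uchar" = , "uint8" = list(what = integer(), size = 1L, signed = FALSE),
    "short" = , "int16" = list(what = integer(), size = 2L, signed = TRUE),
    "ushort" = , "uint16" = list(what = integer(), size = 2L, signed = FALSE),
    "int" = , "int32" = list(what = integer(), size = 4L, signed = TRUE),
    "uint" = , "uint32" = list(what = integer(), size = 4L, signed = TRUE),
    "float" = , "float32" = list(what = numeric(), size = 4L, signed = TRUE),
    "double" = , "float64" = list(what = numeric(), size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type))
}

read_ply_ascii <- function(con, elements) {
  out <- list()
  for (en in names(elements)) {
    el <- elements[[en]]
    lines <- readLines(con, n = el$count)
    toks <- strsplit(trimws(lines), "\\s+")
    if (en == "vertex") {
      pn <- names(el$props)
      m <- t(vapply(toks, function(t) as.numeric(t[seq_along(pn)]),
                    numeric(length(pn))))
      colnames(m) <- pn
      out$vertex <- m
    } else if (en == "face") {
      faces <- lapply(toks, function(t) {
        cnt <- as.integer(t[1L])
        if (cnt != 3L) stop("non-triangular face in PLY (count ", cnt, ")")
        as.integer(t[2:4]) + 1L
      })
      out$faces <- do.call(rbind, faces)
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  for (en in names(elements)) {
    el <- elements[[en]]
    if (en == "vertex") {
      pn <- names(el$props)
      m <- matrix(NA_real_, el$count, length(pn), dimnames = list(NULL, pn))
      for (i in seq_len(el$count)) {
        for (j in seq_along(pn)) {
          ti <- ply_type_info(el$props[[j]]$type)
          m[i, j] <- readBin(con, ti$what, n = 1L, size = ti$size,
                             endian = "little", signed = ti$signed)
        }
      }
      out$vertex <- m
    } else if (en == "face") {
      p <- el$props[[1L]]
      if (!p$list) stop("PLY face element must use a list property")
      ct <- ply_type_info(p$count_type); it <- ply_type_info(p$type)
      faces <- matrix(NA_integer_, el$count, 3L)
      for (i in seq_len(el$count)) {
        cnt <- readBin(con, ct$what, n = 1L, size = ct$size,
                       endian = "little", signed = ct$signed)
        if (cnt != 3L) stop("non-triangular face in PLY (count ", cnt, ")")
        faces[i, ] <- readBin(con, it$what, n = 3L, size = it$size,
                              endian = "little", signed = it$signed) + 1L
      }
      out$faces <- faces
    } else {
      # skip unknown fixed-size elements
      sz <- sum(vapply(el$props, function(p) ply_type_info(p$type)$size, 0))
      readBin(con, raw(), n = sz * el$count)
    }
  }
  out
}

write_ply <- function(mesh, path, binary = FALSE, displacement = NULL) {
  v <- mesh$vertices
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    if (!all(dim(displacement) == dim(v)))
      stop("displacement must be an n x 3 matrix matching the vertices")
  }
  props <- c("x", "y", "z", if (!is.null(displacement)) c("ux", "uy", "uz"))
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(v)),
    sprintf("property double %s", props),
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header")
  vdat <- if (is.null(displacement)) v else cbind(v, displacement)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    writeBin(as.vector(t(vdat)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nrow(f0))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    vtxt <- apply(vdat, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " "))
    ftxt <- paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                  mesh$faces[, 3L] - 1L)
    writeChar(paste0(paste(c(vtxt, ftxt), collapse = "\n"), "\n"), con,
              eos = NULL)
  }
  invisible(path)
}

# ---- STL ---------------------------------------------------------------

read_stl <- function(path) {
  raw <- readBin(path, raw(), n = file.size(path))
  is_ascii <- length(raw) >= 5L &&
    identical(rawToChar(raw[1:5]), "solid") &&
    # binary files may also start with "solid"; check for "facet" in text
    grepl("facet", rawToChar(raw[seq_len(min(1000L, length(raw)))]),
          fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(raw)
  stl_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) stop("malformed ASCII STL: ", path)
  coords <- t(vapply(strsplit(vlines, "\\s+"),
                     function(t) as.numeric(t[2:4]), numeric(3L)))
  coords
}

read_stl_binary <- function(raw) {
  if (length(raw) < 84L) stop("truncated binary STL")
  n_tri <- readBin(raw[81:84], integer(), size = 4L, endian = "little")
  need <- 84L + n_tri * 50L
  if (length(raw) < need) stop("truncated binary STL")
  body <- raw[85:need]
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  m <- matrix(NA_real_, n_tri * 3L, 3L)
  for (i in seq_len(n_tri)) {
    off <- (i - 1L) * 50L
    vals <- readBin(body[(off + 1L):(off + 48L)], numeric(), n = 12L,
                    size = 4L, endian = "little")
    m[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  m
}

# Merge per-facet vertex records by exact coordinate match.
stl_to_mesh <- function(coords) {
  key <- paste(coords[, 1L], coords[, 2L], coords[, 3L], sep = "_")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  fn <- face_normals(mesh)$normal
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.vector(t(rbind(fn[i, ], v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    out <- c("solid mesh")
    for (i in seq_len(nrow(f))) {
      out <- c(out,
        sprintf("facet normal %.9g %.9g %.9g", fn[i, 1L], fn[i, 2L], fn[i, 3L]),
        "outer loop",
        sprintf("vertex %.17g %.17g %.17g",
                v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
        "endloop", "endfacet")
    }
    writeLines(c(out, "endsolid mesh"), path)
  }
  invisible(path)
}
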