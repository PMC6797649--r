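#' Triangle surface meshes
#'
#' A `triangle_mesh` is the package's universal currency: a closed, triangulated
#' surface with vertices in millimetres. It is a plain list with a `vertices`
#' numeric matrix (n x 3), an integer `faces` matrix (m x 3, 1-based), and a
#' cached `normals` matrix of per-vertex unit normals.
#'
#' On construction, vertices not referenced by any face are dropped, face
#' indices are validated, and -- when the mesh is closed -- faces are reoriented
#' so that the signed volume is positive (outward normals).
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param orient if `TRUE` (default) and the mesh is closed, flip the winding
#'   so the enclosed signed volume is positive.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix (triangles only)")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  # drop unreferenced vertices, remapping faces
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3L)
  }
  m <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                 class = "triangle_mesh")
  if (orient && is_closed(m) && signed_volume_mm3(m) < 0) {
    m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  m$normals <- compute_vertex_normals(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_closed(x)) " (closed)" else ""))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param x object to test.
#' @export
is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Number of vertices / faces of a mesh
#' @param mesh a `triangle_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Undirected edge list as a 2-column matrix with first column < second.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# Count of faces incident to each undirected edge.
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  table(key)
}

#' Is the mesh a closed (watertight) surface?
#'
#' Checks that every undirected edge borders exactly two faces and that the
#' Euler characteristic V - E + F equals 2 (genus-0 sphere topology).
#'
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
is_closed <- function(mesh) {
  cnt <- edge_face_counts(mesh)
  if (any(cnt != 2L)) return(FALSE)
  v <- nrow(mesh$vertices); e <- length(cnt); f <- nrow(mesh$faces)
  (v - e + f) == 2L
}

#' One-ring vertex adjacency
#'
#' @param mesh a `triangle_mesh`.
#' @return a list of length `n_vertices(mesh)`; element `i` is the sorted
#'   integer vector of one-ring neighbours of vertex `i`.
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- split(c(e[, 2L], e[, 1L]), factor(c(e[, 1L], e[, 2L]),
                                           levels = seq_len(nrow(mesh$vertices))))
  lapply(adj, function(v) sort(unique(v)))
}

# Sparse uniform graph Laplacian L = D - A (Matrix::sparseMatrix), with
# optional per-edge weights. omega is a function(i, j, mesh) -> weight or a
# single scalar; the default 1.0 matches the uniform-weight protocol.
laplacian_matrix <- function(mesh, omega = 1.0) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  if (is.function(omega)) {
    w <- omega(e[, 1L], e[, 2L], mesh)
  } else {
    w <- rep(as.numeric(omega), nrow(e))
  }
  i <- c(e[, 1L], e[, 2L]); j <- c(e[, 2L], e[, 1L]); w2 <- c(w, w)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w2, dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Discrete uniform-weight Laplacian of a per-vertex field
#'
#' Computes `L(f)_i = sum_{j in N(i)} w_ij (f_i - f_j)` with one-ring
#' neighbourhoods. Applied to vertex positions this is the discrete
#' mean-curvature-normal descriptor; applied to a displacement field it is the
#' differential displacement field whose magnitude measures deformation
#' smoothness.
#'
#' @param mesh a `triangle_mesh`.
#' @param field numeric matrix (n x k) or vector of length n, one row per
#'   vertex. Defaults to the vertex positions.
#' @param omega edge weight: a scalar (default 1.0) or a
#'   `function(i, j, mesh)` returning one weight per edge.
#' @return matrix of the same shape as `field`.
#' @export
discrete_laplacian <- function(mesh, field = mesh$vertices, omega = 1.0) {
  vec <- is.null(dim(field))
  f <- if (vec) matrix(field, ncol = 1L) else as.matrix(field)
  if (nrow(f) != nrow(mesh$vertices))
    stop("field length must equal the vertex count of its mesh")
  L <- laplacian_matrix(mesh, omega)
  out <- as.matrix(L %*% f)
  if (vec) drop(out) else out
}

#' Mean incident-edge length per vertex
#'
#' `l_s`: the arithmetic mean of the Euclidean lengths of all edges incident to
#' each vertex, used as the progressive-search step scale.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex optional single vertex index; if omitted, all vertices.
#' @return numeric vector (mm), one value per requested vertex.
#' @export
mean_edge_length <- function(mesh, vertex = NULL) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  s <- as.vector(rowsum(c(len, len), c(e[, 1L], e[, 2L]),
                        reorder = TRUE))
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  if (any(deg == 0L)) stop("isolated vertex: no incident edges")
  out <- s / deg
  if (is.null(vertex)) out else out[vertex]
}

# Per-face unit normals and (doubled) face areas.
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  a2 <- sqrt(rowSums(cr^2))          # twice the face area
  list(normal = cr / pmax(a2, .Machine$double.eps), area2 = a2, cross = cr)
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals (the unnormalised face cross
#' products accumulate, which weights by face area), then normalised.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric matrix (n x 3) of unit normals.
#' @export
compute_vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  n <- nrow(mesh$vertices)
  acc <- matrix(0, n, 3L)
  for (k in 1:3) {
    s <- rowsum(fn$cross, mesh$faces[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  nrm <- sqrt(rowSums(acc^2))
  acc / pmax(nrm, .Machine$double.eps)
}

# Refresh the cached normals after moving vertices (topology unchanged).
update_normals <- function(mesh) {
  mesh$normals <- compute_vertex_normals(mesh)
  mesh
}

# Signed enclosed volume in mm^3 (divergence theorem, tetrahedra to origin).
signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
      a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
      a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

#' Bounding-box diagonal of a mesh (mm)
#' @param mesh a `triangle_mesh`.
#' @return numeric scalar.
#' @export
bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2L, range)
  sqrt(sum((r[2L, ] - r[1L, ])^2))
}

#' Replace the vertex positions of a mesh (topology preserved)
#' @param mesh a `triangle_mesh`.
#' @param vertices new n x 3 coordinate matrix.
#' @return a `triangle_mesh` with refreshed normals.
#' @export
set_vertices <- function(mesh, vertices) {
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == dim(mesh$vertices)))
    stop("replacement vertices must match the mesh dimensions")
  mesh$vertices <- vertices
  update_normals(mesh)
}
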