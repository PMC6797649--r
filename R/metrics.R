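# Surface-distance and smoothness metrics used to score registrations, plus
# the lobe volume summaries.

# Closest point on one triangle for each query point (vectorised over
# points). Classic region-based closest-point-on-triangle (Voronoi regions
# of the triangle): returns squared distances and the closest points.
point_triangle_closest <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a
  ap <- sweep(p, 2L, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(p, 2L, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp <- sweep(p, 2L, cc)
  d5 <- cp %*% ab; d6 <- cp %*% ac
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc

  n <- nrow(p)
  q <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  set_q <- function(idx, pts) {
    if (any(idx)) { q[idx, ] <<- pts; done[idx] <<- TRUE }
  }
  # vertex regions
  set_q(!done & d1 <= 0 & d2 <= 0, matrix(a, sum(!done & d1 <= 0 & d2 <= 0), 3L, byrow = TRUE))
  i <- !done & d3 >= 0 & d4 <= d3
  set_q(i, matrix(b, sum(i), 3L, byrow = TRUE))
  i <- !done & d6 >= 0 & d5 <= d6
  set_q(i, matrix(cc, sum(i), 3L, byrow = TRUE))
  # edge AB
  i <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(i)) {
    t <- d1[i] / (d1[i] - d3[i])
    set_q(i, matrix(a, sum(i), 3L, byrow = TRUE) + t %o% ab)
  }
  # edge AC
  i <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(i)) {
    t <- d2[i] / (d2[i] - d6[i])
    set_q(i, matrix(a, sum(i), 3L, byrow = TRUE) + t %o% ac)
  }
  # edge BC
  i <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(i)) {
    t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    set_q(i, matrix(b, sum(i), 3L, byrow = TRUE) + t %o% (cc - b))
  }
  # interior
  i <- !done
  if (any(i)) {
    v <- vb[i] / denom[i]; w <- vc[i] / denom[i]
    set_q(i, matrix(a, sum(i), 3L, byrow = TRUE) + v %o% ab + w %o% ac)
  }
  list(d2 = rowSums((p - q)^2), q = q)
}

#' Distance from points to a mesh surface
#'
#' Exact point-to-triangle proximity: for each query point, the Euclidean
#' distance to the nearest point anywhere on the mesh surface (not just its
#' vertices), so coarse and fine meshes are scored fairly.
#'
#' @param points numeric matrix (k x 3) of query points (mm).
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of k distances (mm).
#' @export
surface_distance <- function(points, mesh) {
  closest_point_on_surface(points, mesh)$distance
}

#' Closest point on a mesh surface
#'
#' Exact closest point anywhere on the triangulated surface (faces, edges or
#' vertices) for each query point, by a full scan over triangles -- cheap at
#' the few-hundred-face scale this package works at.
#'
#' @param points numeric matrix (k x 3) of query points (mm).
#' @param mesh a `triangle_mesh`.
#' @return list with `point` (k x 3 closest points) and `distance` (k).
#' @export
closest_point_on_surface <- function(points, mesh) {
  points <- rbind(points)
  v <- mesh$vertices; f <- mesh$faces
  best <- rep(Inf, nrow(points))
  bq <- matrix(NA_real_, nrow(points), 3L)
  for (i in seq_len(nrow(f))) {
    r <- point_triangle_closest(points, v[f[i, 1L], ], v[f[i, 2L], ],
                                v[f[i, 3L], ])
    upd <- r$d2 < best
    if (any(upd)) {
      best[upd] <- r$d2[upd]
      bq[upd, ] <- r$q[upd, , drop = FALSE]
    }
  }
  list(point = bq, distance = sqrt(best))
}

# Pairwise kernel: closest point on triangle (A_r, B_r, C_r) to point P_r,
# fully vectorised over rows. All arguments are M x 3 matrices.
pt_tri_kernel <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- P - A; bp <- P - B; cp <- P - C
  d1 <- rowSums(ap * ab); d2 <- rowSums(ap * ac)
  d3 <- rowSums(bp * ab); d4 <- rowSums(bp * ac)
  d5 <- rowSums(cp * ab); d6 <- rowSums(cp * ac)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  m <- nrow(P)
  q <- matrix(NA_real_, m, 3L)
  done <- rep(FALSE, m)
  put <- function(i, pts) {
    if (any(i)) { q[i, ] <<- pts; done[i] <<- TRUE }
  }
  i <- !done & d1 <= 0 & d2 <= 0; put(i, A[i, , drop = FALSE])
  i <- !done & d3 >= 0 & d4 <= d3; put(i, B[i, , drop = FALSE])
  i <- !done & d6 >= 0 & d5 <= d6; put(i, C[i, , drop = FALSE])
  i <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(i)) {
    t <- d1[i] / (d1[i] - d3[i])
    put(i, A[i, , drop = FALSE] + t * ab[i, , drop = FALSE])
  }
  i <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(i)) {
    t <- d2[i] / (d2[i] - d6[i])
    put(i, A[i, , drop = FALSE] + t * ac[i, , drop = FALSE])
  }
  i <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(i)) {
    t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    put(i, B[i, , drop = FALSE] + t * (C - B)[i, , drop = FALSE])
  }
  i <- !done
  if (any(i)) {
    v <- vb[i] / denom[i]; w <- vc[i] / denom[i]
    put(i, A[i, , drop = FALSE] + v * ab[i, , drop = FALSE] +
           w * ac[i, , drop = FALSE])
  }
  list(d2 = rowSums((P - q)^2), q = q)
}

# Precompute, per target vertex, the triangles incident to it or to any of
# its one-ring neighbours -- the candidate set for pruned closest-point
# queries whose nearest vertex is that vertex.
cp_cache <- function(mesh) {
  nf <- nrow(mesh$faces)
  vf <- split(rep(seq_len(nf), 3L), as.vector(mesh$faces))
  adj <- vertex_adjacency(mesh)
  cand <- lapply(seq_along(adj), function(i)
    unique(unlist(vf[c(i, adj[[i]])], use.names = FALSE)))
  list(cand = cand,
       A = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       B = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       C = mesh$vertices[mesh$faces[, 3L], , drop = FALSE],
       v = mesh$vertices)
}

# Fast closest point: only triangles around each query's nearest target
# vertex are tested, which is exact for well-shaped meshes. Used inside ICP
# loops; the scored metrics use the exhaustive closest_point_on_surface.
closest_point_pruned <- function(points, mesh, cache = NULL) {
  if (is.null(cache)) cache <- cp_cache(mesh)
  v <- cache$v
  d2 <- outer(rowSums(points^2), rowSums(v^2), "+") - 2 * points %*% t(v)
  nn1 <- max.col(-d2, ties.method = "first")
  cand <- cache$cand[nn1]
  len <- lengths(cand)
  pidx <- rep(seq_len(nrow(points)), len)
  tris <- unlist(cand, use.names = FALSE)
  r <- pt_tri_kernel(points[pidx, , drop = FALSE],
                     cache$A[tris, , drop = FALSE],
                     cache$B[tris, , drop = FALSE],
                     cache$C[tris, , drop = FALSE])
  # argmin per point: order by (point, distance), keep first per point
  o <- order(pidx, r$d2)
  first <- o[!duplicated(pidx[o])]
  list(point = r$q[first, , drop = FALSE], distance = sqrt(r$d2[first]))
}

#' Mean surface distance between two meshes (mm)
#'
#' Symmetric: the average, over both directions, of each vertex's distance to
#' the nearest point on the other mesh's surface.
#'
#' @param a,b `triangle_mesh` objects.
#' @return numeric scalar (mm).
#' @export
mean_distance <- function(a, b) {
  d_ab <- surface_distance(a$vertices, b)
  d_ba <- surface_distance(b$vertices, a)
  mean(c(d_ab, d_ba))
}

#' Hausdorff distance between two meshes (mm)
#'
#' Symmetric Hausdorff: the largest of all vertex-to-nearest-surface
#' distances, taken over both directions.
#'
#' @param a,b `triangle_mesh` objects.
#' @return numeric scalar (mm).
#' @export
hausdorff_distance <- function(a, b) {
  max(surface_distance(a$vertices, b), surface_distance(b$vertices, a))
}

#' Smoothness of a displacement field: Laplacian magnitude statistics
#'
#' Per-vertex magnitude of the uniform-weight discrete Laplacian of the
#' displacement field; its mean and maximum summarise how smooth (locally
#' affine) the recovered deformation is.
#'
#' @param mesh a `triangle_mesh`.
#' @param u numeric matrix (n x 3) displacement field on `mesh` (mm).
#' @return named numeric vector `c(mean = ..., max = ...)` (mm).
#' @export
displacement_laplacian_stats <- function(mesh, u) {
  lu <- discrete_laplacian(mesh, u)
  mag <- sqrt(rowSums(lu^2))
  c(mean = mean(mag), max = max(mag))
}

#' Target displacement error (mm)
#'
#' Euclidean norm of the difference between an estimated and a ground-truth
#' displacement vector at an evaluation point.
#'
#' @param u_true,u_est numeric 3-vectors (mm).
#' @return numeric scalar (mm).
#' @export
target_displacement_error <- function(u_true, u_est) {
  sqrt(sum((u_est - u_true)^2))
}

#' Enclosed volume of a closed mesh in cubic centimetres
#'
#' Divergence-theorem volume (sum of signed tetrahedra to the origin), made
#' absolute so the result is orientation-independent, and converted from
#' cubic millimetres to cc.
#'
#' @param mesh a closed `triangle_mesh` with coordinates in mm.
#' @return numeric scalar (cc).
#' @export
lobe_volume <- function(mesh) {
  if (!is_closed(mesh)) stop("lobe_volume requires a closed mesh")
  abs(signed_volume_mm3(mesh)) / 1000
}

#' Deflated-to-inflated volume ratio in percent
#'
#' @param v_inflated inflated-state volume (cc), must be positive.
#' @param v_deflated deflated-state volume (cc).
#' @return `100 * v_deflated / v_inflated`.
#' @export
volume_ratio <- function(v_inflated, v_deflated) {
  if (any(v_inflated <= 0)) stop("inflated volume must be positive")
  100 * v_deflated / v_inflated
}

#' Mean and sample SD of a per-case metric column
#'
#' @param x numeric vector of per-case values (length >= 2).
#' @return named numeric vector `c(mean = ..., sd = ...)`; the SD uses the
#'   sample (n - 1) convention.
#' @export
summarize_table <- function(x) {
  if (length(x) < 2L) stop("need at least two values")
  c(mean = mean(x), sd = stats::sd(x))
}

#' Full metric report for a registered pair
#'
#' @param registered the registered model mesh.
#' @param target the target surface it was matched to.
#' @param u displacement field on the registered mesh (mm), optional.
#' @return a list with `mean_distance`, `hausdorff`, and (when `u` is given)
#'   `ld_mean` / `ld_max`.
#' @export
metric_report <- function(registered, target, u = NULL) {
  rep <- list(mean_distance = mean_distance(registered, target),
              hausdorff = hausdorff_distance(registered, target))
  if (!is.null(u)) {
    ld <- displacement_laplacian_stats(registered, u)
    rep$ld_mean <- unname(ld["mean"])
    rep$ld_max <- unname(ld["max"])
  }
  rep
}
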