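# Quadric-guided iterative edge collapse to an exact vertex count.
#
# Cheap variant of quadric-error-metric simplification: per-vertex plane
# quadrics accumulate under collapse, the collapse position is the best of
# {v_i, v_j, midpoint} under the pooled quadric, and collapses that would
# break the manifold link condition or flip a face normal are rejected.

# per-vertex quadrics as an n x 10 matrix:
# (a11,a12,a13,a22,a23,a33,b1,b2,b3,c), area-weighted plane quadrics
vertex_quadrics <- function(mesh) {
  fn <- face_normals(mesh)
  n <- fn$normal; w <- fn$area2 / 2
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  d <- -rowSums(n * v1)
  K <- cbind(n[, 1L]^2, n[, 1L] * n[, 2L], n[, 1L] * n[, 3L],
             n[, 2L]^2, n[, 2L] * n[, 3L], n[, 3L]^2,
             n[, 1L] * d, n[, 2L] * d, n[, 3L] * d, d^2) * w
  acc <- matrix(0, nrow(mesh$vertices), 10L)
  for (k in 1:3) {
    s <- rowsum(K, mesh$faces[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  acc
}

quadric_error <- function(q, p) {
  # q: length-10 quadric; p: k x 3 candidate positions
  p1 <- p[, 1L]; p2 <- p[, 2L]; p3 <- p[, 3L]
  q[1L] * p1^2 + 2 * q[2L] * p1 * p2 + 2 * q[3L] * p1 * p3 +
    q[4L] * p2^2 + 2 * q[5L] * p2 * p3 + q[6L] * p3^2 +
    2 * (q[7L] * p1 + q[8L] * p2 + q[9L] * p3) + q[10L]
}

#' Resample a closed mesh to an exact vertex count
#'
#' Coarsens a closed genus-0 mesh to exactly `n_vertices` vertices (hence
#' `2 * n_vertices - 4` faces) by iterative edge collapse, choosing at each
#' step the collapse with smallest quadric shape error among the candidate
#' positions (either endpoint or the edge midpoint). Collapses violating the
#' manifold link condition or flipping a face normal are skipped, so the
#' output remains a closed manifold.
#'
#' @param mesh a closed `triangle_mesh` with at least `n_vertices` vertices.
#' @param n_vertices target vertex count (>= 4).
#' @return a closed `triangle_mesh` with exactly `n_vertices` vertices.
#' @export
resample_to <- function(mesh, n_vertices) {
  if (n_vertices < 4L) stop("n_vertices must be at least 4")
  if (nrow(mesh$vertices) < n_vertices)
    stop("mesh has fewer vertices than the requested count")
  if (nrow(mesh$vertices) == n_vertices) return(mesh)

  V <- mesh$vertices
  Fc <- mesh$faces
  nv <- nrow(V); nf <- nrow(Fc)
  v_alive <- rep(TRUE, nv); f_alive <- rep(TRUE, nf)
  Q <- vertex_quadrics(mesh)
  adj <- vertex_adjacency(mesh)
  vf <- split(rep(seq_len(nf), 3L), as.vector(Fc))  # vertex -> incident faces
  vf <- lapply(vf, as.integer)

  e <- mesh_edges(mesh)
  ea <- e[, 1L]; eb <- e[, 2L]
  ne <- length(ea)
  cost <- numeric(ne)
  place <- matrix(0, ne, 3L)

  score_edge <- function(i, j) {
    qq <- Q[i, ] + Q[j, ]
    cand <- rbind(V[i, ], V[j, ], (V[i, ] + V[j, ]) / 2)
    err <- quadric_error(qq, cand)
    k <- which.min(err)
    list(cost = err[k], p = cand[k, ])
  }
  for (k in seq_len(ne)) {
    s <- score_edge(ea[k], eb[k])
    cost[k] <- s$cost; place[k, ] <- s$p
  }

  tri_normal <- function(a, b, cc) {
    u <- b - a; w <- cc - a
    c(u[2L] * w[3L] - u[3L] * w[2L],
      u[3L] * w[1L] - u[1L] * w[3L],
      u[1L] * w[2L] - u[2L] * w[1L])
  }

  collapse_valid <- function(i, j, p) {
    shared <- intersect(vf[[i]], vf[[j]])
    shared <- shared[f_alive[shared]]
    if (length(shared) != 2L) return(NULL)
    opp <- setdiff(as.vector(Fc[shared, ]), c(i, j))
    common <- intersect(adj[[i]], adj[[j]])
    if (!setequal(common, opp) || length(opp) != 2L) return(NULL)
    # normal-flip / degeneracy check on surviving incident faces
    ring <- setdiff(union(vf[[i]], vf[[j]]), shared)
    ring <- ring[f_alive[ring]]
    for (fi in ring) {
      tri <- Fc[fi, ]
      old <- tri_normal(V[tri[1L], ], V[tri[2L], ], V[tri[3L], ])
      vs <- lapply(tri, function(t) if (t == i || t == j) p else V[t, ])
      new <- tri_normal(vs[[1L]], vs[[2L]], vs[[3L]])
      nn <- sqrt(sum(new^2))
      if (nn < 1e-12 || sum(old * new) <= 0) return(NULL)
    }
    shared
  }

  alive_count <- nv
  while (alive_count > n_vertices) {
    k <- which.min(cost)
    if (!is.finite(cost[k]))
      stop("decimation stalled: no valid edge collapse remains")
    i <- ea[k]; j <- eb[k]; p <- place[k, ]
    shared <- collapse_valid(i, j, p)
    if (is.null(shared)) { cost[k] <- Inf; next }

    # collapse j into i at position p
    V[i, ] <- p
    Q[i, ] <- Q[i, ] + Q[j, ]
    f_alive[shared] <- FALSE
    moved <- setdiff(vf[[j]], shared)
    moved <- moved[f_alive[moved]]
    for (fi in moved) Fc[fi, ][Fc[fi, ] == j] <- i
    vf[[i]] <- unique(c(setdiff(vf[[i]], shared), moved))
    vf[[j]] <- integer()
    new_nb <- setdiff(sort(unique(c(adj[[i]], adj[[j]]))), c(i, j))
    for (t in adj[[j]]) {
      if (t == i) next
      a <- adj[[t]]
      a[a == j] <- i
      adj[[t]] <- sort(unique(a))
    }
    adj[[i]] <- new_nb
    adj[[j]] <- integer()
    v_alive[j] <- FALSE
    alive_count <- alive_count - 1L

    # retire edges touching j; rescore edges touching i
    touch_j <- which((ea == j | eb == j))
    cost[touch_j] <- Inf
    # ensure every surviving neighbour of i has exactly one live edge to i
    for (t in new_nb) {
      a <- min(i, t); b <- max(i, t)
      hits <- which(ea == a & eb == b & is.finite(cost))
      if (length(hits) == 0L) {
        ea <- c(ea, a); eb <- c(eb, b)
        s <- score_edge(a, b)
        cost <- c(cost, s$cost); place <- rbind(place, s$p)
      } else {
        if (length(hits) > 1L) cost[hits[-1L]] <- Inf
        s <- score_edge(a, b)
        cost[hits[1L]] <- s$cost; place[hits[1L], ] <- s$p
      }
    }
  }

  keep <- which(v_alive)
  triangle_mesh(V[keep, , drop = FALSE],
                matrix(match(Fc[f_alive, ], keep), ncol = 3L))
}
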