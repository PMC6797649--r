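# Shared fixtures: small exact meshes and dense (independent-path) oracles.

# regular tetrahedron, edge sqrt(8)/sqrt(2)... built on unit cube corners:
# edge length sqrt(8) scaled; use unit-edge version where needed
tetra_mesh <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (edge / (2 * sqrt(2)))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  triangle_mesh(v, f)
}

cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = edge
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = edge
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = edge
  triangle_mesh(v, f)
}

icosahedron_mesh <- function() {
  s <- lobematch:::icosahedron()
  triangle_mesh(s$vertices, s$faces)
}

icosphere_mesh <- function(subdiv = 2, radius = 1) {
  s <- lobematch:::icosphere(subdiv)
  triangle_mesh(s$vertices * radius, s$faces)
}

# square-pyramid cap: apex over a 4-neighbour ring (open mesh, apex = v1)
pyramid_mesh <- function() {
  v <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2))
  triangle_mesh(v, f, orient = FALSE)
}

# random closed mesh: jittered icosphere (star-shaped, stays valid)
random_closed_mesh <- function(seed, subdiv = 1, radius = 10) {
  set.seed(seed)
  s <- lobematch:::icosphere(subdiv)
  r <- radius * (1 + 0.15 * stats::runif(nrow(s$vertices), -1, 1))
  triangle_mesh(s$vertices * r, s$faces)
}

# dense uniform graph Laplacian (degree - adjacency), independent of the
# package's sparse construction
dense_laplacian <- function(mesh) {
  n <- nrow(mesh$vertices)
  A <- matrix(0, n, n)
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    e <- rbind(f[k, c(1, 2)], f[k, c(2, 3)], f[k, c(3, 1)])
    A[e] <- 1
    A[e[, c(2, 1)]] <- 1
  }
  diag(rowSums(A)) - A
}

# dense least-squares oracle for the constrained Laplacian solve:
# stacked system [L; sqrt(delta) S] v = [L v0; sqrt(delta) p]
dense_solve_oracle <- function(mesh, constraints, delta) {
  L <- dense_laplacian(mesh)
  n <- nrow(L)
  S <- matrix(0, length(constraints$index), n)
  S[cbind(seq_along(constraints$index), constraints$index)] <- 1
  A <- rbind(L, sqrt(delta) * S)
  b <- rbind(L %*% mesh$vertices, sqrt(delta) * constraints$p)
  qr.solve(A, b)
}
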