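#' Registration configuration
#'
#' Collects the tunable parameters of the Laplacian-based shape matching
#' loop. Defaults follow the published protocol: uniform Laplacian weights,
#' positional-constraint weight `delta = 10`, normal-compatibility weight
#' `gamma = 1` in the similarity index, displacement-smoothing step
#' `lambda = 1`, and per-iteration similarity thresholds taken as the mean of
#' the top 10% (Q_high) and bottom 2% (Q_low) of the current Q distribution.
#'
#' @param delta positional-constraint weight in the quadratic objective (> 0).
#' @param gamma weight of the normal term in the similarity index Q (>= 0).
#' @param lambda step applied to the Laplacian of the displacement field when
#'   smoothing constraint anchors (>= 0).
#' @param m progressive-search step constant: pull constraints advance a
#'   fraction `l_s / m` of the way to the projected target (>= 1).
#' @param q_high_fraction,q_low_fraction fractions of the Q distribution
#'   averaged to form the pull / anchor thresholds.
#' @param max_iterations hard cap on surface updates.
#' @param stall_window stop when the best max inter-surface distance has not
#'   improved for this many consecutive updates.
#' @param rng_seed seed used by seeded sub-steps (piecewise-affine k-means).
#' @return a list of class `registration_config`.
#' @export
registration_config <- function(delta = 10.0, gamma = 1.0, lambda = 1.0,
                                m = 2.0, q_high_fraction = 0.10,
                                q_low_fraction = 0.02,
                                max_iterations = 3000L, stall_window = 10L,
                                rng_seed = 1L) {
  stopifnot(delta > 0, gamma >= 0, lambda >= 0, m >= 1,
            q_low_fraction > 0, q_low_fraction < q_high_fraction,
            q_high_fraction < 1, max_iterations >= 1, stall_window >= 1)
  structure(list(delta = delta, gamma = gamma, lambda = lambda, m = m,
                 q_high_fraction = q_high_fraction,
                 q_low_fraction = q_low_fraction,
                 max_iterations = as.integer(max_iterations),
                 stall_window = as.integer(stall_window),
                 rng_seed = as.integer(rng_seed)),
            class = "registration_config")
}

# Closed-form least-squares 3x4 affine (linear part + translation) from known
# point pairs: minimises ||X B - Y||_F over B.
affine_fit <- function(x, y) {
  X <- cbind(x, 1)
  qx <- qr(X)
  if (qx$rank < 4L) stop("degenerate geometry: affine system is rank-deficient")
  B <- qr.coef(qx, y)     # 4 x 3
  t(B)                    # 3 x 4: [A | t]
}

apply_affine <- function(B, x) {
  x %*% t(B[, 1:3, drop = FALSE]) +
    matrix(B[, 4L], nrow(x), 3L, byrow = TRUE)
}

# index of nearest row of `to` for each row of `from` (exhaustive)
nearest_vertex <- function(from, to) {
  d2 <- outer(rowSums(from^2), rowSums(to^2), "+") - 2 * from %*% t(to)
  max.col(-d2, ties.method = "first")
}

#' Affine pre-alignment by iterated closest points
#'
#' Iterates closest-point-on-surface correspondence and closed-form affine
#' least squares until the fit stops improving. Matching against the target
#' surface (rather than its vertices) avoids the tangential quantisation
#' bias of vertex-to-vertex ICP on coarse meshes. Used to globally match
#' posture and volume before (and as a baseline for) non-rigid matching.
#'
#' @param source,target `triangle_mesh` objects.
#' @param max_iter iteration cap.
#' @param tol relative RMS improvement below which the loop stops.
#' @return a list with `transform` (3 x 4 matrix), `mesh` (transformed
#'   source) and `rms` (final RMS closest-point distance).
#' @export
affine_align <- function(source, target, max_iter = 100L, tol = 1e-7) {
  x <- source$vertices
  B <- icp_points(x, target, max_iter = max_iter, tol = tol)
  cur <- apply_affine(B, x)
  cp <- closest_point_on_surface(cur, target)
  list(transform = B, mesh = set_vertices(source, cur),
       rms = sqrt(mean(cp$distance^2)))
}

#' Local shape similarity between two oriented points
#'
#' `Q = |v_s - v_t| + gamma * (1 - n_s . n_t)`: Euclidean distance plus a
#' penalty for incompatible normals. Zero iff the points coincide with
#' identical normals.
#'
#' @param v_s,v_t 3D positions (mm).
#' @param n_s,n_t unit normals.
#' @param gamma normal-term weight.
#' @return similarity value Q (mm; lower is more similar).
#' @export
local_similarity <- function(v_s, n_s, v_t, n_t, gamma = 1.0) {
  sqrt(sum((v_s - v_t)^2)) + gamma * (1 - sum(n_s * n_t))
}

# Full n_s x n_t matrices of Q and plain Euclidean distance.
similarity_matrices <- function(vs, ns, vt, nt, gamma) {
  d2 <- outer(rowSums(vs^2), rowSums(vt^2), "+") - 2 * vs %*% t(vt)
  D <- sqrt(pmax(d2, 0))
  Q <- D + gamma * (1 - ns %*% t(nt))
  list(Q = Q, D = D)
}

#' Exhaustive best-match search under the similarity index
#'
#' Evaluates Q for every (template vertex, target vertex) pair and returns,
#' per template vertex, the exact argmin (ties broken by lowest target
#' index).
#'
#' @param template,target `triangle_mesh` objects with cached normals.
#' @param gamma normal-term weight.
#' @return a list with integer `match` (target index per template vertex),
#'   numeric `q` (the minimised Q values) and `dist` (Euclidean distance to
#'   the nearest target *vertex*, used for the termination criterion).
#' @export
correspondence_search <- function(template, target, gamma = 1.0) {
  if (n_vertices(target) < 1L) stop("empty target mesh")
  sm <- similarity_matrices(template$vertices, template$normals,
                            target$vertices, target$normals, gamma)
  match <- max.col(-sm$Q, ties.method = "first")
  q <- sm$Q[cbind(seq_along(match), match)]
  dist <- apply(sm$D, 1L, min)
  list(match = match, q = q, dist = dist)
}

#' Pull / anchor similarity thresholds from a Q distribution
#'
#' `Q_high` is the mean of the `ceiling(q_high_fraction * n)` largest values
#' and `Q_low` the mean of the `ceiling(q_low_fraction * n)` smallest.
#' Vertices above `Q_high` are pulled toward the target; vertices below
#' `Q_low` are anchored in place; the band in between is left free.
#'
#' @param q_values numeric vector of per-vertex Q values.
#' @param q_high_fraction,q_low_fraction tail fractions (defaults 0.10, 0.02).
#' @return named numeric vector `c(q_high = ..., q_low = ...)`.
#' @export
similarity_thresholds <- function(q_values, q_high_fraction = 0.10,
                                  q_low_fraction = 0.02) {
  n <- length(q_values)
  if (n < 1L) stop("empty Q vector")
  s <- sort(q_values)
  k_hi <- ceiling(q_high_fraction * n)
  k_lo <- ceiling(q_low_fraction * n)
  c(q_high = mean(s[(n - k_hi + 1L):n]), q_low = mean(s[seq_len(k_lo)]))
}

# Positional constraints per the progressive rule. Returns a list with
# integer `index`, matrix `p`, and the flag partition. `smooth = FALSE`
# drops the differential-field smoothing (the LSM ablation).
build_constraints <- function(template, target, corr, u, cfg,
                              smooth = TRUE) {
  vs <- template$vertices
  if (smooth && cfg$lambda > 0) {
    vs_s <- vs - cfg$lambda * discrete_laplacian(template, u)
  } else {
    vs_s <- vs
  }
  thr <- similarity_thresholds(corr$q, cfg$q_high_fraction, cfg$q_low_fraction)
  anchor <- corr$q < thr["q_low"]
  pull <- corr$q > thr["q_high"]

  p <- matrix(NA_real_, nrow(vs), 3L)
  p[anchor, ] <- vs_s[anchor, , drop = FALSE]
  if (any(pull)) {
    idx <- which(pull)
    vt <- target$vertices[corr$match[idx], , drop = FALSE]
    nt <- target$normals[corr$match[idx], , drop = FALSE]
    x <- vs_s[idx, , drop = FALSE]
    # orthogonal projection of the smoothed position onto the tangent plane
    # at the matched target vertex
    off <- rowSums((x - vt) * nt)
    proj <- x - off * nt
    ls <- mean_edge_length(template)[idx]
    step <- pmin(ls / cfg$m, 1)   # internal division point, never overshoot
    p[idx, ] <- x + step * (proj - x)
  }
  sel <- anchor | pull
  if (!any(sel))
    stop("degenerate constraint state: every vertex is in the free band")
  list(index = which(sel), p = p[sel, , drop = FALSE],
       flags = ifelse(anchor, "anchor", ifelse(pull, "pull", "free")),
       thresholds = thr)
}

#' Laplacian-constrained quadratic shape update
#'
#' Solves `argmin_v' sum_i ||L(v'_i) - L(v_i)||^2 +
#' delta * sum_{i in C} ||p_i - v'_i||^2` per coordinate via the sparse
#' normal equations `(L'L + delta S'S) v' = L'L v + delta S'p`, where `S`
#' selects the constrained vertices. The first term preserves the current
#' differential coordinates (shape); the second softly attracts constrained
#' vertices to their target positions.
#'
#' @param template a `triangle_mesh` providing topology and current positions.
#' @param constraints a list with `index` (constrained vertex indices) and
#'   `p` (matching target positions).
#' @param delta constraint weight (> 0).
#' @param L optional precomputed sparse Laplacian (topology is fixed across
#'   the iteration loop, so callers reuse it).
#' @return numeric matrix of new vertex positions.
#' @export
laplacian_solve <- function(template, constraints, delta = 10.0, L = NULL) {
  if (length(constraints$index) == 0L)
    stop("constraint set is empty: system is translation-rank-deficient")
  v <- template$vertices
  n <- nrow(v)
  if (is.null(L)) L <- laplacian_matrix(template)
  LtL <- Matrix::crossprod(L)
  s_diag <- numeric(n)
  s_diag[constraints$index] <- delta
  A <- LtL + Matrix::Diagonal(x = s_diag)
  rhs <- as.matrix(LtL %*% v)
  rhs[constraints$index, ] <- rhs[constraints$index, ] + delta * constraints$p
  as.matrix(Matrix::solve(A, rhs))
}

# Shared iteration loop for LSMD (smooth = TRUE) and LSM (smooth = FALSE).
register_laplacian <- function(template, target, cfg, smooth, method) {
  if (!is_closed(template) || !is_closed(target))
    stop("both meshes must be closed surfaces")
  al <- affine_align(template, target)
  mesh <- al$mesh
  base <- mesh$vertices          # start of the Laplacian phase
  L <- laplacian_matrix(mesh)
  LtL <- Matrix::crossprod(L)
  cache <- cp_cache(target)      # for the termination distance

  best <- Inf; stall <- 0L
  best_vertices <- mesh$vertices
  trace <- vector("list", cfg$max_iterations)
  it <- 0L
  while (it < cfg$max_iterations) {
    it <- it + 1L
    corr <- correspondence_search(mesh, target, cfg$gamma)
    u <- mesh$vertices - base
    con <- tryCatch(
      build_constraints(mesh, target, corr, u, cfg, smooth = smooth),
      error = function(e) NULL)
    if (is.null(con)) {
      it <- it - 1L
      attr(trace, "failed") <- "all vertices free"
      break
    }

    # one-sided template-to-target-surface distance for the stall tracker;
    # point-to-surface avoids the sampling floor of the remeshed target
    dist_s <- closest_point_pruned(mesh$vertices, target, cache)$distance
    max_d <- max(dist_s)
    trace[[it]] <- data.frame(
      iteration = it, max_distance = max_d, mean_distance = mean(dist_s),
      n_anchor = sum(con$flags == "anchor"),
      n_pull = sum(con$flags == "pull"),
      n_free = sum(con$flags == "free"))
    if (max_d < best - 1e-12) {
      best <- max_d; stall <- 0L
      best_vertices <- mesh$vertices
    } else {
      stall <- stall + 1L
      if (stall >= cfg$stall_window) break
    }

    s_diag <- numeric(nrow(base))
    s_diag[con$index] <- cfg$delta
    A <- LtL + Matrix::Diagonal(x = s_diag)
    rhs <- as.matrix(LtL %*% mesh$vertices)
    rhs[con$index, ] <- rhs[con$index, ] + cfg$delta * con$p
    mesh <- set_vertices(mesh, as.matrix(Matrix::solve(A, rhs)))
  }

  failed <- attr(trace, "failed")
  trace <- do.call(rbind, trace[seq_len(it)])
  # keep the iterate that achieved the running-best inter-surface distance
  # (the quantity the termination rule monitors), not the last oscillation
  mesh <- set_vertices(mesh, best_vertices)
  structure(list(
    mesh = mesh,
    displacement = mesh$vertices - base,
    affine = al$transform,
    aligned_vertices = base,
    trace = trace,
    iterations = it,
    converged = is.null(failed) && it < cfg$max_iterations,
    failure = failed,
    method = method,
    config = cfg), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: %d iterations%s\n", x$method,
              x$iterations, if (isTRUE(x$converged)) "" else " (cap reached)"))
  if (!is.null(x$trace) && nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final max/mean inter-surface distance: %.3f / %.3f mm\n",
                last$max_distance, last$mean_distance))
  }
  invisible(x)
}

#' Laplacian-based shape matching with a differential displacement field
#'
#' The full non-rigid registration loop: affine pre-alignment, then repeated
#' {normals and Laplacians -> exhaustive similarity search -> percentile
#' thresholds -> progressive positional constraints smoothed through the
#' Laplacian of the cumulative displacement field -> sparse quadratic shape
#' update}, until the running best maximum template-to-target distance stops
#' improving for `cfg$stall_window` updates or `cfg$max_iterations` is hit.
#'
#' @param template,target closed `triangle_mesh` objects; the result keeps
#'   the template's topology.
#' @param cfg a [registration_config()].
#' @return a `registration_result`: registered `mesh`, `displacement` field
#'   (from the affine-aligned template), per-iteration `trace`
#'   (max/mean distance and constraint counts), iteration count and the
#'   affine pre-transform.
#' @export
register_lsmd <- function(template, target, cfg = registration_config()) {
  register_laplacian(template, target, cfg, smooth = TRUE, method = "lsmd")
}

#' Laplacian-based shape matching without displacement smoothing (ablation)
#'
#' Identical loop to [register_lsmd()] except the positional constraints use
#' the raw vertex positions (no differential-displacement smoothing), the
#' classic progressive Laplacian matching baseline.
#'
#' @inheritParams register_lsmd
#' @return a `registration_result`.
#' @export
register_lsm <- function(template, target, cfg = registration_config()) {
  register_laplacian(template, target, cfg, smooth = FALSE, method = "lsm")
}

#' Global affine baseline
#'
#' Affine ICP alone, packaged as a `registration_result` so it can be scored
#' alongside the non-rigid methods.
#'
#' @inheritParams register_lsmd
#' @return a `registration_result`.
#' @export
register_affine <- function(template, target, cfg = registration_config()) {
  al <- affine_align(template, target)
  structure(list(
    mesh = al$mesh,
    displacement = matrix(0, n_vertices(template), 3L),
    affine = al$transform,
    aligned_vertices = al$mesh$vertices,
    trace = NULL, iterations = 0L, converged = TRUE, failure = NULL,
    method = "affine", config = cfg), class = "registration_result")
}

#' Piecewise-affine baseline
#'
#' Partitions the (affine pre-aligned) template vertices into `n_pieces`
#' spatial cells by seeded k-means, fits one affine ICP per cell against the
#' full target, and blends the per-cell maps with inverse-square-distance
#' weights to the cell centroids so the field stays continuous. Cells with
#' fewer than 4 vertices or a rank-deficient fit are merged into the nearest
#' cell.
#'
#' @inheritParams register_lsmd
#' @param n_pieces number of affine cells (>= 1).
#' @return a `registration_result`.
#' @export
register_piecewise_affine <- function(template, target, n_pieces = 4L,
                                      cfg = registration_config()) {
  al <- affine_align(template, target)
  base <- al$mesh$vertices
  if (n_pieces <= 1L) {
    res <- register_affine(template, target, cfg)
    res$method <- "pwa"
    return(res)
  }
  cl <- with_seed(cfg$rng_seed, stats::kmeans(base, centers = n_pieces,
                                              nstart = 5L, iter.max = 100L))
  labels <- cl$cluster
  # merge undersized / degenerate cells into the nearest surviving cell
  repeat {
    sizes <- tabulate(labels, nbins = n_pieces)
    bad <- which(sizes > 0L & sizes < 4L)
    if (length(bad) == 0L) break
    b <- bad[1L]
    centers <- do.call(rbind, lapply(seq_len(n_pieces), function(k)
      if (sizes[k] > 0L) colMeans(base[labels == k, , drop = FALSE])
      else c(Inf, Inf, Inf)))
    d <- rowSums(sweep(centers, 2L, centers[b, ])^2)
    d[b] <- Inf
    labels[labels == b] <- which.min(d)
  }
  cells <- sort(unique(labels))
  fits <- list(); centroids <- list()
  for (k in cells) {
    idx <- which(labels == k)
    sub <- base[idx, , drop = FALSE]
    fit <- tryCatch(icp_points(sub, target), error = function(e) NULL)
    if (is.null(fit)) fit <- cbind(diag(3), 0)
    fits[[as.character(k)]] <- fit
    centroids[[as.character(k)]] <- colMeans(sub)
  }
  C <- do.call(rbind, centroids)
  W <- 1 / (outer(rowSums(base^2), rowSums(C^2), "+") -
              2 * base %*% t(C) + 1e-9)
  W <- W / rowSums(W)
  new_v <- matrix(0, nrow(base), 3L)
  for (j in seq_along(fits)) {
    new_v <- new_v + W[, j] * apply_affine(fits[[j]], base)
  }
  mesh <- set_vertices(al$mesh, new_v)
  structure(list(
    mesh = mesh,
    displacement = new_v - al$mesh$vertices,
    affine = al$transform,
    aligned_vertices = al$mesh$vertices,
    trace = NULL, iterations = 1L, converged = TRUE, failure = NULL,
    method = "pwa", config = cfg), class = "registration_result")
}

# affine ICP of a bare point set against a target mesh surface
icp_points <- function(x, target, max_iter = 50L, tol = 1e-7) {
  cur <- x
  B <- cbind(diag(3), 0)
  rms_prev <- Inf
  cache <- cp_cache(target)
  for (it in seq_len(max_iter)) {
    y <- closest_point_pruned(cur, target, cache)$point
    B <- affine_fit(x, y)
    cur <- apply_affine(B, x)
    rms <- sqrt(mean(rowSums((cur - y)^2)))
    if (is.finite(rms_prev) && rms_prev - rms < tol * max(rms_prev, 1e-12))
      break
    rms_prev <- rms
  }
  B
}

# run expr with a local RNG state, leaving the global stream untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a population template by register-and-average
#'
#' Resamples one seed surface to the working vertex count, registers it to
#' every input surface, and returns the vertex-wise mean shape (same
#' topology), which keeps the template close to all the data it will later be
#' matched to.
#'
#' @param surfaces list of closed `triangle_mesh` objects (>= 2).
#' @param seed_case index of the surface used as the initial template.
#' @param n_vertices working template resolution (default 400, giving 796
#'   triangles on a closed genus-0 surface).
#' @param cfg a [registration_config()].
#' @return a `triangle_mesh` average shape.
#' @export
build_template <- function(surfaces, seed_case = 1L, n_vertices = 400L,
                           cfg = registration_config()) {
  if (length(surfaces) < 2L) stop("need at least two surfaces")
  t0 <- resample_to(surfaces[[seed_case]], n_vertices)
  acc <- matrix(0, n_vertices, 3L)
  for (k in seq_along(surfaces)) {
    res <- tryCatch(register_lsmd(t0, surfaces[[k]], cfg),
                    error = function(e)
                      stop("registration failed for case ", k, ": ",
                           conditionMessage(e)))
    acc <- acc + res$mesh$vertices
  }
  set_vertices(t0, acc / length(surfaces))
}
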