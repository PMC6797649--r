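# Small lobe pair reused across the heavier registration tests
small_lobe <- make_lobe_mesh(2, n_vertices = 200L)
small_cfg <- registration_config(max_iterations = 100L)

test_that("affine least squares and ICP recover known maps", {
  m <- random_closed_mesh(31, subdiv = 2, radius = 20)
  A <- rbind(c(0.9, 0.1, 0), c(-0.05, 0.8, 0.1), c(0, 0.05, 0.7))
  t0 <- c(4, -2, 1)
  y <- m$vertices %*% t(A) + matrix(t0, n_vertices(m), 3, byrow = TRUE)

  # closed-form oracle with known pairs
  B <- lobematch:::affine_fit(m$vertices, y)
  expect_equal(B[, 1:3], A, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(B[, 4], t0, tolerance = 1e-8, ignore_attr = TRUE)

  # identity case
  al <- affine_align(m, m)
  expect_equal(al$mesh$vertices, m$vertices, tolerance = 1e-6)

  # similarity case: x0.5 about the centroid recovers a 0.5 linear part
  ctr <- colMeans(m$vertices)
  half <- set_vertices(m, sweep(sweep(m$vertices, 2, ctr), 1, 0.5, "*") +
                            matrix(ctr, n_vertices(m), 3, byrow = TRUE))
  al2 <- affine_align(m, half)
  expect_equal(al2$transform[, 1:3], 0.5 * diag(3), tolerance = 0.02,
               ignore_attr = TRUE)

  expect_error(lobematch:::affine_fit(matrix(0, 5, 3), matrix(0, 5, 3)),
               "rank-deficient")
})

test_that("local similarity follows its closed form", {
  n <- c(0, 0, 1)
  expect_equal(local_similarity(c(1, 2, 3), n, c(1, 2, 3), n), 0)
  expect_equal(local_similarity(c(0, 0, 0), n, c(3, 4, 0), n), 5)
  expect_equal(local_similarity(c(1, 1, 1), n, c(1, 1, 1), -n, gamma = 1), 2)
  expect_equal(local_similarity(c(0, 0, 0), n, c(3, 4, 0), -n, gamma = 2), 9)
})

test_that("correspondence search is an exact argmin over all pairs", {
  m <- small_lobe
  self <- correspondence_search(m, m, gamma = 1)
  expect_identical(self$match, seq_len(n_vertices(m)))
  expect_lt(max(abs(self$q)), 1e-5)

  set.seed(9)
  a <- random_closed_mesh(51, subdiv = 1, radius = 8)   # 42 vertices
  b <- random_closed_mesh(52, subdiv = 1, radius = 9)
  corr <- correspondence_search(a, b, gamma = 1)
  for (i in seq_len(n_vertices(a))) {
    qs <- vapply(seq_len(n_vertices(b)), function(j)
      local_similarity(a$vertices[i, ], a$normals[i, ],
                       b$vertices[j, ], b$normals[j, ], gamma = 1),
      numeric(1))
    expect_equal(corr$match[i], which.min(qs))
    expect_equal(corr$q[i], min(qs), tolerance = 1e-9)
  }
})

test_that("similarity thresholds use ceiling-count tail means", {
  thr <- similarity_thresholds(1:100)
  expect_equal(unname(thr["q_high"]), mean(91:100))  # 95.5
  expect_equal(unname(thr["q_low"]), mean(1:2))      # 1.5
  thr10 <- similarity_thresholds(1:10)
  expect_equal(unname(thr10["q_high"]), 10)
  expect_equal(unname(thr10["q_low"]), 1)
  thrc <- similarity_thresholds(rep(3.3, 25))
  expect_equal(unname(thrc["q_high"]), 3.3)
  expect_equal(unname(thrc["q_low"]), 3.3)
  expect_error(similarity_thresholds(numeric()), "empty")
})

test_that("positional constraints implement the progressive rule", {
  m <- small_lobe
  n <- n_vertices(m)
  cfg <- registration_config()
  u0 <- matrix(0, n, 3)

  # fabricated correspondence: vertex 1 is the only pull; vertices 2-4 sit
  # strictly below the bottom-2%-mean threshold (the branch tests are strict
  # inequalities, so ties at the threshold stay free)
  q <- rep(1, n); q[1] <- 50
  q[2:5] <- c(1e-5, 2e-5, 3e-5, 1e-2)
  vt <- m$vertices[1, ] + c(0, 0, 4)          # matched target vertex
  nt <- c(0, 0, 1)                            # its tangent plane z = vt_z
  target <- m
  target$vertices[7, ] <- vt
  target$normals[7, ] <- nt
  corr <- list(match = rep(7L, n), q = q)

  con <- lobematch:::build_constraints(m, target, corr, u0, cfg)
  expect_setequal(con$index[con$flags[con$index] == "anchor"], 2:4)
  expect_equal(sum(con$flags == "pull"), 1L)
  # anchors keep their positions when u = 0
  anchors <- con$index[con$flags[con$index] == "anchor"]
  expect_equal(con$p[match(anchors, con$index), ],
               m$vertices[anchors, ], tolerance = 1e-12, ignore_attr = TRUE)
  # the pull moves min(l_s/m, 1) of the way to the tangent-plane projection
  ls1 <- mean_edge_length(m, 1L)
  step <- min(ls1 / cfg$m, 1)
  off <- sum((m$vertices[1, ] - vt) * nt)
  proj <- m$vertices[1, ] - off * nt
  expect_equal(con$p[match(1L, con$index), ],
               m$vertices[1, ] + step * (proj - m$vertices[1, ]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a constant displacement field has zero Laplacian: smoothing is a no-op
  uc <- matrix(rep(c(2, -1, 3), each = n), ncol = 3)
  con2 <- lobematch:::build_constraints(m, target, corr, uc, cfg)
  expect_equal(con2$p, con$p, tolerance = 1e-9)
})

test_that("worked pull example: half of a 4 mm gap when l_s/m = 1/2", {
  # apex ring scaled so the apex's mean incident edge length is exactly 1
  p <- pyramid_mesh()
  s <- 1 / sqrt(2)                     # edges apex-ring have length sqrt(2)*s
  m <- triangle_mesh(p$vertices * s, p$faces, orient = FALSE)
  expect_equal(mean_edge_length(m, 1L), 1, tolerance = 1e-12)
  # wider tail fractions so the 5-vertex toy mesh has a nonempty pull set
  # (the mean of a single top value can never be strictly exceeded)
  cfg <- registration_config(m = 2, q_high_fraction = 0.4,
                             q_low_fraction = 0.39)
  vt <- m$vertices[1, ] - c(0, 0, 4)   # plane 4 mm below the apex
  target <- m
  target$vertices[3, ] <- vt
  target$normals[3, ] <- c(0, 0, 1)
  q <- c(50, 1e-4, 2e-4, 0.5, 1)
  corr <- list(match = rep(3L, 5), q = q)
  con <- lobematch:::build_constraints(m, target, corr,
                                       matrix(0, 5, 3), cfg)
  p1 <- con$p[match(1L, con$index), ]
  expect_equal(p1, m$vertices[1, ] - c(0, 0, 2), tolerance = 1e-12,
               ignore_attr = TRUE)    # moved 2 mm of the 4 mm gap
})

test_that("laplacian solve matches the dense least-squares oracle", {
  # fixing every vertex at its position returns the input
  m <- random_closed_mesh(61, subdiv = 1, radius = 6)
  all_fixed <- list(index = seq_len(n_vertices(m)), p = m$vertices)
  expect_equal(laplacian_solve(m, all_fixed, delta = 10), m$vertices,
               tolerance = 1e-9, ignore_attr = TRUE)

  # single constraint, large delta: pure translation by t
  t0 <- c(2, -1, 3)
  one <- list(index = 5L, p = m$vertices[5, , drop = FALSE] +
                matrix(t0, 1, 3))
  moved <- laplacian_solve(m, one, delta = 1e8)
  expect_equal(moved, sweep(m$vertices, 2, t0, "+"), tolerance = 1e-4,
               ignore_attr = TRUE)

  # 20 random trials against the dense stacked-lstsq oracle
  for (seed in 1:20) {
    mm <- random_closed_mesh(seed, subdiv = 1, radius = 10)  # 42 vertices
    set.seed(seed + 100)
    k <- sample(3:10, 1)
    idx <- sort(sample(n_vertices(mm), k))
    con <- list(index = idx,
                p = mm$vertices[idx, , drop = FALSE] +
                  matrix(rnorm(3 * k), k, 3))
    got <- laplacian_solve(mm, con, delta = 10)
    want <- dense_solve_oracle(mm, con, delta = 10)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }

  expect_error(laplacian_solve(m, list(index = integer(), p = NULL), 10),
               "empty")
})

test_that("solver never increases the quadratic objective", {
  objective <- function(mesh, v2, con, delta) {
    L <- dense_laplacian(mesh)
    sum((L %*% v2 - L %*% mesh$vertices)^2) +
      delta * sum((con$p - v2[con$index, , drop = FALSE])^2)
  }
  for (seed in c(2, 4, 8)) {
    mm <- random_closed_mesh(seed, subdiv = 1)
    set.seed(seed)
    idx <- sort(sample(n_vertices(mm), 6))
    con <- list(index = idx, p = mm$vertices[idx, ] + matrix(rnorm(18), 6, 3))
    v2 <- laplacian_solve(mm, con, delta = 10)
    expect_lte(objective(mm, v2, con, 10),
               objective(mm, mm$vertices, con, 10) + 1e-9)
  }
})

test_that("identity and pure-translation targets are fixed points", {
  m <- small_lobe
  res <- register_lsmd(m, m, small_cfg)
  expect_lt(max(abs(res$displacement)), 1e-6)
  expect_lt(mean_distance(res$mesh, m), 1e-6)

  shifted <- set_vertices(m, sweep(m$vertices, 2, c(8, -5, 3), "+"))
  for (fn in list(register_lsmd, register_lsm)) {
    res2 <- fn(m, shifted, small_cfg)
    u_total <- res2$mesh$vertices - m$vertices
    expect_lt(max(abs(colMeans(u_total) - c(8, -5, 3))), 0.05)
    # recovered field is (nearly) constant: Laplacian of displacement ~ 0
    ld <- displacement_laplacian_stats(res2$mesh, res2$displacement)
    expect_lt(ld["max"], 1e-3)
  }
})

test_that("registration is deterministic and rotation-equivariant", {
  m <- small_lobe
  out <- apply_deflation(m, deflation_params(c = 0.85, rotation_deg = 5,
                                             target_n = 260L, seed = 4))
  r1 <- register_lsmd(m, out$deflated, small_cfg)
  r2 <- register_lsmd(m, out$deflated, small_cfg)
  expect_identical(r1$mesh$vertices, r2$mesh$vertices)
  expect_identical(r1$iterations, r2$iterations)

  # exact 90-degree rotation about z: coordinates permute without rounding
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  rot <- function(mesh) set_vertices(mesh, mesh$vertices %*% t(R))
  r3 <- register_lsmd(rot(m), rot(out$deflated), small_cfg)
  expect_equal(r3$mesh$vertices, r1$mesh$vertices %*% t(R),
               tolerance = 1e-6)
})

test_that("ground-truth deflation is recovered on a synthetic pair", {
  m <- make_lobe_mesh(42, n_vertices = 400L)
  out <- apply_deflation(m, deflation_params(c = 0.78, rotation_deg = 8,
                                             bending = 2, noise_sd = 0.2,
                                             target_n = 520L, seed = 42))
  res <- register_lsmd(m, out$deflated,
                       registration_config(max_iterations = 300L))
  expect_lt(mean_distance(res$mesh, out$deflated),
            0.02 * bbox_diagonal(m))
  u_total <- res$mesh$vertices - m$vertices
  vid <- out$points$vertex
  tde <- sqrt(rowSums((u_total[vid, , drop = FALSE] -
                         out$truth[vid, , drop = FALSE])^2))
  expect_lt(mean(tde), 0.10 * mean(sqrt(rowSums(out$truth^2))))
})

test_that("piecewise affine degenerates to affine and is exact on one map", {
  m <- small_lobe
  out <- apply_deflation(m, deflation_params(c = 0.9, target_n = 240L))
  p1 <- register_piecewise_affine(m, out$deflated, n_pieces = 1L, small_cfg)
  af <- register_affine(m, out$deflated, small_cfg)
  expect_equal(p1$mesh$vertices, af$mesh$vertices, tolerance = 1e-9)

  pid <- register_piecewise_affine(m, m, n_pieces = 3L, small_cfg)
  expect_lt(max(abs(pid$mesh$vertices - m$vertices)), 1e-3)

  # a single global affine target is recovered by every cell
  A <- rbind(c(0.8, 0.05, 0), c(0, 0.9, -0.05), c(0.02, 0, 0.85))
  tgt <- set_vertices(m, m$vertices %*% t(A))
  p3 <- register_piecewise_affine(m, tgt, n_pieces = 3L, small_cfg)
  # each cell's surface-ICP converges to a slightly different affine; after
  # blending the recovery error stays well below the ~6 mm edge length
  expect_lt(mean(sqrt(rowSums((p3$mesh$vertices - tgt$vertices)^2))), 0.6)
})

test_that("template building averages registered shapes", {
  m <- make_lobe_mesh(5, n_vertices = 300L)
  cfg <- registration_config(max_iterations = 60L)
  # identical inputs: template ~ resampled input
  tpl <- build_template(list(m, m), seed_case = 1L, n_vertices = 150L,
                        cfg = cfg)
  expect_equal(n_vertices(tpl), 150L)
  expect_lt(hausdorff_distance(tpl, m), 0.03 * bbox_diagonal(m))

  # +t / -t translates: average is the centred shape
  t0 <- c(6, 0, 0)
  up <- set_vertices(m, sweep(m$vertices, 2, t0, "+"))
  dn <- set_vertices(m, sweep(m$vertices, 2, t0, "-"))
  tpl2 <- build_template(list(up, dn), seed_case = 1L, n_vertices = 150L,
                         cfg = cfg)
  expect_lt(hausdorff_distance(tpl2, resample_to(m, 150L)),
            0.03 * bbox_diagonal(m))
  expect_error(build_template(list(m)), "at least two")
})
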