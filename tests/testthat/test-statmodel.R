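test_that("displacement fields subtract vertex-wise", {
  m <- icosphere_mesh(2, radius = 10)
  expect_equal(displacement_field(m, m), matrix(0, n_vertices(m), 3))
  shifted <- set_vertices(m, sweep(m$vertices, 2, c(1, 0, 0), "+"))
  expect_equal(displacement_field(m, shifted),
               matrix(rep(c(1, 0, 0), each = n_vertices(m)), ncol = 3))
  other <- icosphere_mesh(1)
  expect_error(displacement_field(m, other), "topology")
})

test_that("the two-sample model is rank one", {
  set.seed(8)
  n <- 30
  mu <- matrix(rnorm(3 * n), n, 3)
  d <- matrix(rnorm(3 * n), n, 3)
  model <- fit_deformation_model(list(mu + d, mu - d))
  expect_equal(matrix(model$mean, ncol = 3, byrow = TRUE), mu)
  expect_equal(variance_explained(model, 1), 100)
  # single mode proportional to d
  mode1 <- matrix(model$modes[, 1], ncol = 3, byrow = TRUE)
  cosang <- abs(sum(mode1 * d)) / sqrt(sum(mode1^2) * sum(d^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
  # synthesize at +2: mean + 2 sqrt(lambda1) e1 exactly
  expect_equal(synthesize_mode(model, 1, 2),
               matrix(model$mean + 2 * sqrt(model$eigenvalues[1]) *
                        model$modes[, 1], ncol = 3, byrow = TRUE))
})

test_that("two-factor structure is recovered from 50 samples", {
  set.seed(101)
  n <- 40
  e1 <- rnorm(3 * n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- rnorm(3 * n); e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  mu <- rnorm(3 * n)
  samples <- lapply(1:50, function(i) {
    flat <- mu + rnorm(1, 0, 3) * e1 + rnorm(1, 0, 1) * e2
    matrix(flat, ncol = 3, byrow = TRUE)
  })
  model <- fit_deformation_model(samples)
  m1 <- model$modes[, 1]
  expect_gt(abs(sum(m1 * e1)), 0.99)
  ratio <- model$eigenvalues[1] / model$eigenvalues[2]
  expect_lt(abs(ratio - 9) / 9, 0.30)
})

test_that("the model reconstructs its training data and ignores order", {
  set.seed(5)
  samples <- lapply(1:6, function(i) matrix(rnorm(45), 15, 3))
  model <- fit_deformation_model(samples)
  # completeness: projecting sample deviations on all modes reconstructs them
  for (s in samples) {
    flat <- as.vector(t(s)) - model$mean
    coef <- drop(crossprod(model$modes, flat))
    expect_equal(drop(model$modes %*% coef), flat, tolerance = 1e-6)
  }
  # eigenvalue spectrum: at most n-1 nonzero, descending, orthonormal modes
  expect_lte(sum(model$eigenvalues > 1e-9), 5)
  expect_true(all(diff(model$eigenvalues) <= 1e-9))
  gram <- crossprod(model$modes)
  expect_equal(gram, diag(ncol(model$modes)), tolerance = 1e-8)

  perm <- fit_deformation_model(samples[c(4, 1, 6, 2, 5, 3)])
  expect_equal(perm$eigenvalues, model$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(diag(crossprod(perm$modes[, 1:5], model$modes[, 1:5]))),
               rep(1, 5), tolerance = 1e-6)
})

test_that("variance explained is monotone and complete", {
  set.seed(6)
  samples <- lapply(1:5, function(i) matrix(rnorm(30), 10, 3))
  model <- fit_deformation_model(samples)
  ve <- vapply(seq_along(model$eigenvalues), function(k)
    variance_explained(model, k), numeric(1))
  expect_true(all(diff(ve) >= -1e-12))
  expect_equal(ve[length(ve)], 100)
  toy <- list(mean = rep(0, 6), eigenvalues = c(3, 1),
              modes = diag(6)[, 1:2], n_samples = 3, n_vertices = 2)
  class(toy) <- "deformation_model"
  expect_equal(variance_explained(toy, 1), 75)
  expect_error(variance_explained(toy, 5), "exceeds")
})

test_that("mode synthesis is linear in the weight", {
  set.seed(7)
  samples <- lapply(1:5, function(i) matrix(rnorm(30), 10, 3))
  model <- fit_deformation_model(samples)
  mean_field <- matrix(model$mean, ncol = 3, byrow = TRUE)
  expect_equal(synthesize_mode(model, 1, 0), mean_field)
  expect_equal((synthesize_mode(model, 2, 2) +
                  synthesize_mode(model, 2, -2)) / 2, mean_field,
               tolerance = 1e-12)
  expect_error(synthesize_mode(model, 99, 1), "out of range")
})

test_that("state interpolation is linear and warns on extrapolation", {
  m <- icosphere_mesh(1, radius = 5)
  field <- matrix(rep(c(2, 0, 0), each = n_vertices(m)), ncol = 3)
  expect_equal(interpolate_states(m, field, 0)$vertices, m$vertices)
  expect_equal(interpolate_states(m, field, 1)$vertices,
               sweep(m$vertices, 2, c(2, 0, 0), "+"))
  expect_equal(interpolate_states(m, field, 0.5)$vertices,
               sweep(m$vertices, 2, c(1, 0, 0), "+"))
  expect_warning(interpolate_states(m, field, 1.5), "extrapolat")
})

test_that("hilum linearity separates radial from rotational fields", {
  m <- make_lobe_mesh(3, n_vertices = 300L)
  hilum <- c(-20, 0, 0)
  rel <- sweep(m$vertices, 2, hilum)
  radial <- -0.25 * rel
  lin <- hilum_linearity(m, radial, hilum)
  expect_equal(lin$slope, 0.25, tolerance = 1e-9)
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)

  const <- matrix(rep(c(3, 0, 0), each = n_vertices(m)), ncol = 3)
  lc <- hilum_linearity(m, const, hilum)
  expect_equal(lc$slope, 0, tolerance = 1e-9)
  expect_equal(lc$r_squared, 0)

  # adding rotation about the hilum splits the scatter and lowers R^2
  th <- 15 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  composite <- (rel %*% t(R) - rel) + radial
  lr <- hilum_linearity(m, composite, hilum)
  expect_lt(lr$r_squared, lin$r_squared)
})
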