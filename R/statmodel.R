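# Inter-subject statistical deformation model: per-case displacement fields
# on a shared template topology, summarised by their mean and SVD eigenmodes.

#' Per-vertex displacement field between two corresponding models
#'
#' Deflated minus inflated, vertex-wise. Both meshes must share the template
#' topology so vertices correspond.
#'
#' @param m_inflated,m_deflated `triangle_mesh` objects with identical faces.
#' @return numeric matrix (n x 3) of displacements (mm).
#' @export
displacement_field <- function(m_inflated, m_deflated) {
  if (!identical(dim(m_inflated$vertices), dim(m_deflated$vertices)) ||
      !identical(m_inflated$faces, m_deflated$faces))
    stop("meshes must share the same topology")
  m_deflated$vertices - m_inflated$vertices
}

#' Fit a statistical deformation model by SVD
#'
#' Stacks each sample's displacement field as a flat 3N vector, centres the
#' sample matrix, and takes its singular value decomposition. Eigenvalues are
#' the squared singular values divided by (n - 1) (sample covariance
#' convention); eigenvector signs are fixed by making each mode's
#' largest-magnitude component positive, so synthesised figures are
#' reproducible.
#'
#' @param samples list of n x 3 displacement matrices (equal N), or a list of
#'   `list(id =, field =)` entries.
#' @return a `deformation_model`: `mean` (3N), `eigenvalues` (descending,
#'   mm^2), `modes` (3N x k orthonormal columns), `n_samples`, `n_vertices`.
#' @export
fit_deformation_model <- function(samples) {
  fields <- lapply(samples, function(s) if (is.list(s)) s$field else s)
  if (length(fields) < 2L) stop("need at least two deformation samples")
  flat <- t(vapply(fields, function(f) as.vector(t(f)), numeric(3L * nrow(fields[[1L]]))))
  if (any(is.na(flat))) stop("displacement samples contain NA")
  n <- nrow(flat)
  mu <- colMeans(flat)
  Xc <- sweep(flat, 2L, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (n - 1)
  modes <- sv$v
  # deterministic sign: largest-|component| of each mode positive
  for (k in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(list(mean = mu, eigenvalues = lambda, modes = modes,
                 n_samples = n, n_vertices = length(mu) / 3L),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat(sprintf("deformation_model: %d samples, %d vertices, %d modes\n",
              x$n_samples, x$n_vertices, length(x$eigenvalues)))
  ve <- cumsum(x$eigenvalues) / sum(x$eigenvalues) * 100
  cat(sprintf("  variance explained by first modes: %s\n",
              paste(sprintf("%.1f%%", utils::head(ve, 3L)), collapse = ", ")))
  invisible(x)
}

#' Synthesise a deformation along one eigenmode
#'
#' Returns `mean + weight * sqrt(eigenvalue[mode]) * mode`, reshaped to an
#' n x 3 field. Weights of +/- 2 span about two standard deviations of the
#' training population along that mode; weight 0 returns the mean
#' deformation.
#'
#' @param model a `deformation_model`.
#' @param mode 1-based mode index.
#' @param weight scalar weight in units of the mode's standard deviation.
#' @return numeric matrix (n x 3) displacement field (mm).
#' @export
synthesize_mode <- function(model, mode, weight) {
  if (mode < 1L || mode > ncol(model$modes)) stop("mode index out of range")
  flat <- model$mean +
    weight * sqrt(model$eigenvalues[mode]) * model$modes[, mode]
  matrix(flat, ncol = 3L, byrow = TRUE)
}

#' Cumulative variance explained by the leading modes
#'
#' @param model a `deformation_model`.
#' @param k number of leading modes.
#' @return percentage in [0, 100].
#' @export
variance_explained <- function(model, k) {
  if (k > length(model$eigenvalues)) stop("k exceeds the number of modes")
  tot <- sum(model$eigenvalues)
  if (tot <= 0) stop("model has no variance (all eigenvalues zero)")
  100 * sum(model$eigenvalues[seq_len(k)]) / tot
}

#' Interpolate between inflated and deflated states
#'
#' Linear vertex interpolation `inflated + t * field`; `t = 0` reproduces the
#' inflated state and `t = 1` the deflated state. Values outside [0, 1]
#' extrapolate (with a warning).
#'
#' @param m_inflated a `triangle_mesh`.
#' @param field n x 3 displacement field on it (mm).
#' @param t interpolation parameter.
#' @return a `triangle_mesh`.
#' @export
interpolate_states <- function(m_inflated, field, t) {
  if (t < 0 || t > 1)
    warning("t outside [0, 1]: extrapolating beyond the observed states")
  set_vertices(m_inflated, m_inflated$vertices + t * field)
}

#' Distance-from-hilum linearity of a displacement field
#'
#' For every vertex, pairs the Euclidean distance from the hilum point with
#' the displacement magnitude, and fits an ordinary least-squares line. A
#' nearly pure contraction toward the hilum gives R^2 close to 1; rotational
#' or bending components split the scatter into branches and lower R^2.
#'
#' @param m_inflated a `triangle_mesh` (inflated state).
#' @param field n x 3 displacement field (mm).
#' @param hilum 3-vector, the hilum reference point (mm).
#' @return list with `table` (data.frame distance, magnitude), `slope`,
#'   `intercept`, `r_squared`.
#' @export
hilum_linearity <- function(m_inflated, field, hilum) {
  d <- sqrt(rowSums(sweep(m_inflated$vertices, 2L, hilum)^2))
  mag <- sqrt(rowSums(field^2))
  fit <- stats::lm(mag ~ d)
  ss_tot <- sum((mag - mean(mag))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 0 else
    1 - sum(stats::residuals(fit)^2) / ss_tot
  list(table = data.frame(distance = d, magnitude = mag),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}
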