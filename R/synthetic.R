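# Synthetic lobe-like surfaces with known pneumothorax-style deformations.
# The generator provides closed genus-0 meshes with an identifiable apex
# (tip) and a crease line (ridge), plus analytic ground-truth displacement
# fields, so registration and the deformation model are testable end to end
# without any imaging data.

# ---- icosphere ---------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Loop-style 1-to-4 geometric subdivision of a unit-sphere triangulation,
# reprojecting new vertices onto the sphere.
subdivide_sphere <- function(s) {
  v <- s$vertices; f <- s$faces
  env <- new.env(hash = TRUE)
  verts <- nrow(v)
  newv <- list()
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- env[[key]]
    if (!is.null(id)) return(id)
    p <- (v[i, ] + v[j, ]) / 2
    p <- p / sqrt(sum(p^2))
    verts <<- verts + 1L
    newv[[length(newv) + 1L]] <<- p
    env[[key]] <- verts
    verts
  }
  nf <- matrix(NA_integer_, nrow(f) * 4L, 3L)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    nf[(4L * k - 3L):(4L * k), ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
  }
  list(vertices = rbind(v, do.call(rbind, newv)), faces = nf)
}

# unit-sphere triangulation with 12, 42, 162, 642, 2562, ... vertices
icosphere <- function(subdiv = 3L) {
  s <- icosahedron()
  for (i in seq_len(subdiv)) s <- subdivide_sphere(s)
  s
}

# ---- lobe shape --------------------------------------------------------

# Seeded shape parameters: ellipsoid-like semi-axes (mm), apex elongation,
# medial-face flattening (which leaves a crease -- the "ridge" -- along the
# great circle x = 0), and a low-order smooth radial perturbation.
lobe_params <- function(seed) {
  with_seed(seed, {
    p <- list(
      axes = c(36, 28, 52) * (1 + 0.06 * stats::rnorm(3)),
      tip_amp = 0.35 + 0.10 * stats::runif(1),
      flat_amp = 0.45,
      perturb = 0.03 * stats::rnorm(6))
    p
  })
}

# Map unit directions (k x 3) to lobe surface points (mm). The +z pole is
# the high-curvature tip; the kink of the flattening term at dx = 0 puts a
# ridge along the x = 0 great circle.
lobe_surface <- function(dirs, p) {
  dx <- dirs[, 1L]; dy <- dirs[, 2L]; dz <- dirs[, 3L]
  h <- cbind(dx * dy, dy * dz, dx * dz, dx^2 - dy^2, 3 * dz^2 - 1, dx)
  rmod <- 1 + as.vector(h %*% p$perturb)
  flat <- 1 - p$flat_amp * pmax(0, -dx)          # crease at dx = 0
  tip <- 1 + p$tip_amp * pmax(0, dz)^4           # sharp apex at +z
  cbind(p$axes[1L] * dx * flat,
        p$axes[2L] * dy,
        p$axes[3L] * dz * tip) * rmod
}

# parametric directions of the evaluation points: the apex plus three
# points around the midpoint of the ridge circle (x = 0), midway between
# the apex and the caudal base
eval_point_dirs <- function() {
  psi <- c(72, 90, 108) * pi / 180
  rbind(tip = c(0, 0, 1),
        cbind(0, sin(psi), cos(psi)))
}

#' Generate a lobe-like closed test mesh
#'
#' A smoothly perturbed half-flattened ellipsoid with one high-curvature
#' apex (the tip) and a crease line (the ridge), built on an icosphere
#' triangulation and decimated to exactly `n_vertices`. Deterministic per
#' seed. Typical volumes fall in the 100-300 cc range of canine lung lobes.
#'
#' @param seed integer seed controlling the shape.
#' @param n_vertices vertex count of the returned mesh (>= 100).
#' @param subdiv icosphere subdivision level of the fine generator surface
#'   (3 gives 642 vertices).
#' @return a closed `triangle_mesh` carrying its generator parameters as the
#'   `"generator"` attribute (used by [apply_deflation()]).
#' @export
make_lobe_mesh <- function(seed, n_vertices = 400L, subdiv = 3L) {
  if (n_vertices < 100L) stop("n_vertices must be at least 100")
  p <- lobe_params(seed)
  sp <- icosphere(subdiv)
  while (nrow(sp$vertices) < n_vertices) {
    subdiv <- subdiv + 1L
    sp <- subdivide_sphere(sp)
  }
  fine <- triangle_mesh(lobe_surface(sp$vertices, p), sp$faces)
  mesh <- resample_to(fine, n_vertices)
  attr(mesh, "generator") <- list(seed = seed, params = p, subdiv = subdiv)
  mesh
}

#' Deflation (collapse) parameters for the synthetic generator
#'
#' The analytic deformation is a radial contraction toward the hilum
#' (factor `c`), composed with a rotation about the hilum's cranio-caudal
#' axis and a quadratic transverse bending offset, plus optional
#' normal-directed measurement noise on the target surface only. A
#' contraction of c = 0.78 reproduces the typical observed deflated/inflated
#' volume ratio near 48% (0.78^3).
#'
#' @param hilum 3-vector (mm); contraction centre. Defaults to the lobe
#'   generator's medial-face point when `NULL`.
#' @param c radial contraction factor in (0, 1].
#' @param rotation_deg rotation about the z axis through the hilum (degrees).
#' @param bending transverse offset (mm) reached 50 mm from the hilum,
#'   growing quadratically with distance.
#' @param aniso 3-vector of per-axis multiplicative deviations from `c`
#'   (anisotropic contraction); `c(0, 0, 0)` is isotropic.
#' @param nonlin distance-dependence of the collapse: the effective
#'   contraction tightens by `nonlin` per 60 mm from the hilum, so regions
#'   far from the hilum displace superlinearly (0 keeps the pure radial
#'   closed form).
#' @param apex_collapse,base_collapse amplitudes of localized extra
#'   contraction in angular bands around the apex and the caudal base --
#'   regional collapse a global affine map cannot represent (0 disables).
#' @param noise_sd SD (mm) of normal-directed noise added to the deformed
#'   fine surface before remeshing (never to the ground truth).
#' @param target_n vertex count of the independently remeshed target.
#' @param seed RNG seed for the noise.
#' @return a list of class `deflation_params`.
#' @export
deflation_params <- function(hilum = NULL, c = 0.78, rotation_deg = 0,
                             bending = 0, aniso = c(0, 0, 0), nonlin = 0,
                             apex_collapse = 0, base_collapse = 0,
                             noise_sd = 0, target_n = 520L, seed = 1L) {
  stopifnot(c > 0, c <= 1, noise_sd >= 0, target_n >= 4, length(aniso) == 3,
            nonlin >= 0, apex_collapse >= 0, base_collapse >= 0)
  structure(list(hilum = hilum, c = c, rotation_deg = rotation_deg,
                 bending = bending, aniso = as.numeric(aniso),
                 nonlin = nonlin, apex_collapse = apex_collapse,
                 base_collapse = base_collapse, noise_sd = noise_sd,
                 target_n = as.integer(target_n), seed = as.integer(seed)),
            class = "deflation_params")
}

# Analytic deformation map g(v): anisotropic, regionally modulated
# contraction toward the hilum, then rotation about its cranio-caudal axis,
# then a quadratic transverse bending offset. The distance modulation makes
# distant regions collapse harder (the superlinear behaviour collapsed
# lobes show); the apex/base bands add localized collapse that no global
# affine map can absorb.
deflation_map <- function(v, params, hilum) {
  rel <- sweep(v, 2L, hilum)
  d <- sqrt(rowSums(rel^2))
  dirz <- rel[, 3L] / pmax(d, 1e-9)
  tighten <- params$nonlin * pmin(d / 60, 2) +
    params$apex_collapse * exp(-((dirz - 0.75) / 0.25)^2) +
    params$base_collapse * exp(-((dirz + 0.8) / 0.3)^2)
  for (k in 1:3) {
    s <- pmax(params$c * (1 + params$aniso[k]) - tighten, 0.25)
    rel[, k] <- s * rel[, k]
  }
  th <- params$rotation_deg * pi / 180
  if (th != 0) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    rel <- rel %*% t(R)
  }
  if (params$bending != 0) {
    d2 <- sqrt(rowSums(rel^2))
    rel[, 1L] <- rel[, 1L] + params$bending * (d2 / 50)^2
  }
  sweep(rel, 2L, hilum, "+")
}

default_hilum <- function(gen) {
  # centre of the flattened medial face, pulled slightly inside the surface
  0.9 * as.vector(lobe_surface(matrix(c(-1, 0, 0), 1L), gen$params))
}

#' Apply a known deflation to a synthetic lobe
#'
#' Deforms the lobe by the analytic map of `params` and returns (1) an
#' independently remeshed target surface with a different vertex count and
#' topology (as segmentation-derived surface pairs have), (2) the exact
#' ground-truth displacement field on the source mesh, and (3) evaluation
#' point pairs auto-placed at the apex and three ridge midpoints. Noise, if
#' any, only perturbs the target surface; the ground truth remains the
#' deterministic map.
#'
#' @param mesh a source lobe from [make_lobe_mesh()] (other closed meshes
#'   are deformed directly and decimated, requiring
#'   `target_n <= n_vertices(mesh)`).
#' @param params a [deflation_params()].
#' @return list with `deflated` (`triangle_mesh`), `truth` (n x 3 field on
#'   the source mesh, mm), `points` (data.frame: label, vertex, inflated and
#'   deflated coordinates), `hilum`, `params`.
#' @export
apply_deflation <- function(mesh, params = deflation_params()) {
  gen <- attr(mesh, "generator")
  hilum <- params$hilum
  if (is.null(hilum)) {
    if (is.null(gen)) stop("hilum must be given for non-generated meshes")
    hilum <- default_hilum(gen)
  }
  if (abs(params$bending) > 0.5 * bbox_diagonal(mesh))
    stop("bending amplitude exceeds half the mesh extent; ",
         "reduce `bending` to avoid a self-intersecting surface")

  truth <- deflation_map(mesh$vertices, params, hilum) - mesh$vertices

  if (!is.null(gen)) {
    sp <- icosphere(gen$subdiv)
    fine <- triangle_mesh(lobe_surface(sp$vertices, gen$params), sp$faces)
  } else {
    if (params$target_n > n_vertices(mesh))
      stop("target_n exceeds the source vertex count for a non-generated mesh")
    fine <- mesh
  }
  def_v <- deflation_map(fine$vertices, params, hilum)
  fine_def <- set_vertices(fine, def_v)
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
                       stats::rnorm(n_vertices(fine_def), 0, params$noise_sd))
    fine_def <- set_vertices(fine_def,
                             fine_def$vertices + noise * fine_def$normals)
  }
  if (signed_volume_mm3(fine_def) <= 0)
    stop("deformed surface degenerated (non-positive volume); ",
         "use milder deflation parameters")
  deflated <- resample_to(fine_def, params$target_n)

  # evaluation points: nearest source vertices to the parametric tip/ridge
  # locations, paired with their exact displaced positions
  if (!is.null(gen)) {
    targets <- lobe_surface(eval_point_dirs(), gen$params)
  } else {
    targets <- mesh$vertices[c(which.max(mesh$vertices[, 3L])), , drop = FALSE]
  }
  vid <- nearest_vertex(targets, mesh$vertices)
  pts <- data.frame(
    label = c("tip", paste0("ridge-", seq_len(nrow(targets) - 1L)))[
      seq_len(nrow(targets))],
    vertex = vid,
    x_i = mesh$vertices[vid, 1L], y_i = mesh$vertices[vid, 2L],
    z_i = mesh$vertices[vid, 3L],
    x_d = mesh$vertices[vid, 1L] + truth[vid, 1L],
    y_d = mesh$vertices[vid, 2L] + truth[vid, 2L],
    z_d = mesh$vertices[vid, 3L] + truth[vid, 3L])

  list(deflated = deflated, truth = truth, points = pts, hilum = hilum,
       params = params)
}

#' Generate a seeded population of inflated/deflated lobe pairs
#'
#' Emulates a small-animal study design: per-case shape jitter plus
#' deflation parameters drawn from stated distributions (contraction
#' `c ~ N(c_mean, c_sd)` truncated to (0.5, 0.98], per-axis anisotropy
#' `~ N(0, aniso_sd)`, distance nonlinearity `~ N(nonlin_mean, nonlin_sd)`
#' truncated at 0, rotation `~ N(0, rot_sd)` degrees, bending
#' `~ N(0, bend_sd)` mm). All draws flow from `base_seed`; parameters are
#' logged per case.
#'
#' @param n_cases number of cases (>= 2).
#' @param base_seed master seed.
#' @param variation list of distribution settings: `shape` (0 disables
#'   per-case shape jitter), `c_mean`, `c_sd`, `rot_sd`, `bend_sd`,
#'   `noise_sd`. Missing entries take the defaults shown above.
#' @param n_vertices source-mesh resolution per case.
#' @param target_range integer range the target vertex count is drawn from.
#' @return list of cases, each `list(id, inflated, deflated, truth, points,
#'   hilum, params)`.
#' @export
make_population <- function(n_cases = 11L, base_seed = 7L,
                            variation = list(), n_vertices = 400L,
                            target_range = c(460L, 560L)) {
  if (n_cases < 2L) stop("need at least two cases")
  def <- list(shape = 1, c_mean = 0.78, c_sd = 0.08, rot_sd = 10,
              bend_sd = 2, aniso_sd = 0.05, nonlin_mean = 0.03,
              nonlin_sd = 0.01, apex_mean = 0.03, apex_sd = 0.01,
              base_mean = 0.025, base_sd = 0.01, noise_sd = 0.2)
  var <- utils::modifyList(def, variation)
  draws <- with_seed(base_seed, {
    list(shape_seed = sample.int(1e6L, n_cases),
         noise_seed = sample.int(1e6L, n_cases),
         c = stats::rnorm(n_cases, var$c_mean, var$c_sd),
         rot = stats::rnorm(n_cases, 0, max(var$rot_sd, 1e-12)),
         bend = stats::rnorm(n_cases, 0, max(var$bend_sd, 1e-12)),
         aniso = matrix(stats::rnorm(3L * n_cases, 0,
                                     max(var$aniso_sd, 1e-12)),
                        n_cases, 3L),
         nonlin = stats::rnorm(n_cases, var$nonlin_mean,
                               max(var$nonlin_sd, 1e-12)),
         apex = stats::rnorm(n_cases, var$apex_mean, max(var$apex_sd, 1e-12)),
         base = stats::rnorm(n_cases, var$base_mean, max(var$base_sd, 1e-12)),
         target_n = sample(seq(target_range[1L], target_range[2L]), n_cases,
                           replace = TRUE))
  })
  draws$c <- pmin(pmax(draws$c, 0.5), 0.98)
  draws$nonlin <- pmax(draws$nonlin, 0)
  draws$apex <- pmax(draws$apex, 0)
  draws$base <- pmax(draws$base, 0)
  if (var$rot_sd == 0) draws$rot[] <- 0
  if (var$bend_sd == 0) draws$bend[] <- 0
  if (var$aniso_sd == 0) draws$aniso[] <- 0
  if (var$nonlin_sd == 0) draws$nonlin[] <- var$nonlin_mean
  if (var$apex_sd == 0) draws$apex[] <- var$apex_mean
  if (var$base_sd == 0) draws$base[] <- var$base_mean
  if (var$shape == 0) {
    draws$shape_seed[] <- draws$shape_seed[1L]
    draws$target_n[] <- draws$target_n[1L]
  }
  lapply(seq_len(n_cases), function(k) {
    inflated <- make_lobe_mesh(draws$shape_seed[k], n_vertices = n_vertices)
    dp <- deflation_params(c = draws$c[k], rotation_deg = draws$rot[k],
                           bending = draws$bend[k],
                           aniso = draws$aniso[k, ],
                           nonlin = draws$nonlin[k],
                           apex_collapse = draws$apex[k],
                           base_collapse = draws$base[k],
                           noise_sd = var$noise_sd,
                           target_n = draws$target_n[k],
                           seed = draws$noise_seed[k])
    out <- apply_deflation(inflated, dp)
    list(id = k, inflated = inflated, deflated = out$deflated,
         truth = out$truth, points = out$points, hilum = out$hilum,
         params = dp)
  })
}
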