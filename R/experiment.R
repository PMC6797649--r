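# Desk-scale end-to-end experiment: simulate a population, build a template,
# register with all four methods, score, and fit the deformation model.

#' Default experiment configuration
#'
#' @param n_cases number of synthetic cases.
#' @param n_vertices template / source resolution.
#' @param seed master seed for the population and seeded sub-steps.
#' @param max_iterations iteration cap for the Laplacian methods (300 is the
#'   CI profile; 3000 the full profile).
#' @param methods registration methods to compare.
#' @param n_pieces cell count for the piecewise-affine baseline.
#' @param variation population variation settings (see [make_population()]).
#' @param exclude_cases case ids dropped from the linearity analysis (kept
#'   in all registrations).
#' @return a named list.
#' @export
experiment_config <- function(n_cases = 11L, n_vertices = 400L, seed = 7L,
                              max_iterations = 300L,
                              methods = c("lsmd", "lsm", "pwa", "affine"),
                              n_pieces = 4L, variation = list(),
                              exclude_cases = integer()) {
  list(n_cases = as.integer(n_cases), n_vertices = as.integer(n_vertices),
       seed = as.integer(seed), max_iterations = as.integer(max_iterations),
       methods = methods, n_pieces = as.integer(n_pieces),
       variation = variation, exclude_cases = as.integer(exclude_cases))
}

# register one source onto one target with the requested method
run_method <- function(method, source, target, cfg, n_pieces = 4L) {
  switch(method,
    lsmd = register_lsmd(source, target, cfg),
    lsm = register_lsm(source, target, cfg),
    pwa = register_piecewise_affine(source, target, n_pieces, cfg),
    affine = register_affine(source, target, cfg),
    stop("unknown method: ", method))
}

# score one registration of a synthetic case: surface distances, smoothness
# of the recovered field, and TDE at the case's evaluation points against
# the generator's ground truth
score_case <- function(res, case) {
  u_total <- res$mesh$vertices - case$inflated$vertices
  rep <- metric_report(res$mesh, case$deflated, res$displacement)
  vid <- case$points$vertex
  tde <- vapply(seq_along(vid), function(i)
    target_displacement_error(case$truth[vid[i], ], u_total[vid[i], ]),
    numeric(1L))
  c(md = rep$mean_distance, hd = rep$hausdorff,
    ld_mean = rep$ld_mean, ld_max = rep$ld_max, tde = mean(tde))
}

#' Run the full desk-scale experiment
#'
#' Simulates a seeded population of inflated/deflated lobe pairs, registers
#' each pair with every requested method (the source mesh acts as the
#' template, so ground truth is available at its vertices), tabulates mean
#' distance, Hausdorff distance, Laplacian-of-displacement and target
#' displacement error per method, then builds a population template,
#' registers it to every state, fits the statistical deformation model and
#' the hilum-distance linearity summaries.
#'
#' @param config from [experiment_config()].
#' @param progress print stage messages.
#' @return list with `population`, `metrics` (long data.frame), `summary`
#'   (method x metric means), `model` (a `deformation_model`), `template`,
#'   `variance_explained_2`, `linearity` (per case), `config`.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  say <- function(...) if (progress) message(...)
  cfg <- registration_config(max_iterations = config$max_iterations,
                             rng_seed = config$seed)
  say("simulating ", config$n_cases, " cases")
  pop <- make_population(config$n_cases, base_seed = config$seed,
                         variation = config$variation,
                         n_vertices = config$n_vertices)

  say("registering with: ", paste(config$methods, collapse = ", "))
  rows <- list()
  fits <- list()
  for (case in pop) {
    for (m in config$methods) {
      res <- run_method(m, case$inflated, case$deflated, cfg,
                        config$n_pieces)
      sc <- score_case(res, case)
      rows[[length(rows) + 1L]] <-
        data.frame(case = case$id, method = m, t(sc))
      if (m == "lsmd") fits[[case$id]] <- res
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- stats::aggregate(metrics[, c("md", "hd", "ld_mean", "ld_max",
                                          "tde")],
                              by = list(method = metrics$method), FUN = mean)

  model <- NULL; ve2 <- NA_real_; template <- NULL; linearity <- NULL
  if ("lsmd" %in% config$methods && length(pop) >= 2L) {
    say("building template and deformation model")
    template <- build_template(lapply(pop, `[[`, "inflated"),
                               seed_case = 1L,
                               n_vertices = config$n_vertices, cfg = cfg)
    samples <- list()
    linearity <- list()
    for (case in pop) {
      m_i <- register_lsmd(template, case$inflated, cfg)$mesh
      m_d <- register_lsmd(template, case$deflated, cfg)$mesh
      fld <- displacement_field(m_i, m_d)
      samples[[case$id]] <- fld
      if (!case$id %in% config$exclude_cases) {
        linearity[[as.character(case$id)]] <-
          hilum_linearity(m_i, fld, case$hilum)
      }
    }
    model <- fit_deformation_model(samples)
    # a zero-variation population has no model variance to attribute
    ve2 <- tryCatch(
      variance_explained(model, min(2L, length(model$eigenvalues))),
      error = function(e) NA_real_)
  }

  list(population = pop, metrics = metrics, summary = summary,
       model = model, template = template, variance_explained_2 = ve2,
       linearity = linearity, config = config)
}
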