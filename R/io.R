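# Plain-text CSV I/O for populations, diffusions and association
# matrices, plus the end-to-end pipeline driver used by the command-line
# script.

#' Read a population file
#'
#' CSV with columns `id, x, y` and optionally `radius` and `covariate`.
#' Radii missing from the file must be supplied later (e.g. via
#' `association_matrix(radius = )` after choosing one from the pair
#' correlation function). Covariates are normalised per `normalise`.
#'
#' @param path CSV path.
#' @param window observation window; defaults to the unit square.
#' @param normalise covariate normalisation: `"zscore"` (default),
#'   `"minmax"` or `"none"`.
#' @return list with `pattern` (a [point_pattern()]) and `covariates`
#'   (named vector, or `NULL` when the file has no covariate column).
#' @export
read_population <- function(path, window = c(0, 1, 0, 1),
                            normalise = c("zscore", "minmax", "none")) {
  normalise <- match.arg(normalise)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("population file is empty")
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop("population file must have columns id, x, y")
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("x and y must be numeric")
  radii <- if ("radius" %in% names(df)) df$radius else NA_real_
  pattern <- point_pattern(df$x, df$y, ids = df$id, radii = radii,
                           window = window)
  covariates <- NULL
  if ("covariate" %in% names(df)) {
    if (!is.numeric(df$covariate)) stop("covariate must be numeric")
    v <- df$covariate
    covariates <- switch(normalise,
      zscore = if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v),
      minmax = if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else v - min(v),
      none = v)
    names(covariates) <- df$id
  }
  list(pattern = pattern, covariates = covariates)
}

#' Write a population file
#'
#' @param pattern a [point_pattern()].
#' @param path output CSV path.
#' @param covariates optional per-individual covariate values (written
#'   un-normalised, as given).
#' @return the path, invisibly.
#' @export
write_population <- function(pattern, path, covariates = NULL) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  df <- data.frame(id = pattern$ids, x = pattern$x, y = pattern$y,
                   radius = pattern$radii)
  if (!is.null(covariates)) df$covariate <- as.numeric(covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a diffusion file
#'
#' CSV with columns `id, time` and optionally `censored` (0/1 or
#' logical). An empty `time` or `censored = 1` marks an individual that
#' never acquired the trait before the horizon.
#'
#' @param path CSV path.
#' @param ids optional population ids to validate against (order is
#'   taken from here when given).
#' @param horizon observation horizon (default `Inf`).
#' @return a [diffusion_record()]. A record in which every individual
#'   is censored is returned (it is valid on disk) but flagged with a
#'   warning, since it carries no information.
#' @export
read_diffusion <- function(path, ids = NULL, horizon = Inf) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("diffusion file is empty")
  if (!all(c("id", "time") %in% names(df)))
    stop("diffusion file must have columns id, time")
  df$id <- as.character(df$id)
  if (!is.null(ids)) ids <- as.character(ids)
  cens <- if ("censored" %in% names(df)) as.logical(df$censored) else is.na(df$time)
  if (any(!cens & df$time < 0)) stop("negative acquisition time")
  if (!is.null(ids)) {
    if (!setequal(df$id, ids))
      stop("diffusion ids do not match the population ids")
    ord <- match(ids, df$id)
    df <- df[ord, ]
    cens <- cens[ord]
  }
  if (all(cens)) {
    warning("all individuals censored: record is uninformative")
    rec <- structure(list(ids = df$id, times = rep(NA_real_, nrow(df)),
                          censored = cens, horizon = horizon,
                          innovator = NA),
                     class = "snbda_diffusion")
    return(rec)
  }
  diffusion_record(df$id, df$time, censored = cens, horizon = horizon)
}

#' Write a diffusion file
#'
#' @param record a [diffusion_record()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_diffusion <- function(record, path) {
  stopifnot(inherits(record, "snbda_diffusion"))
  utils::write.csv(data.frame(id = record$ids, time = record$times,
                              censored = as.integer(record$censored)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read an association matrix as CSV
#'
#' The matrix is stored with ids as header row and first column.
#'
#' @param A association matrix.
#' @param path CSV path.
#' @return `write_association`: the path, invisibly;
#'   `read_association`: the matrix with class `"snbda_assoc"`.
#' @export
write_association <- function(A, path) {
  m <- as.matrix(A)
  utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, colnames(m))
  storage.mode(m) <- "double"
  class(m) <- c("snbda_assoc", "matrix", "array")
  m
}

#' Run the full spatial diffusion-analysis pipeline
#'
#' Orchestrates the workflow end to end: obtain inputs (either
#' simulated through [simulate_study()] or read from population and
#' diffusion CSVs), explore the point pattern (pair correlation with a
#' CSR envelope and an interaction-radius suggestion), build the
#' association matrix, fit the requested models by Metropolis-Hastings,
#' discriminate between them by reversible jump, and run the
#' wave-of-advance baseline. All tabular outputs are written as CSV to
#' `outdir` together with a JSON manifest recording the configuration
#' and every seed, so a rerun from the manifest reproduces all outputs
#' exactly.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `outdir` (required); either `simulate` (list of [simulate_study()]
#'   arguments) or `population`/`diffusion` (input CSV paths, plus
#'   optional `horizon`, `window`); `radius` (number or `"auto"`);
#'   `models` (default `1:3`); `n_iter`, `burn_in`, `tuning`,
#'   `move_prob`, `beta_prior`; `n_sim` (envelope count, default 99);
#'   `seed` (master seed, default 1).
#' @return invisibly, a list with the in-memory results (`pattern`,
#'   `A`, `pcf`, `radius`, `fits`, `rj`, `summary`, `wave`, paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stop("config$outdir is required")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  models <- if (is.null(config$models)) 1:3 else as.integer(config$models)
  n_iter <- if (is.null(config$n_iter)) 20000 else config$n_iter
  burn_in <- if (is.null(config$burn_in)) 2000 else config$burn_in
  n_sim <- if (is.null(config$n_sim)) 99 else config$n_sim
  beta_prior <- if (is.null(config$beta_prior)) "signed-log" else config$beta_prior
  move_prob <- if (is.null(config$move_prob)) 0.5 else config$move_prob
  tuning <- if (is.null(config$tuning)) NULL else unlist(config$tuning)
  if (!all(models %in% 1:3)) stop("config$models must be a subset of 1:3")

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- if (is.null(sim_args$seed)) seed else sim_args$seed
    study <- do.call(simulate_study, sim_args)
    pattern <- study$pattern
    covariates <- study$covariates
    diffusions <- study$diffusions
    write_population(pattern, file.path(config$outdir, "population.csv"),
                     covariates = covariates)
    for (i in seq_along(diffusions))
      write_diffusion(diffusions[[i]],
                      file.path(config$outdir, sprintf("diffusion_%02d.csv", i)))
  } else {
    if (is.null(config$population) || is.null(config$diffusion))
      stop("config needs either `simulate` or `population` + `diffusion`")
    window <- if (is.null(config$window)) c(0, 1, 0, 1) else as.numeric(config$window)
    pop <- read_population(config$population, window = window)
    pattern <- pop$pattern
    covariates <- pop$covariates
    horizon <- if (is.null(config$horizon)) Inf else config$horizon
    paths <- config$diffusion
    diffusions <- lapply(paths, read_diffusion, ids = pattern$ids,
                         horizon = horizon)
  }

  # --- exploration and associations --------------------------------------
  pcf <- pair_correlation(pattern, n_sim = n_sim, seed = seed + 1L)
  radius_cfg <- if (is.null(config$radius)) "auto" else config$radius
  suggestion <- suggest_interaction_radius(pcf)
  radius <- if (identical(radius_cfg, "auto")) {
    if (is.na(suggestion$radius))
      stop("pattern consistent with CSR: no interaction radius can be suggested; set config$radius")
    suggestion$radius
  } else as.numeric(radius_cfg)
  utils::write.csv(as.data.frame(pcf), file.path(config$outdir, "pcf.csv"),
                   row.names = FALSE)
  A <- association_matrix(pattern, radius = radius)
  write_association(A, file.path(config$outdir, "association_matrix.csv"))

  # --- model fits ---------------------------------------------------------
  fits <- list()
  summary_rows <- list()
  for (m in models) {
    fit <- mh_sample(m, data = diffusions, A = A, covariates = covariates,
                     n_iter = n_iter, burn_in = burn_in, tuning = tuning,
                     seed = seed + 10L + m, beta_prior = beta_prior)
    fits[[as.character(m)]] <- fit
    ps <- posterior_summary(fit)$parameters
    ps$model <- m
    summary_rows[[as.character(m)]] <- ps
  }
  summary_tab <- do.call(rbind, summary_rows)
  utils::write.csv(summary_tab,
                   file.path(config$outdir, "posterior_summary.csv"),
                   row.names = FALSE)
  for (m in names(fits))
    utils::write.csv(as.data.frame(fits[[m]]$draws),
                     file.path(config$outdir, sprintf("trace_model%s.csv", m)),
                     row.names = FALSE)

  rj <- NULL; probs <- NULL; bf <- NULL
  if (length(models) >= 2) {
    rj <- rjmcmc_sample(models, data = diffusions, A = A,
                        covariates = covariates, n_iter = n_iter,
                        burn_in = burn_in, tuning = tuning,
                        move_prob = move_prob, seed = seed + 20L,
                        beta_prior = beta_prior)
    rj_sum <- posterior_summary(rj)
    probs <- rj_sum$model_probabilities
    utils::write.csv(data.frame(model = names(probs), probability = probs,
                                visits = rj_sum$model_counts),
                     file.path(config$outdir, "model_probabilities.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_len(rj$n_iter),
                                model = rj$model,
                                as.data.frame(rj$draws)),
                     file.path(config$outdir, "trace_rjmcmc.csv"),
                     row.names = FALSE)
    if (all(c(2, 3) %in% models) && all(rj_sum$model_counts[match(c(2, 3), models)] > 0))
      bf <- bayes_factor(rj, 2, 3)
  }

  # --- wave of advance ----------------------------------------------------
  wave <- tryCatch(wave_of_advance(pattern, diffusions[[1]]),
                   error = function(e) NULL)
  if (!is.null(wave))
    utils::write.csv(data.frame(slope = wave$slope, intercept = wave$intercept,
                                slope_se = wave$slope_se, p_value = wave$p_value,
                                r_squared = wave$r_squared, n = wave$n,
                                orientation = wave$orientation),
                     file.path(config$outdir, "wave_of_advance.csv"),
                     row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("snbda")),
    seed = seed, models = models, n_iter = n_iter, burn_in = burn_in,
    n_sim = n_sim, radius = radius, radius_source = if (identical(radius_cfg, "auto")) "pcf" else "config",
    suggestion = suggestion, beta_prior = beta_prior, move_prob = move_prob,
    bayes_factor_2_vs_3 = bf,
    model_probabilities = as.list(probs),
    config = config[setdiff(names(config), "outdir")]
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(pattern = pattern, covariates = covariates, A = A,
                 pcf = pcf, radius = radius, suggestion = suggestion,
                 fits = fits, rj = rj, model_probabilities = probs,
                 bayes_factor = bf, wave = wave, outdir = config$outdir))
}
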