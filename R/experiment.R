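#' Experiment configuration
#'
#' Collects every tunable of the replicate-fitting pipeline with the
#' standard defaults: ten replicate sets of 100 pseudo-presence training
#' points and 100 test points per run, regularization multiplier 1, all
#' smooth feature classes, a 10,000-cell background cap, and both MTP and
#' MTSS thresholds.
#'
#' @param scenario an `nm_scenario` (or NULL if masks/stack given directly
#'   to downstream calls).
#' @param n_sets,n_points,n_test_points replicate layout.
#' @param beta regularization multiplier (>= 0).
#' @param classes feature classes.
#' @param background_max background sample cap.
#' @param criteria thresholds to apply.
#' @param seed master seed; every random draw derives from it.
#' @param out_dir output directory for [run_experiment()].
#' @return object of class `nm_config`.
#' @export
experiment_config <- function(scenario = NULL, n_sets = 10, n_points = 100,
                              n_test_points = 100, beta = 1,
                              classes = c("linear", "quadratic", "product"),
                              background_max = 10000,
                              criteria = c("MTP", "MTSS"),
                              seed = 1, out_dir = NULL) {
  stopifnot(n_sets >= 1, n_points >= 1, n_test_points >= 1, beta >= 0,
            background_max >= 2)
  structure(list(scenario = scenario, n_sets = as.integer(n_sets),
                 n_points = as.integer(n_points),
                 n_test_points = as.integer(n_test_points),
                 beta = beta, classes = classes,
                 background_max = as.integer(background_max),
                 criteria = criteria, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "nm_config")
}

#' Fit the replicate models for one range mask
#'
#' Draws `n_sets` independent pseudo-presence sets from the mask, fits one
#' max-ent model per set against a shared background sample of the native
#' region, and projects each model (clamped) across the full stack.
#'
#' @param stack an `nm_stack`.
#' @param mask an `nm_mask` (training period).
#' @param region boolean `nm_grid`: the background / training region.
#' @param config an `nm_config`.
#' @return list of runs, each holding `model`, `map`, `train_scores`
#'   (training-presence logistic scores), `bg_scores`, `presence`,
#'   and the shared `background` points as an attribute.
#' @export
fit_replicates <- function(stack, mask, region, config) {
  design <- sample_design(n_points = config$n_points, n_sets = config$n_sets,
                          seed = config$seed)
  bg_pts <- sample_background(stack, region, max_n = config$background_max,
                              seed = config$seed)
  bg_tab <- extract_values(stack, bg_pts)
  bg_tab <- bg_tab[bg_tab$valid, ]
  runs <- vector("list", config$n_sets)
  for (i in seq_len(config$n_sets)) {
    pres <- sample_presence(mask, design, set_index = i)
    ptab <- extract_values(stack, pres)
    ptab <- ptab[ptab$valid, ]
    model <- maxent_fit(ptab[BIOCLIM_VARS], bg_tab[BIOCLIM_VARS],
                        beta = config$beta, classes = config$classes)
    map <- project_model(model, stack, clamp = TRUE,
                         run_id = sprintf("%s_%s_run%d", mask$species_label,
                                          mask$period, i),
                         species_label = mask$species_label,
                         period = mask$period)
    runs[[i]] <- list(model = model, map = map,
                      train_scores = predict_logistic(model, ptab),
                      bg_scores = predict_logistic(model, bg_tab),
                      presence = pres)
  }
  attr(runs, "background") <- bg_pts
  runs
}

#' Cell-wise mean of replicate logistic maps
#'
#' @param runs list of runs from [fit_replicates()].
#' @return an `nm_grid` of mean logistic suitability.
#' @export
mean_logistic_map <- function(runs) {
  ref <- runs[[1]]$map$logistic
  acc <- ref$values
  for (r in runs[-1]) acc <- acc + r$map$logistic$values
  grid_create(acc / length(runs), origin = ref$origin,
              cell_size = ref$cell_size, nodata = ref$nodata,
              crs_label = ref$crs_label)
}

# summarize per-run variable contributions as mean +/- SD
contribution_table <- function(runs) {
  tabs <- lapply(runs, function(r) variable_contribution(r$model))
  vars <- tabs[[1]]$variable
  m <- sapply(tabs, function(t) t$percent[match(vars, t$variable)])
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  data.frame(variable = vars,
             mean = rowMeans(m),
             sd = apply(m, 1, function(z) if (length(z) > 1) stats::sd(z) else 0),
             row.names = NULL)
}

#' Run the full replicate experiment on a synthetic scenario
#'
#' The end-to-end procedure for one species: for each period (modern and
#' historical), ten seeded replicate fits, the mean logistic map,
#' cumulative MTP and MTSS maps, same-period evaluation, the
#' modern-trained / historical-tested transfer evaluation, contribution
#' tables, a single-variable jackknife, clamped transfer-region projections
#' with a novelty grid, and a JSON manifest holding every seed and setting.
#' All outputs are written under `config$out_dir` (grids as ESRI ASCII,
#' tables as CSV). Any stage failure aborts with the stage name and leaves
#' a FAILED marker file next to the partial outputs.
#'
#' @param config an `nm_config` whose `scenario` and `out_dir` are set.
#' @return invisibly, a list with the in-memory results (`runs`, `eval`,
#'   `maps`, `tables`, `novelty`, paths).
#' @export
run_experiment <- function(config) {
  sc <- config$scenario
  if (is.null(sc) || !inherits(sc, "nm_scenario")) {
    stop("config$scenario must be an nm_scenario", call. = FALSE)
  }
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir must be set", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- list()
  tryCatch({
    masks <- list(modern = sc$modern_mask, historical = sc$historical_mask)
    runs <- list(); evals <- list(); tables <- list(); maps <- list()
    test_pts <- list()
    for (period in names(masks)) {
      stage <- paste0("fit_", period)
      runs[[period]] <- fit_replicates(sc$stack, masks[[period]],
                                       sc$native_region, config)
      stage <- paste0("test_points_", period)
      tdesign <- sample_design(n_points = config$n_test_points,
                               n_sets = 1, seed = config$seed)
      test_pts[[period]] <- list(
        presence = sample_presence(masks[[period]], tdesign, set_index = 9901,
                                   role = "test"),
        absence = sample_absence(masks[[period]], sc$native_region,
                                 config$n_test_points, config$seed))
      stage <- paste0("maps_", period)
      maps[[period]] <- list(mean_logistic = mean_logistic_map(runs[[period]]))
      write_grid(maps[[period]]$mean_logistic,
                 file.path(out, sprintf("mean_logistic_%s.asc", period)))
    }
    for (period in names(masks)) {
      stage <- paste0("evaluate_", period)
      ev <- evaluate_transfer(runs[[period]],
                              test_pts[[period]]$presence,
                              test_pts[[period]]$absence,
                              train_period = period, test_period = period,
                              criteria = config$criteria)
      evals[[paste0(period, "_", period)]] <- ev
      for (cr in names(ev$cumulative)) {
        write_grid(ev$cumulative[[cr]],
                   file.path(out, sprintf("cumulative_%s_%s.asc",
                                          tolower(cr), period)))
      }
      write_eval(ev, file.path(out, sprintf("evaluation_%s.csv", period)),
                 meta = list(beta = config$beta, seed = config$seed,
                             n_sets = config$n_sets,
                             n_points = config$n_points))
      stage <- paste0("contributions_", period)
      tables[[paste0("contribution_", period)]] <- contribution_table(runs[[period]])
      utils::write.csv(tables[[paste0("contribution_", period)]],
                       file.path(out, sprintf("contribution_%s.csv", period)),
                       row.names = FALSE)
      stage <- paste0("jackknife_", period)
      r1 <- runs[[period]][[1]]
      ptab <- extract_values(sc$stack, r1$presence)
      ttab <- extract_values(sc$stack, test_pts[[period]]$presence)
      btab <- extract_values(sc$stack, attr(runs[[period]], "background"))
      jk <- jackknife_single(ptab[ptab$valid, BIOCLIM_VARS],
                             btab[btab$valid, BIOCLIM_VARS],
                             ttab[ttab$valid, BIOCLIM_VARS],
                             beta = config$beta)
      tables[[paste0("jackknife_", period)]] <- jk
      utils::write.csv(jk, file.path(out, sprintf("jackknife_%s.csv", period)),
                       row.names = FALSE)
    }
    # cross-period transfer: modern-trained models against historical tests
    stage <- "evaluate_transfer_modern_to_historical"
    evals$modern_historical <- evaluate_transfer(
      runs$modern, test_pts$historical$presence, test_pts$historical$absence,
      train_period = "modern", test_period = "historical",
      criteria = config$criteria)
    write_eval(evals$modern_historical,
               file.path(out, "evaluation_modern_train_historical_test.csv"),
               meta = list(beta = config$beta, seed = config$seed))
    # transfer-region novelty (per period, using run 1's model bounds)
    stage <- "novelty"
    nov <- list()
    for (period in names(masks)) {
      nov[[period]] <- novelty(runs[[period]][[1]]$model, sc$stack,
                               region = sc$transfer_region)
      write_grid(nov[[period]]$count,
                 file.path(out, sprintf("novelty_%s.asc", period)))
    }
    stage <- "manifest"
    sc_cfg <- sc$config
    sc_cfg$true_weights <- as.list(sc_cfg$true_weights)  # names survive JSON
    manifest <- list(format = "nichemax-experiment", version = 1L,
                     seed = config$seed, beta = config$beta,
                     n_sets = config$n_sets, n_points = config$n_points,
                     n_test_points = config$n_test_points,
                     classes = config$classes,
                     background_max = config$background_max,
                     criteria = config$criteria,
                     scenario_config = sc_cfg)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res <- list(runs = runs, eval = evals, maps = maps, tables = tables,
                novelty = nov, test_points = test_pts, out_dir = out,
                manifest = manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

# shared helper for the two design curves: mean test AUC for one setting
curve_point <- function(sc, config, period = "historical") {
  mask <- if (period == "historical") sc$historical_mask else sc$modern_mask
  runs <- fit_replicates(sc$stack, mask, sc$native_region, config)
  tdesign <- sample_design(n_points = config$n_test_points, n_sets = 1,
                           seed = config$seed)
  tp <- sample_presence(mask, tdesign, set_index = 9901, role = "test")
  ta <- sample_absence(mask, sc$native_region, config$n_test_points,
                       config$seed)
  ev <- evaluate_transfer(runs, tp, ta, train_period = period,
                          test_period = period, criteria = config$criteria)
  ev$auc_mean
}

#' Training-set-size sensitivity curve
#'
#' Reruns the replicate pipeline at each training-set size and reports the
#' mean test AUC — the experiment used to justify the 100-point default.
#'
#' @param config an `nm_config` with `scenario` set.
#' @param point_counts vector of training-set sizes.
#' @param period which mask to train on (default historical).
#' @return data.frame of `n_points`, `mean_auc`.
#' @export
sample_size_curve <- function(config, point_counts, period = "historical") {
  stopifnot(length(point_counts) >= 1)
  rows <- lapply(point_counts, function(n) {
    cfg <- config; cfg$n_points <- as.integer(n)
    data.frame(n_points = n, mean_auc = curve_point(config$scenario, cfg,
                                                    period))
  })
  do.call(rbind, rows)
}

#' Regularization sensitivity curve
#'
#' Mean test AUC as a function of the regularization multiplier beta,
#' mirroring the comparison of the default multiplier 1 with 0.75.
#'
#' @param config an `nm_config` with `scenario` set.
#' @param betas vector of multipliers.
#' @param period which mask to train on (default historical).
#' @return data.frame of `beta`, `mean_auc`.
#' @export
regularization_curve <- function(config, betas, period = "historical") {
  stopifnot(length(betas) >= 1)
  rows <- lapply(betas, function(b) {
    cfg <- config; cfg$beta <- b
    data.frame(beta = b, mean_auc = curve_point(config$scenario, cfg, period))
  })
  do.call(rbind, rows)
}
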