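#' Run the full invasion-analysis pipeline
#'
#' Wires the stages end to end: community survey statistics, invasion
#' risk scoring, the diversity/climate driver model, the maximum-entropy
#' suitability model, natural-breaks classification with per-class
#' areas, and scenario comparison. Inputs are taken from the paths in
#' `config`; any input left `NULL` is generated synthetically from the
#' pipeline seed, so the default configuration is a fully reproducible
#' demonstration run.
#'
#' @param config a YAML file path or a named list; see
#'   [pipeline_config()] for the recognized fields and defaults.
#' @param ... fields overriding `config`.
#' @return invisibly, a list with each stage's results plus `manifest`
#'   (stage list, seeds, output files and their MD5 hashes). All outputs
#'   are also written under `config$out_dir`.
#' @export
run_invasion_pipeline <- function(config = NULL, ...) {
  cfg <- pipeline_config(config, ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  outputs <- character()
  res <- list()
  note <- function(stage) stages <<- c(stages, stage)
  emit <- function(path) outputs <<- c(outputs, path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------
  stack <- run_stage("inputs", {
    if (!is.null(cfg$raster_dir)) {
      read_env_dir(cfg$raster_dir)
    } else {
      gen_landscape(n_rows = cfg$demo$n_rows, n_cols = cfg$demo$n_cols,
                    cell_size_km = cfg$demo$cell_size_km,
                    seed = cfg$seeds$landscape)
    }
  })
  survey <- run_stage("inputs", {
    if (!is.null(cfg$survey_csv)) {
      read_survey(cfg$survey_csv)
    } else {
      gen_survey(stack, n_plots = cfg$demo$n_plots, invader = cfg$invader,
                 seed = cfg$seeds$survey)
    }
  })
  occurrences <- run_stage("inputs", {
    if (!is.null(cfg$occurrence_csv)) {
      utils::read.csv(cfg$occurrence_csv, stringsAsFactors = FALSE)
    } else {
      truth <- truth_model(linear = c(bio1 = 12, bio16 = 12, bio6 = 3),
                           quadratic = c(bio1 = -12, bio16 = -8))
      gen_occurrences(stack, truth, n = cfg$demo$n_occurrences,
                      species = cfg$invader, seed = cfg$seeds$occurrences)
    }
  })

  # --- survey statistics --------------------------------------------
  res$survey <- run_stage("survey", {
    occ <- occurrence_rate(survey, cfg$invader)
    fam <- family_composition(survey)
    comm <- community_summary(survey)
    div <- survey_diversity(survey)
    utils::write.csv(fam, f <- file.path(cfg$out_dir,
                                         "family_composition.csv"),
                     row.names = FALSE)
    emit(f)
    utils::write.csv(comm, f <- file.path(cfg$out_dir,
                                          "community_summary.csv"),
                     row.names = FALSE)
    emit(f)
    list(occurrence = occ, families = fam, communities = comm,
         diversity = div)
  })
  note("survey")

  # --- risk scoring -------------------------------------------------
  res$risk <- run_stage("risk", {
    sheet <- if (!is.null(cfg$scoresheet_json)) {
      read_risk_scoresheet(cfg$scoresheet_json)
    } else {
      gen_risk_scoresheet(1, species = cfg$invader,
                          seed = cfg$seeds$risk)
    }
    result <- assess(sheet)
    jsonlite::write_json(
      list(species = result$species, P1 = result$P1, P2 = result$P2,
           P3 = result$P3, P4 = result$P4, P = result$P,
           P_display = round(result$P, 2), level = result$level),
      f <- file.path(cfg$out_dir, "risk_assessment.json"),
      auto_unbox = TRUE, digits = NA)
    emit(f)
    result
  })
  note("risk")

  # --- driver model -------------------------------------------------
  res$drivers <- run_stage("drivers", {
    tab <- build_driver_table(survey, stack, cfg$invader,
                              env_vars = cfg$driver_vars)
    screen <- collinearity_screen(tab, threshold = cfg$screen_threshold)
    fit <- fit_glm(tab, predictors = screen$retained)
    utils::write.csv(fit$coefficients,
                     f <- file.path(cfg$out_dir,
                                    "driver_coefficients.csv"),
                     row.names = FALSE)
    emit(f)
    jsonlite::write_json(
      list(r_squared = fit$r_squared, n = fit$n, family = fit$family,
           retained = screen$retained),
      f <- file.path(cfg$out_dir, "driver_fit.json"),
      auto_unbox = TRUE, digits = NA)
    emit(f)
    list(table = tab, screen = screen, fit = fit)
  })
  note("drivers")

  # --- maxent SDM ---------------------------------------------------
  res$sdm <- run_stage("sdm", {
    screen <- spearman_screen(stack, occurrences,
                              threshold = cfg$screen_threshold,
                              n_background = cfg$n_background,
                              seed = cfg$seeds$background)
    background <- sample_background(stack, n = cfg$n_background,
                                    seed = cfg$seeds$background)
    sp <- split_train_test(occurrences, ratio = cfg$split_ratio,
                           seed = cfg$seeds$split)
    model <- fit_maxent(sp$train, background, stack = stack,
                        variables = screen$retained,
                        features = cfg$features,
                        n_hinge_knots = cfg$n_hinge_knots,
                        reg_multiplier = cfg$reg_multiplier,
                        seed = cfg$seeds$background)
    eval_rep <- list(
      auc_train = model_auc(model, sp$train, background, stack),
      auc_test = model_auc(model, sp$test, background, stack),
      split_ratio = cfg$split_ratio, seed = cfg$seeds$split
    )
    contrib <- percent_contribution(model)
    perm <- permutation_importance(model, occurrences, background,
                                   stack = stack,
                                   seed = cfg$seeds$permutation)
    utils::write.csv(contrib, f <- file.path(cfg$out_dir,
                                             "percent_contribution.csv"),
                     row.names = FALSE)
    emit(f)
    utils::write.csv(perm, f <- file.path(cfg$out_dir,
                                          "permutation_importance.csv"),
                     row.names = FALSE)
    emit(f)
    jsonlite::write_json(eval_rep,
                         f <- file.path(cfg$out_dir, "sdm_eval.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(f)
    list(screen = screen, model = model, background = background,
         split = sp, eval = eval_rep, contributions = contrib,
         permutation = perm)
  })
  note("sdm")

  # --- suitability classification -----------------------------------
  res$suitability <- run_stage("suitability", {
    surface <- predict(res$sdm$model, stack)
    breaks <- jenks_breaks(surface, k = 4L, seed = cfg$seeds$jenks)
    classified <- classify_surface(surface, breaks)
    cell_area <- stack$cell_size^2
    current <- class_areas(classified, cell_area, scenario = "current",
                           period = "current")
    f <- file.path(cfg$out_dir, "suitability_current.asc")
    write_asc(surface, f, cell_size = stack$cell_size,
              origin = stack$origin)
    emit(f)
    scen_reports <- list(current = current)
    scen_defs <- scenario_definitions(cfg)
    for (nm in names(scen_defs)) {
      sd_ <- scen_defs[[nm]]
      fut_stack <- if (!is.null(sd_$raster_dir)) {
        read_env_dir(sd_$raster_dir)
      } else {
        gen_scenario_stack(stack, delta_temp = sd_$delta_temp,
                           precip_factor = sd_$precip_factor,
                           seed = sd_$seed)
      }
      fut_surface <- predict(res$sdm$model, fut_stack)
      fut_breaks <- if (cfg$rebin_scenarios) {
        jenks_breaks(fut_surface, k = 4L, seed = cfg$seeds$jenks)
      } else {
        breaks
      }
      fut_classified <- classify_surface(fut_surface, fut_breaks)
      scen_reports[[nm]] <- class_areas(fut_classified, cell_area,
                                        scenario = sd_$scenario,
                                        period = sd_$period)
    }
    list(breaks = breaks, classified = classified, reports = scen_reports)
  })
  note("suitability")

  # --- scenario comparison ------------------------------------------
  res$comparison <- run_stage("comparison", {
    reports <- res$suitability$reports
    tab <- scenario_table(reports)
    deltas <- lapply(reports[-1L], function(r) {
      scenario_delta(reports$current, r)
    })
    utils::write.csv(tab, f <- file.path(cfg$out_dir,
                                         "scenario_table.csv"),
                     row.names = FALSE)
    emit(f)
    delta_tab <- do.call(rbind, lapply(names(deltas), function(nm) {
      d <- deltas[[nm]]
      data.frame(comparison = nm, class = d$class, label = d$label,
                 delta_km2 = d$delta_km2,
                 delta_total_percent = attr(d, "delta_total_percent"))
    }))
    utils::write.csv(delta_tab, f <- file.path(cfg$out_dir,
                                               "scenario_deltas.csv"),
                     row.names = FALSE)
    emit(f)
    list(table = tab, deltas = deltas)
  })
  note("comparison")

  manifest <- list(
    package = "invascape",
    version = as.character(utils::packageVersion("invascape")),
    stages = stages,
    seeds = cfg$seeds,
    outputs = basename(outputs),
    md5 = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                  basename(outputs)))
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Pipeline configuration
#'
#' Builds the full configuration list from a YAML file or a named list,
#' filling defaults. Recognized fields: `out_dir`, `seed` (master seed
#' from which per-stage seeds derive), `invader`, `survey_csv`,
#' `occurrence_csv`, `raster_dir`, `scoresheet_json`, `scenarios` (list
#' of `name`, `scenario`, `period` plus either `raster_dir` or
#' `delta_temp`/`precip_factor`), `screen_threshold` (0.75),
#' `split_ratio` (0.75), `n_background` (10000), `reg_multiplier` (1),
#' `features`, `n_hinge_knots`, `driver_vars`, `rebin_scenarios`
#' (FALSE: future surfaces reuse the current-scenario breaks), and demo
#' sizes under `demo` (`n_rows`, `n_cols`, `cell_size_km`, `n_plots`,
#' `n_occurrences`).
#'
#' @param config YAML path or named list (optional).
#' @param ... overrides.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  config <- utils::modifyList(config, list(...))
  defaults <- list(
    out_dir = file.path(tempdir(), "invascape-run"),
    seed = 42L,
    invader = "Solidago canadensis",
    survey_csv = NULL, occurrence_csv = NULL, raster_dir = NULL,
    scoresheet_json = NULL, scenarios = NULL,
    screen_threshold = 0.75, split_ratio = 0.75,
    n_background = 10000L, reg_multiplier = 1,
    features = c("linear", "quadratic", "hinge"), n_hinge_knots = 5L,
    driver_vars = c("bio1", "bio6", "bio8", "bio17", "bio18"),
    rebin_scenarios = FALSE,
    demo = list(n_rows = 60L, n_cols = 60L, cell_size_km = 0.5,
                n_plots = 595L, n_occurrences = 400L)
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$demo <- utils::modifyList(defaults$demo, as.list(cfg$demo))
  base <- as.integer(cfg$seed)
  cfg$seeds <- list(landscape = base, survey = base + 1L,
                    occurrences = base + 2L, risk = base + 3L,
                    background = base + 4L, split = base + 5L,
                    permutation = base + 6L, jenks = base + 7L,
                    scenarios = base + 8L)
  if (cfg$screen_threshold <= 0 || cfg$screen_threshold >= 1 ||
      cfg$split_ratio <= 0 || cfg$split_ratio >= 1 ||
      cfg$n_background <= 0) {
    stop("invalid configuration: thresholds/ratios must lie in (0, 1) ",
         "and n_background must be positive", call. = FALSE)
  }
  cfg
}

# Scenario definitions: user-specified raster dirs, or the default
# synthetic emulation of three emission pathways at two horizons. The
# default anomalies are kept commensurate with the demo landscape's
# spatial climate spread, so scenario comparison exercises class shifts
# rather than uniform saturation.
scenario_definitions <- function(cfg) {
  if (!is.null(cfg$scenarios)) {
    out <- list()
    for (s in cfg$scenarios) {
      nm <- if (!is.null(s$name)) s$name else
        paste(s$scenario, s$period, sep = "_")
      s$seed <- cfg$seeds$scenarios
      out[[nm]] <- s
    }
    return(out)
  }
  grid <- expand.grid(
    scenario = c("SSP1-2.6", "SSP2-4.5", "SSP5-8.5"),
    period = c("2050s", "2070s"), stringsAsFactors = FALSE
  )
  warming <- c("SSP1-2.6" = 0.15, "SSP2-4.5" = 0.25, "SSP5-8.5" = 0.4)
  horizon <- c("2050s" = 1.0, "2070s" = 1.4)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- grid$scenario[i]
    pd <- grid$period[i]
    out[[paste(sc, pd, sep = "_")]] <- list(
      scenario = sc, period = pd,
      delta_temp = warming[[sc]] * horizon[[pd]],
      precip_factor = 1 + 0.08 * warming[[sc]] * horizon[[pd]],
      seed = cfg$seeds$scenarios + i
    )
  }
  out
}
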