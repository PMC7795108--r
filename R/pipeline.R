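#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. All
#' randomness flows from the single `seed`: the region generator uses it
#' directly and each permutation stage uses a fixed offset substream, so
#' any stage can be reproduced in isolation.
#'
#' @param region A [region_config] (synthetic source) or a directory path
#'   holding a serialized region ([write_region] layout).
#' @param access An [access_params].
#' @param fca_time,fca_space [fca_params] for the two metrics.
#' @param weights_scheme,row_standardize Spatial-weights settings.
#' @param n_permutations,alpha Moran/LISA permutation settings.
#' @param bins Percentile bins for the equity composition tables.
#' @param sweep A [sweep_spec].
#' @param suppress_capital_own Passed to [tertiary_access].
#' @param rule Cost-combination rule, see [od_cost].
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(region = region_config(),
                            access = access_params(),
                            fca_time = fca_params("time"),
                            fca_space = fca_params("space"),
                            weights_scheme = "queen",
                            row_standardize = TRUE,
                            n_permutations = 199, alpha = 0.05,
                            bins = seq(0, 100, by = 10),
                            sweep = sweep_spec(),
                            suppress_capital_own = FALSE,
                            rule = "min", seed = 1L) {
  if (is.character(region) && !dir.exists(region))
    stop("region directory does not exist: ", region)
  structure(list(region = region, access = access, fca_time = fca_time,
                 fca_space = fca_space, weights_scheme = weights_scheme,
                 row_standardize = row_standardize,
                 n_permutations = n_permutations, alpha = alpha,
                 bins = bins, sweep = sweep,
                 suppress_capital_own = suppress_capital_own,
                 rule = rule, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full accessibility analysis
#'
#' Executes every stage in order -- region generation (or load), cost
#' matrices (time without rail, time with rail, space), the six
#' accessibility surfaces, global Moran's I per region and subdivision
#' plus region-wide LISA for every surface, the equity report, and the
#' sensitivity sweep -- writing each artifact to `out_dir` in the standard
#' CSV/GeoJSON/JSON formats and a `manifest.json` listing every file with
#' its MD5 checksum, the full parameter set, and collected warnings.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results (`region`,
#'   `surfaces`, `moran`, `lisa`, `equity`, `sweep`, `manifest`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(stage, msg)
    warnings_log <<- c(warnings_log, paste0("[", stage, "] ", msg))
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      message = function(m) {
        note(stage, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        note(stage, trimws(conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # generate ---------------------------------------------------------------
  region <- run_stage("generate", {
    if (is.character(config$region)) read_region(config$region) else {
      rc <- config$region
      rc$seed <- config$seed
      generate_region(rc)
    }
  })
  write_region(region, file.path(out_dir, "region"))

  # costs + surfaces -------------------------------------------------------
  surf <- run_stage("costs", accessibility_surfaces(
    region, config$access, config$fca_time, config$fca_space,
    config$suppress_capital_own, config$rule))
  write_cost_matrix(surf$costs_time, file.path(out_dir, "costs_time.csv"))
  write_cost_matrix(surf$costs_space, file.path(out_dir, "costs_space.csv"))
  write_cost_matrix(surf$costs_time_rail,
                    file.path(out_dir, "costs_time_rail.csv"))
  labs <- c("Pri_T", "Pri_S", "Sec_T", "Sec_S", "Ter_T", "Ter_S")
  for (lab in labs)
    write_surface(surf[[lab]], file.path(out_dir,
                                         paste0("surface_", lab, ".csv")),
                  region$cells)

  # autocorrelation --------------------------------------------------------
  moran <- run_stage("autocorr", {
    W <- build_weights(region$cells, config$weights_scheme,
                       config$row_standardize)
    out <- list()
    for (lab in labs) {
      out[[lab]] <- moran_by_subdivision(
        surf[[lab]], region, config$weights_scheme,
        config$row_standardize, config$n_permutations,
        seed = config$seed + 1000L)
    }
    out
  })
  lisa <- run_stage("autocorr", {
    W <- build_weights(region$cells, config$weights_scheme,
                       config$row_standardize)
    out <- list()
    for (lab in labs) {
      out[[lab]] <- local_moran(surf[[lab]], W, config$n_permutations,
                                config$alpha, seed = config$seed + 2000L)
      write_moran(out[[lab]], file.path(out_dir,
                                        paste0("lisa_", lab, ".csv")))
    }
    out
  })
  moran_tab <- do.call(rbind, lapply(labs, function(lab) {
    do.call(rbind, lapply(names(moran[[lab]]), function(rn) {
      m <- moran[[lab]][[rn]]
      data.frame(surface = lab, region = rn, global_I = m$global_I,
                 expected_I = m$expected_I, p_value = m$p_value,
                 n = m$n)
    }))
  }))
  utils::write.csv(moran_tab, file.path(out_dir, "moran_global.csv"),
                   row.names = FALSE, quote = FALSE)

  # equity ------------------------------------------------------------------
  equity <- run_stage("equity",
                      equity_report(surf[labs], region, config$bins))
  utils::write.csv(equity$gini, file.path(out_dir, "gini.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(equity$correlations,
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  for (lab in names(equity$composition))
    for (grp in names(equity$composition[[lab]]))
      utils::write.csv(equity$composition[[lab]][[grp]],
                       file.path(out_dir, paste0("composition_", lab, "_",
                                                 grp, ".csv")),
                       row.names = FALSE, quote = FALSE)

  # sensitivity -------------------------------------------------------------
  sweep <- run_stage("sweep", run_sweep(region, config$sweep,
                                        config$access,
                                        costs = surf$costs_time,
                                        rule = config$rule))
  utils::write.csv(sweep$table, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE, quote = FALSE)
  for (key in names(sweep$pairs))
    .write_csv_full(sweep$pairs[[key]],
                    file.path(out_dir, paste0("scatter_",
                                              gsub("=", "_", key),
                                              ".csv")))

  # manifest ----------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  checks <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    seed = config$seed,
    parameters = list(
      access = unclass(config$access),
      fca_time = unclass(config$fca_time),
      fca_space = unclass(config$fca_space),
      weights_scheme = config$weights_scheme,
      row_standardize = config$row_standardize,
      n_permutations = config$n_permutations, alpha = config$alpha,
      rule = config$rule,
      sweep = unclass(config$sweep),
      suppress_capital_own = config$suppress_capital_own),
    warnings = warnings_log,
    artifacts = stats::setNames(as.list(unname(checks)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(region = region, surfaces = surf, moran = moran,
                 lisa = lisa, equity = equity, sweep = sweep,
                 manifest = manifest))
}
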