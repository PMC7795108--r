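#' Sensitivity sweep specification
#'
#' One-at-a-time sweep of the 2SFCA service threshold (30-min steps around
#' the 120-min default) and of the tertiary capacity weight (0.5 steps
#' around the default 2).
#'
#' @param thresholds Catchment thresholds to sweep (metric units).
#' @param weights Tertiary capacity weights to sweep.
#' @param surface `"Sec_T"` or `"Sec_S"` -- which 2SFCA surface to sweep.
#' @param d0_default,weight_default The defaults held fixed while the
#'   other parameter varies.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(thresholds = c(90, 120, 150),
                       weights = c(1.5, 2, 2.5),
                       surface = c("Sec_T", "Sec_S"),
                       d0_default = 120, weight_default = 2) {
  surface <- match.arg(surface)
  stopifnot(length(thresholds) > 0, length(weights) > 0,
            all(thresholds > 0), all(weights > 0),
            d0_default > 0, weight_default > 0)
  structure(list(thresholds = thresholds, weights = weights,
                 surface = surface, d0_default = d0_default,
                 weight_default = weight_default), class = "sweep_spec")
}

#' Nearest-rank percentile summary of a surface
#'
#' The 10th..100th percentiles by the nearest-rank convention (value at
#' position `ceiling(p/100 * n)` of the sorted vector), plus max, min,
#' mid (50th percentile), mean and standard deviation. With
#' `population_weighted = TRUE` the rank position runs over cumulative
#' population share instead of cell count.
#'
#' @param surface An `accessibility_surface` or numeric vector.
#' @param populations Optional per-cell weights (required when
#'   `population_weighted`).
#' @param population_weighted Logical.
#' @return Named numeric vector (`p10`..`p100`, `max`, `min`, `mid`,
#'   `mean`, `std`).
#' @export
percentile_summary <- function(surface, populations = NULL,
                               population_weighted = FALSE) {
  v <- if (inherits(surface, "accessibility_surface")) surface$values else
    surface
  stopifnot(length(v) > 0)
  o <- order(v)
  vs <- v[o]
  pr <- seq(10, 100, by = 10)
  if (population_weighted) {
    if (is.null(populations)) stop("populations required when weighting")
    w <- populations[o]
    cw <- cumsum(w) / sum(w)
    q <- vapply(pr / 100, function(p) vs[which(cw >= p - 1e-12)[1]],
                numeric(1))
  } else {
    q <- vs[ceiling(pr / 100 * length(vs))]
  }
  mid <- q[pr == 50]
  c(stats::setNames(q, paste0("p", pr)),
    max = max(v), min = min(v), mid = unname(mid),
    mean = mean(v), std = stats::sd(v))
}

#' One-at-a-time sensitivity sweep of threshold and capacity weight
#'
#' Recomputes the chosen 2SFCA surface for each catchment threshold
#' (holding the tertiary weight at its default) and for each tertiary
#' capacity weight (holding the threshold at its default), over the
#' secondary + tertiary facility subset. Emits a percentile summary row
#' per parameterization and, for each off-default parameterization, the
#' (default, variant) per-cell value pairs for 45-degree scatter
#' comparison.
#'
#' @param region A `study_region`.
#' @param spec A [sweep_spec].
#' @param access An [access_params].
#' @param costs Optional precomputed [cost_matrix] on the full facility
#'   table (matching the sweep's metric); computed if missing.
#' @param rule Passed to [cost_matrix] when costs are computed here.
#' @return An object of class `sensitivity_result`: list with `table`
#'   (data frame, one row per parameterization), `pairs` (named list of
#'   data frames `default`/`variant`), `surfaces`, `spec`.
#' @export
run_sweep <- function(region, spec = sweep_spec(),
                      access = access_params(), costs = NULL,
                      rule = "min") {
  stopifnot(inherits(spec, "sweep_spec"))
  metric <- if (spec$surface == "Sec_T") "time" else "space"
  if (is.null(costs))
    costs <- cost_matrix(region$cells, region$facilities, region$network,
                         access, metric, rule)
  fac <- region$facilities[region$facilities$level %in%
                             c("secondary", "tertiary"), , drop = FALSE]
  compute <- function(d0, w) {
    f <- fac
    f$capacity_weight[f$level == "tertiary"] <- w
    two_step_fca(costs, region$cells, f,
                 fca_params(metric, d0 = d0))
  }
  runs <- rbind(
    data.frame(param = "threshold", value = spec$thresholds,
               d0 = spec$thresholds, w = spec$weight_default),
    data.frame(param = "weight", value = spec$weights,
               d0 = spec$d0_default, w = spec$weights))
  surfaces <- list(); rows <- list(); pairs <- list()
  default <- compute(spec$d0_default, spec$weight_default)
  for (k in seq_len(nrow(runs))) {
    key <- paste0(runs$param[k], "=", runs$value[k])
    s <- if (runs$d0[k] == spec$d0_default &&
             runs$w[k] == spec$weight_default) default else
      compute(runs$d0[k], runs$w[k])
    surfaces[[key]] <- s
    rows[[key]] <- data.frame(param = runs$param[k],
                              value = runs$value[k],
                              t(percentile_summary(s)))
    if (!(runs$d0[k] == spec$d0_default &&
          runs$w[k] == spec$weight_default))
      pairs[[key]] <- data.frame(cell_id = names(default$values),
                                 default = unname(default$values),
                                 variant = unname(s$values))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 pairs = pairs, surfaces = surfaces, spec = spec),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> surface ", x$spec$surface, "\n", sep = "")
  print(x$table[, c("param", "value", "min", "mid", "mean", "max", "std")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Scatter plot of a sweep comparison against the default parameterization
#'
#' @param x A `sensitivity_result`.
#' @param which Name of the comparison (an element of `x$pairs`).
#' @param ... Passed to [graphics::plot].
#' @export
plot.sensitivity_result <- function(x, which = names(x$pairs)[1], ...) {
  p <- x$pairs[[which]]
  graphics::plot(p$default, p$variant, xlab = "default", ylab = which,
                 main = paste(x$spec$surface, "sensitivity"), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
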