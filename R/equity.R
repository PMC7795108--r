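#' Reciprocal min-max normalization of a cost surface
#'
#' Nearest-cost surfaces measure accessibility as a travel cost (lower =
#' better); before Lorenz/Gini accumulation they are mapped so that higher
#' = better: `y_i = (1/x_i - min(1/x)) / (max(1/x) - min(1/x))`. Index
#' surfaces (`Sec_*`, `Ter_*`) pass through unchanged.
#'
#' @param surface An `accessibility_surface`.
#' @return An `accessibility_surface` (normalized for `Pri_*` labels,
#'   untouched otherwise).
#' @export
invert_normalize <- function(surface) {
  if (!startsWith(surface$label, "Pri")) return(surface)
  x <- surface$values
  if (any(x <= 0)) stop("cost surface must be strictly positive to invert")
  r <- 1 / x
  rng <- range(r)
  y <- if (rng[1] == rng[2]) {
    message("constant cost surface: normalization degenerates to 0")
    r * 0
  } else (r - rng[1]) / (rng[2] - rng[1])
  .surface(y, paste0(surface$label, "_norm"), "normalized", surface$params)
}

#' Lorenz curve and Gini coefficient of population-weighted accessibility
#'
#' Units are sorted by ascending accessibility (ties broken by unit id);
#' the curve accumulates population share on the horizontal axis and
#' population-weighted accessibility share on the vertical axis. The Gini
#' coefficient is twice the area between the curve and the equal-share
#' diagonal, computed by the trapezoid rule: `G = 1 - sum (x_k - x_{k-1})
#' (y_k + y_{k-1})`. Zero-population units carry no mass and are dropped
#' from the accumulation.
#'
#' @param values Per-unit accessibility (higher = better; pass `Pri_*`
#'   surfaces through [invert_normalize] first). May be an
#'   `accessibility_surface`.
#' @param populations Per-unit population weights (same order).
#' @param label Optional label stored on the result.
#' @return An object of class `lorenz_result`: list with `points` (data
#'   frame `pop_share`, `access_share`), `gini`, `label`.
#' @export
lorenz_gini <- function(values, populations, label = NULL) {
  if (inherits(values, "accessibility_surface")) {
    if (is.null(label)) label <- values$label
    values <- values$values
  }
  stopifnot(length(values) == length(populations))
  if (any(populations < 0) || any(values < 0))
    stop("values and populations must be non-negative")
  keep <- populations > 0
  v <- values[keep]; p <- populations[keep]
  if (sum(p) == 0) stop("total population is zero")
  if (sum(p * v) == 0) stop("all accessibility values are zero; ",
                            "Lorenz curve undefined")
  ids <- if (!is.null(names(v))) names(v) else as.character(seq_along(v))
  o <- order(v, ids)
  v <- v[o]; p <- p[o]
  x <- c(0, cumsum(p) / sum(p))
  y <- c(0, cumsum(p * v) / sum(p * v))
  gini <- 1 - sum(diff(x) * (y[-1] + y[-length(y)]))
  structure(list(points = data.frame(pop_share = x, access_share = y),
                 gini = gini, label = label),
            class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat("<lorenz_result>", if (!is.null(x$label)) x$label,
      " Gini =", format(x$gini, digits = 4), "\n")
  invisible(x)
}

#' Plot a Lorenz curve
#'
#' @param x A `lorenz_result`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.lorenz_result <- function(x, ...) {
  graphics::plot(x$points$pop_share, x$points$access_share, type = "l",
                 xlab = "cumulative population share",
                 ylab = "cumulative accessibility share",
                 main = paste0(if (!is.null(x$label))
                   paste0(x$label, ": "), "Gini = ",
                   format(x$gini, digits = 3)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Population-weighted aggregation of a surface to counties
#'
#' County value = `sum(pop_i * value_i) / sum(pop_i)` over the county's
#' cells. Zero-population counties are excluded with a warning.
#'
#' @param surface An `accessibility_surface` (or named numeric by cell id).
#' @param cells Cell table with `id`, `population`, `county_id`.
#' @return Named numeric vector of county values (names = county ids).
#' @export
aggregate_to_county <- function(surface, cells) {
  v <- if (inherits(surface, "accessibility_surface")) surface$values else
    surface
  if (!all(as.character(cells$id) %in% names(v)))
    stop("surface does not cover all cells")
  if (any(is.na(cells$county_id))) stop("unknown county id on some cells")
  v <- v[as.character(cells$id)]
  num <- tapply(cells$population * v, cells$county_id, sum)
  den <- tapply(cells$population, cells$county_id, sum)
  if (any(den == 0))
    warning(sum(den == 0), " zero-population county(ies) excluded")
  out <- num[den > 0] / den[den > 0]
  stats::setNames(as.numeric(out), names(den)[den > 0])
}

#' Pearson correlation between county accessibility and a group share
#'
#' Two-tailed Pearson test (t transform) between per-county accessibility
#' and a per-county population-composition ratio, with the conventional
#' significance stars (`**` p < 0.01, `*` p < 0.05).
#'
#' @param county_values Named numeric, per-county accessibility.
#' @param group_ratios Named numeric, per-county group share; matched to
#'   `county_values` by name when both are named.
#' @return List with `r`, `p`, `stars`, `n`.
#' @export
group_correlation <- function(county_values, group_ratios) {
  if (!is.null(names(county_values)) && !is.null(names(group_ratios))) {
    common <- intersect(names(county_values), names(group_ratios))
    county_values <- county_values[common]
    group_ratios <- group_ratios[common]
  }
  if (length(county_values) < 3)
    stop("need at least 3 counties for a correlation")
  if (stats::sd(county_values) == 0 || stats::sd(group_ratios) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(county_values, group_ratios, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate); p <- ct$p.value
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(r = r, p = p, stars = stars, n = length(county_values))
}

#' Group composition ratios across accessibility percentile bins
#'
#' Cells are ranked by surface value and cut into percentile bins
#' (population-weighted by default: bin edges fall on cumulative
#' population shares; `cell_count = TRUE` bins equal numbers of cells
#' instead). Within each bin the group's share of the bin population is
#' reported together with the complement share (the two sum to 1). A
#' top-10% readout is appended.
#'
#' @param surface An `accessibility_surface` (or named numeric by cell id).
#' @param cells Cell table with `id`, `population`.
#' @param group_counts Per-cell group population (same order as `cells`).
#' @param bins Percentile bin edges over \[0, 100\] (default deciles).
#' @param cell_count Logical; bin by cell count instead of population.
#' @return Data frame with `bin`, `lo`, `hi`, `group_share`,
#'   `complement_share` (NA for empty bins); the final row is the top-10%
#'   bin.
#' @export
quantile_composition <- function(surface, cells, group_counts,
                                 bins = seq(0, 100, by = 10),
                                 cell_count = FALSE) {
  v <- if (inherits(surface, "accessibility_surface")) surface$values else
    surface
  v <- v[as.character(cells$id)]
  stopifnot(length(group_counts) == nrow(cells),
            all(group_counts <= cells$population))
  if (bins[1] != 0 || bins[length(bins)] != 100 || is.unsorted(bins))
    stop("bins must partition [0, 100]")
  o <- order(v, as.character(cells$id))
  pop <- cells$population[o]; grp <- group_counts[o]
  rankpos <- if (cell_count) seq_along(pop) / length(pop) else {
    if (sum(pop) == 0) stop("total population is zero")
    cumsum(pop) / sum(pop)
  }
  edges <- bins / 100
  one_bin <- function(lo, hi) {
    inbin <- rankpos > lo & rankpos <= hi + 1e-12
    if (!any(inbin) || sum(pop[inbin]) == 0)
      return(c(NA_real_, NA_real_))
    gs <- sum(grp[inbin]) / sum(pop[inbin])
    c(gs, 1 - gs)
  }
  res <- t(vapply(seq_len(length(edges) - 1),
                  function(k) one_bin(edges[k], edges[k + 1]),
                  numeric(2)))
  top10 <- one_bin(0.9, 1)
  data.frame(
    bin = c(paste0(bins[-length(bins)], "-", bins[-1], "%"), "top10%"),
    lo = c(bins[-length(bins)], 90), hi = c(bins[-1], 100),
    group_share = c(res[, 1], top10[1]),
    complement_share = c(res[, 2], top10[2]),
    stringsAsFactors = FALSE)
}

#' Full equity report for a set of surfaces
#'
#' For each surface: Lorenz/Gini per region and per subdivision (cost
#' surfaces pass through [invert_normalize] first; index surfaces are used
#' raw), county-level Pearson correlations with the aging and agricultural
#' population shares (raw surfaces, as signed associations), and
#' percentile composition tables for both groups.
#'
#' @param surfaces Named list of `accessibility_surface` objects (e.g.
#'   from [accessibility_surfaces]).
#' @param region A `study_region`.
#' @param bins Percentile bins for [quantile_composition].
#' @return An object of class `equity_report`: list with `gini` (data
#'   frame region x surface), `lorenz` (list of `lorenz_result`),
#'   `correlations` (data frame), `composition` (list of data frames).
#' @export
equity_report <- function(surfaces, region, bins = seq(0, 100, by = 10)) {
  cells <- region$cells
  sub <- region$subdivisions[as.character(cells$city_id)]
  labs <- names(surfaces)[vapply(surfaces, inherits, logical(1),
                                 "accessibility_surface")]
  gini_rows <- list(); lorenz <- list(); cors <- list(); comp <- list()
  county_share <- function(cnt) {
    s <- tapply(cnt, cells$county_id, sum) /
      pmax(tapply(cells$population, cells$county_id, sum), 1)
    stats::setNames(as.numeric(s), names(s))
  }
  aging_share <- county_share(cells$aging)
  agri_share <- county_share(cells$agricultural)
  for (lab in labs) {
    s <- surfaces[[lab]]
    sn <- invert_normalize(s)
    regions <- c(list(region = rep(TRUE, nrow(cells))),
                 lapply(stats::setNames(unique(sub), unique(sub)),
                        function(x) sub == x))
    for (rn in names(regions)) {
      sel <- regions[[rn]]
      lg <- lorenz_gini(sn$values[as.character(cells$id[sel])],
                        cells$population[sel], label = lab)
      gini_rows[[length(gini_rows) + 1]] <-
        data.frame(region = rn, surface = lab, gini = lg$gini)
      if (rn == "region") lorenz[[lab]] <- lg
    }
    cv <- aggregate_to_county(s, cells)
    for (grp in c("aging", "agricultural")) {
      share <- if (grp == "aging") aging_share else agri_share
      gc <- group_correlation(cv, share)
      cors[[length(cors) + 1]] <-
        data.frame(surface = lab, group = grp, r = gc$r, p = gc$p,
                   stars = gc$stars, n = gc$n)
    }
    comp[[lab]] <- list(
      aging = quantile_composition(s, cells, cells$aging, bins),
      agricultural = quantile_composition(s, cells, cells$agricultural,
                                          bins))
  }
  structure(list(gini = do.call(rbind, gini_rows), lorenz = lorenz,
                 correlations = do.call(rbind, cors), composition = comp),
            class = "equity_report")
}

#' @export
print.equity_report <- function(x, ...) {
  cat("<equity_report>\nGini coefficients:\n")
  print(stats::reshape(x$gini, idvar = "region", timevar = "surface",
                       direction = "wide"), row.names = FALSE)
  cat("\nCounty correlations (group share vs accessibility):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  invisible(x)
}
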