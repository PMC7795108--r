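#' Floating-catchment parameters
#'
#' Parameters of the gravity-weighted two-step floating catchment area
#' (2SFCA) computation and of the hierarchical tertiary model. The distance
#' decay is the power law `W(d) = max(d, eps)^-beta`; `eps` is a floor (in
#' the cost metric's units) that keeps the weight finite for co-located
#' supply and demand. Defaults per metric: a 120-min catchment with
#' `eps = 1` min for the time metric, and a 10-km (10000 m) catchment --
#' the two-hour walking distance at 5 km/h -- with `eps = 1000` m for the
#' space metric. `beta = 1` for the secondary-tier 2SFCA; the tertiary
#' model uses `beta_own = 1.5` for own-city hospitals and
#' `beta_capital = 1` for provincial-capital hospitals.
#'
#' @param metric `"time"` (minutes) or `"space"` (meters); sets the default
#'   `d0` and `eps`.
#' @param d0 Catchment threshold in the metric's units (strict `d < d0`).
#' @param beta Decay exponent for the 2SFCA step.
#' @param beta_own,beta_capital Decay exponents of the tertiary model.
#' @param eps Distance floor, same units as the metric.
#' @return An object of class `fca_params`.
#' @export
fca_params <- function(metric = c("time", "space"), d0 = NULL, beta = 1,
                       beta_own = 1.5, beta_capital = 1, eps = NULL) {
  metric <- match.arg(metric)
  if (is.null(d0)) d0 <- if (metric == "time") 120 else 10000
  if (is.null(eps)) eps <- if (metric == "time") 1 else 1000
  stopifnot(d0 > 0, beta >= 0, beta_own >= 0, beta_capital >= 0, eps > 0)
  structure(list(metric = metric, d0 = d0, beta = beta, beta_own = beta_own,
                 beta_capital = beta_capital, eps = eps),
            class = "fca_params")
}

.decay <- function(d, beta, eps) pmax(d, eps)^(-beta)

.surface <- function(values, label, units, params = NULL) {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(label = label, values = values, units = units,
                 params = params), class = "accessibility_surface")
}

#' @export
print.accessibility_surface <- function(x, ...) {
  cat("<accessibility_surface> ", x$label, " (", x$units, "), ",
      length(x$values), " cells\n", sep = "")
  print(summary(unname(x$values)))
  invisible(x)
}

#' Plot an accessibility surface on its demand grid
#'
#' @param x An `accessibility_surface`.
#' @param region The `study_region` the surface was computed on (supplies
#'   the cell grid layout).
#' @param ... Passed to [graphics::image].
#' @export
plot.accessibility_surface <- function(x, region, ...) {
  cells <- region$cells
  n_side <- max(cells$row)
  z <- matrix(NA_real_, n_side, max(cells$col))
  z[cbind(cells$col, cells$row)] <- x$values[as.character(cells$id)]
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  xlab = "column", ylab = "row",
                  main = paste0(x$label, " (", x$units, ")"),
                  col = grDevices::hcl.colors(32, "viridis"), ...)
  invisible(x)
}

# resolve a facility subset to the matching columns of a cost matrix
.subset_cols <- function(costs, facility_ids) {
  idx <- match(as.character(facility_ids), colnames(costs$cost))
  if (anyNA(idx)) stop("facility ids missing from the cost matrix")
  idx
}

#' Nearest-facility cost surface (primary care)
#'
#' The per-cell minimum travel cost to any facility of the subset; lower
#' values mean better accessibility. With the time metric this is the
#' `Pri_T` surface (minutes), with the space metric `Pri_S` (meters).
#'
#' @param costs A [cost_matrix] result.
#' @param facility_ids Facility ids to consider (default: all columns).
#' @return An `accessibility_surface`.
#' @export
nearest_cost <- function(costs, facility_ids = colnames(costs$cost)) {
  if (length(facility_ids) == 0) stop("facility subset must be non-empty")
  idx <- .subset_cols(costs, facility_ids)
  v <- apply(costs$cost[, idx, drop = FALSE], 1, min)
  .surface(v, if (costs$metric == "time") "Pri_T" else "Pri_S",
           if (costs$metric == "time") "min" else "m")
}

# supply-demand ratios for a set of facility columns: S*P / sum_k(D_k W_kj)
# over demand within the (strict) threshold; 0 on empty catchments
.sdr <- function(cost_sub, staff, weight, D, d0, beta, eps,
                 warn = TRUE) {
  Wm <- .decay(cost_sub, beta, eps)
  Wm[!(cost_sub < d0)] <- 0
  denom <- as.vector(crossprod(Wm, D))     # sum over cells per facility
  r <- ifelse(denom > 0, staff * weight / denom, 0)
  if (warn && any(denom == 0))
    message(sum(denom == 0), " facility catchment(s) contain no demand; ",
            "their supply-demand ratio is 0")
  r
}

#' Supply-demand ratio of one facility
#'
#' First 2SFCA step: `R_j = S_j P_j / sum_k D_k W(d_kj)` over the demand
#' cells within the catchment (`d_kj < d0`), with the power-law decay
#' `W(d) = max(d, eps)^-beta`. Returns 0 (with a message) when no demand
#' lies in the catchment.
#'
#' @param facility One row of a facility table (columns `id`, `staff`,
#'   `capacity_weight`).
#' @param costs A [cost_matrix] result.
#' @param cells Cell table with `id` and `population`.
#' @param params An [fca_params].
#' @return A single ratio (staff per decayed person).
#' @export
supply_demand_ratio <- function(facility, costs, cells, params) {
  stopifnot(inherits(params, "fca_params"))
  idx <- .subset_cols(costs, facility$id[1])
  D <- cells$population[match(rownames(costs$cost), as.character(cells$id))]
  .sdr(costs$cost[, idx, drop = FALSE], facility$staff[1],
       facility$capacity_weight[1], D, params$d0, params$beta, params$eps)
}

#' Two-step floating catchment area surface (secondary care)
#'
#' Second 2SFCA step: each cell sums the decayed supply-demand ratios of
#' the facilities within its catchment,
#' `A_i = sum_{j: d_ij < d0} R_j W(d_ij)`. Higher values mean better
#' accessibility; units are staff per person. With the symmetric threshold
#' and decay in both steps, total delivered accessibility is conserved:
#' `sum_i D_i A_i = sum_j S_j P_j` whenever every facility's catchment
#' holds some demand.
#'
#' @param costs A [cost_matrix] result.
#' @param cells Cell table (`id`, `population`).
#' @param facilities Facility subset to use (data frame with `id`, `staff`,
#'   `capacity_weight`).
#' @param params An [fca_params].
#' @return An `accessibility_surface` labelled `Sec_T` or `Sec_S`.
#' @export
two_step_fca <- function(costs, cells, facilities, params) {
  stopifnot(inherits(params, "fca_params"), nrow(facilities) > 0)
  idx <- .subset_cols(costs, facilities$id)
  cm <- costs$cost[, idx, drop = FALSE]
  D <- cells$population[match(rownames(cm), as.character(cells$id))]
  R <- .sdr(cm, facilities$staff, facilities$capacity_weight, D,
            params$d0, params$beta, params$eps)
  Wm <- .decay(cm, params$beta, params$eps)
  Wm[!(cm < params$d0)] <- 0
  A <- as.vector(Wm %*% R)
  names(A) <- rownames(cm)
  if (all(A == 0)) message("all-zero accessibility surface (no facility ",
                           "within the catchment of any cell)")
  .surface(A, if (costs$metric == "time") "Sec_T" else "Sec_S",
           "staff per person", params)
}

#' Hierarchical tertiary-care accessibility surface
#'
#' For serious conditions residents use tertiary hospitals in their own
#' city or in the provincial capital, and rail travel is available, so the
#' surface is the sum of two unthresholded gravity terms:
#' an own-city term (capacity weight 1, decay exponent `beta_own`,
#' competition pool restricted to the city's own cells) and a capital term
#' (capacity weight 2, decay exponent `beta_capital`, competition pool =
#' every cell in the region). Cities without a tertiary hospital get an
#' own-city term of zero. For capital-city residents the capital hospitals
#' enter both terms by construction; `suppress_capital_own = TRUE` drops
#' the own-city term in the capital to avoid that double contribution.
#'
#' @param costs A [cost_matrix] result; for the time metric it should be
#'   computed on the rail-enabled network.
#' @param cells Cell table (`id`, `population`, `city_id`).
#' @param facilities Tertiary facility table (`id`, `staff`, `city_id`).
#' @param capital_city City id of the provincial capital.
#' @param params An [fca_params] (`beta_own`, `beta_capital`, `eps` used;
#'   no `d0` applies).
#' @param suppress_capital_own See Details.
#' @return An `accessibility_surface` labelled `Ter_T` or `Ter_S`.
#' @export
tertiary_access <- function(costs, cells, facilities, capital_city,
                            params = fca_params(costs$metric),
                            suppress_capital_own = FALSE) {
  stopifnot(inherits(params, "fca_params"))
  if ("level" %in% names(facilities))
    facilities <- facilities[facilities$level == "tertiary", , drop = FALSE]
  if (nrow(facilities) == 0) stop("no tertiary facilities supplied")
  ord <- match(rownames(costs$cost), as.character(cells$id))
  D <- cells$population[ord]
  city <- cells$city_id[ord]
  A <- numeric(nrow(costs$cost))
  names(A) <- rownames(costs$cost)
  inf_d0 <- Inf  # Eqs for this tier carry no catchment threshold

  # own-city terms, one city at a time (restricted demand pool)
  for (ct in unique(city)) {
    if (suppress_capital_own && ct == capital_city) next
    jj <- which(facilities$city_id == ct)
    if (length(jj) == 0) {
      message("city ", ct, " has no tertiary hospital; own-city term is 0")
      next
    }
    kk <- which(city == ct)
    cm <- costs$cost[kk, .subset_cols(costs, facilities$id[jj]),
                     drop = FALSE]
    R <- .sdr(cm, facilities$staff[jj], rep(1, length(jj)), D[kk],
              inf_d0, params$beta_own, params$eps, warn = FALSE)
    Wm <- .decay(cm, params$beta_own, params$eps)
    A[kk] <- A[kk] + as.vector(Wm %*% R)
  }

  # capital term: weight 2, province-wide demand pool
  jp <- which(facilities$city_id == capital_city)
  if (length(jp) == 0) {
    message("capital city has no tertiary hospital; capital term is 0")
  } else {
    cm <- costs$cost[, .subset_cols(costs, facilities$id[jp]), drop = FALSE]
    R <- .sdr(cm, facilities$staff[jp], rep(2, length(jp)), D,
              inf_d0, params$beta_capital, params$eps, warn = FALSE)
    Wm <- .decay(cm, params$beta_capital, params$eps)
    A <- A + as.vector(Wm %*% R)
  }
  .surface(A, if (costs$metric == "time") "Ter_T" else "Ter_S",
           "staff per person", params)
}

#' Compute all six accessibility surfaces of a study region
#'
#' Convenience wrapper: nearest-cost surfaces over every facility
#' (`Pri_T`/`Pri_S`), 2SFCA over secondary + tertiary facilities
#' (`Sec_T`/`Sec_S`), and the hierarchical tertiary model over tertiary
#' hospitals with rail enabled for the time metric (`Ter_T`/`Ter_S`).
#'
#' @param region A `study_region`.
#' @param access An [access_params].
#' @param fca_time,fca_space [fca_params] for the two metrics.
#' @param suppress_capital_own Passed to [tertiary_access].
#' @param rule Passed to [cost_matrix].
#' @return Named list of six `accessibility_surface` objects plus the three
#'   cost matrices used (`costs_time`, `costs_space`, `costs_time_rail`).
#' @export
accessibility_surfaces <- function(region, access = access_params(),
                                   fca_time = fca_params("time"),
                                   fca_space = fca_params("space"),
                                   suppress_capital_own = FALSE,
                                   rule = "min") {
  cells <- region$cells
  fac <- region$facilities
  ct <- cost_matrix(cells, fac, region$network, access, "time", rule)
  cs <- cost_matrix(cells, fac, region$network, access, "space", rule)
  ctr <- cost_matrix(cells, fac, region$network_rail, access, "time", rule)
  sec_fac <- fac[fac$level %in% c("secondary", "tertiary"), ]
  ter_fac <- fac[fac$level == "tertiary", ]
  list(
    Pri_T = nearest_cost(ct),
    Pri_S = nearest_cost(cs),
    Sec_T = two_step_fca(ct, cells, sec_fac, fca_time),
    Sec_S = two_step_fca(cs, cells, sec_fac, fca_space),
    Ter_T = tertiary_access(ctr, cells, ter_fac, region$capital_city,
                            fca_time, suppress_capital_own),
    Ter_S = tertiary_access(cs, cells, ter_fac, region$capital_city,
                            fca_space, suppress_capital_own),
    costs_time = ct, costs_space = cs, costs_time_rail = ctr)
}
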