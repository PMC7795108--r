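#' Spatial weight matrix for grid cells
#'
#' Queen or rook contiguity on the regular demand grid (from the cells'
#' `row`/`col` indices), or a distance band on centroids. Isolated units
#' are retained with an all-zero row (and a message). Row standardization
#' divides each non-isolated row by its sum.
#'
#' @param cells Cell table with `id`, `row`, `col`, `x`, `y`.
#' @param scheme `"queen"`, `"rook"` or `"distance_band"`.
#' @param row_standardize Logical.
#' @param band Neighbor distance (meters) for `scheme = "distance_band"`.
#' @return An object of class `spatial_weights`: list with `ids`, `W`
#'   (dense matrix), `scheme`, `row_standardized`.
#' @export
build_weights <- function(cells, scheme = c("queen", "rook",
                                            "distance_band"),
                          row_standardize = TRUE, band = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 units to build spatial weights")
  if (scheme == "distance_band") {
    if (is.null(band)) stop("band (meters) required for distance_band")
    d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
    W <- (d > 0 & d <= band) * 1
  } else {
    dr <- abs(outer(cells$row, cells$row, "-"))
    dc <- abs(outer(cells$col, cells$col, "-"))
    W <- if (scheme == "queen") (pmax(dr, dc) == 1) * 1 else
      ((dr + dc) == 1) * 1
  }
  diag(W) <- 0
  rs <- rowSums(W)
  if (any(rs == 0))
    message(sum(rs == 0), " isolated unit(s) kept with zero weight rows")
  if (row_standardize) W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  dimnames(W) <- list(as.character(cells$id), as.character(cells$id))
  structure(list(ids = as.character(cells$id), W = W, scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

# Moran's I statistic: n * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#                      (sum_ij w_ij * sum_i (x_i - xbar)^2)
.moran_stat <- function(x, W) {
  z <- x - mean(x)
  s0 <- sum(W)
  den <- sum(z^2)
  if (den == 0) stop("degenerate input: surface is constant, ",
                     "Moran's I undefined")
  length(x) * as.numeric(t(z) %*% W %*% z) / (s0 * den)
}

#' Global Moran's I with permutation inference
#'
#' Computes the global spatial autocorrelation index of a surface under a
#' spatial weight matrix and a conditional-randomization pseudo p-value:
#' the values are randomly permuted across the units `n_permutations`
#' times and the observed index is ranked among the simulated ones (one
#' tail, in the direction of departure from the expectation
#' `E[I] = -1/(n-1)`).
#'
#' @param surface An `accessibility_surface` or a named/plain numeric
#'   vector ordered like the weights.
#' @param W A [build_weights] result.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return An object of class `moran_result` with `global_I`,
#'   `expected_I`, `p_value`, `sim_I` (simulated indices), `n`, `scheme`,
#'   `n_permutations`, `seed`.
#' @export
global_moran <- function(surface, W, n_permutations = 999, seed = 1L) {
  x <- .surface_values(surface, W)
  I <- .moran_stat(x, W$W)
  n <- length(x)
  eI <- -1 / (n - 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sim <- vapply(seq_len(n_permutations),
                function(i) .moran_stat(sample(x), W$W), numeric(1))
  p <- if (I >= eI) (1 + sum(sim >= I)) / (n_permutations + 1) else
    (1 + sum(sim <= I)) / (n_permutations + 1)
  structure(list(global_I = I, expected_I = eI, p_value = p, sim_I = sim,
                 n = n, scheme = W$scheme,
                 n_permutations = n_permutations, seed = seed,
                 local = NULL),
            class = "moran_result")
}

.surface_values <- function(surface, W) {
  x <- if (inherits(surface, "accessibility_surface")) surface$values else
    surface
  if (!is.null(names(x)) && !is.null(W$ids)) {
    if (!all(W$ids %in% names(x)))
      stop("surface does not cover all weight-matrix units")
    x <- x[W$ids]
  }
  as.numeric(x)
}

#' Local Moran's I and LISA cluster classification
#'
#' `I_i = z_i * sum_j w_ij z_j` with `z` the standardized surface
#' (population, n-divisor standard deviation, so that
#' `mean(I_i) = global I` under row-standardized weights). Significance by
#' conditional permutation: for each unit the remaining values are
#' permuted among its neighbors `n_permutations` times. Significant units
#' are labelled by the sign pattern of (own z, spatially lagged z):
#' `HH`, `LL`, `LH`, `HL`; others `ns`.
#'
#' @inheritParams global_moran
#' @param alpha Significance level for the LISA labels (default 0.05).
#' @return A `moran_result` whose `local` element is a data frame with
#'   `id`, `local_I`, `p_value`, `cluster`.
#' @export
local_moran <- function(surface, W, n_permutations = 999, alpha = 0.05,
                        seed = 1L) {
  x <- .surface_values(surface, W)
  n <- length(x)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  if (!all(is.finite(z))) stop("degenerate input: surface is constant")
  Wm <- W$W
  lag <- as.vector(Wm %*% z)
  Ii <- z * lag
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  p <- numeric(n)
  for (i in seq_len(n)) {
    wi <- Wm[i, ]
    nb <- which(wi > 0)
    if (length(nb) == 0) { p[i] <- NA_real_; next }
    zo <- z[-i]
    sim <- vapply(seq_len(n_permutations), function(k) {
      z[i] * sum(wi[nb] * sample(zo, length(nb)))
    }, numeric(1))
    p[i] <- if (Ii[i] >= 0) (1 + sum(sim >= Ii[i])) / (n_permutations + 1)
      else (1 + sum(sim <= Ii[i])) / (n_permutations + 1)
  }
  cl <- rep("ns", n)
  sig <- !is.na(p) & p < alpha
  cl[sig & z >= 0 & lag >= 0] <- "HH"
  cl[sig & z < 0 & lag < 0] <- "LL"
  cl[sig & z < 0 & lag >= 0] <- "LH"
  cl[sig & z >= 0 & lag < 0] <- "HL"
  res <- global_moran(x, W, n_permutations = n_permutations, seed = seed)
  res$local <- data.frame(id = W$ids, local_I = Ii, p_value = p,
                          cluster = cl, stringsAsFactors = FALSE)
  res$alpha <- alpha
  res
}

#' @export
print.moran_result <- function(x, ...) {
  cat("<moran_result> global I = ", format(x$global_I, digits = 4),
      " (E[I] = ", format(x$expected_I, digits = 4),
      "), pseudo p = ", format(x$p_value, digits = 3),
      " [", x$n_permutations, " permutations, ", x$scheme,
      " weights]\n", sep = "")
  if (!is.null(x$local)) {
    cat("  LISA classes:\n")
    print(table(x$local$cluster))
  }
  invisible(x)
}

#' Per-subdivision Moran's I of a surface
#'
#' Recomputes contiguity weights within each subdivision's own cells
#' (rather than masking the region-wide matrix) and returns one
#' `moran_result` per subdivision plus the region-wide result.
#'
#' @param surface An `accessibility_surface`.
#' @param region A `study_region`.
#' @param scheme,row_standardize Passed to [build_weights].
#' @param n_permutations,seed Passed to [global_moran].
#' @return Named list of `moran_result` objects (`region` plus one per
#'   subdivision label).
#' @export
moran_by_subdivision <- function(surface, region, scheme = "queen",
                                 row_standardize = TRUE,
                                 n_permutations = 999, seed = 1L) {
  cells <- region$cells
  sub <- region$subdivisions[as.character(cells$city_id)]
  out <- list(region = global_moran(
    surface, build_weights(cells, scheme, row_standardize),
    n_permutations, seed))
  for (s in unique(sub)) {
    cs <- cells[sub == s, , drop = FALSE]
    if (nrow(cs) < 2) next
    Ws <- build_weights(cs, scheme, row_standardize)
    out[[s]] <- global_moran(surface$values[as.character(cs$id)], Ws,
                             n_permutations, seed)
  }
  out
}

#' Write Moran/LISA results as CSV plus a JSON summary
#'
#' @param x A `moran_result`.
#' @param path CSV path for the per-unit table (written only when local
#'   results are present); the global summary goes to `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_moran <- function(x, path) {
  if (!is.null(x$local))
    utils::write.csv(x$local, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(global_I = x$global_I, expected_I = x$expected_I,
         p_value = x$p_value, n = x$n, scheme = x$scheme,
         n_permutations = x$n_permutations, seed = x$seed),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
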