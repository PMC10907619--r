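#' Per-class area table
#'
#' Builds the standard per-epoch area/composition table either from raw
#' per-class areas (`area_table()`) or from a grid (`class_areas()`). Shares
#' are percentages of the non-nodata total.
#'
#' @param areas named numeric vector of per-class areas in hm^2 (names are
#'   class codes) or unnamed, in class-code order 1..n.
#' @param year epoch label.
#' @return data frame of class `area_table` with columns `class`, `name`,
#'   `area_hm2`, `share_pct`, and attributes `year` and `total_hm2`.
#' @export
area_table <- function(areas, year = NA) {
  if (any(areas < 0)) stop("areas must be non-negative")
  codes <- if (!is.null(names(areas))) as.integer(names(areas))
           else seq_along(areas)
  total <- sum(areas)
  out <- data.frame(class = codes, name = lulc_class_names(codes),
                    area_hm2 = as.numeric(areas),
                    share_pct = if (total > 0) areas / total * 100 else 0)
  rownames(out) <- NULL
  structure(out, year = year, total_hm2 = total,
            class = c("area_table", "data.frame"))
}

#' @rdname area_table
#' @param grid an [lulc_grid()]; nodata cells are excluded from counts and
#'   from the share denominator.
#' @export
class_areas <- function(grid, year = grid$year) {
  stopifnot(inherits(grid, "lulc_grid"))
  v <- grid$values[!is.na(grid$values)]
  if (!length(v)) stop("grid is all nodata; no areas to account")
  counts <- tabulate(v, nbins = max(grid$classes))[grid$classes]
  areas <- counts * grid$cell_area
  names(areas) <- grid$classes
  area_table(areas, year = year)
}

#' Single land-use dynamic degree K
#'
#' Annualized relative rate of change of one class's area:
#' `K = ((Ub - Ua) / Ua) * (1 / T) * 100` in percent per year, where `Ua`
#' and `Ub` are the start and end areas and `T` the span in years. Values
#' are returned at full precision; round at the reporting layer
#' (conventionally 2 decimals).
#'
#' @param area_start,area_end areas in hm^2 (`area_start` > 0).
#' @param span_years period length in years (> 0).
#' @return signed percent per year.
#' @export
dynamic_degree <- function(area_start, area_end, span_years) {
  if (any(area_start <= 0)) stop("dynamic degree undefined for zero start area")
  if (span_years <= 0) stop("span_years must be positive")
  (area_end - area_start) / area_start / span_years * 100
}

#' Dynamic-degree table across two epochs
#'
#' @param at_start,at_end [area_table()]s for the two epochs with matching
#'   class sets.
#' @param span_years period length in years.
#' @param digits rounding applied to the reported K column (default 2, the
#'   conventional presentation).
#' @return data frame with columns `class`, `name`, `K_pct_per_yr`.
#' @export
dynamic_degree_table <- function(at_start, at_end, span_years, digits = 2) {
  stopifnot(identical(at_start$class, at_end$class))
  data.frame(class = at_start$class, name = at_start$name,
             K_pct_per_yr = round(dynamic_degree(at_start$area_hm2,
                                                 at_end$area_hm2, span_years),
                                  digits))
}

#' Inter-epoch transition matrix
#'
#' Cross-tabulates aligned grids into an n x n area matrix (hm^2) plus its
#' row-normalized probability form. Row sums of the area form equal the
#' start-epoch class areas; rows with zero area get an identity probability
#' row so the matrix stays stochastic.
#'
#' @param grid_a,grid_b aligned [lulc_grid()]s (identical geometry and class
#'   set).
#' @return object of class `transition_matrix` with fields `area` (hm^2
#'   matrix), `prob` (row-stochastic), `from`, `to` (epoch labels),
#'   `cell_area`.
#' @export
transition_matrix <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "lulc_grid"), inherits(grid_b, "lulc_grid"))
  if (!same_geometry(grid_a, grid_b))
    stop("grids do not share geometry; cannot cross-tabulate")
  if (!identical(grid_a$classes, grid_b$classes))
    stop("grids declare different class sets")
  cl <- grid_a$classes
  ok <- !is.na(grid_a$values) & !is.na(grid_b$values)
  tab <- table(factor(grid_a$values[ok], levels = cl),
               factor(grid_b$values[ok], levels = cl))
  area <- unclass(tab) * grid_a$cell_area
  dimnames(area) <- list(from = cl, to = cl)
  prob <- area / rowSums(area)
  zero <- rowSums(area) == 0
  if (any(zero)) {
    prob[zero, ] <- 0
    prob[cbind(which(zero), which(zero))] <- 1
  }
  structure(list(area = area, prob = prob, from = grid_a$year,
                 to = grid_b$year, cell_area = grid_a$cell_area),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s -> %s, total %g hm^2\n",
              format(x$from), format(x$to), sum(x$area)))
  print(round(x$area, 1))
  invisible(x)
}

#' Markov projection of class areas
#'
#' Projects a base area vector `n_steps` transitions forward:
#' `areas' = areas %*% P^n` with `P` the row-stochastic transition matrix.
#' Total area is conserved (row-stochasticity).
#'
#' @param tm a [transition_matrix()] (its `prob` form is used) or a
#'   row-stochastic matrix.
#' @param base an [area_table()] whose classes match `tm`.
#' @param n_steps number of transition steps (>= 0).
#' @return an [area_table()] for the projected epoch.
#' @export
markov_project <- function(tm, base, n_steps = 1) {
  P <- if (inherits(tm, "transition_matrix")) tm$prob else as.matrix(tm)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix is not row-stochastic")
  stopifnot(inherits(base, "area_table"), nrow(base) == nrow(P), n_steps >= 0)
  x <- base$area_hm2
  for (i in seq_len(n_steps)) x <- as.numeric(x %*% P)
  out <- area_table(stats::setNames(x, base$class),
                    year = attr(base, "year"))
  attr(out, "n_steps") <- n_steps
  out
}

#' Export transition links for flow (Sankey) plotting
#'
#' @param tm a [transition_matrix()].
#' @param keep_diagonal keep same-class persistence links (default `FALSE`,
#'   i.e. change flows only)? Zero-area links are always dropped.
#' @return data frame with columns `from`, `to`, `area_hm2`.
#' @export
sankey_export <- function(tm, keep_diagonal = TRUE) {
  stopifnot(inherits(tm, "transition_matrix"))
  a <- tm$area
  idx <- which(a > 0, arr.ind = TRUE)
  if (!keep_diagonal) idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  cl <- as.integer(rownames(a))
  out <- data.frame(from = cl[idx[, 1]], to = cl[idx[, 2]],
                    area_hm2 = a[idx])
  out[order(out$from, out$to), , drop = FALSE]
}
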