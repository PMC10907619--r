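#' Load a bundled unit-area value-equivalent table
#'
#' Two vintages of the standard Chinese equivalent-factor tables ship with
#' the package: the 2003 nine-function table and the improved 2015
#' eleven-function table (which adds water supply and nutrient cycle
#' maintenance). Construction land carries zero equivalents in both.
#' Conventionally the 2003 table is used for 1990/2000/2010 epochs and the
#' 2015 table for 2020 and later scenarios.
#'
#' @param version `"2003"` or `"2015"`.
#' @return data frame of class `equivalent_table` with columns `version`,
#'   `class`, `class_name`, `fun`, `fun_name`, `category`, `equivalent`.
#' @export
equivalent_table <- function(version = c("2003", "2015")) {
  version <- match.arg(version)
  path <- system.file("extdata",
                      paste0("equivalents_", version, ".csv"),
                      package = "greyplus", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(version = "character"))
  if (any(tab$equivalent < 0)) stop("equivalents must be non-negative")
  if (any(tab$equivalent[tab$class == 5] != 0))
    stop("construction-land equivalents must all be zero")
  structure(tab, class = c("equivalent_table", "data.frame"))
}

#' Table version conventionally used for an epoch
#'
#' @param year epoch year.
#' @return `"2003"` for years before 2020, `"2015"` from 2020 on.
#' @export
equivalent_version_for <- function(year) if (year < 2020) "2003" else "2015"

PACKAGED_EA <- c("1990" = 2006, "2000" = 2043, "2010" = 2107, "2020" = 2181)

#' Standard equivalent Ea (yuan/hm^2)
#'
#' The monetary value of one standard equivalent unit, anchored to the main
#' grain crops: one seventh of the mean grain output value per hectare
#' (`price * yield / 7`). For the four reference study years
#' (1990/2000/2010/2020) authoritative packaged constants
#' (2006/2043/2107/2181 yuan/hm^2) are returned unless grain statistics are
#' supplied explicitly.
#'
#' @param year valuation year.
#' @param grain_stats optional list with `grain_price` (yuan/kg) and
#'   `grain_yield` (kg/hm^2) as [socio_series()] objects covering `year`,
#'   or scalar fields `price` and `yield`.
#' @return list of class `standard_equivalent` with fields `year`, `Ea`,
#'   `source`.
#' @export
standard_equivalent <- function(year, grain_stats = NULL) {
  if (is.null(grain_stats)) {
    key <- as.character(year)
    if (!key %in% names(PACKAGED_EA))
      stop("no packaged standard equivalent for year ", year,
           "; supply grain_stats")
    return(structure(list(year = year, Ea = unname(PACKAGED_EA[key]),
                          source = "packaged"),
                     class = "standard_equivalent"))
  }
  if (inherits(grain_stats$grain_price, "socio_series")) {
    price <- series_at(grain_stats$grain_price, year)
    yield <- series_at(grain_stats$grain_yield, year)
  } else {
    price <- grain_stats$price; yield <- grain_stats$yield
  }
  if (is.null(price) || is.null(yield))
    stop("grain_stats must provide price and yield")
  structure(list(year = year, Ea = price * yield / 7, source = "computed"),
            class = "standard_equivalent")
}

#' Social development stage coefficient L
#'
#' Logistic transform of the Engel coefficient:
#' `L = 1 / (1 + exp(-(1/En - 3)))`. Strictly decreasing in `En`; equals
#' 0.5 at `En = 1/3` and tends to 1 as `En -> 0`.
#'
#' @param En Engel coefficient in (0, 1].
#' @return L in (0, 1).
#' @export
engel_L <- function(En) {
  if (any(En <= 0) || any(En > 1))
    stop("Engel coefficient must lie in (0, 1]")
  1 / (1 + exp(-(1 / En - 3)))
}

#' Biomass correction factor Q
#'
#' `Q = (NPP_region/NPP_nation + FVC_region/FVC_nation) / 2`, the mean of
#' the regional-to-national ratios of net primary productivity and
#' fractional vegetation cover; scales the equivalent table for regional
#' biomass.
#'
#' @param npp_region,npp_nation mean NPP (same units).
#' @param fvc_region,fvc_nation mean FVC (same units).
#' @return Q (dimensionless, > 0).
#' @export
biomass_factor <- function(npp_region, npp_nation, fvc_region, fvc_nation) {
  if (npp_nation <= 0 || fvc_nation <= 0)
    stop("national means must be positive")
  (npp_region / npp_nation + fvc_region / fvc_nation) / 2
}

#' Derive fractional vegetation cover from NDVI (dimidiate pixel model)
#'
#' `FVC = (NDVI - NDVI_soil) / (NDVI_veg - NDVI_soil)` clamped to \[0, 1\],
#' with the bare-soil and full-vegetation endpoints taken as the 5th and
#' 95th percentiles of the NDVI values.
#'
#' @param ndvi numeric NDVI values.
#' @return FVC values in \[0, 1\].
#' @export
fvc_from_ndvi <- function(ndvi) {
  qs <- stats::quantile(ndvi, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  if (qs[2] <= qs[1]) stop("degenerate NDVI range")
  pmin(pmax((ndvi - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Social development correction coefficient PI
#'
#' `PI = A * W` with payment ability `A = GDP_region/GDP_nation` and
#' willingness-to-pay `W = L(En_region)/L(En_nation)` via [engel_L()].
#'
#' @param gdp_region,gdp_nation per-capita GDP (yuan/person, nation > 0).
#' @param engel_region,engel_nation Engel coefficients in (0, 1].
#' @return list with `A`, `W`, `PI`.
#' @export
social_coefficient <- function(gdp_region, gdp_nation,
                               engel_region, engel_nation) {
  if (gdp_nation <= 0) stop("national GDP must be positive")
  A <- gdp_region / gdp_nation
  W <- engel_L(engel_region) / engel_L(engel_nation)
  list(A = A, W = W, PI = A * W)
}

#' Corrected per-class value coefficients VC (yuan/hm^2)
#'
#' Applies the dynamic standard equivalent and both corrections
#' multiplicatively to the equivalent table:
#' `VC_i = Q * PI * Ea * sum_f EC_f(class i)`, with the per-class,
#' per-function breakdown retained. The multiplicative composition point is
#' isolated here so an alternative composition is a one-line change.
#'
#' @param eq an [equivalent_table()].
#' @param Ea standard equivalent in yuan/hm^2 (or a
#'   [standard_equivalent()] object).
#' @param Q biomass correction (default 1).
#' @param PI social development correction (default 1).
#' @return list of class `vc_table`: `vc` named per-class totals
#'   (yuan/hm^2), `per_function` class x function matrix (yuan/hm^2),
#'   `category_map` function -> category, and the scaling factors.
#' @export
corrected_coefficients <- function(eq, Ea, Q = 1, PI = 1) {
  stopifnot(inherits(eq, "equivalent_table"))
  if (inherits(Ea, "standard_equivalent")) Ea <- Ea$Ea
  stopifnot(Ea > 0, Q > 0, PI > 0)
  funs <- unique(eq$fun)
  classes <- sort(unique(eq$class))
  m <- matrix(0, length(classes), length(funs),
              dimnames = list(class = classes, fun = funs))
  m[cbind(match(eq$class, classes), match(eq$fun, funs))] <- eq$equivalent
  per_function <- m * Ea * Q * PI
  vc <- rowSums(per_function)
  cmap <- eq$category[match(funs, eq$fun)]
  names(cmap) <- funs
  structure(list(vc = vc, per_function = per_function, category_map = cmap,
                 Ea = Ea, Q = Q, PI = PI, version = eq$version[1]),
            class = "vc_table")
}

#' Aggregate ecosystem-service value
#'
#' `ESV = sum_i A_i * VC_i`, with per-class, per-function and per-category
#' breakdowns. Total, per-class margin and per-function margin agree by
#' construction.
#'
#' @param at an [area_table()] (areas in hm^2, non-negative).
#' @param vc a [corrected_coefficients()] `vc_table` whose class set covers
#'   the table's classes.
#' @return list of class `esv_report`: `year`, `total` (yuan), `per_class`,
#'   `per_function`, `per_category` (named vectors, yuan), `per_cell_matrix`
#'   (class x function).
#' @export
esv_total <- function(at, vc) {
  stopifnot(inherits(at, "area_table"), inherits(vc, "vc_table"))
  if (any(at$area_hm2 < 0)) stop("negative area")
  if (!all(as.character(at$class) %in% rownames(vc$per_function)))
    stop("vc table does not cover all classes in the area table")
  pf <- vc$per_function[as.character(at$class), , drop = FALSE]
  contrib <- pf * at$area_hm2            # class x function, yuan
  per_class <- rowSums(contrib)
  names(per_class) <- at$class
  per_function <- colSums(contrib)
  per_category <- tapply(per_function, vc$category_map[names(per_function)],
                         sum)
  structure(list(year = attr(at, "year"), total = sum(contrib),
                 per_class = per_class, per_function = per_function,
                 per_category = c(per_category), matrix = contrib,
                 vc = vc),
            class = "esv_report")
}

#' @export
print.esv_report <- function(x, ...) {
  cat(sprintf("<esv_report>%s total %.2f x 10^9 yuan\n",
              if (!is.na(x$year)) paste0(" ", x$year) else "",
              x$total / 1e9))
  invisible(x)
}

#' Derived change statistics across ESV reports
#'
#' Increments, percentage changes and (optionally) per-class contribution
#' shares between a baseline and later epochs or scenarios. Accepts plain
#' named totals so externally reported values can be pushed through the same
#' arithmetic. Rounding (2 decimals) happens here, at the reporting layer.
#'
#' @param totals named numeric vector of totals (same units throughout), or
#'   a list of `esv_report`s; the first element is the baseline.
#' @param class_values optional matrix/data frame of per-class values with
#'   one column per label in `totals`, used for contribution shares of the
#'   increment.
#' @param digits reporting precision (default 2).
#' @return list with `changes` (data frame: label, total, increment,
#'   pct_change vs baseline) and, when `class_values` is given,
#'   `contribution_pct` per class for each non-baseline label.
#' @export
derived_stats <- function(totals, class_values = NULL, digits = 2) {
  if (is.list(totals) && all(vapply(totals, inherits, logical(1), "esv_report"))) {
    labs <- vapply(totals, function(r) as.character(r$year), character(1))
    class_values <- vapply(totals, function(r) r$per_class,
                           numeric(length(totals[[1]]$per_class)))
    colnames(class_values) <- labs
    totals <- stats::setNames(vapply(totals, `[[`, numeric(1), "total"), labs)
  }
  if (length(totals) < 2) stop("need at least two totals")
  base <- totals[1]
  if (base == 0) stop("zero baseline: percentage change undefined")
  inc <- totals - base
  changes <- data.frame(label = names(totals), total = totals,
                        increment = round(inc, digits),
                        pct_change = round(inc / base * 100, digits),
                        row.names = NULL)
  out <- list(changes = changes)
  if (!is.null(class_values)) {
    cv <- as.matrix(class_values)
    base_cv <- cv[, 1]
    contr <- sweep(cv[, -1, drop = FALSE], 1, base_cv)   # per-class increments
    tot_inc <- inc[-1]
    share <- sweep(contr, 2, tot_inc, "/") * 100
    out$class_increments <- contr
    out$contribution_pct <- round(share, digits)
  }
  out
}

#' Contribution share of a class subset to a total increment
#'
#' @param subset_increments numeric increments of the chosen classes.
#' @param total_increment the total increment (non-zero).
#' @param digits reporting precision (default 0, matching the conventional
#'   whole-percent presentation).
#' @return share in percent.
#' @export
contribution_share <- function(subset_increments, total_increment,
                               digits = 0) {
  if (total_increment == 0) stop("zero total increment")
  round(sum(subset_increments) / total_increment * 100, digits)
}

#' Per-cell value-density raster (yuan/hm^2)
#'
#' Looks up the corrected per-class coefficient for every cell; nodata stays
#' `NA`.
#'
#' @param grid an [lulc_grid()].
#' @param vc a `vc_table` covering all classes present.
#' @return numeric matrix of class `esv_grid` (yuan/hm^2) with attributes
#'   `cell_area` and `year`.
#' @export
esv_grid <- function(grid, vc) {
  stopifnot(inherits(grid, "lulc_grid"), inherits(vc, "vc_table"))
  present <- unique(grid$values[!is.na(grid$values)])
  if (!all(as.character(present) %in% names(vc$vc)))
    stop("vc table does not cover all classes present in the grid")
  m <- matrix(vc$vc[as.character(grid$values)], nrow(grid$values),
              ncol(grid$values))
  structure(m, cell_area = grid$cell_area, year = grid$year,
            class = c("esv_grid", class(m)))
}

#' Five-level value map by Jenks natural breaks
#'
#' Classifies a value raster into `k` levels at the Jenks (Fisher optimal
#' partition) breaks that minimize within-class variance. Ties fall to the
#' lower level; breaks are reported as upper-inclusive bounds.
#'
#' @param g an [esv_grid()] (or numeric matrix).
#' @param k number of levels (default 5).
#' @param max_sample cap on the number of cells used to locate the breaks on
#'   very large rasters (sampling is deterministic given the data); the
#'   classification itself is applied to every cell.
#' @return list of class `level_map`: `levels` integer matrix (1..k, `NA`
#'   for nodata) and `breaks` the k-1 internal upper bounds plus the maximum.
#' @export
jenks_levels <- function(g, k = 5, max_sample = 4000) {
  v <- as.numeric(g)
  ok <- !is.na(v)
  x <- v[ok]
  ux <- unique(x)
  if (length(ux) < k)
    stop("fewer distinct values (", length(ux), ") than levels (", k, ")")
  xs <- if (length(x) > max_sample) {
    ## deterministic thinning on the sorted values keeps the distribution shape
    sort(x)[unique(round(seq(1, length(x), length.out = max_sample)))]
  } else x
  br <- jenks_breaks(xs, k)
  lev <- findInterval(v, c(-Inf, br[-k]), left.open = TRUE) # ties -> lower
  lev[!ok] <- NA_integer_
  lev <- matrix(as.integer(lev), nrow(g), ncol(g))
  structure(list(levels = lev, breaks = br, k = k), class = "level_map")
}

#' Jenks natural breaks (Fisher optimal 1-D partition)
#'
#' Exact dynamic-programming minimization of total within-class sum of
#' squares over contiguous partitions of the sorted values.
#'
#' @param x numeric values (at least `k` distinct).
#' @param k number of classes.
#' @return numeric vector of `k` upper-inclusive class bounds (the last is
#'   `max(x)`), strictly increasing.
#' @export
jenks_breaks <- function(x, k) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (length(unique(x)) < k) stop("fewer distinct values than classes")
  if (k == 1) return(max(x))
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  sse <- function(i, j) {   # vectorized over i, scalar j: SSE of x[i..j]
    s <- s1[j] - c(0, s1)[i]
    q <- s2[j] - c(0, s2)[i]
    pmax(q - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)       # D[m, j]: best cost of x[1..j] in m classes
  idx <- matrix(0L, k, n)      # start index of the last class
  jj <- seq_len(n)
  D[1, ] <- pmax(s2 - s1^2 / jj, 0)
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j                  # last class starts at i
      cost <- D[m - 1, i - 1] + sse(i, j)
      best <- which.min(cost)
      D[m, j] <- cost[best]
      idx[m, j] <- i[best]
    }
  }
  ## recover class boundaries
  breaks <- numeric(k)
  j <- n
  for (m in k:2) {
    i <- idx[m, j]
    breaks[m] <- x[j]
    j <- i - 1L
  }
  breaks[1] <- x[j]
  breaks
}
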