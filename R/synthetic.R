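#' Configuration for the synthetic study-system generator
#'
#' Describes a synthetic basin: grid geometry, the land-class set (default six
#' classes in the conventional order cultivated, forest, grassland, water,
#' construction, unused), initial class proportions, a row-stochastic
#' cell-level transition kernel between two epochs, driving-factor link
#' specifications, and socioeconomic series specifications with
#' exponential-trend structure.
#'
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param n_classes number of land classes (codes `1:n_classes`).
#' @param cell_area hm^2 per cell (> 0).
#' @param class_props initial epoch class proportions (length `n_classes`,
#'   summing to 1). Default mimics an arid, grassland-dominated basin.
#' @param transition_kernel `n_classes` x `n_classes` row-stochastic matrix;
#'   entry (s, t) is the probability a cell of class s becomes class t.
#'   Default is the identity (no change).
#' @param factor_specs list of driving-factor specs, each a list with fields
#'   `name`, `from`, `to`, `slope`: the factor is standard normal noise plus
#'   `slope` on cells that undergo the (from, to) transition, i.e. a logistic
#'   (equal-variance Gaussian discriminant) link with logit slope `slope`.
#'   `NULL` derives one linked factor per off-diagonal kernel entry.
#' @param n_factors total number of factor layers (unlinked ones are pure
#'   noise).
#' @param link_slope default logit slope for auto-derived factor links.
#' @param series_specs named list of socioeconomic series specs, each a list
#'   with `v0` (initial value, > 0), `growth` (per-year rate), `sd`
#'   (multiplicative log-normal noise sd) and `units`. `NULL` gives a
#'   realistic default set (population, per-capita GDP and Engel coefficients
#'   for region and nation, grain sown area/yield/price, NPP and FVC means).
#' @param years the year axis of the socioeconomic series.
#' @param seed integer seed threaded through all stochastic operations.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows, grid_cols, n_classes = 6,
                             cell_area = 1,
                             class_props = NULL,
                             transition_kernel = diag(n_classes),
                             factor_specs = NULL, n_factors = 18,
                             link_slope = 3,
                             series_specs = NULL, years = 1990:2020,
                             seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_classes >= 1, cell_area > 0)
  if (is.null(class_props)) {
    class_props <- if (n_classes == 6)
      c(0.10, 0.05, 0.49, 0.04, 0.01, 0.31) else rep(1 / n_classes, n_classes)
  }
  stopifnot(length(class_props) == n_classes, all(class_props >= 0),
            abs(sum(class_props) - 1) < 1e-9)
  transition_kernel <- as.matrix(transition_kernel)
  if (!all(dim(transition_kernel) == c(n_classes, n_classes)))
    stop("transition_kernel must be ", n_classes, " x ", n_classes)
  if (any(transition_kernel < 0) ||
      any(abs(rowSums(transition_kernel) - 1) > 1e-9))
    stop("transition_kernel rows must be non-negative and sum to 1")
  if (is.null(series_specs)) series_specs <- default_series_specs()
  for (nm in names(series_specs))
    if (series_specs[[nm]]$v0 <= 0)
      stop("series '", nm, "' has non-positive initial value")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_classes = as.integer(n_classes), cell_area = cell_area,
         class_props = class_props, transition_kernel = transition_kernel,
         factor_specs = factor_specs, n_factors = as.integer(n_factors),
         link_slope = link_slope, series_specs = series_specs,
         years = years, seed = as.integer(seed)),
    class = "synthetic_config")
}

default_series_specs <- function() {
  list(
    population     = list(v0 = 3.5e5, growth = 0.013, sd = 0, units = "persons"),
    gdp_region     = list(v0 = 3000,  growth = 0.085, sd = 0, units = "yuan/person"),
    gdp_nation     = list(v0 = 5000,  growth = 0.080, sd = 0, units = "yuan/person"),
    engel_region   = list(v0 = 0.52,  growth = -0.012, sd = 0, units = "fraction"),
    engel_nation   = list(v0 = 0.50,  growth = -0.013, sd = 0, units = "fraction"),
    grain_area     = list(v0 = 2.5e5, growth = 0.015, sd = 0, units = "hm2"),
    grain_yield    = list(v0 = 4500,  growth = 0.020, sd = 0, units = "kg/hm2"),
    grain_price    = list(v0 = 1.0,   growth = 0.025, sd = 0, units = "yuan/kg"),
    npp_region     = list(v0 = 280,   growth = 0.004, sd = 0, units = "gC/m2/yr"),
    npp_nation     = list(v0 = 320,   growth = 0.003, sd = 0, units = "gC/m2/yr"),
    fvc_region     = list(v0 = 0.34,  growth = 0.004, sd = 0, units = "fraction"),
    fvc_nation     = list(v0 = 0.46,  growth = 0.002, sd = 0, units = "fraction"))
}

## 4-neighbour cell ids on an nr x nc grid stored column-major
neighbors4 <- function(ids, nr, nc) {
  row <- (ids - 1L) %% nr + 1L
  col <- (ids - 1L) %/% nr + 1L
  c(ids[row > 1L] - 1L, ids[row < nr] + 1L,
    ids[col > 1L] - nr, ids[col < nc] + nr)
}

## Smooth random scalar field: a few random sinusoids + tie-breaking jitter.
## Level sets of the field become the initial class regions, so the map is
## spatially autocorrelated while class counts stay exact.
smooth_field <- function(nr, nc, n_waves = 6) {
  xs <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (j in seq_len(n_waves)) {
    freq <- runif(1, 1, 4); th <- runif(1, 0, pi)
    amp <- runif(1, 0.5, 1); ph <- runif(1, 0, 2 * pi)
    f <- f + amp * sin(2 * pi * freq * (cos(th) * xs + sin(th) * ys) + ph)
  }
  f + rnorm(nr * nc, sd = 1e-4)
}

## Initial epoch: assign classes along field quantiles with exact counts.
synth_base_grid <- function(config) {
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  counts <- largest_remainder(config$class_props * n, n)
  field <- smooth_field(nr, nc)
  v <- integer(n)
  v[order(field)] <- rep.int(seq_len(config$n_classes), counts)
  matrix(v, nr, nc)
}

## Convert `quota` cells out of the available set, as contiguous patches
## grown by 4-neighbour dilation from random seeds.
grow_patches <- function(avail, quota, nr, nc) {
  chosen <- integer(0)
  need <- quota
  while (need > 0) {
    ids <- which(avail)
    if (!length(ids)) break
    seed <- ids[sample.int(length(ids), 1L)]
    avail[seed] <- FALSE
    chosen <- c(chosen, seed)
    need <- need - 1L
    frontier <- seed
    while (need > 0 && length(frontier)) {
      nb <- neighbors4(frontier, nr, nc)
      nb <- unique(nb[avail[nb]])
      if (!length(nb)) break
      if (length(nb) > need) nb <- nb[sample.int(length(nb), need)]
      avail[nb] <- FALSE
      chosen <- c(chosen, nb)
      need <- need - length(nb)
      frontier <- nb
    }
  }
  list(chosen = chosen, avail = avail)
}

#' Generate an aligned pair of categorical land-use grids
#'
#' Builds an initial spatially autocorrelated class map with the configured
#' class proportions (exact cell counts), then applies the configured
#' transition kernel patch-wise: for each origin class the number of cells
#' converted to each destination equals the kernel row times the class count
#' (largest-remainder rounding), and converted cells form contiguous patches
#' grown by neighbourhood dilation from random seeds. Cell-level empirical
#' transition frequencies therefore match the kernel up to rounding.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `start` and `end`, both [lulc_grid()] objects
#'   on identical geometry.
#' @export
generate_lulc_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  K <- config$transition_kernel
  with_seed(config$seed, {
    g1 <- synth_base_grid(config)
    g2 <- g1
    for (s in seq_len(config$n_classes)) {
      cells_s <- which(g1 == s)
      if (!length(cells_s)) next
      quotas <- largest_remainder(K[s, ] * length(cells_s), length(cells_s))
      avail <- logical(nr * nc)
      avail[cells_s] <- TRUE
      dest <- order(quotas, decreasing = TRUE)
      for (t in dest) {
        if (t == s || quotas[t] == 0) next
        res <- grow_patches(avail, quotas[t], nr, nc)
        g2[res$chosen] <- t
        avail <- res$avail
      }
    }
    list(
      start = lulc_grid(g1, cell_area = config$cell_area,
                        classes = seq_len(config$n_classes),
                        year = config$years[1]),
      end = lulc_grid(g2, cell_area = config$cell_area,
                      classes = seq_len(config$n_classes),
                      year = config$years[length(config$years)]))
  })
}

#' Generate a driving-factor stack with known transition links
#'
#' Each linked factor is standard normal noise shifted by `slope` on the
#' cells that undergo its target transition in `pair`; under this
#' equal-variance Gaussian construction the conditional class probability is
#' exactly logistic in the factor with logit slope `slope`, so suitability
#' learners have a known recoverable signal. Unlinked layers are pure noise.
#'
#' @param config a [synthetic_config()].
#' @param pair output of [generate_lulc_pair()] on the same configuration.
#' @return a [factor_stack()] with attribute `links`, a data frame recording
#'   each layer's (from, to, slope) ground truth (slope 0 for noise layers).
#' @export
generate_factor_stack <- function(config, pair) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!same_geometry(pair$start, pair$end) ||
      !identical(dim(pair$start$values),
                 c(config$grid_rows, config$grid_cols)))
    stop("`pair` geometry does not match `config`")
  specs <- config$factor_specs
  if (is.null(specs)) {
    K <- config$transition_kernel
    idx <- which(K > 0 & row(K) != col(K), arr.ind = TRUE)
    specs <- lapply(seq_len(min(nrow(idx), config$n_factors)), function(i) {
      list(name = sprintf("drv_%dto%d", idx[i, 1], idx[i, 2]),
           from = idx[i, 1], to = idx[i, 2], slope = config$link_slope)
    })
  }
  if (length(specs) > config$n_factors)
    stop("more factor_specs than n_factors")
  nr <- config$grid_rows; nc <- config$grid_cols
  a <- pair$start$values; b <- pair$end$values
  with_seed(config$seed + 1L, {
    layers <- list()
    links <- data.frame(name = character(), from = integer(),
                        to = integer(), slope = numeric())
    for (sp in specs) {
      z <- matrix(rnorm(nr * nc), nr, nc)
      changed <- a == sp$from & b == sp$to
      z[changed] <- z[changed] + sp$slope
      layers[[sp$name]] <- z
      links <- rbind(links, data.frame(name = sp$name, from = sp$from,
                                       to = sp$to, slope = sp$slope))
    }
    while (length(layers) < config$n_factors) {
      nm <- sprintf("noise_%02d", length(layers) + 1L)
      layers[[nm]] <- matrix(rnorm(nr * nc), nr, nc)
      links <- rbind(links, data.frame(name = nm, from = NA_integer_,
                                       to = NA_integer_, slope = 0))
    }
    fs <- factor_stack(layers)
    attr(fs, "links") <- links
    fs
  })
}

#' Generate socioeconomic yearbook-style series
#'
#' Each series follows `v0 * (1 + growth)^(year - year0)` with multiplicative
#' log-normal noise of the configured sd (`sd = 0` gives the exact
#' exponential trend, the structure a GM(1,1) grey model assumes).
#'
#' @param config a [synthetic_config()].
#' @return named list of `socio_series` objects (fields `name`, `years`,
#'   `values`, `units`).
#' @export
generate_socio_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  yrs <- config$years
  with_seed(config$seed + 2L, {
    out <- lapply(names(config$series_specs), function(nm) {
      sp <- config$series_specs[[nm]]
      t <- yrs - yrs[1]
      noise <- if (sp$sd > 0) exp(rnorm(length(t), 0, sp$sd)) else 1
      socio_series(nm, yrs, sp$v0 * (1 + sp$growth)^t * noise,
                   units = sp$units)
    })
    names(out) <- names(config$series_specs)
    out
  })
}

#' Socioeconomic time series
#'
#' @param name series name.
#' @param years strictly increasing integer years.
#' @param values numeric values, same length as `years`.
#' @param units free-text units.
#' @return an object of class `socio_series`.
#' @export
socio_series <- function(name, years, values, units = "") {
  if (length(years) != length(values))
    stop("years and values must have the same length")
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  structure(list(name = name, years = years, values = values, units = units),
            class = "socio_series")
}

#' @export
print.socio_series <- function(x, ...) {
  cat(sprintf("<socio_series> %s [%s]: %d years %d-%d\n", x$name, x$units,
              length(x$years), min(x$years), max(x$years)))
  invisible(x)
}

## value of a series at a year (exact match required)
series_at <- function(s, year) {
  i <- match(year, s$years)
  if (is.na(i)) stop("series '", s$name, "' does not cover year ", year)
  s$values[i]
}
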