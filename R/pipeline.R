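#' Derive a constraint set from observed and projected areas
#'
#' Builds a feasible, data-driven analogue of the published constraint set
#' for synthetic or user basins: box bounds bracket the observed and
#' Markov-projected areas with a relative band; the projected population cap
#' is set with head-room above the population row evaluated at the upper
#' grey corner (so every whitening is feasible); the food parameters are
#' calibrated so the cultivated floor sits at a stated fraction of the
#' current cultivated area; the green-cover floor keeps margin below the
#' current green equivalent.
#'
#' @param base an [area_table()] of current areas.
#' @param projected an [area_table()] of projected (e.g. Markov) areas.
#' @param frac_band relative half-width of the box bounds.
#' @param floor_frac cultivated floor as a fraction of current cultivated
#'   area.
#' @param a21,a22 grey intervals (defaults as published).
#' @return a [constraint_set()].
#' @export
constraint_set_from_areas <- function(base, projected, frac_band = 0.2,
                                      floor_frac = 0.5,
                                      a21 = c(0.05, 0.07),
                                      a22 = c(4.31, 6.73)) {
  stopifnot(inherits(base, "area_table"), inherits(projected, "area_table"))
  xb <- base$area_hm2; xp <- projected$area_hm2
  total <- sum(xb)
  lower <- pmax(0, pmin(xb, xp) * (1 - frac_band))
  upper <- pmin(total, pmax(xb, xp) * (1 + frac_band))
  upper <- pmax(upper, lower + 1e-9)
  P <- 1.05 * (a21[2] * sum(pmax(xb, xp)[1:3]) + a22[2] * max(xb[5], xp[5]))
  S <- 538; f0 <- 1; f_ratio <- 0.2668; f_multi <- 1.29
  floor_target <- max(lower[1], floor_frac * xb[1], 1e-9)
  f_yield <- P * S * f0 / (floor_target * f_ratio * f_multi)
  green <- c(0.46, 1, 0.49)
  green_frac <- min(0.2, 0.9 * sum(green * lower[1:3]) / total)
  constraint_set(total_area = total, a21 = a21, a22 = a22, P = P, S = S,
                 f0 = f0, f_yield = f_yield, f_ratio = f_ratio,
                 f_multi = f_multi, green_coef = green,
                 green_floor_frac = green_frac,
                 lower = lower, upper = upper)
}

#' Correction factors for a valuation year from socioeconomic series
#'
#' Computes the dynamic standard equivalent (grain price x yield / 7), the
#' biomass factor Q and the social coefficient PI from the series set,
#' GM(1,1)-forecasting any series that does not reach the year.
#'
#' @param series named list of [socio_series()] (the
#'   [generate_socio_series()] set).
#' @param year valuation year.
#' @return list with `Ea`, `Q`, `PI`.
#' @export
esv_factors_for_year <- function(series, year) {
  g <- function(nm) gm11_forecast_year(series[[nm]], year)
  Ea <- g("grain_price") * g("grain_yield") / 7
  Q <- biomass_factor(g("npp_region"), g("npp_nation"),
                      g("fvc_region"), g("fvc_nation"))
  PI <- social_coefficient(g("gdp_region"), g("gdp_nation"),
                           min(g("engel_region"), 1),
                           min(g("engel_nation"), 1))$PI
  list(Ea = Ea, Q = Q, PI = PI)
}

#' Pipeline run configuration
#'
#' @param synth a [synthetic_config()] describing the study system.
#' @param scenarios scenario modes to run (subset of bau/red/elp/eeb).
#' @param lambda grey whitening weight for the LP scenarios.
#' @param markov_steps Markov steps for the BAU projection.
#' @param allocate run the CA spatial allocation stage?
#' @param with_validation run the historical-replay validation stage?
#' @param with_factors generate the driving-factor stack (required by
#'   allocation)?
#' @param sensitivity_lambdas whitening grid for the sensitivity annex
#'   (`NULL` skips the annex).
#' @param out_dir directory for persisted CSV artifacts (`NULL` keeps
#'   everything in memory).
#' @param target_year scenario horizon label.
#' @param seed master seed; every stochastic stage derives from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth, scenarios = c("bau", "red", "elp", "eeb"),
                            lambda = 0.5, markov_steps = 1, allocate = TRUE,
                            with_validation = TRUE, with_factors = TRUE,
                            sensitivity_lambdas = c(0, 0.5, 1),
                            out_dir = NULL, target_year = 2035, seed = 1L) {
  stopifnot(inherits(synth, "synthetic_config"))
  scenarios <- match.arg(scenarios, c("bau", "red", "elp", "eeb"),
                         several.ok = TRUE)
  if (allocate && !with_factors)
    stop("allocation requested but the factor stack is disabled")
  structure(list(synth = synth, scenarios = scenarios, lambda = lambda,
                 markov_steps = markov_steps, allocate = allocate,
                 with_validation = with_validation,
                 with_factors = with_factors,
                 sensitivity_lambdas = sensitivity_lambdas,
                 out_dir = out_dir, target_year = target_year,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the coupled accounting-valuation-optimization-allocation pipeline
#'
#' Executes, in order: synthetic data generation; LULC accounting (areas,
#' dynamic degrees, transition matrix, Markov projection); equivalent-factor
#' ESV valuation of both epochs with dynamic corrections; GMOP scenario
#' optimization of the class structure at the target year; LEAS suitability
#' learning and CA allocation of each scenario's demand; historical-replay
#' validation; and report assembly. Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @return list of class `report_bundle` (see fields in the returned
#'   object): `areas`, `dynamics`, `transitions`, `esv`,
#'   `scenario_comparison`, `solutions`, `allocations`, `validation`,
#'   `sensitivity`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  synth <- config$synth
  ## --- synthesis ---------------------------------------------------------
  pair <- stage("synthetic", generate_lulc_pair(synth))
  factors <- if (config$with_factors)
    stage("synthetic", generate_factor_stack(synth, pair)) else NULL
  series <- stage("synthetic", generate_socio_series(synth))
  y0 <- synth$years[1]; y1 <- synth$years[length(synth$years)]
  ## --- accounting --------------------------------------------------------
  at0 <- stage("accounting", class_areas(pair$start, y0))
  at1 <- stage("accounting", class_areas(pair$end, y1))
  kt <- stage("accounting", {
    ok <- at0$area_hm2 > 0
    k <- rep(NA_real_, nrow(at0))
    k[ok] <- round2(dynamic_degree(at0$area_hm2[ok], at1$area_hm2[ok],
                                   y1 - y0))
    data.frame(class = at0$class, name = at0$name, K_pct_per_yr = k)
  })
  tm <- stage("accounting", transition_matrix(pair$start, pair$end))
  markov_at <- stage("accounting",
                     markov_project(tm, at1, config$markov_steps))
  ## --- valuation ---------------------------------------------------------
  esv <- stage("valuation", {
    reports <- list()
    for (yr in c(y0, y1)) {
      fac <- esv_factors_for_year(series, yr)
      eq <- equivalent_table(equivalent_version_for(yr))
      vc <- corrected_coefficients(eq, fac$Ea, fac$Q, fac$PI)
      at <- if (yr == y0) at0 else at1
      reports[[as.character(yr)]] <- esv_total(at, vc)
    }
    reports
  })
  ## --- optimization ------------------------------------------------------
  cs <- stage("optimization", constraint_set_from_areas(at1, markov_at))
  solutions <- stage("optimization", {
    out <- list()
    for (mode in config$scenarios) {
      sp <- scenario_spec(mode, lambda = config$lambda)
      out[[mode]] <- solve_scenario(sp, cs, tm = tm, base = at1,
                                    n_steps = config$markov_steps)
    }
    out
  })
  sens <- if (!is.null(config$sensitivity_lambdas) &&
              any(config$scenarios != "bau")) {
    mode <- setdiff(config$scenarios, "bau")[1]
    stage("optimization",
          grey_sensitivity(scenario_spec(mode, lambda = config$lambda),
                           cs, lambda_grid = config$sensitivity_lambdas))
  } else NULL
  ## --- scenario valuation -------------------------------------------------
  fac35 <- stage("valuation", esv_factors_for_year(series, config$target_year))
  vc35 <- stage("valuation", corrected_coefficients(
    equivalent_table(equivalent_version_for(config$target_year)),
    fac35$Ea, fac35$Q, fac35$PI))
  scen_esv <- stage("valuation", {
    out <- list()
    for (mode in names(solutions)) {
      s <- solutions[[mode]]
      if (any(is.na(s$x))) next
      at <- area_table(s$x, year = paste0(config$target_year, "_", mode))
      out[[mode]] <- esv_total(at, vc35)
    }
    out
  })
  ## --- allocation + validation -------------------------------------------
  allocations <- NULL; validation <- NULL; leas <- NULL
  if (config$allocate) {
    if (is.null(factors))
      stop("pipeline stage 'allocation' failed: factor stack missing")
    leas <- stage("allocation", {
      grown <- which(at1$area_hm2 > at0$area_hm2 * 1.001)
      fits <- list()
      for (cl in at1$class[grown]) {
        smp <- extract_expansion_samples(pair$start, pair$end, factors, cl,
                                         sampling_rate = 0.1,
                                         seed = synth$seed + 10L + cl)
        if (sum(smp$y) >= 30)
          fits[[as.character(cl)]] <- fit_leas(smp, factors,
                                               num_trees = 64,
                                               seed = synth$seed + 20L + cl)
      }
      fits
    })
    suit <- lapply(leas, `[[`, "surface")
    flat <- matrix(0.5, nrow(pair$end$values), ncol(pair$end$values))
    for (cl in as.character(at1$class))
      if (is.null(suit[[cl]])) suit[[cl]] <- flat
    allocations <- stage("allocation", {
      out <- list()
      for (mode in names(solutions)) {
        s <- solutions[[mode]]
        if (any(is.na(s$x))) next
        demand <- s$x / sum(s$x) * sum(at1$area_hm2)
        out[[mode]] <- simulate_ca(pair$end, suit,
                                   ca_params(demand,
                                             seed = synth$seed + 30L))
      }
      out
    })
    if (config$with_validation) {
      validation <- stage("validation", {
        demand <- stats::setNames(at1$area_hm2, at1$class)
        replay <- simulate_ca(pair$start, suit,
                              ca_params(demand, seed = synth$seed + 40L))
        validate(replay, pair$end, pair$start)
      })
    }
  }
  ## --- reporting ----------------------------------------------------------
  totals <- c(stats::setNames(esv[[as.character(y1)]]$total,
                              as.character(y1)),
              vapply(scen_esv, `[[`, numeric(1), "total"))
  comparison <- stage("reporting", {
    ds <- derived_stats(totals)
    areas <- do.call(cbind, c(list(base = at1$area_hm2),
                              lapply(solutions, function(s) unname(s$x))))
    rownames(areas) <- at1$name
    list(areas_hm2 = areas, esv = ds$changes)
  })
  bundle <- structure(list(
    pair = pair, series = series,
    areas = list(start = at0, end = at1, markov = markov_at),
    dynamics = kt, transitions = tm, esv = esv, scenario_esv = scen_esv,
    solutions = solutions, sensitivity = sens,
    scenario_comparison = comparison,
    allocations = allocations, validation = validation, leas = leas,
    provenance = list(seed = config$seed, hash = config_hash(config),
                      scenarios = config$scenarios,
                      lambda = config$lambda,
                      package_version =
                        as.character(utils::packageVersion("greyplus")))),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n epochs:",
      paste(names(x$esv), collapse = ", "), "\n scenarios:",
      paste(names(x$solutions), collapse = ", "), "\n seed:",
      x$provenance$seed, "\n")
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$areas$end, file.path(dir, "areas_end.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$dynamics, file.path(dir, "dynamic_degree.csv"),
                   row.names = FALSE)
  utils::write.csv(sankey_export(bundle$transitions),
                   file.path(dir, "transitions.csv"), row.names = FALSE)
  utils::write.csv(bundle$scenario_comparison$esv,
                   file.path(dir, "scenario_esv.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$provenance,
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Reporting-layer consistency arithmetic
#'
#' Pushes totals through the derived-statistics path ([derived_stats()]):
#' increments, percentage changes and optional class contribution shares.
#' Accepts externally supplied totals so published endpoint values can be
#' run through the same code as pipeline output (fixture mode).
#'
#' @param totals named totals (baseline first) or a `report_bundle`.
#' @param class_values optional per-class value matrix (see
#'   [derived_stats()]).
#' @param digits reporting precision.
#' @return the [derived_stats()] list.
#' @export
report_consistency <- function(totals, class_values = NULL, digits = 2) {
  if (inherits(totals, "report_bundle")) {
    b <- totals
    labs <- names(b$esv)
    totals <- stats::setNames(vapply(b$esv, `[[`, numeric(1), "total"), labs)
    class_values <- vapply(b$esv, `[[`,
                           numeric(length(b$esv[[1]]$per_class)),
                           "per_class")
  }
  if (length(totals) < 2) {
    return(list(changes = data.frame(label = character(),
                                     total = numeric(),
                                     increment = numeric(),
                                     pct_change = numeric())))
  }
  derived_stats(totals, class_values, digits = digits)
}
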