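#' Objective coefficients for the land-structure program
#'
#' Three linear objectives over the six class areas x1..x6 (hm^2):
#' economic benefit `E`, ecosystem-service value `V`, and ecological
#' capacity `C` (the latter with the 12% biodiversity set-aside deduction
#' already folded into the printed coefficients; the deduction factor is
#' recorded as metadata).
#'
#' @param E per-class economic coefficients (10^4 yuan/hm^2 scale as
#'   published).
#' @param V per-class ESV coefficients.
#' @param C per-class ecological-capacity coefficients, deduction applied.
#' @param deduction biodiversity set-aside fraction recorded with `C`.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(E = c(4.5, 2.37, 1.02, 0.02, 443.72, 0),
                           V = c(0.64, 2.88, 1.93, 14.6, 0, 0.12),
                           C = c(4.64, 0.59, 0.50, 0.18, 4.64, 0),
                           deduction = 0.12) {
  stopifnot(length(E) == 6, length(V) == 6, length(C) == 6)
  structure(list(E = E, V = V, C = C, deduction = deduction,
                 coef = list(f1 = E, f2 = V, f3 = C)),
            class = "objective_spec")
}

#' Constraint set for the grey land-structure program
#'
#' Houses the published constraint constants: the total-area equality, the
#' grey population row `a21*(x1+x2+x3) + a22*x5 <= P` with interval-valued
#' coefficients, the food-security floor on cultivated land
#' `x1 >= P*S*f0 / (yield * crop_ratio * multi_index)`, the green-equivalent
#' forest-cover floor, and per-class box bounds. Interval notation is
#' normalized to `c(lower, upper)`.
#'
#' @param total_area basin area, hm^2 (equality).
#' @param a21,a22 grey intervals `c(lower, upper)` of the population row.
#' @param P projected population.
#' @param S per-capita food requirement (kg), `f0` self-sufficiency rate,
#'   `f_yield` grain yield (kg/hm^2), `f_ratio` crop cultivation ratio,
#'   `f_multi` multiple-cropping index.
#' @param green_coef green-equivalent coefficients of (cultivated, forest,
#'   grassland).
#' @param green_floor_frac forest-cover floor as a fraction of total area.
#' @param lower,upper per-class box bounds (hm^2), classes 1..6. The
#'   cultivated floor is the food-derived value (computed, see
#'   [cropland_floor()]); its default slot is 0 and the effective bound is
#'   `max(lower[1], cropland_floor)`.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(total_area = 5035616,
                           a21 = c(0.05, 0.07), a22 = c(4.31, 6.73),
                           P = 563578,
                           S = 538, f0 = 1, f_yield = 10845,
                           f_ratio = 0.2668, f_multi = 1.29,
                           green_coef = c(0.46, 1, 0.49),
                           green_floor_frac = 0.20,
                           lower = c(0, 92537, 2364064, 148363, 62739, 0),
                           upper = c(957862, 121697, 2616499, 166058,
                                     91707, 1326661)) {
  a21 <- sort(a21); a22 <- sort(a22)
  stopifnot(total_area > 0, length(lower) == 6, length(upper) == 6,
            all(lower <= upper), all(lower >= 0),
            all(is.finite(c(a21, a22, P, S, f0, f_yield, f_ratio, f_multi))))
  structure(list(total_area = total_area, a21 = a21, a22 = a22, P = P,
                 S = S, f0 = f0, f_yield = f_yield, f_ratio = f_ratio,
                 f_multi = f_multi, green_coef = green_coef,
                 green_floor_frac = green_floor_frac,
                 lower = lower, upper = upper),
            class = "constraint_set")
}

#' Food-derived cultivated-land floor (hm^2)
#'
#' `x1 >= P * S * f0 / (f_yield * f_ratio * f_multi)`.
#'
#' @param cs a [constraint_set()].
#' @return floor on x1 in hm^2.
#' @export
cropland_floor <- function(cs) {
  cs$P * cs$S * cs$f0 / (cs$f_yield * cs$f_ratio * cs$f_multi)
}

#' Whiten a grey interval
#'
#' @param interval `c(lower, upper)`.
#' @param lambda whitening weight in \[0, 1\]; value is
#'   `lower + lambda * (upper - lower)`.
#' @return crisp value.
#' @export
whiten <- function(interval, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  interval[1] + lambda * (interval[2] - interval[1])
}

#' Scenario specification
#'
#' @param mode one of `"bau"` (Markov projection, no LP), `"red"`
#'   (maximize f1), `"elp"` (maximize f2 and f3), `"eeb"` (maximize f1, f2
#'   and f3).
#' @param weights scalarization weights over the scenario's objective set
#'   (non-negative, normalized to sum 1); default equal.
#' @param lambda whitening weights: either one value applied to both grey
#'   intervals or `c(lambda_a21, lambda_a22)`.
#' @param method `"weighted"` (weighted sum of min-max normalized
#'   objectives) or `"lexicographic"` (sequential optimization in the listed
#'   objective order, each later stage constrained to retain earlier optima
#'   within `lex_tol` relative slack).
#' @param lex_tol relative slack retained in lexicographic mode.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("red", "elp", "eeb", "bau"),
                          weights = NULL, lambda = 0.5,
                          method = c("weighted", "lexicographic"),
                          lex_tol = 1e-6) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  objectives <- switch(mode, bau = character(0), red = "f1",
                       elp = c("f2", "f3"), eeb = c("f1", "f2", "f3"))
  if (is.null(weights)) weights <- rep(1, length(objectives))
  if (length(objectives)) {
    stopifnot(length(weights) == length(objectives), all(weights >= 0),
              sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  if (length(lambda) == 1) lambda <- c(lambda, lambda)
  structure(list(mode = mode, objectives = objectives, weights = weights,
                 lambda = lambda, method = method, lex_tol = lex_tol),
            class = "scenario_spec")
}

#' Assemble the linear program for a scenario
#'
#' Resolves the grey intervals at the scenario's whitening weights and lays
#' out the rows: the total-area equality; the population inequality
#' (`<=`); the green-equivalent cover floor (`>=`); and per-class box
#' bounds (including the cultivated cap and the food-derived cultivated
#' floor). Variables are continuous areas in hm^2, implicitly `>= 0`.
#'
#' @param spec a [scenario_spec()] (LP modes only).
#' @param cs a [constraint_set()].
#' @param obj an [objective_spec()].
#' @return list of class `gmop_lp` with components `A1, b1` (<= rows),
#'   `A2, b2` (>= rows), `A3, b3` (equality rows), `lower`, `upper`
#'   (effective box bounds) and `coef` (the three objective vectors).
#' @export
build_lp <- function(spec, cs, obj = objective_spec()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(cs, "constraint_set"))
  if (spec$mode == "bau")
    stop("BAU is a Markov projection; no LP is built for it")
  a21 <- whiten(cs$a21, spec$lambda[1])
  a22 <- whiten(cs$a22, spec$lambda[2])
  pop_row <- c(a21, a21, a21, 0, a22, 0)
  green_row <- c(cs$green_coef, 0, 0, 0)
  lower <- cs$lower
  lower[1] <- max(lower[1], cropland_floor(cs))
  structure(list(
    A1 = matrix(pop_row, 1, 6,
                dimnames = list("population", NULL)), b1 = cs$P,
    A2 = matrix(green_row, 1, 6,
                dimnames = list("green_cover", NULL)),
    b2 = cs$total_area * cs$green_floor_frac,
    A3 = matrix(1, 1, 6, dimnames = list("total_area", NULL)),
    b3 = cs$total_area,
    lower = lower, upper = cs$upper,
    coef = obj$coef, lambda = spec$lambda),
    class = "gmop_lp")
}

## Solve max/min c'x over a gmop_lp (bounds folded into inequality rows)
## with boot::simplex. Returns list(status, x, value).
lp_optimize <- function(lp, cvec, maximize = TRUE) {
  A1 <- rbind(lp$A1, diag(6))
  b1 <- c(lp$b1, lp$upper)
  A2 <- rbind(lp$A2, diag(6))
  b2 <- c(lp$b2, lp$lower)
  ## scale objective and variables to order one; the tableau pivots are
  ## ill-conditioned when areas are ~1e6 against a 1e-10 zero tolerance
  sc_c <- max(abs(cvec), 1)
  sc_x <- max(abs(c(b1, b2, lp$b3)), 1)
  s <- boot::simplex(a = cvec / sc_c, A1 = A1, b1 = b1 / sc_x,
                     A2 = A2, b2 = b2 / sc_x,
                     A3 = lp$A3, b3 = lp$b3 / sc_x, maxi = maximize,
                     eps = 1e-9, n.iter = 500)
  list(status = if (s$solved == 1) "optimal" else
         if (s$solved == 0) "max-iterations" else "infeasible",
       x = as.numeric(s$soln) * sc_x,
       value = as.numeric(s$value) * sc_c * sc_x)
}

#' Solve a scenario of the grey multi-objective program
#'
#' LP modes (`red`, `elp`, `eeb`) solve the scalarized program; `bau`
#' bypasses the LP and returns the Markov projection (supply `tm`, `base`,
#' `n_steps`). Multi-objective scalarization follows the weighted sum of
#' min-max normalized objectives: each objective in the scenario's set is
#' normalized by its own feasible minimum and maximum (two auxiliary LP
#' solves) before weighting, so the composite is scale-free. A
#' lexicographic alternative is available through the scenario `method`.
#'
#' @param spec a [scenario_spec()].
#' @param cs a [constraint_set()].
#' @param obj an [objective_spec()].
#' @param tm,base,n_steps Markov inputs, used only in `bau` mode.
#' @return object of class `gmop_solution`: `x` (named areas, hm^2),
#'   `objectives` (f1, f2, f3 at `x`), `status`, `binding` (names of
#'   constraints with zero slack), `lambda`, `mode`.
#' @export
solve_scenario <- function(spec, cs, obj = objective_spec(),
                           tm = NULL, base = NULL, n_steps = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$mode == "bau") {
    if (is.null(tm) || is.null(base))
      stop("BAU mode needs a transition matrix and base area table")
    at <- markov_project(tm, base, n_steps)
    x <- stats::setNames(at$area_hm2, at$class)
    return(new_solution(x, obj, cs, spec, status = "markov"))
  }
  lp <- build_lp(spec, cs, obj)
  coefs <- lp$coef[spec$objectives]
  cvec <- if (length(coefs) == 1) {
    coefs[[1]]
  } else if (spec$method == "weighted") {
    ## min-max normalize each objective over the feasible region
    comp <- numeric(6)
    for (i in seq_along(coefs)) {
      hi <- lp_optimize(lp, coefs[[i]], TRUE)
      lo <- lp_optimize(lp, coefs[[i]], FALSE)
      if (hi$status != "optimal" || lo$status != "optimal")
        return(infeasible_solution(spec, hi$status))
      rng <- hi$value - lo$value
      if (rng <= 0) rng <- 1
      comp <- comp + spec$weights[i] * coefs[[i]] / rng
    }
    comp
  } else NULL
  if (spec$method == "lexicographic" && length(coefs) > 1) {
    sol <- NULL
    for (i in seq_along(coefs)) {
      res <- lp_optimize(lp, coefs[[i]], TRUE)
      if (res$status != "optimal") return(infeasible_solution(spec, res$status))
      sol <- res
      if (i < length(coefs)) {  # pin this objective within relative slack
        lp$A2 <- rbind(lp$A2, matrix(coefs[[i]], 1, 6,
                                     dimnames = list(paste0("lex_",
                                                            spec$objectives[i]),
                                                     NULL)))
        lp$b2 <- c(lp$b2, res$value - abs(res$value) * spec$lex_tol - 1e-9)
      }
    }
    res <- sol
  } else {
    res <- lp_optimize(lp, cvec, TRUE)
  }
  if (res$status != "optimal") return(infeasible_solution(spec, res$status))
  x <- stats::setNames(res$x, 1:6)
  new_solution(x, obj, cs, spec, status = "optimal")
}

infeasible_solution <- function(spec, status) {
  structure(list(x = rep(NA_real_, 6), objectives = c(f1 = NA, f2 = NA,
                                                      f3 = NA),
                 status = status, binding = character(0),
                 lambda = spec$lambda, mode = spec$mode),
            class = "gmop_solution")
}

new_solution <- function(x, obj, cs, spec, status) {
  if (length(x) == 6) {
    objs <- vapply(obj$coef, function(cf) sum(cf * x), numeric(1))
    fc <- feasibility_check(x, cs, lambda = spec$lambda)
    binding <- fc$constraint[abs(fc$slack) < 1e-6 * max(cs$total_area, 1)]
  } else {
    ## Markov projections may carry a different class count; the LP
    ## machinery (and its 6-class objective/constraint vectors) do not apply
    objs <- c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
    fc <- NULL
    binding <- character(0)
  }
  structure(list(x = x, objectives = objs, status = status,
                 binding = binding, lambda = spec$lambda, mode = spec$mode,
                 feasibility = fc),
            class = "gmop_solution")
}

#' @export
print.gmop_solution <- function(x, ...) {
  cat(sprintf("<gmop_solution> mode %s, status %s\n", x$mode, x$status))
  if (!any(is.na(x$x))) {
    print(round(x$x))
    cat("objectives:", paste(sprintf("%s=%.4g", names(x$objectives),
                                     x$objectives), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check a candidate area vector against every constraint
#'
#' Reports the signed slack of each constraint family (total area equality,
#' population row at the given whitening, green-cover floor, per-class box
#' bounds including the food-derived cultivated floor, non-negativity).
#' Positive slack means satisfied; an empty violation set means feasible.
#'
#' @param x 6-vector of areas (hm^2).
#' @param cs a [constraint_set()].
#' @param lambda whitening weights (scalar or length-2) for the grey rows.
#' @param tol equality tolerance, relative to total area.
#' @return data frame with columns `constraint`, `type`, `value`, `bound`,
#'   `slack`, `violated`.
#' @export
feasibility_check <- function(x, cs, lambda = 0.5, tol = 1e-6) {
  stopifnot(length(x) == 6, inherits(cs, "constraint_set"))
  if (length(lambda) == 1) lambda <- c(lambda, lambda)
  a21 <- whiten(cs$a21, lambda[1]); a22 <- whiten(cs$a22, lambda[2])
  lower <- cs$lower; lower[1] <- max(lower[1], cropland_floor(cs))
  rows <- list(
    list("total_area", "eq", sum(x), cs$total_area,
         -abs(sum(x) - cs$total_area)),
    list("population", "le", a21 * sum(x[1:3]) + a22 * x[5], cs$P,
         cs$P - (a21 * sum(x[1:3]) + a22 * x[5])),
    list("green_cover", "ge", sum(cs$green_coef * x[1:3]),
         cs$total_area * cs$green_floor_frac,
         sum(cs$green_coef * x[1:3]) - cs$total_area * cs$green_floor_frac))
  for (i in 1:6) {
    rows <- c(rows,
              list(list(paste0("x", i, "_lower"), "ge", x[i], lower[i],
                        x[i] - lower[i]),
                   list(paste0("x", i, "_upper"), "le", x[i], cs$upper[i],
                        cs$upper[i] - x[i]),
                   list(paste0("x", i, "_nonneg"), "ge", x[i], 0, x[i])))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(constraint = r[[1]], type = r[[2]], value = r[[3]],
               bound = r[[4]], slack = r[[5]])))
  out$violated <- out$slack < -tol * max(cs$total_area, 1)
  out
}

#' Violations only
#'
#' @param x 6-vector of areas; see [feasibility_check()].
#' @inheritParams feasibility_check
#' @return the violated rows of [feasibility_check()] (zero rows iff
#'   feasible).
#' @export
violations <- function(x, cs, lambda = 0.5, tol = 1e-6) {
  fc <- feasibility_check(x, cs, lambda, tol)
  fc[fc$violated, , drop = FALSE]
}

#' Grey-interval sensitivity sweep
#'
#' Solves the scenario over a grid of whitening weights for the two grey
#' intervals and reports the per-class area range across feasible corners.
#' Infeasible corners are reported, never silently dropped.
#'
#' @param spec a [scenario_spec()] (LP modes).
#' @param cs a [constraint_set()].
#' @param obj an [objective_spec()].
#' @param lambda_grid whitening weights to sweep (applied to both intervals
#'   as a full factorial), default `c(0, 0.5, 1)`.
#' @return list of class `grey_sensitivity`: `solutions` (one per lambda
#'   pair), `grid` (lambda pairs with status), `ranges` (per-class min/max
#'   over feasible solutions).
#' @export
grey_sensitivity <- function(spec, cs, obj = objective_spec(),
                             lambda_grid = c(0, 0.5, 1)) {
  stopifnot(all(lambda_grid >= 0 & lambda_grid <= 1))
  grid <- expand.grid(lambda_a21 = lambda_grid, lambda_a22 = lambda_grid)
  sols <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- scenario_spec(spec$mode, weights = spec$weights,
                        lambda = c(grid$lambda_a21[i], grid$lambda_a22[i]),
                        method = spec$method)
    sols[[i]] <- solve_scenario(sp, cs, obj)
  }
  grid$status <- vapply(sols, `[[`, character(1), "status")
  feas <- grid$status %in% c("optimal", "markov")
  ranges <- if (any(feas)) {
    xm <- do.call(rbind, lapply(sols[feas], `[[`, "x"))
    data.frame(class = 1:6, name = lulc_class_names(1:6),
               min_hm2 = apply(xm, 2, min), max_hm2 = apply(xm, 2, max))
  } else NULL
  structure(list(solutions = sols, grid = grid, ranges = ranges),
            class = "grey_sensitivity")
}

#' @export
print.grey_sensitivity <- function(x, ...) {
  cat("<grey_sensitivity>\n")
  print(x$grid)
  if (!is.null(x$ranges)) print(x$ranges)
  invisible(x)
}
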