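test_that("published constraint constants assemble into the expected rows", {
  cs <- constraint_set()
  # food-derived cultivated floor
  expect_equal(cropland_floor(cs),
               563578 * 538 / (10845 * 0.2668 * 1.29), tolerance = 1e-12)
  expect_equal(round(cropland_floor(cs)), 81233)
  # green-equivalent right-hand side
  lp <- build_lp(scenario_spec("red"), cs)
  expect_equal(lp$b2[1], 5035616 * 0.2)
  expect_equal(lp$b2[1], 1007123.2)
  # whitening endpoints give the printed interval ends
  lp0 <- build_lp(scenario_spec("red", lambda = 0), cs)
  lp1 <- build_lp(scenario_spec("red", lambda = 1), cs)
  expect_equal(unname(lp0$A1[1, c(1, 5)]), c(0.05, 4.31))
  expect_equal(unname(lp1$A1[1, c(1, 5)]), c(0.07, 6.73))
  expect_equal(whiten(c(0.05, 0.07), 0.5), 0.06)
  # grey interval entered in printed (upper, lower) order is normalized
  cs2 <- constraint_set(a21 = c(0.07, 0.05))
  expect_equal(cs2$a21, c(0.05, 0.07))
})

test_that("toy linear program solves by inspection", {
  # max 2 x1 + x2, x1 <= 5, x1 + x2 = 8 -> (5, 3), objective 13
  s <- boot::simplex(a = c(2, 1), A1 = matrix(c(1, 0), 1, 2), b1 = 5,
                     A3 = matrix(1, 1, 2), b3 = 8, maxi = TRUE)
  expect_equal(s$solved, 1)
  expect_equal(as.numeric(s$soln), c(5, 3))
  expect_equal(as.numeric(s$value), 13)
})

test_that("solver matches brute-force vertex enumeration on random instances", {
  obj <- objective_spec()
  n_checked <- 0
  for (seed in 1:30) {
    cs <- random_cs(seed)
    set.seed(seed + 1000)
    cvec <- runif(6, 0, 10)
    oracle <- lp_vertex_oracle(cs, cvec)
    spec <- scenario_spec("red")
    sol <- solve_scenario(spec, cs, objective_spec(E = cvec))
    if (!oracle$feasible) {
      expect_true(sol$status != "optimal",
                  label = paste("instance", seed, "infeasibility agreement"))
    } else {
      expect_equal(sol$status, "optimal",
                   label = paste("instance", seed, "feasibility agreement"))
      expect_lt(abs(sum(cvec * sol$x) - oracle$value) /
                  max(abs(oracle$value), 1), 1e-8)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)   # the instance family is mostly feasible
})

test_that("every returned solution is feasible and beats random points", {
  cs <- constraint_set()
  for (mode in c("red", "elp", "eeb")) {
    sol <- solve_scenario(scenario_spec(mode), cs)
    expect_equal(sol$status, "optimal")
    expect_equal(nrow(violations(sol$x, cs)), 0)
    expect_equal(sum(sol$x), cs$total_area, tolerance = 1e-6)
  }
  # rejection-sample feasible points and confirm the optimum dominates
  sol <- solve_scenario(scenario_spec("red"), cs)
  E <- objective_spec()$E
  set.seed(5)
  pts <- matrix(NA_real_, 0, 6)
  lower <- cs$lower; lower[1] <- max(lower[1], cropland_floor(cs))
  while (nrow(pts) < 1000) {
    m <- 50000
    cand <- cbind(0,
                  runif(m, lower[2], cs$upper[2]),
                  runif(m, lower[3], cs$upper[3]),
                  runif(m, lower[4], cs$upper[4]),
                  runif(m, lower[5], cs$upper[5]),
                  runif(m, lower[6], cs$upper[6]))
    cand[, 1] <- cs$total_area - rowSums(cand[, 2:6])
    ok <- cand[, 1] >= lower[1] & cand[, 1] <= cs$upper[1] &
      0.06 * rowSums(cand[, 1:3]) + 5.52 * cand[, 5] <= cs$P &
      cand %*% c(cs$green_coef, 0, 0, 0) >= cs$total_area * 0.2
    pts <- rbind(pts, cand[ok, , drop = FALSE])
  }
  pts <- pts[1:1000, ]
  expect_true(all(pts %*% E <= sum(E * sol$x) + 1e-6 * sum(E * sol$x)))
})

test_that("2020 observed areas sit outside the 2035 feasible box", {
  cs <- constraint_set()
  x2020 <- c(725534, 113439, 2579527, 166058, 61138, 1389920)
  v <- violations(x2020, cs)
  expect_true("x5_lower" %in% v$constraint)    # construction below 62,739
  expect_true("x6_upper" %in% v$constraint)    # unused above 1,326,661
  # and an all-zero vector breaks the total-area equality
  v0 <- violations(rep(0, 6), cs)
  expect_true("total_area" %in% v0$constraint)
})

test_that("scalarization is weight-scale invariant and bound-monotone", {
  cs <- constraint_set()
  s1 <- solve_scenario(scenario_spec("eeb", weights = c(1, 1, 1)), cs)
  s2 <- solve_scenario(scenario_spec("eeb", weights = c(10, 10, 10)), cs)
  expect_equal(s1$x, s2$x, tolerance = 1e-9)
  # relaxing an upper bound never decreases a maximized objective
  sol <- solve_scenario(scenario_spec("red"), cs)
  cs_relaxed <- constraint_set(upper = cs$upper + c(2e5, 0, 0, 0, 0, 0))
  sol_r <- solve_scenario(scenario_spec("red"), cs_relaxed)
  expect_gte(sol_r$objectives["f1"] + 1e-6, sol$objectives["f1"])
  # lexicographic mode returns a feasible, f1-optimal-first solution
  lex <- solve_scenario(scenario_spec("eeb", method = "lexicographic"), cs)
  expect_equal(lex$status, "optimal")
  expect_equal(nrow(violations(lex$x, cs)), 0)
})

test_that("grey sensitivity reports infeasible corners instead of hiding them", {
  cs <- constraint_set()
  gs <- grey_sensitivity(scenario_spec("red"), cs, lambda_grid = c(0, 0.5, 1))
  expect_equal(nrow(gs$grid), 9)
  # the upper grey corner of the population row is infeasible with the
  # published box bounds (total-area coupling)
  hi <- gs$grid$status[gs$grid$lambda_a21 == 1 & gs$grid$lambda_a22 == 1]
  expect_equal(hi, "infeasible")
  lo <- gs$grid$status[gs$grid$lambda_a21 == 0 & gs$grid$lambda_a22 == 0]
  expect_equal(lo, "optimal")
  expect_true(!is.null(gs$ranges))
  expect_true(all(gs$ranges$min_hm2 <= gs$ranges$max_hm2))
  # singleton grid gives a single solution
  gs1 <- grey_sensitivity(scenario_spec("red"), cs, lambda_grid = 0.5)
  expect_length(gs1$solutions, 1)
})

test_that("objective metadata records the printed coefficients", {
  obj <- objective_spec()
  expect_equal(obj$E, c(4.5, 2.37, 1.02, 0.02, 443.72, 0))
  expect_equal(obj$V, c(0.64, 2.88, 1.93, 14.6, 0, 0.12))
  expect_equal(obj$C, c(4.64, 0.59, 0.50, 0.18, 4.64, 0))
  expect_equal(obj$deduction, 0.12)
  # BAU bypasses the LP entirely
  expect_error(build_lp(scenario_spec("bau"), constraint_set()), "Markov")
  g <- mk_grid(matrix(c(1L, 2L), 1, 2))
  tm <- transition_matrix(g, g)
  base <- class_areas(g)
  sol <- solve_scenario(scenario_spec("bau"), constraint_set(), tm = tm,
                        base = base)
  expect_equal(sol$status, "markov")
  expect_equal(unname(sol$x[1:2]), base$area_hm2[1:2])
})
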