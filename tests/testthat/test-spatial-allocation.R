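# shared small synthetic world for the allocation tests
alloc_world <- local({
  K <- diag(6)
  K[3, 1] <- 0.10; K[3, 3] <- 0.90
  K[6, 3] <- 0.08; K[6, 6] <- 0.92
  cfg <- synthetic_config(150, 150, transition_kernel = K, seed = 11)
  pair <- generate_lulc_pair(cfg)
  fs <- generate_factor_stack(cfg, pair)
  list(cfg = cfg, pair = pair, fs = fs)
})

flat_suit <- function(pair, classes = 1:6, value = 0.5) {
  m <- matrix(value, nrow(pair$end$values), ncol(pair$end$values))
  stats::setNames(rep(list(m), length(classes)), classes)
}

test_that("expansion sampling finds exactly the generator's conversions", {
  w <- alloc_world
  a <- w$pair$start$values; b <- w$pair$end$values
  smp <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 1,
                                   sampling_rate = 1, seed = 1)
  expect_equal(sum(smp$y), sum(b == 1 & a != 1))
  expect_equal(sum(smp$y == 0), sum(a == b))        # rate 1 keeps them all
  # identical grids give zero positives
  smp0 <- extract_expansion_samples(w$pair$start, w$pair$start, w$fs, 1,
                                    sampling_rate = 0.01, seed = 1)
  expect_equal(sum(smp0$y), 0)
  # class absent from both epochs errors
  expect_error(extract_expansion_samples(w$pair$start, w$pair$end, w$fs,
                                         9L, seed = 1), "absent")
})

test_that("suitability learning recovers planted signal and not noise", {
  w <- alloc_world
  smp <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 1,
                                   sampling_rate = 0.1, seed = 2)
  fit <- fit_leas(smp, w$fs, num_trees = 64, holdout = 0.25, seed = 3)
  expect_gt(fit$auc, 0.8)                     # logit slope 3 is learnable
  expect_true(all(fit$surface >= 0 & fit$surface <= 1))
  # pure-noise factors: held-out AUC is chance level
  cfg0 <- synthetic_config(150, 150,
                           transition_kernel = w$cfg$transition_kernel,
                           factor_specs = list(), n_factors = 6, seed = 11)
  fs0 <- generate_factor_stack(cfg0, w$pair)
  smp0 <- extract_expansion_samples(w$pair$start, w$pair$end, fs0, 1,
                                    sampling_rate = 0.1, seed = 2)
  fit0 <- fit_leas(smp0, fs0, num_trees = 64, holdout = 0.25, seed = 3)
  expect_lt(abs(fit0$auc - 0.5), 0.05)
  # constant factor produces a flat surface
  fs_const <- factor_stack(list(c1 = matrix(1, 150, 150)))
  smp_c <- extract_expansion_samples(w$pair$start, w$pair$end, fs_const, 1,
                                     sampling_rate = 0.1, seed = 2)
  fit_c <- fit_leas(smp_c, fs_const, num_trees = 16, seed = 3)
  expect_equal(max(fit_c$surface) - min(fit_c$surface), 0, tolerance = 1e-12)
  # single-class samples are rejected
  smp1 <- smp; smp1$y <- 1L
  expect_error(fit_leas(smp1, w$fs), "single class")
})

test_that("logistic learner is an accepted alternative", {
  w <- alloc_world
  smp <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 1,
                                   sampling_rate = 0.1, seed = 2)
  fit <- fit_leas(smp, w$fs, method = "logistic", holdout = 0.25, seed = 3)
  expect_gt(fit$auc, 0.8)
})

test_that("CA with demand equal to current areas returns the input", {
  w <- alloc_world
  at <- class_areas(w$pair$end)
  demand <- stats::setNames(at$area_hm2, at$class)
  out <- simulate_ca(w$pair$end, flat_suit(w$pair),
                     ca_params(demand, patch_seed_prob = 0, seed = 4))
  expect_identical(out$values, w$pair$end$values)
  expect_equal(attr(out, "iterations"), 0L)
})

test_that("CA meets shifted demand within tolerance and prefers suitable cells", {
  w <- alloc_world
  smp <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 1,
                                   sampling_rate = 0.1, seed = 2)
  fit <- fit_leas(smp, w$fs, num_trees = 64, seed = 3)
  at <- class_areas(w$pair$end)
  demand <- stats::setNames(at$area_hm2, at$class)
  shift <- 0.05 * demand["3"]
  demand["1"] <- demand["1"] + shift
  demand["3"] <- demand["3"] - shift
  suit <- flat_suit(w$pair)
  suit[["1"]] <- fit$surface
  prm <- ca_params(demand, tol = 0.005, seed = 5)
  out <- simulate_ca(w$pair$end, suit, prm)
  expect_true(attr(out, "converged"))
  ach <- attr(out, "achieved"); tgt <- attr(out, "target_cells")
  expect_true(all(abs(ach - tgt) <= 0.005 * prod(dim(out))))
  # total area conserved exactly
  expect_equal(sum(class_areas(out)$area_hm2),
               sum(at$area_hm2))
  # converted cells carry higher suitability than passed-over candidates
  conv <- out$values == 1 & w$pair$end$values == 3
  not_conv <- out$values == 3 & w$pair$end$values == 3
  expect_gt(mean(fit$surface[conv]), mean(fit$surface[not_conv]))
  # seed-determinism: same seed identical, different seed same areas
  out2 <- simulate_ca(w$pair$end, suit, prm)
  expect_identical(out$values, out2$values)
  prm9 <- ca_params(demand, tol = 0.005, seed = 99)
  out9 <- simulate_ca(w$pair$end, suit, prm9)
  expect_false(identical(out$values, out9$values))
  expect_true(all(abs(attr(out9, "achieved") - tgt) <=
                    0.005 * prod(dim(out))))
})

test_that("permission matrix is binding: forbidden transitions never occur", {
  w <- alloc_world
  at <- class_areas(w$pair$end)
  demand <- stats::setNames(at$area_hm2, at$class)
  shift <- 0.04 * demand["3"]
  demand["1"] <- demand["1"] + shift
  demand["3"] <- demand["3"] - shift
  perm <- diag(6); perm[3, 1] <- 1      # only grassland -> cultivated
  out <- simulate_ca(w$pair$end, flat_suit(w$pair),
                     ca_params(demand, permission = perm, seed = 6))
  chg <- which(out$values != w$pair$end$values)
  expect_true(length(chg) > 0)
  expect_true(all(w$pair$end$values[chg] == 3 & out$values[chg] == 1))
  # fully blocked demand errors, naming the class
  perm0 <- diag(6)
  expect_error(simulate_ca(w$pair$end, flat_suit(w$pair),
                           ca_params(demand, permission = perm0, seed = 6)),
               "class 1")
  # demand not summing to the grid area errors
  bad <- demand; bad["1"] <- bad["1"] * 2
  expect_error(simulate_ca(w$pair$end, flat_suit(w$pair),
                           ca_params(bad, seed = 6)), "sum")
})

test_that("allocation with learned suitability beats random placement on FOM", {
  w <- alloc_world
  smp <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 1,
                                   sampling_rate = 0.1, seed = 2)
  fit1 <- fit_leas(smp, w$fs, num_trees = 64, seed = 3)
  smp3 <- extract_expansion_samples(w$pair$start, w$pair$end, w$fs, 3,
                                    sampling_rate = 0.1, seed = 2)
  fit3 <- fit_leas(smp3, w$fs, num_trees = 64, seed = 3)
  at1 <- class_areas(w$pair$end)
  demand <- stats::setNames(at1$area_hm2, at1$class)
  suit <- flat_suit(w$pair)
  suit[["1"]] <- fit1$surface; suit[["3"]] <- fit3$surface
  foms <- vapply(1:5, function(s) {
    sim <- simulate_ca(w$pair$start, suit, ca_params(demand, seed = s))
    validate(sim, w$pair$end, w$pair$start)$fom
  }, numeric(1))
  rand_foms <- vapply(1:5, function(s) {
    sim <- simulate_ca(w$pair$start, flat_suit(w$pair),
                       ca_params(demand, seed = s))
    validate(sim, w$pair$end, w$pair$start)$fom
  }, numeric(1))
  expect_gt(mean(foms), mean(rand_foms))
  expect_gt(mean(foms), 0.15)
})

test_that("validation metrics match hand computation", {
  # printed toy confusion matrix: OA 0.70, kappa 0.40
  ag <- agreement_stats(matrix(c(40, 20, 10, 30), 2, 2))
  expect_equal(ag$overall_accuracy, 0.7)
  expect_equal(ag$kappa, 0.4)
  # perfect agreement scores 1/1/1
  w <- alloc_world
  vr <- validate(w$pair$end, w$pair$end, w$pair$start)
  expect_equal(vr$kappa, 1)
  expect_equal(vr$overall_accuracy, 1)
  expect_equal(vr$fom, 1)
  # simulating pure persistence when change was observed: FOM = 0
  vr0 <- validate(w$pair$start, w$pair$end, w$pair$start)
  expect_equal(vr0$fom, 0)
  expect_true(vr0$kappa <= vr0$overall_accuracy)
  expect_error(validate(w$pair$end, w$pair$end,
                        mk_grid(matrix(1L, 2, 2))), "geometry")
})
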