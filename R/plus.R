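## count of `size` x `size` neighbours (excluding the centre) that satisfy a
## mask, with truncated (non-wrapping) edges
neigh_count <- function(mask, size = 3) {
  stopifnot(size %% 2 == 1)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0, nr, nc)
  storage.mode(mask) <- "double"
  r <- (size - 1) / 2
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sr <- max(1, 1 + dr):min(nr, nr + dr)   # destination rows
    sc <- max(1, 1 + dc):min(nc, nc + dc)
    m[sr, sc] <- m[sr, sc] + mask[sr - dr, sc - dc]
  }
  m
}

#' Extract expansion samples for one class (LEAS)
#'
#' Positives are cells that newly became `class_c` between the two epochs;
#' negatives are unchanged cells, sampled at `sampling_rate`. Each sample
#' carries the raw factor vector at its cell.
#'
#' @param grid_a,grid_b aligned [lulc_grid()]s (earlier, later).
#' @param factors a [factor_stack()] on the same geometry.
#' @param class_c target class code.
#' @param sampling_rate fraction of unchanged cells kept as negatives.
#' @param seed RNG seed for the negative subsample.
#' @return data frame with columns `cell`, `y` (1 = expansion) and one
#'   column per factor layer; attribute `class_c`.
#' @export
extract_expansion_samples <- function(grid_a, grid_b, factors, class_c,
                                      sampling_rate = 1, seed = 1) {
  stopifnot(inherits(grid_a, "lulc_grid"), inherits(grid_b, "lulc_grid"),
            inherits(factors, "factor_stack"))
  if (!same_geometry(grid_a, grid_b) ||
      !identical(dim(grid_a$values), factors$dim))
    stop("grids and factor stack must share geometry")
  a <- grid_a$values; b <- grid_b$values
  if (!any(a == class_c, na.rm = TRUE) && !any(b == class_c, na.rm = TRUE))
    stop("class ", class_c, " absent from both epochs")
  pos <- which(b == class_c & a != class_c & !is.na(a) & !is.na(b))
  neg_all <- which(a == b & !is.na(a))
  neg <- with_seed(seed, {
    if (sampling_rate >= 1) neg_all
    else neg_all[sort(sample.int(length(neg_all),
                                 round(sampling_rate * length(neg_all))))]
  })
  cells <- c(pos, neg)
  fx <- vapply(factors$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1) fx <- matrix(fx, 1)
  out <- data.frame(cell = cells,
                    y = rep(c(1L, 0L), c(length(pos), length(neg))))
  out <- cbind(out, as.data.frame(fx))
  attr(out, "class_c") <- class_c
  out
}

#' Learn a transition-suitability surface from expansion samples (LEAS)
#'
#' Fits a probabilistic classifier (random forest by default, regularized
#' logistic as the light alternative) on expansion samples and scores every
#' cell, producing a per-class suitability surface in \[0, 1\]. Factors are
#' min-max normalized over their full layers; the constants are stored and
#' reused for scoring.
#'
#' @param samples output of [extract_expansion_samples()] (>= 30 positives,
#'   both classes present).
#' @param factors the [factor_stack()] the samples were drawn from.
#' @param method `"ranger"` (probability forest) or `"logistic"`.
#' @param num_trees forest size for `method = "ranger"`.
#' @param holdout fraction of samples held out for an AUC estimate
#'   (0 disables).
#' @param seed RNG seed (holdout split and forest).
#' @return list of class `leas_fit`: `surface` (matrix of suitability),
#'   `auc` (held-out AUC or `NA`), `method`, `class_c`, `normalization`.
#' @export
fit_leas <- function(samples, factors, method = c("ranger", "logistic"),
                     num_trees = 100, holdout = 0, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(factors, "factor_stack"))
  if (length(unique(samples$y)) < 2)
    stop("samples contain a single class; cannot fit")
  if (sum(samples$y == 1) < 30)
    stop("need at least 30 expansion (positive) samples")
  fnames <- names(factors$layers)
  rng <- lapply(factors$layers, range, na.rm = TRUE)
  norm1 <- function(v, r) if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else v * 0
  X <- as.data.frame(mapply(function(nm) norm1(samples[[nm]], rng[[nm]]),
                            fnames, SIMPLIFY = FALSE))
  names(X) <- fnames
  dat <- cbind(y = factor(samples$y, levels = c(0, 1)), X)
  with_seed(seed, {
    test_idx <- if (holdout > 0)
      sample.int(nrow(dat), round(holdout * nrow(dat))) else integer(0)
    train <- if (length(test_idx)) dat[-test_idx, ] else dat
    if (length(unique(train$y)) < 2)
      stop("holdout split removed one class; lower `holdout`")
    model <- if (method == "ranger") {
      ranger::ranger(y ~ ., data = train, probability = TRUE,
                     num.trees = num_trees, seed = seed,
                     num.threads = 1)
    } else {
      stats::glm(y ~ ., data = train, family = stats::binomial())
    }
    score <- function(newx) {
      if (method == "ranger")
        ranger::predictions(stats::predict(model, data = newx,
                                           num.threads = 1))[, "1"]
      else as.numeric(stats::predict(model, newdata = newx,
                                     type = "response"))
    }
    auc <- if (length(test_idx)) {
      auc_score(score(dat[test_idx, -1, drop = FALSE]),
                dat$y[test_idx] == "1")
    } else NA_real_
    full <- as.data.frame(lapply(fnames, function(nm)
      norm1(as.numeric(factors$layers[[nm]]), rng[[nm]])))
    names(full) <- fnames
    surf <- matrix(score(full), factors$dim[1], factors$dim[2])
    structure(list(surface = surf, auc = auc, method = method,
                   class_c = attr(samples, "class_c"),
                   normalization = rng, model = model),
              class = "leas_fit")
  })
}

#' Cellular-automaton allocation parameters
#'
#' @param demand named vector of target class areas (hm^2); must sum to the
#'   grid's total area.
#' @param neighborhood odd window size for the neighbourhood share
#'   (default 3).
#' @param neigh_weights per-class neighbourhood weights (default 1 for every
#'   class).
#' @param permission square 0/1 matrix, rows = from-class, cols = to-class;
#'   1 permits the conversion. Default permits everything.
#' @param patch_seed_prob per-candidate probability of being considered as a
#'   random patch seed away from existing patch edges.
#' @param delta decreasing-threshold decay in (0, 1): a class that cannot
#'   meet its demand in a round has its seeding threshold multiplied by
#'   `delta`.
#' @param max_iter iteration cap.
#' @param tol relative demand tolerance as a fraction of total area
#'   (default 0.001 = 0.1%).
#' @param seed RNG seed; runs are reproducible given the seed.
#' @return object of class `ca_params`.
#' @export
ca_params <- function(demand, neighborhood = 3, neigh_weights = NULL,
                      permission = NULL, patch_seed_prob = 0.02,
                      delta = 0.9, max_iter = 500, tol = 0.001, seed = 1) {
  stopifnot(delta > 0, delta < 1, tol > 0, neighborhood %% 2 == 1)
  structure(list(demand = demand, neighborhood = neighborhood,
                 neigh_weights = neigh_weights, permission = permission,
                 patch_seed_prob = patch_seed_prob, delta = delta,
                 max_iter = max_iter, tol = tol, seed = seed),
            class = "ca_params")
}

#' Patch-generating CA allocation of class demands
#'
#' Allocates per-class area demands onto the grid by iterated local
#' conversion: a cell's conversion score toward a growing class is its
#' learned suitability times the weighted neighbourhood share of that class;
#' cells away from existing patch edges can enter as random patch seeds once
#' their suitability clears a per-class threshold that decays (by `delta`)
#' whenever the class cannot meet demand, so new patches appear where
#' suitability is high. Only cells of permitted, currently-surplus donor
#' classes convert, so total area is conserved exactly and no forbidden
#' transition ever occurs. Iteration stops when every class is within
#' tolerance of its demand or `max_iter` is reached.
#'
#' @param grid_start an [lulc_grid()].
#' @param suitability named list of suitability matrices (one per growing
#'   class code), e.g. `fit_leas()$surface`.
#' @param params a [ca_params()].
#' @return an [lulc_grid()] with attributes `iterations`, `achieved`
#'   (final per-class cell counts), `converged`.
#' @export
simulate_ca <- function(grid_start, suitability, params) {
  stopifnot(inherits(grid_start, "lulc_grid"), inherits(params, "ca_params"))
  v <- grid_start$values
  if (any(is.na(v))) stop("CA allocation expects a gap-free grid")
  nr <- nrow(v); nc <- ncol(v); N <- nr * nc
  classes <- grid_start$classes
  k <- length(classes)
  demand <- params$demand[as.character(classes)]
  if (any(is.na(demand))) stop("demand must cover every class")
  if (abs(sum(demand) - N * grid_start$cell_area) >
      1e-6 * N * grid_start$cell_area)
    stop("demand must sum to the grid total area")
  target <- largest_remainder(demand, N)
  names(target) <- classes
  perm <- params$permission
  if (is.null(perm)) perm <- matrix(1, k, k)
  diag(perm) <- 1
  w <- params$neigh_weights
  if (is.null(w)) w <- rep(1, k)
  counts <- tabulate(v, nbins = max(classes))[classes]
  tol_cells <- max(1, round(params$tol * N))
  deficit <- target - counts
  ## demand feasibility under the permission matrix: a growing class needs
  ## at least one permitted donor class
  for (ci in which(deficit > tol_cells)) {
    donors <- setdiff(which(perm[, ci] == 1), ci)
    if (!length(donors))
      stop("demand for class ", classes[ci],
           " cannot be met: permission matrix blocks all conversions to it")
  }
  tau <- rep(0.9, k)
  nbsz <- params$neighborhood^2 - 1
  it <- 0L
  with_seed(params$seed, {
    repeat {
      deficit <- target - counts
      if (all(abs(deficit) <= tol_cells) || it >= params$max_iter) break
      it <- it + 1L
      converted_this_round <- 0L
      for (ci in order(deficit, decreasing = TRUE)) {
        if (deficit[ci] <= tol_cells || deficit[ci] <= 0) next
        cls <- classes[ci]
        surplus <- counts - target
        donor_cls <- classes[surplus > 0 & perm[, ci] == 1 &
                               classes != cls]
        if (!length(donor_cls)) next
        cand <- which(v %in% donor_cls)
        if (!length(cand)) next
        suit <- suitability[[as.character(cls)]]
        if (is.null(suit))
          stop("no suitability surface for growing class ", cls)
        nbfrac <- neigh_count(v == cls, params$neighborhood)[cand] / nbsz
        base_score <- suit[cand] * w[ci] * nbfrac
        ## random patch seeds: off-edge cells enter when suitability clears
        ## the decaying threshold
        u <- stats::runif(length(cand))
        seed_ok <- u < params$patch_seed_prob & suit[cand] >= tau[ci]
        eligible <- base_score > 0 | seed_ok
        if (!any(eligible)) { tau[ci] <- tau[ci] * params$delta; next }
        idx <- which(eligible)
        sc <- base_score[idx] + 1e-6 * suit[cand[idx]]
        ord <- idx[order(sc, decreasing = TRUE)]
        n_take <- min(deficit[ci], length(ord))
        ## respect per-donor surpluses so donors never undershoot
        take <- integer(0)
        rem <- stats::setNames(surplus[match(donor_cls, classes)], donor_cls)
        for (cell in cand[ord]) {
          s <- as.character(v[cell])
          if (rem[s] > 0) {
            take <- c(take, cell)
            rem[s] <- rem[s] - 1L
            if (length(take) >= n_take) break
          }
        }
        if (!length(take)) { tau[ci] <- tau[ci] * params$delta; next }
        v[take] <- cls
        counts <- tabulate(v, nbins = max(classes))[classes]
        converted_this_round <- converted_this_round + length(take)
        if (length(take) < deficit[ci]) tau[ci] <- tau[ci] * params$delta
      }
      if (converted_this_round == 0L) {
        tau <- tau * params$delta
        if (all(tau < 1e-9)) break
      }
    }
  })
  out <- lulc_grid(v, cell_area = grid_start$cell_area, classes = classes,
                   nodata = grid_start$nodata, xll = grid_start$xll,
                   yll = grid_start$yll, cellsize = grid_start$cellsize,
                   year = grid_start$year)
  deficit <- target - counts
  attr(out, "iterations") <- it
  attr(out, "achieved") <- stats::setNames(counts, classes)
  attr(out, "target_cells") <- target
  attr(out, "converged") <- all(abs(deficit) <= tol_cells)
  out
}

#' Agreement statistics from a confusion matrix
#'
#' @param confusion square matrix of counts, observed in rows, simulated in
#'   columns.
#' @return list with `overall_accuracy` and `kappa` (chance-corrected via
#'   the marginal-product expected agreement).
#' @export
agreement_stats <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  list(overall_accuracy = po, kappa = (po - pe) / (1 - pe))
}

#' Validate a simulated map against observation
#'
#' Overall accuracy and kappa from the cell-level confusion matrix, plus the
#' change-focused figure of merit (FOM): on cells where change was observed
#' or simulated relative to `base`, `FOM = B / (A + B + C + D)` with
#' A = observed change simulated as persistence, B = observed change
#' simulated correctly, C = observed change simulated as the wrong class,
#' D = observed persistence simulated as change.
#'
#' @param sim simulated [lulc_grid()].
#' @param obs observed [lulc_grid()].
#' @param base the start-epoch [lulc_grid()] (required for FOM).
#' @return list of class `validation_report`: `kappa`,
#'   `overall_accuracy`, `fom`, `confusion`, `fom_components`.
#' @export
validate <- function(sim, obs, base) {
  stopifnot(inherits(sim, "lulc_grid"), inherits(obs, "lulc_grid"),
            inherits(base, "lulc_grid"))
  if (!same_geometry(sim, obs) || !same_geometry(sim, base))
    stop("grids do not share geometry")
  cl <- obs$classes
  ok <- !is.na(sim$values) & !is.na(obs$values) & !is.na(base$values)
  s <- sim$values[ok]; o <- obs$values[ok]; b <- base$values[ok]
  confusion <- unclass(table(factor(o, levels = cl), factor(s, levels = cl)))
  names(dimnames(confusion)) <- c("observed", "simulated")
  ag <- agreement_stats(confusion)
  obs_chg <- o != b; sim_chg <- s != b
  A <- sum(obs_chg & !sim_chg)
  B <- sum(obs_chg & sim_chg & s == o)
  C <- sum(obs_chg & sim_chg & s != o)
  D <- sum(!obs_chg & sim_chg)
  fom <- if (A + B + C + D > 0) B / (A + B + C + D) else NA_real_
  structure(list(kappa = ag$kappa, overall_accuracy = ag$overall_accuracy,
                 fom = fom, confusion = confusion,
                 fom_components = c(A = A, B = B, C = C, D = D)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> kappa %.4f, overall accuracy %.2f%%, FOM %.2f%%\n",
    x$kappa, 100 * x$overall_accuracy, 100 * x$fom))
  invisible(x)
}
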