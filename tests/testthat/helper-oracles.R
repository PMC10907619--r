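# Independent oracles used across the suite. These re-derive expected
# results from first principles (enumeration, closed forms) without calling
# the code paths they check.

# Brute-force LP oracle: enumerate basic solutions (all choices of 6 tight
# constraints including the total-area equality), keep feasible ones, return
# the best objective. Rows are rebuilt here directly from the constraint-set
# fields, independently of build_lp().
lp_vertex_oracle <- function(cs, cvec, lambda = 0.5) {
  if (length(lambda) == 1) lambda <- c(lambda, lambda)
  a21 <- cs$a21[1] + lambda[1] * diff(cs$a21)
  a22 <- cs$a22[1] + lambda[2] * diff(cs$a22)
  lower <- cs$lower
  lower[1] <- max(lower[1], cs$P * cs$S * cs$f0 /
                    (cs$f_yield * cs$f_ratio * cs$f_multi))
  A <- rbind(rep(1, 6),                               # = total
             c(a21, a21, a21, 0, a22, 0),             # <= P
             c(cs$green_coef, 0, 0, 0),               # >= green RHS
             diag(6),                                 # <= upper
             diag(6))                                 # >= lower
  b <- c(cs$total_area, cs$P, cs$total_area * cs$green_floor_frac,
         cs$upper, lower)
  dir <- c("=", "<=", ">=", rep("<=", 6), rep(">=", 6))
  scale <- max(abs(b), 1)
  tol <- 1e-7 * scale
  le <- dir == "<="; ge <- dir == ">="
  best <- -Inf; bestx <- NULL; feasible <- FALSE
  combs <- utils::combn(2:nrow(A), 5)
  for (j in seq_len(ncol(combs))) {
    idx <- c(1L, combs[, j])
    x <- tryCatch(solve(A[idx, , drop = FALSE], b[idx]),
                  error = function(e) NULL)
    if (is.null(x)) next
    lhs <- as.numeric(A %*% x)
    if (any(lhs[le] > b[le] + tol) || any(lhs[ge] < b[ge] - tol)) next
    if (abs(lhs[1] - b[1]) > tol) next
    feasible <- TRUE
    v <- sum(cvec * x)
    if (v > best) { best <- v; bestx <- x }
  }
  list(feasible = feasible, value = best, x = bestx)
}

# Random constraint set with the published structure (equality + grey
# population row + green-cover floor + boxes) at a desk scale of ~100 area
# units.
random_cs <- function(seed) {
  set.seed(seed)
  total <- 100
  lower <- runif(6, 0, 6)
  upper <- lower + runif(6, 6, 28)
  # keep the equality attainable inside the boxes
  if (sum(lower) > total * 0.9) lower <- lower * total * 0.5 / sum(lower)
  if (sum(upper) < total * 1.1) upper <- upper * total * 1.3 / sum(upper)
  a21 <- sort(runif(2, 0.02, 0.1))
  a22 <- sort(runif(2, 2, 8))
  # population cap with random tightness (sometimes binding, sometimes not)
  P <- (a21[2] * sum(upper[1:3]) + a22[2] * upper[5]) * runif(1, 0.4, 1.1)
  floor1 <- runif(1, 0, lower[1] + 3)
  constraint_set(total_area = total, a21 = a21, a22 = a22, P = P,
                 S = 1, f0 = 1, f_yield = 1 / max(floor1 / P, 1e-9),
                 f_ratio = 1, f_multi = 1,
                 green_floor_frac = runif(1, 0.02, 0.15),
                 lower = lower, upper = pmin(upper, total))
}

# Exhaustive Jenks oracle: try every contiguous partition of the sorted
# values into k classes, minimize total within-class SSE. Only viable for
# small n.
exhaustive_jenks <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; bestbr <- NULL
  for (j in seq_len(ncol(cuts))) {
    ends <- c(cuts[, j], n)
    starts <- c(1, cuts[, j] + 1)
    tot <- sum(vapply(seq_len(k),
                      function(i) sse(x[starts[i]:ends[i]]), numeric(1)))
    if (tot < best - 1e-12) { best <- tot; bestbr <- x[ends] }
  }
  list(sse = best, breaks = bestbr)
}

# small helper: wrap a matrix as a grid
mk_grid <- function(m, cell_area = 1, year = NA, classes = NULL) {
  lulc_grid(m, cell_area = cell_area, year = year, classes = classes)
}

# a six-class kernel with a handful of realistic transitions
demo_kernel <- function() {
  K <- diag(6)
  K[3, 1] <- 0.06; K[3, 5] <- 0.01; K[3, 3] <- 0.93
  K[6, 3] <- 0.05; K[6, 1] <- 0.02; K[6, 6] <- 0.93
  K[2, 3] <- 0.03; K[2, 2] <- 0.97
  K[4, 6] <- 0.02; K[4, 4] <- 0.98
  K
}
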