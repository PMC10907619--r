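#' @keywords internal
"_PACKAGE"

## Six-class code convention used throughout: 1 cultivated, 2 forest,
## 3 grassland, 4 water, 5 construction, 6 unused.
LULC_CLASS_NAMES <- c("cultivated", "forest", "grassland", "water",
                      "construction", "unused")

#' Class names for integer land-use codes
#'
#' @param codes integer class codes (1-6 in the default convention).
#' @return character vector of class names; codes outside 1-6 are returned as
#'   `"class<code>"`.
#' @export
lulc_class_names <- function(codes = 1:6) {
  ifelse(codes >= 1 & codes <= 6, LULC_CLASS_NAMES[codes],
         paste0("class", codes))
}

## Evaluate an expression under a fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Apportion a continuous target into integer counts (largest remainder)
#'
#' Rounds a vector of non-negative quotas to integers that sum exactly to
#' `total`, assigning leftover units to the largest fractional remainders.
#' Used to convert hectare demands into whole cells.
#'
#' @param x non-negative numeric quotas.
#' @param total integer total the result must sum to; defaults to
#'   `round(sum(x))`.
#' @return integer vector, same length as `x`, summing to `total`.
#' @export
largest_remainder <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  if (sum(x) == 0) {
    out <- integer(length(x))
    out[seq_len(min(total, length(x)))] <- 1L  # degenerate: spread units
    return(out)
  }
  scaled <- x / sum(x) * total
  base <- floor(scaled)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(scaled - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param scores numeric predicted scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 marks positives.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("auc_score() needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

## rounding helper used only at the reporting layer
round2 <- function(x) round(x, 2)
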