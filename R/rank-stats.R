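#' Mann-Whitney U test for two independent samples
#'
#' Self-contained implementation of the two-sided Mann-Whitney U test.
#' The statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j`,
#' counting ties as one half.  For small samples
#' (`n_x + n_y <= exact_limit`) without ties the p-value is exact, by full
#' enumeration of all `choose(n_x + n_y, n_x)` group labelings of the
#' pooled values; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit maximum pooled size for exact enumeration
#'   (default 12).
#' @return a list of class `rank_test` with `statistic` (U of `x` over
#'   `y`), `p_value` (two-sided), `method` (`"exact"` or
#'   `"normal-approximation"`) and the sample sizes.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  b4_assert(length(x) > 0 && length(y) > 0, "size_error",
            "both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  gt <- outer(x, y, ">")
  eq <- outer(x, y, "==")
  u <- sum(gt) + 0.5 * sum(eq)
  mu <- nx * ny / 2
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  if (n <= exact_limit && !has_ties) {
    combs <- utils::combn(n, nx)
    u_all <- apply(combs, 2, function(ix) {
      sum(outer(pooled[ix], pooled[-ix], ">"))
    })
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal-approximation"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n_x = nx, n_y = ny), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks on ties), computed from
#' first principles.
#'
#' @param x,y paired numeric vectors of equal length, at least 3.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  b4_assert(length(x) == length(y), "size_error",
            "x and y must be paired (equal length)")
  b4_assert(length(x) >= 3, "size_error", "need at least 3 pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  b4_assert(denom > 0, "undefined_correlation",
            "correlation undefined for a constant input")
  sum(dx * dy) / denom
}

#' Summarize a vector of 5-point image-quality scores
#'
#' Scores follow the clinical rating scale: 5 artifact-free, 4 minimal
#' artifacts, 3 moderate (usable with caution), 2 strong, 1 unacceptable.
#'
#' @param scores integer vector with values in 1..5.
#' @return a list with `fraction_ge4` (artifact-free or minimal),
#'   `fraction_le2` (relevant information loss), `mean_score` and
#'   `incidence` (relative incidence per score, named "1".."5").
#' @export
score_summary <- function(scores) {
  b4_assert(length(scores) > 0, "size_error", "empty score vector")
  b4_assert(all(scores %in% 1:5), "validation_error",
            "scores must be integers in 1..5")
  counts <- tabulate(scores, nbins = 5)
  list(fraction_ge4 = mean(scores >= 4),
       fraction_le2 = mean(scores <= 2),
       mean_score = mean(scores),
       incidence = stats::setNames(counts / length(scores), as.character(1:5)))
}
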