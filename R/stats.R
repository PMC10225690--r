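#' Farthest-point (Gonzalez k-center) clustering
#'
#' Deterministic greedy k-center clustering: the first center is the data
#' point farthest from the data mean, each subsequent center is the point
#' farthest from all existing centers, and points are labelled by their
#' nearest center (Euclidean distance, ties toward the lowest index).  With
#' k = 2 this isolates a well-separated outlying group, which is how
#' seizures whose fast component does not slow down ictally are split off a
#' frequency-vs-frequency scatter.
#'
#' @param points numeric matrix (rows = points) or data.frame.
#' @param k number of clusters (default 2).
#' @return a `cluster_result`: list with `labels` (integers 1..k), `centers`
#'   (matrix of the chosen points), `center_index`, `max_radius`.
#' @export
farthest_point_cluster <- function(points, k = 2L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < k) stop("need at least k points")
  ctr <- colMeans(pts)
  d0 <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  centers_i <- which.max(d0)
  dist_to_centers <- matrix(NA_real_, n, k)
  dist_to_centers[, 1L] <- sqrt(rowSums(sweep(pts, 2L, pts[centers_i[1L], ])^2))
  while (length(centers_i) < k) {
    dmin <- apply(dist_to_centers[, seq_along(centers_i), drop = FALSE], 1L, min)
    nxt <- which.max(dmin)
    centers_i <- c(centers_i, nxt)
    dist_to_centers[, length(centers_i)] <-
      sqrt(rowSums(sweep(pts, 2L, pts[nxt, ])^2))
  }
  labels <- apply(dist_to_centers, 1L, which.min)
  max_radius <- max(dist_to_centers[cbind(seq_len(n), labels)])
  structure(list(labels = as.integer(labels),
                 centers = pts[centers_i, , drop = FALSE],
                 center_index = centers_i,
                 max_radius = max_radius),
            class = "cluster_result")
}

#' Linear regression through the origin with 95% CI
#'
#' Fits `y = slope * x` by least squares:
#' `slope = sum(x*y) / sum(x^2)`, with
#' `slope_sd = sqrt(sum((y - slope*x)^2) / ((n-1) * sum(x^2)))` and a 95%
#' confidence interval `slope +/- t(0.975, n-1) * slope_sd`.  Used to
#' quantify the proportional ictal reduction of IMF center frequencies
#' (a slope below 1 means frequencies drop during seizures).
#'
#' @param x,y numeric vectors of equal length (n >= 2); `x` not all zero.
#' @return a `regression_fit`: list with `slope`, `slope_sd`, `ci95`
#'   (length-2), `n`.
#' @export
origin_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sum(x^2) == 0) stop("x must not be all zero")
  fit <- stats::lm(y ~ x + 0)
  slope <- unname(stats::coef(fit)[1L])
  n <- length(x)
  sxx <- sum(x^2)
  slope_sd <- sqrt(sum(stats::resid(fit)^2) / ((n - 1) * sxx))
  tq <- stats::qt(0.975, df = n - 1)
  structure(list(slope = slope, slope_sd = slope_sd,
                 ci95 = c(slope - tq * slope_sd, slope + tq * slope_sd),
                 n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.4g +/- %.4g (n = %d)\n",
              x$slope, x$slope_sd, x$n))
  cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Two-tailed Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original rule); the exact null
#' distribution is used for n <= 25 remaining pairs and the normal
#' approximation with continuity correction beyond that.
#'
#' @param a,b numeric vectors of equal length; at least 5 non-zero
#'   differences are required.
#' @return the two-tailed p-value.
#' @export
paired_rank_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (length(d) < 5L) stop("need at least 5 non-zero differences")
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = length(d) <= 25L, correct = TRUE))
  unname(res$p.value)
}
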