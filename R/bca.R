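#' BCa confidence-interval endpoints from bootstrap and jackknife values
#'
#' Implements the bias-corrected and accelerated (BCa) endpoint formulas.
#' The bias term is \code{z0 = qnorm(p0)} with \code{p0} the fraction of
#' bootstrap replicates below the point estimate (ties counted half, so
#' discrete statistics are handled symmetrically); the acceleration is the
#' jackknife skewness
#' \code{a = sum(u^3) / (6 * sum(u^2)^1.5)}, \code{u = mean(jack) - jack}.
#' The adjusted percentile levels are
#' \code{pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))} and the
#' endpoints are read from the bootstrap distribution by inverse ECDF
#' (order statistic at \code{ceiling(B * p)}).
#'
#' Degenerate inputs (all bootstrap replicates equal) yield a zero-width
#' interval with a warning.
#'
#' @param thetaHat point estimate on the original data.
#' @param thetaBoot numeric vector of bootstrap replicate statistics.
#' @param thetaJack numeric vector of leave-one-unit-out statistics.
#' @param conf confidence level (default 0.95).
#' @return numeric vector \code{c(ci_low, ci_high)}.
#' @export
bcaInterval <- function(thetaHat, thetaBoot, thetaJack, conf = 0.95) {
  stopifnot(length(thetaBoot) >= 2L, conf > 0, conf < 1)
  B <- length(thetaBoot)
  if (stats::sd(thetaBoot) == 0) {
    warning("degenerate bootstrap distribution: zero-width interval")
    return(c(ci_low = thetaBoot[1], ci_high = thetaBoot[1]))
  }
  p0 <- (sum(thetaBoot < thetaHat) +
           0.5 * sum(thetaBoot == thetaHat)) / B
  p0 <- min(max(p0, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(p0)
  u <- mean(thetaJack) - thetaJack
  denom <- 6 * sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / denom else 0
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha)
  zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  srt <- sort(thetaBoot)
  pick <- function(p) srt[min(B, max(1L, ceiling(B * p)))]
  c(ci_low = pick(adj(zlo)), ci_high = pick(adj(zhi)))
}

#' BCa bootstrap confidence interval for a statistic of iid units
#'
#' Generic nonparametric bootstrap engine: resamples the units of \code{x}
#' with replacement \code{B} times, recomputes \code{statistic} per
#' replicate, estimates the acceleration by the leave-one-out jackknife
#' and returns \code{\link{bcaInterval}} endpoints.
#'
#' @param x numeric vector (or list) of exchangeable units.
#' @param statistic function of one argument returning a single number.
#' @param B number of bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{B}, \code{thetaBoot}, \code{thetaJack}.
#' @export
bcaCi <- function(x, statistic = mean, B = 1000L, conf = 0.95,
                  seed = 1L) {
  .assertCount(B, "B", min = 2L)
  n <- length(x)
  if (n < 2) stop("need at least 2 resampling units", call. = FALSE)
  thetaHat <- statistic(x)
  set.seed(seed)
  thetaBoot <- vapply(seq_len(B), function(b)
    statistic(x[sample.int(n, n, replace = TRUE)]), numeric(1))
  thetaJack <- vapply(seq_len(n), function(i) statistic(x[-i]),
                      numeric(1))
  ci <- bcaInterval(thetaHat, thetaBoot, thetaJack, conf = conf)
  list(estimate = thetaHat, ci_low = unname(ci[1]),
       ci_high = unname(ci[2]), B = B, thetaBoot = thetaBoot,
       thetaJack = thetaJack)
}
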