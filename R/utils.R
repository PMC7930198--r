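#' Geometric mean and geometric standard deviation of counts
#'
#' All geometric summaries in the package floor counts at 1 before taking
#' logs, so that zero counts neither produce \code{-Inf} nor perturb typical
#' (count >= 1) data. \code{geoSd} uses the sample standard deviation of the
#' log values; a constant vector therefore has \code{geoSd == 1}.
#'
#' @param x numeric vector of non-negative counts.
#' @return a single number; \code{geoSd} of a length-1 vector is \code{NA}.
#' @examples
#' geoMean(c(2, 4, 8))  # 4
#' geoSd(c(2, 4, 8))    # 2
#' geoMean(c(0, 0))     # floored to 1
#' @export
geoMean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(x >= 0))
  exp(mean(log(pmax(x, 1))))
}

#' @rdname geoMean
#' @export
geoSd <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(x >= 0))
  exp(stats::sd(log(pmax(x, 1))))
}

# Column-wise geometric mean of a counts matrix (rows = targets).
.colGeoMean <- function(m) exp(colMeans(log(pmax(m, 1))))

# Derive a stream-specific seed from a master seed, staying inside the
# 32-bit integer range R requires for set.seed().
.offsetSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483646) + 1L
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

.assertFraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}
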