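#' Critical value of the two-sided Grubbs outlier test
#'
#' @param n group size.
#' @param alpha two-sided significance level.
#' @return the critical value of the Grubbs statistic
#'   \code{max|x - mean| / sd}; \code{Inf} for \code{n < 3} (no test
#'   possible).
#' @export
grubbsCritical <- function(n, alpha = 0.01) {
  if (n < 3) return(Inf)
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

# Iterative two-sided Grubbs flags for one numeric vector; at most
# length(x) - 2 points are removed (the test needs n >= 3).
.grubbsFlags <- function(x, alpha = 0.01) {
  flagged <- rep(FALSE, length(x))
  repeat {
    keep <- which(!flagged)
    n <- length(keep)
    if (n < 3) break
    m <- mean(x[keep]); s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) break
    dev <- abs(x[keep] - m)
    i <- which.max(dev)
    if (dev[i] / s > grubbsCritical(n, alpha)) {
      flagged[keep[i]] <- TRUE
    } else break
  }
  flagged
}

#' Flag outlier probes per gene per ROI
#'
#' Within each gene's probe group in each ROI, probes whose
#' \code{log2(count + 1)} value is a statistical outlier are flagged by an
#' iterative two-sided Grubbs test at \code{alpha = 0.01} (the platform
#' convention for probe QC). Genes with fewer than three probes are never
#' flagged, and a gene can never lose all probes in an ROI (the test stops
#' once two probes remain). Negative-control probes are kept probe-level
#' throughout and are never flagged.
#'
#' @param x a \linkS4class{ProbeCountSet}.
#' @param alpha significance level of the Grubbs test.
#' @return logical matrix (probes x ROIs): \code{TRUE} = flagged outlier.
#' @export
flagOutlierProbes <- function(x, alpha = 0.01) {
  stopifnot(is(x, "ProbeCountSet"))
  cc <- assay(x, "counts")
  L <- log2(cc + 1)
  mask <- matrix(FALSE, nrow = nrow(cc), ncol = ncol(cc),
                 dimnames = dimnames(cc))
  tid <- rowData(x)$target_id
  endo <- !rowData(x)$is_negative
  for (g in unique(tid[endo])) {
    idx <- which(tid == g & endo)
    n <- length(idx)
    if (n < 3) next
    sub <- L[idx, , drop = FALSE]
    # vectorized screen: only columns whose max deviation exceeds the
    # full-group critical value need the iterative path
    m <- colMeans(sub)
    s <- sqrt(pmax(0, (colMeans(sub^2) - m^2) * n / (n - 1)))
    gmax <- apply(abs(sweep(sub, 2, m)), 2, max)
    need <- which(s > 0 & gmax / s > grubbsCritical(n, alpha))
    for (j in need) {
      mask[idx, j] <- .grubbsFlags(sub[, j], alpha)
    }
  }
  mask
}

#' Collapse probe counts to target counts
#'
#' The reported count for a gene in an ROI is the geometric mean of its
#' retained (non-flagged) probes' counts, computed in log space with counts
#' floored at 1. Negative probes are excluded: they stay probe-level and
#' feed the limit-of-quantitation computation (\code{\link{rnaLoq}}).
#'
#' @param x a \linkS4class{ProbeCountSet}.
#' @param mask optional logical outlier mask from
#'   \code{\link{flagOutlierProbes}}; \code{NULL} collapses all probes.
#' @return a \linkS4class{TargetCountSet} (\code{analyte = "rna"}) of
#'   endogenous genes, with the ROI annotations carried over.
#' @export
collapseToTargets <- function(x, mask = NULL) {
  stopifnot(is(x, "ProbeCountSet"))
  cc <- assay(x, "counts")
  endo <- !rowData(x)$is_negative
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow = nrow(cc), ncol = ncol(cc))
  }
  stopifnot(identical(dim(mask), dim(cc)))
  L <- log(pmax(cc[endo, , drop = FALSE], 1))
  keep <- !mask[endo, , drop = FALSE]
  if (any(colSums(keep) == 0)) {
    stop("outlier mask retains no probes for some gene/ROI",
         call. = FALSE)
  }
  gidx <- factor(rowData(x)$target_id[endo],
                 levels = unique(rowData(x)$target_id[endo]))
  num <- rowsum(L * keep, gidx)
  den <- rowsum(keep + 0, gidx)
  if (any(den == 0)) {
    stop("a gene lost all probes in some ROI", call. = FALSE)
  }
  collapsed <- exp(num / den)
  TargetCountSet(collapsed, targetClass = "endogenous",
                 roiData = colData(x), analyte = "rna")
}
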