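#' Combined z-score of a gene signature
#'
#' Each gene's expression is standardized across samples (z-score); a
#' sample's signature score is the sum of its gene z-scores divided by the
#' square root of the number of genes retained, \code{sum(z)/sqrt(k)}.
#' Zero-variance genes are dropped from k; if every signature gene has zero
#' variance the score is 0 for all samples. Scores therefore sum to zero
#' across the scoring cohort.
#'
#' @param expr numeric matrix, targets x samples (typically log2
#'   negative-normalized expression).
#' @param genes character vector of signature gene ids; at least one must
#'   be present in \code{expr}.
#' @return named numeric vector of per-sample scores.
#' @export
combinedZScore <- function(expr, genes) {
  expr <- as.matrix(expr)
  present <- intersect(genes, rownames(expr))
  if (!length(present)) {
    stop("no signature gene present in the expression matrix",
         call. = FALSE)
  }
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) {
    return(setNames(rep(0, ncol(expr)), colnames(expr)))
  }
  sub <- sub[keep, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / sds[keep]
  setNames(colSums(z) / sqrt(sum(keep)), colnames(expr))
}

#' Score several signatures, optionally cohort-standardized
#'
#' Applies \code{\link{combinedZScore}} to each gene set. Because the raw
#' combined z-score grows with the square root of the signature size, the
#' default \code{standardize = TRUE} rescales each signature's scores to
#' unit standard deviation across the scoring cohort, making fixed
#' classification thresholds portable across signatures of different
#' sizes. Scores keep mean zero either way.
#'
#' @param expr targets x samples matrix.
#' @param sets named list of gene-id vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param standardize rescale each signature to unit SD.
#' @return numeric matrix, samples x signatures.
#' @export
scoreSignatures <- function(expr, sets, standardize = TRUE) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  out <- vapply(sets, function(g) combinedZScore(expr, g),
                numeric(ncol(expr)))
  if (ncol(expr) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(colnames(expr),
                                                      names(sets)))
  if (standardize) {
    sds <- apply(out, 2, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    out <- sweep(out, 2, sds, `/`)
  }
  out
}

# Axis level from a score: "+" at or above `high` (boundary assigned
# upward), "low" in [low, high), "-" below `low`.
.axisLevel <- function(score, low, high) {
  ifelse(score >= high, "pos", ifelse(score >= low, "low", "neg"))
}

# The nine (AR level, NE level) combinations collapse onto the six printed
# classes: sub-threshold NE under positive AR reads as NE-, and
# sub-threshold AR under positive NE reads as AR-.
.classMap <- c("pos.neg" = "AR+/NE-", "low.neg" = "ARlow/NE-",
               "neg.neg" = "AR-/NE-", "neg.low" = "AR-/NElow",
               "pos.pos" = "AR+/NE+", "neg.pos" = "AR-/NE+",
               "pos.low" = "AR+/NE-", "low.low" = "ARlow/NE-",
               "low.pos" = "AR-/NE+")

#' Classify AR/NE phenotypes from signature scores
#'
#' Each axis is trichotomized by two thresholds (in cohort-standardized
#' z-units, see \code{\link{scoreSignatures}}): positive at or above
#' \code{high}, low in \code{[low, high)}, negative below \code{low}. The
#' nine combinations map onto the six phenotype classes (see
#' \code{\link{phenotypeClasses}}); sub-threshold activity on one axis
#' under a positive call on the other is folded into the negative class of
#' that axis. A missing score yields a missing (\code{NA}) call.
#'
#' @param arScore,neScore numeric vectors of AR and NE signature scores
#'   (equal length, optionally named by sample).
#' @param low,high axis thresholds (defaults -0.5 and +0.5).
#' @return \code{data.frame} with \code{ar_score}, \code{ne_score},
#'   \code{ar_level}, \code{ne_level} and the six-class \code{phenotype}
#'   (\code{NA} = missing).
#' @export
classifyPhenotype <- function(arScore, neScore, low = -0.5, high = 0.5) {
  stopifnot(length(arScore) == length(neScore), low <= high)
  ar <- .axisLevel(arScore, low, high)
  ne <- .axisLevel(neScore, low, high)
  cls <- unname(.classMap[paste(ar, ne, sep = ".")])
  cls[is.na(arScore) | is.na(neScore)] <- NA_character_
  data.frame(ar_score = arScore, ne_score = neScore,
             ar_level = ar, ne_level = ne, phenotype = cls,
             row.names = names(arScore), stringsAsFactors = FALSE)
}

#' Average per-ROI scores to tumor level
#'
#' Tumor-level phenotype calls average the tumor's ROI signature scores
#' first, then classify.
#'
#' @param scores samples x signatures matrix with ROI ids as rownames.
#' @param groups character vector of tumor (or patient) ids aligned with
#'   the rows of \code{scores}.
#' @return matrix of group-mean scores, one row per group.
#' @export
averageScoresBy <- function(scores, groups) {
  stopifnot(nrow(scores) == length(groups))
  rowsum(scores, groups) / as.vector(table(groups)[
    sort(unique(groups))])
}

#' Classical multidimensional scaling of expression profiles
#'
#' Samples are embedded by classical (Torgerson) MDS of their Euclidean
#' distances: double-center \code{-D^2/2}, eigendecompose, and scale the
#' top eigenvectors by the square root of their eigenvalues
#' (\code{stats::cmdscale}). For reproducibility each coordinate's sign is
#' fixed so that its largest-magnitude entry is positive. Exact low-rank
#' geometries (intrinsic dimension <= k) are reproduced exactly.
#'
#' @param x numeric matrix, samples x features (e.g. the transposed log2
#'   NN expression of the phenotype genes).
#' @param k number of dimensions (default 2).
#' @return list with \code{points} (samples x k coordinates) and
#'   \code{eig} (all eigenvalues, nonincreasing).
#' @export
classicalMds <- function(x, k = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("classical MDS needs at least 3 samples",
                  call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  # degenerate geometries (rank < k) are padded with zero coordinates
  # below, so cmdscale's eigenvalue-count warning is expected
  fit <- suppressWarnings(stats::cmdscale(stats::dist(x), k = k,
                                          eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate geometry: pad zero coordinates
    pts <- cbind(pts, matrix(0, nrow = n, ncol = k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(x)
  list(points = pts, eig = fit$eig)
}
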