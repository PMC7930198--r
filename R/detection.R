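#' RNA limit of quantitation from negative probes
#'
#' Per ROI, the LOQ is \code{exp(mean(ln x) + sdMultiplier * sd(ln x))}
#' over the raw negative-probe counts: the geometric mean of the negatives
#' times their geometric standard deviation raised to \code{sdMultiplier}.
#' ("Geometric mean plus two standard deviations" on the log scale and
#' "geomean x GSD^2" are the same number.)
#'
#' @param x a \linkS4class{ProbeCountSet} with at least 3 negative probes.
#' @param sdMultiplier number of log-scale standard deviations (default 2).
#' @return \code{data.frame} with one row per ROI: \code{roi_id},
#'   \code{neg_geomean}, \code{neg_gsd}, \code{loq}.
#' @export
rnaLoq <- function(x, sdMultiplier = 2) {
  stopifnot(is(x, "ProbeCountSet"))
  neg <- negativeCounts(x)
  if (nrow(neg) < 3) {
    stop("at least 3 negative probes are required for the RNA LOQ",
         call. = FALSE)
  }
  ln <- log(pmax(neg, 1))
  m <- colMeans(ln)
  s <- apply(ln, 2, stats::sd)
  data.frame(roi_id = colnames(neg),
             neg_geomean = exp(m),
             neg_gsd = exp(s),
             loq = exp(m + sdMultiplier * s),
             row.names = colnames(neg))
}

#' Protein limit of quantitation from IgG control antibodies
#'
#' Per ROI, the LOQ is \code{multiplier} (default 3) times the geometric
#' mean of the IgG negative-control antibody counts.
#'
#' @param x a \linkS4class{TargetCountSet} with \code{analyte = "protein"}
#'   and at least 2 rows of class \code{"igg"}.
#' @param multiplier LOQ multiple of the IgG geometric mean.
#' @return \code{data.frame} as in \code{\link{rnaLoq}} (\code{neg_gsd} is
#'   the IgG GSD, reported for diagnostics).
#' @export
proteinLoq <- function(x, multiplier = 3) {
  stopifnot(is(x, "TargetCountSet"))
  igg <- assay(x, "counts")[rowData(x)$target_class == "igg", ,
                            drop = FALSE]
  if (nrow(igg) < 2) {
    stop("at least 2 IgG control antibodies are required", call. = FALSE)
  }
  gm <- .colGeoMean(igg)
  data.frame(roi_id = colnames(igg),
             neg_geomean = gm,
             neg_gsd = apply(igg, 2, geoSd),
             loq = multiplier * gm,
             row.names = colnames(igg))
}

#' Detection matrix: targets above the limit of quantitation
#'
#' A target is detected in an ROI iff its count is strictly greater than
#' that ROI's LOQ ("above" read literally; a count exactly at the LOQ is
#' not detected).
#'
#' @param counts a \linkS4class{TargetCountSet} or numeric matrix
#'   (targets x ROIs).
#' @param loq an LOQ table from \code{\link{rnaLoq}} or
#'   \code{\link{proteinLoq}} covering every ROI.
#' @return logical matrix (targets x ROIs); per-ROI detected counts are its
#'   column sums.
#' @export
detectionMatrix <- function(counts, loq) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
       else as.matrix(counts)
  miss <- setdiff(colnames(m), loq$roi_id)
  if (length(miss)) {
    stop("no LOQ for ROI(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sweep(m, 2, loq[colnames(m), "loq"], `>`)
}

#' Apply ROI and gene quality-control filters
#'
#' ROIs are removed, in order of precedence, when flagged missing/fat,
#' purely stromal, sequencing-QC failures, or when their detected-gene
#' count is \code{<= minGenes} (the printed rule is "removed ROIs with
#' <= 100 genes detected"). Genes detected in no retained ROI are then
#' dropped. The attrition ledger reports one row per exclusion reason and
#' sums to input minus retained.
#'
#' @param detection logical detection matrix (genes x ROIs); flagged ROIs
#'   may be absent from it (their assays failed upstream).
#' @param ann validated ROI annotation table covering all arrayed ROIs.
#' @param minGenes detection threshold on the per-ROI detected-gene count.
#' @return list with \code{rois} (retained ROI ids), \code{genes}
#'   (retained gene ids) and \code{ledger} (\code{data.frame} of
#'   reason/n, beginning with \code{arrayed} and ending with
#'   \code{retained}).
#' @export
applyQcFilters <- function(detection, ann, minGenes = 100) {
  ann <- validateRoiAnnotation(ann)
  flags <- strsplit(ann$qc_flags, ";", fixed = TRUE)
  has <- function(fl) vapply(flags, function(f) any(f %in% fl),
                             logical(1))
  missingFat <- has(c("missing", "fat"))
  stromaOnly <- !missingFat & has("stroma_only")
  seqFail <- !missingFat & !stromaOnly & has("seq_fail")
  candidate <- ann$roi_id[!(missingFat | stromaOnly | seqFail)]
  noDet <- setdiff(candidate, colnames(detection))
  if (length(noDet)) {
    stop("unflagged ROI(s) absent from detection matrix: ",
         paste(noDet, collapse = ", "), call. = FALSE)
  }
  detected <- colSums(detection[, candidate, drop = FALSE])
  lowFlag <- has("low_genes")[match(candidate, ann$roi_id)]
  lowGenes <- detected <= minGenes | lowFlag
  rois <- candidate[!lowGenes]
  genes <- rownames(detection)[
    rowSums(detection[, rois, drop = FALSE]) > 0]
  ledger <- data.frame(
    reason = c("arrayed", "missing_fat", "stroma_only", "seq_fail",
               "low_genes", "retained"),
    n = c(nrow(ann), sum(missingFat), sum(stromaOnly), sum(seqFail),
          sum(lowGenes), length(rois)))
  list(rois = rois, genes = genes, ledger = ledger)
}

#' Negative normalization (log2 NN)
#'
#' Each count is divided by its ROI's negative-probe geometric mean and
#' reported on the log2 scale, so a gene at background has value 0 and
#' doubling a count adds exactly 1.
#'
#' @param counts a \linkS4class{TargetCountSet} or matrix.
#' @param loq LOQ table from \code{\link{rnaLoq}} (provides the per-ROI
#'   negative geometric mean).
#' @return numeric matrix of log2 negative-normalized expression.
#' @export
negativeNormalize <- function(counts, loq) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
       else as.matrix(counts)
  miss <- setdiff(colnames(m), loq$roi_id)
  if (length(miss)) {
    stop("no negative geomean for ROI(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  gm <- loq[colnames(m), "neg_geomean"]
  if (any(gm <= 0)) stop("negative geomean must be > 0", call. = FALSE)
  sweep(log2(pmax(m, 1)), 2, log2(gm), `-`)
}

#' Third-quartile (Q3) normalization
#'
#' Each ROI's counts are divided by that ROI's 75th percentile of detected
#' counts (linear-interpolation percentile, \code{quantile} type 7) and
#' rescaled by the geometric mean of all ROIs' 75th percentiles, so the
#' overall count scale is preserved.
#'
#' @param counts a \linkS4class{TargetCountSet} or matrix.
#' @param detection logical detection matrix aligned with \code{counts};
#'   every ROI needs at least 4 detected targets.
#' @return numeric matrix of Q3-normalized counts.
#' @export
q3Normalize <- function(counts, detection) {
  m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
       else as.matrix(counts)
  stopifnot(identical(dim(detection), dim(m)))
  nDet <- colSums(detection)
  if (any(nDet < 4)) {
    stop("fewer than 4 detected targets in ROI(s): ",
         paste(colnames(m)[nDet < 4], collapse = ", "), call. = FALSE)
  }
  q3 <- vapply(seq_len(ncol(m)), function(j)
    stats::quantile(m[detection[, j], j], 0.75, type = 7, names = FALSE),
    numeric(1))
  sweep(m, 2, exp(mean(log(q3))) / q3, `*`)
}

#' Protein signal-to-noise ratios and SNR detection
#'
#' Each antibody count is divided by the per-ROI geometric mean of the IgG
#' control antibodies; an antibody with SNR >= 3 is considered detected
#' (the boundary is inclusive: "below an SNR of 3" is not detected).
#'
#' @param x a \linkS4class{TargetCountSet} with \code{analyte="protein"}
#'   and IgG control rows.
#' @param cutoff SNR detection cutoff (default 3).
#' @return list with \code{snr} (numeric matrix) and \code{detected}
#'   (logical matrix over all rows, IgG rows included for completeness).
#' @export
proteinSnr <- function(x, cutoff = 3) {
  stopifnot(is(x, "TargetCountSet"))
  m <- assay(x, "counts")
  igg <- m[rowData(x)$target_class == "igg", , drop = FALSE]
  if (nrow(igg) < 2) {
    stop("IgG control antibodies are required for SNR", call. = FALSE)
  }
  gm <- .colGeoMean(igg)
  snr <- sweep(m, 2, gm, `/`)
  # inclusive boundary, guarded against floating-point noise in the
  # log-space geometric mean (an SNR of exactly 3 is detected)
  list(snr = snr, detected = snr >= cutoff * (1 - 1e-12))
}

#' Housekeeping normalization of protein counts
#'
#' Each ROI is divided by the geometric mean of its housekeeping
#' (positive-reference) protein counts and rescaled by the cohort
#' geometric mean of those factors, preserving within-ROI antibody ratios
#' exactly.
#'
#' @param x a \linkS4class{TargetCountSet} with \code{analyte="protein"}.
#' @param housekeepers character vector of housekeeping row names;
#'   defaults to rows with \code{target_class == "housekeeping"}.
#' @return numeric matrix of housekeeping-normalized counts.
#' @export
housekeepingNormalize <- function(x, housekeepers = NULL) {
  stopifnot(is(x, "TargetCountSet"))
  m <- assay(x, "counts")
  if (is.null(housekeepers)) {
    housekeepers <- rownames(x)[rowData(x)$target_class ==
                                  "housekeeping"]
  }
  miss <- setdiff(housekeepers, rownames(m))
  if (length(miss) || !length(housekeepers)) {
    stop("housekeeping protein(s) absent: ",
         paste(if (length(miss)) miss else "(none specified)",
               collapse = ", "), call. = FALSE)
  }
  hk <- m[housekeepers, , drop = FALSE]
  fac <- .colGeoMean(hk)
  sweep(m, 2, exp(mean(log(fac))) / fac, `*`)
}
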