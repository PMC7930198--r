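#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' Probe-level DSP counts
#'
#' \code{ProbeCountSet} holds the raw probe-by-ROI count matrix a DSP
#' platform emits, as a \linkS4class{SummarizedExperiment} with one
#' \code{counts} assay. \code{rowData} carries \code{target_id} (the gene a
#' probe reports on, or a per-probe negative-control identifier) and
#' \code{is_negative}; \code{colData} carries the ROI annotations
#' (patient/tumor hierarchy, tissue class, cell counts, QC flags).
#'
#' Validity: a single non-negative \code{counts} assay, unique probe ids,
#' exactly one target per probe.
#'
#' @aliases ProbeCountSet-class
#' @exportClass ProbeCountSet
setClass("ProbeCountSet", contains = "SummarizedExperiment")

setValidity("ProbeCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cc <- assay(object, "counts")
    if (any(cc < 0, na.rm = TRUE)) msg <- c(msg, "counts must be >= 0")
  }
  rd <- rowData(object)
  if (!all(c("target_id", "is_negative") %in% colnames(rd)))
    msg <- c(msg, "rowData must have 'target_id' and 'is_negative'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "ROI ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Target-level DSP counts (collapsed genes, or an antibody panel)
#'
#' \code{TargetCountSet} holds target-by-ROI counts: gene counts after
#' probe collapsing (\code{analyte = "rna"}), or antibody counts
#' (\code{analyte = "protein"}). \code{rowData$target_class} distinguishes
#' \code{"endogenous"} targets from protein \code{"igg"} controls and
#' \code{"housekeeping"} reference proteins.
#'
#' @aliases TargetCountSet-class
#' @exportClass TargetCountSet
setClass("TargetCountSet", contains = "SummarizedExperiment")

setValidity("TargetCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  if (!"target_class" %in% colnames(rd))
    msg <- c(msg, "rowData must have 'target_class'")
  else if (!all(rd$target_class %in%
                c("endogenous", "igg", "housekeeping")))
    msg <- c(msg, "target_class must be endogenous/igg/housekeeping")
  an <- metadata(object)$analyte
  if (is.null(an) || !an %in% c("rna", "protein"))
    msg <- c(msg, "metadata()$analyte must be 'rna' or 'protein'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "target ids (rownames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeCountSet
#'
#' @param counts numeric matrix, probes x ROIs, with probe ids as rownames
#'   and ROI ids as colnames.
#' @param targetId character vector, one target per probe.
#' @param isNegative logical vector flagging negative-control probes.
#' @param roiData optional \code{data.frame}/\code{DataFrame} of ROI
#'   annotations, one row per column of \code{counts} (matched by
#'   \code{roi_id} column or rownames).
#' @return a \linkS4class{ProbeCountSet}.
#' @export
ProbeCountSet <- function(counts, targetId, isNegative, roiData = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(targetId) == nrow(counts),
            length(isNegative) == nrow(counts))
  cd <- .makeRoiData(roiData, colnames(counts))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = DataFrame(target_id = as.character(targetId),
                        is_negative = as.logical(isNegative),
                        row.names = rownames(counts)),
    colData = cd)
  new("ProbeCountSet", se)
}

#' Construct a TargetCountSet
#'
#' @param counts numeric matrix, targets x ROIs.
#' @param targetClass character vector in
#'   \code{c("endogenous", "igg", "housekeeping")}, one per target.
#' @param roiData optional ROI annotation table (see
#'   \code{\link{ProbeCountSet}}).
#' @param analyte \code{"rna"} or \code{"protein"}.
#' @return a \linkS4class{TargetCountSet}.
#' @export
TargetCountSet <- function(counts, targetClass = "endogenous",
                           roiData = NULL,
                           analyte = c("rna", "protein")) {
  counts <- as.matrix(counts)
  analyte <- match.arg(analyte)
  targetClass <- rep_len(as.character(targetClass), nrow(counts))
  cd <- .makeRoiData(roiData, colnames(counts))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = DataFrame(target_class = targetClass,
                        row.names = rownames(counts)),
    colData = cd)
  metadata(se)$analyte <- analyte
  new("TargetCountSet", se)
}

.makeRoiData <- function(roiData, roiIds) {
  if (is.null(roiData)) {
    return(DataFrame(roi_id = roiIds, row.names = roiIds))
  }
  cd <- DataFrame(roiData)
  if ("roi_id" %in% colnames(cd)) {
    rownames(cd) <- cd$roi_id
  } else {
    cd$roi_id <- rownames(cd)
  }
  if (!is.null(roiIds)) {
    miss <- setdiff(roiIds, rownames(cd))
    if (length(miss)) {
      stop("ROIs without annotation: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cd <- cd[roiIds, , drop = FALSE]
  }
  cd
}

#' Accessors for DSP count containers
#'
#' \code{counts} returns the count assay; \code{negativeCounts} the
#' negative-probe submatrix of a \code{ProbeCountSet};
#' \code{probeTargets}/\code{isNegativeProbe} the probe-to-target map;
#' \code{targetClasses} and \code{analyte} describe a
#' \code{TargetCountSet}; \code{roiAnnotation} returns the ROI annotations
#' as a \code{data.frame}.
#'
#' @param x a \linkS4class{ProbeCountSet} or \linkS4class{TargetCountSet}.
#' @return see the individual descriptions.
#' @name dsp-accessors
#' @aliases negativeCounts probeTargets isNegativeProbe targetClasses
#'   analyte roiAnnotation
NULL

#' @rdname dsp-accessors
#' @export
setGeneric("negativeCounts", function(x) standardGeneric("negativeCounts"))

#' @rdname dsp-accessors
#' @export
setGeneric("probeTargets", function(x) standardGeneric("probeTargets"))

#' @rdname dsp-accessors
#' @export
setGeneric("isNegativeProbe", function(x)
  standardGeneric("isNegativeProbe"))

#' @rdname dsp-accessors
#' @export
setGeneric("targetClasses", function(x) standardGeneric("targetClasses"))

#' @rdname dsp-accessors
#' @export
setGeneric("analyte", function(x) standardGeneric("analyte"))

#' @rdname dsp-accessors
#' @export
setGeneric("roiAnnotation", function(x) standardGeneric("roiAnnotation"))

#' @rdname dsp-accessors
#' @export
setMethod("negativeCounts", "ProbeCountSet", function(x) {
  assay(x, "counts")[rowData(x)$is_negative, , drop = FALSE]
})

#' @rdname dsp-accessors
#' @export
setMethod("probeTargets", "ProbeCountSet", function(x)
  setNames(rowData(x)$target_id, rownames(x)))

#' @rdname dsp-accessors
#' @export
setMethod("isNegativeProbe", "ProbeCountSet", function(x)
  setNames(rowData(x)$is_negative, rownames(x)))

#' @rdname dsp-accessors
#' @export
setMethod("targetClasses", "TargetCountSet", function(x)
  setNames(rowData(x)$target_class, rownames(x)))

#' @rdname dsp-accessors
#' @export
setMethod("analyte", "TargetCountSet", function(x) metadata(x)$analyte)

#' @rdname dsp-accessors
#' @export
setMethod("roiAnnotation", "SummarizedExperiment", function(x)
  as.data.frame(colData(x)))

setMethod("show", "ProbeCountSet", function(object) {
  nneg <- sum(rowData(object)$is_negative)
  cat(sprintf(
    "ProbeCountSet: %d probes (%d negative) x %d ROIs, %d targets\n",
    nrow(object), nneg, ncol(object),
    length(unique(rowData(object)$target_id[!rowData(object)$is_negative]))))
  callNextMethod()
})

setMethod("show", "TargetCountSet", function(object) {
  tc <- table(rowData(object)$target_class)
  cat(sprintf("TargetCountSet (%s): %d targets x %d ROIs [%s]\n",
              metadata(object)$analyte, nrow(object), ncol(object),
              paste(names(tc), tc, sep = "=", collapse = ", ")))
  callNextMethod()
})
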