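#' Write / read DSP count matrices as TSV
#'
#' Count tables are tab-separated with a header row of ROI identifiers and
#' one row per probe or antibody. Probe-level tables carry
#' \code{probe_id}, \code{target_id}, \code{probe_class}
#' (endogenous/negative) as leading columns; target-level tables carry
#' \code{target_id} and \code{target_class}
#' (endogenous/igg/housekeeping).
#'
#' @param x a \linkS4class{ProbeCountSet} or \linkS4class{TargetCountSet}.
#' @param path file path.
#' @return \code{writeCountsTsv} returns \code{path} invisibly; the readers
#'   return the reconstructed object (with minimal ROI annotations; use
#'   \code{\link{readDspDataset}} to attach a full annotation table).
#' @export
writeCountsTsv <- function(x, path) {
  cc <- assay(x, "counts")
  if (is(x, "ProbeCountSet")) {
    df <- data.frame(
      probe_id = rownames(x),
      target_id = rowData(x)$target_id,
      probe_class = ifelse(rowData(x)$is_negative, "negative",
                           "endogenous"),
      cc, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      target_id = rownames(x),
      target_class = rowData(x)$target_class,
      cc, check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readProbeCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "target_id", "probe_class")
  if (!all(need %in% colnames(df))) {
    stop("probe count TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  roiCols <- setdiff(colnames(df), need)
  counts <- as.matrix(df[, roiCols, drop = FALSE])
  rownames(counts) <- df$probe_id
  ProbeCountSet(counts, targetId = df$target_id,
                isNegative = df$probe_class == "negative")
}

#' @rdname writeCountsTsv
#' @param analyte \code{"rna"} or \code{"protein"} for
#'   \code{readTargetCountsTsv}.
#' @export
readTargetCountsTsv <- function(path, analyte = c("rna", "protein")) {
  analyte <- match.arg(analyte)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("target_id", "target_class")
  if (!all(need %in% colnames(df))) {
    stop("target count TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  roiCols <- setdiff(colnames(df), need)
  counts <- as.matrix(df[, roiCols, drop = FALSE])
  rownames(counts) <- df$target_id
  TargetCountSet(counts, targetClass = df$target_class,
                 analyte = analyte)
}

.roiAnnotationCols <- c("roi_id", "patient_id", "tumor_id", "site",
                        "tissue_class", "cd3_count", "tumor_pct",
                        "stroma_pct", "qc_flags")
.knownQcFlags <- c("missing", "fat", "stroma_only", "seq_fail",
                   "low_genes")

#' Write / read ROI annotation tables as CSV
#'
#' Annotations record the patient/tumor/ROI hierarchy, anatomic site,
#' tissue class (T, TS, ST or S), CD3+ leukocyte count, tumor/stroma
#' percentages and semicolon-joined QC flags. \code{readRoiAnnotationCsv}
#' accepts a declared column mapping so that externally produced tables
#' with different headers can be loaded without editing the file.
#'
#' @param ann a \code{data.frame} of annotations.
#' @param path file path.
#' @param columns optional named character vector mapping canonical names
#'   (\code{roi_id}, \code{patient_id}, ...) to the file's column names.
#' @return the readers return a validated \code{data.frame} keyed by
#'   \code{roi_id}.
#' @export
writeRoiAnnotationCsv <- function(ann, path) {
  keep <- intersect(.roiAnnotationCols, colnames(ann))
  utils::write.csv(ann[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname writeRoiAnnotationCsv
#' @export
readRoiAnnotationCsv <- function(path, columns = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canonical in names(columns)) {
      src <- columns[[canonical]]
      if (!src %in% colnames(df)) {
        stop("declared column '", src, "' not found in ", path,
             call. = FALSE)
      }
      colnames(df)[colnames(df) == src] <- canonical
    }
  }
  validateRoiAnnotation(df)
}

#' Validate an ROI annotation table
#'
#' Checks the hierarchy columns, tissue classes, QC flag vocabulary, cell
#' counts and the constraint \code{tumor_pct + stroma_pct <= 100}.
#'
#' @param ann data.frame with at least \code{roi_id}, \code{patient_id},
#'   \code{tumor_id}.
#' @return the table, row-keyed by \code{roi_id}, with missing optional
#'   columns filled with defaults.
#' @export
validateRoiAnnotation <- function(ann) {
  need <- c("roi_id", "patient_id", "tumor_id")
  miss <- setdiff(need, colnames(ann))
  if (length(miss)) {
    stop("annotation table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$roi_id)) {
    stop("duplicate roi_id in annotation table", call. = FALSE)
  }
  if (!"tissue_class" %in% colnames(ann)) ann$tissue_class <- "T"
  bad <- !ann$tissue_class %in% c("T", "TS", "ST", "S")
  if (any(bad)) {
    stop("invalid tissue_class for ROI(s): ",
         paste(ann$roi_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!"qc_flags" %in% colnames(ann)) ann$qc_flags <- ""
  ann$qc_flags[is.na(ann$qc_flags)] <- ""
  flags <- strsplit(ann$qc_flags, ";", fixed = TRUE)
  unknown <- setdiff(unique(unlist(flags)), c(.knownQcFlags, ""))
  if (length(unknown)) {
    stop("unknown qc flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if ("cd3_count" %in% colnames(ann) &&
      any(ann$cd3_count < 0, na.rm = TRUE)) {
    stop("cd3_count must be non-negative", call. = FALSE)
  }
  if (all(c("tumor_pct", "stroma_pct") %in% colnames(ann))) {
    over <- (ann$tumor_pct + ann$stroma_pct) > 100 + 1e-8
    if (any(over, na.rm = TRUE)) {
      stop("tumor_pct + stroma_pct > 100 for ROI(s): ",
           paste(ann$roi_id[which(over)], collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(ann) <- ann$roi_id
  ann
}

#' Write / read gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then gene ids. An
#' empty file yields an empty list; a line with fewer than three fields is
#' a parse error reporting the line number.
#'
#' @param sets named list of character vectors (names become set names), or
#'   a list of \code{list(name=, description=, genes=)} entries.
#' @param path file path.
#' @return \code{readGmt} returns a named list of unique gene-id vectors,
#'   with per-set descriptions in \code{attr(,"description")}.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s)) {
      paste(c(s$name, s$description, s$genes), collapse = "\t")
    } else {
      paste(c(names(sets)[i], "", s), collapse = "\t")
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed gene-set line %d in %s (need >= 3 fields)",
                 bad[1], path), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  out <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(out) <- nm
  attr(out, "description") <- setNames(desc, nm)
  out
}

#' Load and cross-validate a DSP dataset from disk
#'
#' Reads a count matrix, its ROI annotations and optional gene sets, and
#' checks that every ROI in the count matrix has an annotation row
#' (unknown ROIs are rejected by name).
#'
#' @param countsPath TSV count matrix (probe- or target-level).
#' @param annotationPath CSV ROI annotation table.
#' @param geneSetPath optional GMT file.
#' @param level \code{"probe"} or \code{"target"}.
#' @param analyte \code{"rna"} or \code{"protein"}.
#' @param columns optional annotation column mapping (see
#'   \code{\link{readRoiAnnotationCsv}}).
#' @return list with elements \code{counts} (a
#'   \linkS4class{ProbeCountSet} or \linkS4class{TargetCountSet} carrying
#'   the annotations in \code{colData}), \code{annotations} and
#'   \code{signatures}.
#' @export
readDspDataset <- function(countsPath, annotationPath,
                           geneSetPath = NULL,
                           level = c("probe", "target"),
                           analyte = c("rna", "protein"),
                           columns = NULL) {
  level <- match.arg(level)
  analyte <- match.arg(analyte)
  x <- if (level == "probe") readProbeCountsTsv(countsPath)
       else readTargetCountsTsv(countsPath, analyte = analyte)
  ann <- readRoiAnnotationCsv(annotationPath, columns = columns)
  unknown <- setdiff(colnames(x), ann$roi_id)
  if (length(unknown)) {
    stop("count-matrix ROI(s) missing from annotations: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  colData(x) <- .makeRoiData(ann, colnames(x))
  sigs <- if (is.null(geneSetPath)) list() else readGmt(geneSetPath)
  list(counts = x, annotations = ann, signatures = sigs)
}

#' Immunohistochemistry H-score
#'
#' Staining is read at three intensity levels (0 none, 1 weak, 2 strong);
#' the H-score is the intensity-weighted sum of the percentage of cells at
#' each level, giving a 0-200 range.
#'
#' @param pct numeric vector of length 3 (percentages at intensities
#'   0, 1, 2) summing to 100; names are ignored, order is intensity
#'   0, 1, 2.
#' @return the H-score in [0, 200].
#' @examples
#' ihcHScore(c(0, 0, 100))   # 200
#' ihcHScore(c(0, 50, 50))   # 150
#' @export
ihcHScore <- function(pct) {
  stopifnot(is.numeric(pct), length(pct) == 3L)
  if (abs(sum(pct) - 100) > 1e-6) {
    stop("intensity percentages must sum to 100", call. = FALSE)
  }
  sum(c(0, 1, 2) * pct)
}

#' Average replicate H-scores
#'
#' Replicate cores are averaged; if one of the replicates is missing the
#' average of the remaining ones is used.
#'
#' @param scores numeric vector of replicate H-scores, possibly with
#'   \code{NA} for missing replicates.
#' @return the averaged score.
#' @export
ihcAverageScore <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stop("all replicate scores are missing", call. = FALSE)
  mean(scores[ok])
}
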