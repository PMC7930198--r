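#' Read a SAM-subset alignment file
#'
#' Parses the plain-text SAM subset used for junction quantification:
#' header lines (\code{@...}) are skipped and the mandatory QNAME, FLAG,
#' RNAME, POS and CIGAR fields are retained. Lines with fewer than six
#' fields are skipped and counted.
#'
#' @param path SAM text file.
#' @return \code{data.frame} with \code{qname}, \code{flag},
#'   \code{rname}, \code{pos}, \code{cigar}; skipped-line count in
#'   \code{attr(,"skipped")}.
#' @export
readSamSubset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 6L
  fields <- fields[ok]
  out <- data.frame(
    qname = vapply(fields, `[[`, character(1), 1L),
    flag = as.integer(vapply(fields, `[[`, character(1), 2L)),
    rname = vapply(fields, `[[`, character(1), 3L),
    pos = as.integer(vapply(fields, `[[`, character(1), 4L)),
    cigar = vapply(fields, `[[`, character(1), 6L),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Write alignment records as a SAM-subset file
#'
#' @param records \code{data.frame} with \code{qname}, \code{flag},
#'   \code{rname}, \code{pos}, \code{cigar}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSamSubset <- function(records, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              "@SQ\tSN:chrX\tLN:156040895",
              "@SQ\tSN:chr1\tLN:248956422")
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$rname,
                  records$pos, records$cigar)
  writeLines(c(header, body), path)
  invisible(path)
}

# Reference-skipping gaps of one CIGAR string relative to a leftmost
# position: data.frame(gapStart, gapEnd) of skipped reference intervals
# (N operations; D operations of length >= minDeletionGap count as gaps
# too). Returns NULL for a malformed CIGAR.
.cigarGaps <- function(cigar, pos, minDeletionGap = 20L) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)  # leftover garbage
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  ref <- pos
  gaps <- list()
  for (t in seq_along(op)) {
    consumes <- op[t] %in% c("M", "D", "N", "=", "X")
    isGap <- op[t] == "N" ||
      (op[t] == "D" && len[t] >= minDeletionGap)
    if (isGap) {
      gaps[[length(gaps) + 1L]] <- c(ref, ref + len[t] - 1L)
    }
    if (consumes) ref <- ref + len[t]
  }
  if (!length(gaps)) {
    return(data.frame(gapStart = integer(), gapEnd = integer()))
  }
  g <- do.call(rbind, gaps)
  data.frame(gapStart = g[, 1], gapEnd = g[, 2])
}

#' Count reads whose splice gap spans a junction interval
#'
#' A record counts iff it aligns to the junction's chromosome and has at
#' least one reference-skipping gap (CIGAR N, or a deletion of at least
#' \code{minDeletionGap} bases) whose donor (last aligned base before the
#' gap) and acceptor (first aligned base after it) both lie within the
#' 1-based inclusive interval. Records are deduplicated by read id so each
#' read counts at most once; records with a malformed CIGAR are skipped
#' and tallied.
#'
#' @param records alignment \code{data.frame} (see
#'   \code{\link{readSamSubset}}).
#' @param junction interval list (see \code{\link{arV7Junction}}).
#' @param minDeletionGap minimum deletion length treated as a splice gap.
#' @return integer count; skipped-record tally in \code{attr(,"skipped")}.
#' @export
countJunctionSpanningReads <- function(records,
                                       junction = arV7Junction(),
                                       minDeletionGap = 20L) {
  onChrom <- records$rname == junction$chrom
  # cheap pre-filter: a qualifying read needs a gap operator and must
  # start at or before the interval end
  cand <- which(onChrom & grepl("[ND]", records$cigar) &
                  records$pos <= junction$end)
  skipped <- 0L
  hits <- character()
  for (i in cand) {
    gaps <- .cigarGaps(records$cigar[i], records$pos[i], minDeletionGap)
    if (is.null(gaps)) { skipped <- skipped + 1L; next }
    if (!nrow(gaps)) next
    donor <- gaps$gapStart - 1L
    acceptor <- gaps$gapEnd + 1L
    if (any(donor >= junction$start & acceptor <= junction$end)) {
      hits <- c(hits, records$qname[i])
    }
  }
  out <- length(unique(hits))
  attr(out, "skipped") <- skipped
  out
}

#' Spliced reads per million (SRPM)
#'
#' @param junctionCount junction-spanning read count.
#' @param totalAlignedReads total aligned reads (> 0).
#' @return \code{junctionCount / (totalAlignedReads / 1e6)}.
#' @examples
#' srpmNormalize(10, 1e7)  # 1
#' @export
srpmNormalize <- function(junctionCount, totalAlignedReads) {
  stopifnot(is.numeric(junctionCount), junctionCount >= 0)
  if (!is.numeric(totalAlignedReads) || totalAlignedReads <= 0) {
    stop("totalAlignedReads must be > 0", call. = FALSE)
  }
  as.numeric(junctionCount) / (totalAlignedReads / 1e6)
}
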