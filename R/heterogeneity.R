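#' Enumerate ROI pairs by concordance stratum
#'
#' The three analysis strata partition all unordered ROI pairs:
#' \code{intratumor} (same tumor), \code{intrapatient} (same patient,
#' different tumors) and \code{interpatient} (different patients).
#' \code{withinpatient} is their union restricted to one patient (any pair
#' sharing a patient) and \code{all} is every pair.
#'
#' @param ann annotation \code{data.frame} with \code{roi_id},
#'   \code{patient_id}, \code{tumor_id}.
#' @param level one of \code{"intratumor"}, \code{"intrapatient"},
#'   \code{"interpatient"}, \code{"withinpatient"}, \code{"all"}.
#' @return \code{data.frame} with \code{roi1}, \code{roi2},
#'   \code{stratum}.
#' @export
pairStrata <- function(ann, level = c("intratumor", "intrapatient",
                                      "interpatient", "withinpatient",
                                      "all")) {
  level <- match.arg(level)
  n <- nrow(ann)
  if (n < 2) stop("need at least two ROIs", call. = FALSE)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  samePat <- ann$patient_id[i] == ann$patient_id[j]
  sameTum <- ann$tumor_id[i] == ann$tumor_id[j]
  stratum <- ifelse(sameTum, "intratumor",
                    ifelse(samePat, "intrapatient", "interpatient"))
  keep <- switch(level,
                 intratumor = stratum == "intratumor",
                 intrapatient = stratum == "intrapatient",
                 interpatient = stratum == "interpatient",
                 withinpatient = samePat,
                 all = rep(TRUE, length(i)))
  data.frame(roi1 = ann$roi_id[i[keep]], roi2 = ann$roi_id[j[keep]],
             stratum = stratum[keep], stringsAsFactors = FALSE)
}

# Agreement indicators for a pair list, dropping pairs with a missing call.
.pairAgreementIndicators <- function(calls, pairs) {
  a <- calls[pairs$roi1]; b <- calls[pairs$roi2]
  ok <- !is.na(a) & !is.na(b)
  (a == b)[ok]
}

#' Exact pair-agreement concordance
#'
#' Enumerates every pair in the stratum; ROIs with a missing phenotype
#' call are excluded. The estimate equals the hypergeometric identity
#' \code{sum(choose(n_g, 2)) / choose(n, 2)} over the class sizes when all
#' pairs of a sample set are used.
#'
#' @param calls named character vector of phenotype calls (names = ROI
#'   ids; \code{NA} = missing).
#' @param pairs pair list from \code{\link{pairStrata}}.
#' @return one-row \code{data.frame}: \code{estimate}, \code{n_pairs},
#'   \code{method}.
#' @export
pairAgreementExact <- function(calls, pairs) {
  agree <- .pairAgreementIndicators(calls, pairs)
  if (!length(agree)) {
    stop("no nonmissing pair in the stratum", call. = FALSE)
  }
  data.frame(estimate = mean(agree), n_pairs = length(agree),
             method = "exact", stringsAsFactors = FALSE)
}

#' Sampled pair-agreement concordance
#'
#' Pairs are drawn uniformly with replacement from the stratum's
#' (nonmissing) pair set; the estimate is the mean agreement indicator and
#' is unbiased for the exact enumeration.
#'
#' @inheritParams pairAgreementExact
#' @param nSamples number of sampled pairs.
#' @param seed integer seed.
#' @return one-row \code{data.frame}: \code{estimate}, \code{n_pairs}
#'   (draws), \code{method}, \code{seed}.
#' @export
pairAgreementSampled <- function(calls, pairs, nSamples = 10000L,
                                 seed = 1L) {
  .assertCount(nSamples, "nSamples")
  agree <- .pairAgreementIndicators(calls, pairs)
  if (!length(agree)) {
    stop("no nonmissing pair in the stratum", call. = FALSE)
  }
  set.seed(seed)
  est <- mean(agree[sample.int(length(agree), nSamples,
                               replace = TRUE)])
  data.frame(estimate = est, n_pairs = nSamples, method = "sampled",
             seed = seed, stringsAsFactors = FALSE)
}

# Pair agreement recomputed on a pseudo-cohort assembled from a vector of
# patient ids (with multiplicity, as drawn by the cluster bootstrap).
.agreementForPatients <- function(patIds, calls, ann, level) {
  pieces <- vector("list", length(patIds))
  for (k in seq_along(patIds)) {
    rows <- ann[ann$patient_id == patIds[k], , drop = FALSE]
    rows$patient_id <- paste0(rows$patient_id, "#", k)
    rows$tumor_id <- paste0(rows$tumor_id, "#", k)
    rows$.call <- calls[rows$roi_id]
    rows$roi_id <- paste0(rows$roi_id, "#", k)
    pieces[[k]] <- rows
  }
  pseudo <- do.call(rbind, pieces)
  pcalls <- setNames(pseudo$.call, pseudo$roi_id)
  pairs <- pairStrata(pseudo, level)
  agree <- .pairAgreementIndicators(pcalls, pairs)
  if (!length(agree)) return(NA_real_)
  mean(agree)
}

#' Phenotype concordance with BCa bootstrap confidence interval
#'
#' Computes the exact (or sampled) pair-agreement estimate for a stratum
#' and, when \code{B > 0}, a bias-corrected and accelerated (BCa) 95\%
#' confidence interval from \code{B} bootstrap replicates. Resampling is
#' clustered on patients (patients drawn with replacement, each carrying
#' all its tumors and ROIs), which preserves the hierarchy that generates
#' between-patient variance; the acceleration is estimated by a
#' leave-one-patient-out jackknife.
#'
#' @param calls named character vector of phenotype calls.
#' @param ann annotation table covering the called ROIs.
#' @param level concordance stratum (see \code{\link{pairStrata}}).
#' @param method \code{"exact"} or \code{"sampled"}.
#' @param nSamples draws for \code{method = "sampled"}.
#' @param B bootstrap replicates (0 = no interval).
#' @param conf confidence level.
#' @param seed integer seed for resampling (and sampling).
#' @return one-row \code{data.frame}: \code{level}, \code{estimate},
#'   \code{ci_low}, \code{ci_high}, \code{n_pairs}, \code{method},
#'   \code{B}, \code{seed}.
#' @export
phenotypeConcordance <- function(calls, ann, level = "intratumor",
                                 method = c("exact", "sampled"),
                                 nSamples = 10000L, B = 1000L,
                                 conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  ann <- ann[ann$roi_id %in% names(calls), , drop = FALSE]
  pairs <- pairStrata(ann, level)
  res <- if (method == "exact") pairAgreementExact(calls, pairs)
         else pairAgreementSampled(calls, pairs, nSamples, seed)
  ciLow <- ciHigh <- NA_real_
  if (B > 0) {
    patients <- unique(ann$patient_id)
    if (length(patients) < 2) {
      warning("single resampling unit: zero-width interval")
      ciLow <- ciHigh <- res$estimate
    } else {
      set.seed(.offsetSeed(seed, 7L))
      thetaBoot <- vapply(seq_len(B), function(b) {
        .agreementForPatients(
          sample(patients, length(patients), replace = TRUE),
          calls, ann, level)
      }, numeric(1))
      thetaJack <- vapply(seq_along(patients), function(i) {
        .agreementForPatients(patients[-i], calls, ann, level)
      }, numeric(1))
      ci <- bcaInterval(res$estimate, thetaBoot[!is.na(thetaBoot)],
                        thetaJack[!is.na(thetaJack)], conf = conf)
      ciLow <- ci[1]; ciHigh <- ci[2]
    }
  }
  data.frame(level = level, estimate = res$estimate, ci_low = ciLow,
             ci_high = ciHigh, n_pairs = res$n_pairs, method = method,
             B = as.integer(B), seed = seed, stringsAsFactors = FALSE)
}

#' Stratified expression-profile correlations
#'
#' Pearson correlation of the gene-expression vectors of every ROI pair,
#' labeled by concordance stratum. Zero-variance profiles are skipped and
#' the number of skipped pairs reported.
#'
#' @param expr targets x ROIs matrix (e.g. log2 NN expression).
#' @param ann annotation table covering the ROIs.
#' @return \code{data.frame} with \code{roi1}, \code{roi2},
#'   \code{stratum}, \code{r}; skipped-pair count in
#'   \code{attr(,"skipped")}.
#' @export
stratifiedProfileCorrelation <- function(expr, ann) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 genes", call. = FALSE)
  ann <- ann[ann$roi_id %in% colnames(expr), , drop = FALSE]
  pairs <- pairStrata(ann, "all")
  sds <- apply(expr, 2, stats::sd)
  ok <- sds > 0
  cmat <- stats::cor(expr[, ok, drop = FALSE])
  usable <- ok[pairs$roi1] & ok[pairs$roi2]
  out <- pairs[usable, , drop = FALSE]
  out$r <- cmat[cbind(out$roi1, out$roi2)]
  attr(out, "skipped") <- sum(!usable)
  out
}

#' Rank-based differential expression between two ROI groups
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value (exact for small,
#' tie-free groups as computed by \code{stats::wilcox.test}), log2 fold
#' change as the difference of group means of the (already log2)
#' expression, and Benjamini-Hochberg adjusted q-values across genes.
#'
#' @param expr targets x samples matrix on the log2 scale.
#' @param groupA,groupB column names or indices of the two groups (each of
#'   size >= 2).
#' @return \code{data.frame} with \code{gene}, \code{log2fc}, \code{p},
#'   \code{q}, ordered as the rows of \code{expr}.
#' @export
differentialExpression <- function(expr, groupA, groupB) {
  expr <- as.matrix(expr)
  a <- expr[, groupA, drop = FALSE]
  b <- expr[, groupB, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(expr)), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (all(c(x, y) == c(x, y)[1])) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  data.frame(gene = rownames(expr),
             log2fc = rowMeans(a) - rowMeans(b),
             p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}
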