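#' The six AR/NE phenotype classes
#'
#' Metastatic castration-resistant prostate cancers are partitioned into six
#' classes by androgen-receptor (AR) and neuroendocrine (NE) program
#' activity: AR+/NE-, ARlow/NE-, AR-/NE-, AR-/NElow, AR+/NE+ (amphicrine)
#' and AR-/NE+.
#'
#' @return character vector of the six class labels.
#' @export
phenotypeClasses <- function() {
  c("AR+/NE-", "ARlow/NE-", "AR-/NE-", "AR-/NElow", "AR+/NE+", "AR-/NE+")
}

# AR / NE program activity (0 = absent, 0.5 = low, 1 = positive) implied by
# each class label.
.classActivity <- function(cls) {
  ar <- c("AR+/NE-" = 1, "ARlow/NE-" = 0.5, "AR-/NE-" = 0,
          "AR-/NElow" = 0, "AR+/NE+" = 1, "AR-/NE+" = 0)
  ne <- c("AR+/NE-" = 0, "ARlow/NE-" = 0, "AR-/NE-" = 0,
          "AR-/NElow" = 0.5, "AR+/NE+" = 1, "AR-/NE+" = 1)
  data.frame(ar_level = unname(ar[cls]), ne_level = unname(ne[cls]))
}

#' Configure a synthetic DSP cohort
#'
#' Defaults emulate the profiled study design: 26 patients, two anatomically
#' distinct metastatic tumors per patient, three spatially distinct ROIs per
#' tumor. Phenotypes are planted per tumor, with a configurable fraction of
#' patients whose second tumor is discordant (default 0.27, i.e. 7/26
#' patients) and of tumors containing one discordant ROI (default 0.04,
#' i.e. roughly 2/53 tumors).
#'
#' @param nPatients,tumorsPerPatient,roisPerTumor positive integers.
#' @param phenotypeWeights named non-negative weights over
#'   \code{\link{phenotypeClasses}} used when phenotypes are drawn randomly;
#'   the default mix is dominated by AR+/NE- as in advanced prostate cancer
#'   cohorts.
#' @param phenotypeAssignment optional character vector of length
#'   \code{nPatients * tumorsPerPatient} fixing each tumor's class (row
#'   order: patient-major) and overriding the random draw.
#' @param discordantTumorFraction probability that a patient's last tumor is
#'   re-drawn from a different class.
#' @param discordantRoiFraction probability that a tumor contains one ROI
#'   re-drawn from a different class.
#' @param roiDepthSpread geometric SD (>= 1) of the per-ROI sampling-depth
#'   factor shared by all analytes of that ROI.
#' @param seed integer master seed; identical configurations and seeds give
#'   byte-identical truth tables.
#' @return a \code{CohortConfig} list.
#' @export
cohortConfig <- function(nPatients = 26L, tumorsPerPatient = 2L,
                         roisPerTumor = 3L,
                         phenotypeWeights = c("AR+/NE-" = 0.60,
                                              "ARlow/NE-" = 0.10,
                                              "AR-/NE-" = 0.08,
                                              "AR-/NElow" = 0.05,
                                              "AR+/NE+" = 0.07,
                                              "AR-/NE+" = 0.10),
                         phenotypeAssignment = NULL,
                         discordantTumorFraction = 0.27,
                         discordantRoiFraction = 0.04,
                         roiDepthSpread = 2.0,
                         seed = 1L) {
  .assertCount(nPatients, "nPatients")
  .assertCount(tumorsPerPatient, "tumorsPerPatient")
  .assertCount(roisPerTumor, "roisPerTumor")
  .assertFraction(discordantTumorFraction, "discordantTumorFraction")
  .assertFraction(discordantRoiFraction, "discordantRoiFraction")
  stopifnot(roiDepthSpread >= 1)
  if (!is.null(phenotypeAssignment)) {
    stopifnot(length(phenotypeAssignment) ==
                nPatients * tumorsPerPatient,
              all(phenotypeAssignment %in% phenotypeClasses()))
  }
  if (is.null(names(phenotypeWeights)) ||
      !all(names(phenotypeWeights) %in% phenotypeClasses()) ||
      any(phenotypeWeights < 0) || sum(phenotypeWeights) <= 0) {
    stop("phenotypeWeights must be non-negative weights named by ",
         "phenotypeClasses()", call. = FALSE)
  }
  structure(list(nPatients = as.integer(nPatients),
                 tumorsPerPatient = as.integer(tumorsPerPatient),
                 roisPerTumor = as.integer(roisPerTumor),
                 phenotypeWeights = phenotypeWeights,
                 phenotypeAssignment = phenotypeAssignment,
                 discordantTumorFraction = discordantTumorFraction,
                 discordantRoiFraction = discordantRoiFraction,
                 roiDepthSpread = roiDepthSpread,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate the ground-truth table for a synthetic cohort
#'
#' Builds the patient/tumor/ROI hierarchy, plants a phenotype class per
#' tumor (with the configured discordant-tumor and discordant-ROI
#' fractions), draws per-tumor activity levels for the proliferation (CCP),
#' FGFR/MEK and RB1-loss programs, a lognormal per-ROI depth factor, and
#' plausible ROI annotations (anatomic site, tissue class, CD3+ cell count,
#' tumor/stroma percentages).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return \code{data.frame} with one row per ROI: ids, planted phenotype,
#'   AR/NE/CCP/FGFR-MEK/RB1 activity levels, depth factor and annotation
#'   columns. The configuration is attached as \code{attr(,"config")}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  cls <- phenotypeClasses()
  w <- rep(0, length(cls)); names(w) <- cls
  w[names(config$phenotypeWeights)] <- config$phenotypeWeights

  nP <- config$nPatients; nT <- config$tumorsPerPatient
  nR <- config$roisPerTumor
  patients <- sprintf("P%02d", seq_len(nP))

  if (!is.null(config$phenotypeAssignment)) {
    tumorClass <- matrix(config$phenotypeAssignment, nrow = nP,
                         ncol = nT, byrow = TRUE)
  } else {
    base <- sample(cls, nP, replace = TRUE, prob = w)
    tumorClass <- matrix(base, nrow = nP, ncol = nT)
    if (nT > 1) {
      disc <- stats::runif(nP) < config$discordantTumorFraction
      for (i in which(disc)) {
        other <- setdiff(cls, base[i])
        wo <- w[other]
        if (sum(wo) <= 0) wo <- rep(1, length(other))
        tumorClass[i, nT] <- sample(other, 1L, prob = wo)
      }
    }
  }

  sites <- c("lymph node", "liver", "lung", "bone", "other")
  recs <- vector("list", nP * nT)
  k <- 0L
  for (i in seq_len(nP)) {
    for (j in seq_len(nT)) {
      k <- k + 1L
      tumorId <- sprintf("%s_T%d", patients[i], j)
      roiCls <- rep(tumorClass[i, j], nR)
      if (nR > 1 && stats::runif(1) < config$discordantRoiFraction) {
        other <- setdiff(cls, tumorClass[i, j])
        roiCls[sample.int(nR, 1L)] <- sample(other, 1L)
      }
      recs[[k]] <- data.frame(
        roi_id = sprintf("%s_R%d", tumorId, seq_len(nR)),
        patient_id = patients[i],
        tumor_id = tumorId,
        site = sample(sites, 1L, prob = c(0.3, 0.3, 0.1, 0.1, 0.2)),
        phenotype = roiCls,
        ccp_level = sample(c(0, 0.5, 1), 1L),
        fgfr_level = sample(c(0, 0.5, 1), 1L),
        rb1_level = sample(c(0, 0.5, 1), 1L),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, recs)
  act <- .classActivity(truth$phenotype)
  truth$ar_level <- act$ar_level
  truth$ne_level <- act$ne_level
  n <- nrow(truth)
  truth$depth_factor <- exp(stats::rnorm(n, 0,
                                         log(config$roiDepthSpread)))
  truth$tissue_class <- sample(c("T", "TS", "ST", "S"), n, replace = TRUE,
                               prob = c(0.55, 0.3, 0.14, 0.01))
  truth$cd3_count <- stats::rnbinom(n, size = 0.35, mu = 13.9)
  truth$tumor_pct <- ifelse(truth$tissue_class == "T", 100,
                     ifelse(truth$tissue_class == "TS",
                            sample(55:95, n, replace = TRUE),
                     ifelse(truth$tissue_class == "ST",
                            sample(5:45, n, replace = TRUE), 0)))
  truth$stroma_pct <- 100 - truth$tumor_pct
  truth$qc_flags <- ""
  rownames(truth) <- truth$roi_id
  attr(truth, "config") <- config
  truth
}

#' Configure the synthetic RNA probe panel
#'
#' Defaults emulate the profiled panel: 2093 endogenous genes, a median of
#' 10 probes per target and 220 negative-control probes. Probe counts per
#' gene are drawn deterministically from a discretized lognormal whose
#' median equals \code{probesPerGene}. The default signature map assigns
#' disjoint gene blocks to the AR, NE, CCP, FGFR_MEK and RB1loss programs.
#'
#' @param nGenes,nNegativeProbes panel geometry (negatives >= 3).
#' @param probesPerGene target median probes per gene.
#' @param signatureMap named list of gene-id vectors; \code{NULL} for the
#'   default block assignment over ids \code{G0001...}.
#' @param effectSize log2-scale mean shift applied to a signature's genes at
#'   full activity (activity 0.5 receives half the shift).
#' @param probeDispersion geometric SD (>= 1) of multiplicative lognormal
#'   probe noise.
#' @param outlierProbeRate,outlierMagnitude probability that a (probe, ROI)
#'   cell is corrupted, and its multiplicative magnitude.
#' @param backgroundGeomean geometric-mean count of negative probes at unit
#'   depth.
#' @param geneBaselineGeomean,geneBaselineGsd lognormal distribution of
#'   per-gene baseline counts across the panel (wide by default so that only
#'   a minority of genes rises above the limit of quantitation, as observed
#'   on tumor ROIs).
#' @return a \code{PanelConfig} list.
#' @export
rnaPanelConfig <- function(nGenes = 2093L, probesPerGene = 10L,
                           nNegativeProbes = 220L, signatureMap = NULL,
                           effectSize = 2, probeDispersion = 1.6,
                           outlierProbeRate = 0.01, outlierMagnitude = 20,
                           backgroundGeomean = 20,
                           geneBaselineGeomean = 25,
                           geneBaselineGsd = 4) {
  .assertCount(nGenes, "nGenes")
  .assertCount(probesPerGene, "probesPerGene")
  .assertCount(nNegativeProbes, "nNegativeProbes", min = 3L)
  stopifnot(probeDispersion >= 1, geneBaselineGsd >= 1,
            effectSize >= 0, outlierMagnitude > 0)
  .assertFraction(outlierProbeRate, "outlierProbeRate")
  genes <- sprintf("G%04d", seq_len(nGenes))
  if (is.null(signatureMap)) {
    k <- max(1L, min(30L, nGenes %/% 5L))
    sigs <- c("AR", "NE", "CCP", "FGFR_MEK", "RB1loss")
    signatureMap <- lapply(seq_along(sigs), function(i)
      genes[seq.int((i - 1L) * k + 1L, i * k)])
    names(signatureMap) <- sigs
  }
  stopifnot(all(unlist(signatureMap) %in% genes))
  structure(list(nGenes = as.integer(nGenes),
                 probesPerGene = as.integer(probesPerGene),
                 nNegativeProbes = as.integer(nNegativeProbes),
                 genes = genes, signatureMap = signatureMap,
                 effectSize = effectSize,
                 probeDispersion = probeDispersion,
                 outlierProbeRate = outlierProbeRate,
                 outlierMagnitude = outlierMagnitude,
                 backgroundGeomean = backgroundGeomean,
                 geneBaselineGeomean = geneBaselineGeomean,
                 geneBaselineGsd = geneBaselineGsd),
            class = "PanelConfig")
}

# Deterministic probe counts per gene: lognormal quantiles discretized so
# the median equals the configured target.
.probeSizes <- function(panel) {
  n <- panel$nGenes
  pmax(1L, as.integer(round(stats::qlnorm(
    stats::ppoints(n), log(panel$probesPerGene), 0.25))))
}

# Gene x ROI activity matrix (0/0.5/1 scale) from the truth table.
.activityMatrix <- function(truth, panel) {
  act <- matrix(0, nrow = panel$nGenes, ncol = nrow(truth),
                dimnames = list(panel$genes, truth$roi_id))
  lv <- list(AR = truth$ar_level, NE = truth$ne_level,
             CCP = truth$ccp_level, FGFR_MEK = truth$fgfr_level,
             RB1loss = truth$rb1_level)
  for (sig in names(panel$signatureMap)) {
    if (!sig %in% names(lv)) next
    act[panel$signatureMap[[sig]], ] <-
      matrix(lv[[sig]], nrow = length(panel$signatureMap[[sig]]),
             ncol = nrow(truth), byrow = TRUE)
  }
  act
}

#' Generate synthetic probe-level RNA counts
#'
#' Counts follow a multiplicative lognormal model:
#' \code{count = round(depth * geneBaseline * 2^(effectSize * activity) *
#' eps)} with \code{eps} lognormal with geometric SD
#' \code{probeDispersion}. Negative probes share a phenotype-independent
#' background level (times ROI depth). A fraction of (probe, ROI) cells is
#' multiplied by \code{outlierMagnitude} to exercise outlier-probe removal.
#'
#' @param truth a truth table from \code{\link{generateCohort}}.
#' @param panel an \code{\link{rnaPanelConfig}}.
#' @param seed integer; defaults to an offset of the cohort seed.
#' @return a \linkS4class{ProbeCountSet} whose \code{colData} holds the ROI
#'   annotations (the planted phenotype is carried in the truth table, not
#'   in the object).
#' @export
generateRnaProbeCounts <- function(truth, panel, seed = NULL) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1L,
            inherits(panel, "PanelConfig"))
  if (is.null(seed)) {
    cfg <- attr(truth, "config")
    seed <- .offsetSeed(if (is.null(cfg)) 0L else cfg$seed, 1L)
  }
  set.seed(seed)
  nRoi <- nrow(truth)
  sizes <- .probeSizes(panel)
  geneIdx <- rep.int(seq_len(panel$nGenes), sizes)
  probeIds <- c(
    paste0(panel$genes[geneIdx], "_p",
           unlist(lapply(sizes, seq_len), use.names = FALSE)),
    sprintf("NEG%03d", seq_len(panel$nNegativeProbes)))
  targetIds <- c(panel$genes[geneIdx],
                 sprintf("NEG%03d", seq_len(panel$nNegativeProbes)))
  isNeg <- c(rep(FALSE, length(geneIdx)),
             rep(TRUE, panel$nNegativeProbes))

  base <- exp(stats::rnorm(panel$nGenes, log(panel$geneBaselineGeomean),
                           log(panel$geneBaselineGsd)))
  act <- .activityMatrix(truth, panel)
  geneMean <- sweep(base * 2 ^ (panel$effectSize * act), 2,
                    truth$depth_factor, `*`)
  mu <- rbind(geneMean[geneIdx, , drop = FALSE],
              matrix(rep(panel$backgroundGeomean * truth$depth_factor,
                         each = panel$nNegativeProbes),
                     nrow = panel$nNegativeProbes))
  nCell <- length(probeIds) * nRoi
  eps <- matrix(exp(stats::rnorm(nCell, 0, log(panel$probeDispersion))),
                nrow = length(probeIds))
  out <- matrix(1, nrow = length(probeIds), ncol = nRoi)
  if (panel$outlierProbeRate > 0) {
    hit <- stats::runif(nCell) < panel$outlierProbeRate
    out[hit] <- panel$outlierMagnitude
  }
  counts <- round(mu * eps * out)
  dimnames(counts) <- list(probeIds, truth$roi_id)
  annCols <- c("roi_id", "patient_id", "tumor_id", "site", "tissue_class",
               "cd3_count", "tumor_pct", "stroma_pct", "qc_flags")
  ProbeCountSet(counts, targetId = targetIds, isNegative = isNeg,
                roiData = truth[, intersect(annCols, colnames(truth))])
}

#' Configure the synthetic protein (antibody) panel
#'
#' Defaults emulate the profiled panel: 57 target antibodies (the first two,
#' AR and SYP, track the planted AR and NE program activity), three IgG
#' negative-control antibodies that are phenotype-independent, and three
#' housekeeping reference proteins (RPS6, Histone H3, GAPDH) that carry ROI
#' depth signal only. Each non-phenotype antibody is planted with a
#' baseline signal-to-noise ratio drawn from a wide lognormal so that only
#' a minority of the panel is detected per ROI.
#'
#' @param nAntibodies,nIgg,nHousekeeping panel geometry
#'   (\code{nIgg >= 2}).
#' @param effectSize log2 shift of the AR/SYP antibodies at full activity.
#' @param dispersion geometric SD (>= 1) of multiplicative count noise.
#' @param iggGeomean geometric-mean IgG count at unit depth.
#' @param baselineSnrGeomean,baselineSnrGsd lognormal distribution of the
#'   planted per-antibody SNR.
#' @param housekeepingGeomean housekeeping count at unit depth.
#' @return a \code{ProteinPanelConfig} list.
#' @export
proteinPanelConfig <- function(nAntibodies = 57L, nIgg = 3L,
                               nHousekeeping = 3L, effectSize = 2,
                               dispersion = 1.5, iggGeomean = 30,
                               baselineSnrGeomean = 1.5,
                               baselineSnrGsd = 3.5,
                               housekeepingGeomean = 800) {
  .assertCount(nAntibodies, "nAntibodies")
  .assertCount(nIgg, "nIgg", min = 2L)
  .assertCount(nHousekeeping, "nHousekeeping")
  stopifnot(dispersion >= 1, baselineSnrGsd >= 1)
  structure(list(nAntibodies = as.integer(nAntibodies),
                 nIgg = as.integer(nIgg),
                 nHousekeeping = as.integer(nHousekeeping),
                 effectSize = effectSize, dispersion = dispersion,
                 iggGeomean = iggGeomean,
                 baselineSnrGeomean = baselineSnrGeomean,
                 baselineSnrGsd = baselineSnrGsd,
                 housekeepingGeomean = housekeepingGeomean),
            class = "ProteinPanelConfig")
}

#' Generate synthetic antibody counts
#'
#' @param truth a truth table from \code{\link{generateCohort}}.
#' @param panel a \code{\link{proteinPanelConfig}}.
#' @param seed integer; defaults to an offset of the cohort seed.
#' @return a \linkS4class{TargetCountSet} (\code{analyte = "protein"}). The
#'   planted per-antibody SNR is stored in \code{rowData()$planted_snr}
#'   (ground truth for recovery tests; \code{NA} for IgG rows).
#' @export
generateProteinCounts <- function(truth, panel, seed = NULL) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1L,
            inherits(panel, "ProteinPanelConfig"))
  if (is.null(seed)) {
    cfg <- attr(truth, "config")
    seed <- .offsetSeed(if (is.null(cfg)) 0L else cfg$seed, 2L)
  }
  set.seed(seed)
  nRoi <- nrow(truth)
  abNames <- c("AR", "SYP",
               sprintf("AB%02d", seq_len(max(0L, panel$nAntibodies - 2L))))
  abNames <- abNames[seq_len(panel$nAntibodies)]
  hkNames <- c("RPS6", "HistoneH3", "GAPDH",
               sprintf("HK%02d", seq_len(panel$nHousekeeping)))
  hkNames <- hkNames[seq_len(panel$nHousekeeping)]
  iggNames <- sprintf("IgG%d", seq_len(panel$nIgg))

  snr <- exp(stats::rnorm(panel$nAntibodies,
                          log(panel$baselineSnrGeomean),
                          log(panel$baselineSnrGsd)))
  # AR/SYP antibodies are phenotype readouts: background SNR when the
  # program is absent, shifted up by effectSize at full activity.
  snr[1] <- 1
  if (panel$nAntibodies >= 2L) snr[2] <- 1
  act <- matrix(0, nrow = panel$nAntibodies, ncol = nRoi)
  act[1, ] <- truth$ar_level
  if (panel$nAntibodies >= 2L) act[2, ] <- truth$ne_level

  depth <- truth$depth_factor
  muAb <- panel$iggGeomean * snr * 2 ^ (panel$effectSize * act)
  muAb <- sweep(muAb, 2, depth, `*`)
  muIgg <- matrix(rep(panel$iggGeomean * depth, each = panel$nIgg),
                  nrow = panel$nIgg)
  muHk <- matrix(rep(panel$housekeepingGeomean * depth,
                     each = panel$nHousekeeping),
                 nrow = panel$nHousekeeping)
  mu <- rbind(muAb, muIgg, muHk)
  eps <- matrix(exp(stats::rnorm(length(mu), 0, log(panel$dispersion))),
                nrow = nrow(mu))
  counts <- round(mu * eps)
  rownames(counts) <- c(abNames, iggNames, hkNames)
  colnames(counts) <- truth$roi_id
  annCols <- c("roi_id", "patient_id", "tumor_id", "site", "tissue_class",
               "cd3_count", "tumor_pct", "stroma_pct", "qc_flags")
  x <- TargetCountSet(
    counts,
    targetClass = c(rep("endogenous", panel$nAntibodies),
                    rep("igg", panel$nIgg),
                    rep("housekeeping", panel$nHousekeeping)),
    roiData = truth[, intersect(annCols, colnames(truth))],
    analyte = "protein")
  rowData(x)$planted_snr <- c(snr, rep(NA_real_, panel$nIgg),
                              rep(NA_real_, panel$nHousekeeping))
  x
}

#' The AR-V7 exon3 to cryptic-exon-3 junction interval
#'
#' @return list with \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive hg38 coordinates chrX:67686127-67694672).
#' @export
arV7Junction <- function() {
  list(chrom = "chrX", start = 67686127L, end = 67694672L)
}

#' Generate synthetic spliced-alignment records
#'
#' Emits \code{totalReads} SAM-style alignment records. A
#' Poisson-distributed number (mean \code{srpmTarget * totalReads / 1e6})
#' carries an N-gap whose donor and acceptor both lie inside the junction
#' interval; the remainder are ungapped or gapped far from the junction.
#'
#' @param srpmTarget target spliced reads per million (>= 0).
#' @param totalReads total number of records to emit.
#' @param seed integer seed.
#' @param junction interval list as returned by \code{\link{arV7Junction}}.
#' @return \code{data.frame} with columns \code{qname}, \code{flag},
#'   \code{rname}, \code{pos}, \code{cigar}.
#' @export
generateJunctionAlignments <- function(srpmTarget, totalReads,
                                       seed = 1L,
                                       junction = arV7Junction()) {
  if (!is.numeric(srpmTarget) || length(srpmTarget) != 1L ||
      is.na(srpmTarget) || srpmTarget < 0) {
    stop("srpmTarget must be a single non-negative rate", call. = FALSE)
  }
  .assertCount(totalReads, "totalReads")
  set.seed(seed)
  nJ <- min(totalReads,
            stats::rpois(1L, srpmTarget * totalReads / 1e6))
  nO <- totalReads - nJ

  # junction-spanning: 38M [gap] 38M with the N-gap fully inside the
  # interval (donor = last aligned base before, acceptor = first after)
  gapStart <- sample.int(junction$end - junction$start - 600L, nJ,
                         replace = TRUE) + junction$start + 50L
  gapLen <- sample(100:500, nJ, replace = TRUE)
  jRec <- data.frame(
    qname = sprintf("junc%07d", seq_len(nJ)),
    flag = rep(0L, nJ), rname = rep(junction$chrom, nJ),
    pos = gapStart - 38L,
    cigar = sprintf("38M%dN38M", gapLen),
    stringsAsFactors = FALSE)

  gappedElsewhere <- stats::runif(nO) < 0.15
  posO <- ifelse(gappedElsewhere,
                 sample.int(1000000L, nO, replace = TRUE) + 500000L,
                 sample.int(150000000L, nO, replace = TRUE))
  oRec <- data.frame(
    qname = sprintf("read%08d", seq_len(nO)),
    flag = 0L,
    rname = ifelse(gappedElsewhere, "chr1", "chrX"),
    pos = posO,
    cigar = ifelse(gappedElsewhere,
                   sprintf("38M%dN38M",
                           sample(100:500, nO, replace = TRUE)),
                   "76M"),
    stringsAsFactors = FALSE)
  rec <- rbind(jRec, oRec)
  rec[sample.int(nrow(rec)), , drop = FALSE]
}

#' Write a simulated DSP dataset to disk
#'
#' Convenience wrapper writing the TSV count matrix, CSV ROI annotations
#' and (optionally) GMT signature sets that \code{\link{readDspDataset}}
#' reads back.
#'
#' @param x a \linkS4class{ProbeCountSet} or \linkS4class{TargetCountSet}.
#' @param dir output directory (created if absent).
#' @param signatures optional named list of gene-id vectors.
#' @return invisibly, the named vector of file paths written.
#' @export
writeDspDataset <- function(x, dir, signatures = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  countsPath <- file.path(dir, "counts.tsv")
  annPath <- file.path(dir, "annotations.csv")
  writeCountsTsv(x, countsPath)
  writeRoiAnnotationCsv(roiAnnotation(x), annPath)
  paths <- c(counts = countsPath, annotations = annPath)
  if (!is.null(signatures)) {
    gmtPath <- file.path(dir, "signatures.gmt")
    writeGmt(signatures, gmtPath)
    paths <- c(paths, signatures = gmtPath)
  }
  invisible(paths)
}
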