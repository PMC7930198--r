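makeNegSet <- function(negPerRoi) {
  counts <- do.call(cbind, negPerRoi)
  colnames(counts) <- names(negPerRoi)
  rownames(counts) <- paste0("NEG", seq_len(nrow(counts)))
  ProbeCountSet(counts, targetId = rownames(counts),
                isNegative = rep(TRUE, nrow(counts)))
}

test_that("RNA LOQ is geomean x GSD^2, identically exp(mu + 2 sigma)", {
  ps <- makeNegSet(list(R1 = c(2, 4, 8), R2 = c(5, 5, 5)))
  loq <- rnaLoq(ps)
  expect_equal(loq["R1", "neg_geomean"], 4)
  expect_equal(loq["R1", "neg_gsd"], 2)
  expect_equal(loq["R1", "loq"], 16)
  expect_equal(loq["R2", "loq"], 5)  # zero dispersion: LOQ = geomean

  # formulation equivalence on random vectors: the two printed readings
  # coincide only under the geometric (log-space) interpretation
  for (i in 1:25) {
    set.seed(i)
    x <- round(exp(rnorm(20, 3, 0.7))) + 1
    byGsd <- geoMean(x) * geoSd(x)^2
    byLog <- exp(mean(log(x)) + 2 * sd(log(x)))
    expect_equal(byGsd, byLog, tolerance = 1e-12)
  }

  tooFew <- makeNegSet(list(R1 = c(3, 9)))
  expect_error(rnaLoq(tooFew), "at least 3")
})

test_that("LOQ grows with negative dispersion at fixed geomean", {
  spread <- function(f) makeNegSet(list(R = c(8 / f, 8, 8 * f)))
  loqs <- vapply(c(1, 1.5, 2, 4),
                 function(f) rnaLoq(spread(f))["R", "loq"], numeric(1))
  expect_true(all(diff(loqs) > 0))
  expect_true(all(loqs >= 8 - 1e-9))
})

test_that("protein LOQ is a multiple of the IgG geometric mean", {
  mk <- function(igg) {
    counts <- matrix(c(igg, 50, 10), ncol = 1,
                     dimnames = list(c(paste0("IgG", seq_along(igg)),
                                       "AB1", "AB2"), "R1"))
    TargetCountSet(counts,
                   targetClass = c(rep("igg", length(igg)),
                                   "endogenous", "endogenous"),
                   analyte = "protein")
  }
  expect_equal(proteinLoq(mk(c(8, 8, 8)))["R1", "loq"], 24)
  expect_equal(proteinLoq(mk(c(1, 8, 64)))["R1", "loq"], 24)
  expect_equal(proteinLoq(mk(c(0, 0)))["R1", "loq"], 3)  # floored at 1
  expect_error(proteinLoq(mk(8)), "at least 2")
})

test_that("detection is strictly above the LOQ", {
  counts <- matrix(c(5, 20, 100, 16, 16, 16), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("R1", "R2")))
  loq <- data.frame(roi_id = c("R1", "R2"), neg_geomean = c(4, 4),
                    neg_gsd = c(2, 2), loq = c(16, 16),
                    row.names = c("R1", "R2"))
  det <- detectionMatrix(counts, loq)
  expect_equal(unname(det[, "R1"]), c(FALSE, TRUE, TRUE))
  expect_equal(sum(det[, "R1"]), 2L)
  expect_equal(unname(det[, "R2"]), rep(FALSE, 3))  # boundary: == LOQ
  expect_error(detectionMatrix(counts[, 1, drop = FALSE],
                               loq[integer(), ]), "no LOQ")
})

test_that("QC filters apply the printed low-gene rule and ledger", {
  ann <- makeAnn(5L, 1L, 1L)
  det <- matrix(FALSE, nrow = 400, ncol = 5,
                dimnames = list(paste0("g", 1:400), ann$roi_id))
  for (i in seq_len(5)) det[seq_len(c(50, 100, 101, 200, 300)[i]), i] <- TRUE
  res <- applyQcFilters(det, ann, minGenes = 100)
  expect_equal(res$rois, ann$roi_id[3:5])  # 100 detected is excluded
  expect_equal(res$ledger$n[res$ledger$reason == "low_genes"], 2L)
  expect_equal(res$genes, paste0("g", 1:300))

  # all clean: identity
  det2 <- det; det2[] <- TRUE
  res2 <- applyQcFilters(det2, ann, minGenes = 100)
  expect_equal(res2$rois, ann$roi_id)
  expect_equal(res2$genes, rownames(det2))

  # ledger counts always sum to input minus retained
  with(res$ledger, expect_equal(
    n[reason == "arrayed"] - sum(n[!reason %in% c("arrayed", "retained")]),
    n[reason == "retained"]))
})

test_that("negative normalization is log2 relative to background", {
  counts <- matrix(c(4, 64, 8), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3"), "R1"))
  loq <- data.frame(roi_id = "R1", neg_geomean = 4, neg_gsd = 2,
                    loq = 16, row.names = "R1")
  nn <- negativeNormalize(counts, loq)
  expect_equal(unname(nn[, 1]), c(0, 4, 1))
  nn2 <- negativeNormalize(counts * 2, loq)
  expect_equal(nn2, nn + 1)  # doubling adds exactly 1
})

test_that("Q3 normalization matches hand-computed factors", {
  counts <- cbind(R1 = c(10, 20, 30, 40, 50),
                  R2 = c(20, 40, 60, 80, 100))
  rownames(counts) <- paste0("g", 1:5)
  det <- matrix(TRUE, 5, 2, dimnames = dimnames(counts))
  q3 <- c(quantile(counts[, 1], 0.75, type = 7),
          quantile(counts[, 2], 0.75, type = 7))  # 40, 80
  expected <- sweep(counts, 2, exp(mean(log(q3))) / q3, `*`)
  expect_equal(q3Normalize(counts, det), expected)

  # identical ROIs: identity
  same <- cbind(R1 = c(5, 10, 20, 40), R2 = c(5, 10, 20, 40))
  rownames(same) <- paste0("g", 1:4)
  detS <- matrix(TRUE, 4, 2, dimnames = dimnames(same))
  expect_equal(q3Normalize(same, detS), same)

  # global scale equivariance; per-ROI scaling preserves within-ROI ratios
  expect_equal(q3Normalize(counts * 7, det),
               q3Normalize(counts, det) * 7)
  out <- q3Normalize(counts, det)
  expect_equal(out[, "R1"] / out[1, "R1"],
               counts[, "R1"] / counts[1, "R1"])

  detBad <- det; detBad[2:5, 1] <- FALSE
  expect_error(q3Normalize(counts, detBad), "R1")
})

test_that("protein SNR divides by IgG geomean with inclusive cutoff", {
  counts <- matrix(c(29.9, 30, 300, 10, 10, 10), ncol = 1,
                   dimnames = list(c("AB1", "AB2", "AB3",
                                     "IgG1", "IgG2", "IgG3"), "R1"))
  x <- TargetCountSet(counts,
                      targetClass = c(rep("endogenous", 3),
                                      rep("igg", 3)),
                      analyte = "protein")
  res <- proteinSnr(x)
  expect_equal(res$snr["AB1", 1], 2.99)
  expect_equal(res$snr["AB2", 1], 3)
  expect_equal(unname(res$detected[c("AB1", "AB2", "AB3"), 1]),
               c(FALSE, TRUE, TRUE))
  # IgG SNRs have geometric mean 1 within the ROI
  expect_equal(exp(mean(log(res$snr[4:6, 1]))), 1)
})

test_that("housekeeping normalization rescales ROIs, not ratios", {
  counts <- cbind(R1 = c(100, 200, 8, 8, 8),
                  R2 = c(100, 200, 4, 4, 4))
  rownames(counts) <- c("AB1", "AB2", "RPS6", "HistoneH3", "GAPDH")
  x <- TargetCountSet(counts,
                      targetClass = c("endogenous", "endogenous",
                                      rep("housekeeping", 3)),
                      analyte = "protein")
  out <- housekeepingNormalize(x)
  # R1's housekeeper geomean is 2x R2's: R1 scaled by half relative to R2
  expect_equal(out["AB1", "R1"] / out["AB1", "R2"], 0.5)
  expect_equal(out["AB2", "R1"] / out["AB1", "R1"],
               counts["AB2", "R1"] / counts["AB1", "R1"])
  expect_error(housekeepingNormalize(x, c("RPS6", "ACTB")), "ACTB")
})

test_that("normalizations preserve within-ROI rank order", {
  dat <- smallCohortData(seed = 23L, nPatients = 3L)
  gs <- collapseToTargets(dat$probes, flagOutlierProbes(dat$probes))
  loq <- rnaLoq(dat$probes)
  cc <- assay(gs, "counts")
  nn <- negativeNormalize(gs, loq)
  det <- detectionMatrix(gs, loq)
  det[1:10, ] <- TRUE  # ensure >= 4 detected everywhere
  q3 <- q3Normalize(cc, det)
  for (j in seq_len(ncol(cc))) {
    expect_equal(order(nn[, j]), order(cc[, j]))
    expect_equal(order(q3[, j]), order(cc[, j]))
  }
})
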