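test_that("pair strata partition all pairs and respect the hierarchy", {
  ann <- makeAnn(3L, 2L, 2L)  # 12 ROIs
  all <- pairStrata(ann, "all")
  expect_equal(nrow(all), choose(12, 2))
  it <- pairStrata(ann, "intratumor")
  ip <- pairStrata(ann, "intrapatient")
  xp <- pairStrata(ann, "interpatient")
  expect_equal(nrow(it), 6L)         # 6 tumors x C(2,2)
  expect_equal(nrow(ip), 3L * 4L)    # per patient: 2x2 cross-tumor
  expect_equal(nrow(it) + nrow(ip) + nrow(xp), nrow(all))
  key <- function(p) paste(p$roi1, p$roi2)
  expect_equal(length(intersect(key(it), key(ip))), 0L)
  expect_setequal(c(key(it), key(ip), key(xp)), key(all))
  wp <- pairStrata(ann, "withinpatient")
  expect_setequal(key(wp), c(key(it), key(ip)))
})

test_that("exact agreement equals the hypergeometric identity", {
  ann <- makeAnn(1L, 2L, 3L)
  calls <- setNames(rep(c("AR+/NE+", "AR+/NE-"), each = 3), ann$roi_id)
  res <- pairAgreementExact(calls, pairStrata(ann, "all"))
  expect_equal(res$estimate, 6 / 15)  # (C(3,2)+C(3,2))/C(6,2) = 40%
  expect_equal(res$n_pairs, 15L)

  # all same -> 1; (A, A, B) -> 1/3
  same <- setNames(rep("AR+/NE-", 6), ann$roi_id)
  expect_equal(pairAgreementExact(same, pairStrata(ann, "all"))$estimate,
               1)
  ann3 <- makeAnn(1L, 1L, 3L)
  aab <- setNames(c("A", "A", "B"), ann3$roi_id)
  expect_equal(pairAgreementExact(aab, pairStrata(ann3, "all"))$estimate,
               1 / 3)

  # identity sum(C(n_g,2))/C(n,2) on random class assignments
  for (i in 1:10) {
    set.seed(i)
    annR <- makeAnn(1L, 1L, 12L)
    cl <- setNames(sample(LETTERS[1:4], 12, replace = TRUE), annR$roi_id)
    est <- pairAgreementExact(cl, pairStrata(annR, "all"))$estimate
    expect_equal(est, sum(choose(table(cl), 2)) / choose(12, 2))
  }

  # missing calls are excluded
  miss <- setNames(c("A", "A", NA), ann3$roi_id)
  resM <- pairAgreementExact(miss, pairStrata(ann3, "all"))
  expect_equal(resM$estimate, 1)
  expect_equal(resM$n_pairs, 1L)
})

test_that("sampled agreement converges to the exact enumeration", {
  ann <- makeAnn(4L, 2L, 3L)
  set.seed(10)
  calls <- setNames(sample(phenotypeClasses()[1:3], nrow(ann),
                           replace = TRUE), ann$roi_id)
  pairs <- pairStrata(ann, "all")
  exact <- pairAgreementExact(calls, pairs)$estimate
  sampled <- pairAgreementSampled(calls, pairs, nSamples = 100000L,
                                  seed = 2L)$estimate
  expect_lt(abs(sampled - exact), 0.01)

  # single-pair stratum: sampled equals exact and is 0 or 1
  ann1 <- makeAnn(1L, 1L, 2L)
  c1 <- setNames(c("A", "B"), ann1$roi_id)
  p1 <- pairStrata(ann1, "all")
  expect_equal(pairAgreementSampled(c1, p1, 50L, seed = 1L)$estimate,
               pairAgreementExact(c1, p1)$estimate)
  expect_equal(pairAgreementExact(c1, p1)$estimate, 0)
})

test_that("concordance is ordered intratumor >= intrapatient >= interpatient", {
  cfg <- cohortConfig(nPatients = 20L, discordantTumorFraction = 0.4,
                      discordantRoiFraction = 0.15, seed = 91L)
  truth <- generateCohort(cfg)
  calls <- setNames(truth$phenotype, truth$roi_id)
  est <- vapply(c("intratumor", "intrapatient", "interpatient"),
                function(lv) phenotypeConcordance(calls, truth, lv,
                                                  B = 0L)$estimate,
                numeric(1))
  expect_gte(est["intratumor"], est["intrapatient"])
  expect_gte(est["intrapatient"], est["interpatient"])
})

test_that("cluster-bootstrap BCa interval brackets the estimate", {
  cfg <- cohortConfig(nPatients = 12L, discordantTumorFraction = 0.3,
                      discordantRoiFraction = 0.2, seed = 17L)
  truth <- generateCohort(cfg)
  calls <- setNames(truth$phenotype, truth$roi_id)
  res <- phenotypeConcordance(calls, truth, "intratumor", B = 200L,
                              seed = 5L)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
  expect_gte(res$ci_low, 0); expect_lte(res$ci_high, 1)

  # all concordant: every replicate is 1 -> degenerate interval (1, 1)
  same <- setNames(rep("AR+/NE-", nrow(truth)), truth$roi_id)
  expect_warning(
    resS <- phenotypeConcordance(same, truth, "intratumor", B = 50L,
                                 seed = 5L),
    "degenerate")
  expect_equal(c(resS$ci_low, resS$ci_high), c(1, 1))
})

test_that("BCa endpoints match a brute-force oracle to 1e-12", {
  set.seed(42)
  x <- rnorm(10, 5, 2)  # 10-unit toy, mean statistic
  fit <- bcaCi(x, statistic = mean, B = 500L, seed = 3L)

  # independent implementation, straight from the BCa endpoint formulas
  th <- mean(x)
  tb <- fit$thetaBoot
  tj <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  B <- length(tb)
  p0 <- (sum(tb < th) + 0.5 * sum(tb == th)) / B
  z0 <- qnorm(min(max(p0, 1 / (2 * B)), 1 - 1 / (2 * B)))
  u <- mean(tj) - tj
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  lev <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  s <- sort(tb)
  oracle <- c(s[min(B, max(1, ceiling(B * lev(qnorm(0.025)))))],
              s[min(B, max(1, ceiling(B * lev(qnorm(0.975)))))])
  expect_equal(fit$ci_low, oracle[1], tolerance = 1e-12)
  expect_equal(fit$ci_high, oracle[2], tolerance = 1e-12)
  expect_equal(fit$thetaJack, tj)

  expect_warning(bcaInterval(1, rep(1, 100), rep(1, 10)), "degenerate")
})

test_that("profile correlations follow the planted hierarchy", {
  # hand-checkable Pearson values
  e <- cbind(R1 = c(1, 2, 3), R2 = c(2, 4, 6), R3 = c(3, 2, 1),
             R4 = c(5, 5, 5))
  rownames(e) <- paste0("g", 1:3)
  ann <- makeAnn(2L, 1L, 2L)
  ann$roi_id <- colnames(e)
  rownames(ann) <- ann$roi_id
  res <- stratifiedProfileCorrelation(e, ann)
  r12 <- res$r[res$roi1 == "R1" & res$roi2 == "R2"]
  r13 <- res$r[res$roi1 == "R1" & res$roi2 == "R3"]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  expect_equal(attr(res, "skipped"), 3L)  # R4 is flat: 3 pairs skipped

  # synthetic cohort: median r ordered intratumor >= intrapatient >=
  # interpatient
  dat <- smallCohortData(seed = 61L, nPatients = 8L,
                         discordantTumorFraction = 0.5)
  gs <- collapseToTargets(dat$probes)
  nn <- negativeNormalize(gs, rnaLoq(dat$probes))
  rr <- stratifiedProfileCorrelation(nn, dat$truth)
  med <- tapply(rr$r, rr$stratum, median)
  expect_gte(med["intratumor"], med["intrapatient"])
  expect_gte(med["intrapatient"], med["interpatient"])
})

test_that("rank-sum differential expression gives exact small-sample p", {
  # complete separation, |A| = 6 vs |B| = 3: p = 2 / C(9,3)
  e <- rbind(sep = c(1:6, 11:13), flat = rep(2, 9))
  colnames(e) <- paste0("S", 1:9)
  res <- differentialExpression(e, paste0("S", 1:6), paste0("S", 7:9))
  expect_equal(res$p[1], 2 / choose(9, 3), tolerance = 1e-12)
  expect_equal(res$p[2], 1)
  expect_equal(res$log2fc[2], 0)

  # complete separation, 3 vs 3: p = 2 / C(6,3) = 0.1
  e2 <- rbind(g = c(1, 2, 3, 10, 11, 12))
  colnames(e2) <- paste0("S", 1:6)
  res2 <- differentialExpression(rbind(e2, e2), paste0("S", 1:3),
                                 paste0("S", 4:6))
  expect_equal(res2$p[1], 0.1, tolerance = 1e-12)

  # rank test: p invariant under monotone transforms of the data
  set.seed(4)
  e3 <- matrix(rexp(40) + 1, nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("S", 1:10)))
  pa <- differentialExpression(e3, 1:5, 6:10)$p
  pb <- differentialExpression(e3^3, 1:5, 6:10)$p
  expect_equal(pa, pb)

  # BH adjustment across genes
  resA <- differentialExpression(e3, 1:5, 6:10)
  expect_equal(resA$q, p.adjust(resA$p, "BH"))
  expect_error(differentialExpression(e3, 1, 2:10), "at least 2")
})
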