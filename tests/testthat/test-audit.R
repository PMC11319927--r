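test_that("signed-rank conventions: zeros dropped, ties mid-ranked", {
  expect_equal(wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  # all-positive differences 1..5: one-sided tail 1/32, two-sided 0.0625
  w <- wilcoxonSignedRank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(w$p, 0.0625)
  expect_equal(w$statistic, 15)
  # mirrored tied differences sit at the null center n(n+1)/4
  w2 <- wilcoxonSignedRank(rep(0, 6), c(1, -1, 2, -2, 3, -3))
  expect_equal(w2$statistic, 10.5)
  expect_error(wilcoxonSignedRank(1:3, 1:4), "equal length")
})

test_that("exact signed-rank p matches full 2^n enumeration", {
  for (i in 1:100) {
    d <- withr::with_seed(3000 + i, {
      n <- sample(3:10, 1)
      # half-integer grid induces frequent ties and zeros
      round(stats::rnorm(n, sd = 2) * 2) / 2
    })
    got <- wilcoxonSignedRank(rep(0, length(d)), d)
    want <- enumWilcoxon(d)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the reference implementation", {
  # tie-free small n: exact path against stats::wilcox.test(exact = TRUE)
  for (i in 1:20) {
    d <- withr::with_seed(4000 + i, stats::rnorm(sample(6:12, 1)))
    got <- wilcoxonSignedRank(rep(0, length(d)), d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  }
  # large n: normal approximation with continuity correction
  d <- withr::with_seed(99, stats::rnorm(60, mean = 0.3))
  got <- wilcoxonSignedRank(rep(0, 60), d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
})

test_that("ICC(2,1) matches the two-way ANOVA mean-squares oracle", {
  expect_equal(icc21(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # constant offset: absolute agreement penalizes it
  expect_lt(icc21(1:4, 2:5), 1)
  expect_equal(icc21(1:4, 2:5), aovICC21(1:4, 2:5), tolerance = 1e-12)
  for (i in 1:50) {
    xy <- withr::with_seed(5000 + i, {
      n <- sample(5:30, 1)
      x <- stats::rnorm(n, 10, 3)
      list(x = x, y = x + stats::rnorm(n, sample(c(0, 1), 1), 1.5))
    })
    expect_equal(icc21(xy$x, xy$y), aovICC21(xy$x, xy$y), tolerance = 1e-10)
  }
})

test_that("r and ICC transform as expected under shifts and scalings", {
  xy <- withr::with_seed(42, {
    x <- stats::rnorm(30, 10, 2)
    list(x = x, y = x + stats::rnorm(30, 0, 1))
  })
  m0 <- agreementMetrics(xy$x, xy$y)
  # common additive constant leaves both invariant
  m1 <- agreementMetrics(xy$x + 5, xy$y + 5)
  expect_equal(m1$r, m0$r, tolerance = 1e-12)
  expect_equal(m1$ICC, m0$ICC, tolerance = 1e-12)
  # affine map of one list: r invariant, ICC not (absolute agreement)
  m2 <- agreementMetrics(xy$x, 2 * xy$y + 3)
  expect_equal(m2$r, m0$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m2$ICC, m0$ICC)))
})

test_that("agreement metrics use the prediction-minus-truth convention", {
  m <- agreementMetrics(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(m$meanDiff, 1)
  expect_equal(m$MAE, 1)
  expect_equal(m$r, 1)
  expect_lt(m$ICC, 1)
  # perfect agreement
  p <- agreementMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$meanDiff, 0); expect_equal(p$MAE, 0)
  expect_equal(p$r, 1); expect_equal(p$ICC, 1)
  # zero variance: undefined markers, not exceptions
  z <- agreementMetrics(c(2, 2, 2), c(2.1, 2.1, 2.1))
  expect_true(is.na(z$r))
})

test_that("Bland-Altman bias and limits follow the definition", {
  b0 <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b0$bias, 0); expect_equal(b0$lowerLoA, 0); expect_equal(b0$upperLoA, 0)
  xy <- withr::with_seed(8, {
    gt <- stats::rnorm(10, 10)
    list(gt = gt, pred = gt + stats::rnorm(10))
  })
  ba <- blandAltman(xy$gt, xy$pred)
  dd <- xy$pred - xy$gt
  expect_equal(ba$bias, mean(dd), tolerance = 1e-12)
  expect_equal(ba$lowerLoA, mean(dd) - 1.96 * stats::sd(dd), tolerance = 1e-12)
  expect_equal(ba$upperLoA, mean(dd) + 1.96 * stats::sd(dd), tolerance = 1e-12)
  expect_equal(ba$points$mean, (xy$gt + xy$pred) / 2)
})

test_that("significance counting is strict, NA-aware and monotone", {
  expect_equal(countSignificant(numeric(0)), 0L)
  expect_equal(countSignificant(c(0.049, 0.05, 0.051)), 1L)
  expect_error(countSignificant(c(0.01, NA)), "NA")
  expect_equal(countSignificant(c(0.01, NA), na.rm = TRUE), 1L)
  ps <- withr::with_seed(3, stats::runif(50))
  alphas <- sort(stats::runif(20))
  counts <- vapply(alphas, function(a) countSignificant(ps, a), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("published p-value rows reproduce the reported significant counts", {
  tabs <- referencePerformanceTables()
  expect_equal(countSignificant(as.numeric(tabs$overall["p", ]), 0.05), 7L)
  expect_equal(countSignificant(as.numeric(tabs$ensemble["p", ]), 0.05,
                                na.rm = TRUE), 1L)
  expect_equal(countSignificant(as.numeric(tabs$male["p", ]), 0.05), 1L)
  expect_equal(countSignificant(as.numeric(tabs$female["p", ]), 0.05), 0L)
})

# Builds a manifest-like object without images for audit tests.
auditManifest <- function(n = 240, seed = 1) {
  withr::with_seed(seed, {
    rec <- data.frame(
      imageId = sprintf("I%03d", 1:n),
      patientId = sprintf("P%03d", rep(seq_len(n / 4), each = 4)),
      sex = rep(sample(c("male", "female"), n / 4, replace = TRUE), each = 4),
      age = rep(stats::runif(n / 4, 18, 70), each = 4),
      ageGroup = "30-49", toothSite = rep(toothSites(), n / 4),
      split = "test", stringsAsFactors = FALSE)
    gt <- matrix(stats::rnorm(n * 9, 10, 2), n, 9,
                 dimnames = list(rec$imageId, indexNames()))
    new("QuantManifest", records = rec, gt = gt, geometries = list(),
        images = array(numeric(0), c(0, 0, 0)), config = list(),
        seed = NA_integer_)
  })
}

test_that("the audit flags engineered sex bias and picks sex", {
  m <- auditManifest(seed = 5)
  rec <- manifestRecords(m)
  pred <- manifestGT(m) + withr::with_seed(6,
    matrix(stats::rnorm(length(manifestGT(m)), 0, 0.3), nrow(manifestGT(m))))
  # bias five indices for female records only (the audited pattern)
  biasIdx <- c("LBAab", "apical2mm", "WTAP", "WBAB", "WBAP")
  pred[rec$sex == "female", biasIdx] <-
    pred[rec$sex == "female", biasIdx] + 1.0
  rep <- subgroupAudit(m, pred)
  expect_s4_class(rep, "AuditReport")
  expect_identical(sensitiveAttribute(rep), "sex")
  expect_gte(auditDisparity(rep)[["sex"]], 4)
  expect_false(rep@noDisparity)
  expect_equal(unname(auditCounts(rep)$sex[["male"]]), 0)
})

test_that("an unbiased model yields the null audit verdict", {
  m <- auditManifest(seed = 7)
  # exact agreement: every stratum test hits the all-zero-differences
  # convention (p = 1), so no stratum is flagged anywhere
  pred <- manifestGT(m)
  rep <- subgroupAudit(m, pred)
  expect_true(all(unlist(auditCounts(rep)) == 0, na.rm = TRUE))
  expect_true(rep@noDisparity)
  # tie-break: first attribute in audit order
  expect_identical(sensitiveAttribute(rep), auditConfig()$attributes[1])
})

test_that("underpowered strata are excluded and recorded", {
  m <- auditManifest(seed = 9)
  m@records$ageGroup <- c(rep("18-29", 3), rep("30-49", nrow(m@records) - 3))
  pred <- manifestGT(m)
  rep <- subgroupAudit(m, pred)
  expect_identical(rep@underpowered$ageGroup, "18-29")
  expect_true(is.na(auditCounts(rep)$ageGroup[["18-29"]]))
})

test_that("the disparity ranking ignores attribute order except tie-breaks", {
  m <- auditManifest(seed = 10)
  rec <- manifestRecords(m)
  pred <- manifestGT(m) + withr::with_seed(11,
    matrix(stats::rnorm(length(manifestGT(m)), 0, 0.3), nrow(manifestGT(m))))
  pred[rec$sex == "male", c("LTAcb", "LTAab", "LBAcb")] <-
    pred[rec$sex == "male", c("LTAcb", "LTAab", "LBAcb")] + 1.2
  r1 <- subgroupAudit(m, pred, auditConfig(attributes = c("sex", "toothSite")))
  r2 <- subgroupAudit(m, pred, auditConfig(attributes = c("toothSite", "sex")))
  expect_identical(sensitiveAttribute(r1), "sex")
  expect_identical(sensitiveAttribute(r2), "sex")
  expect_equal(auditDisparity(r1)[["sex"]], auditDisparity(r2)[["sex"]])
})

test_that("evaluation tables carry the canonical layout", {
  m <- auditManifest(seed = 12)
  pred <- manifestGT(m) + 0.5
  ev <- evalTable(manifestGT(m), pred, model = "primary")
  expect_equal(ev$index, indexNames())
  expect_equal(ev$diffMean, rep(0.5, 9), tolerance = 1e-12)
  expect_equal(ev$MAE, rep(0.5, 9), tolerance = 1e-12)
  expect_true(all(ev$model == "primary"))
})
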