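test_that("population sampling honors the demographic structure", {
  cfg <- populationConfig(nPatients = 1000, seed = 11L)
  pop <- withr::with_seed(11, samplePopulation(cfg))
  expect_equal(nrow(pop), 4000L)
  # one record per tooth site per patient
  tab <- table(pop$patientId, pop$toothSite)
  expect_true(all(tab == 1L))
  # male count within 3 SD of Binomial(1000, 0.388)
  nMale <- sum(pop$sex[!duplicated(pop$patientId)] == "male")
  expect_lt(abs(nMale - 388), 3 * sqrt(1000 * 0.388 * 0.612))
  expect_true(all(pop$age >= 18))
  expect_equal(as.character(parityQuant:::.ageGroup(c(18, 29.9, 30, 49.9, 50, 80))),
               c("18-29", "18-29", "30-49", "30-49", "50+", "50+"))
})

test_that("a single patient yields exactly the four tooth-site records", {
  cfg <- populationConfig(nPatients = 1, seed = 2L)
  pop <- withr::with_seed(5, samplePopulation(cfg))
  expect_equal(nrow(pop), 4L)
  expect_setequal(pop$toothSite, toothSites())
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- populationConfig(nPatients = 30, seed = 3L)
  p1 <- withr::with_seed(9, samplePopulation(cfg))
  p2 <- withr::with_seed(9, samplePopulation(cfg))
  expect_identical(p1, p2)
  g1 <- withr::with_seed(13, sampleGeometry("male", cfg))
  g2 <- withr::with_seed(13, sampleGeometry("male", cfg))
  expect_identical(g1, g2)
})

test_that("config validation rejects invalid populations", {
  expect_error(populationConfig(nPatients = 0), "nPatients")
  expect_error(populationConfig(maleFraction = 1.2), "maleFraction")
  expect_error(populationConfig(sexEffect = 0), "sexEffect")
  expect_error(populationConfig(ageSd = -1), "ageSd")
})

test_that("sexEffect scales male widths by the configured factor", {
  nDraw <- 400
  draw <- function(sex, effect) {
    cfg <- populationConfig(nPatients = 5, sexEffect = effect, seed = 1L)
    withr::with_seed(700 + effect * 10, {
      vapply(seq_len(nDraw), function(i)
        parityQuant:::.analyticIndices(
          parityQuant:::.sampleGeometryParams(sex, cfg))[["apical2mm"]],
        numeric(1))
    })
  }
  # null effect: the distributions coincide up to Monte-Carlo error
  m0 <- draw("male", 1.0); f0 <- draw("female", 1.0)
  se0 <- sqrt(stats::var(m0) / nDraw + stats::var(f0) / nDraw)
  expect_lt(abs(mean(m0) - mean(f0)), 3 * se0)
  # effect 1.3: ratio of mean widths ~ 1.3 within 3 SE
  m1 <- draw("male", 1.3); f1 <- draw("female", 1.3)
  ratio <- mean(m1) / mean(f1)
  seRatio <- ratio * sqrt(stats::var(m1) / nDraw / mean(m1)^2 +
                          stats::var(f1) / nDraw / mean(f1)^2)
  expect_lt(abs(ratio - 1.3), 3 * seRatio)
})

test_that("largest-remainder apportionment matches the 6:2:2 contract", {
  expect_equal(unname(apportionSplit(10)), c(6L, 2L, 2L))
  expect_equal(unname(apportionSplit(5)), c(3L, 1L, 1L))
  expect_equal(unname(apportionSplit(38)), c(23L, 8L, 7L))
  # oracle: independent largest-remainder implementation
  lrOracle <- function(n, r = c(6, 2, 2)) {
    q <- n * r / sum(r); fl <- floor(q)
    extra <- order(-(q - fl), seq_along(q))[seq_len(n - sum(fl))]
    fl[extra] <- fl[extra] + 1
    as.integer(fl)
  }
  for (n in 3:60) expect_equal(unname(apportionSplit(n)), lrOracle(n))
})

test_that("patient-wise split disjointness holds over random configs", {
  for (i in 1:100) {
    info <- withr::with_seed(1000 + i, {
      n <- sample(5:40, 1)
      cfg <- populationConfig(nPatients = n, seed = 1L)
      pop <- samplePopulation(cfg)
      splitOf <- parityQuant:::.assignPatientSplits(pop$patientId)
      list(pop = pop, splitOf = splitOf, n = n)
    })
    sp <- info$splitOf[info$pop$patientId]
    perPatient <- tapply(sp, info$pop$patientId, function(s) length(unique(s)))
    expect_true(all(perPatient == 1L))
    expect_equal(sort(as.integer(table(info$splitOf))),
                 sort(unname(apportionSplit(info$n))))
  }
})

test_that("manifest bookkeeping, split and ground truth are consistent", {
  cfg <- populationConfig(nPatients = 10, seed = 21L)
  m <- buildDataset(cfg, render = FALSE)
  rec <- manifestRecords(m)
  expect_equal(nrow(rec), 40L)
  pat <- rec[!duplicated(rec$patientId), ]
  expect_equal(as.integer(table(factor(pat$split,
    c("train", "validation", "test")))), c(6L, 2L, 2L))
  expect_true(all(tapply(rec$split, rec$patientId,
                         function(s) length(unique(s))) == 1L))
  # GT equals re-measurement of the stored geometry within 1e-6 mm
  gt <- manifestGT(m); geoms <- manifestGeometries(m)
  err <- vapply(seq_len(nrow(gt)), function(i)
    max(abs(measureIndices(geoms[[rec$imageId[i]]]) - gt[i, ])), numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("identical config and seed reproduce the manifest byte-for-byte", {
  cfg <- populationConfig(nPatients = 6, seed = 77L,
                          image = imageConfig(size = 32, pixelSpacing = 1))
  m1 <- buildDataset(cfg)
  m2 <- buildDataset(cfg)
  expect_identical(m1@records, m2@records)
  expect_identical(m1@gt, m2@gt)
  expect_identical(m1@images, m2@images)
})

test_that("rendering orders intensities and is deterministic", {
  g <- axisAlignedGeometry()
  cfgImg <- imageConfig(size = 64, pixelSpacing = 0.5, blurSigma = 0,
                        noiseSd = 0, corticalWidth = 0)
  img <- renderImage(g, cfgImg)
  px <- function(mm) {
    p <- round(mmToPixel(mm, img)) + 1
    img[p[2], p[1]]
  }
  toothVal <- px(c(0, 3))       # inside the root
  boneVal <- px(c(3, 10))       # bone, clear of tooth and margins
  bgVal <- px(c(3, 25))         # apical of the basal boundary (air)
  expect_gt(toothVal, boneVal)
  expect_gt(boneVal, bgVal)
  expect_true(all(img >= 0 & img <= 1))
  # deterministic with zero noise
  expect_identical(img, renderImage(g, cfgImg))
})

test_that("geometry exceeding the field of view errors with its extent", {
  g <- axisAlignedGeometry(basalY = 40)
  expect_error(renderImage(g, imageConfig(size = 32, pixelSpacing = 0.5)),
               "field of view")
})

test_that("noiseless boundary crossing on the render recovers LTAcb", {
  for (seed in c(4, 9)) {
    g <- randomGeometry(seed)
    cfgImg <- imageConfig(size = 128, pixelSpacing = 0.25, noiseSd = 0)
    img <- renderImage(g, cfgImg)
    ta <- g@toothAxis
    thr <- (cfgImg$corticalIntensity + cfgImg$background) / 2
    # sample the intensity profile along the tooth axis, sub-pixel steps
    tGrid <- seq(0, 30, by = 0.02)
    pts <- t(vapply(tGrid, function(t) ta@point + t * ta@dir, numeric(2)))
    pp <- mmToPixel(pts, img)
    inb <- pp[, 1] >= 0 & pp[, 1] <= 127 & pp[, 2] >= 0 & pp[, 2] <= 127
    vals <- rep(NA_real_, length(tGrid))
    # bilinear interpolation
    x0 <- floor(pp[inb, 1]); y0 <- floor(pp[inb, 2])
    fx <- pp[inb, 1] - x0; fy <- pp[inb, 2] - y0
    x1 <- pmin(x0 + 1, 127); y1 <- pmin(y0 + 1, 127)
    at <- function(ix, iy) img[cbind(iy + 1, ix + 1)]
    vals[inb] <- (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x1, y0) +
      (1 - fx) * fy * at(x0, y1) + fx * fy * at(x1, y1)
    # last downward crossing: the profile passes tooth -> bone (below the
    # threshold) -> cortical band -> background, so the basal boundary is
    # the final above-to-below transition
    above <- which(vals >= thr)
    k <- max(above) + 1L
    tCross <- tGrid[k - 1] + 0.02 * (vals[k - 1] - thr) / (vals[k - 1] - vals[k])
    truth <- measureIndices(g)[["LTAcb"]]
    expect_lt(abs(tCross - truth), 2 * cfgImg$pixelSpacing)
  }
})

test_that("left-side tooth images are the mirror of their rendering", {
  m <- smallManifest()
  rec <- manifestRecords(m)
  i <- which(rec$toothSite == "#21")[1]
  g <- manifestGeometries(m)[[rec$imageId[i]]]
  expect_true(is.matrix(manifestImages(m)[, , i]))
  # the stored image columns run palatal-to-buccal (mirrored frame)
  expect_false(isTRUE(all.equal(manifestImages(m)[, , i],
                                manifestImages(m)[, , i][, 64:1])))
})
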