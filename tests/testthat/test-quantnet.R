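test_that("configuration validation lists the backbone options", {
  expect_error(modelConfig("vgg16"), "resnext50")
  expect_silent(modelConfig("Resnet50"))
  expect_error(modelConfig(nHeads = 0), "nHeads")
  expect_error(trainConfig(learningRate = -1), "learningRate")
  expect_error(trainConfig(batchSize = 0), "batchSize")
})

test_that("the backbone family members expand to their stage layouts", {
  spec50 <- parityQuant:::.backboneSpec(modelConfig("resnet50"))
  expect_length(spec50$blocks, 16L)                # 3 + 4 + 6 + 3
  expect_equal(spec50$featDim, 2048L)
  expect_true(all(vapply(spec50$blocks, `[[`, character(1), "type") ==
                  "bottleneck"))
  specX <- parityQuant:::.backboneSpec(modelConfig("resnext50"))
  expect_true(all(vapply(specX$blocks, `[[`, integer(1), "groups") == 32L))
  spec101 <- parityQuant:::.backboneSpec(modelConfig("wide-resnet101"))
  expect_length(spec101$blocks, 33L)               # 3 + 4 + 23 + 3
  specS <- parityQuant:::.backboneSpec(modelConfig("small-resnet"))
  expect_equal(specS$featDim, 32L)
})

test_that("one image yields one prediction per head, in order", {
  mod <- buildModel(modelConfig("small-resnet", inputSize = 32), seed = 1)
  imgs <- withr::with_seed(1, array(stats::runif(32 * 32 * 3), c(32, 32, 3)))
  p <- predictIndices(mod, imgs)
  expect_equal(dim(p), c(3L, 9L))
  expect_identical(colnames(p), indexNames())
  # order preserved and single-image path consistent
  p1 <- predictIndices(mod, imgs[, , 2])
  expect_equal(unname(p1[1, ]), unname(p[2, ]))
  # inference is deterministic
  expect_identical(p, predictIndices(mod, imgs))
  expect_error(predictIndices(mod, imgs[1:16, 1:16, ]), "mismatch")
})

test_that("architecturally identical heads with equal parameters agree", {
  mod <- buildModel(modelConfig("small-resnet", inputSize = 32), seed = 2)
  k <- length(mod@params)
  mod@params[[k]]$W[2, ] <- mod@params[[k]]$W[1, ]
  mod@params[[k]]$b[2] <- mod@params[[k]]$b[1]
  img <- withr::with_seed(3, matrix(stats::runif(32 * 32), 32, 32))
  p <- predictIndices(mod, img)
  expect_equal(unname(p[1, 1]), unname(p[1, 2]), tolerance = 1e-12)
})

test_that("perturbing one head's parameters changes only that head", {
  mod <- buildModel(modelConfig("small-resnet", inputSize = 32), seed = 4)
  img <- withr::with_seed(5, matrix(stats::runif(32 * 32), 32, 32))
  base <- predictIndices(mod, img)
  k <- length(mod@params)
  mod@params[[k]]$W[4, ] <- mod@params[[k]]$W[4, ] + 0.5
  pert <- predictIndices(mod, img)
  expect_false(isTRUE(all.equal(base[1, 4], pert[1, 4])))
  expect_equal(base[1, -4], pert[1, -4], tolerance = 1e-12)
})

test_that("zero learning rate freezes the training history", {
  m <- smallManifest()
  fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                    m, trainConfig(learningRate = 0, epochs = 4, seed = 1,
                                   calibrate = FALSE))
  h <- trainingHistory(fit)
  expect_equal(diff(range(h$valMSE)), 0, tolerance = 1e-10)
})

test_that("flip augmentation is live and training is seed-deterministic", {
  m <- smallManifest()
  mk <- function(flip, seed = 11) trainingHistory(
    trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)), m,
               trainConfig(epochs = 3, seed = seed, augmentFlip = flip,
                           calibrate = FALSE)))
  hFlip <- mk(TRUE); hNoFlip <- mk(FALSE)
  expect_false(isTRUE(all.equal(hFlip$trainMSE, hNoFlip$trainMSE)))
  expect_equal(mk(TRUE), hFlip, tolerance = 1e-12)
})

test_that("training errors on empty splits and records its history", {
  m <- smallManifest()
  m2 <- m; m2@records$split[m2@records$split == "validation"] <- "train"
  expect_error(
    trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)), m2,
               trainConfig(epochs = 1)), "validation")
  fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                    m, trainConfig(epochs = 2, seed = 3))
  expect_equal(nrow(trainingHistory(fit)), 2L)
})

test_that("the desk model can overfit a tiny training set", {
  m <- smallManifest()
  m@records$split <- rep("validation", nrow(m@records))
  m@records$split[1:8] <- "train"
  fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                    m, trainConfig(epochs = 300, seed = 5, augmentFlip = FALSE,
                                   calibrate = FALSE))
  h <- trainingHistory(fit)
  expect_lt(h$trainMSE[300], 0.1 * h$trainMSE[1])
})

test_that("converged on four images, training-set MAE is below 0.5 mm", {
  m <- smallManifest()
  m@records$split <- rep("validation", nrow(m@records))
  m@records$split[1:4] <- "train"
  # flip augmentation on, so both orientations are memorized (inference
  # averages the image with its mirror)
  fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                    m, trainConfig(epochs = 600, seed = 6, augmentFlip = TRUE,
                                   calibrate = FALSE))
  pred <- predictIndices(fit, manifestImages(m)[, , 1:4])
  expect_lt(mean(abs(pred - manifestGT(m)[1:4, ])), 0.5)
})

test_that("selection returns the minimum-validation-MSE candidate", {
  m <- smallManifest()
  mc <- modelConfig("small-resnet", inputSize = 64)
  cands <- list(
    list(model = mc, train = trainConfig(learningRate = 0, epochs = 2,
                                         seed = 1, calibrate = FALSE)),
    list(model = mc, train = trainConfig(epochs = 2, seed = 1,
                                         calibrate = FALSE)))
  best <- selectModel(cands, m)
  tab <- attr(best, "selectionTable")
  expect_equal(nrow(tab), 2L)
  expect_equal(which.min(tab$valMSE), 2L)
  expect_equal(best@trainConfig$learningRate, 5e-4)
  # single candidate: returned as-is; identical candidates: first wins
  one <- selectModel(cands[2], m)
  expect_equal(attr(one, "selectionTable")$candidate, 1L)
  twin <- selectModel(cands[c(2, 2)], m)
  expect_equal(which.min(attr(twin, "selectionTable")$valMSE), 1L)
})

test_that("Grad-CAM respects its output contract", {
  mod <- buildModel(modelConfig("small-resnet", inputSize = 32), seed = 6)
  img <- withr::with_seed(7, matrix(stats::runif(32 * 32), 32, 32))
  map <- gradCAM(mod, img, 1)
  expect_equal(dim(map), c(32L, 32L))
  expect_true(all(map >= 0 & map <= 1))
  # zero head weights produce the all-zero map
  k <- length(mod@params)
  mod@params[[k]]$W[3, ] <- 0
  expect_equal(max(gradCAM(mod, img, 3)), 0)
  expect_error(gradCAM(mod, img, 10), "out of range")
  expect_error(gradCAM(mod, img[1:16, 1:16], 1), "mismatch")
})

test_that("a trained desk model beats the train-mean baseline everywhere", {
  fx <- deskModelFit()
  va <- predictManifest(fx$model, fx$manifest, "validation")
  rec <- manifestRecords(fx$manifest)
  trMean <- colMeans(manifestGT(fx$manifest)[rec$split == "train", ])
  maeModel <- colMeans(abs(va$pred - va$gt))
  maeBase <- colMeans(abs(matrix(trMean, nrow(va$gt), 9, byrow = TRUE) - va$gt))
  for (nm in indexNames()) expect_lt(maeModel[[nm]], maeBase[[nm]])
})

test_that("a trained model attends to the bone region", {
  fx <- deskModelFit()
  te <- parityQuant:::.manifestTensors(fx$manifest, "test", 64)
  rec <- manifestRecords(fx$manifest)[te$idx, ]
  i <- which(rec$toothSite %in% c("#11", "#12"))[1]   # unmirrored frame
  img <- te$x[, , i]
  g <- manifestGeometries(fx$manifest)[[rec$imageId[i]]]
  ref <- renderImage(g, imageConfig(size = 64, pixelSpacing = 0.5,
                                    blurSigma = 0, noiseSd = 0))
  mask <- ref > imageConfig()$background + 0.05
  heat <- gradCAM(fx$model, img, "apical2mm")
  expect_gt(mean(heat[mask]), mean(heat[!mask]))
})

test_that("checkpoints round-trip through plain JSON", {
  m <- smallManifest()
  fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                    m, trainConfig(epochs = 2, seed = 9))
  path <- tempfile(fileext = ".json")
  writeCheckpoint(fit, path)
  back <- readCheckpoint(path)
  img <- manifestImages(m)[, , 3]
  expect_equal(predictIndices(back, img), predictIndices(fit, img),
               tolerance = 1e-12)
  expect_equal(trainingHistory(back)$valMSE, trainingHistory(fit)$valMSE)
})
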