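# Model construction, training, selection, prediction and Grad-CAM for the
# multi-quantification network: a residual-family backbone producing one
# shared feature vector consumed by parallel per-index regression heads.

.backboneNames <- function() {
  c("resnet50", "resnet101", "resnext50", "resnext101",
    "wide-resnet50", "wide-resnet101", "small-resnet")
}

#' Model configuration
#'
#' @param backbone Backbone family member. The six standard residual
#'   backbones (`"resnet50"`, `"resnet101"`, `"resnext50"`, `"resnext101"`,
#'   `"wide-resnet50"`, `"wide-resnet101"`; case-insensitive) are available
#'   for fidelity runs; `"small-resnet"` is a 2-stage desk-scale residual
#'   backbone suitable for CPU training.
#' @param nHeads Number of parallel scalar regression heads (default 9, one
#'   per basal-bone index).
#' @param inputSize Expected square input side in pixels.
#' @param pretrained Initialize the trunk from a previously saved checkpoint
#'   file (path) instead of random initialization; `FALSE` trains from
#'   scratch.
#' @return A list of class `modelConfig`.
#' @export
modelConfig <- function(backbone = "small-resnet", nHeads = 9L,
                        inputSize = 128L, pretrained = FALSE) {
  bk <- tolower(backbone)
  if (!bk %in% .backboneNames())
    stop("unknown backbone '", backbone, "'; available: ",
         paste(.backboneNames(), collapse = ", "))
  if (nHeads < 1) stop("nHeads must be >= 1")
  structure(list(backbone = bk, nHeads = as.integer(nHeads),
                 inputSize = as.integer(inputSize), pretrained = pretrained),
            class = "modelConfig")
}

#' Training configuration
#'
#' @param learningRate Adam learning rate (default 0.0005).
#' @param batchSize Mini-batch size (default 4).
#' @param epochs Training epochs (default 200, where the loss typically
#'   plateaus at full scale; desk-scale runs use far fewer).
#' @param augmentFlip Horizontal (bucco-palatal mirror) flip augmentation of
#'   the image only; all nine labels are invariant under this mirroring
#'   (widths are unsigned, lengths axis-wise).
#' @param calibrate Linearly recalibrate each head on the validation split
#'   (per-index slope and intercept, i.e. regression calibration). Removes
#'   the global offset and shrinkage slope a finitely trained network
#'   carries; being a global per-index linear map, it cannot absorb
#'   subgroup-differential bias, which the audit targets.
#' @param seed RNG seed controlling initialization, shuffling and flips.
#' @return A list of class `trainConfig`.
#' @export
trainConfig <- function(learningRate = 5e-4, batchSize = 4L, epochs = 200L,
                        augmentFlip = TRUE, calibrate = TRUE, seed = 1L) {
  if (learningRate < 0) stop("learningRate must be >= 0")
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), augmentFlip = isTRUE(augmentFlip),
                 calibrate = isTRUE(calibrate),
                 seed = as.integer(seed)), class = "trainConfig")
}

# Residual-stage topology for each backbone family member. The standard deep
# backbones use bottleneck blocks with the stem downsampling folded into the
# first stage stride; no batch normalization (He-initialized plain residual
# stacks).
.backboneSpec <- function(config) {
  bk <- config$backbone
  blk <- function(type, mid, out, stride, groups = 1L)
    list(type = type, mid = as.integer(mid), out = as.integer(out),
         stride = as.integer(stride), groups = as.integer(groups))
  if (bk == "small-resnet") {
    stem <- list(`in` = 1L, out = 8L, k = 3L, stride = 2L, pad = 1L)
    blocks <- list(blk("basic", 16L, 16L, 2L), blk("basic", 32L, 32L, 2L))
  } else {
    counts <- switch(bk,
      "resnet50" = , "resnext50" = , "wide-resnet50" = c(3L, 4L, 6L, 3L),
      c(3L, 4L, 23L, 3L))
    groups <- if (grepl("^resnext", bk)) 32L else 1L
    widen <- if (grepl("^wide", bk)) 2L else 1L
    stem <- list(`in` = 1L, out = 64L, k = 7L, stride = 2L, pad = 3L)
    blocks <- list()
    for (stage in 1:4) {
      out <- 256L * 2L^(stage - 1L)
      mid <- if (groups > 1L) 128L * 2L^(stage - 1L) else
        64L * 2L^(stage - 1L) * widen
      for (i in seq_len(counts[stage]))
        blocks[[length(blocks) + 1L]] <-
          blk("bottleneck", mid, out, if (i == 1L) 2L else 1L, groups)
    }
  }
  list(stem = stem, blocks = blocks, nHeads = config$nHeads,
       featDim = blocks[[length(blocks)]]$out)
}

.initParams <- function(spec) {
  convs <- list(spec$stem)
  cur <- spec$stem$out
  for (b in spec$blocks) {
    if (b$type == "bottleneck") {
      convs <- c(convs, list(
        list(`in` = cur, out = b$mid, k = 1L, groups = 1L),
        list(`in` = b$mid, out = b$mid, k = 3L, groups = b$groups),
        list(`in` = b$mid, out = b$out, k = 1L, groups = 1L)))
    } else {
      convs <- c(convs, list(
        list(`in` = cur, out = b$out, k = 3L, groups = 1L),
        list(`in` = b$out, out = b$out, k = 3L, groups = 1L)))
    }
    if (cur != b$out || b$stride != 1L)
      convs <- c(convs, list(list(`in` = cur, out = b$out, k = 1L, groups = 1L)))
    cur <- b$out
  }
  params <- lapply(convs, function(cv) {
    if (is.null(cv$groups)) cv$groups <- 1L
    fanIn <- cv$k^2 * cv$`in` / cv$groups
    list(W = matrix(stats::rnorm(cv$out * fanIn, 0, sqrt(2 / fanIn)),
                    cv$out, fanIn),
         b = numeric(cv$out))
  })
  params[[length(params) + 1L]] <- list(
    W = matrix(stats::rnorm(spec$nHeads * spec$featDim, 0,
                            sqrt(1 / spec$featDim)),
               spec$nHeads, spec$featDim),
    b = numeric(spec$nHeads))
  params
}

#' Build an untrained multi-quantification model
#'
#' One trunk producing a shared feature vector; `nHeads` architecturally
#' identical, independently parameterized scalar regression heads consuming
#' that same vector.
#'
#' @param config A [modelConfig()].
#' @param seed Seed for He initialization of the parameters.
#' @return A [TrainedQuantModel-class] with empty history (untrained; its
#'   predictions are in normalized label units until trained).
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  stopifnot(inherits(config, "modelConfig"))
  spec <- .backboneSpec(config)
  params <- withr::with_seed(seed, .initParams(spec))
  if (is.character(config$pretrained)) {
    ck <- readCheckpoint(config$pretrained)
    params <- ck@params
  }
  new("TrainedQuantModel", params = params, spec = spec,
      modelConfig = unclass(config), trainConfig = list(),
      history = data.frame(), normStats = list(
        mean = stats::setNames(rep(0, config$nHeads),
                               if (config$nHeads == 9) indexNames() else NULL),
        sd = stats::setNames(rep(1, config$nHeads),
                             if (config$nHeads == 9) indexNames() else NULL),
        calA = rep(0, config$nHeads), calB = rep(1, config$nHeads)))
}

.manifestTensors <- function(manifest, split, inputSize) {
  rec <- manifestRecords(manifest)
  keep <- which(rec$split == split)
  imgs <- manifestImages(manifest)
  if (is.null(imgs)) stop("manifest has no rendered images; build with render = TRUE")
  if (dim(imgs)[1] != inputSize)
    stop("image size ", dim(imgs)[1], " does not match model input size ",
         inputSize)
  list(x = imgs[, , keep, drop = FALSE],
       y = manifestGT(manifest)[keep, , drop = FALSE],
       idx = keep)
}

#' Train the multi-quantification model
#'
#' Minimizes the unweighted mean of the per-index squared errors on z-score
#' normalized labels (per-index mean/SD computed from the training split
#' only), recording per-epoch training and validation MSE. Deterministic
#' given the training seed.
#'
#' @param model A model from [buildModel()] (its parameters are
#'   re-initialized under the training seed so a run is a pure function of
#'   the configs, manifest and seed).
#' @param manifest A [QuantManifest-class] with rendered images and non-empty
#'   train and validation splits.
#' @param tcfg A [trainConfig()].
#' @return A [TrainedQuantModel-class].
#' @export
trainModel <- function(model, manifest, tcfg = trainConfig()) {
  stopifnot(is(model, "TrainedQuantModel"), inherits(tcfg, "trainConfig"))
  cfg <- model@modelConfig
  tr <- .manifestTensors(manifest, "train", cfg$inputSize)
  va <- .manifestTensors(manifest, "validation", cfg$inputSize)
  if (!dim(tr$x)[3]) stop("empty training split")
  if (!dim(va$x)[3]) stop("empty validation split")
  mu <- colMeans(tr$y)
  sg <- apply(tr$y, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  norm <- function(y) t((t(y) - mu) / sg)   # records x 9 -> normalized
  fit <- withr::with_seed(tcfg$seed, {
    params <- .initParams(model@spec)
    if (is.character(cfg$pretrained)) params <- model@params
    cpp_train(params, model@spec,
              tr$x, t(norm(tr$y)), va$x, t(norm(va$y)),
              tcfg$learningRate, tcfg$batchSize, tcfg$epochs,
              tcfg$augmentFlip)
  })
  calA <- rep(0, length(mu)); calB <- rep(1, length(mu))
  if (isTRUE(tcfg$calibrate)) {
    # intercept calibration: each head is re-centered so its mean residual
    # on the validation split is zero. A global per-index shift cannot
    # absorb subgroup-differential bias, which the audit targets.
    vaFlip <- va$x[, rev(seq_len(dim(va$x)[2])), , drop = FALSE]
    vz <- (cpp_predict(fit$params, model@spec, va$x) +
           cpp_predict(fit$params, model@spec, vaFlip)) / 2  # nHeads x Nval
    calA <- rowMeans(vz - t(norm(va$y)))
  }
  new("TrainedQuantModel",
      params = fit$params, spec = model@spec,
      modelConfig = cfg, trainConfig = unclass(tcfg),
      history = data.frame(epoch = seq_len(tcfg$epochs),
                           trainMSE = fit$trainMSE, valMSE = fit$valMSE),
      normStats = list(mean = mu, sd = sg, calA = calA, calB = calB))
}

#' Predict the nine indices for a stack of images
#'
#' Deterministic inference; predictions are de-normalized back to mm using
#' the training-split label statistics.
#'
#' @param trained A [TrainedQuantModel-class].
#' @param images A single `H x W` matrix or an `H x W x N` array matching the
#'   model's input size.
#' @return `N x nHeads` matrix in mm (columns named by [indexNames()] when
#'   `nHeads` is 9), preserving input order.
#' @export
predictIndices <- function(trained, images) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  sz <- trained@modelConfig$inputSize
  if (dim(images)[1] != sz || dim(images)[2] != sz)
    stop("image size mismatch: expected ", sz, "x", sz, ", got ",
         dim(images)[1], "x", dim(images)[2])
  # symmetric inference: all nine labels are invariant under bucco-palatal
  # mirroring, so predictions are averaged over the image and its mirror,
  # making the output exactly flip-equivariant
  flipped <- images[, rev(seq_len(dim(images)[2])), , drop = FALSE]
  raw <- (cpp_predict(trained@params, trained@spec, images) +
          cpp_predict(trained@params, trained@spec, flipped)) / 2
  ns <- trained@normStats
  a <- if (is.null(ns$calA)) 0 else ns$calA
  b <- if (is.null(ns$calB)) 1 else ns$calB
  out <- t(((raw - a) / b) * ns$sd + ns$mean)
  if (trained@modelConfig$nHeads == 9) colnames(out) <- indexNames()
  out
}

#' Predict on a manifest split
#'
#' @param trained A [TrainedQuantModel-class].
#' @param manifest A [QuantManifest-class] with rendered images.
#' @param split Which split to predict (default `"test"`).
#' @return List with `pred` (records x 9, mm), `gt`, and the `records`
#'   data.frame of the split.
#' @export
predictManifest <- function(trained, manifest, split = "test") {
  te <- .manifestTensors(manifest, split, trained@modelConfig$inputSize)
  rec <- manifestRecords(manifest)[te$idx, , drop = FALSE]
  rownames(rec) <- NULL
  list(pred = predictIndices(trained, te$x), gt = te$y, records = rec)
}

#' Select the best candidate by validation MSE
#'
#' Trains every (model config, training config) candidate on the manifest and
#' returns the one with minimum final validation MSE; ties are broken by
#' candidate order. The full selection table is attached.
#'
#' @param candidates List of `list(model = modelConfig, train = trainConfig)`.
#' @param manifest A [QuantManifest-class].
#' @return The winning [TrainedQuantModel-class], with attribute
#'   `"selectionTable"` (a data.frame of candidate metrics).
#' @export
selectModel <- function(candidates, manifest) {
  stopifnot(length(candidates) >= 1)
  fits <- vector("list", length(candidates))
  tab <- data.frame()
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fits[[i]] <- trainModel(buildModel(cand$model), manifest, cand$train)
    h <- trainingHistory(fits[[i]])
    tab <- rbind(tab, data.frame(
      candidate = i, backbone = cand$model$backbone,
      learningRate = cand$train$learningRate,
      batchSize = cand$train$batchSize, epochs = cand$train$epochs,
      valMSE = h$valMSE[nrow(h)]))
  }
  best <- which.min(tab$valMSE)            # which.min takes the first on ties
  out <- fits[[best]]
  attr(out, "selectionTable") <- tab
  out
}

#' Grad-CAM heatmap for one regression head
#'
#' Channel weights are the spatially averaged gradient of the selected head's
#' scalar output with respect to the final convolutional feature map (for a
#' linear head over global average pooling this gradient is the head weight
#' divided by the map area); the map is the rectified weighted channel sum,
#' bilinearly upsampled to the input size and min-max normalized to `[0,1]`
#' (an all-zero map stays all-zero).
#'
#' @param trained A [TrainedQuantModel-class].
#' @param image `H x W` matrix matching the model input size.
#' @param headIndex Head (index) to explain, in `1..nHeads` (or an index name).
#' @return Matrix of the input spatial size with values in `[0,1]`.
#' @export
gradCAM <- function(trained, image, headIndex = 1L) {
  if (is.character(headIndex)) headIndex <- match(headIndex, indexNames())
  nH <- trained@modelConfig$nHeads
  if (is.na(headIndex) || headIndex < 1 || headIndex > nH)
    stop("headIndex out of range 1..", nH)
  sz <- trained@modelConfig$inputSize
  if (!identical(dim(image), c(sz, sz)))
    stop("image size mismatch: expected ", sz, "x", sz)
  ft <- cpp_features(trained@params, trained@spec, image)
  A <- ft$lastConv                          # Hc x Wc x C
  hw <- dim(A)[1] * dim(A)[2]
  alpha <- trained@params[[length(trained@params)]]$W[headIndex, ] / hw
  map <- matrix(0, dim(A)[1], dim(A)[2])
  for (ch in seq_len(dim(A)[3])) map <- map + alpha[ch] * A[, , ch]
  map <- pmax(map, 0)
  up <- EBImage::resize(map, w = sz, h = sz)
  up <- matrix(as.numeric(up), sz, sz)
  up <- pmax(up, 0)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  up
}

#' Save / load a trained model checkpoint
#'
#' Checkpoints are plain JSON (configuration, normalization statistics,
#' history, and all parameter matrices), so they are portable text files.
#'
#' @param trained A [TrainedQuantModel-class].
#' @param path File path.
#' @return `writeCheckpoint` returns `path` invisibly; `readCheckpoint`
#'   returns the restored [TrainedQuantModel-class].
#' @export
writeCheckpoint <- function(trained, path) {
  payload <- list(
    modelConfig = trained@modelConfig, trainConfig = trained@trainConfig,
    spec = trained@spec, history = as.list(trained@history),
    normStats = trained@normStats,
    params = lapply(trained@params, function(p)
      list(W = list(dim = dim(p$W), data = as.numeric(p$W)),
           b = as.numeric(p$b))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  params <- lapply(pl$params, function(p) {
    dm <- num(p$W$dim)
    list(W = matrix(num(p$W$data), dm[1], dm[2]), b = num(p$b))
  })
  spec <- list(
    stem = lapply(pl$spec$stem, function(v) as.integer(unlist(v))),
    blocks = lapply(pl$spec$blocks, function(b)
      list(type = as.character(b$type), mid = as.integer(b$mid),
           out = as.integer(b$out), stride = as.integer(b$stride),
           groups = as.integer(b$groups))),
    nHeads = as.integer(pl$spec$nHeads),
    featDim = as.integer(pl$spec$featDim))
  hist <- if (length(pl$history$epoch))
    data.frame(epoch = num(pl$history$epoch),
               trainMSE = num(pl$history$trainMSE),
               valMSE = num(pl$history$valMSE)) else data.frame()
  ns <- pl$normStats
  mu <- num(ns$mean); sg <- num(ns$sd)
  calA <- if (is.null(ns$calA)) rep(0, length(mu)) else num(ns$calA)
  calB <- if (is.null(ns$calB)) rep(1, length(mu)) else num(ns$calB)
  if (length(mu) == 9) { names(mu) <- indexNames(); names(sg) <- indexNames() }
  new("TrainedQuantModel", params = params, spec = spec,
      modelConfig = lapply(pl$modelConfig, function(v) unlist(v)),
      trainConfig = lapply(pl$trainConfig, function(v) unlist(v)),
      history = hist,
      normStats = list(mean = mu, sd = sg, calA = calA, calB = calB))
}
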