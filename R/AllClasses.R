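#' @import methods
NULL

#' Canonical names of the nine basal-bone indices
#'
#' Four lengths along the tooth axis (TA) and bone axis (BA) — crest-to-basal
#' (`cb`) and apex-to-basal (`ab`) — and five bucco-palatal widths: the
#' bucco-palatal width 2 mm apical to the apex, and the buccal/palatal
#' contour-to-axis widths at the basal level of each axis.
#'
#' @return Character vector of length 9 in the fixed canonical order.
#' @export
#' @examples
#' indexNames()
indexNames <- function() {
  c("LTAcb", "LTAab", "LBAcb", "LBAab",
    "apical2mm", "WTAB", "WTAP", "WBAB", "WBAP")
}

#' Validate a vector of the nine basal-bone indices
#'
#' Checks canonical naming/ordering, finiteness and non-negativity of a
#' 9-vector of measurements in millimetres.
#'
#' @param x Named numeric vector of length 9.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validateIndexVector <- function(x) {
  if (!is.numeric(x) || length(x) != 9L)
    stop("an index vector must be a numeric vector of length 9")
  if (!identical(names(x), indexNames()))
    stop("index vector names must be, in order: ",
         paste(indexNames(), collapse = ", "))
  if (any(!is.finite(x)))
    stop("all 9 index values must be finite")
  if (any(x < 0))
    stop("all 9 index values must be non-negative (lengths in mm)")
  invisible(x)
}

setClass("DirectedLine",
  representation(point = "numeric", dir = "numeric"),
  validity = function(object) {
    if (length(object@point) != 2L || length(object@dir) != 2L)
      return("point and dir must be length-2 numeric")
    n <- sqrt(sum(object@dir^2))
    if (abs(n - 1) > 1e-6)
      return("direction must be unit-norm (tolerance 1e-6)")
    TRUE
  })

#' Construct a directed line
#'
#' A 2D line given by a point on it and a unit direction. Directions are
#' normalized on construction; a zero direction is an error.
#'
#' @param point Numeric length-2 point (mm).
#' @param dir Numeric length-2 direction; normalized internally.
#' @return A `DirectedLine` object.
#' @export
directedLine <- function(point, dir) {
  n <- sqrt(sum(dir^2))
  if (!is.finite(n) || n == 0) stop("direction must be non-zero")
  new("DirectedLine", point = as.numeric(point), dir = as.numeric(dir) / n)
}

#' SagittalGeometry: a tooth + alveolar bone cross-section
#'
#' Landmark/contour representation of one mid-facial sagittal section in
#' continuous millimetre coordinates (y increasing apically): the alveolar
#' crest reference point and root apex on the tooth axis, the directed tooth
#' and bone axes, the basal-bone boundary polyline (toward the nasal floor)
#' and the buccal and palatal bone contours.
#'
#' Invariants enforced by the validity method: unit-norm axis directions, the
#' apex lying on the tooth axis (1e-6 mm), the buccal and palatal contours on
#' opposite sides of the tooth axis, and the basal boundary crossing each axis
#' exactly once.
#'
#' @slot crest Numeric length-2, alveolar crest reference point (mm).
#' @slot apex Numeric length-2, root apex (mm).
#' @slot toothAxis,boneAxis `DirectedLine` axes; the direction points apically.
#' @slot basalBoundary,buccalContour,palatalContour n x 2 matrices of polyline
#'   vertices (mm).
#' @slot pixelSpacing Numeric scalar, mm per pixel for image-space conversion.
#' @export
setClass("SagittalGeometry",
  representation(
    crest = "numeric",
    apex = "numeric",
    toothAxis = "DirectedLine",
    boneAxis = "DirectedLine",
    basalBoundary = "matrix",
    buccalContour = "matrix",
    palatalContour = "matrix",
    pixelSpacing = "numeric"),
  validity = function(object) .validSagittalGeometry(object))

#' @describeIn SagittalGeometry-class Constructor.
#' @param crest,apex Length-2 points (mm).
#' @param toothAxis,boneAxis `DirectedLine` objects (see [directedLine()]).
#' @param basalBoundary,buccalContour,palatalContour n x 2 vertex matrices (mm).
#' @param pixelSpacing mm per pixel.
#' @param validate Run the validity checks (default `TRUE`).
#' @return A `SagittalGeometry` object.
#' @export
sagittalGeometry <- function(crest, apex, toothAxis, boneAxis,
                             basalBoundary, buccalContour, palatalContour,
                             pixelSpacing = 0.25, validate = TRUE) {
  obj <- new("SagittalGeometry",
    crest = as.numeric(crest), apex = as.numeric(apex),
    toothAxis = toothAxis, boneAxis = boneAxis,
    basalBoundary = .asPolyline(basalBoundary),
    buccalContour = .asPolyline(buccalContour),
    palatalContour = .asPolyline(palatalContour),
    pixelSpacing = as.numeric(pixelSpacing))
  if (validate) validObject(obj)
  obj
}

.asPolyline <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L || nrow(m) < 2L)
    stop("polylines must be n x 2 matrices with n >= 2")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

setMethod("show", "SagittalGeometry", function(object) {
  cat("SagittalGeometry (mm coordinates, y apical)\n")
  cat(sprintf("  crest: (%.3f, %.3f)   apex: (%.3f, %.3f)\n",
              object@crest[1], object@crest[2],
              object@apex[1], object@apex[2]))
  ang <- function(a) 180 / pi * atan2(a@dir[1], a@dir[2])
  cat(sprintf("  tooth axis tilt: %.2f deg   bone axis tilt: %.2f deg\n",
              ang(object@toothAxis), ang(object@boneAxis)))
  cat(sprintf("  basal boundary: %d vertices; contours: %d buccal / %d palatal\n",
              nrow(object@basalBoundary), nrow(object@buccalContour),
              nrow(object@palatalContour)))
  cat(sprintf("  pixel spacing: %.4g mm/px\n", object@pixelSpacing))
})

#' QuantManifest: a patient-wise dataset of sagittal sections
#'
#' Holds one record per (patient, tooth site): demographics, the generating
#' or annotated [SagittalGeometry-class], the 9 ground-truth indices, the
#' patient-wise train/validation/test split label, and (optionally) the
#' rendered grayscale images.
#'
#' @slot records `data.frame` with columns `imageId`, `patientId`, `sex`,
#'   `age`, `ageGroup`, `toothSite`, `split`.
#' @slot gt Numeric matrix, images x 9, ground-truth indices in mm
#'   (columns in [indexNames()] order, rownames = image ids).
#' @slot geometries Named list of `SagittalGeometry` (by image id); may be
#'   empty for externally measured datasets.
#' @slot images Numeric array H x W x N of rendered images in `[0,1]`, or a
#'   0-extent array when not rendered.
#' @slot config List: the generating configuration (empty for real data).
#' @slot seed Integer seed the manifest was generated under (NA for real data).
#' @export
setClass("QuantManifest",
  representation(
    records = "data.frame",
    gt = "matrix",
    geometries = "list",
    images = "array",
    config = "list",
    seed = "integer"),
  validity = function(object) .validQuantManifest(object))

.validQuantManifest <- function(object) {
  rec <- object@records
  need <- c("imageId", "patientId", "sex", "age", "ageGroup", "toothSite", "split")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@gt) != nrow(rec))
    return("gt must have one row per record")
  if (!identical(colnames(object@gt), indexNames()))
    return("gt columns must be the canonical index names")
  if (any(!is.finite(object@gt)))
    return("every record needs 9 finite ground-truth values")
  if (!all(rec$split %in% c("train", "validation", "test")))
    return("split must be train/validation/test")
  sp <- tapply(rec$split, rec$patientId, function(s) length(unique(s)))
  if (any(sp > 1L))
    return("split must be patient-wise: no patient may span splits")
  if (length(object@images) &&
      dim(object@images)[3] != nrow(rec))
    return("images array must have one slice per record")
  TRUE
}

setMethod("show", "QuantManifest", function(object) {
  rec <- object@records
  cat(sprintf("QuantManifest: %d images from %d patients\n",
              nrow(rec), length(unique(rec$patientId))))
  tb <- table(factor(rec$split, c("train", "validation", "test")))
  cat(sprintf("  split (images): train %d / validation %d / test %d\n",
              tb[1], tb[2], tb[3]))
  cat(sprintf("  sex (patients): %s\n",
      paste(names(table(rec$sex[!duplicated(rec$patientId)])),
            table(rec$sex[!duplicated(rec$patientId)]),
            sep = "=", collapse = ", ")))
  cat(sprintf("  images: %s; geometries: %d\n",
      if (length(object@images)) paste(dim(object@images), collapse = "x") else "none",
      length(object@geometries)))
})

#' @describeIn QuantManifest-class Records accessor.
#' @param x A `QuantManifest`.
#' @export
manifestRecords <- function(x) x@records

#' @describeIn QuantManifest-class Ground-truth matrix accessor (images x 9, mm).
#' @export
manifestGT <- function(x) x@gt

#' @describeIn QuantManifest-class Image array accessor (H x W x N), or `NULL`
#'   if the manifest was built without rendering.
#' @export
manifestImages <- function(x) if (length(x@images)) x@images else NULL

#' @describeIn QuantManifest-class Geometry list accessor.
#' @export
manifestGeometries <- function(x) x@geometries

#' Subset a manifest by record index
#'
#' Keeps records, ground truth, geometries and images aligned.
#'
#' @param x A [QuantManifest-class].
#' @param i Integer or logical index over records.
#' @return A `QuantManifest` with the selected records.
#' @export
subsetManifest <- function(x, i) {
  rec <- x@records[i, , drop = FALSE]
  rownames(rec) <- NULL
  imgs <- if (length(x@images)) x@images[, , i, drop = FALSE] else x@images
  geoms <- if (length(x@geometries)) x@geometries[rec$imageId] else list()
  new("QuantManifest",
      records = rec,
      gt = x@gt[i, , drop = FALSE],
      geometries = geoms,
      images = if (length(x@images)) imgs else array(numeric(0), c(0, 0, 0)),
      config = x@config, seed = x@seed)
}

#' TrainedQuantModel: a fitted multi-quantification network
#'
#' A residual-family backbone with `nHeads` parallel scalar regression heads
#' over a fully shared trunk feature vector, together with its training
#' history and the per-index label-normalization statistics (computed from the
#' training split only; predictions are de-normalized back to mm).
#'
#' @slot params List of layer parameter matrices.
#' @slot spec List describing the network topology.
#' @slot modelConfig,trainConfig The configurations used.
#' @slot history `data.frame` with one row per completed epoch
#'   (`epoch`, `trainMSE`, `valMSE`; MSE in normalized label units).
#' @slot normStats List with `mean` and `sd`, each length-9 named numeric.
#' @export
setClass("TrainedQuantModel",
  representation(
    params = "list",
    spec = "list",
    modelConfig = "list",
    trainConfig = "list",
    history = "data.frame",
    normStats = "list"))

setMethod("show", "TrainedQuantModel", function(object) {
  cat(sprintf("TrainedQuantModel: backbone '%s', %d heads, input %dpx\n",
              object@modelConfig$backbone, object@modelConfig$nHeads,
              object@modelConfig$inputSize))
  h <- object@history
  if (nrow(h)) {
    cat(sprintf("  epochs: %d; final train MSE %.4g, validation MSE %.4g (normalized)\n",
                nrow(h), h$trainMSE[nrow(h)], h$valMSE[nrow(h)]))
  } else cat("  untrained\n")
})

#' @describeIn TrainedQuantModel-class Per-epoch training history accessor.
#' @param x A `TrainedQuantModel`.
#' @export
trainingHistory <- function(x) x@history

#' AuditReport: subgroup bias audit result
#'
#' For each demographic attribute, level and index, the paired Wilcoxon
#' signed-rank p-value of prediction minus ground truth in that stratum; the
#' per-attribute disparity score (max minus min of significant-index counts
#' over adequately powered levels); and the resulting sensitive attribute.
#'
#' @slot pValues Nested list: attribute -> level -> named length-9 numeric.
#' @slot counts Nested list: attribute -> named integer of significant-index
#'   counts per level (NA for underpowered strata).
#' @slot underpowered Nested list: attribute -> character vector of levels
#'   excluded for having fewer records than the minimum.
#' @slot disparity Named numeric, per-attribute disparity score.
#' @slot sensitiveAttribute Character, the selected attribute.
#' @slot noDisparity Logical: `TRUE` when no attribute reaches the disparity
#'   threshold (the sensitive attribute is then only the documented tie-break).
#' @slot alpha,threshold Numerics: significance level and disparity threshold.
#' @slot attributes Character, the audited attributes in order.
#' @export
setClass("AuditReport",
  representation(
    pValues = "list",
    counts = "list",
    underpowered = "list",
    disparity = "numeric",
    sensitiveAttribute = "character",
    noDisparity = "logical",
    alpha = "numeric",
    threshold = "numeric",
    attributes = "character"),
  validity = function(object) {
    ps <- unlist(object@pValues)
    if (length(ps) && (any(ps < 0 | ps > 1, na.rm = TRUE)))
      return("all p-values must lie in [0,1]")
    if (!(object@sensitiveAttribute %in% object@attributes))
      return("sensitiveAttribute must be one of the audited attributes")
    TRUE
  })

setMethod("show", "AuditReport", function(object) {
  cat("AuditReport (paired Wilcoxon per stratum, alpha =",
      format(object@alpha), ")\n")
  for (a in object@attributes) {
    cnt <- object@counts[[a]]
    cat(sprintf("  %-10s disparity %s | counts: %s\n", a,
        format(object@disparity[[a]]),
        paste(names(cnt), ifelse(is.na(cnt), "underpowered", cnt),
              sep = "=", collapse = ", ")))
  }
  cat("  sensitive attribute:", object@sensitiveAttribute,
      if (object@noDisparity) "(no attribute exceeds disparity threshold)" else "",
      "\n")
})

#' @describeIn AuditReport-class The selected sensitive attribute.
#' @param x An `AuditReport`.
#' @export
sensitiveAttribute <- function(x) x@sensitiveAttribute

#' @describeIn AuditReport-class Per-attribute disparity scores.
#' @export
auditDisparity <- function(x) x@disparity

#' @describeIn AuditReport-class Significant-index counts per attribute level.
#' @export
auditCounts <- function(x) x@counts
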