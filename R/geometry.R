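# Measurement operators for the 4 length and 5 width indices of the
# maxillary alveolar basal bone, on continuous-mm sagittal geometry.

.degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("degenerateGeometryError", "error")))
}

# Parameters t (along the directed line p + t*d) of all crossings of the line
# with a polyline, walking its segments. Segments are treated half-open at
# their far vertex so a crossing at a shared vertex is counted once.
.linePolylineParams <- function(point, dir, poly, tol = 1e-12) {
  ts <- numeric(0)
  n <- nrow(poly)
  px <- point[1]; py <- point[2]; dx <- dir[1]; dy <- dir[2]
  for (k in seq_len(n - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    den <- dx * ey - dy * ex              # cross(d, e)
    if (abs(den) < tol * max(1, abs(ex), abs(ey))) next  # parallel segment
    rx <- a[1] - px; ry <- a[2] - py
    t <- (rx * ey - ry * ex) / den        # cross(r, e) / cross(d, e)
    u <- (rx * dy - ry * dx) / den        # cross(r, d) / cross(d, e)
    lastSeg <- (k == n - 1L)
    if (u >= -1e-12 && (u < 1 - 1e-12 || (lastSeg && u <= 1 + 1e-12)))
      ts <- c(ts, t)
  }
  ts
}

.sideOfLine <- function(point, dir, pts) {
  # sign of cross(dir, pts - point): +1 one side, -1 the other
  sign(dir[1] * (pts[, 2] - point[2]) - dir[2] * (pts[, 1] - point[1]))
}

.validSagittalGeometry <- function(object) {
  ta <- object@toothAxis; ba <- object@boneAxis
  # apex on the tooth axis within 1e-6 mm
  v <- object@apex - ta@point
  perp <- abs(v[1] * ta@dir[2] - v[2] * ta@dir[1])
  if (perp > 1e-6)
    return("apex must lie on the tooth axis (tolerance 1e-6 mm)")
  sb <- .sideOfLine(ta@point, ta@dir, object@buccalContour)
  sp <- .sideOfLine(ta@point, ta@dir, object@palatalContour)
  if (any(sb == 0) || any(sp == 0) ||
      length(unique(sb)) != 1L || length(unique(sp)) != 1L ||
      sb[1] == sp[1])
    return("buccal and palatal contours must lie strictly on opposite sides of the tooth axis")
  for (ax in list(tooth = ta, bone = ba)) {
    ts <- .linePolylineParams(ax@point, ax@dir, object@basalBoundary)
    if (length(ts) != 1L)
      return("basal boundary must intersect each axis exactly once")
  }
  TRUE
}

#' Measurement conventions for the nine indices
#'
#' @param widthLevelOffset Offset in mm along each axis, relative to its
#'   basal-boundary intersection, at which the four axis-referenced widths
#'   (WTAB/WTAP/WBAB/WBAP) are taken. Default 0: at the basal level.
#' @param apicalOffset Offset in mm beyond the apex (away from the crown)
#'   for the bucco-palatal width `apical2mm`. Default 2.
#' @return A list of conventions, to pass to [measureIndices()].
#' @export
measureConfig <- function(widthLevelOffset = 0, apicalOffset = 2) {
  stopifnot(is.finite(widthLevelOffset), is.finite(apicalOffset))
  list(widthLevelOffset = widthLevelOffset, apicalOffset = apicalOffset)
}

#' Length along an axis to the basal boundary
#'
#' Projects `from` onto the directed axis and returns the distance along the
#' axis from that projection to the unique axis/basal-boundary crossing.
#'
#' @param geometry A [SagittalGeometry-class].
#' @param axis A `DirectedLine` (typically the tooth or bone axis).
#' @param from Length-2 point (mm) whose axis projection is the start.
#' @param axisName Label used in degenerate-geometry error messages.
#' @return Non-negative length in mm.
#' @export
lengthAlongAxis <- function(geometry, axis, from, axisName = "axis") {
  ts <- .linePolylineParams(axis@point, axis@dir, geometry@basalBoundary)
  if (length(ts) != 1L)
    .degenerate("degenerate geometry: %s crosses the basal boundary %d times (need exactly 1)",
                axisName, length(ts))
  t0 <- sum((from - axis@point) * axis@dir)
  abs(ts - t0)
}

#' Bucco-palatal width at a level along an axis
#'
#' Takes the perpendicular to `axis` at parameter `level` (mm along the
#' directed axis from its base point) and measures, along that perpendicular,
#' either the buccal-to-palatal contour distance (`side = "both"`) or the
#' distance from the requested contour to the axis. When a contour is crossed
#' more than once the crossing nearest the axis is used.
#'
#' @inheritParams lengthAlongAxis
#' @param level Offset in mm along the axis.
#' @param side One of `"both"`, `"buccal"`, `"palatal"`.
#' @return Non-negative width in mm.
#' @export
widthAtLevel <- function(geometry, axis, level, side = c("both", "buccal", "palatal")) {
  side <- match.arg(side)
  p <- axis@point + level * axis@dir
  n <- c(axis@dir[2], -axis@dir[1])          # perpendicular direction
  hit <- function(contour, label) {
    ts <- .linePolylineParams(p, n, contour)
    if (!length(ts))
      .degenerate("degenerate geometry: perpendicular at level %.3f mm misses the %s contour",
                  level, label)
    ts[which.min(abs(ts))]
  }
  switch(side,
    both = {
      tb <- hit(geometry@buccalContour, "buccal")
      tp <- hit(geometry@palatalContour, "palatal")
      abs(tb - tp)
    },
    buccal = abs(hit(geometry@buccalContour, "buccal")),
    palatal = abs(hit(geometry@palatalContour, "palatal")))
}

#' Measure the nine basal-bone indices of a sagittal geometry
#'
#' Computes, deterministically, the four lengths (crest/apex to the basal
#' boundary along the tooth and bone axes) and five widths (bucco-palatal
#' width 2 mm apical to the apex; buccal and palatal contour-to-axis widths
#' at the basal level of each axis) defined on a [SagittalGeometry-class].
#'
#' @param geometry A valid [SagittalGeometry-class].
#' @param config Conventions from [measureConfig()].
#' @return Named numeric vector of length 9 in [indexNames()] order (mm).
#' @export
#' @examples
#' g <- sagittalGeometry(
#'   crest = c(0, 0), apex = c(0, 13),
#'   toothAxis = directedLine(c(0, 0), c(0, 1)),
#'   boneAxis = directedLine(c(0, 0), c(0, 1)),
#'   basalBoundary = rbind(c(-9, 21), c(9, 21)),
#'   buccalContour = rbind(c(-5, -2), c(-5, 26)),
#'   palatalContour = rbind(c(5, -2), c(5, 26)))
#' measureIndices(g)
measureIndices <- function(geometry, config = measureConfig()) {
  ta <- geometry@toothAxis; ba <- geometry@boneAxis
  withIndex <- function(indexName, expr) {
    tryCatch(expr, degenerateGeometryError = function(e)
      .degenerate("index %s: %s", indexName, conditionMessage(e)))
  }
  tBasalT <- withIndex("LTAcb", {
    ts <- .linePolylineParams(ta@point, ta@dir, geometry@basalBoundary)
    if (length(ts) != 1L)
      .degenerate("tooth axis crosses the basal boundary %d times", length(ts))
    ts
  })
  tBasalB <- withIndex("LBAcb", {
    ts <- .linePolylineParams(ba@point, ba@dir, geometry@basalBoundary)
    if (length(ts) != 1L)
      .degenerate("bone axis crosses the basal boundary %d times", length(ts))
    ts
  })
  tApex <- sum((geometry@apex - ta@point) * ta@dir)
  apicalSign <- if (tApex >= sum((geometry@crest - ta@point) * ta@dir)) 1 else -1

  out <- c(
    LTAcb = withIndex("LTAcb", lengthAlongAxis(geometry, ta, geometry@crest, "tooth axis")),
    LTAab = withIndex("LTAab", lengthAlongAxis(geometry, ta, geometry@apex, "tooth axis")),
    LBAcb = withIndex("LBAcb", lengthAlongAxis(geometry, ba, geometry@crest, "bone axis")),
    LBAab = withIndex("LBAab", lengthAlongAxis(geometry, ba, geometry@apex, "bone axis")),
    apical2mm = withIndex("apical2mm",
      widthAtLevel(geometry, ta, tApex + apicalSign * config$apicalOffset, "both")),
    WTAB = withIndex("WTAB",
      widthAtLevel(geometry, ta, tBasalT + config$widthLevelOffset, "buccal")),
    WTAP = withIndex("WTAP",
      widthAtLevel(geometry, ta, tBasalT + config$widthLevelOffset, "palatal")),
    WBAB = withIndex("WBAB",
      widthAtLevel(geometry, ba, tBasalB + config$widthLevelOffset, "buccal")),
    WBAP = withIndex("WBAP",
      widthAtLevel(geometry, ba, tBasalB + config$widthLevelOffset, "palatal")))
  validateIndexVector(out)
  out
}

#' Rigidly transform (and optionally scale) a geometry
#'
#' Applies `x -> scale * R(angle) x + translation` to every landmark, axis
#' and contour vertex. All nine indices are invariant under rigid motion
#' (`scale = 1`) and scale linearly with `scale`.
#'
#' @param geometry A [SagittalGeometry-class].
#' @param angle Rotation angle in radians (counter-clockwise).
#' @param translation Length-2 numeric (mm).
#' @param scale Positive scale factor.
#' @return The transformed `SagittalGeometry`.
#' @export
transformGeometry <- function(geometry, angle = 0, translation = c(0, 0), scale = 1) {
  stopifnot(scale > 0)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  tp <- function(p) as.numeric(scale * R %*% p + translation)
  tm <- function(m) t(apply(m, 1L, tp))
  tl <- function(l) directedLine(tp(l@point), as.numeric(R %*% l@dir))
  sagittalGeometry(
    crest = tp(geometry@crest), apex = tp(geometry@apex),
    toothAxis = tl(geometry@toothAxis), boneAxis = tl(geometry@boneAxis),
    basalBoundary = tm(geometry@basalBoundary),
    buccalContour = tm(geometry@buccalContour),
    palatalContour = tm(geometry@palatalContour),
    pixelSpacing = geometry@pixelSpacing, validate = FALSE)
}

#' Derive a bone axis from the contours
#'
#' When no bone axis is annotated, a reproducible default is the line through
#' the midpoint of the buccal/palatal contours at crest level and their
#' midpoint at the basal level, measured perpendicular to the tooth axis.
#'
#' @param geometry A [SagittalGeometry-class] (its `boneAxis` slot is ignored).
#' @return A `DirectedLine` pointing apically.
#' @export
deriveBoneAxis <- function(geometry) {
  ta <- geometry@toothAxis
  n <- c(ta@dir[2], -ta@dir[1])
  midAt <- function(level) {
    p <- ta@point + level * ta@dir
    tb <- .linePolylineParams(p, n, geometry@buccalContour)
    tp <- .linePolylineParams(p, n, geometry@palatalContour)
    if (!length(tb) || !length(tp))
      .degenerate("cannot derive bone axis: contour missing at level %.3f", level)
    p + n * (tb[which.min(abs(tb))] + tp[which.min(abs(tp))]) / 2
  }
  tCrest <- sum((geometry@crest - ta@point) * ta@dir)
  ts <- .linePolylineParams(ta@point, ta@dir, geometry@basalBoundary)
  if (length(ts) != 1L)
    .degenerate("cannot derive bone axis: tooth axis/basal boundary crossing not unique")
  a <- midAt(tCrest); b <- midAt(ts)
  directedLine(a, b - a)
}
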