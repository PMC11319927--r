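# Grayscale rendering of a sagittal geometry: bright tooth root over
# mid-gray basal bone over dark background, plus Gaussian blur and noise.

#' Rendering configuration
#'
#' @param size Image side in pixels (square images).
#' @param pixelSpacing mm per pixel; the default 128 px at 0.25 mm/px gives a
#'   32 mm field of view.
#' @param background,boneIntensity,toothIntensity Intensities in `[0,1]`,
#'   ordered background < bone < tooth.
#' @param corticalIntensity Intensity of the bright cortical band along the
#'   basal boundary (the nasal-floor cortical plate); keeps the basal level,
#'   and hence the length indices, sharply localizable.
#' @param corticalWidth Half-width of the cortical band in mm.
#' @param blurSigma Gaussian blur SD in pixels (0 disables).
#' @param noiseSd Additive Gaussian noise SD in intensity units (0 disables).
#' @param palatalMargin Width in mm of the section window palatal of the
#'   crest: the frame is tooth-centered, as clinical sagittal sections are,
#'   and anatomy extending further palatally than this lies outside the
#'   window and is cut off at the image border. Wide (typically male) basal
#'   bone is therefore partially censored — the realistic reason width
#'   indices are harder for large anatomy. `Inf` disables the window (then
#'   any overflow is an error).
#' @param origin Length-2 mm position of the center of pixel (0,0), or `NULL`
#'   for the default tooth-centered frame (crest placed `palatalMargin` from
#'   the palatal border).
#' @return A list of class `imageConfig`.
#' @export
imageConfig <- function(size = 128L, pixelSpacing = 0.25,
                        background = 0.30, boneIntensity = 0.45,
                        toothIntensity = 0.95, corticalIntensity = 0.85,
                        corticalWidth = 1.0, blurSigma = 1.2,
                        noiseSd = 0.07, palatalMargin = 10.5, origin = NULL) {
  stopifnot(size >= 8, pixelSpacing > 0,
            background < boneIntensity, boneIntensity < toothIntensity,
            corticalWidth >= 0, blurSigma >= 0, noiseSd >= 0,
            palatalMargin > 0)
  structure(list(size = as.integer(size), pixelSpacing = pixelSpacing,
                 background = background, boneIntensity = boneIntensity,
                 toothIntensity = toothIntensity,
                 corticalIntensity = corticalIntensity,
                 corticalWidth = corticalWidth, blurSigma = blurSigma,
                 noiseSd = noiseSd, palatalMargin = palatalMargin,
                 origin = origin),
            class = "imageConfig")
}

# Minimum distance from points to a polyline (vectorized over points).
.distToPolyline <- function(px, py, poly) {
  d2 <- rep(Inf, length(px))
  for (k in seq_len(nrow(poly) - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len2 <- ex^2 + ey^2
    t <- ((px - a[1]) * ex + (py - a[2]) * ey) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (px - (a[1] + t * ex))^2 + (py - (a[2] + t * ey))^2)
  }
  sqrt(d2)
}

# Even-odd point-in-polygon, vectorized over points.
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Clip a contour polyline between its crossings with two lines, returning the
# sub-polyline (with exact crossing points as end vertices).
.clipPolyline <- function(poly, lineA, lineB) {
  cross <- function(line) {
    pLine <- line$point; dLine <- line$dir
    n <- nrow(poly)
    for (k in seq_len(n - 1L)) {
      a <- poly[k, ]; b <- poly[k + 1L, ]
      e <- b - a
      den <- dLine[1] * e[2] - dLine[2] * e[1]
      if (abs(den) < 1e-12) next
      r <- a - pLine
      u <- (r[1] * dLine[2] - r[2] * dLine[1]) / den   # cross(r, d) / cross(d, e)
      if (u >= -1e-9 && u <= 1 + 1e-9)
        return(list(k = k, u = min(max(u, 0), 1), pt = a + u * e))
    }
    NULL
  }
  ca <- cross(lineA); cb <- cross(lineB)
  if (is.null(ca) || is.null(cb))
    stop("contour does not span the requested region")
  if (ca$k > cb$k || (ca$k == cb$k && ca$u > cb$u)) { tmp <- ca; ca <- cb; cb <- tmp }
  mid <- if (cb$k > ca$k) poly[seq(ca$k + 1L, cb$k), , drop = FALSE] else NULL
  rbind(ca$pt, mid, cb$pt)
}

#' Render a sagittal geometry to a grayscale image
#'
#' Paints the basal-bone region (between the buccal and palatal contours,
#' from the crest level to the basal boundary) at `boneIntensity` and a
#' tapering tooth root along the tooth axis at `toothIntensity` over the
#' background, then applies Gaussian blur and additive Gaussian noise per the
#' configuration. Pixel centers sit at integer coordinates (0-based); rows
#' index y (increasing apically), columns x.
#'
#' @param geometry A [SagittalGeometry-class].
#' @param config An [imageConfig()].
#' @return `size x size` numeric matrix in `[0,1]`, with attributes
#'   `origin` (mm position of the pixel (0,0) center) and `pixelSpacing`.
#' @export
renderImage <- function(geometry, config = imageConfig()) {
  stopifnot(inherits(config, "imageConfig"))
  ta <- geometry@toothAxis
  nHat <- c(ta@dir[2], -ta@dir[1])
  tCrest <- sum((geometry@crest - ta@point) * ta@dir)
  crestLine <- list(point = ta@point + tCrest * ta@dir, dir = nHat)
  nB <- nrow(geometry@basalBoundary)
  basalLine <- list(point = geometry@basalBoundary[1, ],
                    dir = geometry@basalBoundary[nB, ] - geometry@basalBoundary[1, ])
  buc <- .clipPolyline(geometry@buccalContour, crestLine, basalLine)
  pal <- .clipPolyline(geometry@palatalContour, crestLine, basalLine)
  bonePoly <- rbind(buc, pal[rev(seq_len(nrow(pal))), , drop = FALSE])

  rootLen <- sqrt(sum((geometry@apex - geometry@crest)^2))
  # root half-width: near-constant (incisor roots are), capped by the buccal
  # plate so the root stays inside the bone
  r0 <- min(1.3, 0.8 * widthAtLevel(geometry, ta, tCrest + 0.5, "buccal"))
  tg <- seq(0, rootLen, length.out = 9L)
  rg <- r0 * (1 - (tg / rootLen)^1.5)
  axisPts <- t(vapply(tg + tCrest, function(t) ta@point + t * ta@dir, numeric(2)))
  toothPoly <- rbind(
    axisPts - rg %o% nHat,
    (axisPts + rg %o% nHat)[rev(seq_along(tg)), , drop = FALSE])

  sz <- config$size; sp <- config$pixelSpacing
  fov <- sz * sp
  clip <- is.finite(config$palatalMargin)
  allPts <- rbind(bonePoly, toothPoly)
  origin <- config$origin
  if (is.null(origin)) {
    if (clip) {
      # tooth-centered section window: the crest sits palatalMargin mm from
      # the palatal (right) border; anatomy beyond that border is cut off
      origin <- c(geometry@crest[1] + config$palatalMargin - fov + sp / 2,
                  geometry@crest[2] - 2.5)
    } else {
      ctr <- (apply(allPts, 2, min) + apply(allPts, 2, max)) / 2
      origin <- ctr - sp * (sz - 1) / 2
    }
  }
  lo <- origin - sp / 2
  hi <- origin + sp * (sz - 1) + sp / 2
  ext <- rbind(apply(allPts, 2, min), apply(allPts, 2, max))
  overflow <- c(ext[1, 1] < lo[1], ext[1, 2] < lo[2], ext[2, 2] > hi[2],
                if (!clip) ext[2, 1] > hi[1] else FALSE)
  if (any(overflow))
    stop(sprintf(paste0("geometry exceeds the field of view: extent x [%.2f, %.2f],",
                        " y [%.2f, %.2f] mm vs FOV x [%.2f, %.2f], y [%.2f, %.2f] mm"),
                 ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2],
                 lo[1], hi[1], lo[2], hi[2]))

  xs <- origin[1] + (seq_len(sz) - 1L) * sp
  ys <- origin[2] + (seq_len(sz) - 1L) * sp
  # the image matrix is [i = y row, j = x col]; filling column-major means
  # vector position (j-1)*sz + i, so x repeats each sz, y cycles fast
  pxv <- rep(xs, each = sz)
  pyv <- rep(ys, times = sz)
  img <- matrix(config$background, sz, sz)
  boneMask <- .pointsInPolygon(pxv, pyv, bonePoly)
  img[boneMask] <- config$boneIntensity
  if (config$corticalWidth > 0) {
    nearBasal <- .distToPolyline(pxv, pyv, geometry@basalBoundary) <=
      config$corticalWidth
    img[nearBasal & boneMask] <- config$corticalIntensity
  }
  img[.pointsInPolygon(pxv, pyv, toothPoly)] <- config$toothIntensity
  # matrix(filledVector, sz, sz) is column-major: entry (i, j) has x = xs[j],
  # y = ys[i] by the pxv/pyv construction above
  if (config$blurSigma > 0)
    img <- .gaussianBlur(img, config$blurSigma)
  if (config$noiseSd > 0)
    img <- img + matrix(stats::rnorm(sz * sz, 0, config$noiseSd), sz, sz)
  img <- pmin(pmax(img, 0), 1)
  attr(img, "origin") <- origin
  attr(img, "pixelSpacing") <- sp
  img
}

.gaussianBlur <- function(img, sigma) {
  out <- EBImage::gblur(img, sigma = sigma)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Convert between mm and pixel coordinates of a rendered image
#'
#' @param mm n x 2 matrix or length-2 vector of mm coordinates.
#' @param image A matrix returned by [renderImage()] (uses its `origin` and
#'   `pixelSpacing` attributes).
#' @return 0-based pixel coordinates (x = column, y = row), fractional.
#' @export
mmToPixel <- function(mm, image) {
  origin <- attr(image, "origin"); sp <- attr(image, "pixelSpacing")
  if (is.null(origin)) stop("image has no origin attribute")
  if (is.null(dim(mm))) mm <- matrix(mm, 1)
  sweep(mm, 2, origin) / sp
}
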