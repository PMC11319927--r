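# Demographically structured synthetic sagittal-section generator.
#
# The generator parameterizes the geometry (axis tilts, crest/apex/basal
# positions, straight-line contours) rather than pixels, so the nine
# ground-truth indices have closed forms computed independently of the
# polyline measurement machinery in geometry.R.

.truncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Tooth sites covered by the dataset
#' @return Character vector of the four maxillary incisor sites.
#' @export
toothSites <- function() c("#11", "#12", "#21", "#22")

#' Default morphology distributions (sex-neutral base)
#'
#' Each entry is `c(mean, sd, lo, hi)` of a truncated normal, in mm or
#' radians. Width-governing parameters (`buccalWidth`, `palatalWidth`) are
#' multiplied by the configured `sexEffect` for male patients. Defaults are
#' chosen so the generated ground-truth ranges bracket typical clinical
#' values (crest-to-basal length along the tooth axis around 17.6 +/- 4 mm,
#' bucco-palatal width 2 mm apical to the apex around 9.7 +/- 2.4 mm).
#'
#' @return Named list of length-4 numeric vectors.
#' @export
defaultMorphology <- function() list(
  basalDepth    = c(17.6, 3.0, 10.5, 26),
  rootLength    = c(9.7, 1.5, 5.5, 14),
  toothAngle    = c(0, 0.05, -0.14, 0.14),
  boneAngleOffset = c(0.17, 0.05, 0.04, 0.32),
  boneDx        = c(0, 0.5, -1.4, 1.4),
  buccalWidth   = c(1.55, 0.8, 0.35, 5.5),
  palatalWidth  = c(7.2, 2.0, 2.6, 14),
  buccalSlope   = c(0, 0.012, -0.035, 0.035),
  palatalSlope  = c(0, 0.018, -0.05, 0.05),
  basalSlope    = c(0, 0.04, -0.11, 0.11))

#' Population configuration for the synthetic generator
#'
#' Encodes the study conditions the generator emulates: cohort size, the
#' sex ratio, the age distribution truncated at adulthood, the sex-conditional
#' bone morphology (male widths larger by the multiplicative `sexEffect`),
#' and the rendering parameters.
#'
#' @param nPatients Number of patients (each contributes 4 tooth sites).
#' @param maleFraction Bernoulli probability of a male patient. Default 0.388,
#'   the 388:612 cohort ratio the generator emulates.
#' @param ageMean,ageSd Age distribution in years, truncated at `ageMin`.
#' @param ageMin Minimum age (adult inclusion), years.
#' @param sexEffect Multiplicative factor on the width-governing morphology
#'   means for males (> 0). Default 1.3: males have wider basal bone; set to 1
#'   for a null (sex-free) population.
#' @param morphology Named list as [defaultMorphology()].
#' @param distortion Section-distortion SDs in mm/radians: the rendered image
#'   is produced from a perturbed copy of the measured geometry (emulating
#'   out-of-plane averaging and partial-volume blur of a single sagittal
#'   section), so a single image only partially determines the measured
#'   indices. This sets a realistic accuracy ceiling for image-based
#'   regression; zero all entries for fully image-determined labels. Named
#'   entries: `depth`, `buccalWidth`, `palatalWidth`, `rootLength`.
#' @param image Rendering configuration from [imageConfig()].
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of (config, seed).
#' @return A validated list of class `populationConfig`.
#' @export
populationConfig <- function(nPatients = 1000, maleFraction = 0.388,
                             ageMean = 36.15, ageSd = 13.09, ageMin = 18,
                             sexEffect = 1.3,
                             morphology = defaultMorphology(),
                             distortion = list(depth = 2.0, buccalWidth = 0.55,
                                               palatalWidth = 1.4,
                                               rootLength = 0.8),
                             image = imageConfig(),
                             seed = 1L) {
  if (!is.numeric(nPatients) || nPatients < 1)
    stop("invalid config: nPatients must be >= 1")
  if (maleFraction < 0 || maleFraction > 1)
    stop("invalid config: maleFraction must lie in [0, 1]")
  if (ageSd < 0) stop("invalid config: ageSd must be >= 0")
  if (!is.numeric(sexEffect) || sexEffect <= 0)
    stop("invalid config: sexEffect must be > 0")
  if (any(vapply(morphology, function(p) p[2] < 0, logical(1))))
    stop("invalid config: morphology SDs must be >= 0")
  if (any(unlist(distortion) < 0))
    stop("invalid config: distortion SDs must be >= 0")
  structure(list(
    nPatients = as.integer(nPatients), maleFraction = maleFraction,
    ageMean = ageMean, ageSd = ageSd, ageMin = ageMin,
    sexEffect = sexEffect, morphology = morphology,
    distortion = distortion, image = image,
    seed = as.integer(seed)), class = "populationConfig")
}

.ageGroup <- function(age) {
  cut(age, breaks = c(18, 30, 50, Inf), right = FALSE,
      labels = c("18-29", "30-49", "50+"))
}

#' Sample a synthetic patient population
#'
#' Draws `nPatients` patients (sex Bernoulli, age truncated-normal at the
#' adult minimum) and expands each into one record per tooth site. Uses the
#' current RNG state; wrap in a seed for reproducibility (as
#' [buildDataset()] does).
#'
#' @param config A [populationConfig()].
#' @return `data.frame` with 4 x nPatients rows: `patientId`, `sex`, `age`,
#'   `ageGroup`, `toothSite`.
#' @export
samplePopulation <- function(config) {
  stopifnot(inherits(config, "populationConfig"))
  n <- config$nPatients
  sex <- ifelse(stats::runif(n) < config$maleFraction, "male", "female")
  age <- .truncnorm(n, config$ageMean, config$ageSd, lo = config$ageMin)
  pid <- sprintf("P%05d", seq_len(n))
  df <- data.frame(
    patientId = rep(pid, each = 4L),
    sex = rep(sex, each = 4L),
    age = rep(age, each = 4L),
    ageGroup = as.character(rep(.ageGroup(age), each = 4L)),
    toothSite = rep(toothSites(), times = n),
    stringsAsFactors = FALSE)
  df$imageId <- paste0(df$patientId, "_", sub("#", "T", df$toothSite))
  df
}

# One draw of geometric parameters for a given sex, with bounded retries so
# the resulting geometry satisfies the class invariants.
.sampleGeometryParams <- function(sex, config, maxRetry = 25L) {
  m <- config$morphology
  wf <- if (identical(sex, "male")) config$sexEffect else 1
  d1 <- function(p, f = 1) .truncnorm(1L, p[1] * f, p[2], p[3], p[4])
  for (i in seq_len(maxRetry)) {
    par <- list(
      depth = d1(m$basalDepth), rootLen = d1(m$rootLength),
      theta = d1(m$toothAngle), dtheta = d1(m$boneAngleOffset),
      boneDx = d1(m$boneDx),
      bw = d1(m$buccalWidth, wf), pw = d1(m$palatalWidth, wf),
      mb = d1(m$buccalSlope), mp = d1(m$palatalSlope),
      sB = d1(m$basalSlope))
    if (.paramsFeasible(par)) return(par)
  }
  stop("could not sample a geometry satisfying the invariants after ",
       maxRetry, " retries")
}

.paramsFeasible <- function(par) {
  with(par, {
    denT <- cos(theta) - sB * sin(theta)
    denB <- cos(theta + dtheta) - sB * sin(theta + dtheta)
    if (denT < 0.5 || denB < 0.5) return(FALSE)
    tStar <- depth / denT
    sStar <- (depth + sB * boneDx) / denB
    tHi <- max(tStar, sStar) + 4
    # contours must stay strictly on their side of the tooth axis
    if (bw + mb * (-1.5) < 0.15 || bw + mb * tHi < 0.15) return(FALSE)
    if (pw + mp * (-1.5) < 0.15 || pw + mp * tHi < 0.15) return(FALSE)
    # apex must sit coronal to the basal boundary
    if (rootLen > tStar - 0.75) return(FALSE)
    TRUE
  })
}

# Perturb a parameter draw by the section-distortion SDs, keeping the result
# geometrically feasible (bounded retries, then fall back to the unperturbed
# parameters).
.distortParams <- function(par, distortion, maxRetry = 10L) {
  if (is.null(distortion) || all(unlist(distortion) == 0)) return(par)
  for (i in seq_len(maxRetry)) {
    p <- par
    p$depth   <- par$depth + stats::rnorm(1, 0, distortion$depth %||% 0)
    p$bw      <- par$bw + stats::rnorm(1, 0, distortion$buccalWidth %||% 0)
    p$pw      <- par$pw + stats::rnorm(1, 0, distortion$palatalWidth %||% 0)
    p$rootLen <- par$rootLen + stats::rnorm(1, 0, distortion$rootLength %||% 0)
    if (p$bw >= 0.25 && p$pw >= 1 && p$depth >= 8 && p$depth <= 26.5 &&
        p$rootLen >= 4 && .paramsFeasible(p)) return(p)
  }
  par
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form ground truth from the generating parameters (exact; independent
# of the polyline measurement operators).
.analyticIndices <- function(par) {
  with(par, {
    th <- theta; tb <- theta + dtheta
    tHat <- c(sin(th), cos(th)); nHat <- c(cos(th), -sin(th))
    bHat <- c(sin(tb), cos(tb)); mHat <- c(cos(tb), -sin(tb))
    tStar <- depth / (cos(th) - sB * sin(th))
    sStar <- (depth + sB * boneDx) / (cos(tb) - sB * sin(tb))
    C <- c(0, 0); Cb <- c(boneDx, 0)
    A <- C + rootLen * tHat
    tC <- sum((C - Cb) * bHat)
    tA <- sum((A - Cb) * bHat)
    tApical <- rootLen + 2
    solve2 <- function(col1, col2, rhs) {
      den <- col1[1] * col2[2] - col1[2] * col2[1]
      c((rhs[1] * col2[2] - rhs[2] * col2[1]) / den,
        (col1[1] * rhs[2] - col1[2] * rhs[1]) / den)
    }
    Pb <- Cb + sStar * bHat
    w <- C - Pb
    ub <- solve2(mHat, -tHat + mb * nHat, w - bw * nHat)[1]
    up <- solve2(mHat, -tHat - mp * nHat, w + pw * nHat)[1]
    out <- c(
      LTAcb = tStar,
      LTAab = abs(tStar - rootLen),
      LBAcb = abs(sStar - tC),
      LBAab = abs(sStar - tA),
      apical2mm = (bw + mb * tApical) + (pw + mp * tApical),
      WTAB = bw + mb * tStar,
      WTAP = pw + mp * tStar,
      WBAB = abs(ub),
      WBAP = abs(up))
    out
  })
}

.geometryFromParams <- function(par, pixelSpacing = 0.25) {
  with(par, {
    th <- theta; tbAng <- theta + dtheta
    tHat <- c(sin(th), cos(th)); nHat <- c(cos(th), -sin(th))
    tStar <- depth / (cos(th) - sB * sin(th))
    sStar <- (depth + sB * boneDx) / (cos(tbAng) - sB * sin(tbAng))
    tLo <- -1.5; tHi <- max(tStar, sStar) + 4
    sGrid <- seq(tLo, tHi, length.out = 8L)
    buccal <- t(vapply(sGrid, function(s) s * tHat - (bw + mb * s) * nHat,
                       numeric(2)))
    palatal <- t(vapply(sGrid, function(s) s * tHat + (pw + mp * s) * nHat,
                        numeric(2)))
    xCrossT <- tStar * sin(th)
    xCrossB <- boneDx + sStar * sin(tbAng)
    xSpan <- range(buccal[, 1], palatal[, 1], boneDx, xCrossT, xCrossB)
    xs <- seq(xSpan[1] - 3, xSpan[2] + 3, length.out = 6L)
    basal <- cbind(xs, depth + sB * xs)
    sagittalGeometry(
      crest = c(0, 0), apex = rootLen * tHat,
      toothAxis = directedLine(c(0, 0), tHat),
      boneAxis = directedLine(c(boneDx, 0), c(sin(tbAng), cos(tbAng))),
      basalBoundary = basal, buccalContour = buccal, palatalContour = palatal,
      pixelSpacing = pixelSpacing)
  })
}

#' Sample one sagittal geometry for a demographic record
#'
#' Draws sex-conditional morphology parameters (male width parameters scaled
#' by the configured `sexEffect`) and builds the corresponding
#' [SagittalGeometry-class]. Infeasible draws are rejected and re-drawn a
#' bounded number of times. Uses the current RNG state.
#'
#' @param record A single-row data.frame as produced by [samplePopulation()]
#'   (only its `sex` is used), or a character `"male"`/`"female"`.
#' @param config A [populationConfig()].
#' @return A `SagittalGeometry`.
#' @export
sampleGeometry <- function(record, config) {
  sex <- if (is.character(record)) record else record$sex
  par <- .sampleGeometryParams(sex, config)
  .geometryFromParams(par, pixelSpacing = config$image$pixelSpacing)
}

#' Largest-remainder apportionment of patients across splits
#'
#' Apportions `n` patients to the train/validation/test splits in the given
#' ratio by the largest-remainder rule, ties broken by split order (train,
#' then validation, then test). Matches the ratio exactly when `n` divides.
#'
#' @param n Number of patients.
#' @param ratios Positive weights, default `c(6, 2, 2)`.
#' @return Named integer vector of counts summing to `n`.
#' @export
apportionSplit <- function(n, ratios = c(6, 2, 2)) {
  stopifnot(n >= length(ratios), all(ratios > 0))
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(q))   # largest remainder, then order
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), c("train", "validation", "test"))
}

.assignPatientSplits <- function(patientIds, ratios = c(6, 2, 2)) {
  ids <- unique(patientIds)
  counts <- apportionSplit(length(ids), ratios)
  shuffled <- sample(ids)
  lab <- rep(names(counts), counts)
  stats::setNames(lab, shuffled)
}

#' Build a complete synthetic dataset manifest
#'
#' Generates the population, one geometry + exact ground-truth index vector
#' per (patient, tooth site), a patient-wise 6:2:2 split, and (optionally)
#' the rendered grayscale images. Fully deterministic given
#' `(config, config$seed)`.
#'
#' @param config A [populationConfig()]; needs `nPatients >= 5` so every
#'   split is non-empty.
#' @param render Render images (`TRUE`, needed for model training) or skip
#'   rendering for bookkeeping-only manifests.
#' @param ratios Split weights, default `c(6, 2, 2)`.
#' @return A [QuantManifest-class].
#' @export
buildDataset <- function(config, render = TRUE, ratios = c(6, 2, 2)) {
  stopifnot(inherits(config, "populationConfig"))
  if (config$nPatients < 5)
    stop("nPatients must be >= 5 so that every split is non-empty")
  withr::with_seed(config$seed, {
    rec <- samplePopulation(config)
    n <- nrow(rec)
    gt <- matrix(NA_real_, n, 9, dimnames = list(rec$imageId, indexNames()))
    geoms <- vector("list", n); names(geoms) <- rec$imageId
    renderPars <- vector("list", n)
    for (i in seq_len(n)) {
      par <- tryCatch(.sampleGeometryParams(rec$sex[i], config),
        error = function(e) stop("patient ", rec$patientId[i], ", tooth ",
                                 rec$toothSite[i], ": ", conditionMessage(e)))
      geoms[[i]] <- .geometryFromParams(par, config$image$pixelSpacing)
      gt[i, ] <- .analyticIndices(par)
      renderPars[[i]] <- .distortParams(par, config$distortion)
    }
    splitOf <- .assignPatientSplits(rec$patientId, ratios)
    rec$split <- unname(splitOf[rec$patientId])
    imgs <- array(numeric(0), c(0, 0, 0))
    if (render) {
      sz <- config$image$size
      imgs <- array(NA_real_, c(sz, sz, n))
      for (i in seq_len(n)) {
        rg <- .geometryFromParams(renderPars[[i]], config$image$pixelSpacing)
        im <- tryCatch(renderImage(rg, config$image),
          error = function(e) stop("patient ", rec$patientId[i], ", tooth ",
                                   rec$toothSite[i], ": ", conditionMessage(e)))
        # left-side sites (#21, #22) are the anatomical mirror images of the
        # right-side ones: mirror their rendering so the image population has
        # both chiralities (and horizontal flips map it onto itself)
        if (rec$toothSite[i] %in% c("#21", "#22"))
          im <- im[, rev(seq_len(ncol(im)))]
        imgs[, , i] <- im
      }
    }
    new("QuantManifest",
        records = rec[, c("imageId", "patientId", "sex", "age", "ageGroup",
                          "toothSite", "split")],
        gt = gt, geometries = geoms, images = imgs,
        config = unclass(config), seed = config$seed)
  })
}
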