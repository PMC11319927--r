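# Shared fixtures and independent oracles.

# Canonical axis-aligned section: crest at the origin, vertical coincident
# axes, flat basal boundary at y = 21, vertical contours at x = +/- 5.
axisAlignedGeometry <- function(apexY = 13, basalY = 21, halfWidth = 5) {
  sagittalGeometry(
    crest = c(0, 0), apex = c(0, apexY),
    toothAxis = directedLine(c(0, 0), c(0, 1)),
    boneAxis = directedLine(c(0, 0), c(0, 1)),
    basalBoundary = rbind(c(-halfWidth - 4, basalY), c(halfWidth + 4, basalY)),
    buccalContour = rbind(c(-halfWidth, -2), c(-halfWidth, basalY + 5)),
    palatalContour = rbind(c(halfWidth, -2), c(halfWidth, basalY + 5)))
}

# A generator-style random geometry (uses the package's own sampler under a
# local seed; morphology only, no images).
randomGeometry <- function(seed, sex = "female") {
  cfg <- populationConfig(nPatients = 5, seed = 1L)
  withr::with_seed(seed, sampleGeometry(sex, cfg))
}

# Independent brute-force line/polyline crossing oracle: walks every segment
# and solves the 2x2 linear system with solve(), unlike the package's
# determinant formulation. Returns sorted crossing parameters t.
oracleCrossings <- function(point, dir, poly) {
  ts <- numeric(0)
  for (k in seq_len(nrow(poly) - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    A <- cbind(dir, a - b)
    if (abs(det(A)) < 1e-12) next
    sol <- solve(A, a - point)
    t <- unname(sol[1]); u <- unname(sol[2])
    lastSeg <- k == nrow(poly) - 1L
    if (u >= -1e-12 && (u < 1 - 1e-12 || (lastSeg && u <= 1 + 1e-12)))
      ts <- c(ts, t)
  }
  sort(ts)
}

# Independent re-measurement of the nine indices via oracleCrossings.
oracleMeasure <- function(g, apicalOffset = 2) {
  ta <- g@toothAxis; ba <- g@boneAxis
  lenFrom <- function(axis, from) {
    ts <- oracleCrossings(axis@point, axis@dir, g@basalBoundary)
    stopifnot(length(ts) == 1)
    abs(ts - sum((from - axis@point) * axis@dir))
  }
  widthAt <- function(axis, level, side) {
    p <- axis@point + level * axis@dir
    n <- c(axis@dir[2], -axis@dir[1])
    pick <- function(poly) {
      ts <- oracleCrossings(p, n, poly)
      ts[which.min(abs(ts))]
    }
    switch(side,
      both = abs(pick(g@buccalContour) - pick(g@palatalContour)),
      buccal = abs(pick(g@buccalContour)),
      palatal = abs(pick(g@palatalContour)))
  }
  tBasalT <- oracleCrossings(ta@point, ta@dir, g@basalBoundary)
  tBasalB <- oracleCrossings(ba@point, ba@dir, g@basalBoundary)
  tApex <- sum((g@apex - ta@point) * ta@dir)
  c(LTAcb = lenFrom(ta, g@crest), LTAab = lenFrom(ta, g@apex),
    LBAcb = lenFrom(ba, g@crest), LBAab = lenFrom(ba, g@apex),
    apical2mm = widthAt(ta, tApex + apicalOffset, "both"),
    WTAB = widthAt(ta, tBasalT, "buccal"),
    WTAP = widthAt(ta, tBasalT, "palatal"),
    WBAB = widthAt(ba, tBasalB, "buccal"),
    WBAP = widthAt(ba, tBasalB, "palatal"))
}

# Small rendered manifest shared across tests (built once per session).
.fixtureEnv <- new.env(parent = emptyenv())

smallManifest <- function() {
  if (is.null(.fixtureEnv$manifest)) {
    cfg <- populationConfig(nPatients = 12, seed = 401L,
                            image = imageConfig(size = 64, pixelSpacing = 0.5))
    .fixtureEnv$manifest <- buildDataset(cfg)
  }
  .fixtureEnv$manifest
}

# A modestly trained desk model on a mid-sized dataset, shared by the
# learning-signal and Grad-CAM tests.
deskModelFit <- function() {
  if (is.null(.fixtureEnv$fit)) {
    cfg <- populationConfig(nPatients = 100, seed = 402L,
                            image = imageConfig(size = 64, pixelSpacing = 0.5))
    man <- buildDataset(cfg)
    fit <- trainModel(buildModel(modelConfig("small-resnet", inputSize = 64)),
                      man, trainConfig(epochs = 12, seed = 7L))
    .fixtureEnv$fit <- list(manifest = man, model = fit)
  }
  .fixtureEnv$fit
}

# Full 2^n enumeration oracle for the signed-rank test (mid-ranks kept).
enumWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  pLo <- mean(Ws <= W + 1e-9)
  pHi <- mean(Ws >= W - 1e-9)
  list(statistic = W, p = min(1, 2 * min(pLo, pHi)))
}

# Two-way ANOVA mean-squares ICC(2,1) oracle via aov().
aovICC21 <- function(x, y) {
  n <- length(x); k <- 2
  df <- data.frame(score = c(x, y),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}
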