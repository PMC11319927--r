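# End-to-end demographic-parity workflow: primary fit, subgroup audit,
# subdivision by the sensitive attribute, per-stratum submodels, pooled
# routing ensemble, rater comparison and reporting.

#' Pipeline configuration
#'
#' @param population A [populationConfig()].
#' @param model A [modelConfig()].
#' @param train A [trainConfig()].
#' @param audit An [auditConfig()].
#' @param subdivideBy Optional attribute override for the subdivision stage;
#'   `NULL` uses the audit's sensitive attribute. Must be one of the audited
#'   attributes.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(population = populationConfig(),
                           model = modelConfig(),
                           train = trainConfig(),
                           audit = auditConfig(),
                           subdivideBy = NULL,
                           seed = 1L) {
  if (!is.null(subdivideBy) && !subdivideBy %in% audit$attributes)
    stop("subdivideBy must be one of the audited attributes: ",
         paste(audit$attributes, collapse = ", "))
  structure(list(population = population, model = model, train = train,
                 audit = audit, subdivideBy = subdivideBy,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

# Deterministic per-level seed below 2^31, derived from the global seed and
# the level name.
.levelSeed <- function(seed, level) {
  h <- sum(utf8ToInt(as.character(level)) * seq_along(utf8ToInt(as.character(level))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Primary fit: pooled model, evaluation and audit
#'
#' Builds the synthetic dataset, trains one pooled model on the overall
#' training split, evaluates it on the test split and audits the test-set
#' residual bias per demographic stratum.
#'
#' @param config A [pipelineConfig()].
#' @param manifest Optionally a pre-built [QuantManifest-class] (with images);
#'   by default the manifest is generated from `config$population`.
#' @return List: `model`, `eval` (an [evalTable()] data.frame), `audit`
#'   (an [AuditReport-class]), `manifest`, and `test` (gt/pred/records).
#' @export
runPrimary <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  pop <- config$population
  pop$seed <- .levelSeed(config$seed, "dataset")
  if (is.null(manifest))
    manifest <- .stage("dataset", buildDataset(pop, render = TRUE))
  tcfg <- config$train
  tcfg$seed <- .levelSeed(config$seed, "primary")
  model <- .stage("train-primary",
                  trainModel(buildModel(config$model), manifest, tcfg))
  te <- .stage("predict-test", predictManifest(model, manifest, "test"))
  ev <- evalTable(te$gt, te$pred, model = "primary")
  aud <- .stage("audit",
                subgroupAudit(manifest, te$pred, config$audit))
  list(model = model, eval = ev, audit = aud, manifest = manifest, test = te)
}

#' Subdivide a manifest by a demographic attribute
#'
#' Splits the dataset into one manifest per attribute level and re-draws a
#' fresh patient-wise 6:2:2 split within each level (the subsets get their
#' own train/validation/test cohorts).
#'
#' @param manifest A [QuantManifest-class].
#' @param attribute Record column to subdivide by (e.g. `"sex"`).
#' @param minPatients Smallest admissible level (default 5 patients).
#' @param seed Seed for the within-level re-splits.
#' @return Named list of [QuantManifest-class], one per level; their records
#'   partition the input records.
#' @export
subdivideManifest <- function(manifest, attribute, minPatients = 5L, seed = 1L) {
  rec <- manifestRecords(manifest)
  if (!attribute %in% names(rec))
    stop("attribute not present on every record: ", attribute)
  levels <- sort(unique(rec[[attribute]]))
  out <- list()
  for (l in levels) {
    idx <- which(rec[[attribute]] == l)
    sub <- subsetManifest(manifest, idx)
    npat <- length(unique(sub@records$patientId))
    if (npat < minPatients)
      stop("level '", l, "' of '", attribute, "' has only ", npat,
           " patients (need >= ", minPatients, ")")
    sub@records$split <- withr::with_seed(.levelSeed(seed, l), {
      splitOf <- .assignPatientSplits(sub@records$patientId)
      unname(splitOf[sub@records$patientId])
    })
    validObject(sub)
    out[[l]] <- sub
  }
  out
}

#' Train one submodel per attribute level
#'
#' Identical architecture and hyperparameters across levels; independent
#' seeds derived from the global seed and the level name.
#'
#' @param subsets Named list of manifests from [subdivideManifest()].
#' @param mcfg A [modelConfig()].
#' @param tcfg A [trainConfig()] (its seed is treated as the global seed).
#' @return Named list of [TrainedQuantModel-class].
#' @export
trainSubmodels <- function(subsets, mcfg, tcfg) {
  out <- list()
  for (l in names(subsets)) {
    tl <- tcfg
    tl$seed <- .levelSeed(tcfg$seed, l)
    out[[l]] <- .stage(paste0("train-submodel-", l),
                       trainModel(buildModel(mcfg), subsets[[l]], tl))
  }
  out
}

#' Pool per-level test predictions into the ensemble evaluation
#'
#' The ensemble is a routing pool: every test record is scored by its own
#' level's submodel on that level's (disjoint) test set, and the union of
#' the per-level pairs is evaluated as one set. Pooled MAE is therefore
#' exactly the record-count-weighted mean of the level MAEs.
#'
#' @param perLevel Named list with one entry per level:
#'   `list(gt =, pred =, records =)` as returned by [predictManifest()].
#' @return List: `eval` (the pooled [evalTable()]), `gt`, `pred`, `records`
#'   (with a `level` column).
#' @export
ensemblePool <- function(perLevel) {
  ids <- lapply(perLevel, function(x) x$records$imageId)
  all <- unlist(ids, use.names = FALSE)
  if (anyDuplicated(all))
    stop("level test sets overlap: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  gt <- do.call(rbind, lapply(perLevel, `[[`, "gt"))
  pred <- do.call(rbind, lapply(perLevel, `[[`, "pred"))
  recs <- do.call(rbind, lapply(names(perLevel), function(l) {
    r <- perLevel[[l]]$records
    if (nrow(r)) r$level <- l
    r
  }))
  rownames(recs) <- NULL
  list(eval = evalTable(gt, pred, model = "ensemble"),
       gt = gt, pred = pred, records = recs)
}

#' A rater's measurements on a common image set
#'
#' @param label Rater label (e.g. `"junior"`, `"senior"`, `"GT"`, `"AI"`).
#' @param measurements Numeric matrix, images x 9 (columns [indexNames()]),
#'   with image ids as rownames.
#' @return A list of class `raterSet`.
#' @export
raterSet <- function(label, measurements) {
  stopifnot(is.matrix(measurements), ncol(measurements) == 9,
            !is.null(rownames(measurements)))
  colnames(measurements) <- indexNames()
  structure(list(label = label, measurements = measurements),
            class = "raterSet")
}

#' Simulate a clinician rater
#'
#' A synthetic rater measuring `gt + bias + noise` on the manifest's test
#' images — the harness used to emulate junior/senior clinicians of varying
#' reliability.
#'
#' @param manifest A [QuantManifest-class].
#' @param label Rater label.
#' @param noiseSd Measurement noise SD in mm.
#' @param bias Systematic offset in mm.
#' @param seed RNG seed.
#' @param split Which split to measure (default `"test"`).
#' @return A [raterSet()].
#' @export
simulateRater <- function(manifest, label, noiseSd = 0.5, bias = 0,
                          seed = 1L, split = "test") {
  rec <- manifestRecords(manifest)
  keep <- rec$split == split
  gt <- manifestGT(manifest)[keep, , drop = FALSE]
  m <- withr::with_seed(seed,
    gt + bias + matrix(stats::rnorm(length(gt), 0, noiseSd), nrow(gt)))
  rownames(m) <- rec$imageId[keep]
  raterSet(label, m)
}

#' Inter-rater ICC comparison on a random image subsample
#'
#' Draws a single seeded subsample (default 10%) of the common image set and
#' computes, for every rater pair and index, the ICC(2,1) agreement.
#'
#' @param raters List of [raterSet()] objects (>= 2) covering a common set
#'   of image ids.
#' @param subsampleFraction Fraction of common images to use (default 0.10).
#' @param seed Seed for the single subsample draw.
#' @return 3D array `raters x raters x 9` of ICCs with unit diagonal, plus
#'   attribute `"imageIds"` (the subsample).
#' @export
raterComparison <- function(raters, subsampleFraction = 0.10, seed = 1L) {
  stopifnot(length(raters) >= 2)
  labels <- vapply(raters, `[[`, character(1), "label")
  common <- Reduce(intersect, lapply(raters, function(r) rownames(r$measurements)))
  if (!length(common)) stop("raters have no common image set")
  nPick <- max(2L, ceiling(subsampleFraction * length(common)))
  ids <- withr::with_seed(seed, sample(common, min(nPick, length(common))))
  out <- array(NA_real_, c(length(raters), length(raters), 9),
               dimnames = list(labels, labels, indexNames()))
  for (i in seq_along(raters)) for (j in seq_along(raters)) {
    mi <- raters[[i]]$measurements[ids, , drop = FALSE]
    mj <- raters[[j]]$measurements[ids, , drop = FALSE]
    for (nm in indexNames())
      out[i, j, nm] <- if (i == j) 1 else icc21(mi[, nm], mj[, nm])
  }
  attr(out, "imageIds") <- ids
  out
}

# Significant-index count summed over the strata of an attribute, given
# test-set gt/pred and the stratum labels.
.stratumSignificantCount <- function(gt, pred, strata, alpha = 0.05,
                                     minStratum = 5L) {
  tot <- 0L
  for (l in unique(strata)) {
    idx <- strata == l
    if (sum(idx) < minStratum) next
    ps <- vapply(indexNames(), function(nm)
      wilcoxonSignedRank(gt[idx, nm], pred[idx, nm])$p, numeric(1))
    tot <- tot + countSignificant(ps, alpha)
  }
  tot
}

#' Run the full demographic-parity workflow
#'
#' Primary fit, subgroup audit, subdivision by the sensitive attribute (or
#' an override), per-level submodel training, pooled routing ensemble, final
#' evaluation, Bland-Altman and scatter data, Grad-CAM samples, and the
#' before/after comparison of per-stratum significant-bias counts.
#'
#' @param config A [pipelineConfig()].
#' @param gradcamSamples Images per level for the Grad-CAM gallery.
#' @return A list bundle with components `primary`, `audit`, `subsets`,
#'   `submodels`, `ensemble`, `blandAltman`, `scatter`, `gradcam`, and
#'   `significantCounts` (per-stratum counts for the primary and ensemble
#'   models over the subdivision attribute).
#' @export
runFull <- function(config, gradcamSamples = 2L) {
  primary <- runPrimary(config)
  attrUsed <- if (!is.null(config$subdivideBy)) config$subdivideBy
              else sensitiveAttribute(primary$audit)
  subsets <- .stage("subdivide",
    subdivideManifest(primary$manifest, attrUsed,
                      seed = .levelSeed(config$seed, "subdivide")))
  tcfg <- config$train
  tcfg$seed <- config$seed
  submodels <- trainSubmodels(subsets, config$model, tcfg)
  perLevel <- lapply(names(subsets), function(l)
    predictManifest(submodels[[l]], subsets[[l]], "test"))
  names(perLevel) <- names(subsets)
  ens <- .stage("ensemble", ensemblePool(perLevel))

  ba <- lapply(indexNames(), function(nm)
    blandAltman(ens$gt[, nm], ens$pred[, nm]))
  names(ba) <- indexNames()
  scatter <- lapply(indexNames(), function(nm)
    data.frame(gt = ens$gt[, nm], pred = ens$pred[, nm]))
  names(scatter) <- indexNames()

  gcam <- list()
  for (l in names(subsets)) {
    te <- .manifestTensors(subsets[[l]], "test", config$model$inputSize)
    pick <- withr::with_seed(.levelSeed(config$seed, paste0("gradcam-", l)),
      sample(dim(te$x)[3], min(gradcamSamples, dim(te$x)[3])))
    gcam[[l]] <- lapply(pick, function(i)
      gradCAM(submodels[[l]], te$x[, , i], headIndex = 1L))
  }

  primStrata <- primary$test$records[[attrUsed]]
  ensStrata <- ens$records[[attrUsed]]
  counts <- c(
    primary = .stratumSignificantCount(primary$test$gt, primary$test$pred,
                                       primStrata, config$audit$alpha),
    ensemble = .stratumSignificantCount(ens$gt, ens$pred,
                                        ensStrata, config$audit$alpha))

  list(primary = primary[c("model", "eval", "test")],
       audit = primary$audit, manifest = primary$manifest,
       subdivisionAttribute = attrUsed,
       subsets = subsets, submodels = submodels, ensemble = ens,
       blandAltman = ba, scatter = scatter, gradcam = gcam,
       significantCounts = counts, config = config, seed = config$seed)
}
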