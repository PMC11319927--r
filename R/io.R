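# Plain-text interchange: geometry annotation CSV, manifest CSV + JSON
# sidecar, evaluation-table CSV, audit-report JSON, image files, and the
# packaged clinical reference summary tables.

.fmt <- function(x) sprintf("%.17g", x)

.packPolyline <- function(m) paste(apply(m, 1, function(r)
  paste(.fmt(r), collapse = ",")), collapse = ";")

.unpackPolyline <- function(s) {
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(pts, as.numeric))
}

#' Write / read geometry annotations as CSV
#'
#' One row per image: the landmark coordinates and axes as `x,y` pairs, the
#' three polylines as semicolon-separated `x,y` pairs, all in pixel
#' coordinates (mm divided by `pixelSpacing`), plus the pixel spacing. The
#' round trip is exact (full-precision decimal encoding).
#'
#' @param geometries Named list of [SagittalGeometry-class] (names = image ids).
#' @param path CSV file path.
#' @return `writeAnnotations` returns `path` invisibly; `readAnnotations`
#'   returns a named list of `SagittalGeometry`.
#' @export
writeAnnotations <- function(geometries, path) {
  rows <- lapply(names(geometries), function(id) {
    g <- geometries[[id]]
    px <- function(v) v / g@pixelSpacing
    data.frame(
      imageId = id,
      crest = paste(.fmt(px(g@crest)), collapse = ","),
      apex = paste(.fmt(px(g@apex)), collapse = ","),
      toothAxisPoint = paste(.fmt(px(g@toothAxis@point)), collapse = ","),
      toothAxisDir = paste(.fmt(g@toothAxis@dir), collapse = ","),
      boneAxisPoint = paste(.fmt(px(g@boneAxis@point)), collapse = ","),
      boneAxisDir = paste(.fmt(g@boneAxis@dir), collapse = ","),
      basalBoundary = .packPolyline(px(g@basalBoundary)),
      buccalContour = .packPolyline(px(g@buccalContour)),
      palatalContour = .packPolyline(px(g@palatalContour)),
      pixelSpacing = .fmt(g@pixelSpacing),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    sp <- as.numeric(df$pixelSpacing[i])
    pt <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]) * sp
    dir <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    sagittalGeometry(
      crest = pt(df$crest[i]), apex = pt(df$apex[i]),
      toothAxis = directedLine(pt(df$toothAxisPoint[i]), dir(df$toothAxisDir[i])),
      boneAxis = directedLine(pt(df$boneAxisPoint[i]), dir(df$boneAxisDir[i])),
      basalBoundary = .unpackPolyline(df$basalBoundary[i]) * sp,
      buccalContour = .unpackPolyline(df$buccalContour[i]) * sp,
      palatalContour = .unpackPolyline(df$palatalContour[i]) * sp,
      pixelSpacing = sp)
  })
  names(out) <- df$imageId
  out
}

#' Write a manifest as CSV plus a JSON config sidecar
#'
#' The records and ground truth go to `<path>.csv`; the full generating
#' configuration and seed go to `<path>.json` so the dataset is exactly
#' re-generable.
#'
#' @param manifest A [QuantManifest-class].
#' @param path Base path (without extension).
#' @param images Also write each rendered image (PNG or TIFF) next to the
#'   manifest; `NULL` skips.
#' @return Invisibly, the CSV path.
#' @export
writeManifest <- function(manifest, path, images = NULL) {
  rec <- cbind(manifestRecords(manifest), manifestGT(manifest))
  utils::write.csv(rec, paste0(path, ".csv"), row.names = FALSE)
  cfg <- manifest@config
  cfg$image <- unclass(cfg$image)
  jsonlite::write_json(list(config = cfg, seed = manifest@seed),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(images)) {
    stopifnot(images %in% c("png", "tiff"))
    imgs <- manifestImages(manifest)
    if (is.null(imgs)) stop("manifest has no rendered images")
    dir.create(paste0(path, "_images"), showWarnings = FALSE, recursive = TRUE)
    ids <- manifestRecords(manifest)$imageId
    for (i in seq_along(ids))
      EBImage::writeImage(imgs[, , i],
        file.path(paste0(path, "_images"), paste0(ids[i], ".", images)))
  }
  invisible(paste0(path, ".csv"))
}

#' Write an evaluation table as CSV
#'
#' @param eval A data.frame from [evalTable()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeEvalTable <- function(eval, path) {
  utils::write.csv(eval, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an audit report to JSON
#'
#' @param report An [AuditReport-class].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeAuditReport <- function(report, path) {
  payload <- list(
    alpha = report@alpha,
    disparityThreshold = report@threshold,
    attributes = report@attributes,
    pValues = report@pValues,
    counts = lapply(report@counts, as.list),
    underpowered = report@underpowered,
    disparity = as.list(report@disparity),
    sensitiveAttribute = report@sensitiveAttribute,
    noDisparity = report@noDisparity)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Published clinical reference summary tables
#'
#' Per-index summary statistics (ground-truth and prediction mean/SD, mean
#' difference, MAE, paired Wilcoxon p, Pearson r, ICC) reported for the
#' original 1,000-patient clinical cohort this workflow was developed on:
#' the pooled primary model (`"overall"`) and the demographic-parity
#' submodels/ensemble (`"male"`, `"female"`, `"ensemble"`). Shipped as
#' reference data for arithmetic/counting checks and for comparing synthetic
#' runs against the reported dynamic ranges. The ensemble p-value row was
#' published with one entry missing (8 values for 9 indices); the missing
#' cell is `NA`.
#'
#' @return Named list of data.frames (rows = metrics, columns = the nine
#'   indices in canonical order).
#' @export
referencePerformanceTables <- function() {
  path <- system.file("extdata", "clinical_reference_tables.csv",
                      package = "parityQuant", mustWork = TRUE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(long, long$table), function(d) {
    wide <- do.call(rbind, lapply(split(d, d$metric), function(m)
      stats::setNames(m$value[match(indexNames(), m$index)], indexNames())))
    as.data.frame(wide)
  })
  out[unique(long$table)]
}
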