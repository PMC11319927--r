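# Agreement statistics (paired Wilcoxon signed-rank, MAE/MSE, Pearson r,
# ICC(2,1), Bland-Altman) and the subgroup audit that determines the
# sensitive demographic attribute.

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test of paired differences `pred - gt` with the conventions:
#' zero differences are dropped; tied absolute differences receive mid-ranks;
#' the two-sided p-value comes from the exact null distribution of the
#' positive-rank sum (computed over all 2^n sign assignments of the observed
#' rank vector via generating-function convolution) when the effective n is
#' at most `exactLimit`, and otherwise from the normal approximation with tie
#' and continuity corrections. If every difference is zero, p = 1.
#'
#' @param gt,pred Equal-length numeric vectors (mm).
#' @param exactLimit Largest effective n for the exact null (default 25).
#' @return List with `statistic` (positive-rank sum W), `p` (two-sided),
#'   and `n` (effective n after dropping zeros).
#' @export
#' @examples
#' wilcoxonSignedRank(rep(0, 5), c(1, 2, 3, 4, 5))$p  # 2/2^5 = 0.0625
wilcoxonSignedRank <- function(gt, pred, exactLimit = 25L) {
  if (length(gt) != length(pred))
    stop("gt and pred must have equal length")
  if (!length(gt)) stop("need n >= 1 pairs")
  d <- pred - gt
  if (any(!is.finite(d))) stop("all paired values must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1.0, n = 0L))
  r <- rank(abs(d))                       # mid-ranks under ties
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    # exact null: distribution of W over all 2^n sign assignments; ranks are
    # half-integers at worst, so double them to index an integer lattice
    r2 <- round(2 * r)
    tot <- sum(r2)
    dist <- numeric(tot + 1L)             # dist[w+1] = #assignments with 2W = w
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(tot + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- round(2 * W)
    pLo <- sum(dist[seq_len(w2 + 1L)])
    pHi <- sum(dist[seq(w2 + 1L, tot + 1L)])
    p <- min(1, 2 * min(pLo, pHi))
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, p = p, n = n)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two measurement columns, computed from the two-way
#' ANOVA mean squares (subjects x raters).
#'
#' @param x,y Equal-length numeric vectors (n >= 2 subjects, 2 raters).
#' @return ICC(2,1) as a scalar; `NA` when the between-subject variance is
#'   degenerate (undefined rather than an error).
#' @export
icc21 <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  k <- 2
  m <- cbind(x, y)
  rowM <- rowMeans(m); colM <- colMeans(m); gm <- mean(m)
  MSR <- k * sum((rowM - gm)^2) / (n - 1)
  MSC <- n * sum((colM - gm)^2) / (k - 1)
  SSE <- sum((m - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (!is.finite(den) || abs(den) < .Machine$double.eps * 100) return(NA_real_)
  (MSR - MSE) / den
}

#' Agreement metrics between ground truth and predictions
#'
#' The paired summary used throughout the evaluation tables: mean and SD of
#' the differences (sign convention: prediction minus ground truth), MAE,
#' MSE, Pearson r, and ICC(2,1). With zero variance in either vector, r and
#' ICC are reported as `NA` markers, not errors.
#'
#' @param gt,pred Equal-length numeric vectors in mm (n >= 2 for r and ICC).
#' @return Named list: `meanDiff`, `sdDiff`, `MAE`, `MSE`, `r`, `ICC`, `n`.
#' @export
agreementMetrics <- function(gt, pred) {
  if (length(gt) != length(pred)) stop("gt and pred must have equal length")
  if (any(!is.finite(c(gt, pred)))) stop("all paired values must be finite")
  d <- pred - gt
  r <- if (length(gt) >= 2 && stats::sd(gt) > 0 && stats::sd(pred) > 0)
    stats::cor(gt, pred) else NA_real_
  icc <- if (length(gt) >= 2) icc21(gt, pred) else NA_real_
  list(meanDiff = mean(d),
       sdDiff = if (length(d) >= 2) stats::sd(d) else NA_real_,
       MAE = mean(abs(d)), MSE = mean(d^2),
       r = r, ICC = icc, n = length(gt))
}

#' Bland-Altman analysis
#'
#' Bias (mean of prediction minus ground truth) and 95% limits of agreement
#' (bias +/- 1.96 SD of the differences), with the per-pair (mean,
#' difference) points for plotting.
#'
#' @param gt,pred Equal-length numeric vectors, n >= 2.
#' @return List: `bias`, `lowerLoA`, `upperLoA`, and `points` (a data.frame
#'   with columns `mean` and `difference`).
#' @export
blandAltman <- function(gt, pred) {
  stopifnot(length(gt) == length(pred), length(gt) >= 2)
  d <- pred - gt
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, lowerLoA = bias - 1.96 * s, upperLoA = bias + 1.96 * s,
       points = data.frame(mean = (gt + pred) / 2, difference = d))
}

#' Count significant p-values
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @param alpha Significance level; counting is strict (`p < alpha`).
#' @param na.rm Drop missing entries (e.g. a malformed published row) before
#'   counting.
#' @return Integer count.
#' @export
countSignificant <- function(p, alpha = 0.05, na.rm = FALSE) {
  if (na.rm) p <- p[!is.na(p)]
  if (any(is.na(p))) stop("p-values must not be NA (or use na.rm = TRUE)")
  if (length(p) && (any(p < 0) || any(p > 1)))
    stop("all p-values must lie in [0,1]")
  sum(p < alpha)
}

#' Audit configuration
#'
#' @param alpha Per-test significance level (default 0.05).
#' @param attributes Ordered demographic attributes to audit; the order is
#'   the documented tie-break.
#' @param minStratum Minimum records per stratum; smaller strata are flagged
#'   underpowered and excluded from the disparity score.
#' @param disparityThreshold Disparity below which no attribute is considered
#'   flagged (the report then carries `noDisparity = TRUE`).
#' @return A list of class `auditConfig`.
#' @export
auditConfig <- function(alpha = 0.05,
                        attributes = c("sex", "ageGroup", "toothSite"),
                        minStratum = 5L, disparityThreshold = 2) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  structure(list(alpha = alpha, attributes = attributes,
                 minStratum = as.integer(minStratum),
                 disparityThreshold = disparityThreshold),
            class = "auditConfig")
}

#' Subgroup bias audit
#'
#' For every audited attribute, level and index, runs the paired Wilcoxon
#' signed-rank test of prediction minus ground truth within that stratum of
#' the test records. Each attribute's disparity score is the difference
#' between the largest and smallest significant-index counts over its
#' adequately powered levels; the sensitive attribute is the argmax of
#' disparity, ties broken by the larger total count and then by attribute
#' order.
#'
#' @param manifest A [QuantManifest-class] (its `test` split is audited), or
#'   one already restricted to the records matching `predictions`.
#' @param predictions Numeric matrix, records x 9, aligned to the test
#'   records of `manifest` (mm).
#' @param config An [auditConfig()].
#' @return An [AuditReport-class].
#' @export
subgroupAudit <- function(manifest, predictions, config = auditConfig()) {
  rec <- manifestRecords(manifest)
  gt <- manifestGT(manifest)
  if (any(rec$split == "test") && nrow(predictions) != nrow(rec)) {
    keep <- rec$split == "test"
    rec <- rec[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
  }
  if (nrow(predictions) != nrow(rec))
    stop("predictions must be aligned to the manifest test records (",
         nrow(rec), " records, got ", nrow(predictions), " predictions)")
  pv <- list(); counts <- list(); under <- list()
  disparity <- stats::setNames(numeric(length(config$attributes)),
                               config$attributes)
  totals <- disparity
  for (a in config$attributes) {
    if (!a %in% names(rec)) stop("attribute not present on records: ", a)
    lv <- sort(unique(rec[[a]]))
    pv[[a]] <- list(); cnt <- stats::setNames(rep(NA_integer_, length(lv)), lv)
    under[[a]] <- character(0)
    for (l in lv) {
      idx <- rec[[a]] == l
      if (sum(idx) < config$minStratum) {
        under[[a]] <- c(under[[a]], l)
        pv[[a]][[l]] <- stats::setNames(rep(NA_real_, 9), indexNames())
        next
      }
      ps <- vapply(indexNames(), function(nm)
        wilcoxonSignedRank(gt[idx, nm], predictions[idx, nm])$p, numeric(1))
      pv[[a]][[l]] <- ps
      cnt[l] <- countSignificant(ps, config$alpha)
    }
    counts[[a]] <- cnt
    ok <- cnt[!is.na(cnt)]
    disparity[a] <- if (length(ok)) max(ok) - min(ok) else 0
    totals[a] <- sum(ok)
  }
  ord <- order(-disparity, -totals, seq_along(disparity))
  sens <- config$attributes[ord[1]]
  new("AuditReport",
      pValues = pv, counts = counts, underpowered = under,
      disparity = disparity, sensitiveAttribute = sens,
      noDisparity = max(disparity) < config$disparityThreshold,
      alpha = config$alpha, threshold = config$disparityThreshold,
      attributes = config$attributes)
}

#' Per-index evaluation table
#'
#' One row per index in canonical order: ground-truth and prediction
#' mean +/- SD, mean and SD of the differences (prediction minus ground
#' truth), MAE, MSE, the paired Wilcoxon p-value, Pearson r, and ICC(2,1) —
#' the layout of the published per-index performance tables.
#'
#' @param gt,pred Numeric matrices, records x 9 (columns in [indexNames()]
#'   order), in mm.
#' @param model Label for the evaluated model (`"primary"`, a stratum
#'   submodel, or `"ensemble"`).
#' @return `data.frame` with 9 rows.
#' @export
evalTable <- function(gt, pred, model = "primary") {
  stopifnot(identical(dim(gt), dim(pred)), ncol(gt) == 9)
  rows <- lapply(indexNames(), function(nm) {
    m <- agreementMetrics(gt[, nm], pred[, nm])
    w <- wilcoxonSignedRank(gt[, nm], pred[, nm])
    data.frame(index = nm,
               gtMean = mean(gt[, nm]), gtSD = stats::sd(gt[, nm]),
               predMean = mean(pred[, nm]), predSD = stats::sd(pred[, nm]),
               diffMean = m$meanDiff, diffSD = m$sdDiff,
               MAE = m$MAE, MSE = m$MSE, p = w$p, r = m$r, ICC = m$ICC,
               model = model, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
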