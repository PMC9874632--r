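# Two-level evaluation: point-wise confusion-matrix metrics, and
# object-wise confidence-ranked precision-recall / average precision with
# 1D intersection-over-union matching.

#' Point-wise confusion matrix
#'
#' Entry (i, j) counts the points of true class i predicted as class j.
#' Rows are true classes, columns predicted classes, both 0..nClasses-1.
#'
#' @param truth,predicted integer label vectors of equal length.
#' @param nClasses number of classes (default 8).
#' @return nClasses x nClasses integer matrix with dimnames
#'   list(truth, predicted); the entries sum to \code{length(truth)}.
#' @examples
#' pointwiseConfusion(c(0L, 1L, 1L), c(0L, 1L, 0L))
#' @export
pointwiseConfusion <- function(truth, predicted, nClasses = 8L) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length: ", length(truth), " vs ",
         length(predicted))
  if (any(truth < 0L | truth >= nClasses) ||
      any(predicted < 0L | predicted >= nClasses))
    stop("labels must lie in 0..", nClasses - 1L)
  cm <- matrix(tabulate(truth * nClasses + predicted + 1L,
                        nbins = nClasses^2),
               nClasses, nClasses, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(nClasses - 1L),
                       predicted = 0:(nClasses - 1L))
  cm
}

#' Row-normalized confusion matrix
#'
#' Each row is divided by its ground-truth point count; rows with zero
#' support become NA and are flagged in the "zeroSupport" attribute.
#'
#' @param cm a confusion matrix from [pointwiseConfusion()].
#' @return Matrix of row fractions.
#' @export
normalizeConfusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(cm, 1, rs, "/")
  out[rs == 0, ] <- NA_real_
  attr(out, "zeroSupport") <- which(rs == 0)
  out
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class c: TP is the diagonal entry, FP the rest of its column,
#' FN the rest of its row, TN everything else. Accuracy, precision, recall
#' and F1 (harmonic mean of precision and recall) follow. Ratios with zero
#' denominators are reported as NA, never silently as 0.
#'
#' @param cm a confusion matrix.
#' @param classes classes to report (default: all rows).
#' @return data.frame with one row per class.
#' @export
classMetrics <- function(cm, classes = NULL) {
  lv <- as.integer(rownames(cm))
  if (is.null(classes)) classes <- lv
  tot <- sum(cm)
  rows <- lapply(classes, function(cl) {
    i <- match(cl, lv)
    TP <- cm[i, i]
    FP <- sum(cm[, i]) - TP
    FN <- sum(cm[i, ]) - TP
    TN <- tot - TP - FP - FN
    P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    R <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    F1 <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R)
          else NA_real_
    data.frame(class = cl, support = TP + FN, TP = TP, FP = FP, FN = FN,
               TN = TN, accuracy = (TP + TN) / tot, precision = P,
               recall = R, f1 = F1)
  })
  do.call(rbind, rows)
}

#' Extract label-prediction regions from a point-wise prediction
#'
#' A region is a maximal run of identically labeled points with a nonzero
#' label, bordered by baseline or other labels. Its confidence is the mean
#' softmax probability of its own class over the run. Baseline runs are
#' excluded.
#'
#' @param x a \linkS4class{PredictionResult}, or an integer label vector
#'   (in which case confidences are 1).
#' @return data.frame(class, start, end, confidence) with 1-based inclusive
#'   point intervals.
#' @export
extractRegions <- function(x) {
  if (is(x, "PredictionResult")) {
    labels <- x@labels
    probs <- x@probabilities
  } else {
    labels <- as.integer(x)
    probs <- NULL
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(class = integer(), start = integer(),
                      end = integer(), confidence = numeric()))
  starts <- starts[keep]; ends <- ends[keep]; cls <- r$values[keep]
  conf <- vapply(seq_along(cls), function(i) {
    if (is.null(probs)) return(1)
    mean(probs[starts[i]:ends[i], cls[i] + 1L])
  }, numeric(1))
  data.frame(class = cls, start = starts, end = ends, confidence = conf)
}

#' 1D intersection over union of two point-index intervals
#'
#' Intervals are 1-based inclusive index pairs on the same grid; the IOU
#' counts points: |a intersect b| / |a union b|, 0 when disjoint.
#'
#' @param a,b length-2 integer vectors c(start, end).
#' @return IOU in [0, 1].
#' @examples
#' regionIOU(c(1, 10), c(6, 15))   # 5/15
#' @export
regionIOU <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L || a[2] < a[1] || b[2] < b[1])
    stop("intervals must be nonempty c(start, end) pairs")
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

#' Match ranked predictions to ground truth and build a PR curve
#'
#' Predictions are ranked by confidence (descending; ties by span start).
#' Walking down the list, each prediction is a true positive if its IOU
#' with the best-overlapping unmatched ground-truth region of the same
#' class (and segment, when a \code{segment} column is present) is at least
#' \code{iou}; otherwise a false positive. Matching is greedy one-to-one.
#' Cumulative precision is TP-so-far over predictions-so-far; the recall
#' denominator is the number of ground-truth regions by default, or the
#' total number of predictions under the "predictions" convention.
#'
#' @param pred data.frame(class, start, end, confidence) from
#'   [extractRegions()], optionally with a segment column.
#' @param truth data.frame(class, start, end), same convention.
#' @param iou IOU threshold in (0, 1].
#' @param recallDenominator "truths" (standard) or "predictions".
#' @return data.frame(confidence, class, tp, precision, recall) ordered by
#'   rank, with attributes nTruths and iou.
#' @export
matchAndCurve <- function(pred, truth, iou = 0.5,
                          recallDenominator = c("truths", "predictions")) {
  recallDenominator <- match.arg(recallDenominator)
  if (iou <= 0 || iou > 1) stop("'iou' must lie in (0, 1]")
  hasSeg <- "segment" %in% names(pred) && "segment" %in% names(truth)
  if (!hasSeg) { pred$segment <- 1L; truth$segment <- 1L }
  ord <- order(-pred$confidence, pred$segment, pred$start)
  pred <- pred[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(truth))
  tp <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(!matched & truth$class == pred$class[i] &
                    truth$segment == pred$segment[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j)
      regionIOU(c(pred$start[i], pred$end[i]),
                c(truth$start[j], truth$end[j])), numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou) {
      tp[i] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  cum <- cumsum(tp)
  denom <- if (recallDenominator == "truths") nrow(truth) else nrow(pred)
  out <- data.frame(confidence = pred$confidence, class = pred$class,
                    tp = tp,
                    precision = cum / seq_along(tp),
                    recall = if (denom > 0) cum / denom else rep(0, length(tp)))
  attr(out, "nTruths") <- nrow(truth)
  attr(out, "iou") <- iou
  out
}

#' Average precision from a precision-recall curve
#'
#' All-point interpolation: the interpolated precision at recall R is the
#' maximum precision attained at any recall at least R, and
#' \deqn{AP = \sum_n (R_{n+1} - R_n) P_{interp}(R_{n+1}).}
#'
#' @param curve output of [matchAndCurve()].
#' @return AP in [0, 1]; 0 for an empty curve.
#' @export
averagePrecision <- function(curve) {
  if (!nrow(curve)) return(0)
  rec <- curve$recall
  prec <- curve$precision
  pinterp <- rev(cummax(rev(prec)))
  dr <- diff(c(0, rec))
  sum(dr * pinterp)
}

#' Per-class average precision and its mean
#'
#' Computes AP per multiplet class (1..7) at one IOU threshold and the
#' unweighted mean over classes with at least one ground-truth region;
#' classes without ground truth are excluded and listed in the
#' "excluded" attribute.
#'
#' @param pred,truth region data.frames as in [matchAndCurve()].
#' @param iou IOU threshold.
#' @param classes classes to evaluate (default 1..7).
#' @param ... passed to [matchAndCurve()].
#' @return list(perClass = named numeric vector, mAP = numeric).
#' @export
meanAveragePrecision <- function(pred, truth, iou = 0.5, classes = 1:7,
                                 ...) {
  present <- classes[classes %in% truth$class]
  ap <- vapply(present, function(cl) {
    averagePrecision(matchAndCurve(pred[pred$class == cl, , drop = FALSE],
                                   truth[truth$class == cl, , drop = FALSE],
                                   iou = iou, ...))
  }, numeric(1))
  names(ap) <- present
  out <- list(perClass = ap, mAP = if (length(ap)) mean(ap) else NA_real_)
  attr(out, "excluded") <- setdiff(classes, present)
  out
}

#' Peak-level confusion matrix against an expert peak list
#'
#' Each annotated peak contributes one count at (true class, predicted
#' label at the grid point nearest to its position). A baseline label at
#' that point is counted in the "unassigned" column rather than as a
#' misclassification.
#'
#' @param peaks data.frame with columns \code{position_ppm} and
#'   \code{class} (1..7); extra columns (amplitude, linewidth) are
#'   ignored.
#' @param labels predicted integer label vector.
#' @param axis frequency axis of the prediction, Hz.
#' @param frequencyMHz spectrometer frequency used to convert ppm to Hz.
#' @return 7 x 8 matrix; rows true classes 1..7, columns "unassigned" then
#'   predicted classes 1..7.
#' @export
peakLevelConfusion <- function(peaks, labels, axis, frequencyMHz) {
  stopifnot(all(c("position_ppm", "class") %in% names(peaks)))
  if (any(peaks$class < 1L | peaks$class > 7L))
    stop("peak classes must lie in 1..7")
  posHz <- peaks$position_ppm * frequencyMHz
  bad <- posHz < min(axis) | posHz > max(axis)
  if (any(bad))
    stop("peak position(s) outside the spectrum axis: ",
         paste(format(peaks$position_ppm[bad]), collapse = ", "), " ppm")
  cm <- matrix(0L, 7L, 8L,
               dimnames = list(truth = 1:7,
                               predicted = c("unassigned", 1:7)))
  for (i in seq_len(nrow(peaks))) {
    idx <- which.min(abs(axis - posHz[i]))
    lab <- labels[idx]
    col <- if (lab == 0L) 1L else lab + 1L
    cm[peaks$class[i], col] <- cm[peaks$class[i], col] + 1L
  }
  cm
}
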