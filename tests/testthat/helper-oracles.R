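# Independent brute-force oracles for the evaluation metrics. These work on
# explicit point sets and per-rank curve enumeration, deliberately avoiding
# the package's own run-length and cumulative-sum code paths.

oracle_confusion <- function(y, yhat, K = 8L) {
  cm <- matrix(0L, K, K)
  for (k in seq_along(y)) cm[y[k] + 1L, yhat[k] + 1L] <-
      cm[y[k] + 1L, yhat[k] + 1L] + 1L
  dimnames(cm) <- list(truth = 0:(K - 1L), predicted = 0:(K - 1L))
  cm
}

oracle_class_metrics <- function(y, yhat, cl) {
  TP <- sum(y == cl & yhat == cl)
  FP <- sum(y != cl & yhat == cl)
  FN <- sum(y == cl & yhat != cl)
  TN <- sum(y != cl & yhat != cl)
  P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  R <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  F1 <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R) else NA_real_
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       accuracy = (TP + TN) / length(y), precision = P, recall = R, f1 = F1)
}

oracle_iou <- function(a, b) {
  pa <- seq(a[1], a[2])
  pb <- seq(b[1], b[2])
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# regions of a label vector as a list of point-index sets
oracle_regions <- function(labels) {
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
    if (labels[i] != 0L)
      out[[length(out) + 1L]] <- list(class = labels[i], points = i:j)
    i <- j + 1L
  }
  out
}

# ranked greedy one-to-one matching and exhaustive AP via the interpolated
# precision definition evaluated point by point
oracle_match_ap <- function(predRegions, truthRegions, confidences, t) {
  ord <- order(-confidences,
               vapply(predRegions, function(r) min(r$points), numeric(1)))
  matched <- rep(FALSE, length(truthRegions))
  tp <- logical(length(predRegions))
  for (r in ord) {
    pr <- predRegions[[r]]
    bestIou <- -1; bestJ <- 0L
    for (j in seq_along(truthRegions)) {
      tr <- truthRegions[[j]]
      if (matched[j] || tr$class != pr$class) next
      iou <- length(intersect(pr$points, tr$points)) /
        length(union(pr$points, tr$points))
      if (iou > bestIou) { bestIou <- iou; bestJ <- j }
    }
    if (bestJ > 0L && bestIou >= t) { tp[r] <- TRUE; matched[bestJ] <- TRUE }
  }
  tpRanked <- tp[ord]
  nT <- length(truthRegions)
  if (!length(tpRanked) || nT == 0L) return(0)
  prec <- cumsum(tpRanked) / seq_along(tpRanked)
  rec <- cumsum(tpRanked) / nT
  ap <- 0
  prevR <- 0
  for (n in seq_along(rec)) {
    pint <- max(prec[rec >= rec[n]])
    ap <- ap + (rec[n] - prevR) * pint
    prevR <- rec[n]
  }
  ap
}

# FFT-based discrete Hilbert transform (analytic-signal convention)
oracle_fft_hilbert <- function(y) {
  n <- length(y)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Im(stats::fft(stats::fft(y) * h, inverse = TRUE)) / n
}
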