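test_that("the point-wise confusion matrix counts (truth, prediction) pairs", {
  y <- c(0L, 1L, 1L)
  yh <- c(0L, 1L, 0L)
  cm <- pointwiseConfusion(y, yh)
  expect_equal(cm["1", "1"], 1L)
  expect_equal(cm["1", "0"], 1L)
  expect_equal(cm["0", "0"], 1L)
  expect_equal(sum(cm), 3L)
  # perfect prediction is diagonal
  cmd <- pointwiseConfusion(yh, yh)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0L)
  expect_error(pointwiseConfusion(0:1, 0:2), "length")
  expect_error(pointwiseConfusion(c(0L, 9L), c(0L, 0L)), "0..7")
})

test_that("per-class metrics follow the one-vs-rest definitions", {
  cm <- pointwiseConfusion(c(0L, 1L, 1L), c(0L, 1L, 0L))
  m <- classMetrics(cm, classes = 1L)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$TP + m$FP + m$FN + m$TN, sum(cm))
  # perfect prediction: all metrics 1 for supported classes
  y <- rep(0:3, each = 5)
  cmP <- pointwiseConfusion(y, y, 4L)
  mP <- classMetrics(cmP)
  expect_true(all(mP$accuracy == 1 & mP$precision == 1 &
                    mP$recall == 1 & mP$f1 == 1))
  # harmonic-mean identity: P == R implies F1 == P
  m2 <- classMetrics(pointwiseConfusion(c(1L, 1L, 0L, 2L),
                                        c(1L, 2L, 0L, 1L)), classes = 1L)
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)
})

test_that("zero-denominator metrics are NA, never silently zero", {
  # class 3 never occurs and is never predicted
  cm <- pointwiseConfusion(c(0L, 1L), c(0L, 1L), 4L)
  m <- classMetrics(cm, classes = 3L)
  expect_true(is.na(m$precision) && is.na(m$recall) && is.na(m$f1))
})

test_that("regions are maximal nonzero runs with mean-softmax confidence", {
  expect_equal(nrow(extractRegions(c(0L, 0L, 0L))), 0L)
  r <- extractRegions(c(1L, 1L, 0L, 2L, 2L))
  expect_equal(r$class, c(1L, 2L))
  expect_equal(r$start, c(1L, 4L))
  expect_equal(r$end, c(2L, 5L))
  # confidence is the arithmetic mean of the run's own-class softmax
  probs <- matrix(0.05, 3, 8)
  probs[1, 4] <- 0.6; probs[2, 4] <- 0.8
  probs[3, ] <- c(0.9, rep(0.1 / 7, 7))
  probs[1:2, -4] <- (1 - c(0.6, 0.8)) / 7
  pr <- new("PredictionResult", probabilities = probs,
            labels = c(3L, 3L, 0L))
  reg <- extractRegions(pr)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$confidence, 0.7)
})

test_that("1D IOU counts points of intersection over union", {
  expect_equal(regionIOU(c(3, 8), c(3, 8)), 1)
  expect_equal(regionIOU(c(1, 5), c(10, 12)), 0)
  expect_equal(regionIOU(c(1, 10), c(6, 15)), 5 / 15)
  expect_error(regionIOU(c(5, 3), c(1, 2)), "nonempty")
})

test_that("matching is ranked, greedy, one-to-one and threshold-sensitive", {
  truth <- data.frame(class = c(2L, 3L), start = c(1L, 30L),
                      end = c(10L, 45L))
  exact <- transform(truth, confidence = c(0.9, 0.8))
  cv <- matchAndCurve(exact, truth, iou = 0.5)
  expect_true(all(cv$precision == 1))
  expect_equal(cv$recall[nrow(cv)], 1)

  # single prediction with IOU 0.6: TP at t = 0.5, FP at t = 0.75
  pred <- data.frame(class = 2L, start = 1L, end = 6L, confidence = 0.7)
  expect_equal(regionIOU(c(1, 6), c(1, 10)), 0.6)
  expect_true(matchAndCurve(pred, truth[1, ], iou = 0.5)$tp)
  expect_false(matchAndCurve(pred, truth[1, ], iou = 0.75)$tp)

  # two same-class predictions on one truth: at most one TP
  two <- data.frame(class = 2L, start = c(1L, 1L), end = c(10L, 9L),
                    confidence = c(0.9, 0.8))
  cv2 <- matchAndCurve(two, truth[1, ], iou = 0.5)
  expect_equal(sum(cv2$tp), 1L)
})

test_that("average precision uses all-point interpolation", {
  allTP <- data.frame(precision = c(1, 1), recall = c(0.5, 1))
  expect_equal(averagePrecision(allTP), 1)
  allFP <- data.frame(precision = c(0, 0), recall = c(0, 0))
  expect_equal(averagePrecision(allFP), 0)
  # ranked flags TP, FP, TP with two truths
  cv <- data.frame(precision = c(1, 0.5, 2 / 3), recall = c(0.5, 0.5, 1))
  expect_equal(averagePrecision(cv), 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("point-wise metrics match brute-force enumeration on random vectors", {
  set.seed(421)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    y <- sample(0:7, n, TRUE)
    yh <- sample(0:7, n, TRUE)
    cm <- pointwiseConfusion(y, yh)
    expect_identical(unname(cm), unname(oracle_confusion(y, yh)))
    cl <- sample(0:7, 1)
    m <- classMetrics(cm, classes = cl)
    o <- oracle_class_metrics(y, yh, cl)
    expect_equal(m$TP, o$TP)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
  }
})

test_that("object-wise AP matches exhaustive curve construction on random vectors", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    y <- sample(0:3, n, TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
    yh <- sample(0:3, n, TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
    predRegions <- extractRegions(yh)
    truthRegions <- extractRegions(y)
    if (!nrow(predRegions) || !nrow(truthRegions)) next
    set.seed(1000 + i)
    predRegions$confidence <- runif(nrow(predRegions))
    for (t in c(0.3, 0.5, 0.75)) {
      ap <- averagePrecision(matchAndCurve(predRegions, truthRegions, t))
      oracleAp <- oracle_match_ap(
        lapply(seq_len(nrow(predRegions)), function(k)
          list(class = predRegions$class[k],
               points = predRegions$start[k]:predRegions$end[k])),
        lapply(seq_len(nrow(truthRegions)), function(k)
          list(class = truthRegions$class[k],
               points = truthRegions$start[k]:truthRegions$end[k])),
        predRegions$confidence, t)
      expect_equal(ap, oracleAp, tolerance = 1e-9)
    }
  }
})

test_that("fragmenting a correct region collapses AP while accuracy barely moves", {
  n <- 500
  y <- integer(n); y[101:130] <- 3L
  whole <- extractRegions(y); whole$confidence <- 1
  frag <- data.frame(class = c(3L, 4L), start = c(101L, 116L),
                     end = c(115L, 130L), confidence = c(0.9, 0.8))
  truth <- extractRegions(y)
  apWhole <- averagePrecision(matchAndCurve(whole, truth, 0.75))
  apFrag <- averagePrecision(matchAndCurve(frag, truth, 0.75))
  expect_equal(apWhole, 1)
  expect_lt(apFrag, apWhole)
  yhFrag <- integer(n); yhFrag[101:115] <- 3L; yhFrag[116:130] <- 4L
  acc <- mean(y == yhFrag)
  expect_gt(acc, 0.95)
})

test_that("raising the IOU threshold can only lower AP", {
  set.seed(5)
  for (i in 1:50) {
    n <- 60
    y <- sample(0:3, n, TRUE, prob = c(0.6, 0.13, 0.13, 0.14))
    yh <- y
    flip <- sample(n, 8)
    yh[flip] <- sample(0:3, 8, TRUE)
    pred <- extractRegions(yh)
    truth <- extractRegions(y)
    if (!nrow(pred) || !nrow(truth)) next
    pred$confidence <- runif(nrow(pred), 0.5, 1)
    ap50 <- averagePrecision(matchAndCurve(pred, truth, 0.5))
    ap75 <- averagePrecision(matchAndCurve(pred, truth, 0.75))
    expect_lte(ap75, ap50 + 1e-12)
  }
})

test_that("mAP averages only classes with ground truth", {
  truth <- data.frame(class = c(1L, 2L), start = c(1L, 20L), end = c(10L, 30L))
  pred <- transform(truth, confidence = 1)
  m <- meanAveragePrecision(pred, truth, iou = 0.5)
  expect_equal(unname(m$perClass), c(1, 1))
  expect_equal(m$mAP, 1)
  expect_equal(attr(m, "excluded"), 3:7)
})

test_that("peak-level confusion maps annotated peaks to predicted labels", {
  axis <- seq(0, 100, by = 0.2)
  labels <- integer(length(axis))
  labels[axis >= 39 & axis <= 41] <- 2L
  peaks <- data.frame(position_ppm = c(0.1, 0.05), class = c(2L, 3L))
  cm <- peakLevelConfusion(peaks, labels, axis, 400)  # 0.1 ppm * 400 = 40 Hz
  expect_equal(cm["2", "2"], 1L)             # inside the labeled region
  expect_equal(cm["3", "unassigned"], 1L)    # baseline point, not an error
  expect_equal(sum(cm), 2L)
  expect_error(peakLevelConfusion(data.frame(position_ppm = 2, class = 1L),
                                  labels, axis, 400), "outside")
})
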