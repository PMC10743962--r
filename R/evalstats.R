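# Evaluation statistics for segmentation and angle agreement: overlap
# metrics (IoU, Sorensen-Dice), pixelwise MSE, the pooled two-sample
# t-test, mean absolute percentage error, and a k-fold cross-validation
# harness.

.binarize <- function(m) m != 0

#' Intersection over union of two binary masks
#'
#' `|GT \&\& PR| / |GT || PR|`. Two empty masks score 1 (perfect agreement
#' on absence); one empty mask scores 0.
#'
#' @param gt,pr matrices of the same shape; nonzero = foreground.
#' @return scalar in \[0, 1\].
#' @export
maskIoU <- function(gt, pr) {
  if (!identical(dim(gt), dim(pr))) stop("mask shapes differ")
  g <- .binarize(gt); p <- .binarize(pr)
  u <- sum(g | p)
  if (u == 0) return(1)
  sum(g & p) / u
}

#' Sorensen-Dice coefficient of two binary masks
#'
#' `2 |GT \&\& PR| / (|GT| + |PR|)`. Two empty masks score 1; one empty
#' mask scores 0. For binary masks the identity
#' `dice = 2 iou / (1 + iou)` holds exactly.
#'
#' @inheritParams maskIoU
#' @return scalar in \[0, 1\].
#' @export
maskDice <- function(gt, pr) {
  if (!identical(dim(gt), dim(pr))) stop("mask shapes differ")
  g <- .binarize(gt); p <- .binarize(pr)
  s <- sum(g) + sum(p)
  if (s == 0) return(1)
  2 * sum(g & p) / s
}

#' Pixelwise mean squared error
#'
#' @param gt,pr numeric matrices (images or masks) of the same shape.
#' @return nonnegative scalar.
#' @export
pixelMSE <- function(gt, pr) {
  if (!identical(dim(gt), dim(pr))) stop("shapes differ")
  mean((gt - pr)^2)
}

#' Pooled two-sample t-test
#'
#' Equal-variance (pooled) two-sample t statistic
#' `t = (mean(a) - mean(b)) / (Sp * sqrt(1/n1 + 1/n2))` with `Sp` the
#' pooled standard deviation, `n1 + n2 - 2` degrees of freedom and a
#' two-tailed p-value from the t distribution.
#'
#' @param a,b numeric vectors, each of length >= 2, with nonzero pooled
#'   variance.
#' @return a list with elements `statistic`, `df`, `p.value`, `means`
#'   (length 2), `n` (length 2) and `pooledSD`.
#' @export
twoSampleT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance; t undefined")
  sp <- sqrt(sp2)
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tstat, df = df,
       p.value = 2 * pt(-abs(tstat), df),
       means = c(mean(a), mean(b)), n = c(n1, n2), pooledSD = sp)
}

#' Mean absolute percentage error
#'
#' `mean(|a_i - x_i| / |a_i|) * 100` with `a` the actual (reference) values
#' and `x` the predictions, plus the complementary accuracy `100 - MAPE`.
#' Scale-invariant; zero actual values are rejected.
#'
#' @param actual,predicted numeric vectors of equal length; no zero actuals.
#' @return list with `mape` (percent), `accuracy` (percent) and `n`.
#' @export
mapeScore <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("lengths differ")
  if (any(actual == 0)) stop("MAPE undefined for zero actual values")
  m <- mean(abs(actual - predicted) / abs(actual)) * 100
  list(mape = m, accuracy = 100 - m, n = length(actual))
}

#' k-fold cross-validation of a segmentation trainer
#'
#' Seeded uniform shuffle, contiguous split into `k` disjoint folds
#' covering the dataset; for each fold the trainer is fitted on the other
#' k-1 folds and scored (Dice, IoU, MSE) on the held-out items. The report
#' carries one row per fold plus an aggregate row with the mean and
#' standard deviation of the fold values.
#'
#' @param dataset list of cases, each a list with elements `image` and
#'   `mask` (or [SpinePhantom-class] objects).
#' @param k number of folds (default 10).
#' @param trainer function(cases, seed) returning a predictor
#'   function(image) -> binary mask.
#' @param seed integer seed for the fold shuffle (also passed to trainer).
#' @return data.frame with columns fold, sdc, iou, mse, and (on the
#'   aggregate row) sdcSD, iouSD, mseSD.
#' @export
crossValidate <- function(dataset, k = 10L, trainer, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  n <- length(dataset)
  if (n < k) stop("dataset smaller than the number of folds")
  asCase <- function(x)
    if (is(x, "SpinePhantom"))
      list(image = phantomImage(x), mask = phantomMask(x)) else x
  dataset <- lapply(dataset, asCase)
  ord <- .withSeed(seed, sample.int(n))
  # contiguous split of the shuffled order
  foldId <- integer(n)
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  foldId[ord] <- rep(seq_len(k), times = sizes)
  rows <- lapply(seq_len(k), function(f) {
    test <- dataset[foldId == f]
    train <- dataset[foldId != f]
    predict <- trainer(train, seed)
    m <- vapply(test, function(cs) {
      pr <- predict(cs$image)
      c(maskDice(cs$mask, pr), maskIoU(cs$mask, pr),
        pixelMSE(.binarize(cs$mask) * 1, .binarize(pr) * 1))
    }, numeric(3))
    data.frame(fold = as.character(f), sdc = mean(m[1, ]),
               iou = mean(m[2, ]), mse = mean(m[3, ]),
               sdcSD = NA_real_, iouSD = NA_real_, mseSD = NA_real_)
  })
  rep <- do.call(rbind, rows)
  agg <- data.frame(fold = "mean", sdc = mean(rep$sdc), iou = mean(rep$iou),
                    mse = mean(rep$mse), sdcSD = sd(rep$sdc),
                    iouSD = sd(rep$iou), mseSD = sd(rep$mse))
  out <- rbind(rep, agg)
  attr(out, "foldId") <- foldId
  out
}

#' Ten-radiograph Cobb-angle agreement study
#'
#' Paired Cobb-angle readings for ten AP radiographs: an automated
#' measurement and an expert's manual measurement per image, with the
#' reference vertebrae each reader selected. Feeding the two angle columns
#' to [twoSampleT()] and [mapeScore()] (experts as actual) reproduces the
#' published agreement statistics for this set (|t| = 0.1713 at 18 df,
#' p = 0.866; MAPE 3.87 percent).
#'
#' @return data.frame with columns id, autoUpper, autoLower, autoAngle,
#'   expertUpper, expertLower, expertAngle.
#' @export
cobbAgreementStudy <- function() {
  data.frame(
    id = c("0021", "0055", "0071", "0085", "0103",
           "0123", "0203", "0233", "0253", "0313"),
    autoUpper = c("TH08", "TH12", "TH09", "TH05", "TH06",
                  "TH10", "TH03", "TH05", "TH05", "TH06"),
    autoLower = c("LU03", "LU02", "LU04", "TH11", "TH12",
                  "LU03", "TH09", "LU04", "LU02", "TH12"),
    autoAngle = c(23.80, 12.50, 13.60, 25.30, 24.60,
                  23.10, 41.20, 32.60, 40.60, 16.70),
    expertUpper = c("TH08", "TH12", "TH09", "TH05", "TH06",
                    "TH10", "TH02", "TH05", "TH06", "TH06"),
    expertLower = c("LU03", "LU02", "LU03", "TH11", "TH12",
                    "LU03", "LU01", "LU04", "LU04", "TH12"),
    expertAngle = c(23.50, 13.70, 15.20, 26.20, 24.50,
                    22.90, 43.70, 32.50, 42.50, 17.20),
    stringsAsFactors = FALSE)
}
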