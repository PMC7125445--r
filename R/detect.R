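#' Band-constrained dynamic time warping distance
#'
#' Standard dynamic-programming DTW between equal-length series under a
#' Sakoe-Chiba band of half-width \code{ceiling(r * n)} cells, with squared
#' point cost; the accumulated cost is square-rooted. Symmetric and
#' non-negative; as \code{r} shrinks toward 0 the band forces the diagonal
#' path and the distance equals the Euclidean distance.
#'
#' @param a,b numeric series of equal length
#' @param r band fraction in (0, 1]
#' @return the DTW distance (a single number)
#' @export
dtwDistance <- function(a, b, r = 0.10) {
  stopifnot(length(a) == length(b), r > 0, r <= 1)
  .dtw_band_cpp(as.numeric(a), as.numeric(b), r)
}

#' DTW barycenter average (DBA) of a set of series
#'
#' Shape-based averaging: starting from the medoid (the member minimizing
#' the summed constrained DTW distance to all others), every series is
#' aligned to the current template under the band constraint and each
#' template point is updated to the mean of all points mapped onto it.
#' Iteration stops when the summed DTW distance to the template improves by
#' less than \code{tol} (relative) or after \code{maxIter} refinements.
#'
#' @param series numeric matrix, one series per row (>= 2 rows)
#' @param r Sakoe-Chiba band fraction (default 0.10)
#' @param maxIter maximum refinement iterations (default 10)
#' @param tol relative improvement tolerance (default 1e-4)
#' @return the template as a numeric vector, with attributes
#'   \code{"objective"} (summed DTW distance per iteration, including the
#'   initial medoid) and \code{"medoid"} (initial member index)
#' @export
dbaTemplate <- function(series, r = 0.10, maxIter = 10L, tol = 1e-4) {
  stopifnot(is.matrix(series), nrow(series) >= 2L)
  n <- nrow(series)
  D <- .dtw_cross_cpp(series, series, r)
  medoid <- which.min(rowSums(D))
  template <- series[medoid, ]
  objective <- sum(D[medoid, ])
  objTrace <- objective
  for (iter in seq_len(maxIter)) {
    sums <- numeric(length(template))
    counts <- numeric(length(template))
    for (i in seq_len(n)) {
      path <- .dtw_path_cpp(series[i, ], template, r)
      sums[path[, 2L]] <- sums[path[, 2L]] + series[i, path[, 1L]]
      counts[path[, 2L]] <- counts[path[, 2L]] + 1
    }
    candidate <- ifelse(counts > 0, sums / counts, template)
    newObj <- sum(.dtw_cross_cpp(series, matrix(candidate, 1L), r))
    if (newObj > objective) break # keep the better template
    improved <- (objective - newObj) > tol * max(objective, .Machine$double.eps)
    template <- candidate
    objective <- newObj
    objTrace <- c(objTrace, newObj)
    if (!improved) break
  }
  attr(template, "objective") <- objTrace
  attr(template, "medoid") <- medoid
  template
}

#' F1-maximizing decision threshold over a statistic
#'
#' Candidates are the midpoints between consecutive distinct sorted values
#' plus one candidate below the minimum (predict everything MRCP). The
#' decision rule is \code{statistic >= threshold} predicts MRCP; among
#' candidates achieving the maximal F1 the smallest threshold is returned.
#'
#' @param stat numeric decision statistic per training epoch
#' @param labels factor of epoch labels (MRCP / NON_MRCP)
#' @return list with \code{threshold} and the achieved training \code{f1}
#' @export
chooseThreshold <- function(stat, labels) {
  u <- sort(unique(stat))
  candidates <- if (length(u) > 1L)
    c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2) else u[1L] - 1
  pos <- labels == "MRCP"
  best <- c(threshold = candidates[1L], f1 = -1)
  for (thr in candidates) {
    pred <- stat >= thr
    f1 <- f1Score(sum(pred & pos), sum(pred & !pos), sum(!pred & pos))$f1
    if (f1 > best[["f1"]]) best <- c(threshold = thr, f1 = f1)
  }
  as.list(best)
}

# epochs (EpochSet with exactly 1 channel) -> n x len matrix of series
epochMatrix <- function(epochs) {
  arr <- epochs@data
  if (dim(arr)[1L] != 1L)
    stop("detectors operate on single-channel epochs")
  t(matrix(arr, nrow = dim(arr)[2L], ncol = dim(arr)[3L]))
}

# matched-filter statistic: the epoch is convolved with the time-reversed
# template (= cross-correlation) and the maximum over the central,
# same-length lags is taken
mfStatistic <- function(X, template) {
  n <- ncol(X)
  apply(X, 1L, function(x) {
    full <- stats::convolve(x, template, conj = TRUE, type = "open")
    start <- floor((length(full) - n) / 2) + 1L
    max(full[start:(start + n - 1L)])
  })
}

svmDefaultGamma <- function(X) 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))

# seeded stratified k-fold indices
cvFolds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# grid-searched SVM: kernel in {linear, radial}, C in {0.1,1,10,100},
# gamma in {1/(p*var), 0.01, 0.1}; selected by mean F1 over a seeded
# stratified 3-fold inner cross-validation on the training set
svmGridFit <- function(X, y, seed) {
  gammas <- unique(c(svmDefaultGamma(X), 0.01, 0.1))
  grid <- rbind(
    expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                gamma = NA_real_, stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                gamma = gammas, stringsAsFactors = FALSE))
  k <- 3L
  fold <- cvFolds(y, k, seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L) { f1s[f] <- 0; next }
      fit <- svmCall(X[tr, , drop = FALSE], y[tr], grid[g, ])
      pred <- predict(fit, X[!tr, , drop = FALSE])
      pos <- y[!tr] == "MRCP"
      p <- pred == "MRCP"
      f1s[f] <- f1Score(sum(p & pos), sum(p & !pos), sum(!p & pos))$f1
    }
    scores[g] <- mean(f1s)
  }
  bestIdx <- which.max(scores)
  best <- grid[bestIdx, ]
  list(model = svmCall(X, y, best),
       params = best, cvF1 = scores[bestIdx], grid = cbind(grid, f1 = scores))
}

svmCall <- function(X, y, par) {
  if (par$kernel == "linear")
    e1071::svm(X, y, kernel = "linear", cost = par$cost, scale = FALSE)
  else
    e1071::svm(X, y, kernel = "radial", cost = par$cost, gamma = par$gamma,
               scale = FALSE)
}

# shrinkage LDA: pooled covariance with a ridge toward the average variance,
# equal-prior midpoint decision. Handles p >= n.
ldaFit <- function(X, y, lambda = 1e-3) {
  mu1 <- colMeans(X[y == "MRCP", , drop = FALSE])
  mu0 <- colMeans(X[y == "NON_MRCP", , drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  Xc <- X
  Xc[y == "MRCP", ] <- sweep(X[y == "MRCP", , drop = FALSE], 2L, mu1)
  Xc[y == "NON_MRCP", ] <- sweep(X[y == "NON_MRCP", , drop = FALSE], 2L, mu0)
  S <- crossprod(Xc) / max(n - 2L, 1L)
  Sreg <- S + lambda * (sum(diag(S)) / p) * diag(p)
  w <- solve(Sreg, mu1 - mu0)
  b <- sum(w * (mu1 + mu0)) / 2
  list(w = w, b = b)
}

#' Fit one of the six MRCP detectors on single-channel training epochs
#'
#' \describe{
#'   \item{LDA}{pooled-covariance linear discriminant with a ridge/shrinkage
#'     covariance estimate (the raw sample vector is the feature vector).}
#'   \item{SVM}{libsvm with an internal seeded stratified 3-fold grid search
#'     over kernel (linear/RBF), cost, and gamma.}
#'   \item{NN_ED}{1-nearest-neighbor, Euclidean distance; stores the
#'     training epochs.}
#'   \item{NN_DTW}{1-nearest-neighbor with band-constrained DTW (r = 0.10).}
#'   \item{MF}{matched filter: template is the arithmetic mean of training
#'     MRCP epochs; statistic is the maximum of the convolution of the epoch
#'     with the time-reversed template; F1-maximizing threshold calibrated
#'     on the training set.}
#'   \item{TM}{template matching: template from \code{\link{dbaTemplate}} of
#'     the training MRCP epochs; statistic is minus the constrained DTW
#'     distance to the template; threshold as for MF.}
#' }
#'
#' @param kind detector name
#' @param train single-channel training \code{\linkS4class{EpochSet}} with
#'   both classes present (at least 2 epochs per class)
#' @param seed integer seed (SVM inner cross-validation)
#' @param thresholdEpochs optional \code{\linkS4class{EpochSet}} on which the
#'   MF/TM threshold is calibrated instead of the training set (opt-in
#'   optimistic variant; default NULL calibrates on \code{train})
#' @return a \code{\linkS4class{DetectorModel}}
#' @export
fitDetector <- function(kind = c("LDA", "SVM", "NN_ED", "NN_DTW", "MF", "TM"),
                        train, seed = 1L, thresholdEpochs = NULL) {
  kind <- match.arg(kind)
  y <- epochLabels(train)
  if (any(table(y) < 2L))
    stop("need at least 2 training epochs per class")
  X <- epochMatrix(train)
  len <- ncol(X)
  fit <- list(); threshold <- NA_real_
  meta <- list(seed = as.integer(seed), thresholdOn =
                 if (is.null(thresholdEpochs)) "train" else "external")
  r <- 0.10
  if (kind == "LDA") {
    fit <- ldaFit(X, y)
  } else if (kind == "SVM") {
    sg <- svmGridFit(X, y, seed)
    fit <- list(model = sg$model)
    meta$params <- sg$params
    meta$cvF1 <- sg$cvF1
  } else if (kind %in% c("NN_ED", "NN_DTW")) {
    fit <- list(X = X, y = y)
  } else if (kind %in% c("MF", "TM")) {
    M <- X[y == "MRCP", , drop = FALSE]
    template <- if (kind == "MF") colMeans(M)
                else as.numeric(dbaTemplate(M, r = r))
    fit <- list(template = template)
    calib <- if (is.null(thresholdEpochs)) train else thresholdEpochs
    statC <- detectorStatistic(kind, fit, epochMatrix(calib), r)
    sel <- chooseThreshold(statC, epochLabels(calib))
    threshold <- sel$threshold
    meta$calibrationF1 <- sel$f1
  }
  new("DetectorModel", kind = kind, fit = fit, threshold = threshold,
      dtwBandR = r, epochLength = as.integer(len), fitMeta = meta)
}

detectorStatistic <- function(kind, fit, X, r) {
  if (kind == "MF") mfStatistic(X, fit$template)
  else -drop(.dtw_cross_cpp(X, matrix(fit$template, 1L), r))
}

#' Predict class labels for single-channel epochs
#'
#' Deterministic given the model. Nearest-neighbor ties are broken by the
#' lowest training-epoch index; a MF/TM statistic exactly at the threshold
#' predicts MRCP.
#'
#' @param model a \code{\linkS4class{DetectorModel}}
#' @param epochs a single-channel \code{\linkS4class{EpochSet}} (or a
#'   numeric matrix with one epoch per row)
#' @return factor of predicted labels with levels MRCP, NON_MRCP
#' @export
predictDetector <- function(model, epochs) {
  X <- if (is.matrix(epochs)) epochs else epochMatrix(epochs)
  if (ncol(X) != model@epochLength)
    stop("epoch length does not match the fitted detector")
  kind <- model@kind
  pred <- if (kind == "LDA") {
    ifelse(drop(X %*% model@fit$w) >= model@fit$b, "MRCP", "NON_MRCP")
  } else if (kind == "SVM") {
    as.character(predict(model@fit$model, X))
  } else if (kind == "NN_ED") {
    tr <- model@fit$X
    sq <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
    as.character(model@fit$y[apply(sq, 1L, which.min)])
  } else if (kind == "NN_DTW") {
    D <- .dtw_cross_cpp(X, model@fit$X, model@dtwBandR)
    as.character(model@fit$y[apply(D, 1L, which.min)])
  } else {
    stat <- detectorStatistic(kind, model@fit, X, model@dtwBandR)
    ifelse(stat >= model@threshold, "MRCP", "NON_MRCP")
  }
  factor(pred, levels = c("MRCP", "NON_MRCP"))
}
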