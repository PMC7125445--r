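#' Fit a spatial representation on training epochs
#'
#' The five spatial backends map multichannel epochs to candidate
#' single-channel representations:
#' \describe{
#'   \item{NoF}{no filtering; identity transform, 19 outputs.}
#'   \item{SL}{surface Laplacian with unit distance weights: each working
#'     channel minus the mean of its montage neighbors; 9 outputs. Needs no
#'     fitting.}
#'   \item{ICA}{FastICA unmixing matrix estimated on the concatenation of all
#'     training epochs; 19 component time courses.}
#'   \item{CSP}{common spatial patterns on the two class-average (trace-
#'     normalized, ridge-regularized) covariances; keeps the single filter
#'     maximizing the MRCP/non-MRCP variance ratio; 1 output.}
#'   \item{PCA}{eigenvector rows of the pooled covariance of concatenated
#'     training data; 19 component time courses.}
#' }
#' Every filter row is sign-normalized so its largest-magnitude element is
#' positive, making fits reproducible up to the seed.
#'
#' @param method one of "NoF", "SL", "ICA", "CSP", "PCA"
#' @param train an \code{\linkS4class{EpochSet}} of multichannel training
#'   epochs (both classes present for CSP)
#' @param montage a \code{\link{standardMontage}} (needed for SL)
#' @param seed integer seed (ICA initialization)
#' @param cspFavor which class's variance the retained CSP filter maximizes
#' @return a \code{\linkS4class{SpatialModel}}
#' @export
fitSpatial <- function(method = c("NoF", "SL", "ICA", "CSP", "PCA"),
                       train, montage = standardMontage(), seed = 1L,
                       cspFavor = c("MRCP", "NON_MRCP")) {
  method <- match.arg(method)
  cspFavor <- match.arg(cspFavor)
  ch <- channelNames(train)
  p <- length(ch)
  meta <- list(seed = as.integer(seed))
  if (method == "NoF") {
    W <- diag(p); center <- rep(0, p); outs <- ch
  } else if (method == "SL") {
    work <- intersect(montage$workingChannels, ch)
    W <- matrix(0, length(work), p, dimnames = list(work, ch))
    for (wch in work) {
      nb <- intersect(montage$neighbors[[wch]], ch)
      W[wch, wch] <- 1
      W[wch, nb] <- -1 / length(nb)
    }
    center <- rep(0, p); outs <- work
  } else {
    X <- concatEpochs(train) # p x (samples * epochs)
    center <- rowMeans(X)
    Xc <- X - center
    if (method == "PCA") {
      S <- Xc %*% t(Xc) / ncol(Xc)
      eg <- eigen(S, symmetric = TRUE)
      W <- t(eg$vectors)
      outs <- sprintf("PC%02d", seq_len(p))
      meta$eigenvalues <- eg$values
    } else if (method == "ICA") {
      fi <- fastIcaDeflation(Xc, seed = seed)
      W <- fi$W
      outs <- sprintf("IC%02d", seq_len(p))
      meta$converged <- fi$converged
      meta$iterations <- fi$iterations
      meta$retries <- fi$retries
    } else { # CSP
      y <- epochLabels(train)
      if (nlevels(droplevels(y)) < 2L)
        stop("CSP requires both classes in the training set")
      C1 <- classCovariance(train, "MRCP")
      C2 <- classCovariance(train, "NON_MRCP")
      w <- cspFirstFilter(C1, C2, favor = if (cspFavor == "MRCP") 1L else 2L)
      W <- matrix(w, 1L, p)
      center <- rep(0, p)
      outs <- "CSP1"
    }
  }
  W <- normalizeSigns(W)
  rownames(W) <- outs; colnames(W) <- ch
  new("SpatialModel", method = method, weights = W, center = center,
      outputNames = outs, channelNames = ch, fitMeta = meta)
}

#' Project epochs through a fitted spatial model
#'
#' Each multichannel epoch becomes \code{nrow(weights)} single-channel
#' component time courses, returned as an \code{\linkS4class{EpochSet}}
#' whose "channels" are the model outputs.
#'
#' @param model a \code{\linkS4class{SpatialModel}}
#' @param epochs an \code{\linkS4class{EpochSet}} with channel order matching
#'   the model
#' @return the projected \code{\linkS4class{EpochSet}}
#' @export
applySpatial <- function(model, epochs) {
  if (!identical(channelNames(epochs), model@channelNames))
    stop("epoch channel order does not match the spatial model")
  arr <- epochs@data
  d <- dim(arr)
  out <- array(0, dim = c(nrow(model@weights), d[2L], d[3L]))
  for (i in seq_len(d[3L])) {
    m <- arr[, , i, drop = FALSE]; dim(m) <- d[1:2]
    out[, , i] <- model@weights %*% (m - model@center)
  }
  new("EpochSet", data = out, labels = epochs@labels, fs = epochs@fs,
      channelNames = model@outputNames, band = epochs@band,
      sourceEvent = epochs@sourceEvent)
}

# concatenate all epochs along time: p x (samples * epochs)
concatEpochs <- function(epochs) {
  arr <- epochs@data
  d <- dim(arr)
  matrix(arr, nrow = d[1L], ncol = d[2L] * d[3L])
}

# average trace-normalized covariance of one class's epochs, with a small
# ridge for numerical safety
classCovariance <- function(epochs, class, lambda = 1e-6) {
  idx <- which(epochLabels(epochs) == class)
  arr <- epochs@data
  p <- dim(arr)[1L]
  S <- matrix(0, p, p)
  for (i in idx) {
    m <- arr[, , i, drop = FALSE]; dim(m) <- dim(arr)[1:2]
    Ci <- tcrossprod(m) / ncol(m)
    tr <- sum(diag(Ci))
    if (tr > 0) S <- S + Ci / tr
  }
  S <- S / length(idx)
  S + lambda * (sum(diag(S)) / p) * diag(p)
}

# first CSP filter: generalized eigenvector of (C1, C1 + C2) with the
# largest (favor = 1) eigenvalue, i.e. the spatial direction maximizing the
# class-1 / class-2 variance ratio
cspFirstFilter <- function(C1, C2, favor = 1L) {
  Cc <- C1 + C2
  eg <- eigen(Cc, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  P <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep, drop = FALSE])
  S1 <- P %*% C1 %*% t(P)
  eb <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  j <- if (favor == 1L) 1L else ncol(eb$vectors)
  w <- drop(t(eb$vectors[, j]) %*% P)
  w / sqrt(sum(w^2))
}

# make the largest-magnitude element of every filter row positive
normalizeSigns <- function(W) {
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  W
}

# FastICA by deflation with tanh contrast on pre-whitened data.
# X: p x n, already centered per row. Returns the full unmixing matrix W
# (p x p) such that S = W %*% X has approximately independent rows.
fastIcaDeflation <- function(X, seed = 1L, maxIter = 200L, tol = 1e-4,
                             maxRetries = 3L) {
  p <- nrow(X); n <- ncol(X)
  S <- tcrossprod(X) / n
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, max(eg$values) * 1e-12)
  K <- diag(1 / sqrt(vals)) %*% t(eg$vectors) # whitening, p x p
  Z <- K %*% X
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  converged <- logical(p); iters <- integer(p); retriesUsed <- 0L
  B <- matrix(0, p, p) # orthonormal rows found so far
  for (comp in seq_len(p)) {
    done <- FALSE
    for (retry in 0:maxRetries) {
      set.seed(as.integer(seed) + 1000L * retry + comp)
      w <- stats::rnorm(p); w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxIter)) {
        wx <- drop(crossprod(w, Z)) # 1 x n
        g <- tanh(wx)
        gp <- 1 - g^2
        wNew <- drop(Z %*% g) / n - mean(gp) * w
        # Gram-Schmidt against previously extracted components
        if (comp > 1L) {
          prev <- B[seq_len(comp - 1L), , drop = FALSE]
          wNew <- wNew - drop(t(prev) %*% (prev %*% wNew))
        }
        nrm <- sqrt(sum(wNew^2))
        if (nrm < 1e-12) break
        wNew <- wNew / nrm
        delta <- abs(abs(sum(wNew * w)) - 1)
        w <- wNew
        if (delta < tol) { done <- TRUE; break }
      }
      if (done) { iters[comp] <- it; break }
      retriesUsed <- retriesUsed + 1L
    }
    converged[comp] <- done
    B[comp, ] <- w
  }
  list(W = B %*% K, converged = all(converged), iterations = iters,
       retries = retriesUsed)
}
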