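# orthonormal deviation contrasts for a k-level factor (rows are contrasts)
orthonormalContrasts <- function(k) {
  cc <- stats::contr.helmert(k)
  t(sweep(cc, 2L, sqrt(colSums(cc^2)), "/"))
}

# build the orthonormal projection rows for one effect across all cells.
# Cells are ordered with the FIRST factor varying fastest (expand.grid
# convention); kronecker() varies its second argument's index fastest, so
# the factor matrices are combined in reverse order.
effectProjection <- function(factors, effect) {
  mats <- lapply(names(factors), function(f) {
    k <- length(factors[[f]])
    if (f %in% effect) orthonormalContrasts(k)
    else matrix(1 / sqrt(k), 1L, k)
  })
  Reduce(kronecker, rev(mats))
}

effectSubsets <- function(nms) {
  out <- list()
  for (size in seq_along(nms)) {
    cmb <- utils::combn(nms, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Repeated-measures ANOVA for a balanced within-subject factorial
#'
#' Classical univariate repeated-measures analysis: every effect (main
#' effects and all interactions of the within-subject factors) is tested
#' against its own effect-by-subject error term, with a Greenhouse-Geisser
#' sphericity correction computed per effect from the covariance of that
#' effect's orthonormal within-subject contrast scores:
#' \eqn{\epsilon = tr(S)^2 / (q \, tr(S^2))}, clipped to
#' \eqn{[1/q, 1]} where \eqn{q} is the effect's uncorrected df. Reported
#' sums of squares are Type III, which coincides with the sequential
#' decomposition in this balanced complete design. Partial eta squared is
#' \eqn{SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param response numeric matrix, subjects x cells; cells ordered with the
#'   first factor in \code{factors} varying fastest
#' @param factors named list of factor level vectors, e.g.
#'   \code{list(Freq = ..., SF = ..., Classifier = ...)}
#' @return data.frame with one row per effect: \code{effect}, \code{ss},
#'   \code{df}, \code{epsilon}, \code{dfCorrected}, \code{ms}, \code{errorSs},
#'   \code{errorDf}, \code{errorDfCorrected}, \code{errorMs}, \code{F},
#'   \code{p} (GG-corrected), \code{partialEtaSq}
#' @export
rmAnova <- function(response, factors) {
  stopifnot(is.matrix(response), is.list(factors), length(factors) >= 1L)
  n <- nrow(response)
  if (n < 2L) stop("repeated-measures ANOVA needs at least 2 subjects")
  p <- prod(lengths(factors))
  if (ncol(response) != p)
    stop("response must have one column per factor-level combination")
  effects <- effectSubsets(names(factors))
  rows <- lapply(effects, function(eff) {
    M <- effectProjection(factors, eff)
    q <- nrow(M)
    Z <- response %*% t(M) # n x q contrast scores
    zbar <- colMeans(Z)
    ssEff <- n * sum(zbar^2)
    R <- sweep(Z, 2L, zbar)
    ssErr <- sum(R^2)
    S <- crossprod(R) / (n - 1L)
    trS <- sum(diag(S))
    eps <- if (q == 1L || trS <= 0) 1
           else max(min(trS^2 / (q * sum(S^2)), 1), 1 / q)
    dfErr <- q * (n - 1L)
    msEff <- ssEff / q
    msErr <- ssErr / dfErr
    # degenerate (constant) responses: both SS vanish up to rounding
    degenerate <- (ssEff + ssErr) <= 1e-16 * max(sum(response^2), 1)
    Fval <- if (!degenerate && msErr > 0) msEff / msErr else NA_real_
    pval <- if (is.na(Fval)) NA_real_
            else stats::pf(Fval, q * eps, dfErr * eps, lower.tail = FALSE)
    data.frame(effect = paste(eff, collapse = ":"),
               ss = ssEff, df = q, epsilon = eps,
               dfCorrected = q * eps, ms = ssEff / (q * eps),
               errorSs = ssErr, errorDf = dfErr,
               errorDfCorrected = dfErr * eps,
               errorMs = ssErr / (dfErr * eps),
               F = Fval, p = pval,
               partialEtaSq = if (ssEff + ssErr > 0) ssEff / (ssEff + ssErr)
                              else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-way repeated-measures ANOVA of a factorial F1 table
#'
#' Convenience wrapper around \code{\link{rmAnova}} for the standard
#' spatial-filter x frequency x classifier design (rows for SF, Freq,
#' Classifier and all interactions, each with its own subject-interaction
#' error term and Greenhouse-Geisser correction).
#'
#' @param response subjects x cells matrix (see \code{\link{factorialResponse}})
#' @param factors named list of the three factor level vectors
#' @return see \code{\link{rmAnova}}
#' @export
rmAnova3way <- function(response, factors) {
  stopifnot(length(factors) == 3L)
  rmAnova(response, factors)
}

#' One-way simple-effect repeated-measures ANOVA
#'
#' Tests one within-subject factor with the remaining factors either
#' averaged out or fixed at a single level, e.g. the simple effect of the
#' spatial filter at one frequency band.
#'
#' @param response subjects x cells matrix over the full design
#' @param factors named list of all factor level vectors (cell order as in
#'   \code{\link{rmAnova}})
#' @param factor name of the tested factor
#' @param at optional named list fixing other factors to single levels,
#'   e.g. \code{list(Freq = "0.01-1")}; factors not named are averaged over
#' @return a single-row data.frame as in \code{\link{rmAnova}}
#' @export
rmAnova1way <- function(response, factors, factor, at = list()) {
  stopifnot(factor %in% names(factors))
  cells <- do.call(expand.grid,
                   c(factors, list(stringsAsFactors = FALSE)))
  keep <- rep(TRUE, nrow(cells))
  for (f in names(at)) keep <- keep & cells[[f]] %in% at[[f]]
  sub <- response[, keep, drop = FALSE]
  cellsKept <- cells[keep, , drop = FALSE]
  levs <- factors[[factor]]
  collapsed <- sapply(levs, function(lv)
    rowMeans(sub[, cellsKept[[factor]] == lv, drop = FALSE]))
  out <- rmAnova(collapsed, stats::setNames(list(levs), factor))
  if (length(at))
    out$effect <- paste0(out$effect, " at ",
                         paste(names(at), unlist(at), sep = "=",
                               collapse = ","))
  out
}

#' Bonferroni-adjusted pairwise post hoc comparisons
#'
#' All k(k-1)/2 paired t-tests on subject-level factor means (averaged over
#' the remaining factors), with p-values multiplied by the number of
#' comparisons and clipped at 1.
#'
#' @inheritParams rmAnova1way
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.01)
#' @return data.frame with one row per level pair: \code{levelA},
#'   \code{levelB}, \code{meanDiff}, \code{t}, \code{df}, \code{pRaw},
#'   \code{pAdjusted}, \code{significant}
#' @export
posthocBonferroni <- function(response, factors, factor, alpha = 0.01) {
  stopifnot(factor %in% names(factors))
  cells <- do.call(expand.grid,
                   c(factors, list(stringsAsFactors = FALSE)))
  levs <- factors[[factor]]
  means <- sapply(levs, function(lv)
    rowMeans(response[, cells[[factor]] == lv, drop = FALSE]))
  pairs <- utils::combn(length(levs), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    d <- means[, a] - means[, b]
    if (stats::sd(d) < 1e-12 * max(abs(means), 1)) {
      # constant difference: no evidence against equality when it is zero
      tval <- NA_real_
      praw <- if (abs(mean(d)) < 1e-12) 1 else 0
      dfv <- length(d) - 1
    } else {
      tt <- stats::t.test(means[, a], means[, b], paired = TRUE)
      tval <- unname(tt$statistic); praw <- tt$p.value
      dfv <- unname(tt$parameter)
    }
    data.frame(levelA = levs[a], levelB = levs[b],
               meanDiff = mean(d), t = tval, df = dfv, pRaw = praw,
               pAdjusted = min(1, praw * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$pAdjusted < alpha
  out
}

#' Estimated marginal means of a factor or factor pair
#'
#' Level (or level-combination) means of the response averaged over the
#' remaining factors and subjects, with the standard error computed over
#' subjects.
#'
#' @inheritParams rmAnova1way
#' @param which character vector of one or two factor names
#' @return data.frame with the level columns, \code{emm}, and \code{se}
#' @export
estimatedMarginalMeans <- function(response, factors, which) {
  stopifnot(all(which %in% names(factors)), length(which) %in% 1:2)
  cells <- do.call(expand.grid,
                   c(factors, list(stringsAsFactors = FALSE)))
  combos <- do.call(expand.grid,
                    c(factors[which], list(stringsAsFactors = FALSE)))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    keep <- rep(TRUE, nrow(cells))
    for (f in which) keep <- keep & cells[[f]] == combos[i, f]
    perSubject <- rowMeans(response[, keep, drop = FALSE])
    cbind(combos[i, , drop = FALSE],
          data.frame(emm = mean(perSubject),
                     se = stats::sd(perSubject) / sqrt(length(perSubject))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an ANOVA table for human reading
#'
#' Formats p-values to three decimals with values below 0.001 shown as
#' "<0.001"; the raw machine values stay in the returned data of
#' \code{\link{rmAnova}}.
#'
#' @param tab output of \code{\link{rmAnova}}
#' @return data.frame of formatted character columns
#' @export
formatAnovaTable <- function(tab) {
  data.frame(
    Source = tab$effect,
    `TypeIII.SS` = sprintf("%.3f", tab$ss),
    `Corrected.df` = sprintf("%.3f", tab$dfCorrected),
    `Mean.square` = sprintf("%.3f", tab$ms),
    `F.value` = sprintf("%.3f", tab$F),
    `P.value` = ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p)),
    `Partial.eta.sq` = sprintf("%.3f", tab$partialEtaSq),
    check.names = FALSE, stringsAsFactors = FALSE)
}
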