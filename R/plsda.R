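## Two-class PLS-DA by NIPALS PLS1, VIP scores, leave-one-out cross-
## validation, and label-permutation significance testing.

# Core NIPALS PLS1 on centred X and y; returns weights (unit norm), scores,
# X loadings, y loadings and the response sum of squares explained per LV.
plsNipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp); ssy <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]; ssy <- ssy[seq_len(a - 1)]
      break
    }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - t %*% t(pvec)
    ya <- ya - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t
    q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  list(W = W, P = P, T = Tm, q = q, ssy = ssy)
}

# regression coefficients in original X space (centred)
plsCoefficients <- function(fit) {
  if (ncol(fit$W) == 0) return(NULL)
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  as.numeric(Wstar %*% fit$q)
}

plsPredictRaw <- function(fit, xMean, yMean, Xnew) {
  b <- plsCoefficients(fit)
  if (is.null(b)) return(rep(yMean, nrow(Xnew)))
  as.numeric(sweep(Xnew, 2, xMean) %*% b) + yMean
}

# leave-one-out predicted class scores (numeric, threshold at 0 for +/-1
# coding): each left-out sample gets a model refit on the remainder.
plsLooScores <- function(X, y01, ncomp) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y01[-i]
    xm <- colMeans(Xtr)
    ym <- mean(ytr)
    fit <- plsNipals(sweep(Xtr, 2, xm), ytr - ym, ncomp)
    out[i] <- plsPredictRaw(fit, xm, ym, X[i, , drop = FALSE])
  }
  out
}

#' Fit a two-class PLS-DA model
#'
#' Encodes the two classes as a -1/+1 response (the second factor level,
#' conventionally "treated", is +1), mean-centres the spectral matrix, and
#' extracts latent variables by NIPALS PLS1 so that each LV maximizes
#' covariance between spectra and class response with deflation between
#' components.  Leave-one-out cross-validation (full refit per left-out
#' sample) yields class predictions, sensitivity and specificity with the
#' +1 class as positive.
#'
#' @param spectra a [SpectrumSet] with exactly two classes and at least two
#'   samples per class.
#' @param ncomp number of latent variables (default 2).
#' @return a [PLSDAModel].
#' @export
fitPLSDA <- function(spectra, ncomp = 2L) {
  stopifnot(is(spectra, "SpectrumSet"))
  X <- intensities(spectra)
  labels <- droplevels(classLabels(spectra))
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (any(table(labels) < 2)) stop("at least two samples per class are required")
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must lie in [1, min(samples - 1, variables)]")
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  xm <- colMeans(X)
  fit <- plsNipals(sweep(X, 2, xm), y - mean(y), ncomp)
  if (sum(fit$ssy) <= 0) stop("model explains no response variance")

  vip <- computeVip(fit)

  looScore <- plsLooScores(X, y, ncomp)
  pred <- factor(ifelse(looScore >= 0, levels(labels)[2], levels(labels)[1]),
                 levels = levels(labels))
  pos <- labels == levels(labels)[2]
  sens <- mean(pred[pos] == labels[pos])
  spec <- mean(pred[!pos] == labels[!pos])

  vn <- colnames(X)
  if (is.null(vn)) vn <- as.character(seq_len(p))
  new("PLSDAModel", ncomp = as.integer(ncol(fit$W)), scores = fit$T,
      loadings = fit$P, weights = fit$W, yLoadings = fit$q, ssy = fit$ssy,
      vip = vip, cvPredicted = pred, cvSensitivity = sens,
      cvSpecificity = spec, labels = labels, varNames = vn)
}

# VIP_j = sqrt( p * sum_a w_ja^2 ssy_a / sum_a ssy_a ); with unit-norm
# weight vectors the mean squared VIP over variables is exactly 1.
computeVip <- function(fit) {
  p <- nrow(fit$W)
  wss <- fit$W^2 %*% fit$ssy
  as.numeric(sqrt(p * wss / sum(fit$ssy)))
}

#' Permutation test for PLS-DA model significance
#'
#' The test statistic is leave-one-out classification accuracy.  Class
#' labels are permuted `nPermutations` times, the full fit-and-validate
#' pipeline is repeated for each permutation, and the p value uses the
#' add-one convention `p = (#\{permuted >= observed\} + 1) / (n + 1)`, so it
#' is never zero.
#'
#' @param spectra a [SpectrumSet].
#' @param ncomp latent variables (default 2).
#' @param nPermutations number of label permutations (default 1000).
#' @param seed integer seed controlling the permutations (optional).
#' @return list of class `PermutationResult`: `observedStat` (LOO
#'   accuracy), `permutedStats`, `pValue`, `nPermutations`.
#' @export
plsdaPermutationTest <- function(spectra, ncomp = 2L, nPermutations = 1000L,
                                 seed = NULL) {
  stopifnot(is(spectra, "SpectrumSet"))
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  X <- intensities(spectra)
  labels <- droplevels(classLabels(spectra))
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  looAccuracy <- function(yv) {
    sc <- plsLooScores(X, yv, ncomp)
    mean(sign(sc) == yv | (sc == 0 & yv == 1))
  }
  observed <- looAccuracy(y)
  permuted <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) looAccuracy(sample(y)),
           numeric(1))
  })
  p <- (sum(permuted >= observed) + 1) / (nPermutations + 1)
  structure(list(observedStat = observed, permutedStats = permuted,
                 pValue = p, nPermutations = as.integer(nPermutations)),
            class = "PermutationResult")
}
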