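## Nonparametric group comparison and assay calculations: Mann-Whitney U
## (exact by enumeration for small tie-free samples, tie- and continuity-
## corrected normal approximation otherwise), median +/- MAD summaries,
## caliper tumor volume, and four-parameter logistic immunoassay
## calibration.

#' Two-tailed Mann-Whitney U test with median +/- MAD summaries
#'
#' U is computed from midrank sums.  For tie-free samples with
#' `nA + nB <= maxExact` the two-tailed p value is exact, by full
#' enumeration of all `choose(nA + nB, nA)` rank assignments
#' (`p = 2 * min(P(U <= u), P(U >= u))`, capped at 1); otherwise a normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used.  Summaries are median +/- unscaled MAD.
#'
#' @param a,b numeric vectors of per-tumor values (each non-empty).
#' @param metric label attached to the comparison.
#' @param alpha significance level recorded for reporting (default 0.05).
#' @param maxExact largest combined sample size for the exact enumeration
#'   path (default 12).
#' @return a [GroupComparison].
#' @export
mannWhitneyU <- function(a, b, metric = "", alpha = 0.05, maxExact = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))

  if (!ties && n <= maxExact) {
    dist <- exactUDistribution(na, nb)
    pLe <- sum(dist$prob[dist$u <= u])
    pGe <- sum(dist$prob[dist$u >= u])
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tieTab <- table(c(a, b))
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- na * nb / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal-approximation"
  }
  sa <- medianMAD(a); sb <- medianMAD(b)
  new("GroupComparison", metric = as.character(metric), groupA = a, groupB = b,
      uStatistic = u, pValue = p, method = method,
      medianA = sa[["median"]], madA = sa[["mad"]],
      medianB = sb[["median"]], madB = sb[["mad"]], alpha = alpha)
}

# exact null distribution of U for group sizes na, nb (no ties): enumerate
# all rank subsets of size na.
exactUDistribution <- function(na, nb) {
  n <- na + nb
  cmb <- combn(n, na)
  u <- colSums(cmb) - na * (na + 1) / 2
  tab <- table(u)
  data.frame(u = as.numeric(names(tab)),
             prob = as.numeric(tab) / ncol(cmb))
}

#' Median and (unscaled) median absolute deviation
#'
#' MAD here is the plain median of absolute deviations from the median,
#' with no 1.4826 normal-consistency factor.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector with `median` and `mad`.
#' @export
medianMAD <- function(values) {
  if (length(values) < 1) stop("at least one value is required")
  m <- median(values)
  c(median = m, mad = median(abs(values - m)))
}

#' Caliper tumor volume
#'
#' `volume = 1/2 * length * width^2` (mm^3).  If width exceeds length the
#' two are swapped with a warning.
#'
#' @param length,width caliper measurements in mm (vectorized).
#' @return volumes in mm^3.
#' @export
tumorVolume <- function(length, width) {
  swap <- width > length
  if (any(swap)) {
    warning("width > length for some measurements; swapping")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.5 * length * width^2
}

#' Normalize a tumor volume series to its baseline day
#'
#' @param volumes numeric volumes (mm^3).
#' @param days day labels, same length.
#' @param baselineDay the reference day (default the earliest).
#' @return data.frame with `day`, `volume`, `normalizedVolume`.
#' @export
normalizeVolumeSeries <- function(volumes, days, baselineDay = min(days)) {
  stopifnot(length(volumes) == length(days))
  base <- volumes[match(baselineDay, days)]
  if (is.na(base) || base <= 0) stop("baseline volume missing or non-positive")
  ord <- order(days)
  data.frame(day = days[ord], volume = volumes[ord],
             normalizedVolume = volumes[ord] / base)
}

## ---- four-parameter logistic immunoassay calibration -----------------------

#' Fit a four-parameter logistic calibration curve
#'
#' `y = d + (a - d) / (1 + (x / c)^b)`, fit to standards by least squares
#' with the inflection concentration kept positive (fitted on a log scale).
#' Starting values come from the data extremes and quartiles.
#'
#' @param conc standard concentrations (> 0).
#' @param absorbance measured responses, same length.
#' @return list of class `FourPL` with elements `a`, `b`, `c`, `d` and the
#'   fitted model object.
#' @export
fitFourPL <- function(conc, absorbance) {
  stopifnot(length(conc) == length(absorbance), length(conc) >= 4,
            all(conc > 0))
  ord <- order(conc)
  x <- conc[ord]; y <- absorbance[ord]
  start <- list(a = y[1], d = y[length(y)], logc = log(median(x)), b = 1)
  fit <- minpack.lm::nlsLM(
    y ~ d + (a - d) / (1 + (x / exp(logc))^b),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = exp(unname(cf["logc"])), d = unname(cf["d"]),
                 fit = fit), class = "FourPL")
}

#' Evaluate a four-parameter logistic curve
#' @param model a `FourPL` fit.
#' @param conc concentrations.
#' @return predicted responses.
#' @export
predictFourPL <- function(model, conc) {
  with(model, d + (a - d) / (1 + (conc / c)^b))
}

#' Invert a four-parameter logistic curve
#'
#' Closed-form inverse; responses outside the open asymptote range return
#' `NA` (out of calibration range).
#'
#' @param model a `FourPL` fit.
#' @param absorbance responses to invert.
#' @return concentrations (`NA` where out of range).
#' @export
invertFourPL <- function(model, absorbance) {
  lo <- min(model$a, model$d); hi <- max(model$a, model$d)
  out <- rep(NA_real_, length(absorbance))
  ok <- absorbance > lo & absorbance < hi
  y <- absorbance[ok]
  out[ok] <- model$c * ((model$a - model$d) / (y - model$d) - 1)^(1 / model$b)
  out
}

#' Quantify an immunoassay sample against a 4PL standard curve
#'
#' Fits the standards, filters replicate readings to the usable range
#' (inside the fitted asymptotes and, optionally, a transmittance-derived
#' absorbance window), inverts the mean in-range absorbance, applies the
#' dilution factor, and normalizes the analyte amount to the RNA content of
#' the same sample.
#'
#' @param absorbances replicate absorbance readings for the sample.
#' @param standards data.frame with columns `conc` and `absorbance`.
#' @param dilution dilution factor applied to the sample (default 1).
#' @param rnaNg RNA content of the sample in ng (for the per-ng result).
#' @param transmittanceRange optional acceptance window on transmittance
#'   (e.g. `c(0.2, 0.8)`); readings with `10^(-A)` outside it are excluded.
#' @return list with `concentration` (analyte per volume after dilution
#'   correction), `perNgRna` (concentration / rnaNg, `NA` if `rnaNg`
#'   missing), `nUsed`, `excluded` (logical per replicate), `flagged`
#'   (TRUE when fewer than 2 in-range replicates remained), and `model`.
#' @export
pge2Quantify <- function(absorbances, standards, dilution = 1, rnaNg = NA,
                         transmittanceRange = NULL) {
  model <- fitFourPL(standards$conc, standards$absorbance)
  lo <- min(model$a, model$d); hi <- max(model$a, model$d)
  inRange <- absorbances > lo & absorbances < hi
  if (!is.null(transmittanceRange)) {
    tr <- 10^(-absorbances)
    inRange <- inRange & tr >= min(transmittanceRange) &
      tr <= max(transmittanceRange)
  }
  flagged <- sum(inRange) < 2
  if (!any(inRange)) {
    return(list(concentration = NA_real_, perNgRna = NA_real_, nUsed = 0L,
                excluded = !inRange, flagged = TRUE, model = model))
  }
  conc <- invertFourPL(model, mean(absorbances[inRange])) * dilution
  list(concentration = conc,
       perNgRna = if (is.na(rnaNg)) NA_real_ else conc / rnaNg,
       nUsed = sum(inRange), excluded = !inRange, flagged = flagged,
       model = model)
}
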