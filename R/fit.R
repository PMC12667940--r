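#' Fit a smoothed trajectory for one gene and test temporal variation
#'
#' Fits a cubic regression spline (natural cubic spline basis with `df`
#' basis functions, Gaussian response) of expression on pseudotime and
#' tests it against the intercept-only model with a likelihood-ratio test
#' on a chi-square reference with `df` degrees of freedom.
#'
#' A gene with zero expression variance gets a constant fit and p-value 1.
#'
#' @param expr numeric expression vector over the ordered cells.
#' @param pseudotime strictly increasing numeric vector, same length.
#' @param df spline basis dimension (default 3). Requires
#'   `N >= 2 * (df + 1)`.
#' @return list with `fitted` (length-N numeric) and `pvalue`.
#' @examples
#' pt <- 1:100
#' fitGeneTrajectory(plogis((pt - 50) / 10), pt)$pvalue
#' @export
fitGeneTrajectory <- function(expr, pseudotime, df = 3) {
  n <- length(expr)
  if (length(pseudotime) != n)
    stop("expr and pseudotime must have the same length")
  if (!all(is.finite(expr)))
    stop("expr must be finite")
  if (any(diff(pseudotime) <= 0))
    stop("pseudotime must be strictly increasing")
  if (n < 2 * (df + 1))
    stop("too few cells (", n, ") for a spline with df = ", df,
         "; use a smaller df")
  if (stats::var(expr) == 0)
    return(list(fitted = rep(expr[1], n), pvalue = 1))
  basis <- splines::ns(pseudotime, df = df)
  fit <- stats::lm.fit(cbind(1, basis), expr)
  fitted <- expr - fit$residuals
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((expr - mean(expr))^2)
  pvalue <- .lrtPValue(rss0, rss1, n, df)
  list(fitted = unname(fitted), pvalue = pvalue)
}

# Gaussian likelihood-ratio statistic 2*(ll1 - ll0) = n*log(rss0/rss1)
.lrtPValue <- function(rss0, rss1, n, df) {
  if (rss0 <= 0) return(1)
  if (rss1 <= .Machine$double.xmin) return(0)
  stat <- n * log(rss0 / rss1)
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH-adjusted p-values (capped at 1), in input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustPvalues <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Scale a fitted trajectory to mean 0, sd 1
#'
#' Uses the sample (n-1 denominator) standard deviation. The transform is
#' affine and order-preserving, so the sign pattern of deviations from the
#' mean is unchanged.
#'
#' @param fitted numeric vector with nonzero variance.
#' @return scaled vector with mean 0 and sample sd 1.
#' @examples
#' scaleFitted(c(1, 2, 3))
#' @export
scaleFitted <- function(fitted) {
  s <- stats::sd(fitted)
  if (!is.finite(s) || s == 0)
    stop("cannot scale a zero-variance trajectory; filter constant genes first")
  (fitted - mean(fitted)) / s
}

#' Fit all genes along pseudotime and apply the significance filter
#'
#' Fits every gene of the matrix with [fitGeneTrajectory()] (one shared
#' spline basis, solved jointly for speed), adjusts the p-values with BH
#' over all genes, and retains genes with q-value below `alpha`. Scaled
#' fitted trajectories (mean 0, sd 1) are computed for retained genes only.
#' A gene whose fit fails numerically is kept with p-value 1 and a warning
#' rather than aborting the run.
#'
#' @param m genes x cells matrix, columns in ordering order (aligned with
#'   [alignMatrixToOrdering()] if they are not).
#' @param o A [CellOrdering-class].
#' @param df spline basis dimension (default 3).
#' @param alpha retention level on the BH-adjusted p-value (default 0.05,
#'   strict inequality).
#' @return A [TrajectoryFit-class].
#' @export
fitTrajectories <- function(m, o, df = 3, alpha = 0.05) {
  stopifnot(is(o, "CellOrdering"))
  m <- as.matrix(m)
  if (is.null(rownames(m)))
    stop("expression matrix must have gene identifiers as rownames")
  if (!identical(colnames(m), cellIds(o)))
    m <- alignMatrixToOrdering(m, o)
  pt <- pseudotime(o)
  n <- ncol(m); G <- nrow(m)
  if (n < 2 * (df + 1))
    stop("too few cells (", n, ") for a spline with df = ", df,
         "; use a smaller df")

  basis <- cbind(1, splines::ns(pt, df = df))
  qrX <- qr(basis)
  Y <- t(m)                                   # cells x genes
  fittedT <- qr.fitted(qrX, Y)                # cells x genes
  rss1 <- colSums((Y - fittedT)^2)
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)

  pvals <- vapply(seq_len(G), function(j) {
    if (!all(is.finite(fittedT[, j]))) return(NA_real_)
    .lrtPValue(rss0[j], rss1[j], n, df)
  }, numeric(1))
  failed <- is.na(pvals)
  if (any(failed)) {
    warning(sum(failed), " gene(s) failed to fit and were assigned p-value 1: ",
            paste(utils::head(rownames(m)[failed], 5), collapse = ", "))
    pvals[failed] <- 1
    fittedT[, failed] <- matrix(rep(colMeans(Y)[failed], each = n), nrow = n)
  }

  constant <- rss0 <= 0
  if (any(constant))
    fittedT[, constant] <- matrix(rep(colMeans(Y)[constant], each = n), nrow = n)

  names(pvals) <- rownames(m)
  qvals <- adjustPvalues(pvals)
  fitVar <- apply(fittedT, 2, stats::var)
  degenerate <- !is.finite(fitVar) | fitVar == 0
  retained <- qvals < alpha & !degenerate & !failed

  scaled <- if (any(retained)) {
    t(apply(fittedT[, retained, drop = FALSE], 2, scaleFitted))
  } else {
    matrix(numeric(0), nrow = 0, ncol = n)
  }
  rownames(scaled) <- rownames(m)[retained]
  colnames(scaled) <- cellIds(o)

  message("retained ", sum(retained), " of ", G, " genes at BH alpha = ", alpha)
  new("TrajectoryFit",
      geneIds = rownames(m), cellIds = cellIds(o), pseudotime = pt,
      fitted = structure(t(fittedT), dimnames = dimnames(m)),
      pvalue = pvals, qvalue = qvals, retained = unname(retained),
      scaled = scaled, df = as.numeric(df), alpha = alpha)
}
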