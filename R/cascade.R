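#' Detect switch points of a scaled trajectory
#'
#' A switch point is an index i in `1..N-1` where the scaled fitted
#' trajectory crosses zero between consecutive ordered cells, i.e.
#' `scaled[i] * scaled[i+1] < 0`. Exact zeros are handled by collapsing
#' runs of zeros: if the nonzero neighbours flanking a zero run have
#' opposite signs, one switch is recorded at the last index before the run,
#' preserving "crosses zero" semantics under floating-point exactness.
#'
#' @param scaled numeric vector, typically a [scaleFitted()] output
#'   (mean ~0, sd ~1).
#' @return sorted integer vector of 1-based switch indices (possibly empty).
#' @examples
#' detectSwitchPoints(c(-1.2, -0.3, 0.4, 1.1))  # 2
#' @export
detectSwitchPoints <- function(scaled) {
  n <- length(scaled)
  if (n < 2)
    stop("need at least two cells to detect switch points")
  if (!all(is.finite(scaled)))
    stop("scaled trajectory must be finite")
  s <- sign(scaled)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  flips <- which(s[nz[-length(nz)]] * s[nz[-1]] < 0)
  as.integer(nz[flips])
}

#' Switch-point fractions
#'
#' Converts 1-based switch indices to fractions `i / N` of the trajectory
#' length, the scale on which positions are compared across samples.
#'
#' @param indices integer switch indices from [detectSwitchPoints()].
#' @param nCells number of ordered cells N.
#' @return numeric vector of fractions in (0, 1).
#' @export
switchFractions <- function(indices, nCells) {
  as.numeric(indices) / nCells
}

.patternLabel <- function(signString, k) {
  switch(signString,
    "-+"  = "increasing",
    "+-"  = "decreasing",
    "-+-" = "up_down",
    "+-+" = "down_up",
    sprintf("complex(%d)", k))
}

#' Classify the temporal pattern of a scaled trajectory
#'
#' The trajectory is split into constant-sign segments at its switch
#' points; each segment contributes the sign of its entry of largest
#' absolute value (robust to entries numerically near zero at segment
#' boundaries). The alternating sign string determines the label:
#' `"-+"` increasing, `"+-"` decreasing, `"-+-"` up_down, `"+-+"` down_up,
#' anything else `complex(k)` with k switch points.
#'
#' @param scaled numeric scaled trajectory.
#' @param switches integer switch indices; computed from `scaled` when
#'   omitted.
#' @return list with `signString`, `complexity` (number of switch points)
#'   and `label`.
#' @examples
#' classifyPattern(seq(-1.5, 1.5, length.out = 20))
#' @export
classifyPattern <- function(scaled, switches = detectSwitchPoints(scaled)) {
  n <- length(scaled)
  k <- length(switches)
  if (k == 0) {
    warning("no switch points on a scaled trajectory; labelling complex(0)")
    sgn <- sign(scaled[which.max(abs(scaled))])
    ss <- if (sgn == 0) "" else c("-", "+")[(sgn + 3) / 2]
    return(list(signString = ss, complexity = 0L, label = "complex(0)"))
  }
  bounds <- c(0L, switches, n)
  signs <- vapply(seq_len(k + 1), function(i) {
    seg <- scaled[(bounds[i] + 1L):bounds[i + 1L]]
    sign(seg[which.max(abs(seg))])
  }, numeric(1))
  ss <- paste(c("-", "0", "+")[signs + 2], collapse = "")
  list(signString = ss, complexity = as.integer(k), label = .patternLabel(ss, k))
}

# lexicographic sort key with "-" < "+"
.signKey <- function(signString) chartr("-+", "01", signString)

#' Order genes into a cascade
#'
#' Genes are grouped by temporal pattern, groups ordered by increasing
#' complexity (monotonic before non-monotonic); within equal complexity,
#' sign strings sort lexicographically with `"-" < "+"` (increasing before
#' decreasing, up_down before down_up). Within a group, genes are ordered
#' by their first switch index ascending; remaining ties break by gene id.
#'
#' @param patterns named list of [classifyPattern()] results (one per gene).
#' @param switches named list of integer switch-index vectors, same names.
#' @param nCells number of ordered cells (for the fraction scale).
#' @param pvalue,qvalue optional named numeric vectors carried into the
#'   result table (NA when absent).
#' @return A [CascadeResult-class] with ranks `1..G`.
#' @examples
#' sc <- list(a = seq(-1, 1, length.out = 10), b = seq(1, -1, length.out = 10))
#' sw <- lapply(sc, detectSwitchPoints)
#' pat <- mapply(classifyPattern, sc, sw, SIMPLIFY = FALSE)
#' cascadeOrder(orderGenes(pat, sw, 10))
#' @export
orderGenes <- function(patterns, switches, nCells, pvalue = NULL, qvalue = NULL) {
  genes <- names(patterns)
  if (!identical(sort(genes), sort(names(switches))))
    stop("patterns and switches must cover the same genes")
  switches <- switches[genes]
  if (!length(genes)) {
    return(new("CascadeResult", table = .emptyCascadeTable(),
               switchPoints = list(), nCells = as.integer(nCells)))
  }
  firstIdx <- vapply(switches, function(s)
    if (length(s)) as.numeric(s[1]) else Inf, numeric(1))
  tab <- data.frame(
    gene = genes,
    pattern = vapply(patterns, `[[`, character(1), "label"),
    sign_string = vapply(patterns, `[[`, character(1), "signString"),
    complexity = vapply(patterns, function(p) as.integer(p$complexity), integer(1)),
    n_switch_points = lengths(switches),
    first_switch_index = ifelse(is.finite(firstIdx), firstIdx, NA_real_),
    first_switch_fraction = ifelse(is.finite(firstIdx), firstIdx / nCells, NA_real_),
    pvalue = if (is.null(pvalue)) NA_real_ else unname(pvalue[genes]),
    qvalue = if (is.null(qvalue)) NA_real_ else unname(qvalue[genes]),
    stringsAsFactors = FALSE, row.names = NULL)
  o <- order(tab$complexity, .signKey(tab$sign_string), firstIdx, tab$gene)
  tab <- tab[o, , drop = FALSE]
  tab$cascade_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("CascadeResult", table = tab, switchPoints = switches[tab$gene],
      nCells = as.integer(nCells))
}

.emptyCascadeTable <- function() {
  data.frame(gene = character(), pattern = character(),
             sign_string = character(), complexity = integer(),
             n_switch_points = integer(), first_switch_index = numeric(),
             first_switch_fraction = numeric(), pvalue = numeric(),
             qvalue = numeric(), cascade_rank = integer(),
             stringsAsFactors = FALSE)
}

#' Build the cascade from a trajectory fit
#'
#' Runs switch-point detection and pattern classification on every retained
#' gene's scaled trajectory and orders the genes with [orderGenes()].
#'
#' @param fit A [TrajectoryFit-class].
#' @return A [CascadeResult-class].
#' @export
buildCascade <- function(fit) {
  stopifnot(is(fit, "TrajectoryFit"))
  sc <- scaledValues(fit)
  genes <- rownames(sc)
  switches <- lapply(genes, function(g) detectSwitchPoints(sc[g, ]))
  names(switches) <- genes
  patterns <- lapply(genes, function(g)
    suppressWarnings(classifyPattern(sc[g, ], switches[[g]])))
  names(patterns) <- genes
  orderGenes(patterns, switches, ncol(sc),
             pvalue = pValues(fit)[genes], qvalue = qValues(fit)[genes])
}

#' Fit and order in one step
#'
#' Convenience wrapper: aligns the matrix, fits all genes, and builds the
#' cascade.
#'
#' @inheritParams fitTrajectories
#' @return list with elements `fit` ([TrajectoryFit-class]) and `cascade`
#'   ([CascadeResult-class]).
#' @export
runCascade <- function(m, o, df = 3, alpha = 0.05) {
  fit <- fitTrajectories(m, o, df = df, alpha = alpha)
  list(fit = fit, cascade = buildCascade(fit))
}

#' Alternative gene orderings for comparison heatmaps
#'
#' Orders genes by clustering instead of the cascade rule, for side-by-side
#' contrast with the cascade heatmap. `"hierarchical"`: complete-linkage on
#' the Euclidean distance between scaled trajectories, leaf order.
#' `"kmeans"`: clusters are concatenated by the first zero crossing of
#' their centroid (clusters without a crossing last), genes within a
#' cluster sorted by id; deterministic given `seed`.
#'
#' @param scaled genes x cells matrix of scaled trajectories.
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k number of clusters (kmeans only).
#' @param seed RNG seed for kmeans initialization.
#' @return character vector of gene ids in the alternative order.
#' @export
alternativeOrdering <- function(scaled, method = c("hierarchical", "kmeans"),
                                k = 4, seed = 1) {
  method <- match.arg(method)
  if (is.null(rownames(scaled)))
    stop("scaled matrix must have gene identifiers as rownames")
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(scaled), method = "complete")
    rownames(scaled)[hc$order]
  } else {
    if (k > nrow(scaled))
      stop("k = ", k, " exceeds the number of genes (", nrow(scaled), ")")
    set.seed(seed)
    km <- stats::kmeans(scaled, centers = k)
    firstCross <- vapply(seq_len(k), function(ci) {
      cen <- km$centers[ci, ]
      sw <- detectSwitchPoints(cen)
      if (length(sw)) as.numeric(sw[1]) else Inf
    }, numeric(1))
    unlist(lapply(order(firstCross, seq_len(k)), function(ci)
      sort(rownames(scaled)[km$cluster == ci])), use.names = FALSE)
  }
}
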