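#' Summarize switch-point positions across samples
#'
#' Implements the cross-sample confidence interval for a switch point: the
#' mean of its per-sample positions (on the fraction scale) +/- 2 standard
#' errors, with se = sd across samples / sqrt(number of samples), bounds
#' clipped to \[0, 1\]. This is the construction [analyzeMultiSample()]
#' applies to every switch ordinal of every consistent gene.
#'
#' @param fractions numeric vector of one switch point's per-sample
#'   fractions, or a genes x samples matrix (one row per gene).
#' @return data.frame with columns `mean_fraction`, `se`, `lower`, `upper`
#'   (one row per input row).
#' @examples
#' summarizeSwitchFractions(c(0.4, 0.5, 0.6))
#' @export
summarizeSwitchFractions <- function(fractions) {
  if (is.null(dim(fractions)))
    fractions <- matrix(fractions, nrow = 1)
  if (ncol(fractions) < 2)
    stop("need positions from at least two samples")
  mu <- rowMeans(fractions)
  se <- apply(fractions, 1, stats::sd) / sqrt(ncol(fractions))
  data.frame(mean_fraction = mu, se = se,
             lower = pmax(0, mu - 2 * se), upper = pmin(1, mu + 2 * se),
             row.names = rownames(fractions), stringsAsFactors = FALSE)
}

#' Multi-sample cascade analysis
#'
#' Runs the full per-sample pipeline (fit, significance filter, scaling,
#' switch-point detection, pattern classification) independently on each
#' sample's cells, then keeps the genes that are retained in every sample
#' with an identical sign pattern. For each switch ordinal of a consistent
#' gene, the per-sample positions on the fraction scale (index / sample
#' cell count, so samples of different sizes are comparable) are summarized
#' as mean +/- 2 standard errors (se = sd across samples / sqrt(number of
#' samples)), clipped to \[0, 1\]. The consensus cascade orders consistent
#' genes by pattern complexity and then by mean first-switch fraction.
#'
#' @param m genes x cells matrix covering all samples' cells.
#' @param o A [CellOrdering-class] over all cells (each sample's cells are
#'   taken in this order).
#' @param samples named character vector (cell id -> sample label), e.g.
#'   from [readSampleAssignment()].
#' @param df spline basis dimension per sample fit.
#' @param alpha BH retention level per sample.
#' @param minCells minimum cells required per sample (default 10).
#' @return A [MultiSampleCascade-class].
#' @export
analyzeMultiSample <- function(m, o, samples, df = 3, alpha = 0.05,
                               minCells = 10) {
  stopifnot(is(o, "CellOrdering"))
  if (is.data.frame(samples))
    samples <- stats::setNames(as.character(samples[[2]]),
                               as.character(samples[[1]]))
  ids <- cellIds(o)
  unlabeled <- setdiff(ids, names(samples))
  if (length(unlabeled))
    stop("cells without a sample label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  lab <- samples[ids]
  counts <- table(lab)
  if (any(counts < minCells))
    stop("sample(s) with fewer than ", minCells, " cells: ",
         paste(names(counts)[counts < minCells], collapse = ", "))
  sampleNames <- sort(unique(lab))
  if (length(sampleNames) < 2)
    stop("multi-sample analysis needs at least two samples")

  perSample <- lapply(sampleNames, function(s) {
    cells <- ids[lab == s]
    so <- CellOrdering(cells, pseudotime(o)[lab == s])
    fit <- fitTrajectories(m[, cells, drop = FALSE], so, df = df, alpha = alpha)
    if (!sum(fit@retained))
      warning("sample '", s, "' has zero retained genes")
    list(fit = fit, cascade = buildCascade(fit), nCells = length(cells))
  })
  names(perSample) <- sampleNames

  # consistent = retained everywhere with an identical sign string
  retainedAll <- Reduce(intersect, lapply(perSample, function(x)
    retainedGenes(x$fit)))
  consistent <- retainedAll[vapply(retainedAll, function(g) {
    ss <- vapply(perSample, function(x) {
      tab <- cascadeTable(x$cascade)
      tab$sign_string[tab$gene == g]
    }, character(1))
    length(unique(ss)) == 1
  }, logical(1))]
  consistent <- sort(consistent)

  nS <- length(sampleNames)
  ciRows <- lapply(consistent, function(g) {
    fracs <- lapply(perSample, function(x)
      switchFractions(switchPoints(x$cascade)[[g]], x$nCells))
    K <- length(fracs[[1]])
    if (K == 0) return(NULL)
    do.call(rbind, lapply(seq_len(K), function(k) {
      pos <- vapply(fracs, `[[`, numeric(1), k)
      cbind(data.frame(gene = g, switch_ordinal = k, stringsAsFactors = FALSE),
            summarizeSwitchFractions(pos))
    }))
  })
  switchCI <- if (length(ciRows)) do.call(rbind, ciRows) else
    data.frame(gene = character(), switch_ordinal = integer(),
               mean_fraction = numeric(), se = numeric(),
               lower = numeric(), upper = numeric(), stringsAsFactors = FALSE)
  rownames(switchCI) <- NULL

  consensus <- .consensusCascade(consistent, perSample, switchCI)
  new("MultiSampleCascade", consistentGenes = consistent, switchCI = switchCI,
      consensus = consensus, perSample = lapply(perSample, function(x)
        x[c("fit", "cascade")]), samples = sampleNames)
}

# order consistent genes by complexity, sign string, mean first-switch fraction
.consensusCascade <- function(consistent, perSample, switchCI) {
  if (!length(consistent)) {
    return(new("CascadeResult", table = .emptyCascadeTable(),
               switchPoints = list(), nCells = NA_integer_))
  }
  ref <- cascadeTable(perSample[[1]]$cascade)
  ref <- ref[match(consistent, ref$gene), , drop = FALSE]
  first <- switchCI[switchCI$switch_ordinal == 1, , drop = FALSE]
  meanFirst <- first$mean_fraction[match(consistent, first$gene)]
  tab <- data.frame(
    gene = consistent, pattern = ref$pattern, sign_string = ref$sign_string,
    complexity = ref$complexity, n_switch_points = ref$n_switch_points,
    first_switch_index = NA_real_,
    first_switch_fraction = meanFirst,
    pvalue = NA_real_, qvalue = NA_real_, stringsAsFactors = FALSE)
  o <- order(tab$complexity, .signKey(tab$sign_string),
             ifelse(is.na(meanFirst), Inf, meanFirst), tab$gene)
  tab <- tab[o, , drop = FALSE]
  tab$cascade_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("CascadeResult", table = tab, switchPoints = list(),
      nCells = NA_integer_)
}

#' Write the multi-sample switch-point CI table
#'
#' TSV with columns `gene`, `switch_ordinal`, `mean_fraction`, `se`,
#' `lower`, `upper`, rows in consensus cascade order.
#'
#' @param ms A [MultiSampleCascade-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSwitchCITable <- function(ms, path) {
  stopifnot(is(ms, "MultiSampleCascade"))
  ci <- switchPointCI(ms)
  ord <- cascadeOrder(consensusCascade(ms))
  ci <- ci[order(match(ci$gene, ord), ci$switch_ordinal), , drop = FALSE]
  utils::write.table(ci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
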