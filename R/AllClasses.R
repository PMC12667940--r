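#' @import methods
NULL

#' Ordered cells with pseudotime values
#'
#' Container for a linear cell ordering along a trajectory. Cells are stored
#' in pseudotime order; when no explicit pseudotime is supplied, the i-th
#' cell receives pseudotime i (ranks).
#'
#' @slot cellIds character vector of unique cell identifiers, in trajectory
#'   order.
#' @slot pseudotime numeric vector of strictly increasing pseudotime values,
#'   one per cell.
#'
#' @seealso [readCellOrdering()], [alignMatrixToOrdering()]
#' @export
setClass("CellOrdering",
  representation(cellIds = "character", pseudotime = "numeric"))

setValidity("CellOrdering", function(object) {
  msg <- character()
  if (length(object@cellIds) != length(object@pseudotime))
    msg <- c(msg, "cellIds and pseudotime must have the same length")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, paste0("duplicate cell identifiers: ",
      paste(unique(object@cellIds[duplicated(object@cellIds)]), collapse = ", ")))
  if (length(object@pseudotime) && any(!is.finite(object@pseudotime)))
    msg <- c(msg, "pseudotime values must be finite")
  if (length(object@pseudotime) > 1 && any(diff(object@pseudotime) <= 0))
    msg <- c(msg, "pseudotime must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a CellOrdering
#'
#' @param cellIds character vector of unique cell identifiers in trajectory
#'   order.
#' @param pseudotime strictly increasing numeric vector, one value per cell.
#'   Defaults to the ranks `1..N` ("the pseudotime value of the i-th cell
#'   is i").
#' @return A [CellOrdering-class] object.
#' @examples
#' CellOrdering(c("c1", "c2", "c3"))
#' @export
CellOrdering <- function(cellIds, pseudotime = seq_along(cellIds)) {
  new("CellOrdering", cellIds = as.character(cellIds),
      pseudotime = as.numeric(pseudotime))
}

setMethod("show", "CellOrdering", function(object) {
  cat("CellOrdering with", length(object@cellIds), "cells\n")
  if (length(object@cellIds)) {
    n <- min(3L, length(object@cellIds))
    cat("  first cells:", paste(utils::head(object@cellIds, n), collapse = ", "),
        "...\n")
    cat("  pseudotime range: [", min(object@pseudotime), ",",
        max(object@pseudotime), "]\n")
  }
})

#' Flat gene-set annotation (term to gene mapping)
#'
#' Holds gene sets parsed from GMT or a two-column gene/term table, together
#' with the annotation universe (the union of all member sets). No ontology
#' structure is kept: terms are flat sets.
#'
#' @slot sets named list; each element is a character vector of member genes
#'   for one term. Names are term identifiers.
#' @slot termNames named character vector of human-readable term names,
#'   parallel to `sets`.
#' @slot universe character vector, union of all member sets.
#'
#' @seealso [readAnnotation()], [patternEnrichment()], [temporalEnrichment()]
#' @export
setClass("TermAnnotation",
  representation(sets = "list", termNames = "character", universe = "character"))

setValidity("TermAnnotation", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "term identifiers must be unique and non-NULL")
  if (any(lengths(object@sets) == 0))
    msg <- c(msg, "every term must have a non-empty member set")
  if (!identical(names(object@sets), names(object@termNames)))
    msg <- c(msg, "termNames must be named identically to sets")
  if (length(msg)) msg else TRUE
})

#' Construct a TermAnnotation
#'
#' @param sets named list of character vectors (term id -> member genes).
#' @param termNames optional named character vector of display names; falls
#'   back to the term ids.
#' @return A [TermAnnotation-class] object; the universe is the union of all
#'   member sets.
#' @examples
#' TermAnnotation(list(T1 = c("g1", "g2"), T2 = "g1"))
#' @export
TermAnnotation <- function(sets, termNames = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(termNames)) {
    termNames <- stats::setNames(names(sets), names(sets))
  } else {
    termNames <- stats::setNames(as.character(termNames)[match(names(sets), names(termNames))],
                                 names(sets))
    termNames[is.na(termNames)] <- names(sets)[is.na(termNames)]
  }
  new("TermAnnotation", sets = sets, termNames = termNames,
      universe = unique(unlist(sets, use.names = FALSE)))
}

setMethod("show", "TermAnnotation", function(object) {
  cat("TermAnnotation with", length(object@sets), "terms,",
      length(object@universe), "genes in universe\n")
})

#' Per-gene spline fits along pseudotime
#'
#' Result of [fitTrajectories()]: for every gene, the spline-smoothed
#' expression trajectory, the raw likelihood-ratio p-value, the BH-adjusted
#' q-value, and (for genes passing the significance filter) the fitted
#' values scaled to mean 0 / sd 1.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot cellIds character vector of ordered cell identifiers.
#' @slot pseudotime numeric pseudotime of each ordered cell.
#' @slot fitted genes x cells matrix of fitted expression values.
#' @slot pvalue named numeric vector of raw p-values.
#' @slot qvalue named numeric vector of BH-adjusted p-values.
#' @slot retained named logical; TRUE where qvalue < alpha (and the fit is
#'   non-degenerate).
#' @slot scaled retained-genes x cells matrix of scaled fitted values.
#' @slot df numeric, spline basis dimension used.
#' @slot alpha numeric, significance level used for retention.
#'
#' @export
setClass("TrajectoryFit",
  representation(geneIds = "character", cellIds = "character",
    pseudotime = "numeric", fitted = "matrix", pvalue = "numeric",
    qvalue = "numeric", retained = "logical", scaled = "matrix",
    df = "numeric", alpha = "numeric"))

setValidity("TrajectoryFit", function(object) {
  msg <- character()
  G <- length(object@geneIds)
  N <- length(object@cellIds)
  if (!identical(dim(object@fitted), c(G, N)))
    msg <- c(msg, "fitted must be a genes x cells matrix")
  for (sl in c("pvalue", "qvalue"))
    if (length(slot(object, sl)) != G)
      msg <- c(msg, paste(sl, "must have one entry per gene"))
  if (length(object@retained) != G)
    msg <- c(msg, "retained must have one entry per gene")
  if (any(object@qvalue < object@pvalue - 1e-12, na.rm = TRUE))
    msg <- c(msg, "qvalue must be >= pvalue")
  if (nrow(object@scaled) != sum(object@retained))
    msg <- c(msg, "scaled must have one row per retained gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryFit", function(object) {
  cat("TrajectoryFit:", length(object@geneIds), "genes x",
      length(object@cellIds), "cells\n")
  cat("  spline df:", object@df, " alpha:", object@alpha, "\n")
  cat("  retained (q <", object@alpha, "):", sum(object@retained), "genes\n")
})

#' Cascade-ordered genes with switch points and temporal patterns
#'
#' Result of [buildCascade()] / [orderGenes()]. Genes are grouped by
#' temporal pattern (ordered by increasing complexity = number of switch
#' points) and, within a group, ordered by the location of their first
#' switch point; the resulting rank is the cascade order used by all
#' downstream tables and heatmaps.
#'
#' @slot table data.frame in cascade order with columns `gene`, `pattern`,
#'   `sign_string`, `complexity`, `n_switch_points`, `first_switch_index`,
#'   `first_switch_fraction`, `pvalue`, `qvalue`, `cascade_rank`.
#' @slot switchPoints named list of integer vectors; 1-based indices i
#'   meaning the trajectory crosses zero between ordered cells i and i+1.
#'   Empty for consensus (multi-sample) cascades, where positions live on
#'   the fraction scale in the CI table instead.
#' @slot nCells integer, number of ordered cells (NA for consensus cascades).
#'
#' @export
setClass("CascadeResult",
  representation(table = "data.frame", switchPoints = "list",
                 nCells = "integer"))

setValidity("CascadeResult", function(object) {
  msg <- character()
  need <- c("gene", "pattern", "sign_string", "complexity", "n_switch_points",
            "first_switch_index", "first_switch_fraction", "pvalue", "qvalue",
            "cascade_rank")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must contain columns:", paste(need, collapse = ", ")))
  else {
    G <- nrow(object@table)
    if (G && !identical(sort(object@table$cascade_rank), seq_len(G)))
      msg <- c(msg, "cascade_rank must be a bijection onto 1..G")
    if (G && anyDuplicated(object@table$gene))
      msg <- c(msg, "duplicate genes in cascade table")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CascadeResult", function(object) {
  cat("CascadeResult with", nrow(object@table), "genes\n")
  if (nrow(object@table)) {
    tab <- table(factor(object@table$pattern,
                        levels = unique(object@table$pattern)))
    for (p in names(tab)) cat("  ", p, ": ", tab[[p]], " genes\n", sep = "")
  }
})

#' Multi-sample cascade with switch-point confidence intervals
#'
#' Result of [analyzeMultiSample()]: genes retained in every sample with an
#' identical temporal pattern, the per-switch confidence intervals
#' (mean +/- 2 SE of the switch-point fraction across samples), and the
#' consensus cascade ordered by mean first-switch fraction.
#'
#' @slot consistentGenes character vector of genes retained in all samples
#'   with the same sign pattern everywhere.
#' @slot switchCI data.frame with columns `gene`, `switch_ordinal`,
#'   `mean_fraction`, `se`, `lower`, `upper` (bounds clipped to \[0, 1\]).
#' @slot consensus [CascadeResult-class] over the consistent genes.
#' @slot perSample named list of per-sample results, each a list with
#'   elements `fit` ([TrajectoryFit-class]) and `cascade`
#'   ([CascadeResult-class]).
#' @slot samples character vector of sample labels.
#'
#' @export
setClass("MultiSampleCascade",
  representation(consistentGenes = "character", switchCI = "data.frame",
    consensus = "CascadeResult", perSample = "list", samples = "character"))

setMethod("show", "MultiSampleCascade", function(object) {
  cat("MultiSampleCascade over", length(object@samples), "samples:",
      paste(object@samples, collapse = ", "), "\n")
  cat("  consistent genes:", length(object@consistentGenes), "\n")
  cat("  switch-point CIs:", nrow(object@switchCI), "rows\n")
})
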