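#' Upper-tail hypergeometric p-value
#'
#' `P(X >= count)` for a hypergeometric draw of `querySize` genes from a
#' background of `bgSize` genes of which `termTotal` carry the term.
#'
#' @param count observed number of query genes carrying the term.
#' @param termTotal background genes annotated with the term.
#' @param bgSize background size.
#' @param querySize query size.
#' @return the one-sided over-representation p-value.
#' @export
hyperPValue <- function(count, termTotal, bgSize, querySize) {
  stats::phyper(count - 1, termTotal, bgSize - termTotal, querySize,
                lower.tail = FALSE)
}

#' Over-representation test for one term
#'
#' Tests whether `query` is enriched for `termMembers` against `background`
#' with an upper-tail hypergeometric test. Note the gene-ratio convention:
#' `count / (background genes annotated with the term)` -- the term's
#' coverage by the query, not count over query size (see the vignette).
#'
#' @param query character vector of query genes; must be a subset of
#'   `background`.
#' @param background character vector of background genes.
#' @param termMembers character vector of the term's member genes.
#' @return list with `count`, `geneRatio`, `pvalue`, and `genes` (the query
#'   genes carrying the term).
#' @examples
#' bg <- paste0("g", 1:20)
#' hypergeometricTest(bg[1:5], bg, bg[c(1:4, 6)])
#' @export
hypergeometricTest <- function(query, background, termMembers) {
  query <- unique(query); background <- unique(background)
  extra <- setdiff(query, background)
  if (length(extra))
    stop("query gene(s) not in the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  inBg <- intersect(termMembers, background)
  if (!length(inBg))
    stop("term has no members in the background")
  hits <- intersect(query, inBg)
  count <- length(hits)
  list(count = count,
       geneRatio = count / length(inBg),
       pvalue = hyperPValue(count, length(inBg), length(background),
                            length(query)),
       genes = sort(hits))
}

# run all terms of an annotation against one query; BH across tested terms
.enrichQuery <- function(query, background, ann) {
  sets <- geneSets(ann)
  keep <- vapply(sets, function(g) length(intersect(g, background)) > 0,
                 logical(1))
  sets <- sets[keep]
  if (!length(sets)) return(.emptyEnrichment())
  rows <- lapply(names(sets), function(tid) {
    r <- hypergeometricTest(query, background, sets[[tid]])
    data.frame(term_id = tid, term_name = termNames(ann)[[tid]],
               count = r$count, gene_ratio = r$geneRatio, pvalue = r$pvalue,
               member_genes = paste(r$genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- adjustPvalues(out$pvalue)
  out[, c("term_id", "term_name", "count", "gene_ratio", "pvalue", "qvalue",
          "member_genes")]
}

.emptyEnrichment <- function() {
  data.frame(term_id = character(), term_name = character(),
             count = integer(), gene_ratio = numeric(), pvalue = numeric(),
             qvalue = numeric(), member_genes = character(),
             stringsAsFactors = FALSE)
}

# sort by gene_ratio desc, then pvalue asc, then term_id; truncate to topK
.rankEnrichment <- function(df, topK) {
  df <- df[order(-df$gene_ratio, df$pvalue, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, topK)
}

#' Per-pattern gene-set enrichment
#'
#' For each temporal pattern group of the cascade, tests every annotation
#' term for over-representation of the group's genes. The background is the
#' set of significance-retained genes (all cascade genes) that appear in
#' the annotation universe. P-values are BH-adjusted across the terms
#' tested within one group; rows are ranked by gene ratio (descending,
#' ties by p-value then term id) and truncated to `topK`.
#'
#' @param cascade A [CascadeResult-class].
#' @param ann A [TermAnnotation-class].
#' @param topK rows kept per pattern (default 10).
#' @return named list (one element per pattern, in cascade group order) of
#'   enrichment data.frames.
#' @export
patternEnrichment <- function(cascade, ann, topK = 10) {
  stopifnot(is(cascade, "CascadeResult"), is(ann, "TermAnnotation"))
  tab <- cascadeTable(cascade)
  if (!nrow(tab)) stop("empty cascade")
  background <- intersect(tab$gene, annotationUniverse(ann))
  pats <- unique(tab$pattern)
  res <- lapply(pats, function(p) {
    query <- intersect(tab$gene[tab$pattern == p], background)
    if (length(query) < 2) {
      warning("pattern '", p, "' has fewer than 2 annotated genes; skipping")
      return(.emptyEnrichment())
    }
    .rankEnrichment(.enrichQuery(query, background, ann), topK)
  })
  names(res) <- pats
  res
}

#' Sliding-window specification over one pattern group
#'
#' Splits the `1..G` cascade ranks of a group into windows of size
#' `ceiling(G / nWindows)`; with `overlap = 0` (the default) windows are
#' non-overlapping and cover every gene exactly once.
#'
#' @param G number of genes in the group.
#' @param nWindows requested number of windows.
#' @param overlap genes shared between consecutive windows.
#' @return data.frame with columns `window`, `start`, `end` (1-based,
#'   inclusive ranks).
#' @export
windowSpec <- function(G, nWindows = 10, overlap = 0) {
  if (nWindows > G)
    stop("nWindows = ", nWindows, " exceeds the group size (", G,
         "); use fewer windows")
  size <- ceiling(G / nWindows)
  step <- size - overlap
  if (step < 1) stop("overlap must be smaller than the window size (", size, ")")
  starts <- seq(1L, G, by = step)
  ends <- pmin(starts + size - 1L, G)
  # drop trailing windows that add no genes beyond the previous one
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(window = seq_along(starts), start = starts, end = ends)
}

#' Temporal (sliding-window) enrichment along the cascade
#'
#' Runs the over-representation analysis within sliding windows of one
#' pattern group's cascade order, localizing terms to trajectory stages.
#' P-values are BH-adjusted within each window. The display set is the
#' union over windows of each window's `topK` terms by gene ratio,
#' filtered to q-value < `qCut`; for those terms a terms x windows gene
#' ratio matrix, q-value matrix and significance mask are returned.
#'
#' @param cascade A [CascadeResult-class].
#' @param ann A [TermAnnotation-class].
#' @param pattern which pattern group to analyze (default `"increasing"`).
#' @param nWindows number of windows (default 10).
#' @param topK terms per window entering the display union (default 5).
#' @param qCut q-value cutoff for the display set (default 0.05).
#' @param overlap genes shared by consecutive windows (default 0).
#' @return list with `windows` (the [windowSpec()] table), `results`
#'   (per-window enrichment data.frames), `displayTerms`, and matrices
#'   `geneRatio`, `qvalue`, `significant` (terms x windows).
#' @export
temporalEnrichment <- function(cascade, ann, pattern = "increasing",
                               nWindows = 10, topK = 5, qCut = 0.05,
                               overlap = 0) {
  stopifnot(is(cascade, "CascadeResult"), is(ann, "TermAnnotation"))
  tab <- cascadeTable(cascade)
  genes <- tab$gene[tab$pattern == pattern]
  if (!length(genes))
    stop("no genes with pattern '", pattern, "' in the cascade")
  background <- intersect(tab$gene, annotationUniverse(ann))
  ws <- windowSpec(length(genes), nWindows, overlap)
  results <- lapply(seq_len(nrow(ws)), function(w) {
    query <- intersect(genes[ws$start[w]:ws$end[w]], background)
    if (length(query) < 2) return(.emptyEnrichment())
    .enrichQuery(query, background, ann)
  })
  display <- sort(unique(unlist(lapply(results, function(df) {
    top <- .rankEnrichment(df, topK)
    top$term_id[top$qvalue < qCut]
  }))))
  nW <- nrow(ws)
  ratio <- qmat <- matrix(NA_real_, nrow = length(display), ncol = nW,
                          dimnames = list(display, paste0("window", seq_len(nW))))
  for (w in seq_len(nW)) {
    df <- results[[w]]
    i <- match(display, df$term_id)
    ratio[, w] <- df$gene_ratio[i]
    qmat[, w] <- df$qvalue[i]
  }
  list(windows = ws, results = results, displayTerms = display,
       geneRatio = ratio, qvalue = qmat,
       significant = !is.na(qmat) & qmat < qCut)
}

#' Write enrichment results
#'
#' Per-pattern results go to one TSV with a leading `pattern` column;
#' temporal results write a gene-ratio matrix TSV and a parallel q-value
#' matrix TSV (suffix `.qvalue.tsv`).
#'
#' @param x output of [patternEnrichment()] or [temporalEnrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(x, path) {
  if (is.list(x) && !is.null(x$geneRatio)) {
    ratio <- data.frame(term_id = rownames(x$geneRatio), x$geneRatio,
                        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(ratio, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    qp <- sub("\\.tsv$", "", path)
    qv <- data.frame(term_id = rownames(x$qvalue), x$qvalue,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(qv, paste0(qp, ".qvalue.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    rows <- lapply(names(x), function(p)
      if (nrow(x[[p]])) cbind(pattern = p, x[[p]]) else NULL)
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- cbind(pattern = character(), .emptyEnrichment())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
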