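#' @importFrom grDevices colorRampPalette dev.off pdf png svg
#' @importFrom graphics abline axis image layout mtext par points segments
#'   title legend
NULL

.openDevice <- function(out, fmt, width = 7, height = 7) {
  switch(fmt,
    png = grDevices::png(out, width = width, height = height, units = "in",
                         res = 150),
    pdf = grDevices::pdf(out, width = width, height = height),
    svg = grDevices::svg(out, width = width, height = height),
    stop("unsupported format: ", fmt))
}

.divergingPalette <- function(n = 255) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

# symmetric colour limit: max |scaled| capped at `cap`
.colorLimit <- function(m, cap = 3) min(cap, max(abs(m)))

.writeSidecar <- function(df, out) {
  side <- paste0(out, ".tsv")
  utils::write.table(df, side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(side)
}

.drawHeatmapPanel <- function(m, lim, xlab = "pseudotime (cell rank)") {
  mc <- pmin(pmax(m, -lim), lim)
  graphics::image(x = seq_len(ncol(mc)), y = seq_len(nrow(mc)),
                  z = t(mc[rev(seq_len(nrow(mc))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = .divergingPalette(),
                  xlab = xlab, ylab = "", axes = FALSE, useRaster = TRUE)
  graphics::axis(1)
}

#' Cascade heatmap
#'
#' Renders the scaled fitted trajectories as a heatmap with rows in cascade
#' order (top = rank 1), a symmetric diverging colour scale centred at 0
#' (limits +/- max|scaled|, capped at `cap`), horizontal separators between
#' pattern groups, and optional marker-gene labels on the row axis. A
#' machine-readable sidecar TSV (`<out>.tsv`) records the rendered row
#' order, pattern, rank, and the colour limit, so tests can assert figure
#' content without image diffing.
#'
#' @param scaled genes x cells matrix of scaled fitted values (rows must
#'   cover all cascade genes).
#' @param cascade A [CascadeResult-class].
#' @param markers genes to label on the row axis (unknown markers are
#'   skipped with a warning).
#' @param out output file path.
#' @param fmt `"png"`, `"pdf"` or `"svg"`.
#' @param cap colour-limit cap (default 3).
#' @return `out`, invisibly.
#' @export
plotCascadeHeatmap <- function(scaled, cascade, markers = character(),
                               out, fmt = c("png", "pdf", "svg"), cap = 3) {
  fmt <- match.arg(fmt)
  stopifnot(is(cascade, "CascadeResult"))
  ord <- cascadeOrder(cascade)
  missingGenes <- setdiff(ord, rownames(scaled))
  if (length(missingGenes))
    stop("scaled matrix is missing cascade gene(s): ",
         paste(utils::head(missingGenes, 5), collapse = ", "))
  m <- scaled[ord, , drop = FALSE]
  lim <- .colorLimit(m, cap)
  tab <- cascadeTable(cascade)
  groupEnds <- cumsum(table(factor(tab$pattern, levels = unique(tab$pattern))))

  bad <- setdiff(markers, ord)
  if (length(bad))
    warning("marker(s) not in the cascade, skipped: ",
            paste(bad, collapse = ", "))
  markers <- intersect(markers, ord)

  .openDevice(out, fmt)
  op <- graphics::par(mar = c(4, 6, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  .drawHeatmapPanel(m, lim)
  G <- nrow(m)
  inner <- groupEnds[-length(groupEnds)]
  if (length(inner))
    graphics::abline(h = G - inner + 0.5, lwd = 1.5, col = "black")
  if (length(markers)) {
    at <- G - match(markers, ord) + 1
    graphics::axis(2, at = at, labels = markers, las = 2, cex.axis = 0.6,
                   tick = FALSE)
  }
  graphics::title("Gene expression cascade")

  .writeSidecar(data.frame(gene = ord, cascade_rank = tab$cascade_rank,
                           pattern = tab$pattern, color_limit = lim,
                           stringsAsFactors = FALSE), out)
  invisible(out)
}

#' Multi-sample cascade heatmap with switch-point CIs
#'
#' One heatmap panel per sample, all sharing the consensus row order; on
#' each panel a grey interval glyph spans the lower..upper switch-point
#' fraction of the pseudotime axis (a single dot when the CI has zero
#' width), with a point at the mean fraction. The sidecar TSV records the
#' row order and every CI glyph's coordinates.
#'
#' @param ms A [MultiSampleCascade-class].
#' @param out output file path.
#' @param fmt `"png"`, `"pdf"` or `"svg"`.
#' @param cap colour-limit cap (default 3).
#' @return `out`, invisibly.
#' @export
plotMultisampleHeatmap <- function(ms, out, fmt = c("png", "pdf", "svg"),
                                   cap = 3) {
  fmt <- match.arg(fmt)
  stopifnot(is(ms, "MultiSampleCascade"))
  ord <- cascadeOrder(consensusCascade(ms))
  if (!length(ord)) stop("no consistent genes to plot")
  mats <- lapply(ms@perSample, function(x) {
    sc <- scaledValues(x$fit)
    miss <- setdiff(ord, rownames(sc))
    if (length(miss))
      stop("consistent gene(s) missing in a sample: ",
           paste(utils::head(miss, 5), collapse = ", "))
    sc[ord, , drop = FALSE]
  })
  lim <- .colorLimit(do.call(cbind, mats), cap)
  ci <- switchPointCI(ms)
  nS <- length(mats)
  G <- length(ord)

  .openDevice(out, fmt, width = 4 * nS, height = 6)
  op <- graphics::par(mfrow = c(1, nS), mar = c(4, 2, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (s in seq_len(nS)) {
    m <- mats[[s]]
    .drawHeatmapPanel(m, lim)
    graphics::title(ms@samples[s])
    N <- ncol(m)
    rows <- match(ci$gene, ord)
    y <- G - rows + 1
    w <- which(ci$upper > ci$lower)
    if (length(w))
      graphics::segments(ci$lower[w] * N, y[w], ci$upper[w] * N, y[w],
                         col = "grey40", lwd = 2)
    graphics::points(ci$mean_fraction * N, y, pch = 16, cex = 0.4,
                     col = "grey20")
  }

  .writeSidecar(
    data.frame(gene = c(ord, ci$gene),
               row = c(seq_len(G), match(ci$gene, ord)),
               kind = c(rep("row", G), rep("ci", nrow(ci))),
               mean_fraction = c(rep(NA_real_, G), ci$mean_fraction),
               lower = c(rep(NA_real_, G), ci$lower),
               upper = c(rep(NA_real_, G), ci$upper),
               color_limit = lim, stringsAsFactors = FALSE), out)
  invisible(out)
}

#' Enrichment dot plots
#'
#' For per-pattern results (a data.frame), dots sit at x = gene ratio, one
#' term per row (ordered by gene ratio), size proportional to count,
#' colour by q-value. For temporal results (a [temporalEnrichment()] list),
#' a terms x windows dot grid with size proportional to gene ratio and
#' filled dots where the term is significant. An empty input warns and
#' writes no file.
#'
#' @param x enrichment data.frame or [temporalEnrichment()] output.
#' @param out output file path.
#' @param fmt `"png"`, `"pdf"` or `"svg"`.
#' @return `out` invisibly, or `NULL` when the input is empty.
#' @export
plotEnrichmentDots <- function(x, out, fmt = c("png", "pdf", "svg")) {
  fmt <- match.arg(fmt)
  temporal <- is.list(x) && !is.data.frame(x) && !is.null(x$geneRatio)
  if (temporal && nrow(x$geneRatio) == 0 || !temporal && NROW(x) == 0) {
    warning("empty enrichment input; no plot written")
    return(invisible(NULL))
  }
  .openDevice(out, fmt, width = 7, height = 5)
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  if (temporal) {
    ratio <- x$geneRatio
    o <- order(apply(ratio, 1, max, na.rm = TRUE))
    ratio <- ratio[o, , drop = FALSE]
    sig <- x$significant[o, , drop = FALSE]
    nT <- nrow(ratio); nW <- ncol(ratio)
    plot(NA, xlim = c(0.5, nW + 0.5), ylim = c(0.5, nT + 0.5), axes = FALSE,
         xlab = "switch-point window", ylab = "")
    graphics::axis(1, at = seq_len(nW))
    graphics::axis(2, at = seq_len(nT), labels = rownames(ratio), las = 2,
                   cex.axis = 0.6, tick = FALSE)
    for (i in seq_len(nT)) for (j in seq_len(nW)) {
      r <- ratio[i, j]
      if (!is.na(r) && r > 0)
        graphics::points(j, i, cex = 0.5 + 2.5 * r,
                         pch = if (sig[i, j]) 16 else 1, col = "#B2182B")
    }
    side <- data.frame(term_id = rownames(ratio), row = seq_len(nT),
                       max_gene_ratio = apply(ratio, 1, max, na.rm = TRUE),
                       stringsAsFactors = FALSE)
  } else {
    df <- x[order(x$gene_ratio), , drop = FALSE]
    n <- nrow(df)
    qcol <- grDevices::colorRampPalette(c("#B2182B", "#2166AC"))(100)
    qidx <- pmin(100, pmax(1, ceiling(df$qvalue * 100)))
    plot(df$gene_ratio, seq_len(n), xlim = c(0, max(df$gene_ratio) * 1.1),
         ylim = c(0.5, n + 0.5), axes = FALSE, xlab = "gene ratio",
         ylab = "", pch = 16, col = qcol[qidx],
         cex = 0.5 + 2 * df$count / max(df$count))
    graphics::axis(1)
    graphics::axis(2, at = seq_len(n), labels = df$term_id, las = 2,
                   cex.axis = 0.6, tick = FALSE)
    side <- data.frame(term_id = df$term_id, row = seq_len(n),
                       gene_ratio = df$gene_ratio, count = df$count,
                       qvalue = df$qvalue, stringsAsFactors = FALSE)
  }
  .writeSidecar(side, out)
  invisible(out)
}
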