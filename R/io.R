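#' Read a normalized expression matrix
#'
#' Reads a genes x cells matrix of normalized expression from one of the
#' supported on-disk formats. Identifiers are case-sensitive exact strings;
#' no symbol mapping is attempted. Values must be numeric and finite --
#' preprocessing (filtering, normalization) is expected to have happened
#' upstream.
#'
#' @param path file (csv/tsv/h5) or directory (mtx) to read.
#' @param format one of `"mtx"` (MatrixMarket triplet directory with
#'   `matrix.mtx`, `features.tsv`/`genes.tsv`, `barcodes.tsv`), `"csv"`/
#'   `"tsv"` (dense; first column gene ids, header row cell ids), or `"h5"`
#'   (HDF5 with datasets `matrix`, `gene_ids`, `cell_ids`; requires the
#'   rhdf5 package).
#' @param orientation for `"h5"` only: whether the stored matrix is
#'   `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @return numeric matrix, genes as rows, with gene/cell ids as dimnames.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gene = c("g1", "g2"), c1 = c(0, 1), c2 = c(2, 3)),
#'           f, row.names = FALSE)
#' readExpressionMatrix(f, "csv")
#' @export
readExpressionMatrix <- function(path, format = c("mtx", "csv", "tsv", "h5"),
                                 orientation = c("genes_by_cells", "cells_by_genes")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input not found: ", path)
  m <- switch(format,
    csv = .readDenseMatrix(path, sep = ","),
    tsv = .readDenseMatrix(path, sep = "\t"),
    mtx = .readMtxDir(path),
    h5  = .readH5Matrix(path, match.arg(orientation)))
  .checkExpressionMatrix(m)
  m
}

.checkExpressionMatrix <- function(m) {
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value at gene '", rownames(m)[bad[1, 1]],
         "', cell '", colnames(m)[bad[1, 2]], "'")
  invisible(m)
}

.readDenseMatrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2)
    stop("dense matrix needs a gene-id column plus at least one cell column: ",
         path)
  genes <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, colnames(df)[-1]))
  badNA <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(badNA))
    stop("non-numeric entry at row ", badNA[1, 1] + 1L, " (gene '",
         genes[badNA[1, 1]], "'), column ", badNA[1, 2] + 1L, " (cell '",
         colnames(vals)[badNA[1, 2]], "') of ", path)
  vals
}

.readMtxDir <- function(path) {
  if (!dir.exists(path))
    stop("mtx format expects a directory: ", path)
  pick <- function(cands) {
    hit <- cands[file.exists(file.path(path, cands))]
    if (!length(hit))
      stop("missing file in mtx directory (looked for ",
           paste(cands, collapse = " or "), "): ", path)
    file.path(path, hit[1])
  }
  mtx <- pick(c("matrix.mtx", "matrix.mtx.txt"))
  feat <- pick(c("features.tsv", "genes.tsv", "features.txt", "genes.txt"))
  bars <- pick(c("barcodes.tsv", "barcodes.txt"))
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  cells <- utils::read.table(bars, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  if (nrow(m) != length(genes))
    stop("matrix has ", nrow(m), " rows but ", length(genes), " features")
  if (ncol(m) != length(cells))
    stop("matrix has ", ncol(m), " columns but ", length(cells), " barcodes")
  dimnames(m) <- list(genes, cells)
  m
}

.readH5Matrix <- function(path, orientation) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading h5 requires the rhdf5 package")
  m <- rhdf5::h5read(path, "matrix")
  genes <- as.character(rhdf5::h5read(path, "gene_ids"))
  cells <- as.character(rhdf5::h5read(path, "cell_ids"))
  if (orientation == "cells_by_genes") m <- t(m)
  dimnames(m) <- list(genes, cells)
  m
}

#' Read a cell ordering / pseudotime file
#'
#' One-column input (one cell id per line) assigns pseudotime `1..N` in file
#' order. Two-column tab-separated input (cell id, pseudotime) is sorted by
#' pseudotime ascending; tied pseudotime values are an error because the
#' ordering must be strict.
#'
#' @param path path to the ordering file.
#' @return A [CellOrdering-class].
#' @export
readCellOrdering <- function(path) {
  if (!file.exists(path))
    stop("input not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("empty ordering file: ", path)
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2))
      stop("two-column ordering has a line without a pseudotime value: line ",
           which(lengths(parts) < 2)[1])
    ids <- vapply(parts, `[[`, character(1), 1)
    pt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
    if (anyNA(pt))
      stop("non-numeric pseudotime at line ", which(is.na(pt))[1])
    if (anyDuplicated(ids))
      stop("duplicate cell identifier in ordering: ",
           ids[duplicated(ids)][1])
    o <- order(pt)
    ids <- ids[o]; pt <- pt[o]
    if (any(diff(pt) == 0))
      stop("tied pseudotime values; the ordering must be strictly increasing")
    CellOrdering(ids, pt)
  } else {
    ids <- trimws(lines)
    if (anyDuplicated(ids))
      stop("duplicate cell identifier in ordering: ",
           ids[duplicated(ids)][1])
    CellOrdering(ids)
  }
}

#' Read a cell-to-sample assignment table
#'
#' Two tab-separated columns, cell id then sample label, no header.
#'
#' @param path path to the table.
#' @return named character vector mapping cell id to sample label.
#' @export
readSampleAssignment <- function(path) {
  if (!file.exists(path))
    stop("input not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2)
    stop("sample assignment needs two tab-separated columns: ", path)
  if (anyDuplicated(df[[1]]))
    stop("duplicate cell identifier in sample assignment: ",
         df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Read a flat gene-set annotation
#'
#' GMT format: one term per line, `term<TAB>description<TAB>gene1<TAB>...`.
#' Two-column TSV: `gene<TAB>term` rows, grouped into sets. Terms that end
#' up with zero member genes are dropped with a warning.
#'
#' @param path path to the annotation file.
#' @param format `"gmt"` or `"tsv"`.
#' @return A [TermAnnotation-class]; the universe is the union of all
#'   member sets.
#' @export
readAnnotation <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2)
    if (length(short))
      stop("malformed GMT line ", short[1], ": need term and description")
    ids <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(ids))
      stop("duplicate term identifier: ", ids[duplicated(ids)][1])
    nms <- vapply(parts, `[[`, character(1), 2)
    sets <- lapply(parts, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    empty <- lengths(sets) == 0
    if (any(empty)) {
      warning("dropping ", sum(empty), " term(s) with no member genes: ",
              paste(ids[empty], collapse = ", "))
      sets <- sets[!empty]; ids <- ids[!empty]; nms <- nms[!empty]
    }
    if (!length(sets))
      stop("no usable terms in ", path)
    TermAnnotation(stats::setNames(sets, ids), stats::setNames(nms, ids))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2)
      stop("two-column annotation needs gene<TAB>term rows: ", path)
    sets <- lapply(split(df[[1]], df[[2]]), unique)
    TermAnnotation(sets)
  }
}

#' Align an expression matrix to a cell ordering
#'
#' Reorders (and subsets) the columns of the matrix so that they follow the
#' ordering exactly. Cells present in the matrix but absent from the
#' ordering are dropped with a message -- orderings produced by trajectory
#' tools often cover a single branch. A cell in the ordering that the matrix
#' does not contain is an error.
#'
#' @param m genes x cells numeric matrix with cell ids as colnames.
#' @param o A [CellOrdering-class].
#' @return the matrix with columns exactly in ordering order. Idempotent.
#' @export
alignMatrixToOrdering <- function(m, o) {
  stopifnot(is(o, "CellOrdering"))
  ids <- cellIds(o)
  missing <- setdiff(ids, colnames(m))
  if (length(missing))
    stop("ordering references cell(s) absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dropped <- ncol(m) - length(ids)
  if (dropped > 0)
    message(dropped, " cell(s) in the matrix are absent from the ordering and were dropped")
  m[, ids, drop = FALSE]
}

#' Write the per-gene cascade results table
#'
#' Writes a TSV with one row per gene in cascade order, with columns
#' `gene`, `pattern`, `n_switch_points`, `first_switch_index`,
#' `first_switch_fraction`, `pvalue`, `qvalue`, `cascade_rank`. Switch
#' indices are 1-based. Re-running on the same input produces a
#' byte-identical file.
#'
#' @param cascade A [CascadeResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readResultsTable()]
#' @export
writeResultsTable <- function(cascade, path) {
  stopifnot(is(cascade, "CascadeResult"))
  tab <- cascadeTable(cascade)
  out <- data.frame(gene = tab$gene, pattern = tab$pattern,
                    n_switch_points = tab$n_switch_points,
                    first_switch_index = tab$first_switch_index,
                    first_switch_fraction = tab$first_switch_fraction,
                    pvalue = tab$pvalue, qvalue = tab$qvalue,
                    cascade_rank = tab$cascade_rank,
                    stringsAsFactors = FALSE)
  if (!nrow(out))
    warning("no significant genes; writing a header-only results table")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a cascade results table
#'
#' @param path path written by [writeResultsTable()].
#' @return data.frame with the table's columns, rows in cascade order.
#' @export
readResultsTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", pattern = "character"))
}
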