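#' Simulation configuration for planted-cascade data
#'
#' Describes a synthetic dataset with planted temporal patterns: sigmoidal
#' increasing/decreasing genes whose scaled trajectory crosses zero at a
#' planted fraction t*, Gaussian-bump up_down / inverted-bump down_up genes
#' with two planted crossings, and flat null genes. Gaussian noise is added
#' on the normalized-expression scale, matching the Gaussian fitting
#' family. With multiple samples, each gene's crossing fraction is jittered
#' across samples by a truncated normal.
#'
#' @param nCells cells per sample (default 300).
#' @param nSamples number of samples (default 1).
#' @param nIncreasing,nDecreasing,nUpDown,nDownUp,nNull gene counts per
#'   pattern (defaults 150/150/100/100/100).
#' @param amplitude signal amplitude on the normalized scale (default 1).
#' @param noiseSd Gaussian noise sd (default 0.3).
#' @param jitterSd cross-sample sd of the crossing fraction (default 0.03).
#' @param sigmoidWidth sigmoid width as a fraction of the trajectory
#'   (default 0.08; narrow enough that genuine switches at fractions
#'   0.25/0.75 remain reachable after mean-centering).
#' @param bumpSd Gaussian-bump sd as a fraction of the trajectory
#'   (default 0.12).
#' @param tstar optional list with numeric vectors `increasing` /
#'   `decreasing` of planted first-crossing fractions (recycled); drawn
#'   uniformly from `tstarRange` when NULL.
#' @param bumpCenter optional numeric vector of bump centers (recycled);
#'   drawn uniformly from `bumpCenterRange` when NULL.
#' @param tstarRange,bumpCenterRange sampling ranges (defaults
#'   (0.25, 0.75) and (0.35, 0.65)).
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(nCells = 300, nSamples = 1,
                             nIncreasing = 150, nDecreasing = 150,
                             nUpDown = 100, nDownUp = 100, nNull = 100,
                             amplitude = 1, noiseSd = 0.3, jitterSd = 0.03,
                             sigmoidWidth = 0.08, bumpSd = 0.12,
                             tstar = NULL, bumpCenter = NULL,
                             tstarRange = c(0.25, 0.75),
                             bumpCenterRange = c(0.35, 0.65), seed = 1) {
  cfg <- list(nCells = nCells, nSamples = nSamples,
              nIncreasing = nIncreasing, nDecreasing = nDecreasing,
              nUpDown = nUpDown, nDownUp = nDownUp, nNull = nNull,
              amplitude = amplitude, noiseSd = noiseSd, jitterSd = jitterSd,
              sigmoidWidth = sigmoidWidth, bumpSd = bumpSd, tstar = tstar,
              bumpCenter = bumpCenter, tstarRange = tstarRange,
              bumpCenterRange = bumpCenterRange, seed = seed)
  counts <- unlist(cfg[c("nIncreasing", "nDecreasing", "nUpDown", "nDownUp",
                         "nNull")])
  if (any(counts < 0) || cfg$nCells < 2 || cfg$nSamples < 1)
    stop("counts must be non-negative and nCells >= 2")
  if (cfg$noiseSd < 0 || cfg$jitterSd < 0 || cfg$amplitude <= 0)
    stop("amplitude must be positive, noiseSd and jitterSd non-negative")
  fr <- c(cfg$tstarRange, cfg$bumpCenterRange, cfg$tstar, cfg$bumpCenter)
  if (any(unlist(fr) <= 0 | unlist(fr) >= 1))
    stop("crossing fractions and centers must lie strictly in (0, 1)")
  class(cfg) <- "SimulationConfig"
  cfg
}

# sigmoid center m such that the mean-centered sigmoid over i/N crosses
# zero exactly (to grid resolution) at fraction tstar. The crossing moves
# monotonically with m only between the saturation turning point and 0.5,
# so the root is bracketed on that branch; a tstar below the reachable
# minimum is an infeasible config. tstar > 0.5 is solved by symmetry.
.sigmoidCenter <- function(tstar, width, nCells) {
  x <- seq_len(nCells) / nCells
  crossing <- function(m) {
    s <- stats::plogis((x - m) / width)
    s <- s - mean(s)
    i <- which(s[-nCells] * s[-1] < 0)[1]
    if (is.na(i)) return(0.5)  # flat saturation; centered crossing mid-range
    x[i]
  }
  if (tstar == 0.5) return(0.5)
  if (tstar > 0.5) return(1 - .sigmoidCenter(1 - tstar, width, nCells))
  turn <- stats::optimize(crossing, c(-0.5, 0.5))
  if (tstar < turn$objective)
    stop("infeasible config: a crossing at fraction ", tstar,
         " is unreachable for sigmoid width ", width,
         " (minimum reachable: ", round(turn$objective, 3), ")")
  stats::uniroot(function(m) crossing(m) - tstar, lower = turn$minimum,
                 upper = 0.5, tol = 1e-7)$root
}

# noiseless crossing fractions of a signal after mean-centering
.plantedCrossings <- function(signal, nCells) {
  s <- signal - mean(signal)
  detectSwitchPoints(s) / nCells
}

# smallest crossing fraction reachable by a mean-centered sigmoid of the
# given width on an N-cell grid
.reachableMinCrossing <- function(width, nCells) {
  x <- seq_len(nCells) / nCells
  crossing <- function(m) {
    s <- stats::plogis((x - m) / width)
    s <- s - mean(s)
    i <- which(s[-nCells] * s[-1] < 0)[1]
    if (is.na(i)) return(0.5)
    x[i]
  }
  stats::optimize(crossing, c(-0.5, 0.5))$objective
}

#' Simulate a planted-cascade dataset
#'
#' Generates expression matrices (genes x cells), cell orderings with
#' pseudotime `1..N`, a cell-to-sample assignment, and a ground-truth table
#' listing each gene's planted pattern and crossing fractions -- enough to
#' score retention, labels, switch localization and enrichment downstream
#' without re-reading generator internals.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `matrices` (named list per sample), `orderings`
#'   (named list of [CellOrdering-class]), `expr` (all samples' columns
#'   combined), `ordering` (first sample's, for single-sample use),
#'   `samples` (named character cell -> sample), `truth` (data.frame:
#'   `gene`, `pattern`, `f1`, `f2`), and `config`.
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  N <- cfg$nCells
  x <- seq_len(N) / N
  counts <- c(increasing = cfg$nIncreasing, decreasing = cfg$nDecreasing,
              up_down = cfg$nUpDown, down_up = cfg$nDownUp, null = cfg$nNull)
  G <- sum(counts)
  if (G == 0) stop("no genes to simulate")
  genes <- sprintf("gene%04d", seq_len(G))
  pattern <- rep(names(counts), counts)

  set.seed(cfg$seed)
  pick <- function(given, nm, n, range) {
    v <- if (!is.null(given)) rep_len(given, n) else
      stats::runif(n, range[1], range[2])
    v
  }
  tsInc <- pick(cfg$tstar$increasing, "increasing", counts[["increasing"]],
                cfg$tstarRange)
  tsDec <- pick(cfg$tstar$decreasing, "decreasing", counts[["decreasing"]],
                cfg$tstarRange)
  centers <- pick(cfg$bumpCenter, "bump",
                  counts[["up_down"]] + counts[["down_up"]],
                  cfg$bumpCenterRange)

  # base (sample-independent) planted parameters and truth
  baseParam <- vector("list", G)
  f1 <- f2 <- rep(NA_real_, G)
  iInc <- which(pattern == "increasing"); iDec <- which(pattern == "decreasing")
  iUp <- which(pattern == "up_down"); iDn <- which(pattern == "down_up")
  for (k in seq_along(iInc)) baseParam[[iInc[k]]] <- tsInc[k]
  for (k in seq_along(iDec)) baseParam[[iDec[k]]] <- tsDec[k]
  bumpCt <- centers
  for (k in seq_along(iUp)) baseParam[[iUp[k]]] <- bumpCt[k]
  for (k in seq_along(iDn)) baseParam[[iDn[k]]] <- bumpCt[length(iUp) + k]

  signalFor <- function(pat, par, N) {
    xx <- seq_len(N) / N
    A <- cfg$amplitude
    switch(pat,
      increasing = A * stats::plogis((xx - .sigmoidCenter(par, cfg$sigmoidWidth, N)) / cfg$sigmoidWidth),
      decreasing = A * (1 - stats::plogis((xx - .sigmoidCenter(par, cfg$sigmoidWidth, N)) / cfg$sigmoidWidth)),
      up_down = A * exp(-(xx - par)^2 / (2 * cfg$bumpSd^2)),
      down_up = -A * exp(-(xx - par)^2 / (2 * cfg$bumpSd^2)),
      null = rep(A / 2, N))
  }

  for (j in seq_len(G)) {
    if (pattern[j] == "null") next
    cr <- .plantedCrossings(signalFor(pattern[j], baseParam[[j]], N), N)
    if (pattern[j] %in% c("up_down", "down_up")) {
      if (length(cr) != 2)
        stop("infeasible config: bump for gene ", genes[j],
             " does not produce two crossings inside (0, 1)")
      f1[j] <- cr[1]; f2[j] <- cr[2]
    } else {
      f1[j] <- cr[1]
    }
  }

  sampleNames <- sprintf("sample%d", seq_len(cfg$nSamples))
  matrices <- list(); orderings <- list(); assign <- character(0)
  for (s in seq_len(cfg$nSamples)) {
    set.seed(cfg$seed + s)
    cells <- sprintf("s%d_c%04d", s, seq_len(N))
    m <- matrix(0, nrow = G, ncol = N, dimnames = list(genes, cells))
    # jittered sigmoid crossings are clamped to the reachable fraction range
    rmin <- .reachableMinCrossing(cfg$sigmoidWidth, N) + 1e-3
    for (j in seq_len(G)) {
      par <- baseParam[[j]]
      if (cfg$nSamples > 1 && !is.null(par)) {
        jit <- par + stats::rnorm(1, 0, cfg$jitterSd)
        par <- if (pattern[j] %in% c("increasing", "decreasing"))
          min(max(jit, rmin), 1 - rmin) else min(max(jit, 0.05), 0.95)
      }
      m[j, ] <- signalFor(pattern[j], par, N) +
        stats::rnorm(N, 0, cfg$noiseSd)
    }
    matrices[[sampleNames[s]]] <- m
    orderings[[sampleNames[s]]] <- CellOrdering(cells)
    assign <- c(assign, stats::setNames(rep(sampleNames[s], N), cells))
  }

  truth <- data.frame(gene = genes, pattern = pattern, f1 = f1, f2 = f2,
                      stringsAsFactors = FALSE)
  list(matrices = matrices, orderings = orderings,
       expr = do.call(cbind, matrices), ordering = orderings[[1]],
       samples = assign, truth = truth, config = cfg)
}

#' Simulate a flat gene-set annotation with planted enrichment
#'
#' Background terms draw members uniformly from the gene list; planted
#' terms draw at least a `plantedPurity` fraction of their members from
#' their assigned gene set (e.g. the genes of one pattern or of an early
#' switch window), so downstream enrichment has a known positive control.
#'
#' @param genes character vector of all gene ids (the annotation universe
#'   candidates).
#' @param nTerms number of background terms (default 40).
#' @param termSizeRange inclusive range of background term sizes
#'   (default 10..30).
#' @param plantedTerms named list of character vectors: term id -> the
#'   assigned gene set to enrich for.
#' @param plantedPurity fraction of a planted term's members drawn from its
#'   assigned set (default 0.9; must be >= 0.8 to count as planted).
#' @param seed RNG seed.
#' @return A [TermAnnotation-class].
#' @export
simulateAnnotation <- function(genes, nTerms = 40, termSizeRange = c(10, 30),
                               plantedTerms = list(), plantedPurity = 0.9,
                               seed = 1) {
  if (!length(genes)) stop("no genes to annotate")
  if (plantedPurity < 0.8 || plantedPurity > 1)
    stop("plantedPurity must be in [0.8, 1]")
  set.seed(seed)
  sets <- list()
  for (tid in names(plantedTerms)) {
    assigned <- unique(plantedTerms[[tid]])
    if (!length(assigned))
      stop("planted term '", tid, "' has size 0")
    nOut <- round(length(assigned) * (1 - plantedPurity) / plantedPurity)
    pool <- setdiff(genes, assigned)
    out <- if (nOut > 0 && length(pool)) sample(pool, min(nOut, length(pool)))
           else character(0)
    sets[[tid]] <- c(assigned, out)
  }
  for (i in seq_len(nTerms)) {
    size <- sample(seq(termSizeRange[1], termSizeRange[2]), 1)
    if (size > length(genes))
      stop("term size ", size, " exceeds the number of genes")
    if (size == 0) stop("term size 0 is not allowed")
    sets[[sprintf("BG%03d", i)]] <- sample(genes, size)
  }
  TermAnnotation(sets)
}

#' Write a TermAnnotation as GMT
#'
#' @param ann A [TermAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(ann, path) {
  stopifnot(is(ann, "TermAnnotation"))
  lines <- vapply(termIds(ann), function(tid)
    paste(c(tid, termNames(ann)[[tid]], geneSets(ann)[[tid]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
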