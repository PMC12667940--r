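test_that("hypergeometric p-value and gene ratio match the exact example", {
  bg <- paste0("g", 1:20)
  term <- bg[1:5]
  query <- bg[c(1:4, 6)]           # 4 of the 5 term genes
  r <- hypergeometricTest(query, bg, term)
  expect_equal(r$count, 4)
  expect_equal(r$geneRatio, 4 / 5)
  expect_equal(r$pvalue, 76 / 15504, tolerance = 1e-12)
  expect_setequal(r$genes, bg[1:4])
})

test_that("degenerate hypergeometric cases behave as defined", {
  bg <- paste0("g", 1:10)
  # count 0 still has full upper tail: P(X >= 0) = 1
  r0 <- hypergeometricTest(bg[6:8], bg, bg[1:3])
  expect_equal(r0$count, 0)
  expect_equal(r0$pvalue, 1)
  # saturated: query = term = background
  rs <- hypergeometricTest(bg, bg, bg)
  expect_equal(rs$pvalue, 1)
  expect_equal(rs$geneRatio, 1)
  expect_error(hypergeometricTest(c("gX"), bg, bg[1:3]), "not in the background")
  expect_error(hypergeometricTest(bg[1:2], bg, "gZ"), "no members")
})

test_that("gene ratio is 1 exactly when the query holds every term member", {
  set.seed(55)
  bg <- paste0("g", 1:50)
  for (i in 1:50) {
    term <- sample(bg, sample(2:20, 1))
    query <- sample(bg, sample(2:30, 1))
    r <- hypergeometricTest(query, bg, term)
    expect_lte(r$geneRatio, 1)
    expect_equal(r$geneRatio == 1, all(term %in% query))
  }
})

test_that("hypergeometric p-values match the factorial tail oracle", {
  set.seed(66)
  for (i in 1:500) {
    N <- sample(2:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    lowest <- max(0, n + K - N)
    cnt <- sample(lowest:min(n, K), 1)
    expect_equal(hyperPValue(cnt, K, N, n), hyperTailOracle(cnt, K, N, n),
                 tolerance = 1e-12)
  }
})

# cascade + annotation with a term planted on the increasing pattern group
plantedFixture <- function(seed = 77) {
  cfg <- simulationConfig(nCells = 200, nIncreasing = 30, nDecreasing = 30,
                          nUpDown = 0, nDownUp = 0, nNull = 10, seed = seed)
  sim <- simulateDataset(cfg)
  res <- quietRun(sim$expr, sim$ordering)
  tab <- cascadeTable(res$cascade)
  inc <- tab$gene[tab$pattern == "increasing"]
  ann <- simulateAnnotation(tab$gene, nTerms = 25, termSizeRange = c(5, 15),
                            plantedTerms = list(PLANTED = inc),
                            plantedPurity = 1, seed = seed + 1)
  list(sim = sim, res = res, tab = tab, inc = inc, ann = ann)
}

test_that("a term planted on one pattern ranks first for that pattern", {
  fx <- plantedFixture()
  # tiny pattern groups may legitimately warn about <2 annotated genes
  pe <- suppressWarnings(patternEnrichment(fx$res$cascade, fx$ann))
  incRows <- pe$increasing
  expect_equal(incRows$term_id[1], "PLANTED")
  expect_true(all(incRows$pvalue[1] <= incRows$pvalue[-1]))
  expect_true(all(vapply(pe, nrow, integer(1)) <= 10))
})

test_that("annotations disjoint from the cascade give empty results", {
  fx <- plantedFixture(seed = 78)
  annOther <- TermAnnotation(list(TX = c("zz1", "zz2"), TY = c("zz3", "zz4")))
  warns <- capture_warnings(pe <- patternEnrichment(fx$res$cascade, annOther))
  expect_true(any(grepl("fewer than 2", warns)))
  expect_true(all(vapply(pe, nrow, integer(1)) == 0))
})

test_that("topK larger than the number of terms returns all terms", {
  fx <- plantedFixture(seed = 79)
  pe <- suppressWarnings(patternEnrichment(fx$res$cascade, fx$ann, topK = 1000))
  expect_lte(nrow(pe$increasing), length(termIds(fx$ann)))
  expect_gt(nrow(pe$increasing), 10)
})

test_that("window specs partition the group ranks", {
  ws <- windowSpec(100, 10)
  expect_equal(nrow(ws), 10)
  expect_equal(ws$start, seq(1, 91, by = 10))
  expect_equal(ws$end, seq(10, 100, by = 10))
  # non-overlapping default covers every rank exactly once
  covered <- unlist(mapply(seq, ws$start, ws$end, SIMPLIFY = FALSE))
  expect_identical(covered, 1:100)
  # uneven division still covers everything
  ws2 <- windowSpec(95, 10)
  covered2 <- unlist(mapply(seq, ws2$start, ws2$end, SIMPLIFY = FALSE))
  expect_identical(sort(unique(covered2)), 1:95)
  expect_error(windowSpec(5, 10), "fewer windows")
})

test_that("temporal enrichment localizes an early-switch planted term", {
  cfg <- simulationConfig(nCells = 250, nIncreasing = 100, nDecreasing = 0,
                          nUpDown = 0, nDownUp = 0, nNull = 0,
                          tstarRange = c(0.25, 0.75), seed = 83)
  sim <- simulateDataset(cfg)
  res <- quietRun(sim$expr, sim$ordering)
  tab <- cascadeTable(res$cascade)
  # plant a term on the 12 genes with the earliest true crossings
  early <- sim$truth$gene[order(sim$truth$f1)][1:12]
  ann <- simulateAnnotation(tab$gene, nTerms = 30, termSizeRange = c(5, 20),
                            plantedTerms = list(EARLY = early),
                            plantedPurity = 1, seed = 84)
  te <- temporalEnrichment(res$cascade, ann, nWindows = 10)
  expect_true("EARLY" %in% te$displayTerms)
  expect_true(te$significant["EARLY", 1])
  expect_false(any(te$significant["EARLY", 4:10]))
})

test_that("a zero q-value cutoff empties the display set", {
  fx <- plantedFixture(seed = 80)
  te <- temporalEnrichment(fx$res$cascade, fx$ann, nWindows = 5, qCut = 0)
  expect_length(te$displayTerms, 0)
  expect_equal(nrow(te$geneRatio), 0)
})

test_that("raw p-values are calibrated under a random annotation", {
  set.seed(91)
  genes <- sprintf("g%04d", 1:300)
  ann <- simulateAnnotation(genes, nTerms = 60, termSizeRange = c(10, 40),
                            seed = 92)
  ps <- unlist(lapply(1:40, function(i) {
    query <- sample(genes, 25)
    df <- pseudocascade:::.enrichQuery(query, genes, ann)
    df$pvalue
  }))
  expect_gte(length(ps), 2000)
  # discrete upper-tail p-values are super-uniform: P(p < .05) <= .05
  expect_lt(mean(ps < 0.05), 0.07)
})
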