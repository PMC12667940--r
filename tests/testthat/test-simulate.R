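test_that("identical seeds give byte-identical datasets", {
  cfg <- simulationConfig(nCells = 80, nIncreasing = 5, nDecreasing = 5,
                          nUpDown = 3, nDownUp = 3, nNull = 4, seed = 3)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateDataset(simulationConfig(nCells = 80, nIncreasing = 5,
                                         nDecreasing = 5, nUpDown = 3,
                                         nDownUp = 3, nNull = 4, seed = 4))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("the chain simulate -> fit -> cascade -> enrich is deterministic", {
  run <- function() {
    cfg <- simulationConfig(nCells = 120, nIncreasing = 15, nDecreasing = 10,
                            nUpDown = 0, nDownUp = 0, nNull = 5, seed = 12)
    sim <- simulateDataset(cfg)
    res <- quietRun(sim$expr, sim$ordering)
    tab <- cascadeTable(res$cascade)
    ann <- simulateAnnotation(tab$gene, nTerms = 10,
                              termSizeRange = c(4, 8), seed = 13)
    pe <- patternEnrichment(res$cascade, ann)
    list(tab = tab, pe = pe)
  }
  expect_identical(run(), run())
})

test_that("noiseless sigmoids recover their planted crossing end to end", {
  cfg <- simulationConfig(nCells = 200, nIncreasing = 10, nDecreasing = 0,
                          nUpDown = 0, nDownUp = 0, nNull = 0, noiseSd = 0,
                          tstar = list(increasing = 0.5), seed = 6)
  sim <- simulateDataset(cfg)
  res <- quietRun(sim$expr, sim$ordering)
  tab <- cascadeTable(res$cascade)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$n_switch_points == 1))
  expect_true(all(abs(tab$first_switch_fraction - 0.5) <= 0.02))
})

test_that("planted crossings in the truth table match the noiseless signals", {
  cfg <- simulationConfig(nCells = 150, nIncreasing = 4, nDecreasing = 4,
                          nUpDown = 4, nDownUp = 4, nNull = 2, noiseSd = 0,
                          seed = 9)
  sim <- simulateDataset(cfg)
  res <- quietRun(sim$expr, sim$ordering)
  tab <- cascadeTable(res$cascade)
  truth <- sim$truth
  for (g in tab$gene) {
    tr <- truth[truth$gene == g, ]
    expect_equal(tab$pattern[tab$gene == g], tr$pattern)
    # df = 3 spline approximation shifts noiseless crossings slightly;
    # bump crossings sit on shallow flanks, and off-centre bumps shift
    # their first crossing the most under the smoother
    tol <- if (tr$pattern %in% c("up_down", "down_up")) 0.12 else 0.06
    expect_lt(abs(tab$first_switch_fraction[tab$gene == g] - tr$f1), tol)
  }
  # bump genes carry two planted crossings, monotone genes one
  expect_true(all(is.na(truth$f2[truth$pattern %in% c("increasing", "decreasing")])))
  expect_true(all(!is.na(truth$f2[truth$pattern %in% c("up_down", "down_up")])))
  expect_true(all(is.na(truth$f1[truth$pattern == "null"])))
})

test_that("an unreachable planted crossing is an infeasible config", {
  cfg <- simulationConfig(nCells = 100, nIncreasing = 1, nDecreasing = 0,
                          nUpDown = 0, nDownUp = 0, nNull = 0,
                          sigmoidWidth = 0.1,
                          tstar = list(increasing = 0.1), seed = 1)
  expect_error(simulateDataset(cfg), "infeasible|unreachable")
  expect_error(simulationConfig(tstarRange = c(0, 0.5)), "strictly in")
  expect_error(simulationConfig(noiseSd = -1), "non-negative")
})

test_that("multi-sample output is consistently labelled and jittered", {
  cfg <- simulationConfig(nCells = 60, nSamples = 3, nIncreasing = 4,
                          nDecreasing = 4, nUpDown = 0, nDownUp = 0,
                          nNull = 2, seed = 15)
  sim <- simulateDataset(cfg)
  expect_length(sim$matrices, 3)
  expect_length(sim$samples, 180)
  expect_setequal(unique(sim$samples), paste0("sample", 1:3))
  expect_identical(colnames(sim$expr), names(sim$samples))
  # samples differ (noise and jitter are sample-specific)
  expect_false(identical(unname(sim$matrices[[1]]), unname(sim$matrices[[2]])))
})

test_that("planted annotation terms are dominated by their assigned set", {
  genes <- sprintf("g%03d", 1:200)
  assigned <- genes[1:20]
  ann <- simulateAnnotation(genes, nTerms = 10, termSizeRange = c(5, 10),
                            plantedTerms = list(P1 = assigned),
                            plantedPurity = 0.9, seed = 33)
  members <- geneSets(ann)$P1
  expect_gte(mean(members %in% assigned), 0.8)
  expect_error(simulateAnnotation(genes,
                                  plantedTerms = list(P0 = character(0))),
               "size 0")
})

test_that("simulated ground truth scores downstream retention", {
  cfg <- simulationConfig(nCells = 150, nIncreasing = 10, nDecreasing = 0,
                          nUpDown = 0, nDownUp = 0, nNull = 20, seed = 19)
  sim <- simulateDataset(cfg)
  fit <- quietFit(sim$expr, sim$ordering)
  truth <- sim$truth
  sig <- truth$gene[truth$pattern != "null"]
  expect_setequal(intersect(retainedGenes(fit), sig), sig)
  expect_lt(length(setdiff(retainedGenes(fit), sig)), 5)
})
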