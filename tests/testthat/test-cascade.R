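test_that("switch points match the worked examples", {
  expect_equal(detectSwitchPoints(c(-1.2, -0.3, 0.4, 1.1)), 2L)
  expect_equal(switchFractions(2L, 4), 0.5)
  expect_equal(detectSwitchPoints(c(0.5, 0.7, 0.9)), integer(0))
  expect_error(detectSwitchPoints(1.0), "at least two")
})

test_that("exact-zero runs collapse to one switch at the last index before", {
  # crossing through a single exact zero
  expect_equal(detectSwitchPoints(c(-1, 0, 1)), 1L)
  # run of zeros with opposite flanks
  expect_equal(detectSwitchPoints(c(-2, -1, 0, 0, 0, 1, 2)), 2L)
  # zero run with same-sign flanks is no crossing
  expect_equal(detectSwitchPoints(c(1, 0, 0, 2)), integer(0))
  # leading/trailing zeros never create crossings
  expect_equal(detectSwitchPoints(c(0, 0, 1, -1, 0)), 3L)
})

test_that("switch detection equals the brute-force sign scan", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(2:500, 1)
    v <- rnorm(n)
    expect_identical(detectSwitchPoints(v), as.integer(scanOracle(v)))
  }
})

test_that("temporal patterns classify by alternating segment signs", {
  up <- seq(-1.5, 1.5, length.out = 40)
  p <- classifyPattern(up)
  expect_equal(p$signString, "-+")
  expect_equal(p$label, "increasing")
  expect_equal(p$complexity, 1L)

  down <- rev(up)
  expect_equal(classifyPattern(down)$label, "decreasing")

  x <- seq(0, 1, length.out = 60)
  bump <- scaleFitted(exp(-(x - 0.5)^2 / 0.02))
  pb <- classifyPattern(bump)
  expect_equal(pb$signString, "-+-")
  expect_equal(pb$label, "up_down")
  expect_equal(classifyPattern(-bump)$label, "down_up")

  wig <- scaleFitted(sin(2 * pi * 2.5 * x))
  expect_match(classifyPattern(wig)$label, "^complex\\(")
})

test_that("classification without any switch warns and labels complex(0)", {
  expect_warning(p <- classifyPattern(c(0.5, 0.7, 0.9)), "complex\\(0\\)")
  expect_equal(p$label, "complex(0)")
  expect_equal(p$complexity, 0L)
})

test_that("negating trajectories swaps paired labels, switch points fixed", {
  set.seed(17)
  x <- seq(0, 1, length.out = 80)
  cases <- list(scaleFitted(plogis((x - 0.4) / 0.07)),
                scaleFitted(-plogis((x - 0.6) / 0.07)),
                scaleFitted(exp(-(x - 0.5)^2 / 0.02)),
                scaleFitted(-exp(-(x - 0.45)^2 / 0.03)))
  swap <- c(increasing = "decreasing", decreasing = "increasing",
            up_down = "down_up", down_up = "up_down")
  for (v in cases) {
    expect_identical(detectSwitchPoints(-v), detectSwitchPoints(v))
    expect_equal(classifyPattern(-v)$label,
                 unname(swap[classifyPattern(v)$label]))
  }
})

test_that("cascade order follows pattern complexity then first switch", {
  mk <- function(ss) {
    lab <- switch(ss, "-+" = "increasing", "+-" = "decreasing",
                  "-+-" = "up_down", "+-+" = "down_up")
    list(signString = ss, complexity = nchar(ss) - 1L, label = lab)
  }
  pats <- list(A = mk("-+"), B = mk("+-"), C = mk("-+"))
  sw <- list(A = 10L, B = 5L, C = 3L)
  cas <- orderGenes(pats, sw, 100)
  expect_identical(cascadeOrder(cas), c("C", "A", "B"))
  expect_equal(cascadeTable(cas)$first_switch_fraction, c(0.03, 0.10, 0.05))
})

test_that("ties in pattern and switch index break by gene id", {
  p <- list(signString = "-+", complexity = 1L, label = "increasing")
  cas <- orderGenes(list(g2 = p, g1 = p), list(g2 = 4L, g1 = 4L), 50)
  expect_identical(cascadeOrder(cas), c("g1", "g2"))
})

test_that("random cascades match a brute-force sort and are a total order", {
  set.seed(99)
  x <- seq(0, 1, length.out = 60)
  genes <- sprintf("g%03d", 1:200)
  scaled <- t(sapply(seq_along(genes), function(i) {
    kind <- sample(4, 1)
    v <- switch(kind,
      plogis((x - runif(1, 0.2, 0.8)) / 0.06),
      -plogis((x - runif(1, 0.2, 0.8)) / 0.06),
      exp(-(x - runif(1, 0.35, 0.65))^2 / 0.02),
      -exp(-(x - runif(1, 0.35, 0.65))^2 / 0.02))
    scaleFitted(v + rnorm(60, 0, 0.05))
  }))
  rownames(scaled) <- genes
  sw <- apply(scaled, 1, detectSwitchPoints, simplify = FALSE)
  pats <- lapply(genes, function(g)
    suppressWarnings(classifyPattern(scaled[g, ], sw[[g]])))
  names(pats) <- genes
  cas <- orderGenes(pats, sw, 60)
  tab <- cascadeTable(cas)

  expect_identical(sort(tab$cascade_rank), seq_len(nrow(tab)))
  expect_true(all(diff(tab$complexity) >= 0))
  for (grp in split(tab, tab$sign_string)) {
    expect_true(all(diff(grp[order(grp$cascade_rank), "first_switch_index"]) >= 0))
  }

  # brute-force comparator oracle
  key <- chartr("-+", "01", tab$sign_string)
  o <- order(tab$complexity, key, tab$first_switch_index, tab$gene)
  expect_identical(o, seq_len(nrow(tab)))

  # re-running produces the identical permutation
  cas2 <- orderGenes(pats, sw, 60)
  expect_identical(cascadeOrder(cas2), cascadeOrder(cas))
})

test_that("empty input produces a valid empty cascade", {
  cas <- orderGenes(setNames(list(), character(0)),
                    setNames(list(), character(0)), 10)
  expect_s4_class(cas, "CascadeResult")
  expect_equal(nrow(cascadeTable(cas)), 0)
})

test_that("alternative orderings behave as documented", {
  x <- seq(0, 1, length.out = 40)
  scaled <- rbind(a = scaleFitted(plogis((x - 0.3) / 0.05)),
                  b = scaleFitted(plogis((x - 0.7) / 0.05)),
                  c = scaleFitted(plogis((x - 0.3) / 0.05)),
                  d = scaleFitted(-plogis((x - 0.5) / 0.05)))
  hc <- alternativeOrdering(scaled, "hierarchical")
  # identical trajectories a and c are adjacent leaves
  expect_equal(abs(diff(match(c("a", "c"), hc))), 1)

  expect_identical(alternativeOrdering(scaled, "kmeans", k = 1),
                   sort(rownames(scaled)))
  o1 <- alternativeOrdering(scaled, "kmeans", k = 2, seed = 9)
  o2 <- alternativeOrdering(scaled, "kmeans", k = 2, seed = 9)
  expect_identical(o1, o2)
  expect_error(alternativeOrdering(scaled, "kmeans", k = 10), "exceeds")
})
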