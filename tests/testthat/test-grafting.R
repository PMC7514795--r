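test_that("template matching follows the worked example", {
  tplA <- list(attrs = 1L, left = list(`1` = c(1L, 2L)), right = list(`1` = 0L))
  tplB <- list(attrs = c(3L, 6L),
               left = list(`3` = 2L, `6` = 0L), right = list(`3` = 0L, `6` = 1L))
  tplC <- list(attrs = c(4L, 8L),
               left = list(`4` = 1L, `8` = 0L), right = list(`4` = 0L, `8` = 1L))
  G <- workedSpeciesG()
  expect_equal(matchTemplate(G, tplA), "left")    # a1 = 1 is in L1
  expect_equal(matchTemplate(G, tplB), "left")    # a3 = 2, a6 = 0
  expect_equal(matchTemplate(G, tplC), "inconclusive")  # a8 missing
  # a value outside both value sets is inconclusive
  Q <- G; Q[1] <- 7L
  expect_equal(matchTemplate(Q, tplA), "inconclusive")

  dp <- list(node = "R", templates = list(tplA, tplB, tplC))
  tal <- matchAtNode(G, dp)
  expect_equal(tal$m, 2L)
  expect_equal(tal$n, 0L)
  expect_equal(tal$K, 3L)
  # tallies are invariant to template order
  dp2 <- list(node = "R", templates = list(tplC, tplB, tplA))
  expect_equal(matchAtNode(G, dp2)[c("m", "n")], tal[c("m", "n")])
})

test_that("the worked-example species descends left at the root", {
  cm <- workedMatrix()
  tr <- readTreeNewick("(((X,Y),Z),I);")
  cdt <- suppressWarnings(
    buildConceptDecisionTree(tr, cm, gaParams(popSize = 30, maxGen = 20, seed = 4)))
  res <- graftSpecies(cdt, workedSpeciesG(), "G")
  step1 <- res$placement$path[[1]]
  expect_gt(step1$m, step1$n)
  expect_equal(step1$side, "left")
  expect_true("G" %in% res$tree$tip.label)
})

test_that("a species identical to a leaf becomes that leaf's sibling", {
  set.seed(3)
  seedTr <- cdtphylo:::.ensureNodeLabels(simulateTree(8, seed = 30))
  cm <- cladeIndicatorMatrix(seedTr)   # every decision point separable
  cdt <- suppressWarnings(buildConceptDecisionTree(
    seedTr, cm, gaParams(popSize = 40, maxGen = 40, seed = 6)))
  twinOf <- seedTr$tip.label[1]
  m2 <- rbind(stateMatrix(cm), twin = stateMatrix(cm)[twinOf, ])
  res <- graftAll(cdt, characterMatrix(m2), "twin")
  tr <- finalTree(res)
  twinEdge <- tr$edge[tr$edge[, 2] == match("twin", tr$tip.label), 1]
  sibs <- tr$tip.label[tr$edge[tr$edge[, 1] == twinEdge, 2]]
  expect_true(twinOf %in% sibs)
})

test_that("an all-missing species stacks at the root", {
  cm <- workedMatrix()
  tr <- readTreeNewick("(((X,Y),Z),I);")
  cdt <- suppressWarnings(
    buildConceptDecisionTree(tr, cm, gaParams(popSize = 20, maxGen = 10, seed = 4)))
  res <- graftSpecies(cdt, rep(NA_integer_, 8), "blank")
  expect_length(res$placement$path, 1L)
  expect_equal(res$placement$path[[1]]$m, 0L)
  expect_equal(res$placement$path[[1]]$n, 0L)
  expect_true(res$placement$stacked)
  expect_equal(res$placement$attachment, seedTree(cdt)$node.label[1])
})

test_that("Wagner distance is an ordered-state difference sum", {
  expect_equal(wagnerDistance(c(1L, 2L, 0L), c(1L, 2L, 0L)), 0)
  expect_equal(wagnerDistance(c(0L, 1L, 2L), c(1L, 1L, 0L)), 3)
  expect_equal(wagnerDistance(c(NA, 1L), c(0L, NA)), Inf)
  set.seed(14)
  for (i in 1:20) {
    x <- sample(0:3, 6, replace = TRUE)
    y <- sample(0:3, 6, replace = TRUE)
    z <- sample(0:3, 6, replace = TRUE)
    expect_equal(wagnerDistance(x, y), wagnerDistance(y, x))
    expect_lte(wagnerDistance(x, z),
               wagnerDistance(x, y) + wagnerDistance(y, z))
  }
  # missing attributes are skipped, not imputed
  expect_equal(wagnerDistance(c(NA, 1L, 5L), c(2L, 1L, 0L)), 5)
})

test_that("stacked polytomies resolve by closest Wagner pair first", {
  # seed tree with an unseparable root so all three graft species stack
  m <- rbind(X = c(0L, 9L), Y = c(0L, 9L), Z = c(0L, 9L),
             A = c(0L, 0L), B = c(1L, 0L), C = c(5L, 0L))
  cm <- characterMatrix(m)
  tr <- readTreeNewick("((X,Y),Z);")
  cdt <- suppressWarnings(
    buildConceptDecisionTree(tr, cm, gaParams(popSize = 6, maxGen = 2, seed = 1)))
  res <- graftAll(cdt, cm, c("A", "B", "C"))
  tr2 <- finalTree(res)
  expect_true(ape::is.binary(tr2))
  # d(A,B) = 1 < d(B,C) = 4 < d(A,C) = 5: A,B merged first
  anc <- function(tips) ape::getMRCA(tr2, tips)
  expect_false(anc(c("A", "B")) == anc(c("A", "B", "C")))
  expect_equal(anc(c("A", "C")), anc(c("B", "C")))
})

test_that("grafting preserves the seed topology and every placement", {
  fx <- makeFixture(simParams(nTaxa = 14, nChars = 30, nStates = 3,
                              changeRate = 0.12, maskProportion = 0.2, seed = 21))
  cdt <- suppressWarnings(
    buildConceptDecisionTree(fx$seedTree, fx$matrix,
                             gaParams(popSize = 20, maxGen = 10, seed = 22)))
  expect_equal(writeTreeNewick(finalTree(graftAll(cdt, fx$matrix, character(0)))),
               writeTreeNewick(ape::read.tree(text = writeTreeNewick(seedTree(cdt)))))
  res <- graftAll(cdt, fx$matrix, fx$sub2)
  tr <- finalTree(res)
  expect_equal(length(tr$tip.label), length(fx$sub1) + length(fx$sub2))
  # seed topology unchanged after dropping the grafted tips
  back <- ape::drop.tip(tr, fx$sub2)
  expect_equal(phangorn::RF.dist(back, seedTree(cdt)), 0)
  # deterministic replay
  res2 <- graftAll(cdt, fx$matrix, fx$sub2)
  expect_identical(placements(res), placements(res2))
  expect_equal(writeTreeNewick(finalTree(res2)), writeTreeNewick(tr))
})

test_that("fully separating characters recover every placement", {
  set.seed(60)
  ok <- 0L; tot <- 0L
  for (s in 1:5) {
    model <- simulateTree(12, seed = 60 + s)
    cm <- cladeIndicatorMatrix(model)
    sp <- cherrySplit(model)
    sub1 <- sp$sub1; sub2 <- sp$sub2
    seedTr <- cdtphylo:::.ensureNodeLabels(ape::drop.tip(model, sub2))
    cdt <- suppressWarnings(
      buildConceptDecisionTree(seedTr, cm, gaParams(popSize = 40, maxGen = 60,
                                                    seed = s)))
    res <- suppressWarnings(graftAll(cdt, cm, sub2))
    acc <- pathAccuracy(model, finalTree(res), sub2, sub1)$perSpecies
    ok <- ok + sum(acc == 1); tot <- tot + length(acc)
  }
  expect_gte(ok / tot, 0.9)
})
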