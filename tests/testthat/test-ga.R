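test_that("chromosome decoding follows the shared-code rule", {
  tpl <- decodeChromosome(c(1L, 3L, 0L, 4L, 5L, 7L, 10L, 9L, 9L, 8L))
  expect_length(tpl, 8L)                       # 6 singletons + {8,9} + {10}
  expect_false(any(vapply(tpl, function(t) 3L %in% t, TRUE)))  # code 0 excluded
  expect_true(any(vapply(tpl, identical, TRUE, c(8L, 9L))))
  expect_true(any(vapply(tpl, identical, TRUE, 10L)))
  expect_equal(sort(unlist(tpl)), c(1L, 2L, 4L:10L))

  expect_equal(decodeChromosome(rep(0L, 6)), list())
  expect_equal(decodeChromosome(rep(5L, 6)), list(1:6))
})

test_that("decoding depends only on the induced partition", {
  set.seed(55)
  for (i in 1:20) {
    N <- 8L
    codes <- sample(0:N, N, replace = TRUE)
    # relabel the non-zero codes consistently
    lut <- c(0L, sample(N) )
    relab <- ifelse(codes == 0L, 0L, lut[codes + 1L])
    expect_equal(decodeChromosome(codes), decodeChromosome(as.integer(relab)))
  }
})

test_that("fitness scores positive-region-preserving templates by size", {
  # attribute 1 alone separates D, N = 4
  m <- cbind(c(0L, 0L, 1L, 1L), matrix(0L, 4, 3))
  rownames(m) <- letters[1:4]
  tab <- decisionTable(characterMatrix(m), rownames(m),
                       setNames(c(0L, 0L, 1L, 1L), rownames(m)))
  expect_equal(templateFitness(c(1L, 0L, 0L, 0L), tab), 0.75)
  expect_equal(templateFitness(rep(2L, 4), tab), 0)   # template = C
  expect_equal(templateFitness(rep(0L, 4), tab), 0)   # empty set
})

test_that("fitness agrees with brute-force positive-region evaluation", {
  set.seed(77)
  for (i in 1:30) {
    tab <- randomTable(6, sample(4:6, 1), missingFrac = 0.1)
    N <- length(tab$C)
    codes <- sample(0:N, N, replace = TRUE)
    expect_equal(templateFitness(codes, tab), bfFitness(codes, tab),
                 tolerance = 1e-12)
  }
})

test_that("single-point crossover swaps suffixes and conserves codes", {
  expect_equal(gaCrossover(c(1L, 1L), c(1L, 1L)), list(a = c(1L, 1L), b = c(1L, 1L)))
  set.seed(9)
  repeat {  # find a draw with the cut after site 2
    kids <- gaCrossover(c(1L, 1L, 1L, 1L), c(2L, 2L, 2L, 2L))
    if (identical(kids$a, c(1L, 1L, 2L, 2L))) break
  }
  expect_equal(kids$b, c(2L, 2L, 1L, 1L))
  for (i in 1:20) {
    a <- sample(0:6, 6, replace = TRUE); b <- sample(0:6, 6, replace = TRUE)
    kids <- gaCrossover(a, b)
    expect_equal(sort(c(kids$a, kids$b)), sort(c(a, b)))
  }
  expect_equal(gaCrossover(3L, 5L), list(a = 3L, b = 5L))  # N = 1
})

test_that("basic-bit mutation changes one site with probability pm", {
  codes <- c(2L, 0L, 1L)
  expect_equal(gaMutate(codes, 0), codes)
  set.seed(13)
  out <- gaMutate(1L, 1)
  expect_true(out %in% 0:1 && out != 1L)
  changed <- replicate(4000, !identical(gaMutate(codes, 0.5), codes))
  p <- mean(changed)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
  # a mutated chromosome differs at exactly one site
  for (i in 1:20) {
    out <- gaMutate(codes, 1)
    expect_equal(sum(out != codes), 1L)
    expect_true(all(out %in% 0:3))
  }
})

test_that("roulette selection is fitness-proportional with elitism", {
  pop <- list(c(1L, 0L), c(2L, 0L))
  set.seed(3)
  draws <- unlist(replicate(20000, gaSelect(pop, c(3, 1), nSelect = 1)[[1]][1]))
  p <- mean(draws == 1L)
  expect_lt(abs(p - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
  # all-zero fitness: uniform fallback
  draws0 <- unlist(replicate(2000, gaSelect(pop, c(0, 0), nSelect = 1)[[1]][1]))
  expect_gt(mean(draws0 == 1L), 0.4)
  # the previous best replaces the worst when it dominates
  out <- gaSelect(pop, c(1, 1), nSelect = 2,
                  prevBest = list(c(9L, 9L)), prevBestFitness = 5)
  expect_true(any(vapply(out, identical, TRUE, c(9L, 9L))))
})

test_that("the repair operator lifts templates to full mutual information", {
  # D separated only by attribute 3
  m <- cbind(0L, 0L, c(0L, 0L, 1L, 1L), 0L)
  rownames(m) <- letters[1:4]
  tab <- decisionTable(characterMatrix(m), rownames(m),
                       setNames(c(0L, 0L, 1L, 1L), rownames(m)))
  out <- gaModify(rep(0L, 4), tab)
  expect_true(3L %in% unlist(decodeChromosome(out)))
  # already-complete template untouched
  codes <- c(0L, 0L, 3L, 0L)
  expect_equal(gaModify(codes, tab), codes)
  # random tables: every repaired template reaches I(C;D)
  set.seed(19)
  for (i in 1:25) {
    tab <- randomTable(7, 5, missingFrac = 0.1)
    out <- gaModify(sample(0:5, 5, replace = TRUE), tab)
    miC <- mutualInformation(tab, tab$C)
    for (B in decodeChromosome(out))
      expect_equal(mutualInformation(tab, B), miC, tolerance = 1e-9)
  }
})

test_that("the reduction search is reproducible and tracks best-ever fitness", {
  set.seed(1)
  tab <- randomTable(6, 4, missingFrac = 0.1)
  p <- gaParams(popSize = 12, maxGen = 10, seed = 42)
  r1 <- runReduction(tab, p)
  r2 <- runReduction(tab, p)
  expect_identical(r1$chromosome, r2$chromosome)
  expect_identical(r1$templates, r2$templates)
  expect_false(is.unsorted(r1$log$best))   # elitism: best-ever non-decreasing
  # every returned template preserves the positive region
  for (B in r1$templates)
    expect_setequal(positiveRegion(tab, B), positiveRegion(tab, tab$C))
})

test_that("a constant decision yields an empty template set with a warning", {
  m <- matrix(sample(0:1, 12, replace = TRUE), 4, 3)
  rownames(m) <- letters[1:4]
  tab <- decisionTable(characterMatrix(m), rownames(m),
                       setNames(rep(0L, 4), rownames(m)))
  expect_warning(r <- runReduction(tab, gaParams(popSize = 4, maxGen = 2)),
                 "constant")
  expect_length(r$templates, 0L)
})

test_that("the search space for N = 2 has (N+1)^N = 9 chromosomes", {
  grid <- do.call(expand.grid, rep(list(0:2), 2))
  expect_equal(nrow(grid), 9L)
  expect_equal(nrow(unique(grid)), 9L)
})
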