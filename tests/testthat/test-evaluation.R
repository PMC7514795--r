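test_that("path sequences list nested backbone clades from the root", {
  tr <- readTreeNewick("((X,Y),Z);")
  sq <- pathSequence(tr, "X", c("X", "Y", "Z"))
  expect_equal(sq, c("X|Y|Z", "X|Y"))
  expect_equal(pathSequence(tr, "Z", c("X", "Y", "Z")), "X|Y|Z")
  expect_error(pathSequence(tr, "W", c("X", "Y")), "not in tree")
  # strict nesting on random trees
  set.seed(17)
  for (i in 1:10) {
    tr <- simulateTree(10)
    bb <- sample(tr$tip.label, 6)
    sq <- pathSequence(tr, sample(tr$tip.label, 1), bb)
    sets <- strsplit(sq, "|", fixed = TRUE)
    for (j in seq_along(sets)[-1]) {
      expect_true(all(sets[[j]] %in% sets[[j - 1]]))
      expect_lt(length(sets[[j]]), length(sets[[j - 1]]))
    }
  }
})

test_that("sequence accuracy is the shared fraction of the standard path", {
  expect_equal(sequenceAccuracy(c(1, 2, 4, 5, 8, 10), c(1, 2, 4, 5, 8, 9)),
               5 / 6)
  expect_equal(sequenceAccuracy(letters[1:3], letters[1:3]), 1)
  expect_error(sequenceAccuracy(character(0), "a"), "empty")
})

test_that("identical trees score perfect path accuracy", {
  set.seed(23)
  tr <- simulateTree(12)
  bb <- sample(tr$tip.label, 7)
  acc <- pathAccuracy(tr, tr, setdiff(tr$tip.label, bb), bb)
  expect_equal(acc$mean, 1)
  expect_true(all(acc$perSpecies == 1))
})

test_that("path accuracy matches an independent clade-set recomputation", {
  set.seed(29)
  for (i in 1:5) {
    model <- simulateTree(10)
    other <- simulateTree(10)          # same labels, different topology
    bb <- sort(sample(model$tip.label, 6))
    sp <- setdiff(model$tip.label, bb)
    got <- pathAccuracy(model, other, sp, bb)$perSpecies
    for (s in sp) {
      seqOf <- function(tr) {
        ntip <- length(tr$tip.label)
        path <- ape::nodepath(tr, ntip + 1L, match(s, tr$tip.label))
        ids <- unique(vapply(path[path > ntip], function(v) {
          tips <- tr$tip.label[phangorn::Descendants(tr, v, "tips")[[1]]]
          paste(sort(intersect(tips, bb)), collapse = "|")
        }, ""))
        ids[nzchar(ids)]
      }
      expect_equal(got[[s]],
                   length(intersect(seqOf(model), seqOf(other))) /
                     length(seqOf(model)))
    }
  }
})

test_that("tree length is the minimum number of state changes", {
  m <- rbind(A = c(0L, 0L), B = c(0L, 0L), C = c(1L, 0L), D = c(1L, 0L))
  tr <- readTreeNewick("((A,B),(C,D));")
  expect_equal(treeLength(tr, characterMatrix(m)), 1L)
  mSame <- matrix(2L, 4, 3, dimnames = list(LETTERS[1:4], NULL))
  expect_equal(treeLength(tr, characterMatrix(mSame)), 0L)
})

test_that("tree length agrees with exhaustive enumeration and leaf addition", {
  set.seed(33)
  for (i in 1:6) {
    n <- sample(6:8, 1)
    tr <- simulateTree(n)
    m <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3,
                dimnames = list(tr$tip.label, NULL))
    m[sample(length(m), 2)] <- NA
    cm <- characterMatrix(m)
    expect_equal(treeLength(tr, cm), bfTreeLength(tr, cm))
    # dropping a leaf can only shorten the tree
    drop <- sample(tr$tip.label, 1)
    expect_lte(treeLength(ape::drop.tip(tr, drop), cm), treeLength(tr, cm))
  }
})

test_that("masking hits the requested number of observed entries", {
  set.seed(37)
  m <- matrix(sample(0:2, 50, replace = TRUE), 5, 10,
              dimnames = list(paste0("s", 1:5), NULL))
  cm <- characterMatrix(m)
  expect_identical(stateMatrix(maskMissing(cm, "s1", 0)), m)
  out <- maskMissing(cm, c("s2", "s3"), 0.5, seed = 1)
  expect_equal(sum(is.na(stateMatrix(out)["s2", ])), 5L)
  expect_equal(sum(is.na(stateMatrix(out)["s3", ])), 5L)
  expect_identical(stateMatrix(out)["s1", ], m["s1", ])
  # different seeds mask different cells but the same count
  out2 <- maskMissing(cm, "s2", 0.5, seed = 2)
  expect_equal(sum(is.na(stateMatrix(out2)["s2", ])), 5L)
  expect_false(identical(which(is.na(stateMatrix(out)["s2", ])),
                         which(is.na(stateMatrix(out2)["s2", ]))))
  expect_identical(stateMatrix(maskMissing(cm, "s4", 0.5, seed = 9)),
                   stateMatrix(maskMissing(cm, "s4", 0.5, seed = 9)))
})

test_that("a perfectly separable fixture bootstraps to accuracy 1", {
  model <- simulateTree(10, seed = 44)
  cm <- cladeIndicatorMatrix(model, copies = 8L)  # robust to resampling
  sp <- cherrySplit(model, maxSub2 = 3L)
  sub1 <- sp$sub1; sub2 <- sp$sub2
  seedTr <- cdtphylo:::.ensureNodeLabels(ape::drop.tip(model, sub2))
  b <- suppressWarnings(
    bootstrapAccuracy(model, seedTr, cm, sub2, proportion = 0,
                      replicates = 2, params = gaParams(popSize = 40, maxGen = 40),
                      seed = 4))
  expect_equal(b$mean, 1)
  # fixed seed reproduces the replicate stream
  b2 <- suppressWarnings(
    bootstrapAccuracy(model, seedTr, cm, sub2, proportion = 0,
                      replicates = 2, params = gaParams(popSize = 40, maxGen = 40),
                      seed = 4))
  expect_identical(b$accuracies, b2$accuracies)
})
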