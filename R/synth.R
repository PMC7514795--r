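#' Parameters for the synthetic-fixture generator
#'
#' Defaults emulate a mid-sized published morphological matrix (tens of
#' taxa, tens of attributes, a few states per character) with a moderate
#' per-edge change rate, and a 60/40 split between seed (sub1) and grafted
#' (sub2) species.
#'
#' @param nTaxa number of taxa (>= 4).
#' @param nChars number of characters (>= 1).
#' @param nStates number of discrete states per character (>= 2).
#' @param changeRate per-edge probability in `(0, 1)` that a character
#'   jumps to a different state.
#' @param maskProportion fraction of each sub2 row masked as missing.
#' @param sub1Fraction fraction of taxa designated relatively complete.
#' @param seed optional integer seed.
#' @return a validated list of class `sim_params`.
#' @export
simParams <- function(nTaxa = 40L, nChars = 60L, nStates = 3L,
                      changeRate = 0.15, maskProportion = 0,
                      sub1Fraction = 0.6, seed = NULL) {
  stopifnot(nTaxa >= 4L, nChars >= 1L, nStates >= 2L,
            changeRate > 0, changeRate < 1,
            maskProportion >= 0, maskProportion <= 1,
            sub1Fraction > 0, sub1Fraction < 1)
  structure(list(nTaxa = as.integer(nTaxa), nChars = as.integer(nChars),
                 nStates = as.integer(nStates), changeRate = changeRate,
                 maskProportion = maskProportion,
                 sub1Fraction = sub1Fraction, seed = seed),
            class = "sim_params")
}

#' Simulate a rooted binary model tree
#'
#' Random sequential addition: starting from a two-leaf tree, each new leaf
#' attaches to a uniformly chosen edge (including the root edge), which
#' draws uniformly from the rooted binary labelled topologies. Leaves are
#' labelled `t1..tn`.
#'
#' @param nTaxa number of leaves (>= 4).
#' @param seed optional integer seed.
#' @return a `phylo` with labelled internal nodes.
#' @export
simulateTree <- function(nTaxa, seed = NULL) {
  stopifnot(nTaxa >= 4L)
  if (!is.null(seed)) set.seed(seed)
  nextNode <- 1L
  newNode <- function() {
    id <- paste0("s", nextNode); nextNode <<- nextNode + 1L; id
  }
  root <- newNode()
  # edges as parent/child vectors over string ids
  parent <- c(root, root); child <- c("t1", "t2")
  for (k in 3L:nTaxa) {
    leaf <- paste0("t", k)
    j <- sample.int(length(child) + 1L, 1L)
    v <- newNode()
    if (j > length(child)) {          # attach above the root
      parent <- c(parent, v, v); child <- c(child, root, leaf)
      root <- v
    } else {                          # split edge p -> c0 at new node v
      c0 <- child[j]
      child[j] <- v
      parent <- c(parent, v, v); child <- c(child, c0, leaf)
    }
  }
  kids <- split(child, parent)
  build <- function(id) {
    if (startsWith(id, "t") && !id %in% names(kids)) return(id)
    paste0("(", paste(vapply(kids[[id]], build, ""), collapse = ","), ")", id)
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

#' Simulate discrete characters on a tree
#'
#' Each character evolves independently root-to-tip: the root state is
#' uniform over the states, and along each edge the state jumps with
#' probability `changeRate` to a uniformly chosen different state
#' (an Mk-like process). The matrix is complete (no missing values).
#'
#' @param tree a rooted `phylo`.
#' @param params a [simParams()] (only `nChars`, `nStates`, `changeRate`
#'   are used).
#' @param seed optional integer seed.
#' @param detail if `TRUE`, also return the realized number of change
#'   events (an upper bound on the parsimony length on the true tree).
#' @return a [CharacterMatrix-class] over the tips, or (with
#'   `detail = TRUE`) a list with `matrix` and `nChanges`.
#' @export
simulateCharacters <- function(tree, params, seed = NULL, detail = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nNode <- ntip + tree$Nnode
  edge <- reorder(tree, "cladewise")$edge  # parents before descendants
  nChanges <- 0L
  states <- matrix(NA_integer_, nNode, params$nChars)
  states[ntip + 1L, ] <- sample.int(params$nStates, params$nChars,
                                    replace = TRUE)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    s <- states[p, ]
    flip <- runif(params$nChars) < params$changeRate
    if (any(flip)) {
      nChanges <- nChanges + sum(flip)
      jump <- function(x) {
        alt <- setdiff(seq_len(params$nStates), x)
        alt[sample.int(length(alt), 1L)]
      }
      s[flip] <- vapply(s[flip], jump, 0L)
    }
    states[ch, ] <- s
  }
  m <- states[seq_len(ntip), , drop = FALSE] - 1L  # states coded 0..k-1
  rownames(m) <- tree$tip.label
  cm <- characterMatrix(m)
  if (detail) list(matrix = cm, nChanges = nChanges) else cm
}

#' Generate a complete synthetic fixture with known ground truth
#'
#' Simulates a model tree and characters, designates a random
#' `sub1Fraction` of the taxa as relatively complete (sub1), prunes the
#' model tree to sub1 to obtain the seed tree (isolating the grafting
#' machinery from seed-tree error), and masks the sub2 rows at
#' `maskProportion`. sub2 is ordered by decreasing completeness.
#'
#' @param params a [simParams()].
#' @return list with `modelTree`, `matrix` (masked), `completeMatrix`,
#'   `sub1`, `sub2`, `seedTree`, `params`.
#' @export
makeFixture <- function(params = simParams()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  model <- simulateTree(params$nTaxa)
  cm <- simulateCharacters(model, params)
  n1 <- ceiling(params$sub1Fraction * params$nTaxa)
  if (n1 < 3L) stop("sub1 would have fewer than 3 species")
  sub1 <- sort(sample(model$tip.label, n1))
  sub2 <- setdiff(model$tip.label, sub1)
  seedTr <- ape::drop.tip(model, sub2)
  seedTr <- .ensureNodeLabels(seedTr)
  masked <- maskMissing(cm, sub2, params$maskProportion)
  comp <- completeness(masked)[sub2]
  sub2 <- names(comp)[order(-comp)]
  list(modelTree = model, matrix = masked, completeMatrix = cm,
       sub1 = sub1, sub2 = sub2, seedTree = seedTr, params = params)
}
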