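#' Root-to-attachment path sequence of a species
#'
#' The sequence of internal nodes from the root down to the species'
#' terminal attachment, with each node identified by the sorted set of
#' backbone (seed/sub1) leaves below it. Content-based clade identifiers
#' make path sequences comparable across trees that differ in which grafted
#' taxa they contain. Nodes containing no backbone leaf are dropped and
#' consecutive duplicates collapsed, so the sequence is strictly nested.
#'
#' @param tree a `phylo`.
#' @param species a tip label of `tree`.
#' @param backbone character vector of backbone (sub1) leaf labels.
#' @return character vector of clade identifiers, root first.
#' @export
pathSequence <- function(tree, species, backbone) {
  tip <- match(species, tree$tip.label)
  if (is.na(tip)) stop("species not in tree: ", species)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- ape::nodepath(tree, from = root, to = tip)
  nodes <- nodes[nodes > ntip]  # internal nodes only
  ids <- vapply(nodes, function(v) {
    leaves <- intersect(.cladeLeaves(tree, v), backbone)
    if (!length(leaves)) return(NA_character_)
    paste(sort(leaves), collapse = "|")
  }, "")
  ids <- ids[!is.na(ids)]
  ids[c(TRUE, ids[-1L] != ids[-length(ids)])]
}

#' Overlap accuracy of two path sequences
#'
#' The fraction of the standard path sequence that the computed sequence
#' reproduces: `|Seqs ∩ Seqc| / |Seqs|`, treating both sequences as sets of
#' node identifiers.
#'
#' @param seqs the standard (model-tree) path sequence.
#' @param seqc the computed path sequence.
#' @return fraction in `[0, 1]`.
#' @examples
#' sequenceAccuracy(c(1, 2, 4, 5, 8, 10), c(1, 2, 4, 5, 8, 9))  # 5/6
#' @export
sequenceAccuracy <- function(seqs, seqc) {
  if (!length(seqs)) stop("the standard path sequence is empty")
  length(intersect(seqs, seqc)) / length(unique(seqs))
}

#' Mean path accuracy of placed species
#'
#' For each species, compares its path sequence in the accepted model tree
#' (the standard sequence) with its path sequence in the test tree, via
#' [sequenceAccuracy()]; clade identifiers are content-based over the
#' backbone leaves so the two trees need not share grafted taxa.
#'
#' @param modelTree the accepted `phylo` (contains all species).
#' @param testTree the inferred `phylo`.
#' @param species non-empty character vector of species to score.
#' @param backbone backbone (sub1) leaf labels used for clade identity.
#' @return list with `mean` and the named `perSpecies` vector.
#' @export
pathAccuracy <- function(modelTree, testTree, species, backbone) {
  if (!length(species)) stop("species set must be non-empty")
  per <- vapply(species, function(s)
    sequenceAccuracy(pathSequence(modelTree, s, backbone),
                     pathSequence(testTree, s, backbone)), 0)
  list(mean = mean(per), perSpecies = per)
}

#' Parsimony tree length of a character matrix on a tree
#'
#' The minimum total number of unordered character-state changes the tree
#' implies (Fitch small parsimony summed over attributes), with missing
#' values acting as wildcards. Shorter trees imply fewer morphological
#' changes and are preferred.
#'
#' @param tree a `phylo` whose tips are rows of `cm`.
#' @param cm a [CharacterMatrix-class].
#' @return non-negative integer.
#' @export
treeLength <- function(tree, cm) {
  m <- stateMatrix(cm)
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss)) stop("tips without matrix rows: ", paste(miss, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  lev <- sort(unique(as.vector(m[!is.na(m)])))
  if (length(lev) <= 1L) return(0L)
  chr <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
  chr[is.na(chr)] <- "?"
  dat <- phangorn::phyDat(chr, type = "USER", levels = as.character(lev),
                          ambiguity = "?")
  as.integer(phangorn::parsimony(tree, dat, method = "sankoff"))
}

#' Mask a proportion of entries as missing
#'
#' For each species in `speciesSet`, sets a uniformly chosen
#' `round(proportion * N)` of its observed entries to missing; other
#' species are untouched. Reproducible via `seed`.
#'
#' @param cm a [CharacterMatrix-class].
#' @param speciesSet species whose rows are masked.
#' @param proportion fraction in `[0, 1]` of each row to mask.
#' @param seed optional integer seed.
#' @return a new [CharacterMatrix-class].
#' @export
maskMissing <- function(cm, speciesSet, proportion, seed = NULL) {
  stopifnot(proportion >= 0, proportion <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- stateMatrix(cm)
  k <- round(proportion * ncol(m))
  for (sp in speciesSet) {
    obs <- which(!is.na(m[sp, ]))
    if (k > 0L && length(obs))
      m[sp, obs[sample.int(length(obs), min(k, length(obs)))]] <- NA_integer_
  }
  characterMatrix(m)
}

#' Bootstrap the grafting accuracy under masking
#'
#' Per replicate: resamples attributes (columns) with replacement — the
#' standard character bootstrap — rebuilds the concept decision tree on the
#' resampled matrix, masks the graft species at `proportion`, grafts them,
#' and scores the mean path accuracy against the model tree. Returns the
#' replicate mean and a percentile confidence interval.
#'
#' @param modelTree accepted `phylo` over all species.
#' @param seedTree `phylo` over the sub1 species.
#' @param cm complete [CharacterMatrix-class] over all species.
#' @param sub2 species to graft, ordered by decreasing completeness.
#' @param proportion masking proportion in `[0, 1]`.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param params [gaParams()] for the per-replicate rebuild.
#' @param seed optional integer seed for the whole replicate stream.
#' @param level confidence level for the percentile interval.
#' @return list with `mean`, `ci` (two-sided percentile bounds) and the
#'   per-replicate `accuracies`.
#' @export
bootstrapAccuracy <- function(modelTree, seedTree, cm, sub2, proportion,
                              replicates = 1000L, params = gaParams(),
                              seed = NULL, level = 0.95) {
  stopifnot(replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  params$seed <- NULL  # one stream for all replicates
  m <- stateMatrix(cm)
  accs <- vapply(seq_len(replicates), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    cmB <- characterMatrix(m[, cols, drop = FALSE])
    cdt <- suppressWarnings(buildConceptDecisionTree(seedTree, cmB, params))
    cmMasked <- maskMissing(cmB, sub2, proportion)
    res <- suppressWarnings(graftAll(cdt, cmMasked, sub2))
    pathAccuracy(modelTree, finalTree(res), sub2, seedTree$tip.label)$mean
  }, 0)
  alpha <- (1 - level) / 2
  list(mean = mean(accs),
       ci = unname(quantile(accs, c(alpha, 1 - alpha))),
       accuracies = accs)
}
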