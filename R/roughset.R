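#' Build a decision table for one decision point
#'
#' A decision table is the universe of species under one internal node of
#' the seed tree, their binary left/right labels, and the full condition
#' attribute set of the character matrix. Rough-set attribute reduction
#' operates on these tables.
#'
#' @param cm a [CharacterMatrix-class].
#' @param species character vector: the universe U (must be rows of `cm`).
#' @param labels named 0/1 vector over `species`: the decision attribute D
#'   (0 = left/A subtree, 1 = right/B subtree).
#' @return a `decision_table`: list with `species`, `labels`, `states`
#'   (the matrix restricted to U) and `C` (all attribute indices).
#' @export
decisionTable <- function(cm, species, labels) {
  m <- stateMatrix(cm)
  if (!all(species %in% rownames(m)))
    stop("species not in matrix: ",
         paste(setdiff(species, rownames(m)), collapse = ", "))
  labels <- labels[species]
  if (anyNA(labels)) stop("every species in the universe needs a decision label")
  if (!all(labels %in% c(0L, 1L))) stop("decision labels must be 0 or 1")
  structure(list(species = species,
                 labels = setNames(as.integer(labels), species),
                 states = m[species, , drop = FALSE],
                 C = seq_len(ncol(m))),
            class = "decision_table")
}

# Integer block keys for the B-equivalence relation. A species missing any
# attribute of B cannot be asserted equal to anything and gets its own
# singleton block (a per-row key).
.blockKeys <- function(tab, B) {
  sub <- tab$states[, B, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "\r")
  hasNA <- rowSums(is.na(sub)) > 0L
  key[hasNA] <- paste0("\rNA\r", which(hasNA))
  match(key, unique(key))
}

#' Equivalence classes under an attribute subset
#'
#' Partitions the universe: two species share a block iff they agree on
#' every attribute of `B`. A species with a missing value on any attribute
#' of `B` forms a singleton block (missingness is never treated as
#' equality). Blocks are ordered by first occurrence in the universe.
#'
#' @param tab a [decisionTable()].
#' @param B non-empty integer vector of attribute indices (1-based).
#' @return list of character vectors of species ids partitioning U.
#' @export
equivalenceClasses <- function(tab, B) {
  .checkB(tab, B)
  keys <- .blockKeys(tab, B)
  unname(split(tab$species, keys))  # keys number blocks by first occurrence
}

.checkB <- function(tab, B) {
  if (!length(B)) stop("attribute subset B must be non-empty")
  if (!all(B %in% tab$C))
    stop("attribute index out of range: ", paste(setdiff(B, tab$C), collapse = ", "))
  invisible(B)
}

#' Lower approximation of a species set
#'
#' The union of B-equivalence blocks wholly contained in `X`; always a
#' subset of `X`.
#'
#' @inheritParams equivalenceClasses
#' @param X character vector of species ids, a subset of the universe.
#' @return character vector of species ids.
#' @export
lowerApproximation <- function(tab, B, X) {
  if (!all(X %in% tab$species)) stop("X must be a subset of the universe")
  blocks <- equivalenceClasses(tab, B)
  inX <- vapply(blocks, function(b) all(b %in% X), TRUE)
  out <- unlist(blocks[inX], use.names = FALSE)
  if (is.null(out)) character(0) else out
}

#' Positive region of the decision under an attribute subset
#'
#' Union over the decision classes of their B-lower approximations: the
#' species whose B-block is label-pure. Monotone non-decreasing as B grows.
#'
#' @inheritParams equivalenceClasses
#' @return character vector of species ids (in universe order).
#' @export
positiveRegion <- function(tab, B) {
  .checkB(tab, B)
  keys <- .blockKeys(tab, B)
  pure <- vapply(split(tab$labels, keys), function(l) length(unique(l)) == 1L, TRUE)
  tab$species[pure[as.character(keys)]]
}

#' Shannon entropy of a label multiset
#'
#' Base-2 Shannon entropy with the convention `0 * log(0) = 0`.
#'
#' @param labels non-empty vector of discrete values.
#' @return entropy in bits, in `[0, log2(#distinct values)]`.
#' @export
shannonEntropy <- function(labels) {
  if (!length(labels)) stop("entropy of an empty multiset is undefined")
  p <- tabulate(match(labels, unique(labels)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# H(D | partition induced by B); B empty = one block = H(D)
.condEntropy <- function(tab, B) {
  if (!length(B)) return(shannonEntropy(tab$labels))
  keys <- .blockKeys(tab, B)
  n <- length(keys)
  sum(vapply(split(tab$labels, keys), function(l)
    length(l) / n * shannonEntropy(l), 0))
}

#' Mutual information between an attribute subset and the decision
#'
#' `I(B; D) = H(D) - H(D|B)` over the B-equivalence partition, in bits.
#' Non-negative and bounded by `H(D)`; monotone non-decreasing in B.
#'
#' @inheritParams equivalenceClasses
#' @return mutual information in bits.
#' @export
mutualInformation <- function(tab, B) {
  .checkB(tab, B)
  shannonEntropy(tab$labels) - .condEntropy(tab, B)
}

#' Significance of adding one attribute to a reduct
#'
#' `SGF(a, R, D) = H(D|R) - H(D | R + a)`: the mutual-information gain from
#' joining attribute `a` to the attribute set `R`. Non-negative up to
#' floating tolerance. `R` may be empty.
#'
#' @inheritParams equivalenceClasses
#' @param a a single attribute index not in `R`.
#' @param R integer vector of attribute indices (possibly empty).
#' @return gain in bits.
#' @export
attributeSignificance <- function(tab, a, R = integer(0)) {
  stopifnot(length(a) == 1L, a %in% tab$C)
  if (a %in% R) stop("attribute ", a, " is already in the reduct")
  .condEntropy(tab, R) - .condEntropy(tab, c(R, a))
}
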