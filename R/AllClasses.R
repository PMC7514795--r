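#' @import methods
#' @importFrom stats setNames quantile runif median
#' @importFrom utils head
NULL

#' CharacterMatrix: a discrete species-by-attribute table
#'
#' The central data container: a species-against-attributes matrix of
#' discrete morphological states coded as small non-negative integers, with
#' `NA` marking missing ("?") entries. Rows are species, columns are
#' attributes numbered 1..N; all interfaces use 1-based attribute indices.
#'
#' @slot states integer matrix; rownames are unique species labels, `NA`
#'   encodes a missing observation.
#'
#' @seealso [characterMatrix()], [readCharacterMatrix()], [completeness()]
#' @exportClass CharacterMatrix
setClass("CharacterMatrix", representation(states = "matrix"))

setValidity("CharacterMatrix", function(object) {
  m <- object@states
  msgs <- character()
  if (!is.matrix(m) || nrow(m) < 1L || ncol(m) < 1L)
    msgs <- c(msgs, "'states' must be a matrix with at least one species and one attribute")
  ids <- rownames(m)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "species labels (rownames) must be non-empty")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate species label: '%s'", ids[duplicated(ids)][1L]))
  v <- m[!is.na(m)]
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    msgs <- c(msgs, "observed states must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CharacterMatrix
#'
#' @param states a matrix (or object coercible to one) of non-negative
#'   integer states with `NA` for missing values; rownames give the species
#'   labels.
#' @param species optional character vector of species labels overriding the
#'   rownames.
#' @return a validated [CharacterMatrix-class] object.
#' @examples
#' m <- rbind(X = c(1, 0, NA), Y = c(0, 0, 1))
#' cm <- characterMatrix(m)
#' nAttributes(cm)
#' @export
characterMatrix <- function(states, species = NULL) {
  m <- as.matrix(states)
  if (!is.null(species)) rownames(m) <- species
  storage.mode(m) <- "integer"
  new("CharacterMatrix", states = m)
}

#' @describeIn characterMatrix species labels, in matrix order.
#' @param x a CharacterMatrix.
#' @export
speciesIds <- function(x) rownames(x@states)

#' @describeIn characterMatrix number of attributes (columns).
#' @export
nAttributes <- function(x) ncol(x@states)

#' @describeIn characterMatrix number of species (rows).
#' @export
nSpecies <- function(x) nrow(x@states)

#' @describeIn characterMatrix the underlying integer matrix (`NA` = missing).
#' @export
stateMatrix <- function(x) x@states

setMethod("show", "CharacterMatrix", function(object) {
  m <- object@states
  miss <- mean(is.na(m))
  cat(sprintf("CharacterMatrix: %d species x %d attributes (%.1f%% missing)\n",
              nrow(m), ncol(m), 100 * miss))
  shown <- head(rownames(m), 5L)
  cat("  species:", paste(shown, collapse = ", "),
      if (nrow(m) > 5L) "..." else "", "\n")
})

#' ConceptDecisionTree: a seed phylogeny with decision points
#'
#' A rooted binary seed tree over the relatively complete species, whose
#' internal nodes each carry a decision point: a list of concept-sample
#' templates (attribute subsets with disjoint left/right observed-value
#' sets) produced by genetic-algorithm rough-set attribute reduction.
#'
#' @slot seedTree the (binary, rooted) `phylo` seed tree; internal nodes are
#'   labelled with stable ids.
#' @slot decisionPoints named list, one entry per internal node id; each is a
#'   list with elements `node` and `templates` (see [extractValueSets()]).
#' @slot metadata list: GA parameters, seed, and the left-child convention
#'   (label 0 = first child in Newick order).
#'
#' @seealso [buildConceptDecisionTree()], [graftAll()]
#' @exportClass ConceptDecisionTree
setClass("ConceptDecisionTree",
         representation(seedTree = "ANY", decisionPoints = "list",
                        metadata = "list"))

setValidity("ConceptDecisionTree", function(object) {
  tr <- object@seedTree
  if (!inherits(tr, "phylo")) return("'seedTree' must be a phylo object")
  if (is.null(tr$node.label) || anyDuplicated(tr$node.label))
    return("seed tree internal nodes must carry unique labels")
  if (!all(names(object@decisionPoints) %in% tr$node.label))
    return("decision points must be keyed by internal node labels")
  TRUE
})

setMethod("show", "ConceptDecisionTree", function(object) {
  k <- vapply(object@decisionPoints, function(dp) length(dp$templates), 0L)
  cat(sprintf("ConceptDecisionTree: %d tips, %d decision points\n",
              length(object@seedTree$tip.label), length(k)))
  cat(sprintf("  templates per node: min %d / median %s / max %d\n",
              if (length(k)) min(k) else 0L,
              if (length(k)) format(median(k)) else "0",
              if (length(k)) max(k) else 0L))
  if (any(k == 0L))
    cat("  note:", sum(k == 0L), "decision point(s) have no surviving template\n")
})

#' @describeIn buildConceptDecisionTree the seed `phylo` tree of a
#'   ConceptDecisionTree.
#' @param cdt a ConceptDecisionTree.
#' @export
seedTree <- function(cdt) cdt@seedTree

#' @describeIn buildConceptDecisionTree named list of decision points.
#' @export
decisionPoints <- function(cdt) cdt@decisionPoints

#' GraftResult: the completed phylogeny and its placement audit trail
#'
#' @slot tree the final `phylo` tree containing seed and grafted species.
#' @slot placements named list (one per grafted species) with the
#'   root-to-attachment path: per step `node`, `side`, `m`, `n`, `K`.
#' @slot stackedNodes character vector of node ids where species stacking
#'   (a polytomy) occurred before Wagner resolution.
#' @slot metadata list (species order, seed, unresolved polytomies).
#' @seealso [graftAll()]
#' @exportClass GraftResult
setClass("GraftResult",
         representation(tree = "ANY", placements = "list",
                        stackedNodes = "character", metadata = "list"))

setMethod("show", "GraftResult", function(object) {
  cat(sprintf("GraftResult: %d tips after grafting %d species\n",
              length(object@tree$tip.label), length(object@placements)))
  if (length(object@stackedNodes))
    cat("  stacking resolved at:", paste(object@stackedNodes, collapse = ", "), "\n")
})

#' @describeIn graftAll the final `phylo` tree of a GraftResult.
#' @param x a GraftResult.
#' @export
finalTree <- function(x) x@tree

#' @describeIn graftAll the per-species placement paths.
#' @export
placements <- function(x) x@placements
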