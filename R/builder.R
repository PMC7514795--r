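#' Decision table for one internal node of the seed tree
#'
#' The universe is the set of leaf species under `node`; species under the
#' first child (the A subtree, first in Newick order) get decision label 0
#' and species under the second child (B subtree) get 1. The condition set
#' is every attribute of the matrix.
#'
#' @param tree a rooted binary `phylo` whose tips are rows of `cm`.
#' @param node an internal node: ape node number or node label.
#' @param cm a [CharacterMatrix-class].
#' @return a [decisionTable()].
#' @export
nodeDecisionTable <- function(tree, node, cm) {
  tree <- .ensureNodeLabels(tree)
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    node <- match(node, tree$node.label) + ntip
    if (is.na(node)) stop("unknown internal node label")
  }
  if (node <= ntip) stop("node must be internal")
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  if (length(kids) != 2L)
    stop("decision points need a binary node; found ", length(kids), " children")
  left <- .cladeLeaves(tree, kids[1L])
  right <- .cladeLeaves(tree, kids[2L])
  U <- c(left, right)
  if (length(U) < 2L) stop("node has fewer than 2 leaves")
  labels <- setNames(c(rep(0L, length(left)), rep(1L, length(right))), U)
  decisionTable(cm, U, labels)
}

#' Observed left/right value sets for a template
#'
#' For each attribute of the template, collects the distinct non-missing
#' states among the left (label 0) and right (label 1) species of the
#' decision table. The template is rejected (returns `NULL`) if, for any
#' attribute, the two value sets intersect or either is empty — such a
#' template could not discriminate the two subtrees.
#'
#' @param templateAttrs non-empty integer vector of attribute indices.
#' @param tab a [decisionTable()].
#' @return a concept template: list with `attrs`, `left`, `right` (the
#'   latter two are per-attribute value sets named by attribute index), or
#'   `NULL` if rejected.
#' @export
extractValueSets <- function(templateAttrs, tab) {
  stopifnot(length(templateAttrs) >= 1L)
  leftSp <- tab$labels == 0L
  left <- right <- list()
  for (a in templateAttrs) {
    lv <- sort(unique(tab$states[leftSp, a]))
    rv <- sort(unique(tab$states[!leftSp, a]))
    lv <- lv[!is.na(lv)]; rv <- rv[!is.na(rv)]
    if (!length(lv) || !length(rv) || length(intersect(lv, rv)))
      return(NULL)
    left[[as.character(a)]] <- lv
    right[[as.character(a)]] <- rv
  }
  list(attrs = as.integer(templateAttrs), left = left, right = right)
}

#' Build a concept decision tree from a seed phylogeny
#'
#' Turns every internal node of the seed tree into a decision point: a
#' binary left/right decision table is formed from the leaves under the
#' node, the genetic attribute-reduction search ([runReduction()]) proposes
#' concept-sample templates, and each template is annotated with its
#' observed left/right value sets ([extractValueSets()]); templates whose
#' value sets overlap or are empty are dropped. Polytomies in the seed tree
#' are resolved into a caterpillar (in input child order) with a warning,
#' since decision points need a binary A/B split.
#'
#' @param tree rooted `phylo` seed tree; every tip must be a row of `cm`.
#' @param cm a [CharacterMatrix-class].
#' @param params a [gaParams()]; `params$seed` makes the whole build
#'   deterministic.
#' @return a [ConceptDecisionTree-class].
#' @examples
#' cm <- characterMatrix(rbind(X = c(1L, 0L), Y = c(1L, 1L), Z = c(0L, 0L)))
#' tr <- readTreeNewick("((X,Y),Z);")
#' cdt <- buildConceptDecisionTree(tr, cm, gaParams(popSize = 10, maxGen = 5, seed = 1))
#' @export
buildConceptDecisionTree <- function(tree, cm, params = gaParams()) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, speciesIds(cm))
  if (length(miss))
    stop("seed-tree leaves missing from the matrix: ", paste(miss, collapse = ", "))
  if (!ape::is.binary(tree)) {
    warning("seed tree has polytomies; resolving into a caterpillar")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree <- .ensureNodeLabels(tree)
  if (!is.null(params$seed)) set.seed(params$seed)
  innerParams <- params
  innerParams$seed <- NULL  # one seeded stream for the whole build
  ntip <- length(tree$tip.label)
  dps <- list()
  for (v in ntip + seq_len(tree$Nnode)) {
    lab <- tree$node.label[v - ntip]
    tab <- nodeDecisionTable(tree, v, cm)
    red <- runReduction(tab, innerParams)
    templates <- Filter(Negate(is.null),
                        lapply(red$templates, extractValueSets, tab = tab))
    if (!length(templates))
      warning("no surviving template at node ", lab, " (K = 0)")
    dps[[lab]] <- list(node = lab, templates = templates,
                       fitness = red$fitness)
  }
  new("ConceptDecisionTree", seedTree = tree, decisionPoints = dps,
      metadata = list(seed = params$seed, gaParams = params[c("popSize", "pc", "pm", "maxGen")],
                      leftChild = "first child in Newick order = label 0"))
}
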