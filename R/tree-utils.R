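# Internal mutable-ish tree representation used during grafting: a named
# list of nodes (id -> list(parent, children, leaf)). Internal node ids are
# the phylo node labels; leaf ids are the tip labels, so seed-tree decision
# points stay addressable while the tree grows.

.ensureNodeLabels <- function(tree, prefix = "N") {
  if (is.null(tree$node.label) || anyNA(tree$node.label) ||
      any(!nzchar(tree$node.label)) || anyDuplicated(tree$node.label)) {
    tree$node.label <- paste0(prefix, seq_len(tree$Nnode))
  }
  if (any(tree$node.label %in% tree$tip.label))
    tree$node.label <- paste0(prefix, seq_len(tree$Nnode))
  tree
}

.phyloToTlist <- function(tree) {
  ntip <- length(tree$tip.label)
  idOf <- function(v) if (v <= ntip) tree$tip.label[v] else tree$node.label[v - ntip]
  nodes <- list()
  for (v in seq_len(ntip))
    nodes[[tree$tip.label[v]]] <- list(parent = NA_character_,
                                       children = character(0), leaf = TRUE)
  for (v in ntip + seq_len(tree$Nnode))
    nodes[[idOf(v)]] <- list(parent = NA_character_,
                             children = character(0), leaf = FALSE)
  for (e in seq_len(nrow(tree$edge))) {
    p <- idOf(tree$edge[e, 1L]); c <- idOf(tree$edge[e, 2L])
    nodes[[c]]$parent <- p
    nodes[[p]]$children <- c(nodes[[p]]$children, c)
  }
  list(nodes = nodes, root = idOf(ntip + 1L))
}

.tlistToNewick <- function(tl) {
  build <- function(id) {
    nd <- tl$nodes[[id]]
    if (nd$leaf) return(id)
    paste0("(", paste(vapply(nd$children, build, ""), collapse = ","), ")", id)
  }
  paste0(build(tl$root), ";")
}

.tlistToPhylo <- function(tl) {
  ape::read.tree(text = .tlistToNewick(tl))
}

.tlistLeaves <- function(tl, id) {
  nd <- tl$nodes[[id]]
  if (nd$leaf) return(id)
  unlist(lapply(nd$children, .tlistLeaves, tl = tl), use.names = FALSE)
}

# leaves under each node of a phylo, as tip-label character vectors
.cladeLeaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  tree$tip.label[tips]
}
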