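# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (pairwise comparisons, exhaustive enumeration) so the
# package implementation is checked against a different mechanism.

# random decision table: nSp species, nAttr attributes, states 0..(k-1),
# a fraction of entries missing, random binary labels (both classes present)
randomTable <- function(nSp, nAttr, nStates = 3L, missingFrac = 0) {
  m <- matrix(sample(0:(nStates - 1L), nSp * nAttr, replace = TRUE),
              nSp, nAttr)
  if (missingFrac > 0) {
    idx <- which(runif(nSp * nAttr) < missingFrac)
    m[idx] <- NA_integer_
  }
  rownames(m) <- paste0("sp", seq_len(nSp))
  labels <- integer(nSp)
  while (length(unique(labels)) < 2L)
    labels <- sample(0:1, nSp, replace = TRUE)
  decisionTable(characterMatrix(m), rownames(m), setNames(labels, rownames(m)))
}

# brute-force equivalence classes: pairwise agreement (species with any
# missing value on B relate to nothing), then connected components
bfBlocks <- function(tab, B) {
  sp <- tab$species
  n <- length(sp)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vi <- tab$states[i, B]; vj <- tab$states[j, B]
    if (!anyNA(vi) && !anyNA(vj) && all(vi == vj))
      comp[comp == comp[j]] <- comp[i]
  }
  unname(split(sp, comp)[unique(as.character(comp))])
}

bfLower <- function(tab, B, X) {
  out <- character(0)
  for (b in bfBlocks(tab, B)) if (all(b %in% X)) out <- c(out, b)
  out
}

bfPos <- function(tab, B) {
  out <- character(0)
  for (lbl in unique(tab$labels)) {
    X <- tab$species[tab$labels == lbl]
    out <- c(out, bfLower(tab, B, X))
  }
  out
}

bfEntropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# I(B;D) from the joint frequency table: H(B) + H(D) - H(B,D)
bfMI <- function(tab, B) {
  key <- apply(tab$states[, B, drop = FALSE], 1L, paste, collapse = "/")
  key[apply(is.na(tab$states[, B, drop = FALSE]), 1L, any)] <-
    paste0("na", seq_along(key))[apply(is.na(tab$states[, B, drop = FALSE]), 1L, any)]
  bfEntropy(key) + bfEntropy(tab$labels) -
    bfEntropy(paste(key, tab$labels))
}

# brute-force chromosome fitness: re-derives POS per template from scratch
bfFitness <- function(codes, tab) {
  N <- length(codes)
  tot <- 0
  for (B in decodeChromosome(codes)) {
    if (setequal(bfPos(tab, B), bfPos(tab, tab$C)))
      tot <- tot + (N - length(B)) / N
  }
  tot
}

# exhaustive optimum over all (N+1)^N chromosomes (N <= 4)
bfBestFitness <- function(tab) {
  N <- length(tab$C)
  grid <- do.call(expand.grid, rep(list(0:N), N))
  best <- 0
  for (r in seq_len(nrow(grid))) {
    f <- bfFitness(as.integer(grid[r, ]), tab)
    if (f > best) best <- f
  }
  best
}

# exhaustive small-parsimony length: enumerate every assignment of states
# to internal nodes and count changes on edges
bfTreeLength <- function(tree, cm) {
  m <- stateMatrix(cm)[tree$tip.label, , drop = FALSE]
  states <- sort(unique(as.vector(m[!is.na(m)])))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  total <- 0L
  for (ch in seq_len(ncol(m))) {
    tipv <- m[, ch]
    grid <- do.call(expand.grid, rep(list(states), nint))
    bestc <- Inf
    for (r in seq_len(nrow(grid))) {
      asg <- c(rep(NA_integer_, ntip), as.integer(grid[r, ]))
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
        sa <- asg[a]
        sb <- if (b <= ntip) tipv[b] else asg[b]
        if (is.na(sb)) next  # missing tip: free choice, never forces a change
        if (sa != sb) cost <- cost + 1L
      }
      if (cost < bestc) bestc <- cost
    }
    total <- total + bestc
  }
  total
}

# a matrix of perfect clade-indicator characters for a tree: one column per
# clade (internal node) and one per tip, each 1 exactly inside the clade,
# replicated `copies` times. Every decision point of any subtree of `tree`
# is then cleanly separable — including cherries, via the tip columns —
# and the redundancy keeps that true under column resampling.
cladeIndicatorMatrix <- function(tree, copies = 3L) {
  ntip <- length(tree$tip.label)
  nodes <- seq_len(ntip + tree$Nnode)
  m <- sapply(nodes, function(v) {
    as.integer(tree$tip.label %in%
                 tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1L]]])
  })
  rownames(m) <- tree$tip.label
  characterMatrix(m[, rep(seq_len(ncol(m)), copies)])
}

# split tips so every graft species is the model sibling of a retained
# leaf (a cherry partner): such species have a determined root-to-leaf
# signal under clade-indicator characters, unlike stem species
cherrySplit <- function(tree, maxSub2 = 4L) {
  ntip <- length(tree$tip.label)
  sub2 <- character(0)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (all(kids <= ntip) && length(sub2) < maxSub2)
      sub2 <- c(sub2, tree$tip.label[kids[1]])
  }
  list(sub1 = sort(setdiff(tree$tip.label, sub2)), sub2 = sub2)
}

# the worked-example style 5-species matrix: attributes 1..8; attributes
# 1, 3, 4, 6, 8 cleanly separate {X,Y,Z} from {I}; 2, 5, 7 are constant
workedMatrix <- function() {
  m <- rbind(
    X = c(1L, 0L, 2L, 1L, 1L, 0L, 0L, 0L),
    Y = c(2L, 0L, 2L, 1L, 1L, 0L, 0L, 0L),
    Z = c(1L, 0L, 2L, 1L, 1L, 0L, 0L, 0L),
    I = c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L))
  characterMatrix(m)
}

workedSpeciesG <- function() {
  c(1L, 0L, 2L, 1L, 1L, 0L, 0L, NA)
}
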