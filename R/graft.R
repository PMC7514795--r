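#' Match one species against one concept-sample template
#'
#' Returns `"left"` if, for every attribute of the template, the species'
#' state is observed and lies in the template's left value set; `"right"`
#' analogously; otherwise `"inconclusive"` — including whenever any
#' template attribute is missing in the species, in which case neither
#' tally is accumulated.
#'
#' @param Q integer vector: the species' full attribute row (`NA` =
#'   missing), indexed 1..N.
#' @param template a concept template from [extractValueSets()].
#' @return one of `"left"`, `"right"`, `"inconclusive"`.
#' @export
matchTemplate <- function(Q, template) {
  vals <- Q[template$attrs]
  if (anyNA(vals)) return("inconclusive")
  keys <- as.character(template$attrs)
  inL <- all(vapply(seq_along(keys), function(i)
    vals[i] %in% template$left[[keys[i]]], TRUE))
  if (inL) return("left")
  inR <- all(vapply(seq_along(keys), function(i)
    vals[i] %in% template$right[[keys[i]]], TRUE))
  if (inR) return("right")
  "inconclusive"
}

#' Tally template matches at one decision point
#'
#' Evaluates all K templates of the decision point; `m` counts templates
#' matching the left (A) subtree, `n` the right (B) subtree. The tally is
#' invariant to template order.
#'
#' @param Q the species' attribute row.
#' @param decisionPoint a decision point (element of [decisionPoints()]).
#' @return list with `m`, `n`, `K`.
#' @export
matchAtNode <- function(Q, decisionPoint) {
  res <- vapply(decisionPoint$templates, matchTemplate, "", Q = Q)
  list(m = sum(res == "left"), n = sum(res == "right"),
       K = length(res))
}

#' Wagner distance between two attribute rows
#'
#' Sum of absolute state differences over the attributes observed in both
#' species (ordered-state semantics); attributes missing in either species
#' are skipped. Returns `Inf` when no attribute is jointly observed.
#'
#' @param xa,xb equal-length integer vectors (`NA` = missing).
#' @return non-negative number, possibly `Inf`.
#' @export
wagnerDistance <- function(xa, xb) {
  stopifnot(length(xa) == length(xb))
  ok <- !is.na(xa) & !is.na(xb)
  if (!any(ok)) return(Inf)
  sum(abs(xa[ok] - xb[ok]))
}

# --- internal grafting engine on the tlist representation -------------------

# Descend from the root following m/n tallies; returns the updated tlist
# plus the placement record. `dps` maps seed internal node id -> decision
# point; grafted internal nodes carry no decision point (K = 0 there).
.graftOne <- function(tl, dps, Q, speciesId) {
  path <- list()
  cur <- tl$root
  repeat {
    nd <- tl$nodes[[cur]]
    if (nd$leaf) {
      tl <- .attachSibling(tl, cur, speciesId)
      return(list(tl = tl, placement = list(
        species = speciesId, path = path, attachment = cur, stacked = FALSE)))
    }
    dp <- dps[[cur]]
    tal <- if (is.null(dp)) list(m = 0L, n = 0L, K = 0L) else matchAtNode(Q, dp)
    if (tal$m > tal$n) side <- "left"
    else if (tal$n > tal$m) side <- "right"
    else side <- "stop"
    path[[length(path) + 1L]] <- list(node = cur, side = side,
                                      m = tal$m, n = tal$n, K = tal$K)
    if (side == "stop") {
      tl <- .attachChild(tl, cur, speciesId)
      return(list(tl = tl, placement = list(
        species = speciesId, path = path, attachment = cur, stacked = TRUE)))
    }
    cur <- nd$children[if (side == "left") 1L else 2L]
  }
}

# new internal node replacing `at` in its parent's child list, with
# children (at, species): the grafted species becomes `at`'s sibling
.attachSibling <- function(tl, at, speciesId) {
  newId <- paste0("g_", speciesId)
  parent <- tl$nodes[[at]]$parent
  tl$nodes[[newId]] <- list(parent = parent, children = c(at, speciesId),
                            leaf = FALSE)
  tl$nodes[[speciesId]] <- list(parent = newId, children = character(0),
                                leaf = TRUE)
  tl$nodes[[at]]$parent <- newId
  if (is.na(parent)) tl$root <- newId
  else {
    ch <- tl$nodes[[parent]]$children
    ch[ch == at] <- newId
    tl$nodes[[parent]]$children <- ch
  }
  tl
}

# the grafted species becomes an extra child of `at` (species stacking)
.attachChild <- function(tl, at, speciesId) {
  tl$nodes[[speciesId]] <- list(parent = at, children = character(0),
                                leaf = TRUE)
  tl$nodes[[at]]$children <- c(tl$nodes[[at]]$children, speciesId)
  tl
}

#' Graft a single species onto a concept decision tree
#'
#' Starting at the root, tallies template matches at each decision point
#' and descends into the A subtree if `m > n` or the B subtree if
#' `n > m`. Descent stops at a leaf (the species is attached as its
#' sibling, under a fresh internal node) or at a node where `m = n`
#' (including `K = 0`), where the species is attached as an additional
#' child — species stacking, later resolved by [wagnerDistance()]
#' agglomeration in [graftAll()].
#'
#' @param cdt a [ConceptDecisionTree-class].
#' @param Q the species' attribute row (`NA` = missing), length
#'   `nAttributes` of the build matrix.
#' @param speciesId label for the new leaf (must not already be in the
#'   tree).
#' @return list with `tree` (a `phylo`) and `placement` (species, per-node
#'   path of `(node, side, m, n, K)`, attachment node id, stacked flag).
#' @export
graftSpecies <- function(cdt, Q, speciesId) {
  tl <- .phyloToTlist(seedTree(cdt))
  if (speciesId %in% names(tl$nodes)) stop("species already in tree: ", speciesId)
  res <- .graftOne(tl, decisionPoints(cdt), Q, speciesId)
  list(tree = .tlistToPhylo(res$tl), placement = res$placement)
}

# agglomerative resolution of one stacked polytomy: repeatedly merge the
# two children whose leaf sets have minimal single-linkage Wagner distance
.resolveNode <- function(tl, at, states, counter) {
  repeat {
    ch <- tl$nodes[[at]]$children
    if (length(ch) <= 2L) return(list(tl = tl, counter = counter, unresolved = FALSE))
    leaves <- lapply(ch, .tlistLeaves, tl = tl)
    best <- NULL; bestD <- Inf; bestKey <- NULL
    for (i in seq_along(ch)[-length(ch)]) for (j in (i + 1L):length(ch)) {
      d <- min(vapply(leaves[[i]], function(a)
        min(vapply(leaves[[j]], function(b)
          wagnerDistance(states[a, ], states[b, ]), 0)), 0))
      key <- paste(sort(c(min(leaves[[i]]), min(leaves[[j]]))), collapse = "\r")
      if (d < bestD - 1e-12 ||
          (abs(d - bestD) <= 1e-12 && !is.null(bestKey) && key < bestKey)) {
        bestD <- d; best <- c(i, j); bestKey <- key
      }
    }
    if (!is.finite(bestD)) {
      warning("all pairwise Wagner distances undefined at node ", at,
              "; leaving polytomy")
      return(list(tl = tl, counter = counter, unresolved = TRUE))
    }
    counter <- counter + 1L
    newId <- paste0("r", counter, "_", at)
    pair <- ch[best]
    tl$nodes[[newId]] <- list(parent = at, children = pair, leaf = FALSE)
    for (p in pair) tl$nodes[[p]]$parent <- newId
    tl$nodes[[at]]$children <- c(setdiff(ch, pair), newId)
  }
}

#' Graft every incomplete species and resolve stacking
#'
#' Grafts the species of `sub2` one by one (callers should order `sub2` by
#' decreasing completeness), then resolves any stacked polytomies by
#' agglomerative merging of the closest children under single-linkage
#' Wagner distance, with lexicographic tie-breaks. The seed topology over
#' `sub1` is never altered — grafting only adds nodes.
#'
#' @param cdt a [ConceptDecisionTree-class].
#' @param cm the [CharacterMatrix-class] holding rows for all species
#'   (seed and grafts; graft rows may contain `NA`).
#' @param sub2 character vector of species to graft, in grafting order.
#' @return a [GraftResult-class].
#' @export
graftAll <- function(cdt, cm, sub2) {
  states <- stateMatrix(cm)
  missing <- setdiff(sub2, rownames(states))
  if (length(missing))
    stop("species to graft missing from the matrix: ",
         paste(missing, collapse = ", "))
  tl <- .phyloToTlist(seedTree(cdt))
  dps <- decisionPoints(cdt)
  placements <- list()
  for (sp in sub2) {
    if (sp %in% names(tl$nodes)) stop("species already in tree: ", sp)
    res <- .graftOne(tl, dps, states[sp, ], sp)
    tl <- res$tl
    placements[[sp]] <- res$placement
  }
  stacked <- unique(vapply(Filter(function(p) p$stacked, placements),
                           function(p) p$attachment, ""))
  counter <- 0L
  unresolved <- character(0)
  for (at in stacked) {
    res <- .resolveNode(tl, at, states, counter)
    tl <- res$tl; counter <- res$counter
    if (res$unresolved) unresolved <- c(unresolved, at)
  }
  new("GraftResult", tree = .tlistToPhylo(tl), placements = placements,
      stackedNodes = stacked,
      metadata = list(order = sub2, unresolved = unresolved))
}
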