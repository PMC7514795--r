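#' Parameters for the genetic attribute-reduction search
#'
#' @param popSize population size (>= 2).
#' @param pc crossover probability in `[0, 1]`.
#' @param pm mutation probability in `[0, 1]`.
#' @param maxGen number of generations.
#' @param seed optional integer seed; when given the search is fully
#'   reproducible.
#' @return a validated list of class `ga_params`.
#' @export
gaParams <- function(popSize = 50L, pc = 0.8, pm = 0.1, maxGen = 100L,
                     seed = NULL) {
  stopifnot(popSize >= 2L, pc >= 0, pc <= 1, pm >= 0, pm <= 1, maxGen >= 1L)
  structure(list(popSize = as.integer(popSize), pc = pc, pm = pm,
                 maxGen = as.integer(maxGen), seed = seed),
            class = "ga_params")
}

#' Decode a chromosome into a set of concept-sample templates
#'
#' A chromosome is an integer vector of length N (one site per attribute)
#' with codes in `0..N`. Code 0 excludes the attribute; attributes sharing
#' a non-zero code form one template; unique non-zero codes give singleton
#' templates. Chromosomes inducing the same partition decode identically,
#' and templates are ordered by their smallest attribute index.
#'
#' @param codes integer vector, values in `0..length(codes)`.
#' @return list of sorted integer vectors (the templates); may be empty.
#' @examples
#' decodeChromosome(c(1, 3, 0, 4, 5, 7, 10, 9, 9, 8))
#' @export
decodeChromosome <- function(codes) {
  N <- length(codes)
  if (any(codes < 0L | codes > N))
    stop("chromosome codes must lie in 0..", N)
  sel <- which(codes != 0L)
  if (!length(sel)) return(list())
  groups <- unname(split(sel, codes[sel]))  # members already ascending
  groups[order(vapply(groups, `[`, 0L, 1L))]
}

#' Fitness of a chromosome on a decision table
#'
#' Each decoded template contributes `(|C| - r_n) / |C|` if it preserves
#' the positive region of the full condition set (`POS_B(D) = POS_C(D)`),
#' and 0 otherwise; the fitness is the sum over templates. Smaller
#' positive-region-preserving templates therefore score higher, and a
#' chromosome may bundle several independent reduct-like templates.
#'
#' @param codes a chromosome (see [decodeChromosome()]).
#' @param tab a [decisionTable()].
#' @return non-negative fitness score.
#' @export
templateFitness <- function(codes, tab) {
  .gaFitness(codes, .rsEvaluator(tab))
}

# Cached rough-set evaluator for one decision table. Each attribute column
# is pre-coded as a canonical integer key (missing entries get a per-row
# code, which realizes the singleton-block policy for NA); the partition
# under an attribute subset is built by integer key-combination, so
# positive-region size and conditional entropy are cheap, and SGF scans
# reuse the parent partition. POS_B is always a subset of POS_C
# (monotonicity), so preservation reduces to a size comparison.
.rsEvaluator <- function(tab) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  states <- tab$states
  labels <- unname(tab$labels)
  n <- length(labels)
  N <- length(tab$C)
  colKeys <- matrix(0L, n, N)
  for (j in seq_len(N)) {
    v <- states[, j]
    v[is.na(v)] <- n + seq_len(n)[is.na(v)] + max(v, 0L, na.rm = TRUE)
    colKeys[, j] <- match(v, unique(v))
  }
  combine <- function(k, j) {
    z <- k * (n + 1L) + colKeys[, j]
    match(z, unique(z))
  }
  partOf <- function(Bs) Reduce(combine, Bs[-1L], init = colKeys[, Bs[1L]])
  hD <- shannonEntropy(labels)
  statsFromPart <- function(part) {
    nn <- tabulate(part)
    k1 <- tabulate(part[labels == 1L], nbins = length(nn))
    posSize <- sum(nn[k1 == 0L | k1 == nn])
    p <- k1 / nn
    mixed <- p > 0 & p < 1
    hCond <- if (any(mixed)) {
      pm <- p[mixed]
      -sum((pm * log2(pm) + (1 - pm) * log2(1 - pm)) * nn[mixed]) / n
    } else 0
    list(posSize = posSize, mi = hD - hCond, hCond = hCond, part = part)
  }
  stats <- function(B) {
    Bs <- sort.int(B)
    key <- paste(Bs, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- statsFromPart(partOf(Bs))
    cache[[key]] <- out
    out
  }
  tstats <- .cppTableStats(colKeys, as.integer(labels))
  list(stats = stats, posC = tstats$posC, miC = hD - tstats$hC, hC = tstats$hC,
       hD = hD, C = tab$C, nAttr = N, colKeys = colKeys,
       labels = as.integer(labels))
}

.gaFitness <- function(codes, ev) {
  .cppFitness(ev$colKeys, ev$labels, as.integer(codes), ev$posC)
}

#' Roulette-wheel selection with optimal preservation
#'
#' Samples `nSelect` individuals with replacement, with probability
#' proportional to fitness (uniform if every fitness is zero). If the best
#' fitness of the previous generation exceeds the worst fitness selected,
#' the previous best individual replaces the worst (ties among previous
#' bests broken uniformly at random).
#'
#' @param population list of chromosomes.
#' @param fitnesses numeric vector aligned with `population`.
#' @param nSelect number of individuals to draw (default the population
#'   size).
#' @param prevBest optional list of the previous generation's best
#'   individual(s).
#' @param prevBestFitness fitness of `prevBest`.
#' @return list of `nSelect` chromosomes.
#' @export
gaSelect <- function(population, fitnesses, nSelect = length(population),
                     prevBest = NULL, prevBestFitness = NULL) {
  stopifnot(length(population) == length(fitnesses))
  total <- sum(fitnesses)
  prob <- if (total > 0) fitnesses / total else NULL
  idx <- sample.int(length(population), nSelect, replace = TRUE, prob = prob)
  out <- population[idx]
  outFit <- fitnesses[idx]
  if (!is.null(prevBest) && length(prevBest) &&
      !is.null(prevBestFitness) && prevBestFitness > min(outFit)) {
    worst <- which.min(outFit)
    pick <- if (length(prevBest) > 1L) sample.int(length(prevBest), 1L) else 1L
    out[[worst]] <- prevBest[[pick]]
  }
  out
}

#' Single-point crossover
#'
#' Cuts both parents after a uniformly chosen site in `1..N-1` and swaps
#' the suffixes. Length-1 parents are returned unchanged.
#'
#' @param a,b equal-length chromosomes.
#' @return list with elements `a` and `b`, the two children.
#' @export
gaCrossover <- function(a, b) {
  stopifnot(length(a) == length(b))
  N <- length(a)
  if (N < 2L) return(list(a = a, b = b))
  k <- sample.int(N - 1L, 1L)
  tailIdx <- (k + 1L):N
  childA <- a; childB <- b
  childA[tailIdx] <- b[tailIdx]
  childB[tailIdx] <- a[tailIdx]
  list(a = childA, b = childB)
}

#' Basic-bit mutation
#'
#' With probability `pm` the chromosome is mutated: one site chosen
#' uniformly is set to a uniformly drawn *different* code in `0..N`.
#'
#' @param codes a chromosome.
#' @param pm mutation probability in `[0, 1]`.
#' @return the (possibly mutated) chromosome.
#' @export
gaMutate <- function(codes, pm) {
  if (stats::runif(1L) >= pm) return(codes)
  N <- length(codes)
  site <- sample.int(N, 1L)
  alt <- setdiff(0:N, codes[site])
  codes[site] <- alt[sample.int(length(alt), 1L)]
  codes
}

#' Entropy-based repair of a chromosome
#'
#' For each decoded template R whose mutual information with the decision
#' falls short of `I(C; D)`, repeatedly joins the attribute of `C \ R`
#' with maximal significance gain `SGF(a, R, D)` to the template (sites get
#' the template's shared code; a chromosome with no template seeds one with
#' code `a = a`), until `I(R; D) = I(C; D)` within tolerance (1e-9 bits).
#' Ties prefer currently unselected attributes, then the smallest index.
#' Templates already at full mutual information are never raided: when only
#' their members remain as candidates, the largest such donor template is
#' absorbed whole, which completes the deficient template immediately (the
#' union's partition refines the donor's) without damaging any finished
#' template. Every template is therefore MI-complete on exit.
#'
#' @inheritParams templateFitness
#' @return the repaired chromosome.
#' @export
gaModify <- function(codes, tab) {
  .gaModify(codes, tab, .rsEvaluator(tab))
}

.gaModify <- function(codes, tab, ev) {
  .cppModify(ev$colKeys, ev$labels, as.integer(codes), ev$hC)
}

#' Run the genetic attribute-reduction search
#'
#' Searches the `(N+1)^N` chromosome space for a set of concept-sample
#' templates maximizing [templateFitness()]. Each generation performs
#' single-point crossover on individuals chosen with probability `pc`,
#' basic-bit mutation over the combined parent/offspring pool, roulette
#' selection over that pool with optimal preservation of the previous
#' generation's best, then entropy-based repair of every individual.
#' Returns the best-ever individual, with templates that fail to preserve
#' the positive region filtered out.
#'
#' @param tab a [decisionTable()].
#' @param params a [gaParams()] list.
#' @return list of class `reduction_result`: `templates` (list of 1-based
#'   attribute vectors), `fitness`, `chromosome`, `log` (per-generation
#'   best/mean fitness), `seed`.
#' @export
runReduction <- function(tab, params = gaParams()) {
  stopifnot(inherits(tab, "decision_table"))
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- length(tab$C)
  if (length(unique(tab$labels)) < 2L) {
    warning("decision labels are constant; no discrimination to encode")
    return(structure(list(templates = list(), fitness = 0,
                          chromosome = rep(0L, N),
                          log = data.frame(gen = integer(), best = numeric(),
                                           mean = numeric()),
                          seed = params$seed),
                     class = "reduction_result"))
  }
  ev <- .rsEvaluator(tab)
  pop <- lapply(seq_len(params$popSize), function(i)
    sample(0:N, N, replace = TRUE))
  pop <- lapply(pop, .gaModify, tab = tab, ev = ev)
  fit <- vapply(pop, .gaFitness, 0, ev = ev)
  bestEver <- pop[[which.max(fit)]]
  bestEverFit <- max(fit)
  log <- data.frame(gen = 0L, best = max(fit), mean = mean(fit))
  for (gen in seq_len(params$maxGen)) {
    chosen <- which(stats::runif(params$popSize) < params$pc)
    if (length(chosen) %% 2L == 1L) chosen <- chosen[-length(chosen)]
    offspring <- list()
    if (length(chosen) >= 2L) {
      chosen <- sample(chosen)
      for (p in seq(1L, length(chosen), by = 2L)) {
        kids <- gaCrossover(pop[[chosen[p]]], pop[[chosen[p + 1L]]])
        offspring <- c(offspring, list(kids$a, kids$b))
      }
    }
    pool <- c(pop, offspring)
    pool <- lapply(pool, gaMutate, pm = params$pm)
    poolFit <- vapply(pool, .gaFitness, 0, ev = ev)
    prevBestIdx <- which(fit == max(fit))
    pop <- gaSelect(pool, poolFit, nSelect = params$popSize,
                    prevBest = pop[prevBestIdx], prevBestFitness = max(fit))
    pop <- lapply(pop, .gaModify, tab = tab, ev = ev)
    fit <- vapply(pop, .gaFitness, 0, ev = ev)
    if (max(fit) > bestEverFit) {
      bestEverFit <- max(fit)
      bestEver <- pop[[which.max(fit)]]
    }
    log <- rbind(log, data.frame(gen = gen, best = bestEverFit, mean = mean(fit)))
  }
  templates <- Filter(function(B) ev$stats(B)$posSize == ev$posC,
                      decodeChromosome(bestEver))
  structure(list(templates = templates, fitness = bestEverFit,
                 chromosome = bestEver, log = log, seed = params$seed),
            class = "reduction_result")
}
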