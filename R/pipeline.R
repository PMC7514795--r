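#' Run the full placement pipeline
#'
#' Executes the four-stage workflow: split the species by completeness,
#' build the concept decision tree on the seed phylogeny, graft the
#' incomplete species, and evaluate the result (parsimony tree length, and
#' path accuracy when a model tree is supplied). Artifacts are written to
#' `config$outDir` when given: `final.nwk`, `placements.json`,
#' `report.json`.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{matrix}{a [CharacterMatrix-class] or a file path.}
#'     \item{dialect}{matrix dialect for file input (optional).}
#'     \item{seedTree}{a `phylo` or Newick file path (required).}
#'     \item{modelTree}{optional accepted `phylo`/path for accuracy.}
#'     \item{threshold}{completeness threshold (default 0.9).}
#'     \item{ga}{list of [gaParams()] arguments.}
#'     \item{seed}{global integer seed.}
#'     \item{outDir}{optional output directory.}
#'   }
#' @return the report list, invisibly when `outDir` is written.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config needs the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$matrix)) stop("config$matrix is required")
  cm <- if (is(config$matrix, "CharacterMatrix")) config$matrix
        else readCharacterMatrix(config$matrix, dialect = config$dialect)
  if (is.null(config$seedTree)) stop("config$seedTree is required")
  seedTr <- if (inherits(config$seedTree, "phylo")) config$seedTree
            else readTreeNewick(file = config$seedTree)
  modelTr <- if (is.null(config$modelTree)) NULL
             else if (inherits(config$modelTree, "phylo")) config$modelTree
             else readTreeNewick(file = config$modelTree)
  threshold <- if (is.null(config$threshold)) 0.9 else config$threshold
  ga <- do.call(gaParams, c(config$ga, if (is.null(config$ga$seed))
    list(seed = config$seed)))

  split <- splitSpecies(cm, threshold)
  extra <- setdiff(seedTr$tip.label, split$sub1)
  if (length(extra))
    stop("seed-tree leaves below the completeness threshold: ",
         paste(extra, collapse = ", "))
  others <- setdiff(speciesIds(cm), seedTr$tip.label)
  sub2 <- others[order(-split$completeness[others])]
  cdt <- buildConceptDecisionTree(seedTr, cm, ga)
  res <- graftAll(cdt, cm, sub2)

  report <- list(
    seed = config$seed, threshold = threshold,
    gaParams = ga[c("popSize", "pc", "pm", "maxGen")],
    sub1 = seedTr$tip.label, sub2 = sub2,
    templatesPerNode = vapply(decisionPoints(cdt),
                              function(dp) length(dp$templates), 0L),
    treeLength = treeLength(finalTree(res), cm),
    stackedNodes = res@stackedNodes)
  if (!is.null(modelTr)) {
    acc <- pathAccuracy(modelTr, finalTree(res), sub2, seedTr$tip.label)
    report$meanAccuracy <- acc$mean
    report$perSpeciesAccuracy <- acc$perSpecies
  }
  out <- list(tree = finalTree(res), placements = placements(res),
              report = report)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeTreeNewick(out$tree, file.path(config$outDir, "final.nwk"))
    jsonlite::write_json(out$placements,
                         file.path(config$outDir, "placements.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
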