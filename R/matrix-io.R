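#' Read a character matrix from NEXUS, TNT or CSV
#'
#' Parses a discrete species-against-attributes matrix. `"?"` (and `"-"` in
#' NEXUS/TNT) denote missing data and become `NA`. Polymorphic codings such
#' as `{01}` or `[01]` are rejected. In CSV and TNT, states of 10 or more
#' are supported (CSV cells are whole tokens; TNT rows may be
#' whitespace-separated); NEXUS matrices are limited to single-symbol
#' states.
#'
#' @param path file path.
#' @param dialect one of `"csv"`, `"nexus"`, `"tnt"`; default guesses from
#'   the file extension (`.nex`/`.nexus`, `.tnt`, else CSV).
#' @param header for CSV only: does the first row hold column names? Default
#'   auto-detects (a first row whose non-leading cells are not all
#'   states/`?` is taken as a header).
#' @return a [CharacterMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("X,1,0,?", "Y,0,0,1"), f)
#' readCharacterMatrix(f)
#' @export
readCharacterMatrix <- function(path, dialect = NULL, header = NA) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("nex", "nexus", "nxs")) "nexus"
               else if (ext == "tnt") "tnt" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "nexus", "tnt"))
  switch(dialect,
         csv   = .readCsvMatrix(path, header),
         nexus = .readNexusMatrix(path),
         tnt   = .readTntMatrix(path))
}

.parseStateToken <- function(tok, where) {
  tok <- trimws(tok)
  if (tok %in% c("?", "-")) return(NA_integer_)
  if (grepl("^[{\\[]", tok))
    stop("polymorphic codings like '{01}' are not supported (", where, ")")
  v <- suppressWarnings(as.integer(tok))
  if (is.na(v) || v < 0L)
    stop("cannot parse state '", tok, "' (", where, ")")
  v
}

.readCsvMatrix <- function(path, header = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV matrix: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  looksLikeState <- function(x) grepl("^\\s*([0-9]+|\\?|-)\\s*$", x)
  if (is.na(header))
    header <- !all(looksLikeState(cells[[1L]][-1L]))
  if (header) { cells <- cells[-1L]; lines <- lines[-1L] }
  if (!length(cells)) stop("CSV matrix has a header but no data rows: ", path)
  n <- length(cells[[1L]]) - 1L
  if (n < 1L) stop("CSV rows need a species id plus at least one state (line 1)")
  ids <- vapply(cells, function(r) trimws(r[[1L]]), "")
  if (anyDuplicated(ids)) stop("duplicate species '", ids[duplicated(ids)][1L], "' in ", path)
  states <- matrix(NA_integer_, length(cells), n, dimnames = list(ids, NULL))
  for (i in seq_along(cells)) {
    r <- cells[[i]]
    if (length(r) - 1L != n)
      stop(sprintf("line %d of %s has %d states, expected %d",
                   i + as.integer(header), path, length(r) - 1L, n))
    states[i, ] <- vapply(r[-1L], .parseStateToken, 0L,
                          where = sprintf("line %d", i + as.integer(header)))
  }
  characterMatrix(states)
}

.readNexusMatrix <- function(path) {
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) stop("NEXUS parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ids <- names(dat)
  if (anyDuplicated(ids)) stop("duplicate species '", ids[duplicated(ids)][1L], "' in ", path)
  n <- length(dat[[1L]])
  states <- matrix(NA_integer_, length(dat), n, dimnames = list(ids, NULL))
  for (i in seq_along(dat)) {
    row <- dat[[i]]
    if (length(row) != n)
      stop("species '", ids[i], "' has ", length(row), " states, expected ", n)
    states[i, ] <- vapply(row, function(s) {
      if (length(s) > 1L)
        stop("polymorphic codings like '{01}' are not supported (species ", ids[i], ")")
      .parseStateToken(s, paste0("species ", ids[i]))
    }, 0L)
  }
  characterMatrix(states)
}

# TNT xread: "xread [comment] nchar ntax  name states name states ... ;"
.readTntMatrix <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("'[^']*'", "", txt)  # quoted comments
  m <- regmatches(txt, regexpr("xread.*?;", txt, ignore.case = TRUE))
  if (!length(m)) stop("no xread block found in ", path)
  body <- sub(";$", "", sub("^xread", "", m, ignore.case = TRUE))
  toks <- strsplit(trimws(body), "\\s+")[[1L]]
  if (length(toks) < 2L) stop("malformed xread header in ", path)
  nchar_ <- suppressWarnings(as.integer(toks[1L]))
  ntax <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(nchar_) || is.na(ntax)) stop("malformed xread dimensions in ", path)
  toks <- toks[-(1:2)]
  ids <- character(ntax)
  states <- matrix(NA_integer_, ntax, nchar_)
  pos <- 1L
  for (i in seq_len(ntax)) {
    if (pos > length(toks)) stop("xread block in ", path, " ended early (species ", i, ")")
    ids[i] <- toks[pos]; pos <- pos + 1L
    row <- character(0)
    while (length(row) < nchar_ && pos <= length(toks)) {
      tok <- toks[pos]; pos <- pos + 1L
      row <- c(row, if (grepl(",", tok, fixed = TRUE))
                      strsplit(tok, ",", fixed = TRUE)[[1L]]
                    else strsplit(tok, "")[[1L]])
    }
    if (length(row) != nchar_)
      stop("species '", ids[i], "' in ", path, " has ", length(row),
           " states, expected ", nchar_)
    states[i, ] <- vapply(row, .parseStateToken, 0L, where = paste0("species ", ids[i]))
  }
  if (anyDuplicated(ids)) stop("duplicate species '", ids[duplicated(ids)][1L], "' in ", path)
  rownames(states) <- ids
  characterMatrix(states)
}

#' Write a character matrix
#'
#' Writes `cm` in one of the supported dialects so that
#' `readCharacterMatrix(writeCharacterMatrix(...))` round-trips. Missing
#' values are written as `"?"`. NEXUS output requires all states < 10
#' (single symbols); CSV and TNT support multi-digit states.
#'
#' @param cm a [CharacterMatrix-class].
#' @param path output file path.
#' @param dialect `"csv"`, `"nexus"` or `"tnt"`.
#' @return `path`, invisibly.
#' @export
writeCharacterMatrix <- function(cm, path, dialect = c("csv", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  m <- stateMatrix(cm)
  tok <- matrix(as.character(m), nrow(m), ncol(m))
  tok[is.na(tok)] <- "?"
  ids <- speciesIds(cm)
  lines <- switch(dialect,
    csv = vapply(seq_len(nrow(m)), function(i)
      paste(c(ids[i], tok[i, ]), collapse = ","), ""),
    nexus = {
      if (any(m[!is.na(m)] > 9L))
        stop("NEXUS output supports single-symbol states (< 10) only")
      syms <- sort(unique(as.vector(m[!is.na(m)])))
      c("#NEXUS", "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
        sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=?;", paste(syms, collapse = "")),
        "  MATRIX",
        vapply(seq_len(nrow(m)), function(i)
          paste0("    ", ids[i], "  ", paste(tok[i, ], collapse = "")), ""),
        "  ;", "END;")
    },
    tnt = c(sprintf("xread %d %d", ncol(m), nrow(m)),
            vapply(seq_len(nrow(m)), function(i)
              paste0(ids[i], " ", paste(tok[i, ], collapse = ",")), ""),
            ";"))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a rooted seed tree in Newick format
#'
#' Thin validating wrappers around [ape::read.tree()] / [ape::write.tree()].
#' The tree is interpreted as rooted; leaf labels must be unique. Reading
#' the output of [writeTreeNewick()] reproduces the topology and labels.
#'
#' @param text a Newick string, or a file path via `file`.
#' @param file optional path to read from / write to.
#' @return `readTreeNewick`: a `phylo`; `writeTreeNewick`: the Newick string
#'   (invisibly, if `file` is given).
#' @examples
#' tr <- readTreeNewick("((X,Y),Z);")
#' writeTreeNewick(tr)
#' @export
readTreeNewick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    tryCatch(ape::read.tree(file), error = function(e)
      stop("Newick parse error in ", file, ": ", conditionMessage(e)))
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e)
      stop("Newick parse error: ", conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse error: unbalanced parentheses or empty input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' @rdname readTreeNewick
#' @param tree a `phylo` object.
#' @export
writeTreeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

#' Per-species completeness
#'
#' Fraction of non-missing entries in each species' attribute row; values
#' lie in `[0, 1]` and are unaffected by attribute order.
#'
#' @param cm a [CharacterMatrix-class].
#' @return named numeric vector over species.
#' @export
completeness <- function(cm) {
  m <- stateMatrix(cm)
  setNames(rowMeans(!is.na(m)), rownames(m))
}

#' Split species into seed (sub1) and graft (sub2) sets
#'
#' Species at or above the completeness threshold form `sub1` (used to build
#' the seed tree); the rest form `sub2`, sorted by decreasing completeness so
#' that grafting starts with the most reliable species. Ties keep matrix
#' order.
#'
#' @param cm a [CharacterMatrix-class].
#' @param threshold completeness fraction in `[0, 1]`; default 0.9.
#' @return list with `sub1`, `sub2` (character vectors) and the
#'   `completeness` vector.
#' @export
splitSpecies <- function(cm, threshold = 0.9) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  comp <- completeness(cm)
  sub1 <- names(comp)[comp >= threshold]
  if (length(sub1) < 3L)
    stop("only ", length(sub1), " species reach completeness ", threshold,
         "; at least 3 are needed to form a seed tree")
  rest <- comp[setdiff(names(comp), sub1)]
  sub2 <- names(rest)[order(-rest)]
  list(sub1 = sub1, sub2 = sub2, completeness = comp)
}
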