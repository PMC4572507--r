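## Ontology parsing, DAG operations and information content.

#' Construct an Ontology from component vectors
#'
#' Low-level constructor used by [parseOBO()] and [syntheticOntology()].
#' Verifies acyclicity (naming one offending edge on failure), resolves the
#' root (the unique parentless term) and derives children, depths and the
#' undirected is-a graph used for path lengths.
#'
#' @param ids character term identifiers.
#' @param labels named character labels (names = `ids`).
#' @param synonyms named list of character synonym vectors.
#' @param parents named list of character is-a parent vectors.
#' @param abnormalityRoot identifier of the category subroot, or `NULL` to
#'   use a term labelled "phenotypic abnormality" when present, else the root.
#' @return An [Ontology-class] object.
#' @export
makeOntology <- function(ids, labels, synonyms, parents, abnormalityRoot = NULL) {
  if (!length(ids)) stop("ontology has no terms")
  ids <- as.character(ids)
  labels <- setNames(as.character(labels[ids]), ids)
  synonyms <- setNames(lapply(ids, function(i) as.character(synonyms[[i]])), ids)
  parents <- setNames(lapply(ids, function(i) unique(as.character(parents[[i]]))), ids)

  missingTarget <- unlist(lapply(ids, function(i) setdiff(parents[[i]], ids)),
                          use.names = FALSE)
  if (length(missingTarget))
    stop("is_a target not defined in ontology: ",
         paste(unique(missingTarget), collapse = ", "))

  edges <- do.call(rbind, lapply(ids, function(i) {
    p <- parents[[i]]
    if (length(p)) cbind(child = rep(i, length(p)), parent = p) else NULL
  }))

  gdir <- igraph::make_empty_graph(n = 0, directed = TRUE)
  gdir <- igraph::add_vertices(gdir, length(ids), name = ids)
  if (!is.null(edges))
    gdir <- igraph::add_edges(gdir, rbind(edges[, "parent"], edges[, "child"]))
  if (!igraph::is_dag(gdir)) {
    cyc <- igraph::feedback_arc_set(gdir)
    ends <- igraph::ends(gdir, cyc[1])
    stop(sprintf("cycle detected in is-a hierarchy (involving edge %s -> %s)",
                 ends[2], ends[1]))
  }

  roots <- ids[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  root <- roots

  children <- setNames(vector("list", length(ids)), ids)
  for (i in ids) children[[i]] <- character()
  if (!is.null(edges))
    for (k in seq_len(nrow(edges)))
      children[[edges[k, "parent"]]] <-
        c(children[[edges[k, "parent"]]], edges[k, "child"])

  ## longest root-to-term path, over a topological order
  ord <- igraph::V(gdir)$name[as.integer(igraph::topo_sort(gdir, mode = "out"))]
  depth <- setNames(rep(0L, length(ids)), ids)
  for (t in ord) {
    p <- parents[[t]]
    if (length(p)) depth[[t]] <- max(depth[p]) + 1L
  }

  if (is.null(abnormalityRoot)) {
    hit <- ids[tolower(labels) == "phenotypic abnormality"]
    abnormalityRoot <- if (length(hit) == 1L) hit else root
  }
  if (!(abnormalityRoot %in% ids))
    stop("abnormalityRoot not found in ontology: ", abnormalityRoot)

  gund <- igraph::as_undirected(gdir, mode = "collapse")
  new("Ontology", terms = ids, labels = labels, synonyms = synonyms,
      parents = parents, children = children, depth = depth,
      root = root, abnormalityRoot = abnormalityRoot, graph = gund)
}

#' Parse an OBO ontology
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file: `id`, `name`,
#' `synonym` (all scopes retained) and `is_a` lines. Obsolete terms are
#' dropped. Only is-a relationships are loaded; other relationship types are
#' ignored. Acyclicity and referential integrity are verified.
#'
#' @param source path to an OBO file, or a character vector of OBO lines.
#' @param abnormalityRoot see [makeOntology()].
#' @return An [Ontology-class].
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: large head", "is_a: T:1")
#' ont <- parseOBO(obo)
#' @export
parseOBO <- function(source, abnormalityRoot = NULL) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- trimws(lines)

  ids <- character(); labels <- character()
  synonyms <- list(); parents <- list()
  cur <- NULL; inTerm <- FALSE

  obsolete <- character()
  flush <- function() {
    if (is.null(cur) || !nzchar(cur$id)) return()
    if (cur$obsolete) { obsolete <<- c(obsolete, cur$id); return() }
    if (!nzchar(cur$name)) stop("term without a name: ", cur$id)
    ids <<- c(ids, cur$id)
    labels[[cur$id]] <<- cur$name
    synonyms[[cur$id]] <<- cur$synonyms
    parents[[cur$id]] <<- cur$isa
  }
  newTerm <- function() list(id = "", name = "", synonyms = character(),
                             isa = character(), obsolete = FALSE)

  for (ln in lines) {
    if (ln == "[Term]") { flush(); cur <- newTerm(); inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      tgt <- strsplit(tgt, "[[:space:]]+")[[1]][1]
      cur$isa <- c(cur$isa, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      if (grepl("true", ln)) cur$obsolete <- TRUE
    }
  }
  flush()

  if (!length(ids)) stop("no [Term] stanzas found")
  ## is_a links to obsolete (dropped) terms are pruned like the terms
  ## themselves; links to terms never defined remain and trip the
  ## referential-integrity check in makeOntology()
  parents <- lapply(parents, function(p) p[!(p %in% obsolete)])
  makeOntology(ids, labels, synonyms, parents, abnormalityRoot)
}

checkTerm <- function(ontology, t) {
  bad <- setdiff(t, ontology@terms)
  if (length(bad))
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(t)
}

#' Term accessors
#'
#' @param ontology an [Ontology-class].
#' @return `ontologyTerms`: all term ids; `termLabel`: named labels;
#'   `termSynonyms`: synonym list; `topLevelTerms`: the children of the
#'   abnormality subroot (the top-level phenotype categories).
#' @export
ontologyTerms <- function(ontology) ontology@terms

#' @rdname ontologyTerms
#' @param t term id(s).
#' @export
termLabel <- function(ontology, t = ontology@terms) {
  checkTerm(ontology, t); ontology@labels[t]
}

#' @rdname ontologyTerms
#' @export
termSynonyms <- function(ontology, t = ontology@terms) {
  checkTerm(ontology, t); ontology@synonyms[t]
}

#' @rdname ontologyTerms
#' @export
topLevelTerms <- function(ontology) {
  sort(ontology@children[[ontology@abnormalityRoot]])
}

#' @rdname ontologyTerms
#' @export
ontologyRoot <- function(ontology) ontology@root

#' @rdname ontologyTerms
#' @export
abnormalityRoot <- function(ontology) ontology@abnormalityRoot

#' Transitive ancestors or descendants of a term
#'
#' Transitive closure over is-a edges. `reflexive = TRUE` includes the term
#' itself.
#'
#' @param ontology an [Ontology-class].
#' @param t a term id.
#' @param reflexive include `t` itself?
#' @return character vector of term ids (unordered).
#' @export
termAncestors <- function(ontology, t, reflexive = FALSE) {
  checkTerm(ontology, t)
  out <- character(); frontier <- t
  seen <- c(t)
  while (length(frontier)) {
    nxt <- unique(unlist(ontology@parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    out <- c(out, nxt); seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (reflexive) c(t, out) else out
}

#' @rdname termAncestors
#' @export
termDescendants <- function(ontology, t, reflexive = FALSE) {
  checkTerm(ontology, t)
  out <- character(); frontier <- t
  seen <- c(t)
  while (length(frontier)) {
    nxt <- unique(unlist(ontology@children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    out <- c(out, nxt); seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (reflexive) c(t, out) else out
}

## Reflexive ancestor incidence matrix (terms x terms), computed once per
## call in topological order; backbone of MICA and subsumption matching.
ancestorMatrix <- function(ontology) {
  ids <- ontology@terms
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  ord <- ids[order(ontology@depth[ids])]
  for (t in ord) {
    A[t, t] <- TRUE
    for (p in ontology@parents[[t]]) A[t, ] <- A[t, ] | A[p, ]
  }
  A
}

#' Group terms by their top-level category ancestors
#'
#' Assigns each term to every top-level category (child of the abnormality
#' subroot) among its reflexive ancestors, mirroring the grouping of
#' clustering seeds by their common top-level ancestor. A term with several
#' top-level ancestors appears in every such group; downstream candidates
#' are deduplicated.
#'
#' @param ontology an [Ontology-class].
#' @param terms character term ids, all descendants of the abnormality
#'   subroot (or top-level terms themselves).
#' @return named list: top-level term id -> character vector of input terms.
#'   Empty input gives an empty list.
#' @export
topLevelGroups <- function(ontology, terms) {
  terms <- unique(as.character(terms))
  if (!length(terms)) return(setNames(list(), character()))
  checkTerm(ontology, terms)
  tl <- ontology@children[[ontology@abnormalityRoot]]
  groups <- setNames(vector("list", length(tl)), tl)
  for (t in terms) {
    anc <- termAncestors(ontology, t, reflexive = TRUE)
    hit <- intersect(tl, anc)
    if (!length(hit))
      stop("term outside the abnormality subtree: ", t, call. = FALSE)
    for (g in hit) groups[[g]] <- c(groups[[g]], t)
  }
  groups[lengths(groups) > 0L]
}

#' Shortest path length between two terms
#'
#' Number of is-a edges connecting two terms when edges are treated as
#' undirected; 0 iff the terms coincide.
#'
#' @param ontology an [Ontology-class].
#' @param t1,t2 term ids.
#' @return non-negative integer.
#' @export
termDistance <- function(ontology, t1, t2) {
  checkTerm(ontology, c(t1, t2))
  if (t1 == t2) return(0L)
  as.integer(igraph::distances(ontology@graph, v = t1, to = t2)[1, 1])
}

#' Pairwise shortest-path matrix over a term set
#'
#' @param ontology an [Ontology-class].
#' @param terms character term ids.
#' @return integer matrix of pairwise is-a path lengths.
#' @export
termDistanceMatrix <- function(ontology, terms) {
  terms <- as.character(terms)
  checkTerm(ontology, terms)
  d <- igraph::distances(ontology@graph, v = terms, to = terms)
  storage.mode(d) <- "integer"
  d
}

#' Corpus-driven term frequencies and information content
#'
#' Computes p(t) = (number of items annotated with t or any of its
#' descendants) / nItems, each item counted at most once per term, and
#' IC(t) = -log p(t). An item annotated with a term is implicitly annotated
#' with all of that term's ancestors, so p is monotonically non-decreasing
#' towards the root. Terms with p = 0 get an `Inf` IC sentinel and are never
#' MICA winners.
#'
#' @param ontology an [Ontology-class].
#' @param annotations list of character term vectors, one per annotated item
#'   (e.g. per abstract, or per disease for the disease-level annotation
#'   frequency used in semantic similarity).
#' @param nItems total number of items (>= number of annotated items;
#'   defaults to `length(annotations)`).
#' @param base logarithm base; default natural.
#' @return An [ICTable-class].
#' @examples
#' # seven items on a term and three on its descendants out of 1,000 give
#' # p = 10/1000 = 0.01 and IC = -ln(0.01)
#' @export
termFrequencies <- function(ontology, annotations, nItems = length(annotations),
                            base = exp(1)) {
  nItems <- as.integer(nItems)
  if (is.na(nItems) || nItems < 1L) stop("nItems must be >= 1")
  ids <- ontology@terms
  counts <- setNames(rep(0L, length(ids)), ids)
  for (terms in annotations) {
    terms <- unique(as.character(terms))
    if (!length(terms)) next
    checkTerm(ontology, terms)
    closure <- unique(unlist(
      lapply(terms, termAncestors, ontology = ontology, reflexive = TRUE),
      use.names = FALSE))
    counts[closure] <- counts[closure] + 1L
  }
  p <- counts / nItems
  ic <- ifelse(p > 0, -log(p) / log(base), Inf)
  ic[p > 0 & ic < 0] <- 0  # guard against -0
  new("ICTable", frequency = p, ic = setNames(as.numeric(ic), ids),
      nItems = nItems, base = base)
}

#' @rdname termFrequencies
#' @param x an [ICTable-class].
#' @export
icValues <- function(x) x@ic

#' @rdname termFrequencies
#' @export
icFrequencies <- function(x) x@frequency

#' Most informative common ancestor (MICA)
#'
#' The common (reflexive) ancestor of two terms maximizing information
#' content. Ties are broken deterministically: greatest depth (longest
#' distance from the root), then lexicographically smallest id. Terms with
#' undefined IC (p = 0) cannot win.
#'
#' @param ontology an [Ontology-class].
#' @param ic an [ICTable-class] on the same ontology.
#' @param t1,t2 term ids.
#' @return the MICA term id (`micaTerm`) or its IC value (`micaIC`).
#' @export
micaTerm <- function(ontology, ic, t1, t2) {
  checkTerm(ontology, c(t1, t2))
  common <- intersect(termAncestors(ontology, t1, reflexive = TRUE),
                      termAncestors(ontology, t2, reflexive = TRUE))
  vals <- ic@ic[common]
  finite <- is.finite(vals)
  if (!any(finite))
    stop("no common ancestor with defined IC for ", t1, " and ", t2)
  common <- common[finite]; vals <- vals[finite]
  best <- common[vals == max(vals)]
  if (length(best) > 1L) {
    d <- ontology@depth[best]
    best <- best[d == max(d)]
    best <- sort(best)[1]
  }
  best
}

#' @rdname micaTerm
#' @export
micaIC <- function(ontology, ic, t1, t2) {
  unname(ic@ic[micaTerm(ontology, ic, t1, t2)])
}

#' Write / read an IC table as a 3-column TSV
#'
#' Columns: term_id, frequency, ic (`Inf` serialized literally). Item count
#' and log base travel as `#` header comments so the table round-trips.
#'
#' @param x an [ICTable-class].
#' @param path output file.
#' @export
writeICTable <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("#nitems\t%d", x@nItems),
               sprintf("#base\t%.17g", x@base),
               "term_id\tfrequency\tic"), con)
  writeLines(sprintf("%s\t%.17g\t%.17g", names(x@frequency),
                     x@frequency, x@ic), con)
  invisible(path)
}

#' @rdname writeICTable
#' @export
readICTable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  nItems <- as.integer(sub("^#nitems\t", "", hdr[startsWith(hdr, "#nitems")]))
  base <- as.numeric(sub("^#base\t", "", hdr[startsWith(hdr, "#base")]))
  body <- lines[!startsWith(lines, "#")][-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  new("ICTable",
      frequency = setNames(as.numeric(vapply(parts, `[[`, "", 2L)), ids),
      ic = setNames(as.numeric(vapply(parts, `[[`, "", 3L)), ids),
      nItems = nItems, base = base)
}
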