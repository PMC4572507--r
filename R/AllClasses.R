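#' @import methods
#' @importFrom stats setNames rpois runif quantile ks.test
#' @importFrom utils head combn read.delim write.table
NULL

setOldClass("igraph")

#' Ontology of phenotype terms
#'
#' An is-a DAG of ontology terms with labels and synonyms. Built by
#' [parseOBO()] or [syntheticOntology()]. The `abnormalityRoot` is the subroot
#' whose direct children act as the top-level phenotype categories used for
#' grouping (for the HPO this is "Phenotypic abnormality"; it defaults to the
#' ontology root when no such term can be identified).
#'
#' @slot terms character vector of term identifiers.
#' @slot labels named character, primary label per term.
#' @slot synonyms named list of character vectors (synonyms of all scopes).
#' @slot parents named list of character vectors of is-a parents.
#' @slot children named list, inverse of `parents`.
#' @slot depth named integer, length of the longest root-to-term path.
#' @slot root identifier of the unique parentless term.
#' @slot abnormalityRoot identifier of the category subroot.
#' @slot graph undirected `igraph` over is-a edges (used for path lengths).
#'
#' @seealso [termAncestors()], [topLevelGroups()], [termDistance()]
#' @export
setClass("Ontology",
  representation(
    terms = "character",
    labels = "character",
    synonyms = "list",
    parents = "list",
    children = "list",
    depth = "integer",
    root = "character",
    abnormalityRoot = "character",
    graph = "igraph"
  )
)

setValidity("Ontology", function(object) {
  msg <- character()
  ids <- object@terms
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated term identifiers")
  if (!all(nzchar(ids))) msg <- c(msg, "empty term identifier")
  if (length(ids)) {
    if (!(object@root %in% ids)) msg <- c(msg, "root is not a term")
    if (!(object@abnormalityRoot %in% ids))
      msg <- c(msg, "abnormalityRoot is not a term")
    badParent <- !unlist(lapply(object@parents, function(p) all(p %in% ids)),
                         use.names = FALSE)
    if (any(badParent))
      msg <- c(msg, paste0("is-a target missing for: ",
                           paste(head(ids[badParent], 3L), collapse = ", ")))
    if (any(!nzchar(object@labels))) msg <- c(msg, "empty term label")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", length(object@terms), "terms\n")
  cat("  root:", object@root,
      sprintf("(%s)\n", object@labels[[object@root]]))
  cat("  abnormality subroot:", object@abnormalityRoot,
      sprintf("(%s)\n", object@labels[[object@abnormalityRoot]]))
  cat("  top-level categories:",
      length(object@children[[object@abnormalityRoot]]), "\n")
})

#' Term frequencies and information content
#'
#' Per-term annotation frequencies p(t) and information content
#' IC(t) = -log p(t), computed with subsumption propagation (an item
#' annotated with t counts towards every ancestor of t). Terms never
#' annotated have p = 0 and carry an `Inf` IC sentinel; they are excluded
#' from MICA maximization and TFIDFIC.
#'
#' @slot frequency named numeric in [0,1].
#' @slot ic named numeric, `-log(frequency)` in the configured base.
#' @slot nItems number of annotated items the table was computed from.
#' @slot base logarithm base (default natural).
#'
#' @seealso [termFrequencies()], [micaTerm()]
#' @export
setClass("ICTable",
  representation(frequency = "numeric", ic = "numeric",
                 nItems = "integer", base = "numeric")
)

setValidity("ICTable", function(object) {
  msg <- character()
  if (length(object@frequency) != length(object@ic))
    msg <- c(msg, "frequency and ic length mismatch")
  f <- object@frequency
  if (any(f < 0 | f > 1)) msg <- c(msg, "frequencies outside [0,1]")
  if (any(object@ic < 0, na.rm = TRUE)) msg <- c(msg, "negative IC")
  if (object@nItems < 1L) msg <- c(msg, "nItems must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ICTable", function(object) {
  ann <- sum(object@frequency > 0)
  cat("ICTable over", length(object@frequency), "terms (",
      ann, "annotated ) from", object@nItems, "items; log base",
      format(object@base, digits = 4), "\n")
})

#' Normalized-phrase lexicon for concept recognition
#'
#' Maps normalized label/synonym phrases to the sets of terms they name.
#' Ambiguous phrases (one phrase, several terms) are retained as sets.
#'
#' @slot entries named list: normalized phrase -> character vector of terms.
#' @slot maxTokens longest indexed phrase, in tokens; bounds the scan window.
#'
#' @seealso [buildLexicalIndex()], [recognizeText()]
#' @export
setClass("LexicalIndex",
  representation(entries = "list", maxTokens = "integer")
)

setMethod("show", "LexicalIndex", function(object) {
  cat("LexicalIndex:", length(object@entries), "phrases, window",
      object@maxTokens, "tokens\n")
})

#' Disease-tagged abstract corpus
#'
#' Maps each whitelisted disease descriptor to the abstracts tagged with it,
#' and (after [attachMentions()]) each abstract to the set of ontology terms
#' recognized in it. An abstract tagged with several whitelisted diseases
#' belongs to each of them.
#'
#' @slot diseaseAbstracts named list: disease id -> character abstract ids.
#' @slot mentions named list: abstract id -> character term ids (deduplicated;
#'   abstract-level presence, not mention counts).
#' @slot nDiseases number of diseases retained (the corpus-wide T_D used by
#'   the IDF denominator's numerator).
#'
#' @seealso [filterByMesh()], [computeTermStats()]
#' @export
setClass("DiseaseCorpus",
  representation(diseaseAbstracts = "list", mentions = "list",
                 nDiseases = "integer")
)

setValidity("DiseaseCorpus", function(object) {
  msg <- character()
  if (length(object@diseaseAbstracts) != object@nDiseases)
    msg <- c(msg, "nDiseases does not match the disease map")
  if (any(lengths(object@diseaseAbstracts) == 0L))
    msg <- c(msg, "disease with no abstracts")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiseaseCorpus", function(object) {
  nab <- length(unique(unlist(object@diseaseAbstracts, use.names = FALSE)))
  cat("DiseaseCorpus:", object@nDiseases, "diseases,", nab, "abstracts,",
      length(object@mentions), "abstracts with mentions\n")
})

#' Filtering parameters
#'
#' The three tuning parameters of the annotation filter: `n`, the TFIDF
#' threshold creating the clustering seeds; `m`, the TFIDFIC threshold
#' pruning the leftover terms; and `e`, the density margin governing
#' incremental extension of the minimum-density seed subset.
#'
#' @slot n TFIDF seed threshold (>= 0).
#' @slot m TFIDFIC pruning threshold (>= 0).
#' @slot e density margin (>= 0).
#' @export
setClass("FilterParams",
  representation(n = "numeric", m = "numeric", e = "numeric")
)

setValidity("FilterParams", function(object) {
  if (length(object@n) != 1L || length(object@m) != 1L ||
      length(object@e) != 1L) return("n, m, e must be scalars")
  if (object@n < 0 || object@m < 0 || object@e < 0)
    return("n, m, e must be non-negative")
  TRUE
})

setMethod("show", "FilterParams", function(object) {
  cat(sprintf("FilterParams(n = %g, m = %g, e = %g)\n",
              object@n, object@m, object@e))
})

#' Phenotypic disease network
#'
#' Weighted undirected graph over diseases; an edge joins two diseases whose
#' symmetric semantic similarity strictly exceeds the `simcut` threshold.
#' Isolated diseases are excluded. Each node carries one or more disease
#' category labels; an edge whose endpoints share no category is "gray".
#'
#' @slot nodes character disease ids (all with degree >= 1).
#' @slot categories named list: disease id -> character category labels.
#' @slot edges data.frame with columns `a`, `b`, `weight` (weight may be NA
#'   on randomized networks, where weights are meaningless).
#' @slot simcut similarity cutoff the network was built with.
#'
#' @seealso [buildCDN()], [grayEdgeFraction()], [gefSignificance()]
#' @export
setClass("CDN",
  representation(nodes = "character", categories = "list",
                 edges = "data.frame", simcut = "numeric")
)

setValidity("CDN", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("a", "b", "weight") %in% names(e)))
    return("edges must have columns a, b, weight")
  if (nrow(e)) {
    if (any(e$a == e$b)) msg <- c(msg, "self-loop edge")
    if (!all(c(e$a, e$b) %in% object@nodes))
      msg <- c(msg, "edge endpoint not among nodes")
    w <- e$weight
    if (any(!is.na(w) & w <= object@simcut))
      msg <- c(msg, "edge weight not exceeding simcut")
    key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicated edge")
    deg <- table(c(e$a, e$b))
    if (!all(object@nodes %in% names(deg)))
      msg <- c(msg, "isolated node retained")
  } else if (length(object@nodes)) {
    msg <- c(msg, "isolated node retained")
  }
  if (!all(object@nodes %in% names(object@categories)))
    msg <- c(msg, "node without category labels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CDN", function(object) {
  cat("CDN:", length(object@nodes), "diseases,", nrow(object@edges),
      "edges (simcut", format(object@simcut), ")\n")
})

#' Gray-edge-fraction significance report
#'
#' Result of a randomization test on the gray-edge fraction of a disease
#' network: the observed GEF, the null GEF distribution over replicates, an
#' add-one empirical p-value, and (when no null value reached the observed
#' GEF) the conventional strict bound "p < 1/replicates".
#'
#' @slot observed observed gray-edge fraction.
#' @slot grayEdges,totalEdges observed gray and total edge counts.
#' @slot nulls numeric null GEF values, one per replicate.
#' @slot pValue add-one empirical p-value, (1 + #\{null <= observed\}) / (1 + R).
#' @slot bound strict bound string (e.g. "p < 0.001") or NA.
#' @slot method "er" (edge randomization) or "ar" (annotation randomization).
#' @slot seed seed used for the replicates.
#' @export
setClass("GEFReport",
  representation(observed = "numeric", grayEdges = "integer",
                 totalEdges = "integer", nulls = "numeric",
                 pValue = "numeric", bound = "character",
                 method = "character", seed = "integer")
)

setMethod("show", "GEFReport", function(object) {
  cat(sprintf("GEF %.4f (%d gray / %d edges); %s null over %d replicates\n",
              object@observed, object@grayEdges, object@totalEdges,
              object@method, length(object@nulls)))
  cat(sprintf("  empirical p = %.6g%s\n", object@pValue,
              if (!is.na(object@bound)) paste0(" (", object@bound, ")") else ""))
})
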