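## Subsumption-extended Jaccard overlap and MICA-based symmetric semantic
## similarity between annotation sets.

## TRUE iff a and b are identical or related by subsumption (any distance)
subsumptionRelated <- function(ontology, a, b) {
  a == b || a %in% termAncestors(ontology, b) || b %in% termAncestors(ontology, a)
}

## size of a maximum bipartite matching between A and B where a pair is
## matchable iff identical or subsumption-related; each term used once
subsumptionMatchSize <- function(ontology, A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (!length(A) || !length(B)) return(0L)
  rel <- outer(A, B, Vectorize(function(a, b) subsumptionRelated(ontology, a, b)))
  if (!any(rel)) return(0L)
  idx <- which(rel, arr.ind = TRUE)
  va <- paste0("A#", A); vb <- paste0("B#", B)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(va) + length(vb),
                            name = c(va, vb),
                            type = c(rep(FALSE, length(va)),
                                     rep(TRUE, length(vb))))
  g <- igraph::add_edges(g, rbind(va[idx[, 1]], vb[idx[, 2]]))
  as.integer(igraph::max_bipartite_match(g)$matching_size)
}

#' Subsumption-extended Jaccard index
#'
#' Jaccard overlap of two annotation sets where a term of one set matches a
#' term of the other not only on identity but also when one is an ancestor
#' of the other (e.g. "cranial hyperostosis" matches its child "calvarial
#' hyperostosis"). Matched pairs form a maximum bipartite matching M, each
#' term consumable once, and J = |M| / (|A| + |B| - |M|), which reduces to
#' the classic Jaccard when only exact matches exist and stays within
#' [0, 1]. Two empty sets give 0 by convention.
#'
#' @param ontology an [Ontology-class].
#' @param A,B character term vectors (deduplicated internally).
#' @return real in [0, 1].
#' @export
extendedJaccard <- function(ontology, A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (!length(A) && !length(B)) return(0)
  m <- subsumptionMatchSize(ontology, A, B)
  m / (length(A) + length(B) - m)
}

#' Pairwise MICA information-content matrix
#'
#' IC of the most informative common ancestor for every pair of the given
#' terms, the kernel of the semantic similarity scores. Computed once and
#' reusable across many set comparisons (annotation-randomization
#' replicates in particular). Pairs whose only common ancestors have
#' undefined IC get 0.
#'
#' @param ontology an [Ontology-class].
#' @param ic an [ICTable-class].
#' @param terms term ids (default: every ontology term).
#' @return symmetric numeric matrix with `terms` dimnames.
#' @export
micaICMatrix <- function(ontology, ic, terms = ontologyTerms(ontology)) {
  terms <- unique(as.character(terms))
  checkTerm(ontology, terms)
  A <- ancestorMatrix(ontology)[terms, , drop = FALSE]
  w <- ic@ic[colnames(A)]
  usable <- which(is.finite(w) & colSums(A) > 0)
  M <- matrix(NA_real_, length(terms), length(terms),
              dimnames = list(terms, terms))
  ## fill from the most informative ancestor downward: the first ancestor
  ## shared by a pair is its MICA
  for (k in usable[order(-w[usable])]) {
    rows <- which(A[, k])
    if (!length(rows)) next
    sub <- M[rows, rows, drop = FALSE]
    if (!anyNA(sub)) next
    sub[is.na(sub)] <- w[k]
    M[rows, rows] <- sub
  }
  M[is.na(M)] <- 0
  M
}

#' Directed and symmetric semantic similarity between annotation sets
#'
#' `simDirected` scores D1 against D2 as the average, over the terms s of
#' D1, of the best match max over t in D2 of IC(MICA(s, t)); it is
#' asymmetric. `simSymmetric` is the arithmetic mean of the two directions.
#' An empty D2 scores 0; `simSymmetric` requires both sets non-empty
#' (diseases without annotations are excluded upstream).
#'
#' @param ontology an [Ontology-class].
#' @param ic an [ICTable-class] (for disease-level similarity, computed
#'   from the disease annotation sets, i.e. frequency = proportion of
#'   diseases annotated with the term or a descendant).
#' @param D1,D2 character term vectors.
#' @param micaM optional precomputed [micaICMatrix()] covering both sets.
#' @return non-negative real.
#' @export
simDirected <- function(ontology, ic, D1, D2, micaM = NULL) {
  D1 <- unique(as.character(D1)); D2 <- unique(as.character(D2))
  if (!length(D1)) stop("D1 must be non-empty")
  if (!length(D2)) return(0)
  M <- micaM %||% micaICMatrix(ontology, ic, unique(c(D1, D2)))
  mean(apply(M[D1, D2, drop = FALSE], 1L, max))
}

#' @rdname simDirected
#' @export
simSymmetric <- function(ontology, ic, D1, D2, micaM = NULL) {
  D1 <- unique(as.character(D1)); D2 <- unique(as.character(D2))
  if (!length(D1) || !length(D2))
    stop("symmetric similarity needs two non-empty sets")
  M <- micaM %||% micaICMatrix(ontology, ic, unique(c(D1, D2)))
  (simDirected(ontology, ic, D1, D2, micaM = M) +
     simDirected(ontology, ic, D2, D1, micaM = M)) / 2
}

#' Pairwise symmetric similarity matrix over annotation sets
#'
#' Computes every unordered pair once; the diagonal holds each disease's
#' self-similarity (the mean IC of its terms).
#'
#' @param ontology an [Ontology-class].
#' @param ic an [ICTable-class].
#' @param sets named list: disease id -> non-empty character term vector.
#' @param micaM optional precomputed [micaICMatrix()].
#' @return symmetric numeric matrix with disease-id dimnames.
#' @export
pairwiseSimilarity <- function(ontology, ic, sets, micaM = NULL) {
  ids <- names(sets)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sets must carry unique disease ids as names")
  if (any(lengths(sets) == 0L)) stop("empty annotation set")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  M <- micaM %||% micaICMatrix(ontology, ic,
                               unique(unlist(sets, use.names = FALSE)))
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    S[i, i] <- simSymmetric(ontology, ic, sets[[i]], sets[[i]], micaM = M)
    if (i < n) for (j in seq.int(i + 1L, n)) {
      v <- simSymmetric(ontology, ic, sets[[i]], sets[[j]], micaM = M)
      S[i, j] <- v; S[j, i] <- v
    }
  }
  S
}

#' Write a similarity matrix as TSV
#'
#' Either long form (`disease_a`, `disease_b`, `score`; unordered pairs
#' including the diagonal) or a square matrix with row/column headers.
#'
#' @param sim symmetric similarity matrix.
#' @param path file path.
#' @param shape `"long"` or `"matrix"`.
#' @export
writeSimilarity <- function(sim, path, shape = c("long", "matrix")) {
  shape <- match.arg(shape)
  if (shape == "matrix") {
    write.table(sim, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    ids <- rownames(sim)
    con <- file(path, "w"); on.exit(close(con))
    writeLines("disease_a\tdisease_b\tscore", con)
    for (i in seq_along(ids)) for (j in seq.int(i, length(ids)))
      writeLines(sprintf("%s\t%s\t%.17g", ids[i], ids[j], sim[i, j]), con)
  }
  invisible(path)
}
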