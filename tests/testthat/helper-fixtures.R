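# Fixtures built in code and independent oracles used across the suite.

chainOBO <- function() c(
  "[Term]", "id: T:R", "name: root",
  "[Term]", "id: T:A", "name: alpha", "is_a: T:R ! root",
  "[Term]", "id: T:B", "name: beta", "is_a: T:A")

diamondOBO <- function() c(
  "[Term]", "id: T:R", "name: root",
  "[Term]", "id: T:A", "name: alpha", "is_a: T:R",
  "[Term]", "id: T:B", "name: beta", "is_a: T:R",
  "[Term]", "id: T:C", "name: gamma", "is_a: T:A", "is_a: T:B")

## depth-5 chain under the root: ci at i edges from c0
chainDepthOntology <- function(n = 6) {
  lines <- c("[Term]", "id: C:0", "name: c zero")
  for (i in seq_len(n))
    lines <- c(lines, "[Term]", sprintf("id: C:%d", i),
               sprintf("name: c%d label", i), sprintf("is_a: C:%d", i - 1))
  parseOBO(lines)
}

## hand-built mini phenotype ontology with three top-level categories,
## multi-word labels/synonyms and a parent/child hyperostosis pair
toyPhenoOBO <- function() c(
  "[Term]", "id: HP:0000001", "name: All",
  "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
  "is_a: HP:0000001",
  "[Term]", "id: HP:0000924", "name: Abnormality of the skeletal system",
  "is_a: HP:0000118",
  "[Term]", "id: HP:0000707", "name: Abnormality of the nervous system",
  "is_a: HP:0000118",
  "[Term]", "id: HP:0001871", "name: Abnormality of the blood",
  "is_a: HP:0000118",
  "[Term]", "id: HP:0011842", "name: Abnormality of skeletal morphology",
  "is_a: HP:0000924",
  "[Term]", "id: HP:0000256", "name: Macrocephaly",
  "synonym: \"large head\" EXACT []",
  "is_a: HP:0011842",
  "[Term]", "id: HP:0001167", "name: Finger",
  "is_a: HP:0011842",
  "[Term]", "id: HP:0009381", "name: Short finger",
  "is_a: HP:0001167",
  "[Term]", "id: HP:0001500", "name: Broad finger",
  "is_a: HP:0001167",
  "[Term]", "id: HP:0004437", "name: Cranial hyperostosis",
  "is_a: HP:0011842",
  "[Term]", "id: HP:0005472", "name: Calvarial hyperostosis",
  "is_a: HP:0004437",
  "[Term]", "id: HP:0002315", "name: Headache",
  "is_a: HP:0000707",
  "[Term]", "id: HP:0001268", "name: Mental deterioration",
  "synonym: \"cognitive decline\" RELATED []",
  "is_a: HP:0000707",
  ## a term under two top-level categories
  "[Term]", "id: HP:0999999", "name: Neuroskeletal sign",
  "is_a: HP:0011842", "is_a: HP:0000707",
  "[Term]", "id: HP:0001903", "name: Anemia",
  "is_a: HP:0001871",
  ## shared synonym collision
  "[Term]", "id: HP:0000969", "name: Edema",
  "synonym: \"dropsy\" EXACT []",
  "is_a: HP:0001871",
  "[Term]", "id: HP:0011720", "name: Ear swelling",
  "synonym: \"dropsy\" BROAD []",
  "is_a: HP:0011842")

toyPhenoOntology <- function() parseOBO(toyPhenoOBO())

makeRecords <- function(...) {
  rows <- list(...)
  data.frame(id = vapply(rows, `[[`, "", 1),
             title = vapply(rows, `[[`, "", 2),
             abstract = vapply(rows, `[[`, "", 3),
             mesh = I(lapply(rows, `[[`, 4)),
             stringsAsFactors = FALSE)
}

## ---- independent oracles -------------------------------------------------

## breadth-first-search distance over the undirected is-a adjacency,
## built directly from the parent lists
oracleBFSDist <- function(ont, t1, t2) {
  if (t1 == t2) return(0L)
  adj <- lapply(ontologyTerms(ont), function(t)
    unique(c(ont@parents[[t]], ont@children[[t]])))
  names(adj) <- ontologyTerms(ont)
  dist <- setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[[t1]] <- 0L
  frontier <- t1
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) for (v in adj[[u]]) {
      if (is.na(dist[[v]])) {
        dist[[v]] <- dist[[u]] + 1L
        if (v == t2) return(dist[[v]])
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

## transitive closure of the ancestor relation by iterated squaring
## (Warshall-style), independent of the package's frontier walk
oracleAncestors <- function(ont, t) {
  ids <- ontologyTerms(ont)
  R <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) R[i, ont@parents[[i]]] <- TRUE
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  ids[R[t, ]]
}

## exhaustive minimum-density subset with the documented tie-breaks,
## written as a flat enumeration over all subsets
oracleMinDensity <- function(ont, group) {
  group <- sort(unique(group))
  if (length(group) == 1L) return(group)
  D <- termDistanceMatrix(ont, group)
  best <- NULL
  n <- length(group)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) < 2L) next
    ids <- group[idx]
    v <- D[ids, ids][upper.tri(diag(length(ids)))]
    cand <- list(sd = sqrt(mean((v - mean(v))^2)), size = length(ids),
                 meanDist = mean(v), ids = ids)
    if (is.null(best)) { best <- cand; next }
    tol <- 1e-12
    take <- FALSE
    if (cand$sd < best$sd - tol) take <- TRUE
    else if (cand$sd <= best$sd + tol) {
      if (cand$size > best$size) take <- TRUE
      else if (cand$size == best$size) {
        if (cand$meanDist < best$meanDist - tol) take <- TRUE
        else if (cand$meanDist <= best$meanDist + tol &&
                 paste(cand$ids, collapse = "\r") <
                 paste(best$ids, collapse = "\r")) take <- TRUE
      }
    }
    if (take) best <- cand
  }
  best$ids
}

## brute-force maximum bipartite matching by recursion over A's terms
oracleMaxMatching <- function(rel) {
  if (!length(rel)) return(0L)
  recur <- function(i, usedB) {
    if (i > nrow(rel)) return(0L)
    best <- recur(i + 1L, usedB)  # leave A[i] unmatched
    for (j in seq_len(ncol(rel))) {
      if (rel[i, j] && !usedB[j]) {
        usedB[j] <- TRUE
        best <- max(best, 1L + recur(i + 1L, usedB))
        usedB[j] <- FALSE
      }
    }
    best
  }
  recur(1L, rep(FALSE, ncol(rel)))
}

## greedy matching (first available partner) for the greedy <= maximum bound
oracleGreedyMatching <- function(rel) {
  if (!length(rel)) return(0L)
  usedB <- rep(FALSE, ncol(rel))
  m <- 0L
  for (i in seq_len(nrow(rel))) {
    j <- which(rel[i, ] & !usedB)
    if (length(j)) { usedB[j[1]] <- TRUE; m <- m + 1L }
  }
  m
}

subsumptionRel <- function(ont, A, B) {
  outer(A, B, Vectorize(function(a, b) {
    a == b || a %in% termAncestors(ont, b) || b %in% termAncestors(ont, a)
  }))
}

plainJaccard <- function(A, B) {
  if (!length(union(A, B))) return(0)
  length(intersect(A, B)) / length(union(A, B))
}

## micro-averaged F-score computed straight from the definition
oracleMicroF <- function(models, gold) {
  tp <- fp <- fn <- 0L
  for (d in names(gold)) {
    A <- unique(models[[d]]); G <- unique(gold[[d]])
    tp <- tp + length(intersect(A, G))
    fp <- fp + length(setdiff(A, G))
    fn <- fn + length(setdiff(G, A))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}
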