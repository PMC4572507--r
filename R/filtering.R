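## Annotation filtering: TFIDF/TFIDFIC weighting, minimum-density seed
## clustering and incremental density-bounded extension, plus evaluation
## and per-category parameter learning.

#' Filtering parameter constructor
#'
#' Defaults (n = 5, m = 10, e = 1) are on the natural-log score scale: a
#' seed needs roughly two supporting abstracts at moderate specificity
#' (tf = 2 with idf about 2.5), a leftover survives pruning at a comparable
#' TFIDF backed by an informative term (IC around 4), and extension accepts
#' terms shifting the pairwise-distance spread by at most one.
#'
#' @param n TFIDF seed threshold.
#' @param m TFIDFIC pruning threshold.
#' @param e density margin.
#' @return A [FilterParams-class].
#' @export
filterParams <- function(n = 5, m = 10, e = 1) {
  new("FilterParams", n = as.numeric(n), m = as.numeric(m), e = as.numeric(e))
}

#' Per-(disease, term) frequency and specificity statistics
#'
#' For every (disease, term) pair with at least one mentioning abstract:
#' TF = number of the disease's abstracts mentioning the term at least once
#' (mention counts within an abstract do not matter); IDF = log of the total
#' number of diseases T_D divided by the number of diseases with at least
#' one mentioning abstract; TFIDF = TF x IDF; TFIDFIC = TFIDF x IC(term).
#' Terms with undefined IC (p = 0) are excluded from TFIDFIC (set to 0).
#'
#' @param corpus a [DiseaseCorpus-class] with mentions attached.
#' @param ic an [ICTable-class] (abstract-level IC of the same corpus).
#' @return data.frame with columns `disease`, `term`, `tf`, `idf`, `tfidf`,
#'   `ic`, `tfidfic`.
#' @export
computeTermStats <- function(corpus, ic) {
  tD <- nDiseases(corpus)
  if (tD == 0L) stop("corpus has no diseases")
  base <- ic@base

  perDisease <- lapply(corpus@diseaseAbstracts, function(abs) {
    terms <- unlist(corpus@mentions[abs], use.names = FALSE)
    if (is.null(terms)) integer() else table(terms)
  })
  ## document frequency: number of diseases mentioning each term
  df <- table(unlist(lapply(perDisease, names), use.names = FALSE))

  rows <- lapply(names(perDisease), function(d) {
    tf <- perDisease[[d]]
    if (!length(tf)) return(NULL)
    term <- names(tf)
    idf <- log(tD / as.numeric(df[term])) / log(base)
    icv <- ic@ic[term]
    tfidf <- as.numeric(tf) * idf
    tfidfic <- ifelse(is.finite(icv), tfidf * icv, 0)
    data.frame(disease = d, term = term, tf = as.integer(tf), idf = idf,
               tfidf = tfidf, ic = unname(icv), tfidfic = tfidfic,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(disease = character(), term = character(),
                      tf = integer(), idf = numeric(), tfidf = numeric(),
                      ic = numeric(), tfidfic = numeric())
  rownames(out) <- NULL
  out
}

#' Split a disease's terms into clustering seeds and leftovers
#'
#' Seeds are the terms whose TFIDF reaches the threshold `n` (ties at the
#' threshold are seeds); everything else is a leftover, later considered
#' for density-bounded extension.
#'
#' @param stats [computeTermStats()] rows of a single disease.
#' @param n TFIDF threshold.
#' @return list with character vectors `seeds` and `leftovers`.
#' @export
selectSeeds <- function(stats, n) {
  if (!nrow(stats)) stop("stats must be non-empty")
  if (length(unique(stats$disease)) > 1L)
    stop("selectSeeds expects the stats of a single disease")
  isSeed <- stats$tfidf >= n
  list(seeds = stats$term[isSeed], leftovers = stats$term[!isSeed])
}

#' Density of a term set
#'
#' Population standard deviation of the array of pairwise shortest-path
#' lengths between all unordered pairs of the set. Low density means the
#' terms sit close together in the ontology.
#'
#' @param ontology an [Ontology-class].
#' @param terms at least two term ids.
#' @param dist optional precomputed distance matrix over `terms`.
#' @return non-negative real.
#' @export
termSetDensity <- function(ontology, terms, dist = NULL) {
  terms <- unique(as.character(terms))
  if (length(terms) < 2L) stop("density needs at least two terms")
  d <- dist %||% termDistanceMatrix(ontology, terms)
  popSD(d[terms, terms][upper.tri(diag(length(terms)))])
}

## comparator state for subset search: minimize sd, then maximize size,
## then minimize mean pairwise distance, then smallest sorted-id key
betterSubset <- function(cand, best, tol = 1e-12) {
  if (is.null(best)) return(TRUE)
  if (cand$sd < best$sd - tol) return(TRUE)
  if (cand$sd > best$sd + tol) return(FALSE)
  if (cand$size != best$size) return(cand$size > best$size)
  if (abs(cand$meanDist - best$meanDist) > tol)
    return(cand$meanDist < best$meanDist)
  cand$key < best$key
}

subsetStats <- function(ids, D) {
  v <- D[ids, ids][upper.tri(diag(length(ids)))]
  m <- mean(v)
  list(sd = sqrt(mean((v - m)^2)), size = length(ids), meanDist = m,
       key = paste(sort(ids), collapse = "\r"), terms = ids)
}

#' Minimum-density subset of a term group
#'
#' Finds the subset (size >= 2; singleton groups return themselves) of a
#' top-level group minimizing the density ([termSetDensity()]). Groups of up
#' to `exhaustiveLimit` terms are solved by exact exhaustive enumeration;
#' larger groups use a nearest-insertion proximity ordering whose prefixes
#' are scanned for the minimum-density one (the exhaustive search remains
#' the correctness oracle at small sizes). Ties are broken
#' deterministically: lower density, then larger subset, then smaller mean
#' pairwise distance, then lexicographically smallest sorted id list.
#'
#' @param ontology an [Ontology-class].
#' @param group character term ids (non-empty).
#' @param exhaustiveLimit largest group size solved exactly (default 12).
#' @return character vector, the selected subset.
#' @export
minDensitySubset <- function(ontology, group, exhaustiveLimit = 12L) {
  group <- unique(as.character(group))
  if (!length(group)) stop("group must be non-empty")
  if (length(group) == 1L) return(group)
  group <- sort(group)
  D <- termDistanceMatrix(ontology, group)
  n <- length(group)

  best <- NULL
  if (n <= exhaustiveLimit) {
    for (size in 2:n) {
      combos <- combn(group, size, simplify = FALSE)
      for (ids in combos) {
        cand <- subsetStats(ids, D)
        if (betterSubset(cand, best)) best <- cand
      }
    }
  } else {
    ## nearest-insertion ordering: start from the closest pair, repeatedly
    ## append the term with the smallest total distance to the working set
    off <- D; diag(off) <- Inf
    start <- which(off == min(off), arr.ind = TRUE)
    start <- start[order(group[start[, 1]], group[start[, 2]]), , drop = FALSE]
    ord <- group[sort(start[1, ])]
    rest <- setdiff(group, ord)
    while (length(rest)) {
      tot <- vapply(rest, function(t) sum(D[t, ord]), 0)
      pick <- rest[order(tot, rest)][1]
      ord <- c(ord, pick)
      rest <- setdiff(rest, pick)
    }
    for (size in 2:n) {
      cand <- subsetStats(ord[seq_len(size)], D)
      if (betterSubset(cand, best)) best <- cand
    }
  }
  sort(best$terms)
}

#' Density-bounded extension of a seed subset
#'
#' Leftover terms of one top-level group whose TFIDFIC reaches the pruning
#' threshold `m` are considered in descending TFIDFIC order (lexicographic
#' id tie-break). Each is provisionally appended to the working subset; it
#' is accepted iff the resulting density stays within the margin `e` of the
#' original seed-subset density. Accepted terms join the working subset, so
#' acceptance is incremental and order-dependent by design.
#'
#' @param ontology an [Ontology-class].
#' @param seedSubset the minimum-density subset of the group's seeds.
#' @param seedDensity its density (0 for singleton subsets).
#' @param leftovers data.frame with columns `term`, `tfidfic` for the
#'   group's leftover terms.
#' @param m TFIDFIC pruning threshold.
#' @param e density margin.
#' @return character vector of accepted leftover terms.
#' @export
extendCandidates <- function(ontology, seedSubset, seedDensity, leftovers,
                             m, e) {
  if (!length(seedSubset)) stop("seedSubset must be non-empty")
  surv <- leftovers[leftovers$tfidfic >= m, , drop = FALSE]
  if (!nrow(surv)) return(character())
  surv <- surv[order(-surv$tfidfic, surv$term), , drop = FALSE]

  working <- unique(seedSubset)
  accepted <- character()
  allTerms <- unique(c(working, surv$term))
  D <- termDistanceMatrix(ontology, allTerms)
  for (t in surv$term) {
    if (t %in% working) next
    nd <- termSetDensity(ontology, c(working, t), dist = D)
    if (abs(nd - seedDensity) <= e) {
      working <- c(working, t)
      accepted <- c(accepted, t)
    }
  }
  accepted
}

#' Run the annotation filter over a corpus
#'
#' Per disease: terms are split into seeds and leftovers by the TFIDF
#' threshold; seeds are grouped by top-level category; each group is
#' reduced to its minimum-density subset (the candidate core); leftovers
#' pruned by TFIDFIC are grouped the same way and extended into the core
#' under the density margin; the final candidate set is the deduplicated
#' union. Diseases whose category appears in `perCategoryParams` use those
#' parameters. A disease with no recognized terms yields an empty model
#' (flag `"empty"`); a disease where no term passes the seed threshold
#' falls back to its single highest-TFIDF term (flag `"fallback"`). Terms
#' outside the abnormality subtree are ignored.
#'
#' @param ontology an [Ontology-class].
#' @param corpus a [DiseaseCorpus-class] with mentions attached.
#' @param ic an [ICTable-class] for TFIDFIC.
#' @param params global [FilterParams-class].
#' @param categoryMap optional named character, disease -> category.
#' @param perCategoryParams optional named list of [FilterParams-class]
#'   keyed by category.
#' @param diseases diseases to process (default all).
#' @return named list of models; each model is a list with elements
#'   `disease`, `terms`, `provenance` (named character:
#'   `"seed-subset"`, `"density-extended"` or `"fallback"`) and `flag`
#'   (`"ok"`, `"fallback"` or `"empty"`).
#' @export
runFilter <- function(ontology, corpus, ic, params = filterParams(),
                      categoryMap = NULL, perCategoryParams = NULL,
                      diseases = diseaseIds(corpus)) {
  stats <- computeTermStats(corpus, ic)
  tl <- topLevelTerms(ontology)
  inAbn <- function(term) {
    length(intersect(tl, termAncestors(ontology, term, reflexive = TRUE))) > 0L
  }

  out <- setNames(vector("list", length(diseases)), diseases)
  for (d in diseases) {
    p <- params
    if (!is.null(perCategoryParams) && !is.null(categoryMap) &&
        d %in% names(categoryMap)) {
      cand <- perCategoryParams[[categoryMap[[d]]]]
      if (!is.null(cand)) p <- cand
    }
    ds <- stats[stats$disease == d, , drop = FALSE]
    ds <- ds[vapply(ds$term, inAbn, TRUE), , drop = FALSE]
    if (!nrow(ds)) {
      out[[d]] <- list(disease = d, terms = character(),
                       provenance = setNames(character(), character()),
                       flag = "empty")
      next
    }
    ss <- selectSeeds(ds, p@n)
    if (!length(ss$seeds)) {
      top <- ds[order(-ds$tfidf, ds$term), , drop = FALSE]$term[1]
      out[[d]] <- list(disease = d, terms = top,
                       provenance = setNames("fallback", top),
                       flag = "fallback")
      next
    }
    seedGroups <- topLevelGroups(ontology, ss$seeds)
    leftGroups <- if (length(ss$leftovers))
      topLevelGroups(ontology, ss$leftovers) else list()

    core <- character(); extended <- character()
    for (g in names(seedGroups)) {
      sub <- minDensitySubset(ontology, seedGroups[[g]])
      den <- if (length(sub) >= 2L) termSetDensity(ontology, sub) else 0
      core <- c(core, sub)
      lg <- leftGroups[[g]]
      if (!is.null(lg) && length(lg)) {
        lf <- ds[ds$term %in% lg, c("term", "tfidfic"), drop = FALSE]
        extended <- c(extended,
                      extendCandidates(ontology, sub, den, lf, p@m, p@e))
      }
    }
    core <- unique(core)
    extended <- setdiff(unique(extended), core)
    terms <- c(core, extended)
    prov <- setNames(c(rep("seed-subset", length(core)),
                       rep("density-extended", length(extended))), terms)
    out[[d]] <- list(disease = d, terms = terms, provenance = prov,
                     flag = "ok")
  }
  out
}

## normalize models/gold arguments into a named list of character vectors
termSetList <- function(x) {
  lapply(x, function(el) {
    if (is.list(el) && !is.null(el$terms)) unique(as.character(el$terms))
    else unique(as.character(el))
  })
}

#' Score disease models against a gold standard
#'
#' Counts per-disease true positives, false positives and false negatives
#' by set comparison, micro-averaging across diseases (and categories, when
#' a category map is given). In `"subsumption"` mode a model term matches a
#' gold term when they are identical or one is an ancestor of the other;
#' matches are counted through a maximum bipartite matching so each term is
#' used at most once. Precision = TP/(TP+FP), recall = TP/(TP+FN), F-score
#' their harmonic mean; ratios with zero denominators are reported as 0 and
#' flagged via `undefinedPrecision`/`undefinedRecall`.
#'
#' @param models named list of models ([runFilter()]) or of character term
#'   vectors.
#' @param gold named list: disease -> character gold term vector. Every
#'   gold disease must be present in `models`.
#' @param matchMode `"exact"` or `"subsumption"`.
#' @param ontology required for subsumption mode.
#' @param categoryMap optional named character disease -> category for
#'   per-category aggregates.
#' @return list with `overall` (micro-averaged counts and scores),
#'   `perDisease` (data.frame) and, if requested, `perCategory`.
#' @export
evaluateModels <- function(models, gold, matchMode = c("exact", "subsumption"),
                           ontology = NULL, categoryMap = NULL) {
  matchMode <- match.arg(matchMode)
  if (matchMode == "subsumption" && is.null(ontology))
    stop("subsumption mode needs an ontology")
  ms <- termSetList(models)
  gs <- termSetList(gold)
  missing <- setdiff(names(gs), names(ms))
  if (length(missing))
    stop("gold disease(s) without a model: ", paste(missing, collapse = ", "))

  rows <- lapply(names(gs), function(d) {
    A <- ms[[d]]; G <- gs[[d]]
    tp <- if (matchMode == "exact") length(intersect(A, G))
          else subsumptionMatchSize(ontology, A, G)
    data.frame(disease = d, tp = tp, fp = length(A) - tp,
               fn = length(G) - tp, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  score <- function(tp, fp, fn) {
    undefP <- (tp + fp) == 0L
    undefR <- (tp + fn) == 0L
    precision <- ifelse(undefP, 0, tp / (tp + fp))
    recall <- ifelse(undefR, 0, tp / (tp + fn))
    f <- ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0)
    list(precision = precision, recall = recall, f_score = f,
         undefinedPrecision = undefP, undefinedRecall = undefR)
  }
  sc <- score(per$tp, per$fp, per$fn)
  per$precision <- sc$precision; per$recall <- sc$recall
  per$f_score <- sc$f_score

  ov <- score(sum(per$tp), sum(per$fp), sum(per$fn))
  overall <- c(list(tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn)), ov)
  res <- list(overall = overall, perDisease = per)

  if (!is.null(categoryMap)) {
    cats <- categoryMap[per$disease]
    agg <- lapply(split(per, cats), function(x) {
      s <- score(sum(x$tp), sum(x$fp), sum(x$fn))
      data.frame(tp = sum(x$tp), fp = sum(x$fp), fn = sum(x$fn),
                 precision = s$precision, recall = s$recall,
                 f_score = s$f_score)
    })
    pc <- do.call(rbind, agg)
    pc <- cbind(category = rownames(pc), pc)
    rownames(pc) <- NULL
    res$perCategory <- pc
  }
  res
}

#' Learn per-category filtering parameters by grid search
#'
#' For each disease category present in the gold standard, exhaustively
#' evaluates every grid point (`grid$n` x `grid$m` x `grid$e`) on the
#' category's gold diseases and keeps the point maximizing the objective.
#' Ties keep the smallest `n`, then `m`, then `e`. Categories without gold
#' diseases are skipped with a warning.
#'
#' @param ontology,corpus,ic as in [runFilter()].
#' @param gold named list disease -> gold terms.
#' @param categoryMap named character disease -> category.
#' @param grid list with numeric vectors `n`, `m`, `e`.
#' @param objective `"f_score"` or `"precision"`.
#' @param matchMode passed to [evaluateModels()].
#' @return named list: category -> list(`params` = [FilterParams-class],
#'   `objective` = achieved value).
#' @export
learnParameters <- function(ontology, corpus, ic, gold, categoryMap,
                            grid, objective = c("f_score", "precision"),
                            matchMode = "exact") {
  objective <- match.arg(objective)
  if (!all(c("n", "m", "e") %in% names(grid)) || !all(lengths(grid[c("n", "m", "e")]) > 0))
    stop("grid must provide non-empty n, m and e value lists")
  cats <- sort(unique(unname(categoryMap)))
  out <- list()
  for (cat in cats) {
    dis <- intersect(names(gold), names(categoryMap)[categoryMap == cat])
    if (!length(dis)) {
      warning("category without gold diseases skipped: ", cat)
      next
    }
    best <- NULL
    for (nv in sort(grid$n)) for (mv in sort(grid$m)) for (ev in sort(grid$e)) {
      p <- filterParams(nv, mv, ev)
      models <- runFilter(ontology, corpus, ic, p, diseases = dis)
      ev2 <- evaluateModels(models, gold[dis], matchMode = matchMode,
                            ontology = ontology)
      val <- ev2$overall[[objective]]
      if (is.null(best) || val > best$objective + 1e-12)
        best <- list(params = p, objective = val)
    }
    out[[cat]] <- best
  }
  out
}

#' Write / read disease models as TSV
#'
#' Body columns: disease_id, term_id, provenance. Every processed disease is
#' additionally recorded in a `#model` header comment with its flag, so
#' empty and fallback models round-trip.
#'
#' @param models output of [runFilter()].
#' @param path file path.
#' @export
writeModels <- function(models, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in models)
    writeLines(sprintf("#model\t%s\t%s", m$disease, m$flag), con)
  writeLines("disease_id\tterm_id\tprovenance", con)
  for (m in models)
    if (length(m$terms))
      writeLines(sprintf("%s\t%s\t%s", m$disease, m$terms,
                         m$provenance[m$terms]), con)
  invisible(path)
}

#' @rdname writeModels
#' @export
readModels <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#model\t")]
  parts <- strsplit(sub("^#model\t", "", hdr), "\t", fixed = TRUE)
  out <- list()
  for (p in parts)
    out[[p[1]]] <- list(disease = p[1], terms = character(),
                        provenance = setNames(character(), character()),
                        flag = p[2])
  body <- lines[!startsWith(lines, "#")][-1]
  for (row in strsplit(body, "\t", fixed = TRUE)) {
    d <- row[1]
    out[[d]]$terms <- c(out[[d]]$terms, row[2])
    out[[d]]$provenance[row[2]] <- row[3]
  }
  out
}

#' Write / read filter parameter configurations
#'
#' YAML or JSON (chosen from the extension) with a `global` section and an
#' optional `categories` section of per-category overrides.
#'
#' @param params global [FilterParams-class].
#' @param perCategory optional named list of [FilterParams-class].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @export
writeFilterParams <- function(params, path, perCategory = NULL) {
  asList <- function(p) list(n = p@n, m = p@m, e = p@e)
  x <- list(global = asList(params))
  if (!is.null(perCategory)) x$categories <- lapply(perCategory, asList)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFilterParams
#' @export
readFilterParams <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  fromList <- function(l) filterParams(l$n, l$m, l$e)
  list(global = fromList(x$global),
       categories = lapply(x$categories %||% list(), fromList))
}
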