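## Synthetic ontologies and corpora with planted disease models.
##
## The generator emulates the statistical structure the annotation filter
## assumes: each disease's true terms are concentrated in one or two
## top-level categories and mentioned repeatedly across that disease's
## abstracts, while noise terms are scattered uniformly over the ontology.

## deterministic coined word for term k: unique, single-token, disjoint from
## the filler vocabulary (fixed-width base-20 syllables => prefix-free)
coinWord <- function(k, prefix = "ph") {
  syl <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
           "po", "ra", "so", "tu", "ve", "wi", "xo", "yu", "za", "bo")
  k0 <- k - 1L
  s <- character()
  repeat {
    s <- c(syl[k0 %% 20L + 1L], s)
    k0 <- k0 %/% 20L
    if (k0 == 0L) break
  }
  paste0(prefix, paste(s, collapse = ""))
}

fillerVocab <- c(
  "patient", "clinical", "study", "report", "cohort", "analysis", "onset",
  "treatment", "therapy", "outcome", "observed", "presented", "history",
  "examination", "findings", "associated", "severe", "chronic", "acute",
  "bilateral", "progressive", "diagnosis", "symptoms", "features",
  "evaluation", "followup", "baseline", "control", "group", "series")

#' Generate a random toy phenotype ontology
#'
#' Builds a DAG with a root, an abnormality subroot, `nTopLevel` top-level
#' category terms and randomly attached descendant terms. Each descendant
#' belongs to a single category subtree; with probability `pExtraParent` it
#' receives a second parent within the same subtree, so the result is a
#' genuine DAG rather than a tree. Labels are coined single-token words
#' (unique, never colliding with the synthetic filler vocabulary); a
#' fraction of terms additionally carries a coined synonym.
#'
#' @param nTerms total number of terms including root, subroot and
#'   top-level terms (>= nTopLevel + 3).
#' @param nTopLevel number of top-level categories.
#' @param seed RNG seed (deterministic output).
#' @param pExtraParent probability of a second within-category parent.
#' @param synonymProb probability a term carries a synonym.
#' @return An [Ontology-class].
#' @export
syntheticOntology <- function(nTerms = 120L, nTopLevel = 5L, seed = 1L,
                              pExtraParent = 0.15, synonymProb = 0.3) {
  nTerms <- as.integer(nTerms); nTopLevel <- as.integer(nTopLevel)
  if (nTerms < nTopLevel + 3L)
    stop("nTerms must be at least nTopLevel + 3")
  withSeed(seed, {
    rootId <- "HP:0000001"; abnId <- "HP:0000118"
    tlIds <- sprintf("HP:%07d", 100L + seq_len(nTopLevel))
    nInner <- nTerms - 2L - nTopLevel
    innerIds <- sprintf("HP:%07d", 1000L + seq_len(nInner))
    ids <- c(rootId, abnId, tlIds, innerIds)

    labels <- c("all", "phenotypic abnormality",
                sprintf("abnormality of organ system %d", seq_len(nTopLevel)),
                vapply(seq_len(nInner), coinWord, ""))
    names(labels) <- ids
    parents <- setNames(vector("list", length(ids)), ids)
    parents[[rootId]] <- character()
    parents[[abnId]] <- rootId
    for (tl in tlIds) parents[[tl]] <- abnId

    category <- setNames(rep(NA_character_, length(ids)), ids)
    category[tlIds] <- tlIds
    members <- setNames(as.list(tlIds), tlIds)  # per-category attachable terms
    for (t in innerIds) {
      cat <- sampleVec(tlIds, 1L)
      pool <- members[[cat]]
      par <- sampleVec(pool, 1L)
      if (length(pool) > 1L && runif(1) < pExtraParent) {
        extra <- sampleVec(setdiff(pool, par), 1L)
        ## avoid creating a parent that is an ancestor of the other parent
        par <- unique(c(par, extra))
      }
      parents[[t]] <- par
      category[[t]] <- cat
      members[[cat]] <- c(members[[cat]], t)
    }

    synonyms <- setNames(vector("list", length(ids)), ids)
    for (k in seq_along(innerIds)) {
      if (runif(1) < synonymProb)
        synonyms[[innerIds[k]]] <- coinWord(k, prefix = "sy")
    }
    makeOntology(ids, labels, synonyms, parents, abnormalityRoot = abnId)
  })
}

#' Generate a synthetic disease-tagged corpus with planted truth
#'
#' Plants a phenotype-term model for each of `nDiseases` diseases (terms
#' drawn from the leaves of one or two top-level categories, mirroring the
#' assumption that a disease affects few major organ systems) and writes
#' abstracts in which each planted term's label is mentioned with
#' probability `mentionProb` per abstract, plus a Poisson(`noiseRate`)
#' number of off-plant noise terms per abstract drawn uniformly from the
#' rest of the abnormality subtree. Abstracts are filler text with embedded
#' labels; each abstract is MeSH-tagged with its disease. Disease
#' categories are assigned round-robin. Deterministic given `seed`.
#'
#' @param ontology an [Ontology-class] (e.g. [syntheticOntology()]).
#' @param nDiseases,termsPerDisease,abstractsPerDisease counts (>= 1).
#' @param mentionProb per-abstract probability that a planted term appears.
#' @param noiseRate expected number of noise terms per abstract.
#' @param nCategories number of disease categories.
#' @param seed RNG seed.
#' @return list with `records` (abstract data.frame, see [readAbstracts()]),
#'   `truth` (list: `planted` disease -> terms, `params` the full parameter
#'   record including the seed) and `categories` (named character,
#'   disease -> category).
#' @export
generateSyntheticCorpus <- function(ontology, nDiseases = 30L,
                                    termsPerDisease = 8L,
                                    abstractsPerDisease = 20L,
                                    mentionProb = 0.6, noiseRate = 2,
                                    nCategories = 5L, seed = 1L) {
  if (any(c(nDiseases, termsPerDisease, abstractsPerDisease, nCategories) < 1L))
    stop("all counts must be >= 1")
  tl <- topLevelTerms(ontology)
  leaves <- ontology@terms[lengths(ontology@children[ontology@terms]) == 0L]
  leaves <- setdiff(leaves, c(ontology@root, ontology@abnormalityRoot, tl))
  if (length(leaves) < termsPerDisease)
    stop("ontology has fewer than termsPerDisease leaf terms")
  abnTerms <- termDescendants(ontology, ontology@abnormalityRoot)
  abnTerms <- setdiff(abnTerms, tl)

  withSeed(seed, {
    diseases <- sprintf("D%04d", seq_len(nDiseases))
    categories <- setNames(
      sprintf("CAT%d", (seq_len(nDiseases) - 1L) %% nCategories + 1L),
      diseases)

    groupLeaves <- lapply(tl, function(g)
      intersect(termDescendants(ontology, g), leaves))
    names(groupLeaves) <- tl

    planted <- setNames(vector("list", nDiseases), diseases)
    for (d in diseases) {
      nGroups <- if (runif(1) < 0.35) 2L else 1L
      gs <- sampleVec(tl, min(nGroups, length(tl)))
      pool <- unlist(groupLeaves[gs], use.names = FALSE)
      while (length(pool) < termsPerDisease && length(gs) < length(tl)) {
        gs <- c(gs, sampleVec(setdiff(tl, gs), 1L))
        pool <- unlist(groupLeaves[gs], use.names = FALSE)
      }
      if (length(pool) < termsPerDisease)
        stop("not enough leaf terms in the ontology for termsPerDisease")
      planted[[d]] <- sort(sampleVec(pool, termsPerDisease))
    }

    recs <- vector("list", nDiseases * abstractsPerDisease)
    k <- 0L
    for (d in diseases) {
      noisePool <- setdiff(abnTerms, planted[[d]])
      for (j in seq_len(abstractsPerDisease)) {
        k <- k + 1L
        id <- sprintf("%s-a%03d", d, j)
        mentioned <- planted[[d]][runif(termsPerDisease) < mentionProb]
        nNoise <- rpois(1L, noiseRate)
        noise <- if (nNoise > 0L)
          sampleVec(noisePool, min(nNoise, length(noisePool))) else character()
        chunks <- c(unname(ontology@labels[c(mentioned, noise)]),
                    sampleVec(fillerVocab, 6L, replace = TRUE))
        chunks <- sampleVec(chunks, length(chunks))
        recs[[k]] <- list(
          id = id,
          title = paste(sampleVec(fillerVocab, 4L, replace = TRUE),
                        collapse = " "),
          abstract = paste(chunks, collapse = " "),
          mesh = d)
      }
    }
    records <- data.frame(
      id = vapply(recs, `[[`, "", "id"),
      title = vapply(recs, `[[`, "", "title"),
      abstract = vapply(recs, `[[`, "", "abstract"),
      mesh = I(lapply(recs, function(r) r$mesh)),
      stringsAsFactors = FALSE)

    truth <- list(
      planted = planted,
      params = list(nDiseases = nDiseases, termsPerDisease = termsPerDisease,
                    abstractsPerDisease = abstractsPerDisease,
                    mentionProb = mentionProb, noiseRate = noiseRate,
                    nCategories = nCategories, seed = seed))
    list(records = records, truth = truth, categories = categories)
  })
}

#' @rdname generateSyntheticCorpus
#' @param truth the `truth` element of a generated corpus.
#' @param path JSON output file.
#' @export
writeSyntheticTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname generateSyntheticCorpus
#' @export
readSyntheticTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted <- lapply(x$planted, as.character)
  x
}

#' End-to-end recovery experiment on a synthetic corpus
#'
#' Generates a synthetic corpus, recognizes mentions, runs the annotation
#' filter and scores the recovered models against the planted truth,
#' alongside two baselines: the unfiltered raw recognized term sets and a
#' size-matched random selection from each disease's raw terms.
#'
#' @param seed RNG seed (also drives the generator).
#' @param ontology ontology to use; default a fresh [syntheticOntology()]
#'   built from the same seed.
#' @param params [FilterParams-class] for the filter.
#' @param ... passed to [generateSyntheticCorpus()].
#' @return list with micro-averaged F-scores `fFiltered`, `fRaw`,
#'   `fRandom`, plus the evaluation objects.
#' @export
syntheticRecovery <- function(seed = 1L, ontology = NULL,
                              params = filterParams(), ...) {
  ontology <- ontology %||% syntheticOntology(seed = seed)
  gen <- generateSyntheticCorpus(ontology, seed = seed, ...)
  idx <- buildLexicalIndex(ontology)
  mentions <- recognizeAbstracts(idx, gen$records)
  corpus <- filterByMesh(gen$records, names(gen$truth$planted))
  corpus <- attachMentions(corpus, mentions)
  ic <- termFrequencies(ontology, abstractAnnotations(corpus))
  models <- runFilter(ontology, corpus, ic, params)
  gold <- gen$truth$planted

  raw <- rawDiseaseTerms(corpus)
  evF <- evaluateModels(models, gold)
  evR <- evaluateModels(raw, gold)
  rnd <- withSeed(seed + 997L, {
    lapply(setNames(names(models), names(models)), function(d) {
      size <- min(length(models[[d]]$terms), length(raw[[d]]))
      if (size == 0L) character() else sampleVec(raw[[d]], size)
    })
  })
  evRnd <- evaluateModels(rnd, gold)
  list(fFiltered = evF$overall$f_score, fRaw = evR$overall$f_score,
       fRandom = evRnd$overall$f_score,
       evalFiltered = evF, evalRaw = evR, evalRandom = evRnd)
}

#' Recovery study across independent synthetic corpora
#'
#' Runs [syntheticRecovery()] once per seed and averages the three F-scores,
#' the study-level summary used to show that the annotation filter recovers
#' planted disease models better than the unfiltered raw term sets and a
#' size-matched random selection.
#'
#' @param seeds integer vector of generator seeds (one corpus each).
#' @param ... passed through to [syntheticRecovery()].
#' @return list with `meanFiltered`, `meanRaw`, `meanRandom` and the
#'   per-seed data.frame `perSeed`.
#' @export
recoveryStudy <- function(seeds = 1:20, ...) {
  per <- do.call(rbind, lapply(seeds, function(s) {
    r <- syntheticRecovery(seed = s, ...)
    data.frame(seed = s, fFiltered = r$fFiltered, fRaw = r$fRaw,
               fRandom = r$fRandom)
  }))
  list(meanFiltered = mean(per$fFiltered), meanRaw = mean(per$fRaw),
       meanRandom = mean(per$fRandom), perSeed = per)
}

#' Planted two-block modular disease network
#'
#' Builds a similarity matrix whose within-block pairs exceed the simcut
#' with probability `pWithin` and whose between-block pairs never do, then
#' thresholds it into a [CDN-class] whose categories are the blocks. The
#' observed gray-edge fraction is 0 by construction, the strongly modular
#' fixture used to exercise the randomization significance tests.
#'
#' @param nBlocks,nodesPerBlock block structure.
#' @param pWithin within-block edge probability.
#' @param simcut similarity cutoff.
#' @param seed RNG seed.
#' @return A [CDN-class].
#' @export
syntheticModularCDN <- function(nBlocks = 2L, nodesPerBlock = 20L,
                                pWithin = 0.5, simcut = 2, seed = 1L) {
  withSeed(seed, {
    n <- nBlocks * nodesPerBlock
    ids <- sprintf("D%03d", seq_len(n))
    block <- sprintf("BLOCK%d", rep(seq_len(nBlocks), each = nodesPerBlock))
    names(block) <- ids
    sim <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (block[i] == block[j] && runif(1) < pWithin) {
        w <- simcut + runif(1, 0.1, 1.5)
        sim[i, j] <- w; sim[j, i] <- w
      }
    }
    diag(sim) <- simcut + 2
    buildCDN(sim, block, simcut = simcut)
  })
}
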