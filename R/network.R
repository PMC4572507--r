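## The phenotypic disease network: construction from pairwise similarity,
## gray-edge fraction and the two randomization significance tests.

#' Build the disease network from a similarity matrix
#'
#' Draws an edge between every pair of diseases whose similarity strictly
#' exceeds `simcut` (a pair at exactly the cutoff gets no edge); diseases
#' left without any edge are dropped. Each retained disease carries its
#' category label set (a disease may belong to several categories).
#'
#' @param sim symmetric similarity matrix with disease-id dimnames.
#' @param categories named character or named list covering every matrix
#'   disease; values are category labels (possibly several per disease).
#' @param simcut similarity cutoff (>= 0).
#' @return A [CDN-class].
#' @export
buildCDN <- function(sim, categories, simcut = 2) {
  if (simcut < 0) stop("simcut must be non-negative")
  ids <- rownames(sim)
  if (is.null(ids) || !identical(ids, colnames(sim)))
    stop("sim must have matching disease-id dimnames")
  catList <- if (is.list(categories)) lapply(categories, as.character)
             else lapply(as.list(categories), as.character)
  missing <- setdiff(ids, names(catList))
  if (length(missing))
    stop("categories missing for: ", paste(missing, collapse = ", "))

  n <- length(ids)
  ut <- which(upper.tri(sim) & sim > simcut, arr.ind = TRUE)
  edges <- data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
                      weight = sim[ut], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b)))
  new("CDN", nodes = nodes, categories = catList[nodes], edges = edges,
      simcut = as.numeric(simcut))
}

#' Network accessors
#'
#' @param cdn a [CDN-class].
#' @return `cdnNodes`: disease ids; `cdnEdges`: the edge data.frame;
#'   `cdnCategories`: category label sets; `cdnDegrees`: named degree
#'   counts.
#' @export
cdnNodes <- function(cdn) cdn@nodes

#' @rdname cdnNodes
#' @export
cdnEdges <- function(cdn) cdn@edges

#' @rdname cdnNodes
#' @export
cdnCategories <- function(cdn) cdn@categories

#' @rdname cdnNodes
#' @export
cdnDegrees <- function(cdn) {
  deg <- table(factor(c(cdn@edges$a, cdn@edges$b), levels = cdn@nodes))
  setNames(as.integer(deg), names(deg))
}

## logical vector: is each edge gray (endpoint category sets disjoint)?
edgeIsGray <- function(cdn) {
  if (!nrow(cdn@edges)) return(logical())
  vapply(seq_len(nrow(cdn@edges)), function(k) {
    !length(intersect(cdn@categories[[cdn@edges$a[k]]],
                      cdn@categories[[cdn@edges$b[k]]]))
  }, TRUE)
}

#' Gray-edge fraction of a disease network
#'
#' An edge is gray iff its endpoints share no disease category; the GEF is
#' the proportion of gray edges among all edges. Low GEF means the
#' phenotype-derived network clusters agree with the disease
#' classification.
#'
#' @param cdn a [CDN-class] with at least one edge.
#' @return list with `grayEdges`, `totalEdges`, `fraction`.
#' @export
grayEdgeFraction <- function(cdn) {
  total <- nrow(cdn@edges)
  if (!total) stop("gray-edge fraction is undefined on an edgeless network")
  gray <- sum(edgeIsGray(cdn))
  list(grayEdges = as.integer(gray), totalEdges = as.integer(total),
       fraction = gray / total)
}

cdnAsIgraph <- function(cdn) {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(cdn@nodes), name = cdn@nodes)
  if (nrow(cdn@edges))
    g <- igraph::add_edges(g, rbind(cdn@edges$a, cdn@edges$b))
  g
}

igraphAsCDN <- function(g, cdn) {
  e <- igraph::as_edgelist(g)
  edges <- data.frame(a = e[, 1], b = e[, 2], weight = NA_real_,
                      stringsAsFactors = FALSE)
  new("CDN", nodes = cdn@nodes, categories = cdn@categories,
      edges = edges, simcut = cdn@simcut)
}

#' Degree-preserving edge randomization
#'
#' Repeatedly draws two edges A-B and X-Y at random and rewires them to
#' A-Y and X-B; a trial is skipped when a rewired edge already exists or
#' would be a self-loop, so the degree of every node (and the edge count)
#' is preserved exactly. `nSwaps` counts attempted trials, not successes.
#' Deterministic given `seed`. Edge weights are meaningless after
#' rewiring and are set to `NA`.
#'
#' @param cdn a [CDN-class] with at least two edges.
#' @param nSwaps number of attempted swaps (default 10 x edge count).
#' @param seed RNG seed.
#' @return a rewired [CDN-class].
#' @export
edgeRandomize <- function(cdn, nSwaps = 10L * nrow(cdn@edges), seed = 1L) {
  if (nrow(cdn@edges) < 2L) stop("edge randomization needs >= 2 edges")
  withSeed(seed, {
    g <- cdnAsIgraph(cdn)
    if (nSwaps > 0L)
      g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = nSwaps))
    igraphAsCDN(g, cdn)
  })
}

#' Randomize disease annotation sets
#'
#' Per disease, replaces `floor(fraction x set size)` uniformly chosen
#' terms with terms drawn uniformly from the abnormality subtree, avoiding
#' duplicates within the set; set sizes are preserved. Deterministic given
#' `seed`.
#'
#' @param sets named list: disease -> character term vector.
#' @param fraction fraction of each set to replace, in [0, 1].
#' @param ontology an [Ontology-class] supplying the replacement pool.
#' @param seed RNG seed.
#' @return named list of randomized sets.
#' @export
annotationRandomize <- function(sets, fraction = 0.5, ontology, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  pool <- termDescendants(ontology, ontology@abnormalityRoot)
  withSeed(seed, {
    lapply(sets, function(terms) {
      terms <- unique(as.character(terms))
      k <- floor(fraction * length(terms))
      if (k == 0L) return(terms)
      drop <- sampleVec(terms, k)
      kept <- setdiff(terms, drop)
      ## replacements avoid every original term (a dropped term must not be
      ## redrawn) and are distinct, so exactly |terms| - k originals survive
      avail <- setdiff(pool, terms)
      repl <- sampleVec(avail, min(k, length(avail)))
      c(kept, repl)
    })
  })
}

#' Significance of the gray-edge fraction by randomization
#'
#' Compares the observed GEF against a null distribution from either
#' degree-preserving edge randomization (`"er"`: the network is rewired,
#' categories kept) or annotation randomization (`"ar"`: half of each
#' disease's terms are replaced at random, the whole similarity matrix and
#' network are rebuilt per replicate, so replicate networks may differ in
#' node and edge count; the replicate simcut defaults to the observed one
#' but can be lowered, e.g. to 1.4, to keep replicate networks comparable
#' in size). The empirical p-value uses the add-one convention
#' p = (1 + #\{null <= observed\}) / (1 + replicates), never exactly 0; when
#' no null value reaches the observed GEF the conventional strict bound
#' "p < 1/replicates" is reported alongside.
#'
#' @param cdn the observed [CDN-class].
#' @param method `"er"` or `"ar"`.
#' @param replicates number of null replicates.
#' @param seed RNG seed; replicate seeds are derived from it.
#' @param nSwaps attempted swaps per er replicate (default 10 x edges).
#' @param arInputs for `"ar"`: list with `sets` (disease -> terms), `ic`
#'   (the [ICTable-class] used for similarity), `categories` (covering all
#'   diseases in `sets`), `ontology`, and optionally `simcut` and
#'   `fraction` (default 0.5).
#' @return A [GEFReport-class].
#' @export
gefSignificance <- function(cdn, method = c("er", "ar"), replicates = 1000L,
                            seed = 1L, nSwaps = NULL, arInputs = NULL) {
  method <- match.arg(method)
  obs <- grayEdgeFraction(cdn)
  replicates <- as.integer(replicates)
  seed <- as.integer(seed)

  nulls <- numeric(replicates)
  if (method == "er") {
    if (nrow(cdn@edges) < 2L) stop("er needs >= 2 edges")
    nSwaps <- as.integer(nSwaps %||% (10L * nrow(cdn@edges)))
    g0 <- cdnAsIgraph(cdn)
    grayable <- cdn  # reuse categories/nodes; only edges change
    withSeed(seed, {
      for (r in seq_len(replicates)) {
        g <- igraph::rewire(g0, igraph::keeping_degseq(loops = FALSE,
                                                       niter = nSwaps))
        rc <- igraphAsCDN(g, grayable)
        nulls[r] <- grayEdgeFraction(rc)$fraction
      }
    })
  } else {
    if (is.null(arInputs) ||
        !all(c("sets", "ic", "categories", "ontology") %in% names(arInputs)))
      stop("ar requires arInputs with sets, ic, categories and ontology")
    simcut <- arInputs$simcut %||% cdn@simcut
    fraction <- arInputs$fraction %||% 0.5
    ont <- arInputs$ontology
    micaM <- micaICMatrix(ont, arInputs$ic)
    withSeed(seed, {
      repSeeds <- sample.int(.Machine$integer.max - 1L, replicates)
      for (r in seq_len(replicates)) {
        rsets <- annotationRandomize(arInputs$sets, fraction, ont,
                                     seed = repSeeds[r])
        sim <- pairwiseSimilarity(ont, arInputs$ic, rsets, micaM = micaM)
        rc <- buildCDN(sim, arInputs$categories, simcut = simcut)
        nulls[r] <- if (nrow(rc@edges)) grayEdgeFraction(rc)$fraction
                    else NA_real_
      }
    })
    if (anyNA(nulls)) {
      warning(sum(is.na(nulls)), " replicate(s) produced an edgeless ",
              "network and were dropped from the null")
      nulls <- nulls[!is.na(nulls)]
      replicates <- length(nulls)
    }
  }

  hits <- sum(nulls <= obs$fraction)
  p <- (1 + hits) / (1 + replicates)
  bound <- if (hits == 0L) sprintf("p < %.3g", 1 / replicates) else NA_character_
  new("GEFReport", observed = obs$fraction,
      grayEdges = obs$grayEdges, totalEdges = obs$totalEdges,
      nulls = nulls, pValue = p, bound = bound, method = method,
      seed = seed)
}

#' Calibration of the GEF permutation p-value under a shuffled-label null
#'
#' Checks that the empirical p-values of [gefSignificance()] are honest:
#' each calibration draw destroys the category-network association by
#' shuffling the node labels and randomizing the observed network itself
#' with one degree-preserving rewiring pass, so the observed GEF and the
#' edge-randomized null GEFs are exchangeable draws and the resulting
#' p-values should be approximately uniform on (0, 1].
#'
#' Because the GEF lives on a discrete lattice, ties between the observed
#' and null values are common, and the deliberately conservative
#' `<=`-with-add-one convention of [gefSignificance()] then makes reported
#' p-values stochastically larger than uniform. The calibration therefore
#' ranks each observed value among its nulls with the standard randomized
#' tie-breaking, which is exactly uniform under exchangeability; the
#' conservative reported p-value is by construction at least as large.
#'
#' @param cdn a [CDN-class] with at least two edges.
#' @param nOuter number of calibration p-values to draw.
#' @param innerReplicates null replicates per p-value.
#' @param seed RNG seed (all draw seeds derive from it).
#' @return list with `pValues` (length `nOuter`, randomized-rank) and
#'   `ks`, the two-sided Kolmogorov-Smirnov distance of the p-values from
#'   the uniform distribution.
#' @export
gefPValueCalibration <- function(cdn, nOuter = 200L, innerReplicates = 99L,
                                 seed = 1L) {
  nOuter <- as.integer(nOuter)
  ps <- withSeed(seed, {
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * nOuter),
                    ncol = 3L)
    vapply(seq_len(nOuter), function(i) {
      sh <- cdn
      perm <- withSeed(seeds[i, 1L], sample(length(cdn@nodes)))
      sh@categories <- setNames(cdn@categories[perm], cdn@nodes)
      obs <- edgeRandomize(sh, seed = seeds[i, 2L])
      rep <- gefSignificance(obs, "er", replicates = innerReplicates,
                             seed = seeds[i, 3L])
      below <- sum(rep@nulls < rep@observed)
      ties <- sum(rep@nulls == rep@observed)
      (below + sample.int(ties + 1L, 1L)) / (innerReplicates + 1L)
    }, 0)
  })
  s <- sort(ps)
  steps <- seq_along(s) / length(s)
  ks <- max(abs(steps - s), abs(steps - 1 / length(s) - s))
  list(pValues = ps, ks = ks)
}

#' Export / import a disease network
#'
#' `"edge-tsv"` is lossless: `#simcut` and `#node` header comments carry
#' the cutoff and per-node category sets, followed by
#' `disease_a  disease_b  weight  is_gray` rows; [importCDN()] restores an
#' identical network. `"sif"` writes Cytoscape simple-interaction lines
#' (`a sim b`); `"graphml"` writes GraphML with weight and category
#' attributes. An empty network yields a valid empty document.
#'
#' @param cdn a [CDN-class].
#' @param path output file.
#' @param format `"edge-tsv"`, `"sif"` or `"graphml"`.
#' @export
exportGraph <- function(cdn, path, format = c("edge-tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("#simcut\t%.17g", cdn@simcut), con)
    for (nd in cdn@nodes)
      writeLines(sprintf("#node\t%s\t%s", nd,
                         paste(cdn@categories[[nd]], collapse = "|")), con)
    writeLines("disease_a\tdisease_b\tweight\tis_gray", con)
    if (nrow(cdn@edges)) {
      gray <- edgeIsGray(cdn)
      writeLines(sprintf("%s\t%s\t%s\t%s", cdn@edges$a, cdn@edges$b,
                         ifelse(is.na(cdn@edges$weight), "NA",
                                sprintf("%.17g", cdn@edges$weight)),
                         ifelse(gray, "true", "false")), con)
    }
  } else if (format == "sif") {
    lines <- if (nrow(cdn@edges))
      sprintf("%s\tsim\t%s", cdn@edges$a, cdn@edges$b) else character()
    writeLines(lines, path)
  } else {
    g <- cdnAsIgraph(cdn)
    if (length(cdn@nodes))
      igraph::V(g)$categories <- vapply(cdn@categories[cdn@nodes], paste,
                                        "", collapse = "|")
    if (nrow(cdn@edges))
      igraph::E(g)$weight <- cdn@edges$weight
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportGraph
#' @export
importCDN <- function(path) {
  lines <- readLines(path)
  simcut <- as.numeric(sub("^#simcut\t", "",
                           lines[startsWith(lines, "#simcut\t")]))
  nodeLines <- strsplit(sub("^#node\t", "",
                            lines[startsWith(lines, "#node\t")]),
                        "\t", fixed = TRUE)
  nodes <- vapply(nodeLines, `[[`, "", 1L)
  categories <- setNames(lapply(nodeLines, function(p) {
    if (length(p) < 2L || !nzchar(p[2])) character()
    else strsplit(p[2], "|", fixed = TRUE)[[1]]
  }), nodes)
  body <- lines[!startsWith(lines, "#")][-1]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[[`, "", 1L),
                        b = vapply(parts, `[[`, "", 2L),
                        weight = as.numeric(vapply(parts, `[[`, "", 3L)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(), b = character(), weight = numeric())
  }
  new("CDN", nodes = nodes, categories = categories, edges = edges,
      simcut = simcut)
}
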