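## Disease-tagged corpus assembly: abstract record I/O, MeSH descriptor
## filtering and attachment of recognized mentions.

#' Read / write abstract records
#'
#' Two equivalent dialects: line-delimited JSON with fields `id`, `title`,
#' `abstract` and `mesh` (array of MeSH descriptor ids), or a 4-column TSV
#' (`id`, `title`, `abstract`, `mesh`, the last `|`-separated). The format
#' is chosen from the `format` argument or the file extension
#' (`.jsonl`/`.ndjson` vs `.tsv`).
#'
#' @param path file path.
#' @param format "jsonl", "tsv" or NULL to infer from the extension.
#' @return data.frame with columns `id`, `title`, `abstract` (character)
#'   and `mesh` (list of character vectors).
#' @export
readAbstracts <- function(path, format = NULL) {
  format <- format %||% inferRecordFormat(path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    data.frame(
      id = vapply(recs, function(r) as.character(r$id), ""),
      title = vapply(recs, function(r) as.character(r$title %||% ""), ""),
      abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), ""),
      mesh = I(lapply(recs, function(r) as.character(unlist(r$mesh)))),
      stringsAsFactors = FALSE)
  } else if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                     colClasses = "character")
    data.frame(id = df$id, title = df$title, abstract = df$abstract,
               mesh = I(lapply(strsplit(df$mesh, "|", fixed = TRUE),
                               function(x) x[nzchar(x)])),
               stringsAsFactors = FALSE)
  } else stop("unknown abstract record format: ", format)
}

#' @rdname readAbstracts
#' @param records a record data.frame as returned by `readAbstracts`.
#' @export
writeAbstracts <- function(records, path, format = NULL) {
  format <- format %||% inferRecordFormat(path)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(k) {
      jsonlite::toJSON(list(id = records$id[k], title = records$title[k],
                            abstract = records$abstract[k],
                            mesh = records$mesh[[k]]),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, path)
  } else if (format == "tsv") {
    df <- data.frame(id = records$id, title = records$title,
                     abstract = records$abstract,
                     mesh = vapply(records$mesh, paste, "", collapse = "|"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unknown abstract record format: ", format)
  invisible(path)
}

inferRecordFormat <- function(path) {
  if (grepl("\\.(jsonl|ndjson|json)$", path)) "jsonl"
  else if (grepl("\\.(tsv|txt)$", path)) "tsv"
  else stop("cannot infer record format from path: ", path)
}

#' Assemble a disease corpus by MeSH descriptor filtering
#'
#' An abstract is retained iff it has a non-empty body and carries at least
#' one whitelisted disease descriptor; it is then assigned to every
#' whitelisted descriptor it carries (independently of how many MeSH terms
#' tag it, and ignoring major-topic flags). Whitelist diseases matching no
#' abstract are dropped from the corpus with a warning, decrementing the
#' disease count.
#'
#' @param records abstract record data.frame ([readAbstracts()]).
#' @param whitelist character vector of disease MeSH descriptor ids.
#' @return A [DiseaseCorpus-class] (mentions not yet attached).
#' @export
filterByMesh <- function(records, whitelist) {
  whitelist <- unique(as.character(whitelist))
  if (!length(whitelist)) stop("whitelist must be non-empty")
  keepBody <- nzchar(records$abstract)
  dmap <- setNames(vector("list", length(whitelist)), whitelist)
  for (k in which(keepBody)) {
    hits <- intersect(records$mesh[[k]], whitelist)
    for (d in hits) dmap[[d]] <- c(dmap[[d]], records$id[k])
  }
  dmap <- lapply(dmap, unique)
  empty <- names(dmap)[lengths(dmap) == 0L]
  if (length(empty)) {
    warning("whitelist diseases with no abstracts dropped: ",
            paste(empty, collapse = ", "))
    dmap <- dmap[lengths(dmap) > 0L]
  }
  new("DiseaseCorpus", diseaseAbstracts = dmap, mentions = list(),
      nDiseases = length(dmap))
}

#' Attach recognized mentions to a corpus
#'
#' Populates the per-abstract term sets from a mention table, deduplicated
#' to abstract-level presence (five mentions of one term in one abstract
#' count once). Mentions for abstracts not in the corpus are skipped with a
#' warning.
#'
#' @param corpus a [DiseaseCorpus-class].
#' @param mentions mention data.frame ([recognizeAbstracts()]).
#' @return the corpus with `mentions` populated.
#' @export
attachMentions <- function(corpus, mentions) {
  known <- unique(unlist(corpus@diseaseAbstracts, use.names = FALSE))
  if (is.null(mentions) || !nrow(mentions)) return(corpus)
  orphan <- !(mentions$abstract_id %in% known)
  if (any(orphan)) {
    warning(sum(orphan), " mention(s) for unknown abstracts skipped")
    mentions <- mentions[!orphan, , drop = FALSE]
  }
  sets <- lapply(split(mentions$term, mentions$abstract_id), unique)
  cur <- corpus@mentions
  for (a in names(sets)) cur[[a]] <- unique(c(cur[[a]], sets[[a]]))
  corpus@mentions <- cur
  corpus
}

#' Corpus accessors
#'
#' @param corpus a [DiseaseCorpus-class].
#' @return `diseaseIds`: disease identifiers; `nDiseases`: the disease
#'   count T_D; `diseaseAbstracts`: abstract ids per disease;
#'   `abstractTerms`: recognized term set of one abstract (empty if none).
#' @export
diseaseIds <- function(corpus) names(corpus@diseaseAbstracts)

#' @rdname diseaseIds
#' @export
nDiseases <- function(corpus) corpus@nDiseases

#' @rdname diseaseIds
#' @param disease a disease id.
#' @export
diseaseAbstracts <- function(corpus, disease) {
  if (!(disease %in% names(corpus@diseaseAbstracts)))
    stop("unknown disease: ", disease)
  corpus@diseaseAbstracts[[disease]]
}

#' @rdname diseaseIds
#' @param abstractId an abstract id.
#' @export
abstractTerms <- function(corpus, abstractId) {
  corpus@mentions[[abstractId]] %||% character()
}

#' Per-disease raw annotation sets
#'
#' Union of the recognized term sets over all abstracts of each disease —
#' the unfiltered input to the annotation filter.
#'
#' @param corpus a [DiseaseCorpus-class] with mentions attached.
#' @return named list: disease id -> character term ids.
#' @export
rawDiseaseTerms <- function(corpus) {
  lapply(corpus@diseaseAbstracts, function(abs) {
    unique(unlist(corpus@mentions[abs], use.names = FALSE)) %||% character()
  })
}

#' Per-abstract annotation sets of the whole corpus
#'
#' One term set per corpus abstract (abstracts without mentions give empty
#' sets), the item list from which abstract-level information content is
#' computed.
#'
#' @param corpus a [DiseaseCorpus-class] with mentions attached.
#' @return named list: abstract id -> character term ids.
#' @export
abstractAnnotations <- function(corpus) {
  ids <- unique(unlist(corpus@diseaseAbstracts, use.names = FALSE))
  setNames(lapply(ids, function(a) corpus@mentions[[a]] %||% character()), ids)
}
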