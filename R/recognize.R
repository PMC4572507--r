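## Dictionary-based concept recognition over term labels and synonyms.

#' Normalize a phrase for dictionary lookup
#'
#' Lowercases, replaces punctuation with spaces and collapses whitespace.
#' Idempotent and deterministic; no stemming by default (the downstream
#' frequency/specificity filter is designed to absorb recognizer noise, so
#' the recognizer errs conservative).
#'
#' @param text character vector.
#' @return normalized character vector.
#' @examples
#' normalizeText("Large  Head.")   # "large head"
#' normalizeText("short-finger")   # "short finger"
#' @export
normalizeText <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Build the normalized-phrase index of an ontology
#'
#' Indexes every term label and every synonym (all scopes) under its
#' normalized form. A phrase naming several terms keeps the full set; the
#' recognizer emits one mention per mapped term.
#'
#' @param ontology an [Ontology-class].
#' @param maxTokens longest phrase window, in tokens (default 7, which
#'   covers phenotype label lengths in practice).
#' @return A [LexicalIndex-class].
#' @export
buildLexicalIndex <- function(ontology, maxTokens = 7L) {
  entries <- new.env(parent = emptyenv())
  add <- function(phrase, term) {
    key <- normalizeText(phrase)
    if (!nzchar(key)) return()
    if (lengths(gregexpr("[^ ]+", key)) > maxTokens) return()
    cur <- entries[[key]]
    entries[[key]] <- unique(c(cur, term))
  }
  for (t in ontology@terms) {
    add(ontology@labels[[t]], t)
    for (s in ontology@synonyms[[t]]) add(s, t)
  }
  lst <- as.list(entries)
  new("LexicalIndex", entries = lst,
      maxTokens = as.integer(maxTokens))
}

## token spans of a string: matrix with start/end (1-based inclusive) and
## the lowercased token text
tokenSpans <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L)
    return(list(start = integer(), end = integer(), token = character()))
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  list(start = start, end = end,
       token = tolower(substring(text, start, end)))
}

#' Recognize ontology-term mentions in text
#'
#' Greedy longest-match, left-to-right, non-overlapping scan over token
#' windows of up to `maxTokens` tokens. An ambiguous phrase yields one
#' mention per mapped term at the same span. No negation handling: "no
#' headache" still yields a headache mention by design.
#'
#' @param index a [LexicalIndex-class].
#' @param abstractId identifier attached to the mentions.
#' @param text the text to scan.
#' @return data.frame with columns `abstract_id`, `term`, `start`, `end`
#'   (0-based, half-open character offsets) and `surface` (the matched
#'   substring).
#' @export
recognizeText <- function(index, abstractId, text) {
  stopIfNot1String(abstractId, "abstractId")
  toks <- tokenSpans(text)
  n <- length(toks$token)
  outTerm <- character(); outStart <- integer()
  outEnd <- integer(); outSurface <- character()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq.int(min(index@maxTokens, n - i + 1L), 1L)) {
      key <- paste(toks$token[i:(i + len - 1L)], collapse = " ")
      terms <- index@entries[[key]]
      if (!is.null(terms)) {
        s <- toks$start[i]; e <- toks$end[i + len - 1L]
        outTerm <- c(outTerm, terms)
        outStart <- c(outStart, rep(s - 1L, length(terms)))
        outEnd <- c(outEnd, rep(e, length(terms)))
        outSurface <- c(outSurface, rep(substring(text, s, e), length(terms)))
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  data.frame(abstract_id = rep(abstractId, length(outTerm)),
             term = outTerm, start = outStart, end = outEnd,
             surface = outSurface, stringsAsFactors = FALSE)
}

#' Recognize mentions across a set of abstract records
#'
#' Scans the title and the body of each record separately (so no phrase can
#' straddle the title/body boundary) and reports body offsets relative to
#' the record's `title` + newline + `body` concatenation.
#'
#' @param index a [LexicalIndex-class].
#' @param records a data.frame of abstract records as returned by
#'   [readAbstracts()] (columns `id`, `title`, `abstract`).
#' @return a mention data.frame as in [recognizeText()].
#' @export
recognizeAbstracts <- function(index, records) {
  out <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    mt <- recognizeText(index, records$id[k], records$title[k])
    mb <- recognizeText(index, records$id[k], records$abstract[k])
    if (nrow(mb)) {
      off <- nchar(records$title[k]) + 1L
      mb$start <- mb$start + off
      mb$end <- mb$end + off
    }
    out[[k]] <- rbind(mt, mb)
  }
  do.call(rbind, out)
}

#' Write / read mentions as TSV
#'
#' Columns: abstract_id, term_id, start, end, surface.
#'
#' @param mentions mention data.frame.
#' @param path file path.
#' @export
writeMentions <- function(mentions, path) {
  df <- data.frame(abstract_id = mentions$abstract_id,
                   term_id = mentions$term, start = mentions$start,
                   end = mentions$end, surface = mentions$surface)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMentions
#' @export
readMentions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(abstract_id = as.character(df$abstract_id),
             term = as.character(df$term_id),
             start = as.integer(df$start), end = as.integer(df$end),
             surface = as.character(df$surface), stringsAsFactors = FALSE)
}
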