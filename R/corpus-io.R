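# Corpus ingestion: PubMed XML, JSON Lines fallback, and deterministic
# rule-based sentence segmentation.

# Abbreviations that suppress a sentence boundary after their period.
ABBREV_GUARD <- "\\b(Fig|Figs|al|e\\.g|i\\.e|vs|cf|Dr|Prof|No|St|approx|ca)\\.$"

# Trimmed sentence intervals (0-based half-open) for each text.
# A boundary is a whitespace gap preceded by terminal punctuation [.!?]
# and followed by an uppercase letter or digit, unless the preceding
# text ends in a guarded abbreviation. Texts without terminal
# punctuation yield a single sentence covering all non-whitespace.
segmentIntervals <- function(texts) {
  out <- vector("list", length(texts))
  gaps <- gregexpr("(?<=[.!?])\\s+(?=[A-Z0-9])", texts, perl = TRUE)
  for (i in seq_along(texts)) {
    txt <- texts[i]
    n <- nchar(txt)
    if (!nzchar(trimws(txt))) {
      out[[i]] <- data.frame(item = integer(0), start = integer(0),
                             end = integer(0))
      next
    }
    g <- gaps[[i]]
    cut0 <- integer(0); cut1 <- integer(0)
    if (g[1] != -1L) {
      gs <- as.integer(g) - 1L                    # 0-based gap start
      ge <- gs + attr(g, "match.length")
      pre <- substr0(txt, pmax(0L, gs - 10L), gs)
      keep <- !grepl(ABBREV_GUARD, pre)
      cut0 <- gs[keep]; cut1 <- ge[keep]
    }
    segStart <- c(0L, cut1)
    segEnd <- c(cut0, n)
    seg <- substr0(txt, segStart, segEnd)
    lead <- attr(regexpr("^\\s*", seg), "match.length")
    trail <- attr(regexpr("\\s*$", seg), "match.length")
    s <- segStart + lead
    e <- segEnd - trail
    ok <- e > s
    out[[i]] <- data.frame(item = i, start = s[ok], end = e[ok])
  }
  do.call(rbind, out)
}

# Build the sentence table for a document data.frame: title is sentence 1,
# abstract sentences follow, all intervals into paste(title, abstract).
buildSentenceTable <- function(docs) {
  if (!nrow(docs))
    return(data.frame(doc_id = character(0), sentence_index = integer(0),
                      start = integer(0), end = integer(0)))
  titleLen <- nchar(docs$title)
  tLead <- attr(regexpr("^\\s*", docs$title), "match.length")
  tTrail <- attr(regexpr("\\s*$", docs$title), "match.length")
  tRows <- data.frame(doc_id = docs$doc_id, sentence_index = 1L,
                      start = tLead, end = titleLen - tTrail,
                      stringsAsFactors = FALSE)
  tRows <- tRows[tRows$end > tRows$start, , drop = FALSE]
  aInt <- segmentIntervals(docs$abstract)
  if (nrow(aInt)) {
    off <- titleLen[aInt$item] + 1L     # the joining space
    idx <- stats::ave(aInt$item, aInt$item, FUN = seq_along)
    aRows <- data.frame(doc_id = docs$doc_id[aInt$item],
                        sentence_index = idx + 1L,
                        start = aInt$start + off, end = aInt$end + off,
                        stringsAsFactors = FALSE)
  } else {
    aRows <- tRows[0, ]
  }
  out <- rbind(tRows, aRows)
  out[order(match(out$doc_id, docs$doc_id), out$sentence_index), ,
      drop = FALSE]
}

#' Construct a Corpus from a document table
#'
#' Sentence segmentation is applied immediately: the title becomes
#' sentence 1 and the abstract is split at terminal punctuation followed
#' by whitespace and an uppercase letter or digit, with an abbreviation
#' guard list (Fig., et al., e.g., ...). Segmentation is deterministic
#' and idempotent.
#'
#' @param documents data.frame with character columns \code{doc_id},
#'   \code{title}, \code{abstract}.
#' @return a [Corpus-class] object.
#' @examples
#' corp <- newCorpus(data.frame(doc_id = "d1", title = "A study.",
#'                              abstract = "VEGFA rose. IL6 fell."))
#' sentenceTable(corp)
#' @export
newCorpus <- function(documents) {
  need <- c("doc_id", "title", "abstract")
  if (!is.data.frame(documents) || !all(need %in% names(documents)))
    stop("documents must be a data.frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  documents <- documents[, need, drop = FALSE]
  for (cc in need) documents[[cc]] <- as.character(documents[[cc]])
  documents$abstract[is.na(documents$abstract)] <- ""
  if (anyDuplicated(documents$doc_id))
    stop("duplicate doc_id: ",
         paste(unique(documents$doc_id[duplicated(documents$doc_id)]),
               collapse = ", "), call. = FALSE)
  rownames(documents) <- NULL
  sent <- buildSentenceTable(documents)
  rownames(sent) <- NULL
  new("Corpus", documents = documents, sentences = sent)
}

#' Re-run sentence segmentation on a corpus
#'
#' @param corpus a [Corpus-class]
#' @return the corpus with its sentence table rebuilt (idempotent).
#' @export
segmentSentences <- function(corpus) {
  newCorpus(corpus@documents)
}

#' Read a PubMed/MEDLINE XML article set
#'
#' One document per \code{PubmedArticle} element, in file order. Articles
#' without an abstract are retained with empty abstract text. Multiple
#' \code{AbstractText} sections (structured abstracts) are joined with a
#' space.
#'
#' @param path path to a PubmedArticleSet XML file.
#' @return a [Corpus-class]
#' @export
readPubmedXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//Article/ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Article/Abstract/AbstractText")
    data.frame(doc_id = pmid, title = title,
               abstract = paste(xml2::xml_text(abst), collapse = " "),
               stringsAsFactors = FALSE)
  })
  docs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(doc_id = character(0), title = character(0),
               abstract = character(0))
  docs$title[is.na(docs$title)] <- ""
  newCorpus(docs)
}

#' Read a JSON Lines corpus
#'
#' Each line is a JSON object with keys \code{doc_id}, \code{title} and
#' \code{abstract}. Sentence intervals present in a dump are ignored and
#' recomputed, so a write/read round trip reproduces the corpus exactly.
#'
#' @param path path to the JSON Lines file.
#' @return a [Corpus-class]
#' @export
readCorpusJsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("invalid JSON on line ", i, ": ", conditionMessage(e),
           call. = FALSE))
    miss <- setdiff(c("doc_id", "title", "abstract"), names(rec))
    if (length(miss))
      stop("line ", i, " missing key(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    recs[[i]] <- data.frame(doc_id = rec$doc_id, title = rec$title,
                            abstract = rec$abstract,
                            stringsAsFactors = FALSE)
  }
  docs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(doc_id = character(0), title = character(0),
               abstract = character(0))
  newCorpus(docs)
}

#' Write a corpus as JSON Lines
#'
#' Emits one object per document with its sentence intervals (0-based
#' half-open pairs) for downstream consumers.
#'
#' @param corpus a [Corpus-class]
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeCorpusJsonl <- function(corpus, path) {
  d <- corpus@documents
  s <- corpus@sentences
  bySent <- split(s[, c("start", "end")], s$doc_id)
  lines <- vapply(seq_len(nrow(d)), function(i) {
    si <- bySent[[d$doc_id[i]]]
    ints <- if (is.null(si)) list() else
      unname(lapply(seq_len(nrow(si)), function(j)
        c(si$start[j], si$end[j])))
    jsonlite::toJSON(list(doc_id = d$doc_id[i], title = d$title[i],
                          abstract = d$abstract[i], sentences = ints),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
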