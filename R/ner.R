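# Dictionary-based gene mention tagging: case-insensitive, hyphen/space
# equivalent, token-boundary anchored, longest-match; plus pattern-based
# conjunction resolution ("IL-2, -4 and -6" -> IL2, IL4, IL6).

#' Build a gene lexicon from a table
#'
#' Aliases (canonical symbol plus synonyms) are indexed under a normalized
#' key (case-folded, non-alphanumerics removed) so that \code{IL-6},
#' \code{il 6} and \code{IL6} all match. Keys that map to more than one
#' gene after normalization are ambiguous and dropped from the index with
#' a message. An optional stop list removes aliases that collide with
#' common words.
#'
#' @param entries data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{synonyms} (pipe-separated, may be empty).
#' @param stopList character vector of alias surface forms to exclude.
#' @return a [GeneLexicon-class]
#' @export
makeLexicon <- function(entries, stopList = character(0)) {
  need <- c("gene_id", "symbol", "synonyms")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    stop("entries must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  entries <- entries[, need, drop = FALSE]
  for (cc in need) entries[[cc]] <- as.character(entries[[cc]])
  entries$synonyms[is.na(entries$synonyms)] <- ""
  if (anyDuplicated(entries$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(entries$gene_id[duplicated(entries$gene_id)]),
               collapse = ", "), call. = FALSE)
  syn <- strsplit(entries$synonyms, "|", fixed = TRUE)
  nsyn <- lengths(syn)
  alias <- c(entries$symbol, unlist(syn))
  gid <- c(entries$gene_id, rep(entries$gene_id, nsyn))
  keep <- nzchar(alias)
  alias <- alias[keep]; gid <- gid[keep]
  stop_keys <- normalizeKey(stopList)
  idx <- data.frame(key = normalizeKey(alias), gene_id = gid,
                    alias = alias, stringsAsFactors = FALSE)
  idx <- idx[nzchar(idx$key) & !(idx$key %in% stop_keys), , drop = FALSE]
  idx <- idx[!duplicated(paste(idx$key, idx$gene_id)), , drop = FALSE]
  amb <- unique(idx$key[duplicated(idx$key)])
  if (length(amb)) {
    message(length(amb),
            " ambiguous alias(es) dropped from the match index: ",
            paste(utils::head(amb, 5), collapse = ", "),
            if (length(amb) > 5) ", ..." else "")
    idx <- idx[!(idx$key %in% amb), , drop = FALSE]
  }
  rownames(idx) <- NULL
  new("GeneLexicon", entries = entries, index = idx,
      dropped = as.character(amb))
}

#' Read a gene lexicon TSV
#'
#' Expects tab-separated columns \code{gene_id}, \code{symbol},
#' \code{synonyms} (pipe-separated), emulating an NCBI gene_info extract.
#'
#' @param path path to the TSV file.
#' @param stopListPath optional path to a one-alias-per-line stop list.
#' @return a [GeneLexicon-class]
#' @export
readLexicon <- function(path, stopListPath = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  stopList <- if (is.null(stopListPath)) character(0) else {
    sl <- readLines(stopListPath, warn = FALSE)
    sl[nzchar(trimws(sl))]
  }
  makeLexicon(tab, stopList = stopList)
}

#' Write a gene lexicon TSV
#' @param lexicon a [GeneLexicon-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeLexicon <- function(lexicon, path) {
  utils::write.table(lexicon@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Maximum surface length in tokens an alias can span. A one-token alias
# like "IL6" may surface hyphenated or spaced ("IL-6", "il 6"), so the
# bound is the larger of the alias's own token count and the number of
# letter/digit segments in its normalized key.
maxAliasTokens <- function(index) {
  if (!nrow(index)) return(1L)
  ntok <- lengths(gregexpr("[A-Za-z0-9]+", index$alias))
  nseg <- lengths(gregexpr("[a-z]+|[0-9]+", index$key))
  max(1L, ntok, nseg)
}

# Core matcher used for gene mentions and disease phrases alike.
# `strings` are sentence texts; returns matches with 0-based half-open
# character spans within each string. Longest match wins; overlapping
# shorter or later candidates are discarded left to right.
matchPhrases <- function(strings, index, maxTokens) {
  toks <- tokenizeAll(strings)
  empty <- data.frame(item = integer(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      surface = character(0), stringsAsFactors = FALSE)
  if (!nrow(toks)) return(empty)
  key <- normalizeKey(toks$token)
  cands <- vector("list", maxTokens)
  nt <- nrow(toks)
  gram <- key
  for (n in seq_len(maxTokens)) {
    if (n > nt) break
    if (n > 1L) {
      # key of tokens i..i+n-1; items are contiguous, so an n-gram stays
      # within one sentence iff its first and last token share the item
      gram <- paste0(gram[seq_len(nt - n + 1L)], key[n:nt])
    }
    valid <- toks$item[seq_len(nt - n + 1L)] == toks$item[n:nt]
    hit <- match(gram, index$key)
    pos <- which(!is.na(hit) & valid)
    if (length(pos))
      cands[[n]] <- data.frame(item = toks$item[pos],
                               start = toks$start[pos],
                               end = toks$end[pos + n - 1L],
                               gene_id = index$gene_id[hit[pos]],
                               ntok = n, stringsAsFactors = FALSE)
  }
  cands <- do.call(rbind, cands)
  if (is.null(cands) || !nrow(cands)) return(empty)
  # greedy longest-match, left to right, non-overlapping within an item
  cands <- cands[order(cands$item, cands$start, -cands$ntok), , drop = FALSE]
  keep <- logical(nrow(cands))
  lastItem <- -1L; lastEnd <- -1L
  for (i in seq_len(nrow(cands))) {
    if (cands$item[i] != lastItem) { lastItem <- cands$item[i]; lastEnd <- -1L }
    if (cands$start[i] >= lastEnd) { keep[i] <- TRUE; lastEnd <- cands$end[i] }
  }
  cands <- cands[keep, , drop = FALSE]
  cands$surface <- substr0(strings[cands$item], cands$start, cands$end)
  cands$ntok <- NULL
  rownames(cands) <- NULL
  cands
}

# Sentence strings of a corpus, with bookkeeping columns.
sentenceStrings <- function(corpus) {
  s <- corpus@sentences
  txt <- documentText(corpus)
  s$text <- substr0(txt[s$doc_id], s$start, s$end)
  s
}

#' Tag gene mentions in a corpus
#'
#' Deterministic dictionary matching of lexicon aliases against every
#' sentence (titles are sentence 1 and scanned by default). Matching is
#' case-insensitive with hyphen/space equivalence and anchored at token
#' boundaries; the longest match wins and emitted spans do not overlap.
#' Coordinated elided forms are expanded afterwards when
#' \code{resolveConjunctions = TRUE} (see [resolveConjunctions()]).
#'
#' @param corpus a [Corpus-class]
#' @param lexicon a [GeneLexicon-class]
#' @param scanTitles scan titles (sentence 1) as well as abstracts.
#' @param conjunctions expand coordinated elided mentions.
#' @return data.frame with columns \code{doc_id}, \code{sentence_index},
#'   \code{start}, \code{end} (0-based half-open spans into the joined
#'   title+abstract text), \code{surface}, \code{gene_id},
#'   \code{expanded} (TRUE for conjunction-derived mentions, whose spans
#'   point at the eliding fragment).
#' @export
tagMentions <- function(corpus, lexicon, scanTitles = TRUE,
                        conjunctions = TRUE) {
  s <- sentenceStrings(corpus)
  if (!scanTitles) s <- s[s$sentence_index != 1L, , drop = FALSE]
  hits <- matchPhrases(s$text, lexicon@index, maxAliasTokens(lexicon@index))
  out <- data.frame(doc_id = s$doc_id[hits$item],
                    sentence_index = s$sentence_index[hits$item],
                    start = hits$start + s$start[hits$item],
                    end = hits$end + s$start[hits$item],
                    surface = hits$surface, gene_id = hits$gene_id,
                    expanded = rep(FALSE, nrow(hits)),
                    stringsAsFactors = FALSE)
  if (conjunctions && nrow(out)) {
    exp <- expandConjunctions(s, hits, lexicon)
    if (nrow(exp)) out <- rbind(out, exp)
    out <- out[order(match(out$doc_id, corpus@documents$doc_id),
                     out$sentence_index, out$start, out$expanded), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Fragment list following an anchor mention: ", -4", "/9", " and -6" ...
CONJ_FRAGMENT <- "^(\\s*(?:[,/]|and|or)\\s*-?\\s*)([0-9]+|[A-Z])(?![A-Za-z0-9])"

# Split an anchor surface into (base, suffix): numeric suffix preferred,
# else a single trailing letter after a hyphen ("VEGF-A" -> VEGF + A).
anchorBase <- function(surface) {
  m <- regmatches(surface, regexec("^(.*[^0-9])[-\\s]?([0-9]+)$", surface))[[1]]
  if (length(m) == 3L) return(sub("[-\\s]+$", "", m[2]))
  m <- regmatches(surface, regexec("^(.*[A-Za-z0-9])-([A-Za-z])$", surface))[[1]]
  if (length(m) == 3L) return(m[2])
  NA_character_
}

# Internal worker shared by tagMentions and resolveConjunctions.
# `s` are sentence rows (with $text, $doc_id, $sentence_index, $start);
# `hits` are matcher rows with sentence-local spans.
expandConjunctions <- function(s, hits, lexicon) {
  empty <- data.frame(doc_id = character(0), sentence_index = integer(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), gene_id = character(0),
                      expanded = logical(0), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  res <- list()
  for (i in seq_len(nrow(hits))) {
    base <- anchorBase(hits$surface[i])
    if (is.na(base) || !nzchar(base)) next
    txt <- s$text[hits$item[i]]
    pos <- hits$end[i]
    repeat {
      rest <- substr0(txt, pos, nchar(txt))
      m <- regexpr(CONJ_FRAGMENT, rest, perl = TRUE)
      if (m == -1L) break
      cap <- regmatches(rest, regexec(CONJ_FRAGMENT, rest, perl = TRUE))[[1]]
      sufStart <- pos + nchar(cap[2])        # skip separator
      sufEnd <- sufStart + nchar(cap[3])
      hit <- match(normalizeKey(paste0(base, cap[3])), lexicon@index$key)
      if (!is.na(hit))
        res[[length(res) + 1L]] <- data.frame(
          doc_id = s$doc_id[hits$item[i]],
          sentence_index = s$sentence_index[hits$item[i]],
          start = sufStart + s$start[hits$item[i]],
          end = sufEnd + s$start[hits$item[i]],
          surface = cap[3], gene_id = lexicon@index$gene_id[hit],
          expanded = TRUE, stringsAsFactors = FALSE)
      pos <- sufEnd
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[!duplicated(paste(out$doc_id, out$sentence_index, out$start,
                        out$gene_id)), , drop = FALSE]
}

#' Expand coordinated elided gene mentions in one sentence
#'
#' Applies the conjunction patterns ("IL-2, -4 and -6", "MMP-2/9",
#' "VEGF-A/B") to mentions already tagged in a sentence: the suffix of an
#' anchored mention is replaced by each coordinated suffix, the candidate
#' is re-validated against the lexicon, and valid expansions are emitted
#' as mentions whose spans point at the eliding fragment. Sentences
#' without a coordination pattern are returned unchanged.
#'
#' @param sentenceText the sentence string.
#' @param mentions data.frame of mentions in this sentence with columns
#'   \code{start}, \code{end}, \code{surface}, \code{gene_id} (spans
#'   local to \code{sentenceText}).
#' @param lexicon a [GeneLexicon-class]
#' @return \code{mentions} plus any expanded mentions (column
#'   \code{expanded} marks them).
#' @export
resolveConjunctions <- function(sentenceText, mentions, lexicon) {
  if (!nrow(mentions)) {
    mentions$expanded <- logical(0)
    return(mentions)
  }
  if (is.null(mentions$expanded)) mentions$expanded <- FALSE
  s <- data.frame(doc_id = "", sentence_index = 1L, start = 0L,
                  text = sentenceText, stringsAsFactors = FALSE)
  hits <- data.frame(item = 1L, start = mentions$start,
                     end = mentions$end, surface = mentions$surface,
                     gene_id = mentions$gene_id, stringsAsFactors = FALSE)
  exp <- expandConjunctions(s, hits, lexicon)
  if (!nrow(exp)) return(mentions)
  add <- data.frame(start = exp$start, end = exp$end,
                    surface = exp$surface, gene_id = exp$gene_id,
                    expanded = TRUE, stringsAsFactors = FALSE)
  common <- intersect(names(mentions), names(add))
  out <- rbind(mentions[, common, drop = FALSE], add[, common, drop = FALSE])
  out[order(out$start, out$expanded), , drop = FALSE]
}

#' Write tagged mentions as TSV
#' @param mentions mention data.frame from [tagMentions()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMentions <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
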