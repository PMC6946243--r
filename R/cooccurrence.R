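# Gene-disease association scoring: document-level binary co-occurrence
# counts and the exact hypergeometric upper-tail statistic.

#' Exact hypergeometric upper tail
#'
#' Probability of observing at least \code{k} documents citing both a
#' gene and the disease when the \code{m} gene documents and \code{n}
#' disease documents are placed independently at random among \code{N}
#' documents:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(m,n)}
#'   \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}}.}
#' Computed in log space (log-binomials with a log-sum-exp reduction);
#' whichever tail has fewer terms is summed directly and complemented if
#' needed, so small upper tails keep full relative precision and no
#' intermediate quantity overflows for \eqn{N} up to \eqn{10^7}.
#'
#' The default is the inclusive tail \eqn{P(X \ge k)}, the standard
#' over-representation convention; \code{strict = TRUE} gives the strict
#' tail \eqn{P(X > k)}.
#'
#' @param k,m,n,N integer vectors (recycled): documents citing both, the
#'   gene, the disease, and the corpus size. Requires
#'   \code{0 <= k <= min(m, n)} and \code{m, n <= N}.
#' @param strict use the strict tail \eqn{P(X > k)}.
#' @return numeric vector of probabilities in \[0, 1\]; \code{k = 0}
#'   always gives 1 for the inclusive tail.
#' @examples
#' hypergeomTail(2, 4, 5, 20)   # 241/969
#' hypergeomTail(3, 3, 3, 30)   # 1/choose(30, 3)
#' @export
hypergeomTail <- function(k, m, n, N, strict = FALSE) {
  len <- max(length(k), length(m), length(n), length(N))
  k <- rep_len(as.numeric(k), len); m <- rep_len(as.numeric(m), len)
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  bad <- is.na(k) | is.na(m) | is.na(n) | is.na(N) |
    k != floor(k) | m != floor(m) | n != floor(n) | N != floor(N)
  if (any(bad)) stop("k, m, n, N must be integers", call. = FALSE)
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (any(m < 0 | m > N | n < 0 | n > N))
    stop("m and n must lie in [0, N]", call. = FALSE)
  if (any(k < 0 | k > pmin(m, n)))
    stop("k must lie in [0, min(m, n)]", call. = FALSE)
  if (strict) {
    atMax <- k >= pmin(m, n)
    out <- numeric(len)
    if (any(!atMax))
      out[!atMax] <- hypergeomTail(k[!atMax] + 1, m[!atMax], n[!atMax],
                                   N[!atMax])
    return(out)
  }
  vapply(seq_len(len), function(i)
    hg_tail_one(k[i], m[i], n[i], N[i]), numeric(1))
}

# Scalar worker: inclusive upper tail via log-space enumeration of the
# shorter tail.
hg_tail_one <- function(k, m, n, N) {
  lo <- max(0, m + n - N)
  hi <- min(m, n)
  if (k <= lo) return(1)
  lpmf <- function(i) lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  # sum the tail on k's side of the mode: the direct sum keeps full
  # relative precision exactly when the upper tail is the small one,
  # while 1 - (lower sum) is accurate when the upper tail is near 1
  if (k >= m * (n / N)) {
    lt <- lpmf(k:hi)
    mx <- max(lt)
    min(1, exp(mx) * sum(exp(lt - mx)))
  } else {
    lt <- lpmf(lo:(k - 1))
    mx <- max(lt)
    max(0, 1 - exp(mx) * sum(exp(lt - mx)))
  }
}

# Document-level hit sets from a mention table: unique doc ids per gene.
mentionDocSets <- function(mentions) {
  if (!nrow(mentions)) return(list())
  lapply(split(mentions$doc_id, mentions$gene_id), unique)
}

#' Count document-level gene-disease co-occurrence
#'
#' Binary counting at the document level (title + abstract): a document
#' counts once for a gene or for the disease no matter how many mentions
#' it contains. \code{N} is the corpus size, \code{n} the number of
#' documents matching any disease phrase (identical across genes),
#' \code{m} the documents mentioning the gene and \code{k} the documents
#' mentioning both.
#'
#' @param corpus a [Corpus-class] (must be non-empty).
#' @param mentions mention table from [tagMentions()].
#' @param diseaseTerms non-empty character vector of disease phrases,
#'   matched with the same case-folded, hyphen/space-equivalent,
#'   token-boundary rules as gene aliases.
#' @return data.frame with one row per mentioned gene: \code{gene_id},
#'   \code{k}, \code{m}, \code{n}, \code{N}.
#' @export
countGeneDisease <- function(corpus, mentions, diseaseTerms) {
  if (length(corpus) < 1L)
    stop("corpus is empty; scoring requires N >= 1", call. = FALSE)
  if (!length(diseaseTerms) || !any(nzchar(diseaseTerms)))
    stop("diseaseTerms must be a non-empty set of phrases", call. = FALSE)
  dz <- tagPhrases(corpus, diseaseTerms)
  dzDocs <- unique(dz$doc_id)
  geneDocs <- mentionDocSets(mentions)
  ids <- names(geneDocs)
  m <- vapply(geneDocs, length, 0L)
  k <- vapply(geneDocs, function(d) sum(d %in% dzDocs), 0L)
  out <- data.frame(gene_id = ids, k = unname(k), m = unname(m),
                    n = length(dzDocs), N = length(corpus),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Locate disease-phrase matches in a corpus
#'
#' Same matcher as gene tagging, applied to an ad-hoc phrase list.
#'
#' @inheritParams countGeneDisease
#' @param phrases character vector of phrases.
#' @return data.frame of matches with \code{doc_id},
#'   \code{sentence_index}, \code{start}, \code{end}, \code{surface}.
#' @export
tagPhrases <- function(corpus, phrases) {
  phrases <- phrases[nzchar(phrases)]
  idx <- data.frame(key = normalizeKey(phrases),
                    gene_id = phrases, alias = phrases,
                    stringsAsFactors = FALSE)
  idx <- idx[!duplicated(idx$key), , drop = FALSE]
  s <- sentenceStrings(corpus)
  hits <- matchPhrases(s$text, idx, maxAliasTokens(idx))
  data.frame(doc_id = s$doc_id[hits$item],
             sentence_index = s$sentence_index[hits$item],
             start = hits$start + s$start[hits$item],
             end = hits$end + s$start[hits$item],
             surface = hits$surface, stringsAsFactors = FALSE)
}

#' Score all mentioned genes against the disease
#'
#' One association result per gene with \code{m >= 1}, ordered by
#' ascending p-value with ties broken by descending \code{k} then
#' lexicographic \code{gene_id}. By default significance is the raw
#' p-value below \code{alpha} with no multiplicity correction;
#' \code{correction = "BH"} applies Benjamini-Hochberg and flags
#' adjusted values below \code{alpha} instead.
#'
#' @param counts count table from [countGeneDisease()].
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param correction "none" (default) or "BH".
#' @param strict use the strict tail \eqn{P(X > k)} instead of the
#'   inclusive \eqn{P(X \ge k)}.
#' @param lexicon optional [GeneLexicon-class] to attach symbols.
#' @return data.frame with columns \code{gene_id}, \code{symbol} (if a
#'   lexicon is given), \code{k}, \code{m}, \code{n}, \code{N},
#'   \code{p_value}, \code{p_adjusted} (BH mode only),
#'   \code{significant}.
#' @export
scoreAllGenes <- function(counts, alpha = 0.05,
                          correction = c("none", "BH"),
                          strict = FALSE, lexicon = NULL) {
  correction <- match.arg(correction)
  stopifnotScalarProb(alpha, "alpha")
  counts <- counts[counts$m >= 1L, , drop = FALSE]
  out <- counts
  out$p_value <- if (nrow(out))
    hypergeomTail(out$k, out$m, out$n, out$N, strict = strict) else numeric(0)
  if (correction == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  if (!is.null(lexicon))
    out <- cbind(out[, "gene_id", drop = FALSE],
                 symbol = geneSymbols(lexicon, out$gene_id),
                 out[, setdiff(names(out), "gene_id"), drop = FALSE])
  out <- out[order(out$p_value, -out$k, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by co-citation frequency with the disease
#'
#' Orders genes by descending \code{k} (documents citing both the gene
#' and the disease), ties broken by \code{gene_id}, and returns the top
#' of the list — the "most frequently cited genes" view.
#'
#' @param counts count table from [countGeneDisease()].
#' @param top how many genes to return (>= 1); if larger than the number
#'   of genes, all are returned.
#' @param lexicon optional [GeneLexicon-class] to attach symbols.
#' @return data.frame with \code{rank}, \code{gene_id}, optional
#'   \code{symbol}, and \code{k}.
#' @export
rankByFrequency <- function(counts, top = 20L, lexicon = NULL) {
  if (!is.numeric(top) || length(top) != 1L || top < 1)
    stop("top must be a count >= 1", call. = FALSE)
  ord <- counts[order(-counts$k, counts$gene_id), , drop = FALSE]
  ord <- utils::head(ord, top)
  out <- data.frame(rank = seq_len(nrow(ord)), gene_id = ord$gene_id,
                    k = ord$k, stringsAsFactors = FALSE)
  if (!is.null(lexicon))
    out <- cbind(out[, c("rank", "gene_id")],
                 symbol = geneSymbols(lexicon, out$gene_id),
                 k = out$k)
  rownames(out) <- NULL
  out
}

#' Write association results as TSV
#' @param results data.frame from [scoreAllGenes()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeAssociations <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
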