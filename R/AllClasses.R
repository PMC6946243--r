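#' @import methods
#' @importFrom stats lm coef phyper rbinom rhyper runif setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

#' Corpus of bibliographic records
#'
#' A \code{Corpus} holds one row per document (identifier, title, abstract)
#' together with a sentence table: 0-based, half-open character intervals
#' into the document text (title and abstract joined by a single space).
#' The title is always sentence 1; abstract sentences follow in order.
#' All co-occurrence counting downstream is defined over these documents
#' and sentences.
#'
#' @slot documents data.frame with columns \code{doc_id}, \code{title},
#'   \code{abstract}.
#' @slot sentences data.frame with columns \code{doc_id},
#'   \code{sentence_index} (1-based ordinal), \code{start}, \code{end}
#'   (0-based half-open intervals into the joined document text).
#'
#' @seealso [readPubmedXml()], [readCorpusJsonl()], [segmentSentences()]
#' @export
setClass("Corpus",
  representation(documents = "data.frame", sentences = "data.frame"))

setValidity("Corpus", function(object) {
  d <- object@documents
  s <- object@sentences
  msgs <- character(0)
  need <- c("doc_id", "title", "abstract")
  if (!all(need %in% names(d)))
    msgs <- c(msgs, paste("documents must have columns:",
                          paste(need, collapse = ", ")))
  else if (anyDuplicated(d$doc_id))
    msgs <- c(msgs, "duplicate doc_id in corpus")
  needs <- c("doc_id", "sentence_index", "start", "end")
  if (!all(needs %in% names(s)))
    msgs <- c(msgs, paste("sentences must have columns:",
                          paste(needs, collapse = ", ")))
  else if (nrow(s)) {
    if (!all(s$doc_id %in% d$doc_id))
      msgs <- c(msgs, "sentence table references unknown doc_id")
    if (any(s$start < 0) || any(s$end <= s$start))
      msgs <- c(msgs, "sentence intervals must be non-empty and non-negative")
    # within each document: ordered and non-overlapping
    ord <- order(s$doc_id, s$sentence_index)
    so <- s[ord, ]
    same <- so$doc_id[-1] == so$doc_id[-nrow(so)]
    if (nrow(so) > 1 && any(same & so$start[-1] < so$end[-nrow(so)]))
      msgs <- c(msgs, "sentence intervals overlap or are out of order")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Corpus number of documents (the statistic's N)
#' @param x,object a \code{Corpus}
#' @export
setMethod("length", "Corpus", function(x) nrow(x@documents))

setMethod("show", "Corpus", function(object) {
  cat("Corpus with", nrow(object@documents), "documents,",
      nrow(object@sentences), "sentences\n")
})

#' @describeIn Corpus the document table
#' @export
documents <- function(x) x@documents

#' @describeIn Corpus the sentence interval table
#' @export
sentenceTable <- function(x) x@sentences

#' @describeIn Corpus joined title + abstract text, named by doc_id
#' @export
documentText <- function(x) {
  d <- x@documents
  txt <- ifelse(nchar(d$abstract) > 0,
                paste(d$title, d$abstract), d$title)
  setNames(txt, d$doc_id)
}

#' Gene lexicon with a normalized alias index
#'
#' Maps canonical symbols and synonyms to stable gene identifiers
#' (Entrez-style numeric strings). Matching downstream is case-insensitive
#' with hyphen/space equivalence, so each alias is indexed under a
#' normalized key (lower-cased, non-alphanumerics removed). Aliases whose
#' normalized key maps to more than one gene are dropped at load time.
#'
#' @slot entries data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{synonyms} (pipe-separated).
#' @slot index data.frame with columns \code{key} (normalized alias),
#'   \code{gene_id}, \code{alias} (original surface form).
#' @slot dropped character, normalized keys removed because they were
#'   ambiguous across genes.
#'
#' @seealso [readLexicon()], [makeLexicon()]
#' @export
setClass("GeneLexicon",
  representation(entries = "data.frame", index = "data.frame",
                 dropped = "character"))

setValidity("GeneLexicon", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@entries$gene_id))
    msgs <- c(msgs, "duplicate gene_id in lexicon")
  if (any(!nzchar(object@entries$symbol)))
    msgs <- c(msgs, "empty canonical symbol")
  if (nrow(object@index) &&
      anyDuplicated(object@index$key))
    msgs <- c(msgs, "ambiguous alias key survived indexing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneLexicon", function(object) {
  cat("GeneLexicon:", nrow(object@entries), "genes,",
      nrow(object@index), "indexed aliases")
  if (length(object@dropped))
    cat(" (", length(object@dropped), " ambiguous aliases dropped)", sep = "")
  cat("\n")
})

#' @describeIn GeneLexicon the gene entry table
#' @param x a \code{GeneLexicon}
#' @export
lexiconEntries <- function(x) x@entries

#' @describeIn GeneLexicon map gene ids to canonical symbols
#' @param gene_id character vector of gene identifiers
#' @export
geneSymbols <- function(x, gene_id) {
  x@entries$symbol[match(gene_id, x@entries$gene_id)]
}

#' Merged undirected gene network
#'
#' Edges are unordered gene pairs stored in canonical order
#' (\code{gene_a < gene_b}), deduplicated by pair with evidence from all
#' contributing sources concatenated. Relation types follow the KEGG
#' vocabulary (\code{ECrel}, \code{PPrel}, \code{GErel}) plus
#' \code{cocitation} for sentence-level co-citation edges, which carry the
#' hypergeometric p-value of the supporting co-citation test.
#'
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{types} (semicolon-joined relation types), \code{evidence}
#'   (semicolon-joined provenance tags), \code{p_value} (minimum
#'   co-citation p among merged evidence, NA for curated-only edges).
#'
#' @seealso [mergeNetwork()], [identifyHubs()], [fitPowerLaw()]
#' @export
setClass("GeneNetwork", representation(edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  need <- c("gene_a", "gene_b", "types", "evidence", "p_value")
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste("edges must have columns:",
                          paste(need, collapse = ", ")))
  else if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) msgs <- c(msgs, "self-loop edge")
    if (any(e$gene_a > e$gene_b))
      msgs <- c(msgs, "edge pair not in canonical order")
    if (anyDuplicated(paste(e$gene_a, e$gene_b)))
      msgs <- c(msgs, "duplicate edge pair")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", length(networkNodes(object)), "nodes,",
      nrow(object@edges), "edges\n")
})

#' @describeIn GeneNetwork the deduplicated edge table
#' @param x a \code{GeneNetwork}
#' @export
networkEdges <- function(x) x@edges

#' @describeIn GeneNetwork sorted vector of node identifiers
#' @export
networkNodes <- function(x) {
  sort(unique(c(x@edges$gene_a, x@edges$gene_b)))
}

#' @describeIn GeneNetwork named integer vector of node degrees
#' @export
networkDegrees <- function(x) {
  nodes <- networkNodes(x)
  if (!length(nodes)) return(setNames(integer(0), character(0)))
  tab <- table(factor(c(x@edges$gene_a, x@edges$gene_b), levels = nodes))
  setNames(as.integer(tab), nodes)
}

#' Power-law fit of a degree distribution
#'
#' @slot exponent numeric, the fitted exponent gamma of
#'   \eqn{c(d) \propto d^{-\gamma}}.
#' @slot method "ls" (least squares on log degree vs log count) or "mle"
#'   (discrete maximum likelihood).
#' @slot dMin numeric, smallest degree included in the fit.
#' @slot goodness numeric, R-squared of the log-log regression (ls) or the
#'   Kolmogorov-Smirnov distance between empirical and fitted tails (mle).
#' @slot isPowerLaw logical, FALSE when the fitted exponent is not
#'   positive (e.g. a flat degree histogram).
#'
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
  representation(exponent = "numeric", method = "character",
                 dMin = "numeric", goodness = "numeric",
                 isPowerLaw = "logical"))

setValidity("PowerLawFit", function(object) {
  if (object@isPowerLaw && object@exponent <= 0)
    "a power-law fit must have a positive exponent" else TRUE
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit (%s): gamma = %.4f, %s = %.4f, d_min = %g%s\n",
              object@method, object@exponent,
              if (object@method == "ls") "R^2" else "KS",
              object@goodness, object@dMin,
              if (object@isPowerLaw) "" else " [not power-law]"))
})

#' Ground truth of a simulated corpus
#'
#' Records what the generator planted so that recovery can be scored:
#' the disease-associated gene set, the planted co-mention edge set, and
#' the realized per-gene document counts (which the tagging and counting
#' pipeline must reproduce exactly on the generated text).
#'
#' @slot plantedGenes character, gene ids planted with enrichment > 1.
#' @slot plantedEdges data.frame with columns \code{gene_a}, \code{gene_b}
#'   (canonical order), the planted co-mention pairs.
#' @slot counts data.frame with columns \code{gene_id}, \code{m}
#'   (documents mentioning the gene), \code{k} (documents mentioning gene
#'   and disease).
#' @slot nDiseaseDocs integer, documents containing the disease phrase.
#' @slot nDocs integer, corpus size.
#'
#' @seealso [simulateCorpus()], [evaluateRecovery()]
#' @export
setClass("SyntheticTruth",
  representation(plantedGenes = "character", plantedEdges = "data.frame",
                 counts = "data.frame", nDiseaseDocs = "integer",
                 nDocs = "integer"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", object@nDocs, "documents (",
      object@nDiseaseDocs, "disease-positive ),",
      length(object@plantedGenes), "planted genes,",
      nrow(object@plantedEdges), "planted edges\n")
})
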