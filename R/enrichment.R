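# Over-representation analysis of a gene set against GO / pathway
# collections, using the same exact hypergeometric tail as the
# association statistic.

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated term id, description,
#' then gene ids. Duplicate genes within a line are stored once; lines
#' whose gene list is empty after deduplication are rejected.
#'
#' @param path path to the GMT file.
#' @param namespace namespace assigned to every term in this file: one of
#'   "BP", "CC", "MF", "PATHWAY".
#' @return annotation data.frame in long form: \code{term_id},
#'   \code{term_name}, \code{namespace}, \code{gene_id}.
#' @export
readGmt <- function(path, namespace = c("PATHWAY", "BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT line ", i, " has an empty gene list", call. = FALSE)
    out[[i]] <- data.frame(term_id = f[1], term_name = f[2],
                           namespace = namespace, gene_id = genes,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read GO annotations in GAF 2.x format
#'
#' Keeps columns DB Object ID (used as the gene id), GO ID and aspect;
#' rows carrying a NOT qualifier are skipped, as are comment lines
#' starting with "!". Aspects P/F/C map to namespaces BP/MF/CC.
#'
#' @param path path to the GAF file.
#' @return annotation data.frame in long form (as [readGmt()]); the GO id
#'   doubles as the term name.
#' @export
readGaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines))
    return(data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), gene_id = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 9L)
  if (length(short))
    stop("GAF line ", short[1], " has fewer than 9 columns", call. = FALSE)
  gene <- vapply(f, `[`, "", 2L)
  qual <- vapply(f, `[`, "", 4L)
  term <- vapply(f, `[`, "", 5L)
  aspect <- vapply(f, `[`, "", 9L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  gene <- gene[keep]; term <- term[keep]; aspect <- aspect[keep]
  map <- c(P = "BP", F = "MF", C = "CC")
  if (any(!aspect %in% names(map)))
    stop("unknown GAF aspect code: ",
         paste(unique(aspect[!aspect %in% names(map)]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(term_id = term, term_name = term,
                    namespace = unname(map[aspect]), gene_id = gene,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$term_id, out$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of a gene set
#'
#' For each term, the p-value is the exact upper tail
#' \eqn{P(X \ge \mathrm{overlap})} of a hypergeometric draw of
#' \code{query_size} genes from a background universe containing
#' \code{term_size} term genes — equivalently the one-sided Fisher exact
#' test on the 2x2 overlap table. Term gene sets are intersected with the
#' background before testing. The background defaults to every gene that
#' carries at least one annotation.
#'
#' @param query character vector of gene ids (must be a subset of the
#'   background).
#' @param annotations long-form annotation data.frame from [readGmt()] /
#'   [readGaf()] (or several, row-bound).
#' @param background background gene universe; default: all annotated
#'   genes.
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @return data.frame sorted by ascending p-value with columns
#'   \code{term_id}, \code{term_name}, \code{namespace}, \code{overlap},
#'   \code{term_size}, \code{query_size}, \code{background_size},
#'   \code{p_value}, \code{significant}.
#' @export
enrichGeneSets <- function(query, annotations, background = NULL,
                           alpha = 0.05) {
  stopifnotScalarProb(alpha, "alpha")
  query <- unique(as.character(query))
  if (is.null(background))
    background <- unique(annotations$gene_id)
  background <- unique(as.character(background))
  off <- setdiff(query, background)
  if (length(off))
    stop("query genes missing from the background universe: ",
         paste(off, collapse = ", "), call. = FALSE)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  terms <- unique(ann[, c("term_id", "term_name", "namespace")])
  genesByTerm <- split(ann$gene_id, ann$term_id)
  termSize <- vapply(genesByTerm, function(g) length(unique(g)), 0L)
  overlap <- vapply(genesByTerm, function(g)
    length(intersect(unique(g), query)), 0L)
  ord <- match(terms$term_id, names(genesByTerm))
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    namespace = terms$namespace,
                    overlap = unname(overlap[ord]),
                    term_size = unname(termSize[ord]),
                    query_size = length(query),
                    background_size = length(background),
                    stringsAsFactors = FALSE)
  out$p_value <- if (nrow(out))
    hypergeomTail(out$overlap, out$term_size, out$query_size,
                  out$background_size) else numeric(0)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize enrichment results by namespace
#'
#' Partitions significant terms by namespace (BP / CC / MF / PATHWAY) —
#' the data backbone of the usual per-category histogram. Namespaces
#' present in the input appear even when they have no significant term.
#'
#' @param results data.frame from [enrichGeneSets()].
#' @return data.frame with \code{namespace}, \code{n_significant},
#'   \code{n_terms}, \code{term_ids} (semicolon-joined significant term
#'   ids, ordered by p-value).
#' @export
summarizeByNamespace <- function(results) {
  spaces <- sort(unique(results$namespace))
  rows <- lapply(spaces, function(ns) {
    r <- results[results$namespace == ns, , drop = FALSE]
    sig <- r[r$significant, , drop = FALSE]
    sig <- sig[order(sig$p_value, sig$term_id), , drop = FALSE]
    data.frame(namespace = ns, n_significant = nrow(sig),
               n_terms = nrow(r),
               term_ids = paste(sig$term_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(namespace = character(0), n_significant = integer(0),
               n_terms = integer(0), term_ids = character(0))
  rownames(out) <- NULL
  out
}
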