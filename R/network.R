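# Gene network assembly from curated relations (KGML, PPI tables) and
# sentence-level co-citation; degree topology, power-law fit, hubs.

emptyEdgeList <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             type = character(0), evidence = character(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Read relations from a KGML pathway file
#'
#' Extracts ECrel / PPrel / GErel relations between gene entries of a
#' KGML (KEGG Markup Language) document. Entry names are split on
#' whitespace and stripped of their organism prefix ("hsa:7124" ->
#' "7124"); relations touching non-gene entries (compounds, maps) are
#' skipped. Relations between multi-gene entries expand to all cross
#' pairs. Relation subtypes (binding, activation, ...) are preserved in
#' the evidence tag.
#'
#' @param path path to the KGML XML file.
#' @return edge data.frame with columns \code{gene_a}, \code{gene_b}
#'   (canonical order), \code{type}, \code{evidence}, \code{p_value}
#'   (NA for curated edges).
#' @export
readKgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed KGML in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  entries <- xml2::xml_find_all(doc, ".//entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  enames <- lapply(strsplit(xml2::xml_attr(entries, "name"), "\\s+"),
                   function(x) sub("^[A-Za-z]+:", "", x[nzchar(x)]))
  geneOf <- setNames(enames, eid)
  isGene <- setNames(etype == "gene", eid)
  rels <- xml2::xml_find_all(doc, ".//relation")
  out <- list()
  for (r in rels) {
    rtype <- xml2::xml_attr(r, "type")
    if (!rtype %in% c("ECrel", "PPrel", "GErel")) next
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    if (!isTRUE(isGene[e1]) || !isTRUE(isGene[e2])) next
    sub <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    ev <- if (length(sub)) paste0("kgml:", paste(sub, collapse = ","))
          else "kgml"
    pairs <- expand.grid(a = geneOf[[e1]], b = geneOf[[e2]],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    if (!nrow(pairs)) next
    cp <- canonicalPair(pairs$a, pairs$b)
    out[[length(out) + 1L]] <- data.frame(
      gene_a = cp$a, gene_b = cp$b, type = rtype, evidence = ev,
      p_value = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(emptyEdgeList())
  edges <- do.call(rbind, out)
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b,
                                   edges$type)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read a two-column protein-protein interaction table
#'
#' MIPS-style export: two tab-separated gene id columns, no header by
#' default. Self-interactions are dropped; reciprocal duplicates
#' collapse to one canonical pair. When a lexicon is supplied, rows
#' referencing unknown ids are skipped with a message.
#'
#' @param path path to the TSV file.
#' @param lexicon optional [GeneLexicon-class] used to validate ids.
#' @param header does the file have a header line?
#' @return edge data.frame (see [readKgml()]), typed PPrel with evidence
#'   tag "ppi-table".
#' @export
readPpiTable <- function(path, lexicon = NULL, header = FALSE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("PPI table must have two columns", call. = FALSE)
  a <- tab[[1]]; b <- tab[[2]]
  if (!is.null(lexicon)) {
    known <- lexicon@entries$gene_id
    bad <- !(a %in% known) | !(b %in% known)
    if (any(bad))
      message(sum(bad), " PPI row(s) skipped: gene id not in lexicon")
    a <- a[!bad]; b <- b[!bad]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(emptyEdgeList())
  cp <- canonicalPair(a, b)
  edges <- data.frame(gene_a = cp$a, gene_b = cp$b, type = "PPrel",
                      evidence = "ppi-table", p_value = NA_real_,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Sentence-level co-citation edges
#'
#' Counts gene pairs at sentence granularity: with \code{N'} the total
#' number of sentences in the corpus, \code{m'} and \code{n'} the
#' sentences mentioning each gene and \code{k'} the sentences mentioning
#' both, the pair's p-value is the exact hypergeometric upper tail
#' \eqn{P(X \ge k')}. Pairs with \code{p < alpha} and at least
#' \code{minSupport} co-citing sentences become edges of type
#' \code{cocitation} carrying their p-value.
#'
#' @param corpus a [Corpus-class]
#' @param mentions mention table from [tagMentions()].
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param minSupport minimum number of co-citing sentences (default 2,
#'   suppressing single-sentence coincidences; set to 1 to disable).
#' @return edge data.frame (see [readKgml()]) with the co-citation
#'   p-value in \code{p_value}.
#' @export
cocitationEdges <- function(corpus, mentions, alpha = 0.05,
                            minSupport = 2L) {
  stopifnotScalarProb(alpha, "alpha")
  if (!is.numeric(minSupport) || minSupport < 1)
    stop("minSupport must be >= 1", call. = FALSE)
  Ns <- nrow(corpus@sentences)
  if (!nrow(mentions) || Ns == 0L) return(emptyEdgeList())
  sentKey <- paste(mentions$doc_id, mentions$sentence_index, sep = "\r")
  u <- !duplicated(paste(sentKey, mentions$gene_id))
  sk <- sentKey[u]; gid <- mentions$gene_id[u]
  mPrime <- table(gid)
  genesBySent <- split(gid, sk)
  genesBySent <- genesBySent[lengths(genesBySent) >= 2L]
  if (!length(genesBySent)) return(emptyEdgeList())
  pairs <- do.call(rbind, lapply(genesBySent, function(g) {
    g <- sort(g)
    t(utils::combn(g, 2L))
  }))
  pairKey <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  kPrime <- table(pairKey)
  first <- !duplicated(pairKey)
  a <- pairs[first, 1]; b <- pairs[first, 2]
  kk <- as.integer(kPrime[pairKey[first]])
  keep <- kk >= minSupport
  a <- a[keep]; b <- b[keep]; kk <- kk[keep]
  if (!length(a)) return(emptyEdgeList())
  p <- hypergeomTail(kk, as.integer(mPrime[a]), as.integer(mPrime[b]), Ns)
  sig <- p < alpha
  if (!any(sig)) return(emptyEdgeList())
  edges <- data.frame(gene_a = a[sig], gene_b = b[sig],
                      type = "cocitation", evidence = "cocitation",
                      p_value = p[sig], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Merge edge lists into an undirected gene network
#'
#' Takes any number of edge data.frames (from [readKgml()],
#' [readPpiTable()], [cocitationEdges()] or an existing network's edge
#' table) and forms their undirected union: the same pair arriving from
#' several sources becomes one edge whose relation types and evidence
#' tags are concatenated and whose p-value is the smallest co-citation p
#' among the sources. Merging is commutative and idempotent. Nodes exist
#' only through edges, so no degree-0 node is retained.
#'
#' @param ... edge data.frames.
#' @param restrictTo optional gene id vector: keep only edges touching
#'   this set.
#' @param restrictMode with \code{restrictTo}: "neighbors" keeps edges
#'   with at least one endpoint in the set (the set plus its direct
#'   partners), "strict" requires both endpoints.
#' @return a [GeneNetwork-class]
#' @export
mergeNetwork <- function(..., restrictTo = NULL,
                         restrictMode = c("neighbors", "strict")) {
  restrictMode <- match.arg(restrictMode)
  lists <- list(...)
  lists <- lists[!vapply(lists, is.null, TRUE)]
  if (!length(lists)) stop("need at least one edge list", call. = FALSE)
  lists <- lapply(lists, function(e) {
    if (is(e, "GeneNetwork")) e <- e@edges
    if ("types" %in% names(e) && !("type" %in% names(e)))
      names(e)[names(e) == "types"] <- "type"
    if (!nrow(e)) return(emptyEdgeList())
    e[, c("gene_a", "gene_b", "type", "evidence", "p_value"), drop = FALSE]
  })
  e <- do.call(rbind, lists)
  if (nrow(e)) {
    cp <- canonicalPair(e$gene_a, e$gene_b)
    e$gene_a <- cp$a; e$gene_b <- cp$b
    e <- e[e$gene_a != e$gene_b, , drop = FALSE]
  }
  if (!is.null(restrictTo) && nrow(e)) {
    inA <- e$gene_a %in% restrictTo
    inB <- e$gene_b %in% restrictTo
    e <- e[if (restrictMode == "strict") inA & inB else inA | inB, ,
           drop = FALSE]
  }
  if (!nrow(e)) {
    em <- emptyEdgeList()
    names(em)[names(em) == "type"] <- "types"
    return(new("GeneNetwork", edges = em))
  }
  key <- paste(e$gene_a, e$gene_b, sep = "\r")
  agg <- lapply(split(seq_len(nrow(e)), key), function(i) {
    typ <- sort(unique(unlist(strsplit(e$type[i], ";", fixed = TRUE))))
    ev <- sort(unique(unlist(strsplit(e$evidence[i], ";", fixed = TRUE))))
    p <- e$p_value[i]
    data.frame(gene_a = e$gene_a[i[1]], gene_b = e$gene_b[i[1]],
               types = paste(typ, collapse = ";"),
               evidence = paste(ev, collapse = ";"),
               p_value = if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("GeneNetwork", edges = edges)
}

#' Exact degree histogram of a network
#'
#' @param network a non-empty [GeneNetwork-class]
#' @return data.frame with \code{degree} and \code{count}; counts sum to
#'   the number of nodes.
#' @export
degreeHistogram <- function(network) {
  deg <- networkDegrees(network)
  if (!length(deg)) stop("network is empty", call. = FALSE)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Fit a power law to a degree distribution
#'
#' Default method "ls" regresses log count on log degree over degrees at
#' least \code{dMin} (matching the straight-line presentation of a
#' log-log degree plot) and reports the exponent \eqn{\gamma} = -slope
#' with the regression R-squared. Method "mle" is the discrete
#' maximum-likelihood estimate
#' \eqn{\hat\gamma = 1 + n\left(\sum_i \ln \frac{d_i}{d_{\min}-1/2}\right)^{-1}}
#' with the Kolmogorov-Smirnov distance between the empirical and fitted
#' tail as goodness; \code{dMin = "auto"} scans candidate \code{dMin}
#' values and keeps the one minimizing the KS distance (least squares on
#' the raw histogram is known to be biased; the MLE is the statistically
#' preferred estimator). A non-positive fitted exponent (e.g. a flat
#' histogram) is flagged as not power-law.
#'
#' @param x a [GeneNetwork-class] or a degree histogram data.frame from
#'   [degreeHistogram()].
#' @param method "ls" (default) or "mle".
#' @param dMin smallest degree included in the fit (default 1), or
#'   "auto" for KS-optimal selection (mle only).
#' @param minTail smallest number of observations allowed in the fitted
#'   tail during the "auto" scan.
#' @return a [PowerLawFit-class]
#' @export
fitPowerLaw <- function(x, method = c("ls", "mle"), dMin = 1,
                        minTail = 10L) {
  method <- match.arg(method)
  hist <- if (is(x, "GeneNetwork")) degreeHistogram(x) else x
  if (!all(c("degree", "count") %in% names(hist)))
    stop("x must be a GeneNetwork or a degree histogram", call. = FALSE)
  hist <- hist[hist$count > 0, , drop = FALSE]
  if (method == "ls") {
    if (!is.numeric(dMin)) stop("dMin must be numeric for ls", call. = FALSE)
    h <- hist[hist$degree >= dMin, , drop = FALSE]
    if (nrow(h) < 3L)
      stop("power-law fit needs >= 3 distinct degrees", call. = FALSE)
    lx <- log(h$degree); ly <- log(h$count)
    if (stats::sd(ly) == 0)
      return(new("PowerLawFit", exponent = 0, method = "ls",
                 dMin = as.numeric(dMin), goodness = 0,
                 isPowerLaw = FALSE))
    fit <- stats::lm(ly ~ lx)
    gamma <- -unname(stats::coef(fit)[2])
    # direct R^2: summary.lm warns on an exactly collinear fit
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
    return(new("PowerLawFit", exponent = gamma, method = "ls",
               dMin = as.numeric(dMin), goodness = r2,
               isPowerLaw = gamma > 0))
  }
  degrees <- rep(hist$degree, hist$count)
  if (length(unique(degrees)) < 3L)
    stop("power-law fit needs >= 3 distinct degrees", call. = FALSE)
  mleAt <- function(dm) {
    d <- degrees[degrees >= dm]
    g <- 1 + length(d) / sum(log(d / (dm - 0.5)))
    xs <- sort(unique(d))
    emp <- cumsum(as.numeric(table(d))) / length(d)
    ks <- max(abs(emp - (1 - (xs / (dm - 0.5))^(1 - g))))
    list(gamma = g, ks = ks, dMin = dm, n = length(d))
  }
  if (identical(dMin, "auto")) {
    best <- NULL
    for (dm in sort(unique(degrees))) {
      if (sum(degrees >= dm) < minTail) break
      cand <- mleAt(dm)
      if (is.null(best) || cand$ks < best$ks) best <- cand
    }
    if (is.null(best)) best <- mleAt(min(degrees))
  } else {
    best <- mleAt(dMin)
  }
  new("PowerLawFit", exponent = best$gamma, method = "mle",
      dMin = as.numeric(best$dMin), goodness = best$ks,
      isPowerLaw = best$gamma > 0)
}

#' Identify hub genes by degree
#'
#' Ranks nodes by descending degree (ties by gene id) and selects hubs
#' by one of three rules: \code{top_fraction} (default 0.05, the highest
#' 5 percent of nodes by degree), \code{top_k}, or
#' \code{degree_threshold}. Ties at the cutoff degree are all included,
#' so the selection is stable under node relabeling.
#'
#' @param network a non-empty [GeneNetwork-class]
#' @param rule selection rule.
#' @param param rule parameter: fraction in (0, 1\], count >= 1, or
#'   minimum degree.
#' @param lexicon optional [GeneLexicon-class] to attach symbols.
#' @return data.frame with \code{rank}, \code{gene_id}, optional
#'   \code{symbol}, \code{degree}; attributes \code{rule} and
#'   \code{param} record the selection.
#' @export
identifyHubs <- function(network,
                         rule = c("top_fraction", "top_k",
                                  "degree_threshold"),
                         param = 0.05, lexicon = NULL) {
  rule <- match.arg(rule)
  deg <- networkDegrees(network)
  if (!length(deg)) stop("network is empty", call. = FALSE)
  if (!is.numeric(param) || length(param) != 1L || is.na(param))
    stop("param must be a single number", call. = FALSE)
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  cutoff <- switch(rule,
    top_fraction = {
      if (param <= 0 || param > 1)
        stop("top_fraction param must be in (0, 1]", call. = FALSE)
      deg[[min(length(deg), max(1L, ceiling(param * length(deg))))]]
    },
    top_k = {
      if (param < 1 || param != floor(param))
        stop("top_k param must be a count >= 1", call. = FALSE)
      deg[[min(length(deg), param)]]
    },
    degree_threshold = {
      if (param < 0) stop("degree_threshold param must be >= 0",
                          call. = FALSE)
      param
    })
  sel <- deg[deg >= cutoff]
  out <- data.frame(rank = seq_along(sel), gene_id = names(sel),
                    degree = unname(sel), stringsAsFactors = FALSE)
  if (!is.null(lexicon))
    out <- cbind(out[, c("rank", "gene_id")],
                 symbol = geneSymbols(lexicon, out$gene_id),
                 degree = out$degree)
  attr(out, "rule") <- rule
  attr(out, "param") <- param
  out
}

# igraph view of a network, nodes/edges/attributes preserved.
asIgraph <- function(network) {
  e <- network@edges
  nodes <- networkNodes(network)
  if (!nrow(e))
    return(igraph::make_empty_graph(n = length(nodes), directed = FALSE))
  df <- data.frame(from = e$gene_a, to = e$gene_b, types = e$types,
                   evidence = e$evidence, p_value = e$p_value,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Export a network to SIF, GraphML or edge-list TSV
#'
#' SIF lines are \code{gene_a <tab> types <tab> gene_b}; GraphML (via
#' igraph) carries relation types, evidence and co-citation p-values as
#' edge attributes and round-trips losslessly through
#' [readNetworkGraphml()]; TSV is the raw edge table.
#'
#' @param network a [GeneNetwork-class]
#' @param path output path.
#' @param format one of "sif", "graphml", "tsv".
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, path,
                          format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- network@edges
  if (format == "sif") {
    writeLines(if (nrow(e))
      paste(e$gene_a, e$types, e$gene_b, sep = "\t") else character(0),
      path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Import a network from GraphML
#'
#' @param path a GraphML file written by [exportNetwork()].
#' @return a [GeneNetwork-class]
#' @export
readNetworkGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0L) {
    em <- emptyEdgeList()
    names(em)[names(em) == "type"] <- "types"
    return(new("GeneNetwork", edges = em))
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  cp <- canonicalPair(ends[, 1], ends[, 2])
  p <- igraph::edge_attr(g, "p_value")
  if (is.null(p)) p <- rep(NA_real_, nrow(ends))
  p[is.nan(p)] <- NA_real_
  edges <- data.frame(gene_a = cp$a, gene_b = cp$b,
                      types = igraph::edge_attr(g, "types"),
                      evidence = igraph::edge_attr(g, "evidence"),
                      p_value = p, stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("GeneNetwork", edges = edges)
}
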