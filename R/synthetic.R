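# Synthetic corpus / lexicon / relation-file generator with known ground
# truth: the testbed standing in for a live bibliographic snapshot.

#' Generator configuration
#'
#' Describes the statistical structure of a simulated corpus: every
#' document is independently disease-positive with probability
#' \code{piDisease} (the disease phrase is then inserted in its title);
#' each gene is mentioned in a document with probability \code{piGene},
#' raised to \code{min(1, rho * piGene)} in disease-positive documents
#' for the planted genes only. Planted co-mention edges (a
#' preferential-attachment scale-free graph over the genes when
#' \code{mAttach > 0}) are realized by emitting both genes in one extra
#' sentence of a \code{edgeDocRate} fraction of documents. Gene mentions
#' are otherwise independent across genes given disease status, matching
#' the hypergeometric null.
#'
#' @param nDocs number of documents (>= 1).
#' @param nGenes number of genes in the lexicon (>= 1).
#' @param piDisease disease prevalence in (0, 1); default 0.2.
#' @param piGene background per-document gene mention probability in
#'   (0, 1); default 0.01.
#' @param nPlanted number of planted disease-associated genes (the first
#'   \code{nPlanted} gene ids); default 0.
#' @param rho enrichment factor >= 1 for planted genes;
#'   \code{rho * piGene} is clipped at 1 with a warning.
#' @param mAttach preferential-attachment parameter of the planted
#'   co-mention graph; 0 (default) plants no graph.
#' @param edgeDocRate per-document realization probability of each
#'   planted co-mention edge; default 0.002.
#' @param sentencesPerAbstract template sentences per abstract; default 5.
#' @param synonymUseRate probability that a mention is emitted as a
#'   synonym rather than the canonical symbol; default 0.3.
#' @param conjFraction fraction of eligible sentences (two or more gene
#'   mentions) emitted as a coordinated elided form ("G-0001/0002") to
#'   exercise conjunction resolution; default 0.
#' @param diseaseTerm the disease phrase; default
#'   "bronchopulmonary dysplasia".
#' @param seed mandatory integer RNG seed.
#' @return a validated \code{GeneratorConfig} list.
#' @export
generatorConfig <- function(nDocs, nGenes, piDisease = 0.2,
                            piGene = 0.01, nPlanted = 0L, rho = 1,
                            mAttach = 0L, edgeDocRate = 0.002,
                            sentencesPerAbstract = 5L,
                            synonymUseRate = 0.3, conjFraction = 0,
                            diseaseTerm = "bronchopulmonary dysplasia",
                            seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  if (!is.numeric(nDocs) || nDocs < 1)
    stop("nDocs must be >= 1", call. = FALSE)
  if (!is.numeric(nGenes) || nGenes < 1)
    stop("nGenes must be >= 1", call. = FALSE)
  stopifnotScalarProb(piDisease, "piDisease")
  stopifnotScalarProb(piGene, "piGene")
  if (rho < 1) stop("rho must be >= 1", call. = FALSE)
  if (nPlanted < 0 || nPlanted > nGenes)
    stop("nPlanted must lie in [0, nGenes]", call. = FALSE)
  if (conjFraction < 0 || conjFraction > 1)
    stop("conjFraction must lie in [0, 1]", call. = FALSE)
  pPlanted <- rho * piGene
  if (pPlanted > 1) {
    warning("rho * piGene exceeds 1; clipped to 1")
    pPlanted <- 1
  }
  structure(list(nDocs = as.integer(nDocs), nGenes = as.integer(nGenes),
                 piDisease = piDisease, piGene = piGene,
                 nPlanted = as.integer(nPlanted), rho = rho,
                 pPlanted = pPlanted, mAttach = as.integer(mAttach),
                 edgeDocRate = edgeDocRate,
                 sentencesPerAbstract = as.integer(sentencesPerAbstract),
                 synonymUseRate = synonymUseRate,
                 conjFraction = conjFraction, diseaseTerm = diseaseTerm,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Gene ids and symbols for a config: Entrez-style numeric id strings and
# "G"-prefixed zero-padded symbols (G0001, ...).
syntheticSymbols <- function(nGenes) {
  width <- max(4L, nchar(as.character(nGenes)))
  sprintf("G%0*d", width, seq_len(nGenes))
}

#' Generate a synthetic gene lexicon
#'
#' Symbols are G0001, G0002, ...; each gene receives 0-3 collision-free
#' synonyms. Output is byte-identical for identical config and seed.
#'
#' @param config a [generatorConfig()].
#' @param path optional path; when given the lexicon TSV is written.
#' @return a [GeneLexicon-class]
#' @export
simulateLexicon <- function(config, path = NULL) {
  set.seed(config$seed + 1L)
  sym <- syntheticSymbols(config$nGenes)
  nsyn <- sample(0:3, config$nGenes, replace = TRUE)
  syn <- vapply(seq_len(config$nGenes), function(i) {
    if (nsyn[i] == 0L) return("")
    paste(sprintf("SYN%s%s", LETTERS[seq_len(nsyn[i])],
                  sub("^G", "", sym[i])), collapse = "|")
  }, "")
  entries <- data.frame(gene_id = as.character(1000L + seq_len(config$nGenes)),
                        symbol = sym, synonyms = syn,
                        stringsAsFactors = FALSE)
  lex <- makeLexicon(entries)
  if (!is.null(path)) writeLexicon(lex, path)
  lex
}

#' Sample a preferential-attachment (scale-free) graph
#'
#' Barabasi-Albert-style growth with an exact edge-count convention:
#' the process starts from a seed dyad (nodes 1-2, one edge) and each
#' arriving node attaches to \code{min(existing, mAttach)} distinct
#' earlier nodes chosen with probability proportional to their current
#' degree, giving \eqn{1 + \sum_{v=3}^{n} \min(v-1, m)} edges
#' (\eqn{2(n-2)+1} for \code{mAttach = 2}). Deterministic under
#' \code{seed}.
#'
#' @param n number of nodes (>= 2).
#' @param mAttach edges added per arriving node (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame of edges with integer node columns \code{a},
#'   \code{b}.
#' @export
sampleScaleFreeGraph <- function(n, mAttach, seed) {
  if (mAttach < 1) stop("mAttach must be >= 1", call. = FALSE)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  set.seed(seed)
  deg <- integer(n); deg[1:2] <- 1L
  froms <- vector("list", n); froms[[1]] <- 1L
  tos <- vector("list", n); tos[[1]] <- 2L
  if (n > 2) for (v in 3:n) {
    m <- min(v - 1L, mAttach)
    pick <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
    deg[pick] <- deg[pick] + 1L
    deg[v] <- m
    froms[[v]] <- pick
    tos[[v]] <- rep(v, m)
  }
  data.frame(a = unlist(froms), b = unlist(tos))
}

#' Generate a synthetic corpus with ground truth
#'
#' Documents are bags of template sentences. Disease-positive documents
#' carry the disease phrase in their title. Every mentioned gene is
#' placed as a surface form (symbol or, with probability
#' \code{synonymUseRate}, a synonym) in a random abstract sentence;
#' realized planted edges add one extra sentence mentioning both
#' endpoint genes. When \code{conjFraction > 0}, a fraction of sentences
#' with two or more mentions render their first two genes as a
#' coordinated elided form ("G-0001/0002"). The returned truth stores
#' the realized per-gene document counts, which re-tagging the generated
#' text must reproduce exactly.
#'
#' @param config a [generatorConfig()].
#' @param lexicon optional [GeneLexicon-class]; default
#'   \code{simulateLexicon(config)}.
#' @param dir optional directory: writes \code{corpus.jsonl} and
#'   \code{truth.json} there.
#' @return list with elements \code{corpus} ([Corpus-class]),
#'   \code{truth} ([SyntheticTruth-class]) and \code{lexicon}.
#' @export
simulateCorpus <- function(config, lexicon = NULL, dir = NULL) {
  if (is.null(lexicon)) lexicon <- simulateLexicon(config)
  set.seed(config$seed + 2L)
  nD <- config$nDocs; nG <- config$nGenes; nS <- config$sentencesPerAbstract
  sym <- lexicon@entries$symbol
  gid <- lexicon@entries$gene_id
  synList <- strsplit(lexicon@entries$synonyms, "|", fixed = TRUE)
  diseased <- runif(nD) < config$piDisease
  # per-document gene incidence under the mixture model
  prob <- matrix(config$piGene, nrow = nD, ncol = nG)
  if (config$nPlanted > 0)
    prob[diseased, seq_len(config$nPlanted)] <- config$pPlanted
  inc <- matrix(runif(nD * nG), nD, nG) < prob
  hit <- which(inc, arr.ind = TRUE)
  mentionDoc <- hit[, 1]; mentionGene <- hit[, 2]
  # planted co-mention edges: one extra sentence per realized (edge, doc)
  plantedEdges <- data.frame(gene_a = character(0), gene_b = character(0))
  edgeDoc <- integer(0); edgeA <- integer(0); edgeB <- integer(0)
  if (config$mAttach > 0) {
    pg <- sampleScaleFreeGraph(nG, config$mAttach, config$seed + 3L)
    set.seed(config$seed + 4L)
    realized <- matrix(runif(nrow(pg) * nD), nrow(pg), nD) < config$edgeDocRate
    rhit <- which(realized, arr.ind = TRUE)
    edgeDoc <- rhit[, 2]
    edgeA <- pg$a[rhit[, 1]]
    edgeB <- pg$b[rhit[, 1]]
    cp <- canonicalPair(gid[pg$a], gid[pg$b])
    plantedEdges <- data.frame(gene_a = cp$a, gene_b = cp$b,
                               stringsAsFactors = FALSE)
  }
  # choose surface form per mention
  surfaceOf <- function(geneIdx) {
    useSyn <- runif(length(geneIdx)) < config$synonymUseRate
    out <- sym[geneIdx]
    for (i in which(useSyn)) {
      syn <- synList[[geneIdx[i]]]
      syn <- syn[nzchar(syn)]
      if (length(syn)) out[i] <- syn[sample.int(length(syn), 1L)]
    }
    out
  }
  sentOf <- sample.int(nS, length(mentionDoc), replace = TRUE)
  surf <- surfaceOf(mentionGene)
  # assemble abstract sentences: template filler, gene lists, edge extras
  sentMat <- matrix("", nD, nS)
  key <- paste(mentionDoc, sentOf)
  bySent <- split(seq_along(mentionDoc), key)
  conj <- runif(length(bySent)) < config$conjFraction
  si <- 0L
  for (idx in bySent) {
    si <- si + 1L
    d <- mentionDoc[idx[1]]; s <- sentOf[idx[1]]
    forms <- surf[idx]
    if (conj[si] && length(idx) >= 2L) {
      # coordinated elided form of the first two symbols: "G-0001/0002"
      s1 <- sym[mentionGene[idx[1]]]; s2 <- sym[mentionGene[idx[2]]]
      pair <- sprintf("%s-%s/%s", sub("^G", "G", substr(s1, 1, 1)),
                      sub("^G", "", s1), sub("^G", "", s2))
      forms <- c(pair, surf[idx[-(1:2)]])
    }
    sentMat[d, s] <- paste0("Expression of ",
                            paste(forms, collapse = ", "),
                            " was measured in this cohort.")
  }
  empty <- sentMat == ""
  sentMat[empty] <- "No additional markers were assessed."
  abstracts <- apply(sentMat, 1, paste, collapse = " ")
  if (length(edgeDoc)) {
    extra <- paste0(sym[edgeA], " interacts with ", sym[edgeB], ".")
    extraByDoc <- vapply(split(extra, edgeDoc), paste, "", collapse = " ")
    di <- as.integer(names(extraByDoc))
    abstracts[di] <- paste(abstracts[di], extraByDoc)
  }
  titles <- ifelse(diseased,
                   paste0("Clinical study ", seq_len(nD), " in ",
                          config$diseaseTerm, "."),
                   paste0("Clinical study ", seq_len(nD), "."))
  corpus <- newCorpus(data.frame(doc_id = sprintf("doc%06d", seq_len(nD)),
                                 title = titles, abstract = abstracts,
                                 stringsAsFactors = FALSE))
  # realized truth counts: background incidence plus edge-sentence mentions
  for (i in seq_along(edgeDoc)) {
    inc[edgeDoc[i], edgeA[i]] <- TRUE
    inc[edgeDoc[i], edgeB[i]] <- TRUE
  }
  m <- colSums(inc)
  k <- colSums(inc & diseased)
  counts <- data.frame(gene_id = gid, m = as.integer(m),
                       k = as.integer(k), stringsAsFactors = FALSE)
  truth <- new("SyntheticTruth",
               plantedGenes = gid[seq_len(config$nPlanted)],
               plantedEdges = plantedEdges, counts = counts,
               nDiseaseDocs = sum(diseased), nDocs = nD)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCorpusJsonl(corpus, file.path(dir, "corpus.jsonl"))
    writeTruthJson(truth, file.path(dir, "truth.json"))
  }
  list(corpus = corpus, truth = truth, lexicon = lexicon)
}

#' Write / read synthetic ground truth as JSON
#' @param truth a [SyntheticTruth-class]
#' @param path file path
#' @return \code{path} (write) or a [SyntheticTruth-class] (read)
#' @export
writeTruthJson <- function(truth, path) {
  obj <- list(planted_genes = truth@plantedGenes,
              planted_edges = truth@plantedEdges,
              counts = truth@counts,
              n_disease_docs = truth@nDiseaseDocs,
              n_docs = truth@nDocs)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  pe <- as.data.frame(obj$planted_edges, stringsAsFactors = FALSE)
  if (!nrow(pe)) pe <- data.frame(gene_a = character(0),
                                  gene_b = character(0))
  new("SyntheticTruth",
      plantedGenes = as.character(obj$planted_genes),
      plantedEdges = pe,
      counts = as.data.frame(obj$counts, stringsAsFactors = FALSE),
      nDiseaseDocs = as.integer(obj$n_disease_docs),
      nDocs = as.integer(obj$n_docs))
}

#' Generate synthetic relation files
#'
#' Plants a preferential-attachment scale-free graph over the lexicon's
#' genes and partitions its edges among a KGML-style XML file (relation
#' types ECrel / PPrel / GErel) and a two-column PPI TSV, the formats
#' the network stage consumes. Byte-identical for identical config and
#' seed.
#'
#' @param config a [generatorConfig()] with \code{mAttach >= 1}.
#' @param dir output directory (created if needed); writes
#'   \code{relations.kgml} and \code{ppi.tsv}.
#' @return invisible list with the planted edge data.frame
#'   (\code{gene_a}, \code{gene_b}, \code{source}) and the file paths.
#' @export
simulateRelationFiles <- function(config, dir) {
  if (config$mAttach < 1)
    stop("mAttach must be >= 1 to plant a relation graph", call. = FALSE)
  g <- sampleScaleFreeGraph(config$nGenes, config$mAttach,
                            config$seed + 5L)
  set.seed(config$seed + 6L)
  gid <- as.character(1000L + seq_len(config$nGenes))
  src <- sample(c("ECrel", "PPrel", "GErel", "ppi"), nrow(g),
                replace = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kgmlPath <- file.path(dir, "relations.kgml")
  ppiPath <- file.path(dir, "ppi.tsv")
  inKgml <- src != "ppi"
  used <- sort(unique(c(g$a[inKgml], g$b[inKgml])))
  entryId <- setNames(seq_along(used), used)
  lines <- c("<?xml version=\"1.0\"?>",
             "<pathway name=\"synthetic\" org=\"syn\" number=\"0001\">",
             sprintf("  <entry id=\"%d\" name=\"syn:%s\" type=\"gene\"/>",
                     entryId[as.character(used)], gid[used]),
             sprintf(paste0("  <relation entry1=\"%d\" entry2=\"%d\"",
                            " type=\"%s\"><subtype name=\"binding\"/>",
                            "</relation>"),
                     entryId[as.character(g$a[inKgml])],
                     entryId[as.character(g$b[inKgml])], src[inKgml]),
             "</pathway>")
  writeLines(lines, kgmlPath)
  ppi <- g[src == "ppi", , drop = FALSE]
  writeLines(paste(gid[ppi$a], gid[ppi$b], sep = "\t"), ppiPath)
  cp <- canonicalPair(gid[g$a], gid[g$b])
  invisible(list(edges = data.frame(gene_a = cp$a, gene_b = cp$b,
                                    source = src,
                                    stringsAsFactors = FALSE),
                 kgml = kgmlPath, ppi = ppiPath))
}

#' Score recovery of planted signal
#'
#' Gene level: precision, recall and the empirical false-positive rate
#' among tested non-planted genes, comparing the significant genes of an
#' association table against the planted set. Edge level (optional):
#' Jaccard index between recovered co-citation pairs and planted
#' co-mention pairs.
#'
#' @param results association table from [scoreAllGenes()].
#' @param truth a [SyntheticTruth-class].
#' @param edges optional co-citation edge data.frame from
#'   [cocitationEdges()] (or a [GeneNetwork-class]).
#' @return one-row data.frame: \code{n_tested}, \code{n_significant},
#'   \code{precision} (NA when nothing is called), \code{recall},
#'   \code{fpr}, and \code{edge_jaccard} when edges are given.
#' @export
evaluateRecovery <- function(results, truth, edges = NULL) {
  known <- truth@counts$gene_id
  if (length(setdiff(results$gene_id, known)))
    stop("results contain gene ids absent from the truth: ",
         paste(utils::head(setdiff(results$gene_id, known), 5),
               collapse = ", "), call. = FALSE)
  planted <- truth@plantedGenes
  called <- results$gene_id[results$significant]
  tested <- results$gene_id
  tp <- length(intersect(called, planted))
  nonPlantedTested <- setdiff(tested, planted)
  fp <- length(intersect(called, nonPlantedTested))
  out <- data.frame(
    n_tested = length(tested), n_significant = length(called),
    precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(planted)) tp / length(planted) else NA_real_,
    fpr = if (length(nonPlantedTested))
      fp / length(nonPlantedTested) else NA_real_)
  if (!is.null(edges)) {
    if (is(edges, "GeneNetwork")) edges <- edges@edges
    got <- unique(paste(edges$gene_a, edges$gene_b, sep = "\r"))
    want <- unique(paste(truth@plantedEdges$gene_a,
                         truth@plantedEdges$gene_b, sep = "\r"))
    un <- union(got, want)
    out$edge_jaccard <- if (length(un))
      length(intersect(got, want)) / length(un) else NA_real_
  }
  out
}
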