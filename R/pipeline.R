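# End-to-end orchestration: mine -> enrich -> network -> hubs, driven by
# a single config, with a run manifest for byte-identical reproduction.

#' Build a pipeline configuration
#'
#' Collects every input path and threshold of the full analysis. Paths
#' must exist at validation time. Every stage threshold surfaces as a
#' named key with its conventional default (alpha = 0.05 for both the
#' association and enrichment stages, raw p-values, top 5 percent of
#' nodes as hubs, co-citation support of 2).
#'
#' @param corpus path to the corpus (.jsonl or PubMed .xml).
#' @param lexicon path to the lexicon TSV.
#' @param outputDir output directory (must not contain previous outputs
#'   unless \code{overwrite = TRUE} at run time).
#' @param diseaseTerms character vector of disease phrases.
#' @param gmt,gaf optional annotation files (GMT / GAF); when both are
#'   NULL the enrichment stage is skipped.
#' @param gmtNamespace namespace for the GMT file (default "PATHWAY").
#' @param kgml,ppi optional relation files for the network stage.
#' @param alphaAssociation,alphaEnrichment,alphaCocitation significance
#'   thresholds in (0, 1).
#' @param correction "none" (raw p, default) or "BH".
#' @param strictTail use the strict tail \eqn{P(X > k)}.
#' @param scanTitles scan titles for mentions (default TRUE).
#' @param cocitationSupport minimum co-citing sentences for an edge.
#' @param hubRule,hubParam hub selection rule and parameter
#'   (see [identifyHubs()]).
#' @param networkRestrict "significant" restricts the merged network to
#'   significant genes plus their direct partners; "none" keeps all.
#' @param stopList optional alias stop-list path.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(corpus, lexicon, outputDir,
                           diseaseTerms = "bronchopulmonary dysplasia",
                           gmt = NULL, gaf = NULL,
                           gmtNamespace = "PATHWAY",
                           kgml = NULL, ppi = NULL,
                           alphaAssociation = 0.05,
                           alphaEnrichment = 0.05,
                           alphaCocitation = 0.05,
                           correction = c("none", "BH"),
                           strictTail = FALSE, scanTitles = TRUE,
                           cocitationSupport = 2L,
                           hubRule = "top_fraction", hubParam = 0.05,
                           networkRestrict = c("significant", "none"),
                           stopList = NULL, seed = 1L) {
  correction <- match.arg(correction)
  networkRestrict <- match.arg(networkRestrict)
  for (a in c(alphaAssociation, alphaEnrichment, alphaCocitation))
    stopifnotScalarProb(a, "alpha")
  paths <- list(corpus = corpus, lexicon = lexicon, gmt = gmt, gaf = gaf,
                kgml = kgml, ppi = ppi, stopList = stopList)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("config path for '", nm, "' does not exist: ", p,
           call. = FALSE)
  }
  if (!length(diseaseTerms) || !any(nzchar(diseaseTerms)))
    stop("diseaseTerms must be non-empty", call. = FALSE)
  structure(list(corpus = corpus, lexicon = lexicon,
                 outputDir = outputDir, diseaseTerms = diseaseTerms,
                 gmt = gmt, gaf = gaf, gmtNamespace = gmtNamespace,
                 kgml = kgml, ppi = ppi,
                 alphaAssociation = alphaAssociation,
                 alphaEnrichment = alphaEnrichment,
                 alphaCocitation = alphaCocitation,
                 correction = correction, strictTail = strictTail,
                 scanTitles = scanTitles,
                 cocitationSupport = as.integer(cocitationSupport),
                 hubRule = hubRule, hubParam = hubParam,
                 networkRestrict = networkRestrict,
                 stopList = stopList, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path path to the YAML config file.
#' @return a \code{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (nm in c("corpus", "lexicon", "gmt", "gaf", "kgml", "ppi",
               "stopList"))
    y[[nm]] <- resolve(y[[nm]])
  if (!is.null(y$outputDir) && !startsWith(y$outputDir, "/"))
    y$outputDir <- file.path(base, y$outputDir)
  do.call(pipelineConfig, y)
}

loadCorpusFile <- function(path) {
  if (grepl("\\.xml$", path, ignore.case = TRUE)) readPubmedXml(path)
  else readCorpusJsonl(path)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

writeManifest <- function(config, dir, files) {
  paths <- file.path(dir, files)
  obj <- list(config = unclass(config),
              config_md5 = configHash(config),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("litGeneNet")),
              outputs = setNames(as.list(unname(tools::md5sum(paths))),
                                 files))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                              pretty = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
}

prepareOutputDir <- function(dir, files, overwrite) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  existing <- files[file.exists(file.path(dir, files))]
  if (length(existing) && !overwrite)
    stop("output(s) already present in ", dir, ": ",
         paste(existing, collapse = ", "),
         " (outputs are write-once; use overwrite = TRUE)", call. = FALSE)
}

#' Run the mining stage
#'
#' Chains corpus parsing, sentence segmentation, mention tagging with
#' conjunction resolution, document-level counting and hypergeometric
#' scoring; writes \code{associations.tsv}, \code{mentions.tsv} and a
#' \code{manifest.json} with the config hash and output checksums.
#' Re-running the same config reproduces every output byte-identically.
#'
#' @param config a [pipelineConfig()].
#' @param overwrite allow overwriting existing outputs.
#' @return the association data.frame, invisibly.
#' @export
runMine <- function(config, overwrite = FALSE) {
  files <- c("associations.tsv", "mentions.tsv")
  prepareOutputDir(config$outputDir, files, overwrite)
  res <- mineStage(config)
  writeMentions(res$mentions, file.path(config$outputDir, "mentions.tsv"))
  writeAssociations(res$associations,
                    file.path(config$outputDir, "associations.tsv"))
  writeManifest(config, config$outputDir, files)
  message("mine: ", length(res$corpus), " documents, ",
          nrow(res$mentions), " mentions, ",
          nrow(res$associations), " genes tested, ",
          sum(res$associations$significant), " significant")
  invisible(res$associations)
}

mineStage <- function(config) {
  corpus <- withStage("parse", loadCorpusFile(config$corpus))
  lexicon <- withStage("lexicon",
                       readLexicon(config$lexicon, config$stopList))
  mentions <- withStage("tag",
    tagMentions(corpus, lexicon, scanTitles = config$scanTitles))
  counts <- withStage("count",
    countGeneDisease(corpus, mentions, config$diseaseTerms))
  associations <- withStage("score",
    scoreAllGenes(counts, alpha = config$alphaAssociation,
                  correction = config$correction,
                  strict = config$strictTail, lexicon = lexicon))
  list(corpus = corpus, lexicon = lexicon, mentions = mentions,
       associations = associations)
}

#' Run the full pipeline
#'
#' Mining, then enrichment of the significant gene set (skipped with a
#' notice when no annotation file is configured), then the merged
#' network (curated relations plus sentence-level co-citation), degree
#' histogram, power-law fit and hub table. When no gene is significant
#' the network falls back to co-citation edges over all mentioned genes.
#' A stage failure halts the run; outputs already written are preserved.
#'
#' @param config a [pipelineConfig()].
#' @param overwrite allow overwriting existing outputs.
#' @return invisible list with all stage results.
#' @export
runAll <- function(config, overwrite = FALSE) {
  files <- c("associations.tsv", "mentions.tsv", "enrichment.tsv",
             "namespace_summary.tsv", "network_edges.tsv", "network.sif",
             "network.graphml", "degree_histogram.tsv", "powerlaw.json",
             "hubs.tsv")
  prepareOutputDir(config$outputDir, files, overwrite)
  res <- mineStage(config)
  out <- config$outputDir
  writeMentions(res$mentions, file.path(out, "mentions.tsv"))
  writeAssociations(res$associations, file.path(out, "associations.tsv"))
  sigGenes <- res$associations$gene_id[res$associations$significant]
  message("mine: ", length(res$corpus), " documents -> ",
          nrow(res$associations), " genes tested -> ",
          length(sigGenes), " significant")

  written <- c("associations.tsv", "mentions.tsv")
  annotations <- NULL
  if (!is.null(config$gmt) || !is.null(config$gaf)) {
    annotations <- withStage("enrich", rbind(
      if (!is.null(config$gmt)) readGmt(config$gmt, config$gmtNamespace),
      if (!is.null(config$gaf)) readGaf(config$gaf)))
  }
  if (!is.null(annotations) && length(sigGenes)) {
    enr <- withStage("enrich", {
      bg <- unique(annotations$gene_id)
      enrichGeneSets(intersect(sigGenes, bg), annotations,
                     alpha = config$alphaEnrichment)
    })
    utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summarizeByNamespace(enr),
                       file.path(out, "namespace_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, "enrichment.tsv", "namespace_summary.tsv")
    message("enrich: ", sum(enr$significant), " of ", nrow(enr),
            " terms significant")
  } else {
    message("enrich: skipped (",
            if (is.null(annotations)) "no annotation file configured"
            else "no significant genes", ")")
  }

  network <- withStage("network", {
    cocit <- cocitationEdges(res$corpus, res$mentions,
                             alpha = config$alphaCocitation,
                             minSupport = config$cocitationSupport)
    curated <- list(
      if (!is.null(config$kgml)) readKgml(config$kgml),
      if (!is.null(config$ppi)) readPpiTable(config$ppi, res$lexicon))
    curated <- curated[!vapply(curated, is.null, TRUE)]
    restrict <- if (config$networkRestrict == "significant" &&
                    length(sigGenes)) sigGenes else NULL
    do.call(mergeNetwork, c(list(cocit), curated,
                            list(restrictTo = restrict)))
  })
  exportNetwork(network, file.path(out, "network_edges.tsv"), "tsv")
  exportNetwork(network, file.path(out, "network.sif"), "sif")
  exportNetwork(network, file.path(out, "network.graphml"), "graphml")
  written <- c(written, "network_edges.tsv", "network.sif",
               "network.graphml")
  message("network: ", length(networkNodes(network)), " nodes, ",
          nrow(networkEdges(network)), " edges")

  fit <- NULL; hubs <- NULL
  if (nrow(networkEdges(network))) {
    hist <- degreeHistogram(network)
    utils::write.table(hist, file.path(out, "degree_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, "degree_histogram.tsv")
    fit <- tryCatch(fitPowerLaw(hist), error = function(e) NULL)
    if (!is.null(fit)) {
      writeLines(jsonlite::toJSON(list(exponent = fit@exponent,
                                       method = fit@method,
                                       d_min = fit@dMin,
                                       goodness = fit@goodness,
                                       is_power_law = fit@isPowerLaw),
                                  auto_unbox = TRUE, digits = NA),
                 file.path(out, "powerlaw.json"))
      written <- c(written, "powerlaw.json")
    }
    hubs <- identifyHubs(network, rule = config$hubRule,
                         param = config$hubParam, lexicon = res$lexicon)
    utils::write.table(hubs, file.path(out, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, "hubs.tsv")
    message("hubs: ", nrow(hubs), " genes (rule ", config$hubRule, ")")
  }
  writeManifest(config, out, written)
  invisible(list(associations = res$associations, network = network,
                 powerLaw = fit, hubs = hubs))
}
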