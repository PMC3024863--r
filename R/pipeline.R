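# End-to-end pipeline runners behind the exec/causaltf command-line wrapper.
# All outputs are deterministic functions of the inputs (no timestamps), so
# reruns are byte-identical.

.provHeader <- function() {
  sprintf("# causalTF %s",
          as.character(utils::packageVersion("causalTF")))
}

.writeTSV <- function(tab, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provHeader(), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline run configuration from YAML
#'
#' Recognised keys: input paths (`tf_dna`, `ptm`, `modulator`, `roster`,
#' `expression` or `degs`, optional `universe` and `gene_product`), thresholds
#' (`lls_threshold` 4, `min_set_size` 4, `ranksum_alpha` 0.005, `valid_p`
#' 0.01, `top_k` 20, `deg_criterion`, `deg_threshold`), `out_dir`, `seed`.
#' Missing thresholds take the defaults in parentheses.
#'
#' @param path YAML file path.
#' @param overrides named list of values that win over the file's.
#' @return a validated config list.
#' @export
loadRunConfig <- function(path, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  cfg[names(overrides)] <- overrides
  defaults <- list(lls_threshold = 4, min_set_size = 4L,
                   ranksum_alpha = 0.005, valid_p = 0.01, top_k = 20L,
                   deg_criterion = "p_le", deg_threshold = 0.01,
                   seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$ranksum_alpha >= 0, cfg$ranksum_alpha <= 1,
            cfg$valid_p >= 0, cfg$valid_p <= 1,
            cfg$min_set_size >= 1, cfg$top_k >= 1)
  cfg
}

.loadNetwork <- function(cfg) {
  for (k in c("tf_dna", "roster")) {
    if (is.null(cfg[[k]])) stop("config is missing required input: ", k)
    if (!file.exists(cfg[[k]])) stop("input file not found: ", cfg[[k]])
  }
  tx <- readInteractionTable(cfg$tf_dna, "transcription",
                             scoreThreshold = cfg$lls_threshold)
  ptm <- if (!is.null(cfg$ptm))
    readInteractionTable(cfg$ptm, "modification") else NULL
  modu <- if (!is.null(cfg$modulator))
    readInteractionTable(cfg$modulator, "modification") else NULL
  gp <- if (!is.null(cfg$gene_product)) {
    tab <- utils::read.delim(cfg$gene_product, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (!all(c("gene", "protein") %in% names(tab)))
      stop("gene_product table needs 'gene' and 'protein' columns: ",
           cfg$gene_product)
    stats::setNames(tab$protein, tab$gene)
  } else character()
  buildNetwork(tx, ptm, modu, tfRoster = readGeneList(cfg$roster),
               geneProduct = gp)
}

.loadDEGs <- function(cfg) {
  if (!is.null(cfg$degs)) {
    genes <- readGeneList(cfg$degs)
    new("DEGSet", genes = genes,
        criterion = list(statistic = "precomputed", threshold = NA,
                         direction = "listed"),
        measuredUniverse = character())
  } else if (!is.null(cfg$expression)) {
    selectDEGs(readExpressionTable(cfg$expression), cfg$deg_criterion,
               cfg$deg_threshold)
  } else stop("config needs either 'degs' or 'expression'")
}

#' Run the full ranking pipeline
#'
#' Reads the edge tables, assembles the network, selects candidate TFs,
#' builds their six downstream sets, scores them against the DEG list,
#' applies the rank-sum acceptability filter and ranks the candidates.
#' Writes `ranked.tsv`, `acceptability.tsv`, `downstream_sets.gmt` and
#' `provenance.json` into `out_dir`.
#'
#' @param config a config list from [loadRunConfig()] (or built by hand).
#' @return invisibly, a list with the ranked `data.frame`, the
#'   [ModelAcceptability-class], and the output paths.
#' @export
runRank <- function(config) {
  net <- .loadNetwork(config)
  degs <- .loadDEGs(config)
  universe <- if (!is.null(config$universe)) readGeneList(config$universe)
    else if (length(measuredUniverse(degs))) measuredUniverse(degs)
    else geneUniverse(net)
  d <- intersect(degGenes(degs), universe)
  degs <- new("DEGSet", genes = d, criterion = degCriterion(degs),
              measuredUniverse = universe)
  cands <- candidateTFs(net, config$min_set_size)
  if (length(cands) < 2L)
    stop("fewer than 2 candidate TFs pass the size filter; cannot rank")
  setsList <- lapply(cands, allDownstreamSets, net = net)
  results <- lapply(setsList, scoreTF, degs = degs, universe = universe)
  acc <- acceptableModels(results, alpha = config$ranksum_alpha)
  ranked <- rankCandidates(results, acc, validP = config$valid_p)

  outDir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ranked = file.path(outDir, "ranked.tsv"),
                acceptability = file.path(outDir, "acceptability.tsv"),
                gmt = file.path(outDir, "downstream_sets.gmt"),
                provenance = file.path(outDir, "provenance.json"))
  rk <- ranked
  rk$minP <- formatC(rk$minP, digits = 17, format = "g")
  .writeTSV(rk, paths$ranked)
  at <- acceptabilityTable(acc)
  at$ranksumP <- formatC(at$ranksumP, digits = 17, format = "g")
  .writeTSV(at, paths$acceptability)
  writeGeneSetsGMT(setsList, paths$gmt)

  inputs <- Filter(Negate(is.null),
                   config[c("tf_dna", "ptm", "modulator", "roster",
                            "expression", "degs", "universe")])
  prov <- list(
    package = "causalTF",
    version = as.character(utils::packageVersion("causalTF")),
    thresholds = config[c("lls_threshold", "min_set_size", "ranksum_alpha",
                          "valid_p", "top_k", "deg_criterion",
                          "deg_threshold")],
    universe_size = length(universe),
    n_degs = length(degGenes(degs)),
    n_candidates = length(cands),
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1))))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(ranked = ranked, acceptability = acc, paths = paths))
}

#' Evaluate a ranked result against a gold TF set
#'
#' @param rankedPath `ranked.tsv` written by [runRank()].
#' @param goldPath gene list of gold-positive TFs.
#' @param candidatesPath gene list of the candidate pool.
#' @param outPath where to write the TSV report.
#' @param unprofiledPath optional gene list of unprofiled identifiers.
#' @param pThreshold valid-finding threshold on `minP` (default 0.01).
#' @param topK optional rank gate; `NULL` (default) predicts every valid
#'   finding regardless of rank.
#' @return invisibly, the [EvaluationReport-class].
#' @export
runEvaluate <- function(rankedPath, goldPath, candidatesPath, outPath,
                        unprofiledPath = NULL, pThreshold = 0.01,
                        topK = NULL) {
  ranked <- utils::read.delim(rankedPath, comment.char = "#",
                              stringsAsFactors = FALSE)
  predicted <- ranked$tf[ranked$minP <= pThreshold]
  if (!is.null(topK))
    predicted <- intersect(predicted, ranked$tf[ranked$rank <= topK])
  gold <- readGeneList(goldPath)
  cands <- readGeneList(candidatesPath)
  unprof <- if (!is.null(unprofiledPath)) readGeneList(unprofiledPath)
    else character()
  report <- confusionVsGold(predicted, gold, cands, unprof)
  writeEvaluationReport(report, outPath)
  invisible(report)
}

#' Run a simulation scenario and write its artifacts
#'
#' Writes the network edge tables (`transcription.tsv`,
#' `modification.tsv`), the roster and DEG list, a ground-truth record
#' (`truth.json`) and a recovery summary (`recovery.tsv`) to `outDir`.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param outDir output directory.
#' @param nReplicates replicates for the recovery summary (default 20).
#' @return invisibly, the [recoveryExperiment()] summary.
#' @export
runSimulate <- function(scenario, outDir, nReplicates = 20L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- generateNetwork(scenario)
  trueTF <- .resolveTrueTF(scenario, net)
  .writeTSV(transcriptionEdges(net), file.path(outDir, "transcription.tsv"))
  .writeTSV(modificationEdges(net), file.path(outDir, "modification.tsv"))
  writeLines(tfRoster(net), file.path(outDir, "roster.txt"))
  degs <- simulatePerturbation(net, trueTF, scenario@trueModel,
                               scenario@tpr, scenario@fpr,
                               seed = scenario@seed + 1000000L)
  writeLines(degGenes(degs), file.path(outDir, "degs.txt"))
  jsonlite::write_json(
    list(true_tf = trueTF, true_model = scenario@trueModel,
         tpr = scenario@tpr, fpr = scenario@fpr, seed = scenario@seed),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  summ <- recoveryExperiment(scenario, nReplicates)
  .writeTSV(summ$replicates, file.path(outDir, "recovery.tsv"))
  invisible(summ)
}
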