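# Synthetic networks and perturbation DEG lists with known ground truth.
# RNG discipline: every sampling function seeds a private stream and
# restores the caller's .Random.seed on exit, so network generation and
# DEG sampling never perturb each other.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The toy six-model network
#'
#' The small worked example behind the model definitions: focal TF A
#' transcribes g1, g2, g3; A phosphorylates TF B (whose target is g4); g2
#' codes for TF C (target g5), g4 for TF D (target g6) and g5 for TF F
#' (target g8); g1 is a modulator protein X that modifies TF E (target g7).
#' A's six downstream sets are then {g1,g2,g3}, {g1..g4}, {g1..g6},
#' {g1,g2,g3,g4,g7}, {g1..g7} and {g1..g8}.
#'
#' @return a [RegulatoryNetwork-class].
#' @examples
#' modelSets(allDownstreamSets(toyNetwork(), "A"))
#' @export
toyNetwork <- function() {
  tx <- new("EdgeTable", kind = "transcription", records = data.frame(
    source = c("A", "A", "A", "B", "C", "D", "E", "F"),
    target = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    score = NA_real_, stringsAsFactors = FALSE))
  ptm <- new("EdgeTable", kind = "modification", records = data.frame(
    source = "A", target = "B", subkind = "kinase",
    stringsAsFactors = FALSE))
  modu <- new("EdgeTable", kind = "modification", records = data.frame(
    source = "g1", target = "E", subkind = "modulator",
    stringsAsFactors = FALSE))
  buildNetwork(tx, ptm, modu,
               tfRoster = c("A", "B", "C", "D", "E", "F"),
               geneProduct = c(g2 = "C", g4 = "D", g5 = "F"))
}

#' Construct a synthetic scenario
#'
#' Validated constructor for [SyntheticScenario-class]; see that class for
#' the meaning and defaults of every parameter. Defaults describe a
#' yeast-scale study: 140 TFs over a ~6000-gene universe with moderately
#' noisy DEG calling (tpr 0.8, fpr 0.02).
#'
#' @param nTF,nGenes,meanOutDegree,cascadeFraction,nKinaseEdges,nModulators
#'   network parameters; see [SyntheticScenario-class].
#' @param trueTF perturbed TF (default `""`: the first generated TF).
#' @param trueModel model the perturbation propagates through.
#' @param tpr,fpr DEG-calling rates.
#' @param seed integer seed.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nTF = 140L, nGenes = 6000L, meanOutDegree = 20,
                              cascadeFraction = 0.15, nKinaseEdges = 60L,
                              nModulators = 30L, trueTF = "",
                              trueModel = "I", tpr = 0.8, fpr = 0.02,
                              seed = 1L) {
  new("SyntheticScenario", nTF = as.integer(nTF), nGenes = as.integer(nGenes),
      meanOutDegree = meanOutDegree, cascadeFraction = cascadeFraction,
      nKinaseEdges = as.integer(nKinaseEdges),
      nModulators = as.integer(nModulators), trueTF = trueTF,
      trueModel = trueModel, tpr = tpr, fpr = fpr, seed = as.integer(seed))
}

#' Generate a random layered regulatory network
#'
#' TF identifiers double as their coding-gene identifiers (the yeast-ORF
#' convention), so a transcription edge onto a TF id creates a cascade.
#' Each TF draws `1 + Poisson(meanOutDegree - 1)` transcription targets; a
#' `Binomial(outDegree, cascadeFraction)` share of them are other TFs, the
#' rest background genes. `nKinaseEdges` TF -> TF kinase edges and
#' `nModulators` modulator -> TF edges (modulator proteins drawn from
#' background genes that are transcription targets) are then sprinkled in.
#' Pure function of (scenario parameters, seed).
#'
#' @param scenario a [SyntheticScenario-class].
#' @return a [RegulatoryNetwork-class].
#' @examples
#' net <- generateNetwork(syntheticScenario(nTF = 10, nGenes = 100, seed = 7))
#' net
#' @export
generateNetwork <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  validObject(scenario)
  .withSeed(scenario@seed, {
    tfs <- sprintf("TF%03d", seq_len(scenario@nTF))
    genes <- sprintf("G%05d", seq_len(scenario@nGenes))
    src <- character(); tgt <- character()
    for (tf in tfs) {
      deg <- 1L + stats::rpois(1L, scenario@meanOutDegree - 1)
      nTfTgt <- stats::rbinom(1L, deg, scenario@cascadeFraction)
      nTfTgt <- min(nTfTgt, scenario@nTF - 1L)
      tfTgt <- if (nTfTgt > 0L) sample(setdiff(tfs, tf), nTfTgt)
        else character()
      nGeneTgt <- min(deg - nTfTgt, scenario@nGenes)
      geneTgt <- if (nGeneTgt > 0L) sample(genes, nGeneTgt) else character()
      tg <- c(tfTgt, geneTgt)
      src <- c(src, rep(tf, length(tg)))
      tgt <- c(tgt, tg)
    }
    tx <- data.frame(source = src, target = tgt, score = NA_real_,
                     stringsAsFactors = FALSE)
    tx <- tx[!duplicated(paste(tx$source, tx$target, sep = "\r")), ,
             drop = FALSE]
    rownames(tx) <- NULL

    mod <- data.frame(source = character(), target = character(),
                      subkind = character(), stringsAsFactors = FALSE)
    if (scenario@nKinaseEdges > 0L && scenario@nTF >= 2L) {
      ks <- sample(tfs, scenario@nKinaseEdges, replace = TRUE)
      kt <- vapply(ks, function(s) sample(setdiff(tfs, s), 1L), character(1))
      km <- data.frame(source = ks, target = kt, subkind = "kinase",
                       stringsAsFactors = FALSE)
      mod <- rbind(mod, km)
    }
    eligible <- intersect(unique(tx$target), genes)  # transcribed non-TF genes
    nMods <- min(scenario@nModulators, length(eligible))
    if (nMods > 0L && scenario@nTF >= 1L) {
      xs <- sample(eligible, nMods)
      xt <- sample(tfs, nMods, replace = TRUE)
      mm <- data.frame(source = xs, target = xt, subkind = "modulator",
                       stringsAsFactors = FALSE)
      mod <- rbind(mod, mm)
    }
    mod <- mod[!duplicated(paste(mod$source, mod$target, mod$subkind,
                                 sep = "\r")), , drop = FALSE]
    rownames(mod) <- NULL
    new("RegulatoryNetwork", tfRoster = tfs, transcription = tx,
        modification = mod, geneProduct = character())
  })
}

.resolveTrueTF <- function(scenario, net) {
  if (nzchar(scenario@trueTF)) scenario@trueTF else tfRoster(net)[1L]
}

#' Simulate the DEG list of a TF perturbation
#'
#' Each gene of the true model's downstream set enters the DEG list with
#' probability `tpr`; every other universe gene with probability `fpr`.
#' The measured universe is the network's gene universe.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param trueTF the perturbed TF.
#' @param trueModel the model its effect propagates through.
#' @param tpr,fpr DEG-calling rates in `[0, 1]`.
#' @param seed integer seed (private stream; the caller's RNG state is
#'   untouched).
#' @return a [DEGSet-class].
#' @export
simulatePerturbation <- function(net, trueTF, trueModel, tpr, fpr, seed) {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (!trueModel %in% MODEL_IDS) stop("trueModel must be one of I..VI")
  if (tpr < 0 || tpr > 1 || fpr < 0 || fpr > 1)
    stop("tpr and fpr must be in [0, 1]")
  trueSet <- downstreamSet(net, trueTF, trueModel)
  universe <- geneUniverse(net)
  trueSet <- intersect(trueSet, universe)
  if (!length(trueSet))
    warning("true downstream set is empty; DEGs drawn from background only")
  background <- setdiff(universe, trueSet)
  .withSeed(as.integer(seed), {
    d <- c(trueSet[stats::runif(length(trueSet)) < tpr],
           background[stats::runif(length(background)) < fpr])
    new("DEGSet", genes = sort(d),
        criterion = list(statistic = "simulated",
                         threshold = c(tpr = tpr, fpr = fpr),
                         direction = "membership"),
        measuredUniverse = universe)
  })
}

#' Perturbation-recovery experiment
#'
#' Generates the scenario's network once, then for each replicate draws a
#' DEG list from the true TF/model and runs the full pipeline (downstream
#' sets for every candidate TF, hypergeometric scoring, rank-sum
#' acceptability filter, ranking). Reports how often the true TF was
#' correctly identified (valid finding within the top `topK`), the rank
#' distribution, and how often the best model matched the true model.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param nReplicates number of DEG replicates (>= 1).
#' @param minSize candidate-TF downstream-size filter (default 4).
#' @param alpha rank-sum acceptability threshold (default 0.005).
#' @param topK,pThreshold correct-identification rule (defaults 20, 0.01).
#' @return a list: `recoveryFraction`, `bestModelFraction`, `ranks`
#'   (integer vector), `replicates` (per-replicate `data.frame`),
#'   `nCandidates`, `trueTF`, `trueModel`.
#' @export
recoveryExperiment <- function(scenario, nReplicates, minSize = 4L,
                               alpha = 0.005, topK = 20L, pThreshold = 0.01) {
  stopifnot(is(scenario, "SyntheticScenario"), nReplicates >= 1L)
  net <- generateNetwork(scenario)
  trueTF <- .resolveTrueTF(scenario, net)
  cands <- candidateTFs(net, minSize)
  if (!trueTF %in% cands)
    stop("perturbed TF does not pass the candidate filter: ", trueTF)
  setsList <- lapply(cands, allDownstreamSets, net = net)
  universe <- geneUniverse(net)
  reps <- lapply(seq_len(nReplicates), function(r) {
    degs <- simulatePerturbation(net, trueTF, scenario@trueModel,
                                 scenario@tpr, scenario@fpr,
                                 seed = scenario@seed + 1000000L + r)
    results <- suppressWarnings(
      lapply(setsList, scoreTF, degs = degs, universe = universe))
    acc <- acceptableModels(results, alpha = alpha)
    ranked <- rankCandidates(results, acc, validP = pThreshold)
    i <- match(trueTF, ranked$tf)
    data.frame(replicate = r, rank = ranked$rank[i], minP = ranked$minP[i],
               bestModel = ranked$bestModel[i],
               correct = correctlyIdentified(ranked, trueTF, topK, pThreshold),
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, reps)
  list(recoveryFraction = mean(reps$correct),
       bestModelFraction = mean(reps$bestModel == scenario@trueModel),
       ranks = reps$rank, replicates = reps, nCandidates = length(cands),
       trueTF = trueTF, trueModel = scenario@trueModel)
}
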