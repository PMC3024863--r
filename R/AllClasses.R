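#' @import methods
NULL

MODEL_IDS <- c("I", "II", "III", "IV", "V", "VI")

MODEL_LABELS <- c(
  I   = "simple direct",
  II  = "PTM-mediated direct",
  III = "two-layer cascade",
  IV  = "PTM-mediated two-layer cascade",
  V   = "hybrid two-layer cascade",
  VI  = "three-layer cascade"
)

EDGE_KINDS <- c("transcription", "modification")
PTM_SUBKINDS <- c("kinase", "phosphatase", "modulator")

.nonEmptyChr <- function(x) {
  is.character(x) && !anyNA(x) && all(nzchar(x))
}

#' EdgeTable: a typed directed edge list
#'
#' Holds either transcription (regulator -> target gene, optional
#' log-likelihood score) or modification (modifier protein -> substrate
#' protein, with a subkind among kinase/phosphatase/modulator) edges.
#' Records are deduplicated on load and retain load order.
#'
#' @slot kind `"transcription"` or `"modification"`.
#' @slot records `data.frame` with columns `source`, `target`, and `score`
#'   (transcription, `NA` when absent) or `subkind` (modification).
#'
#' @seealso [readInteractionTable()], [buildNetwork()]
#' @export
setClass("EdgeTable",
  representation(kind = "character", records = "data.frame"),
  prototype(kind = "transcription",
            records = data.frame(source = character(), target = character(),
                                 score = numeric(),
                                 stringsAsFactors = FALSE))
)

setValidity("EdgeTable", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% EDGE_KINDS)
    msgs <- c(msgs, "kind must be one of 'transcription', 'modification'")
  rec <- object@records
  if (!all(c("source", "target") %in% names(rec)))
    msgs <- c(msgs, "records must have 'source' and 'target' columns")
  else {
    if (nrow(rec) && !.nonEmptyChr(rec$source))
      msgs <- c(msgs, "edge sources must be non-empty strings")
    if (nrow(rec) && !.nonEmptyChr(rec$target))
      msgs <- c(msgs, "edge targets must be non-empty strings")
    if (identical(object@kind, "transcription")) {
      if (!"score" %in% names(rec))
        msgs <- c(msgs, "transcription records need a 'score' column (NA allowed)")
      key <- paste(rec$source, rec$target, sep = "\r")
      if (anyDuplicated(key))
        msgs <- c(msgs, "duplicate (source, target) transcription records")
    } else {
      if (!"subkind" %in% names(rec))
        msgs <- c(msgs, "modification records need a 'subkind' column")
      else if (nrow(rec) && !all(rec$subkind %in% PTM_SUBKINDS))
        msgs <- c(msgs, sprintf("subkind must be one of: %s",
                                paste(PTM_SUBKINDS, collapse = ", ")))
      if ("score" %in% names(rec) && nrow(rec) && !all(is.na(rec$score)))
        msgs <- c(msgs, "score is only meaningful on transcription edges")
      key <- paste(rec$source, rec$target, rec$subkind, sep = "\r")
      if (anyDuplicated(key))
        msgs <- c(msgs, "duplicate (source, target, subkind) modification records")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RegulatoryNetwork: transcription + modification edges over a TF roster
#'
#' The integrated network the downstream models are built on. Transcription
#' edges run from a TF (protein identifier) to a target gene; modification
#' edges run from a modifier protein to a substrate protein and carry a
#' subkind (kinase, phosphatase or modulator). `geneProduct` optionally maps
#' a target-gene identifier to the protein it codes for; unmapped genes code
#' for the protein of the same identifier (the yeast-ORF convention).
#'
#' @slot tfRoster character vector of TF (protein) identifiers.
#' @slot transcription `data.frame(source, target, score)`.
#' @slot modification `data.frame(source, target, subkind)`.
#' @slot geneProduct named character vector, gene id -> protein id.
#'
#' @seealso [buildNetwork()], [downstreamSet()], [geneUniverse()]
#' @export
setClass("RegulatoryNetwork",
  representation(tfRoster = "character",
                 transcription = "data.frame",
                 modification = "data.frame",
                 geneProduct = "character"),
  prototype(tfRoster = character(),
            transcription = data.frame(source = character(),
                                       target = character(),
                                       score = numeric(),
                                       stringsAsFactors = FALSE),
            modification = data.frame(source = character(),
                                      target = character(),
                                      subkind = character(),
                                      stringsAsFactors = FALSE),
            geneProduct = character())
)

setValidity("RegulatoryNetwork", function(object) {
  msgs <- character()
  if (anyDuplicated(object@tfRoster))
    msgs <- c(msgs, "tfRoster contains duplicates")
  tx <- object@transcription
  if (nrow(tx)) {
    bad <- setdiff(unique(tx$source), object@tfRoster)
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "transcription-edge source(s) not in tfRoster: %s",
        paste(bad, collapse = ", ")))
  }
  md <- object@modification
  if (nrow(md) && !all(md$subkind %in% PTM_SUBKINDS))
    msgs <- c(msgs, "modification subkinds must be kinase/phosphatase/modulator")
  gp <- object@geneProduct
  if (length(gp) && (is.null(names(gp)) || any(!nzchar(names(gp)))))
    msgs <- c(msgs, "geneProduct must be a named character vector")
  if (length(msgs)) msgs else TRUE
})

#' DEGSet: a set of differentially expressed genes
#'
#' @slot genes character vector of DEG identifiers.
#' @slot criterion list recording how the set was selected
#'   (`statistic`, `threshold`, `direction`).
#' @slot measuredUniverse character vector of all genes profiled in the
#'   experiment (length 0 when not provided).
#'
#' @seealso [selectDEGs()], [scoreTF()]
#' @export
setClass("DEGSet",
  representation(genes = "character", criterion = "list",
                 measuredUniverse = "character"),
  prototype(genes = character(), criterion = list(),
            measuredUniverse = character())
)

setValidity("DEGSet", function(object) {
  msgs <- character()
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "DEG identifiers must be unique")
  if (length(object@measuredUniverse) &&
      !all(object@genes %in% object@measuredUniverse))
    msgs <- c(msgs, "DEGs must be a subset of the measured universe")
  if (length(msgs)) msgs else TRUE
})

#' DownstreamSets: the six expected-target gene sets of one TF
#'
#' One gene set per regulation model I-VI, together with the mediator
#' proteins each model recruited (roles B, C, D, E, X, F).
#'
#' @slot tf the focal TF identifier.
#' @slot sets named list, model id -> character vector of downstream genes.
#' @slot mediators named list, model id -> named list of role -> identifiers.
#'
#' @seealso [allDownstreamSets()], [modelSets()]
#' @export
setClass("DownstreamSets",
  representation(tf = "character", sets = "list", mediators = "list"),
  prototype(tf = NA_character_, sets = list(), mediators = list())
)

setValidity("DownstreamSets", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@sets)), sort(MODEL_IDS)))
    msgs <- c(msgs, "sets must be named I..VI")
  else {
    s <- object@sets
    ok <- all(s$I %in% s$II) && all(s$II %in% s$III) &&
      all(s$II %in% s$IV) && setequal(s$V, union(s$III, s$IV)) &&
      all(s$V %in% s$VI)
    if (!ok)
      msgs <- c(msgs, "model nesting violated (need I<=II<=III, II<=IV, V=III+IV, V<=VI)")
  }
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentResult: per-model hypergeometric overlap scores for one TF
#'
#' @slot tf the TF identifier.
#' @slot table `data.frame(model, K, k, p)`: expected-target set size K,
#'   overlap count k with the DEGs, and the upper-tail hypergeometric
#'   p-value, one row per model I-VI.
#' @slot n number of DEGs.
#' @slot N universe size.
#'
#' @seealso [scoreTF()], [rankCandidates()]
#' @export
setClass("EnrichmentResult",
  representation(tf = "character", table = "data.frame",
                 n = "integer", N = "integer"),
  prototype(tf = NA_character_,
            table = data.frame(model = character(), K = integer(),
                               k = integer(), p = numeric(),
                               stringsAsFactors = FALSE),
            n = 0L, N = 0L)
)

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  tb <- object@table
  if (!all(c("model", "K", "k", "p") %in% names(tb)))
    msgs <- c(msgs, "table must have columns model, K, k, p")
  else if (nrow(tb)) {
    if (!identical(tb$model, MODEL_IDS))
      msgs <- c(msgs, "table must have one row per model I..VI, in order")
    if (any(tb$k > pmin(tb$K, object@n)) || any(tb$k < 0L))
      msgs <- c(msgs, "overlap counts must satisfy 0 <= k <= min(K, n)")
    if (any(tb$p <= 0 | tb$p > 1))
      msgs <- c(msgs, "p-values must be in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelAcceptability: which models survive the rank-sum filter
#'
#' For each model m != I, a two-sample Wilcoxon rank-sum test compares the
#' candidate-wide distribution of model-m overlap p-values with Model I's.
#' Models whose distribution differs (test p <= alpha) are unacceptable;
#' Model I is always acceptable.
#'
#' @slot table `data.frame(model, ranksumP, acceptable)`.
#' @slot alpha the significance threshold used (default 0.005).
#'
#' @seealso [acceptableModels()]
#' @export
setClass("ModelAcceptability",
  representation(table = "data.frame", alpha = "numeric"),
  prototype(table = data.frame(model = character(), ranksumP = numeric(),
                               acceptable = logical(),
                               stringsAsFactors = FALSE),
            alpha = 0.005)
)

setValidity("ModelAcceptability", function(object) {
  msgs <- character()
  tb <- object@table
  if (!all(c("model", "ranksumP", "acceptable") %in% names(tb)))
    msgs <- c(msgs, "table needs columns model, ranksumP, acceptable")
  else if (nrow(tb)) {
    if (!identical(tb$model, MODEL_IDS))
      msgs <- c(msgs, "table must cover models I..VI in order")
    if (!isTRUE(tb$acceptable[tb$model == "I"]))
      msgs <- c(msgs, "Model I must always be acceptable")
    other <- tb[tb$model != "I", ]
    if (!all(other$acceptable == (other$ranksumP > object@alpha)))
      msgs <- c(msgs, "acceptable must equal (ranksumP > alpha) for models != I")
  }
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a single value in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: confusion counts and Jaccard score against a gold set
#'
#' @slot tp,fp,fn non-negative integer counts.
#' @slot jaccard `tp / (tp + fp + fn)`.
#' @slot unprofiled identifiers excluded from counting because the
#'   experiment did not profile them.
#'
#' @seealso [confusionVsGold()], [jaccardScore()]
#' @export
setClass("EvaluationReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 jaccard = "numeric", unprofiled = "character"),
  prototype(tp = 0L, fp = 0L, fn = 0L, jaccard = NA_real_,
            unprofiled = character())
)

setValidity("EvaluationReport", function(object) {
  msgs <- character()
  if (object@tp < 0L || object@fp < 0L || object@fn < 0L)
    msgs <- c(msgs, "counts must be non-negative")
  denom <- object@tp + object@fp + object@fn
  if (denom > 0L &&
      !isTRUE(all.equal(object@jaccard, object@tp / denom)))
    msgs <- c(msgs, "jaccard must equal tp/(tp+fp+fn)")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticScenario: parameters for a simulated perturbation study
#'
#' Describes a random layered regulatory network (TF count, background gene
#' count, transcription out-degree, cascade fraction, PTM edge counts), the
#' perturbed TF and the regulation model its effect propagates through, and
#' the DEG-calling noise: `tpr` is the probability a true downstream gene is
#' called differentially expressed, `fpr` the probability for a background
#' gene.
#'
#' @slot nTF number of TFs.
#' @slot nGenes number of background (non-TF-coding) genes.
#' @slot meanOutDegree mean transcription out-degree per TF (>= 1; degrees
#'   are 1 + Poisson(meanOutDegree - 1)).
#' @slot cascadeFraction probability a transcription target is a TF-coding
#'   gene, enabling cascades.
#' @slot nKinaseEdges number of TF -> TF kinase edges.
#' @slot nModulators number of modulator proteins (drawn from transcription
#'   targets) given a modulator -> TF edge.
#' @slot trueTF identifier of the perturbed TF ("" = first generated TF).
#' @slot trueModel model id the perturbation propagates through.
#' @slot tpr,fpr DEG-calling rates in `[0, 1]`.
#' @slot seed integer seed; identical seed + parameters give identical output.
#'
#' @seealso [syntheticScenario()], [generateNetwork()],
#'   [simulatePerturbation()], [recoveryExperiment()]
#' @export
setClass("SyntheticScenario",
  representation(nTF = "integer", nGenes = "integer",
                 meanOutDegree = "numeric", cascadeFraction = "numeric",
                 nKinaseEdges = "integer", nModulators = "integer",
                 trueTF = "character", trueModel = "character",
                 tpr = "numeric", fpr = "numeric", seed = "integer"),
  prototype(nTF = 140L, nGenes = 6000L, meanOutDegree = 20,
            cascadeFraction = 0.15, nKinaseEdges = 60L, nModulators = 30L,
            trueTF = "", trueModel = "I", tpr = 0.8, fpr = 0.02, seed = 1L)
)

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  if (object@nTF < 0L || object@nGenes < 0L ||
      object@nKinaseEdges < 0L || object@nModulators < 0L)
    msgs <- c(msgs, "counts must be non-negative")
  if (object@nTF >= 1L && object@meanOutDegree < 1)
    msgs <- c(msgs, "meanOutDegree must be >= 1")
  if (object@cascadeFraction < 0 || object@cascadeFraction > 1)
    msgs <- c(msgs, "cascadeFraction must be in [0, 1]")
  if (object@cascadeFraction > 0 && object@nTF < 2L)
    msgs <- c(msgs, "cascadeFraction > 0 requires at least 2 TFs")
  if (object@nKinaseEdges > 0L && object@nTF < 2L)
    msgs <- c(msgs, "kinase edges require at least 2 TFs")
  if (object@tpr < 0 || object@tpr > 1 || object@fpr < 0 || object@fpr > 1)
    msgs <- c(msgs, "tpr and fpr must be in [0, 1]")
  if (!object@trueModel %in% MODEL_IDS)
    msgs <- c(msgs, "trueModel must be one of I..VI")
  if (length(msgs)) msgs else TRUE
})
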