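#' Jaccard similarity score of a prediction
#'
#' `tp / (tp + fp + fn)`; full precision, rounding only at presentation.
#'
#' @param tp,fp,fn non-negative counts.
#' @return the score in `[0, 1]`.
#' @examples
#' round(jaccardScore(18, 35, 15), 3)
#' @export
jaccardScore <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  denom <- tp + fp + fn
  if (denom == 0) stop("Jaccard score undefined: tp + fp + fn = 0")
  tp / denom
}

#' Confusion counts of predicted regulators against a gold set
#'
#' Predictions the experiment never profiled are removed before counting
#' (they are neither confirmed nor refuted), then
#' `tp = |predicted & gold|`, `fp = |predicted \ gold|`,
#' `fn = |gold \ predicted|`.
#'
#' @param predicted predicted TF identifiers; must be a subset of
#'   `candidates`.
#' @param gold gold-positive TF identifiers; must be a subset of
#'   `candidates`.
#' @param candidates the candidate TF pool both sets live in.
#' @param unprofiled identifiers not profiled by the experiment.
#' @return an [EvaluationReport-class].
#' @export
confusionVsGold <- function(predicted, gold, candidates,
                            unprofiled = character()) {
  predicted <- unique(predicted); gold <- unique(gold)
  bad <- setdiff(predicted, candidates)
  if (length(bad))
    stop("predicted TFs outside the candidate pool: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(gold, candidates)
  if (length(bad))
    stop("gold TFs outside the candidate pool: ", paste(bad, collapse = ", "))
  pred <- setdiff(predicted, unprofiled)
  tp <- length(intersect(pred, gold))
  fp <- length(setdiff(pred, gold))
  fn <- length(setdiff(gold, pred))
  new("EvaluationReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn),
      jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
      unprofiled = intersect(unique(unprofiled), predicted))
}

#' Gold positive set from fold changes
#'
#' Candidates whose absolute signed fold-change ratio meets the threshold
#' (default two-fold; a printed value of -3.3 means 3.3-fold down).
#' Candidates absent from the profile are returned as unprofiled.
#'
#' @param profile `data.frame` with columns `gene` and `fold_change`.
#' @param candidates candidate TF identifiers.
#' @param foldThreshold threshold on the ratio magnitude (default 2).
#' @param log2Input set `TRUE` when `fold_change` holds log2 ratios; they
#'   are compared as `2^|fc| >= foldThreshold`.
#' @return `list(gold = <identifiers>, unprofiled = <identifiers>)`.
#' @export
goldFromFoldChange <- function(profile, candidates, foldThreshold = 2,
                               log2Input = FALSE) {
  .checkProfile(profile)
  if (!"fold_change" %in% names(profile))
    stop("profile needs a 'fold_change' column")
  idx <- match(candidates, profile$gene)
  unprofiled <- candidates[is.na(idx) | is.na(profile$fold_change[idx])]
  profiled <- setdiff(candidates, unprofiled)
  fc <- profile$fold_change[match(profiled, profile$gene)]
  mag <- if (log2Input) 2^abs(fc) else abs(fc)
  list(gold = profiled[mag >= foldThreshold], unprofiled = unprofiled)
}

#' Prediction rate over a collection of perturbation experiments
#'
#' @param nCorrect number of experiments whose perturbed TF was correctly
#'   identified.
#' @param nExperiments total number of experiments (> 0).
#' @param percentage return the half-up rounded percentage instead of the
#'   fraction.
#' @return fraction in `[0, 1]`, or an integer percentage.
#' @examples
#' predictionRate(36, 128, percentage = TRUE)  # 28
#' @export
predictionRate <- function(nCorrect, nExperiments, percentage = FALSE) {
  if (nExperiments <= 0) stop("prediction rate undefined: no experiments")
  if (nCorrect < 0 || nCorrect > nExperiments)
    stop("need 0 <= nCorrect <= nExperiments")
  r <- nCorrect / nExperiments
  if (percentage) floor(r * 100 + 0.5) else r
}

#' Write / read an evaluation report as TSV
#'
#' Round-trips losslessly: counts, Jaccard at full precision, and the
#' unprofiled identifiers.
#'
#' @param report an [EvaluationReport-class].
#' @param path file path.
#' @return `writeEvaluationReport`: the path, invisibly;
#'   `readEvaluationReport`: an [EvaluationReport-class].
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  tab <- data.frame(
    tp = report@tp, fp = report@fp, fn = report@fn,
    jaccard = formatC(report@jaccard, digits = 17, format = "g"),
    unprofiled = paste(report@unprofiled, collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvaluationReport
#' @export
readEvaluationReport <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(unprofiled = "character"))
  unprof <- if (nzchar(tab$unprofiled))
    strsplit(tab$unprofiled, ",", fixed = TRUE)[[1L]] else character()
  new("EvaluationReport", tp = as.integer(tab$tp), fp = as.integer(tab$fp),
      fn = as.integer(tab$fn), jaccard = as.numeric(tab$jaccard),
      unprofiled = unprof)
}
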