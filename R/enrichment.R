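#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing `k` or more of the `n` DEGs inside an
#' expected-target set of size `K`, drawn from a universe of `N` genes:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Returns 1 when `k = 0`.
#'
#' @param k overlap count, `0 <= k <= min(K, n)`.
#' @param K expected-target set size, `K <= N`.
#' @param n DEG count, `n <= N`.
#' @param N universe size.
#' @return the upper-tail p-value in `(0, 1]`.
#' @examples
#' hypergeomOverlapPvalue(3, 3, 3, 10)  # 1/120
#' @export
hypergeomOverlapPvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop(sprintf("invalid hypergeometric bounds: k=%s K=%s n=%s N=%s",
                 k, K, n, N))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Score a TF's six downstream sets against a DEG set
#'
#' Each model set is intersected with the universe; its overlap with the
#' DEGs is scored with [hypergeomOverlapPvalue()] at `n = |D|`,
#' `N = |universe|`.
#'
#' @param sets a [DownstreamSets-class].
#' @param degs a [DEGSet-class]; its genes must lie inside `universe`.
#' @param universe character vector of background genes. Defaults to the
#'   DEG set's measured universe when present (the background should match
#'   what could have been called a DEG).
#' @return an [EnrichmentResult-class].
#' @examples
#' net <- toyNetwork()
#' d <- new("DEGSet", genes = paste0("g", 1:8),
#'          measuredUniverse = paste0("g", 1:8))
#' scoreTF(allDownstreamSets(net, "A"), d)
#' @export
scoreTF <- function(sets, degs, universe = NULL) {
  stopifnot(is(sets, "DownstreamSets"), is(degs, "DEGSet"))
  if (is.null(universe)) {
    universe <- measuredUniverse(degs)
    if (!length(universe))
      stop("no universe given and the DEG set has no measured universe")
  }
  universe <- unique(universe)
  if (!length(universe)) stop("the gene universe is empty")
  D <- intersect(degGenes(degs), universe)
  if (length(D) < length(degGenes(degs)))
    stop("DEGs must be a subset of the universe")
  n <- length(D)
  N <- length(universe)
  if (n == 0L)
    warning("empty DEG set: all overlap p-values are 1")
  tab <- do.call(rbind, lapply(MODEL_IDS, function(m) {
    Tm <- intersect(sets@sets[[m]], universe)
    K <- length(Tm)
    k <- length(intersect(Tm, D))
    data.frame(model = m, K = K, k = k,
               p = hypergeomOverlapPvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  }))
  new("EnrichmentResult", tf = sets@tf, table = tab,
      n = as.integer(n), N = as.integer(N))
}

.pMatrix <- function(results) {
  stopifnot(length(results) >= 1L)
  tfs <- vapply(results, focalTF, character(1))
  p <- t(vapply(results, function(r) {
    stats::setNames(r@table$p, r@table$model)[MODEL_IDS]
  }, numeric(length(MODEL_IDS))))
  rownames(p) <- tfs
  p
}

#' Rank-sum acceptability filter over the candidate-wide p-value distributions
#'
#' For each model m != I, the distribution of overlap p-values across all
#' candidate TFs is compared with Model I's by a two-sample Wilcoxon
#' rank-sum test. A model whose distribution is significantly different
#' (test p <= `alpha`) would let many TFs gain spuriously significant
#' overlaps and is declared unacceptable; Model I is always acceptable.
#'
#' @param results list of [EnrichmentResult-class] over all candidate TFs
#'   (at least 2).
#' @param alpha rejection threshold on the rank-sum p-value (default 0.005).
#' @param alternative `"two.sided"` (default) or `"less"` (shift toward
#'   smaller model-m p-values only).
#' @return a [ModelAcceptability-class].
#' @export
acceptableModels <- function(results, alpha = 0.005,
                             alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (length(results) < 2L)
    stop("acceptability needs enrichment results for at least 2 candidate TFs")
  p <- .pMatrix(results)
  ranksum <- vapply(MODEL_IDS, function(m) {
    if (m == "I") return(NA_real_)
    x <- p[, "I"]
    y <- p[, m]
    if (length(unique(c(x, y))) == 1L) return(1)  # all tied: no information
    pv <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative)$p.value)
    if (is.na(pv)) 1 else pv
  }, numeric(1))
  tab <- data.frame(model = MODEL_IDS, ranksumP = ranksum,
                    acceptable = is.na(ranksum) | ranksum > alpha,
                    stringsAsFactors = FALSE)
  new("ModelAcceptability", table = tab, alpha = alpha)
}

#' Rank candidate TFs by minimum acceptable-model p-value
#'
#' Each TF's ranking p-value is the minimum overlap p-value over the
#' acceptable models; the best model is the one attaining it (ties go to
#' the lower-numbered model). TFs are sorted by that p-value ascending,
#' ties broken by larger overlap count at the best model, then by TF
#' identifier. A TF is a valid finding when its minimum p-value is at or
#' below `validP`.
#'
#' @param results list of [EnrichmentResult-class].
#' @param acceptability a [ModelAcceptability-class] computed from the same
#'   result collection.
#' @param validP valid-finding threshold (default 0.01).
#' @return `data.frame(rank, tf, bestModel, minP, kBest, KBest, n, N, valid)`.
#' @export
rankCandidates <- function(results, acceptability, validP = 0.01) {
  stopifnot(is(acceptability, "ModelAcceptability"))
  if (!length(results))
    return(data.frame(rank = integer(), tf = character(),
                      bestModel = character(), minP = numeric(),
                      kBest = integer(), KBest = integer(), n = integer(),
                      N = integer(), valid = logical(),
                      stringsAsFactors = FALSE))
  ok <- isAcceptable(acceptability)
  okModels <- MODEL_IDS[ok[MODEL_IDS]]
  rows <- do.call(rbind, lapply(results, function(r) {
    tb <- r@table[r@table$model %in% okModels, , drop = FALSE]
    i <- which.min(tb$p)  # first minimum = lower-numbered model
    data.frame(tf = r@tf, bestModel = tb$model[i], minP = tb$p[i],
               kBest = tb$k[i], KBest = tb$K[i], n = r@n, N = r@N,
               stringsAsFactors = FALSE)
  }))
  ord <- order(rows$minP, -rows$kBest, rows$tf)
  rows <- rows[ord, , drop = FALSE]
  rows <- cbind(rank = seq_len(nrow(rows)), rows)
  rows$valid <- rows$minP <= validP
  rownames(rows) <- NULL
  rows
}

#' Was the perturbed TF correctly identified?
#'
#' True when the TF is a valid finding (minimum acceptable-model p-value at
#' or below `pThreshold`) and ranks within the top `topK` candidates.
#'
#' @param ranked output of [rankCandidates()].
#' @param trueTF identifier of the actually perturbed TF; must be among
#'   the ranked candidates.
#' @param topK rank cutoff (default 20).
#' @param pThreshold valid-finding threshold (default 0.01).
#' @return logical.
#' @export
correctlyIdentified <- function(ranked, trueTF, topK = 20L, pThreshold = 0.01) {
  i <- match(trueTF, ranked$tf)
  if (is.na(i))
    stop("perturbed TF is not among the ranked candidates: ", trueTF)
  ranked$minP[i] <= pThreshold && ranked$rank[i] <= topK
}
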