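test_that("hypergeometric overlap p-values match exact enumeration", {
  expect_equal(hypergeomOverlapPvalue(0, 5, 10, 100), 1)
  expect_equal(hypergeomOverlapPvalue(3, 3, 3, 10), 1 / 120)
  expect_equal(hypergeomOverlapPvalue(1, 3, 3, 10), 85 / 120)

  cases <- expand.grid(K = c(1, 3, 7), n = c(2, 5, 9), N = c(12, 20))
  for (i in seq_len(nrow(cases))) {
    K <- cases$K[i]; n <- cases$n[i]; N <- cases$N[i]
    for (k in 0:min(K, n))
      expect_equal(hypergeomOverlapPvalue(k, K, n, N),
                   hyperTailEnum(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeomOverlapPvalue(4, 3, 5, 10), "bounds")
  expect_error(hypergeomOverlapPvalue(1, 11, 5, 10), "bounds")
})

test_that("the overlap p-value is strictly decreasing in k while below 1", {
  for (pars in list(c(10, 20, 100), c(5, 5, 30), c(50, 40, 1000))) {
    K <- pars[1]; n <- pars[2]; N <- pars[3]
    p <- vapply(0:min(K, n), hypergeomOverlapPvalue, numeric(1),
                K = K, n = n, N = N)
    expect_true(all(diff(p) <= 0))
    strict <- which(p[-length(p)] < 1)
    expect_true(all(p[strict + 1] < p[strict]))
  }
})

test_that("tail stays within a sane envelope of the Gaussian at large N", {
  N <- 1e4; K <- 1e3; n <- 1e3
  mu <- n * K / N
  sdev <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  k <- round(mu + 4 * sdev)
  p <- hypergeomOverlapPvalue(k, K, n, N)
  gauss <- stats::pnorm(4, lower.tail = FALSE)
  expect_gt(p, gauss / 3)
  expect_lt(p, gauss * 3)
})

test_that("scoreTF computes per-model overlaps against the universe", {
  net <- toyNetwork()
  universe <- c(paste0("g", 1:8), sprintf("bg%02d", 1:92))
  sets <- allDownstreamSets(net, "A")

  degs <- makeDEGSet(paste0("g", 1:8), universe)
  res <- scoreTF(sets, degs, universe)
  tab <- enrichmentTable(res)
  expect_equal(tab$model, c("I", "II", "III", "IV", "V", "VI"))
  expect_equal(tab$k, c(3L, 4L, 6L, 5L, 7L, 8L))
  expect_equal(tab$K, tab$k)  # every set fully differentially expressed
  expect_lt(tab$p[tab$model == "VI"], tab$p[tab$model == "I"])
  expect_equal(res@n, 8L)
  expect_equal(res@N, 100L)

  # DEGs disjoint from every set -> all p = 1
  disjoint <- makeDEGSet(sprintf("bg%02d", 1:8), universe)
  expect_true(all(enrichmentTable(scoreTF(sets, disjoint, universe))$p == 1))

  # perfect overlap attains the minimum possible p for that (K, n, N)
  pTop <- enrichmentTable(res)$p[1]
  expect_equal(pTop, hypergeomOverlapPvalue(3, 3, 8, 100))

  expect_error(scoreTF(sets, degs, character()), "universe")
  expect_error(scoreTF(sets, makeDEGSet("absent", "absent"), universe),
               "subset")
  expect_warning(scoreTF(sets, makeDEGSet(character(), universe), universe),
                 "empty DEG set")
})

test_that("identical p-value distributions keep every model acceptable", {
  mkres <- function(tf, p) {
    new("EnrichmentResult", tf = tf,
        table = data.frame(model = c("I", "II", "III", "IV", "V", "VI"),
                           K = 10L, k = 1L, p = p, stringsAsFactors = FALSE),
        n = 10L, N = 100L)
  }
  res <- lapply(1:20, function(i) mkres(sprintf("T%02d", i),
                                        rep(i / 21, 6)))
  acc <- acceptableModels(res)
  expect_true(all(acceptabilityTable(acc)$acceptable))
  expect_true(all(acceptabilityTable(acc)$ranksumP[-1] == 1))

  # all values tied across both samples
  tied <- lapply(1:5, function(i) mkres(sprintf("T%d", i), rep(0.5, 6)))
  expect_true(all(acceptabilityTable(acceptableModels(tied))$acceptable))

  expect_error(acceptableModels(res[1]), "at least 2")

  # alpha = 0: every model acceptable no matter how different
  shifted <- lapply(1:30, function(i) {
    p1 <- i / 31
    mkres(sprintf("S%02d", i), c(p1, rep(p1 / 1000, 5)))
  })
  expect_true(all(acceptabilityTable(
    acceptableModels(shifted, alpha = 0))$acceptable))
  # ...and at the default alpha those same models are rejected
  accS <- acceptableModels(shifted)
  expect_equal(acceptabilityTable(accS)$acceptable,
               c(TRUE, rep(FALSE, 5)))
})

test_that("rank-sum acceptability is invariant under monotone p transforms", {
  set.seed(42)
  mk <- function(p6) {
    lapply(seq_len(nrow(p6)), function(i)
      new("EnrichmentResult", tf = sprintf("T%02d", i),
          table = data.frame(model = c("I", "II", "III", "IV", "V", "VI"),
                             K = 10L, k = 1L, p = p6[i, ],
                             stringsAsFactors = FALSE),
          n = 10L, N = 100L))
  }
  p6 <- matrix(runif(40 * 6), 40, 6)
  p6[, 3] <- p6[, 3] / 50  # make one model clearly shifted
  a1 <- acceptabilityTable(acceptableModels(mk(p6)))
  a2 <- acceptabilityTable(acceptableModels(mk(sqrt(p6))))  # monotone map
  expect_equal(a1$acceptable, a2$acceptable)
  expect_equal(a1$ranksumP, a2$ranksumP)
})

test_that("candidates are ranked by minimum acceptable-model p-value", {
  mkres <- function(tf, p, k = rep(1L, 6)) {
    new("EnrichmentResult", tf = tf,
        table = data.frame(model = c("I", "II", "III", "IV", "V", "VI"),
                           K = pmax(k, 5L), k = k, p = p,
                           stringsAsFactors = FALSE),
        n = 10L, N = 1000L)
  }
  accAll <- new("ModelAcceptability",
                table = data.frame(model = c("I", "II", "III", "IV", "V", "VI"),
                                   ranksumP = c(NA, rep(0.5, 5)),
                                   acceptable = TRUE, stringsAsFactors = FALSE),
                alpha = 0.005)
  accNoII <- new("ModelAcceptability",
                 table = data.frame(model = c("I", "II", "III", "IV", "V", "VI"),
                                    ranksumP = c(NA, 0.001, rep(0.5, 4)),
                                    acceptable = c(TRUE, FALSE, rep(TRUE, 4)),
                                    stringsAsFactors = FALSE),
                 alpha = 0.005)

  hit <- mkres("TFX", c(0.02, 1e-6, 0.02, 0.03, 0.05, 0.9))
  decoys <- lapply(1:9, function(i) mkres(sprintf("D%02d", i), rep(1, 6)))
  ranked <- rankCandidates(c(list(hit), decoys), accAll)
  expect_equal(ranked$tf[1], "TFX")
  expect_equal(ranked$bestModel[1], "II")
  expect_equal(ranked$minP[1], 1e-6)
  expect_true(ranked$valid[1])
  expect_false(any(ranked$valid[-1]))
  expect_equal(ranked$rank, 1:10)

  # acceptability masking: Model II unacceptable -> fall back to Model I
  ranked2 <- rankCandidates(c(list(hit), decoys), accNoII)
  expect_equal(ranked2$bestModel[1], "I")
  expect_equal(ranked2$minP[1], 0.02)
  expect_false(ranked2$valid[1])

  # argmin ties resolve to the lower-numbered model
  tie <- mkres("TIE", c(0.5, 0.01, 0.01, 0.5, 0.5, 0.5))
  expect_equal(rankCandidates(list(tie, decoys[[1]]), accAll)$bestModel[1],
               "II")

  # ranking ties break by larger overlap count, then identifier
  a <- mkres("ZZ", rep(0.5, 6), k = rep(4L, 6))
  b <- mkres("AA", rep(0.5, 6), k = rep(2L, 6))
  c3 <- mkres("BB", rep(0.5, 6), k = rep(2L, 6))
  rk <- rankCandidates(list(b, a, c3), accAll)
  expect_equal(rk$tf, c("ZZ", "AA", "BB"))

  # permutation invariance of the input order
  rk2 <- rankCandidates(list(c3, a, b), accAll)
  expect_equal(rk, rk2)
  expect_equal(nrow(rankCandidates(list(), accAll)), 0L)
})

test_that("correct identification needs a valid p-value and a top-k rank", {
  ranked <- data.frame(rank = 1:30, tf = sprintf("T%02d", 1:30),
                       minP = rep(c(1e-8, 0.02), 15),
                       stringsAsFactors = FALSE)
  expect_true(correctlyIdentified(ranked, "T01"))
  ranked$minP[22] <- 1e-8
  expect_false(correctlyIdentified(ranked, "T22"))  # rank 22 > top 20
  expect_false(correctlyIdentified(ranked, "T06"))  # p 0.02 > 0.01
  expect_error(correctlyIdentified(ranked, "absent"), "not among")
})

test_that("a fully expressed downstream set sends the perturbed TF to rank 1", {
  for (seed in 1:10) {
    net <- smallRandomNetwork(seed, nTF = 10L, nGenes = 80L)
    cands <- candidateTFs(net, 4L)
    if (length(cands) < 2L) next
    trueTF <- cands[1]
    degs <- simulatePerturbation(net, trueTF, "I", tpr = 1, fpr = 0,
                                 seed = seed)
    results <- lapply(cands, function(tf)
      scoreTF(allDownstreamSets(net, tf), degs, geneUniverse(net)))
    ranked <- rankCandidates(results, acceptableModels(results))
    expect_equal(ranked$tf[1], trueTF, info = paste("seed", seed))
    expect_true(correctlyIdentified(ranked, trueTF))
  }
})
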