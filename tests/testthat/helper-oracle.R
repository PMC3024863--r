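# Independent oracles, deliberately written as naive enumerations so they
# share no code path with the package internals.

# Upper-tail hypergeometric by direct summation of binomial-coefficient
# ratios: P(X >= k) = sum_{j>=k} C(K,j) C(N-K, n-j) / C(N,n).
hyperTailEnum <- function(k, K, n, N) {
  js <- seq.int(k, min(K, n))
  if (!length(js)) return(0)
  sum(vapply(js, function(j) {
    if (n - j > N - K) return(0)
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, numeric(1)))
}

# Brute-force role-path enumerator. Walks every admissible path of TF-to-TF
# length <= 2 ending in a transcription edge, row by row, and collects the
# terminal genes. Role patterns (focal TF a, -T-> transcription,
# -M-> kinase/phosphatase, -Mod-> modulator; prod() maps a gene to the
# protein it codes for; all nodes within a path distinct):
#   I  : a -T-> g
#   II : I  + a -M-> B -T-> g                      (B a TF)
#   III: II + a -T-> c, C=prod(c) -T-> g           (C a TF)
#            + a -M-> B -T-> d, D=prod(d) -T-> g   (D a TF)
#   IV : II + a -T-> x, X=prod(x) -Mod-> E -T-> g  (E a TF)
#   V  : III union IV
#   VI : V  + a -T-> c, C -T-> f, F=prod(f) -T-> g (F a TF)
oracleDownstreamSet <- function(net, a, model) {
  tx <- transcriptionEdges(net)
  md <- modificationEdges(net)
  roster <- tfRoster(net)
  gp <- geneProduct(net)
  prod1 <- function(g) if (g %in% names(gp)) unname(gp[[g]]) else g

  genesI <- character(); genesB <- character(); genesC <- character()
  genesD <- character(); genesE <- character(); genesF <- character()

  for (i in seq_len(nrow(tx)))
    if (tx$source[i] == a) genesI <- c(genesI, tx$target[i])

  ptmRows <- which(md$subkind %in% c("kinase", "phosphatase"))
  modRows <- which(md$subkind == "modulator")

  # role B
  for (i in ptmRows) {
    if (md$source[i] != a) next
    b <- md$target[i]
    if (b == a || !(b %in% roster)) next
    for (j in seq_len(nrow(tx)))
      if (tx$source[j] == b) genesB <- c(genesB, tx$target[j])
    # role D under this B
    for (j in seq_len(nrow(tx))) {
      if (tx$source[j] != b) next
      d <- prod1(tx$target[j])
      if (d %in% c(a, b) || !(d %in% roster)) next
      for (l in seq_len(nrow(tx)))
        if (tx$source[l] == d) genesD <- c(genesD, tx$target[l])
    }
  }

  # roles C, F, X/E hang off a's transcription targets
  for (i in seq_len(nrow(tx))) {
    if (tx$source[i] != a) next
    p <- prod1(tx$target[i])
    if (p == a) next
    if (p %in% roster) {  # role C
      for (j in seq_len(nrow(tx))) {
        if (tx$source[j] != p) next
        genesC <- c(genesC, tx$target[j])
        f <- prod1(tx$target[j])
        if (!(f %in% c(a, p)) && f %in% roster)  # role F
          for (l in seq_len(nrow(tx)))
            if (tx$source[l] == f) genesF <- c(genesF, tx$target[l])
      }
    }
    # role X -> E
    for (j in modRows) {
      if (md$source[j] != p) next
      e <- md$target[j]
      if (e %in% c(a, p) || !(e %in% roster)) next
      for (l in seq_len(nrow(tx)))
        if (tx$source[l] == e) genesE <- c(genesE, tx$target[l])
    }
  }

  out <- switch(model,
    I   = genesI,
    II  = c(genesI, genesB),
    III = c(genesI, genesB, genesC, genesD),
    IV  = c(genesI, genesB, genesE),
    V   = c(genesI, genesB, genesC, genesD, genesE),
    VI  = c(genesI, genesB, genesC, genesD, genesE, genesF))
  sort(unique(out))
}

# small random network for property tests (<= 60 nodes by default)
smallRandomNetwork <- function(seed, nTF = 8L, nGenes = 40L) {
  generateNetwork(syntheticScenario(
    nTF = nTF, nGenes = nGenes, meanOutDegree = 4, cascadeFraction = 0.3,
    nKinaseEdges = 6L, nModulators = 5L, seed = seed))
}

makeDEGSet <- function(genes, universe) {
  new("DEGSet", genes = unique(genes), measuredUniverse = unique(universe))
}

# shuffle edge-record order without changing content
shuffleNetwork <- function(net, seed) {
  tx <- transcriptionEdges(net)
  md <- modificationEdges(net)
  set.seed(seed)
  tx <- tx[sample(nrow(tx)), , drop = FALSE]
  if (nrow(md)) md <- md[sample(nrow(md)), , drop = FALSE]
  rownames(tx) <- rownames(md) <- NULL
  new("RegulatoryNetwork", tfRoster = tfRoster(net), transcription = tx,
      modification = md, geneProduct = geneProduct(net))
}

TOY_SETS <- list(
  I   = c("g1", "g2", "g3"),
  II  = c("g1", "g2", "g3", "g4"),
  III = c("g1", "g2", "g3", "g4", "g5", "g6"),
  IV  = c("g1", "g2", "g3", "g4", "g7"),
  V   = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
  VI  = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"))
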