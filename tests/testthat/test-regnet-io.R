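writeTSVLines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("interaction tables are thresholded strictly and deduplicated", {
  path <- writeTSVLines(c("source\ttarget\tscore",
                          "A\tg1\t5.0", "A\tg2\t3.9", "B\tg3\t4.1"))
  et <- readInteractionTable(path, "transcription", scoreThreshold = 4)
  expect_equal(edgeRecords(et)$source, c("A", "B"))
  expect_equal(edgeRecords(et)$target, c("g1", "g3"))
  # boundary: a score exactly at the threshold is dropped (strict >)
  path2 <- writeTSVLines(c("source\ttarget\tscore", "A\tg1\t4.0"))
  expect_equal(nrow(edgeRecords(
    readInteractionTable(path2, "transcription", scoreThreshold = 4))), 0L)

  dup <- writeTSVLines(c("source\ttarget\tscore",
                         "A\tg1\t5.0", "A\tg1\t5.0"))
  expect_equal(nrow(edgeRecords(readInteractionTable(dup, "transcription"))), 1L)

  empty <- writeTSVLines("source\ttarget\tscore")
  expect_equal(nrow(edgeRecords(readInteractionTable(empty, "transcription"))), 0L)
})

test_that("table loading is idempotent and errors are informative", {
  path <- writeTSVLines(c("source\ttarget\tscore",
                          "A\tg1\t5.0", "B\tg2\t6.1"))
  et1 <- readInteractionTable(path, "transcription")
  et2 <- readInteractionTable(path, "transcription")
  expect_identical(edgeRecords(et1), edgeRecords(et2))

  expect_error(readInteractionTable(file.path(tempdir(), "absent.tsv"),
                                    "transcription"), "not found")
  bad <- writeTSVLines(c("source\ttarget\tscore", "A\tg1\t5.0\textra"))
  expect_error(readInteractionTable(bad, "transcription"), "line 2")
  emptyId <- writeTSVLines(c("source\ttarget\tscore", "\tg1\t5.0"))
  expect_error(readInteractionTable(emptyId, "transcription"),
               "line 2.*empty identifier")
  noScore <- writeTSVLines(c("source\ttarget", "A\tg1"))
  expect_error(readInteractionTable(noScore, "transcription",
                                    scoreThreshold = 4), "score")
})

test_that("raising the score threshold never adds records", {
  path <- writeTSVLines(c("source\ttarget\tscore",
                          sprintf("TF%d\tg%d\t%.2f", rep(1:5, each = 6),
                                  1:30, seq(0, 8, length.out = 30))))
  sizes <- vapply(c(0, 2, 4, 6, 8), function(th)
    nrow(edgeRecords(readInteractionTable(path, "transcription",
                                          scoreThreshold = th))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("buildNetwork validates the roster and recomputes the universe", {
  net <- toyNetwork()
  expect_setequal(tfRoster(net), c("A", "B", "C", "D", "E", "F"))
  expect_setequal(geneUniverse(net), paste0("g", 1:8))
  expect_equal(nrow(modificationEdges(net)), 2L)
  # universe is recomputable from the transcription targets
  expect_setequal(geneUniverse(net), unique(transcriptionEdges(net)$target))

  emptyTx <- new("EdgeTable", kind = "transcription",
                 records = data.frame(source = character(),
                                      target = character(),
                                      score = numeric(),
                                      stringsAsFactors = FALSE))
  emptyNet <- buildNetwork(emptyTx, tfRoster = character())
  expect_length(geneUniverse(emptyNet), 0L)

  roz <- new("EdgeTable", kind = "transcription",
             records = data.frame(source = "Z", target = "g1",
                                  score = NA_real_, stringsAsFactors = FALSE))
  expect_error(buildNetwork(roz, tfRoster = c("A", "B")), "Z")
})

test_that("conflicting-subkind modification records are kept distinct", {
  tx <- new("EdgeTable", kind = "transcription",
            records = data.frame(source = "A", target = "g1",
                                 score = NA_real_, stringsAsFactors = FALSE))
  ptm <- new("EdgeTable", kind = "modification",
             records = data.frame(source = c("A", "A"), target = c("B", "B"),
                                  subkind = c("kinase", "phosphatase"),
                                  stringsAsFactors = FALSE))
  net <- buildNetwork(tx, ptm, tfRoster = c("A", "B"))
  expect_equal(nrow(modificationEdges(net)), 2L)
})

test_that("DEG selection uses inclusive thresholds per criterion", {
  prof <- data.frame(gene = c("g1", "g2", "g3"),
                     p_value = c(0.01, 0.011, 0.5))
  expect_equal(degGenes(selectDEGs(prof, "p_le", 0.01)), "g1")
  expect_setequal(measuredUniverse(selectDEGs(prof, "p_le", 0.01)),
                  c("g1", "g2", "g3"))

  zprof <- data.frame(gene = c("g1", "g2", "g3"),
                      z_score = c(2.0, -2.5, 1.9))
  expect_setequal(degGenes(selectDEGs(zprof, "abs_z_ge", 2)), c("g1", "g2"))

  fprof <- data.frame(gene = c("t1", "t2", "t3"),
                      fold_change = c(2.0, -2.1, 1.9))
  expect_setequal(degGenes(selectDEGs(fprof, "abs_fold_ge", 2)), c("t1", "t2"))

  expect_error(selectDEGs(fprof, "p_le", 0.01), "p_value")

  deg <- selectDEGs(prof, "p_le", 0.01)
  expect_equal(degCriterion(deg)$statistic, "p_value")
  expect_equal(degCriterion(deg)$threshold, 0.01)
})

test_that("DEG selection boundary behaviour: alpha 1 keeps all, tiny alpha none", {
  prof <- data.frame(gene = sprintf("g%d", 1:20),
                     p_value = seq(0.001, 1, length.out = 20))
  expect_setequal(degGenes(selectDEGs(prof, "p_le", 1)), prof$gene)
  expect_length(degGenes(selectDEGs(prof, "p_le", 1e-6)), 0L)
})

test_that("gene lists are trimmed, deduplicated, comments skipped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "g1", "  g2  ", "g2", "", "# tail"), path)
  expect_equal(readGeneList(path), c("g1", "g2"))

  onlyComments <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a", "# b"), onlyComments)
  expect_length(readGeneList(onlyComments), 0L)
  expect_error(readGeneList(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("GMT export writes one line per (TF, model) and round-trips", {
  net <- toyNetwork()
  sets <- allDownstreamSets(net, "A")
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSetsGMT(sets, path)
  lines <- readLines(path)
  expect_length(lines, 6L)
  lineI <- strsplit(lines[grepl("^A\\|I\t", lines)], "\t")[[1]]
  expect_equal(lineI[1], "A|I")
  expect_setequal(lineI[-(1:2)], c("g1", "g2", "g3"))

  back <- readGeneSetsGMT(path)
  expect_equal(names(back), paste0("A|", c("I", "II", "III", "IV", "V", "VI")))
  for (m in names(TOY_SETS))
    expect_setequal(back[[paste0("A|", m)]], TOY_SETS[[m]])

  # empty collection -> empty file
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSetsGMT(list(), empty)
  expect_length(readLines(empty), 0L)
})

test_that("GMT output agrees with an independent GMT reader", {
  skip_if_not_installed("fgsea")
  net <- toyNetwork()
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSetsGMT(list(allDownstreamSets(net, "A"),
                        allDownstreamSets(net, "B")), path)
  ours <- readGeneSetsGMT(path)
  theirs <- fgsea::gmtPathways(path)
  expect_equal(names(ours), names(theirs))
  for (nm in names(ours))
    expect_setequal(ours[[nm]], theirs[[nm]])
})
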