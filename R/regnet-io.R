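#' Read a TF-DNA or PTM interaction table
#'
#' Reads a tab-separated edge table with a header row and columns
#' `source`, `target`, and optionally `score` (transcription edges only;
#' the log-likelihood score, LLS) and `subkind` (modification edges:
#' kinase, phosphatase or modulator). Records are deduplicated, keeping
#' the first occurrence, and retain load order.
#'
#' @param path path to the TSV file.
#' @param kind `"transcription"` or `"modification"`.
#' @param scoreThreshold optional; keep only records with
#'   `score > scoreThreshold` (strict, matching the LLS > 4 rule used to
#'   call an interaction high-confidence).
#' @param subkind optional; when the table has no `subkind` column, assign
#'   this subkind to every modification record.
#'
#' @return an [EdgeTable-class].
#'
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("source\ttarget\tscore", "A\tg1\t5.0", "A\tg2\t3.9"), tsv)
#' readInteractionTable(tsv, "transcription", scoreThreshold = 4)
#'
#' @export
readInteractionTable <- function(path, kind = c("transcription", "modification"),
                                 scoreThreshold = NULL, subkind = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("interaction table not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineNo <- which(keep)  # file line numbers of retained rows
  lines <- lines[keep]
  if (!length(lines)) stop("interaction table is empty (no header): ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (!all(c("source", "target") %in% header))
    stop("interaction table must have 'source' and 'target' columns: ", path)
  ncols <- length(header)
  body <- fields[-1L]
  rows <- lineNo[-1L]  # file line numbers of the body rows
  badn <- which(lengths(body) != ncols)
  if (length(badn))
    stop(sprintf("malformed row in %s: line %d has %d column(s), expected %d",
                 path, rows[badn[1L]], lengths(body)[badn[1L]], ncols))
  tab <- if (length(body)) {
    m <- do.call(rbind, body)
    colnames(m) <- header
    as.data.frame(m, stringsAsFactors = FALSE)
  } else {
    stats::setNames(as.data.frame(matrix(character(), 0L, ncols),
                                  stringsAsFactors = FALSE), header)
  }
  tab$source <- trimws(tab$source)
  tab$target <- trimws(tab$target)
  bad <- which(!nzchar(tab$source) | !nzchar(tab$target))
  if (length(bad))
    stop(sprintf("malformed row in %s: line %d has an empty identifier",
                 path, rows[bad[1L]]))

  if (!is.null(scoreThreshold)) {
    if (!"score" %in% names(tab))
      stop("scoreThreshold given but table has no 'score' column: ", path)
    score <- suppressWarnings(as.numeric(tab$score))
    nanum <- which(is.na(score) & nzchar(trimws(tab$score)))
    if (length(nanum))
      stop(sprintf("malformed row in %s: line %d has a non-numeric score",
                   path, rows[nanum[1L]]))
    tab <- tab[!is.na(score) & score > scoreThreshold, , drop = FALSE]
  }

  rec <- data.frame(source = tab$source, target = tab$target,
                    stringsAsFactors = FALSE)
  if (kind == "transcription") {
    rec$score <- if ("score" %in% names(tab))
      suppressWarnings(as.numeric(tab$score)) else NA_real_
    key <- paste(rec$source, rec$target, sep = "\r")
  } else {
    rec$subkind <- if ("subkind" %in% names(tab)) trimws(tab$subkind)
      else if (!is.null(subkind)) rep(subkind, nrow(rec))
      else stop("modification table needs a 'subkind' column or a subkind= argument: ",
                path)
    key <- paste(rec$source, rec$target, rec$subkind, sep = "\r")
  }
  rec <- rec[!duplicated(key), , drop = FALSE]
  rownames(rec) <- NULL
  new("EdgeTable", kind = kind, records = rec)
}

#' Assemble a validated regulatory network
#'
#' Merges a TF-DNA transcription edge table with PTM edge tables
#' (kinase/phosphatase-substrate pairs and modulator -> TF pairs) over an
#' explicit TF roster. Every transcription-edge source must be in the
#' roster; modification records with the same endpoints but different
#' subkinds are kept as distinct records.
#'
#' @param tfDna [EdgeTable-class] of kind `"transcription"`.
#' @param ptmEdges [EdgeTable-class] of kind `"modification"` with subkinds
#'   kinase/phosphatase (may be empty).
#' @param modulatorEdges [EdgeTable-class] of kind `"modification"` with
#'   subkind modulator (may be empty).
#' @param tfRoster character vector of TF identifiers.
#' @param geneProduct optional named character vector mapping a target-gene
#'   identifier to the protein it codes for; unmapped genes code for the
#'   identically named protein.
#'
#' @return a [RegulatoryNetwork-class].
#'
#' @examples
#' net <- toyNetwork()
#' geneUniverse(net)
#'
#' @export
buildNetwork <- function(tfDna, ptmEdges = NULL, modulatorEdges = NULL,
                         tfRoster = character(), geneProduct = character()) {
  stopifnot(is(tfDna, "EdgeTable"))
  if (edgeKind(tfDna) != "transcription")
    stop("tfDna must be a transcription EdgeTable")
  mod <- data.frame(source = character(), target = character(),
                    subkind = character(), stringsAsFactors = FALSE)
  for (et in list(ptmEdges, modulatorEdges)) {
    if (is.null(et)) next
    stopifnot(is(et, "EdgeTable"))
    if (edgeKind(et) != "modification")
      stop("PTM/modulator edges must be modification EdgeTables")
    mod <- rbind(mod, edgeRecords(et)[c("source", "target", "subkind")])
  }
  if (!is.null(ptmEdges) &&
      !all(edgeRecords(ptmEdges)$subkind %in% c("kinase", "phosphatase")))
    stop("ptmEdges subkinds must be kinase or phosphatase")
  if (!is.null(modulatorEdges) &&
      !all(edgeRecords(modulatorEdges)$subkind == "modulator"))
    stop("modulatorEdges subkind must be modulator")
  mod <- mod[!duplicated(paste(mod$source, mod$target, mod$subkind,
                               sep = "\r")), , drop = FALSE]
  rownames(mod) <- NULL
  tx <- edgeRecords(tfDna)
  offenders <- setdiff(unique(tx$source), tfRoster)
  if (length(offenders))
    stop("transcription-edge source(s) not in tfRoster: ",
         paste(offenders, collapse = ", "))
  new("RegulatoryNetwork", tfRoster = unique(tfRoster), transcription = tx,
      modification = mod, geneProduct = geneProduct)
}

#' Select differentially expressed genes from an expression-statistics table
#'
#' Applies one of the DEG criteria to an expression profile: `p_le`
#' (p-value at or below a significance level, the p <= 0.01 rule used for
#' knockout profiles), `abs_z_ge` (absolute z-score at or above a cutoff,
#' the |z| >= 2 rule), or `abs_fold_ge` (absolute signed fold change at or
#' above a cutoff). All thresholds are inclusive.
#'
#' @param profile a `data.frame` with column `gene` and the statistic column
#'   the criterion needs: `p_value`, `z_score`, or `fold_change`.
#' @param criterion one of `"p_le"`, `"abs_z_ge"`, `"abs_fold_ge"`.
#' @param threshold the cutoff value.
#'
#' @return a [DEGSet-class]; `measuredUniverse` is set to all profiled genes
#'   and the criterion is recorded.
#'
#' @examples
#' prof <- data.frame(gene = c("g1", "g2", "g3"),
#'                    p_value = c(0.01, 0.011, 0.5))
#' degGenes(selectDEGs(prof, "p_le", 0.01))
#'
#' @export
selectDEGs <- function(profile, criterion = c("p_le", "abs_z_ge", "abs_fold_ge"),
                       threshold) {
  criterion <- match.arg(criterion)
  .checkProfile(profile)
  col <- switch(criterion, p_le = "p_value", abs_z_ge = "z_score",
                abs_fold_ge = "fold_change")
  if (!col %in% names(profile))
    stop(sprintf("criterion '%s' needs a '%s' column in the profile",
                 criterion, col))
  x <- profile[[col]]
  if (anyNA(x))
    stop(sprintf("criterion '%s': statistic '%s' is missing for %d gene(s)",
                 criterion, col, sum(is.na(x))))
  keep <- if (criterion == "p_le") x <= threshold else abs(x) >= threshold
  dir <- if (criterion == "p_le") "<=" else ">= (absolute)"
  new("DEGSet", genes = unique(profile$gene[keep]),
      criterion = list(statistic = col, threshold = threshold, direction = dir),
      measuredUniverse = unique(profile$gene))
}

.checkProfile <- function(profile) {
  if (!is.data.frame(profile) || !"gene" %in% names(profile))
    stop("expression profile must be a data.frame with a 'gene' column")
  if (anyDuplicated(profile$gene))
    stop("expression profile has duplicated gene records")
  if ("p_value" %in% names(profile)) {
    p <- profile$p_value
    if (any(!is.na(p) & (p < 0 | p > 1)))
      stop("p-values must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Read an expression-statistics table
#'
#' TSV with header; needs a `gene` column and any of `fold_change`,
#' `p_value`, `z_score`.
#'
#' @param path path to the TSV file.
#' @return a `data.frame`, one row per gene.
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab))
    stop("expression table must have a 'gene' column: ", path)
  tab$gene <- trimws(tab$gene)
  .checkProfile(tab)
  tab
}

#' Read a plain-text gene list
#'
#' One identifier per line; lines starting with `#` are ignored and
#' surrounding whitespace is trimmed. Returns a deduplicated set.
#'
#' @param path path to the file.
#' @return character vector of identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write downstream gene sets in GMT format
#'
#' One line per (TF, model): set name `"<TF>|<model>"`, description = the
#' model label, then the member genes, all tab-separated.
#'
#' @param sets a [DownstreamSets-class] or a list of them.
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readGeneSetsGMT()]
#' @export
writeGeneSetsGMT <- function(sets, path) {
  if (is(sets, "DownstreamSets")) sets <- list(sets)
  lines <- character()
  for (ds in sets) {
    stopifnot(is(ds, "DownstreamSets"))
    if (is.na(ds@tf) || !nzchar(ds@tf))
      stop("every downstream set needs a non-empty TF name")
    for (m in MODEL_IDS) {
      lines <- c(lines, paste(c(paste0(ds@tf, "|", m), MODEL_LABELS[[m]],
                                ds@sets[[m]]), collapse = "\t"))
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; each element carries its GMT
#'   description as attribute `"description"`.
#' @seealso [writeGeneSetsGMT()]
#' @export
readGeneSetsGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", ln)
    genes <- if (length(f) > 2L) f[-(1:2)] else character()
    attr(genes, "description") <- f[2L]
    out[[f[1L]]] <- genes
  }
  out
}
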