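# Six downstream gene-set models per TF, bounded at TF-to-TF path length 2.
#
# Roles (all relative to a focal TF A):
#   B: TF post-translationally modified (kinase/phosphatase edge) by A
#   C: TF coded by a transcription target of A
#   D: TF coded by a transcription target of B
#   X: any protein coded by a transcription target of A ("modulator")
#   E: TF modified by a modulator edge from X
#   F: TF coded by a transcription target of C
# Self-edges are retained in storage but ignored while recruiting mediators,
# and a protein fills at most one role per path (A-B-D, A-C-F, A-X-E all
# have distinct nodes).

.knownIds <- function(net) {
  unique(c(net@tfRoster,
           net@transcription$source, net@transcription$target,
           net@modification$source, net@modification$target,
           names(net@geneProduct), unname(net@geneProduct)))
}

.assertKnown <- function(net, id) {
  if (length(id) != 1L || is.na(id) || !nzchar(id))
    stop("identifier must be a single non-empty string")
  if (!id %in% .knownIds(net))
    stop("unknown identifier: ", id)
  invisible(id)
}

# protein coded by a gene: explicit map first, else the gene id itself
.product <- function(net, genes) {
  gp <- net@geneProduct
  out <- genes
  hit <- genes %in% names(gp)
  out[hit] <- gp[genes[hit]]
  out
}

.txTargets <- function(net, protein) {
  net@transcription$target[net@transcription$source == protein]
}

.modSubstrates <- function(net, protein, subkinds) {
  md <- net@modification
  out <- md$target[md$source == protein & md$subkind %in% subkinds]
  out[out != protein]  # self-modification ignored in traversal
}

# TFs coded by the transcription targets of `protein`, excluding `exclude`
.tfsAmongTargets <- function(net, protein, exclude) {
  prods <- .product(net, .txTargets(net, protein))
  setdiff(intersect(unique(prods), net@tfRoster), exclude)
}

#' Direct transcription targets of a regulator
#'
#' @param net a [RegulatoryNetwork-class].
#' @param regulator a known protein identifier.
#' @return character vector of target-gene identifiers (possibly empty).
#' @examples
#' directTargets(toyNetwork(), "A")
#' @export
directTargets <- function(net, regulator) {
  stopifnot(is(net, "RegulatoryNetwork"))
  .assertKnown(net, regulator)
  unique(.txTargets(net, regulator))
}

#' Mediating TFs of a focal TF, by relation
#'
#' `ptm_substrate`: TFs the focal TF modifies through kinase/phosphatase
#' edges (role B). `transcribed_tf`: TFs coded by the focal TF's
#' transcription targets (role C). `modulator_modified`: TFs modified by a
#' modulator edge whose source protein is coded by a transcription target
#' of the focal TF (role E via X). The focal TF is excluded from every
#' mediator set.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param tf the focal TF identifier.
#' @param relation one of `"ptm_substrate"`, `"transcribed_tf"`,
#'   `"modulator_modified"`.
#' @return character vector of mediator TF identifiers.
#' @examples
#' mediatorTFs(toyNetwork(), "A", "ptm_substrate")
#' @export
mediatorTFs <- function(net, tf,
                        relation = c("ptm_substrate", "transcribed_tf",
                                     "modulator_modified")) {
  stopifnot(is(net, "RegulatoryNetwork"))
  relation <- match.arg(relation)
  .assertKnown(net, tf)
  out <- switch(relation,
    ptm_substrate = {
      subs <- .modSubstrates(net, tf, c("kinase", "phosphatase"))
      intersect(unique(subs), net@tfRoster)
    },
    transcribed_tf = .tfsAmongTargets(net, tf, exclude = tf),
    modulator_modified = {
      xs <- setdiff(unique(.product(net, .txTargets(net, tf))), tf)
      es <- unlist(lapply(xs, function(x)
        .modSubstrates(net, x, "modulator")), use.names = FALSE)
      intersect(unique(es), net@tfRoster)
    })
  setdiff(out, tf)
}

.unionTargets <- function(net, proteins) {
  if (!length(proteins)) return(character())
  unique(unlist(lapply(proteins, .txTargets, net = net), use.names = FALSE))
}

.buildAllSets <- function(net, tf) {
  I <- unique(.txTargets(net, tf))

  B <- mediatorTFs(net, tf, "ptm_substrate")
  II <- union(I, .unionTargets(net, B))

  C <- mediatorTFs(net, tf, "transcribed_tf")
  # role D: TFs coded by targets of B, distinct from the path nodes {tf, B}
  D <- unique(unlist(lapply(B, function(b)
    .tfsAmongTargets(net, b, exclude = c(tf, b))), use.names = FALSE))
  if (is.null(D)) D <- character()
  III <- union(II, union(.unionTargets(net, C), .unionTargets(net, D)))

  E <- mediatorTFs(net, tf, "modulator_modified")
  IV <- union(II, .unionTargets(net, E))

  V <- union(III, IV)

  # role F: TFs coded by targets of C, distinct from the path nodes {tf, C}
  Fm <- unique(unlist(lapply(C, function(cc)
    .tfsAmongTargets(net, cc, exclude = c(tf, cc))), use.names = FALSE))
  if (is.null(Fm)) Fm <- character()
  VI <- union(V, .unionTargets(net, Fm))

  X <- setdiff(unique(.product(net, .txTargets(net, tf))), tf)
  X <- X[vapply(X, function(x)
    length(intersect(.modSubstrates(net, x, "modulator"), net@tfRoster)) > 0L,
    logical(1))]

  srt <- function(v) sort(unique(v))
  list(sets = list(I = srt(I), II = srt(II), III = srt(III),
                   IV = srt(IV), V = srt(V), VI = srt(VI)),
       mediators = list(
         I = list(),
         II = list(B = srt(B)),
         III = list(B = srt(B), C = srt(C), D = srt(D)),
         IV = list(B = srt(B), X = srt(X), E = srt(E)),
         V = list(B = srt(B), C = srt(C), D = srt(D), X = srt(X), E = srt(E)),
         VI = list(B = srt(B), C = srt(C), D = srt(D), X = srt(X), E = srt(E),
                   F = srt(Fm))))
}

#' Downstream gene set of a TF under one regulation model
#'
#' Model I: direct targets. II: I plus targets of TFs the focal TF
#' modifies (role B). III: II plus targets of TFs coded by the focal TF's
#' targets (role C) and of TFs coded by B's targets (role D). IV: II plus
#' targets of TFs modified by a modulator protein coded by a target of the
#' focal TF (role E via X). V: III union IV. VI: V plus targets of TFs coded
#' by C's targets (role F). No longer paths are admitted.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param tf focal TF identifier.
#' @param model one of `"I"`..`"VI"`.
#' @return character vector of downstream gene identifiers (sorted).
#' @examples
#' downstreamSet(toyNetwork(), "A", "VI")
#' @export
downstreamSet <- function(net, tf, model) {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (length(model) != 1L || !model %in% MODEL_IDS)
    stop("model must be one of ", paste(MODEL_IDS, collapse = ", "))
  .assertKnown(net, tf)
  .buildAllSets(net, tf)$sets[[model]]
}

#' All six downstream gene sets of a TF
#'
#' @param net a [RegulatoryNetwork-class].
#' @param tf focal TF identifier.
#' @return a [DownstreamSets-class] with the six sets and the mediators
#'   (roles B, C, D, E, X, F) each model recruited.
#' @examples
#' allDownstreamSets(toyNetwork(), "A")
#' @export
allDownstreamSets <- function(net, tf) {
  stopifnot(is(net, "RegulatoryNetwork"))
  .assertKnown(net, tf)
  parts <- .buildAllSets(net, tf)
  new("DownstreamSets", tf = tf, sets = parts$sets,
      mediators = parts$mediators)
}

#' Candidate TFs by minimum downstream-set size
#'
#' A TF qualifies as a candidate causal regulator when at least one of its
#' six model sets has `minSize` or more genes (default 4, the rule that
#' selected 139 candidate TFs from the integrated yeast network).
#'
#' @param net a [RegulatoryNetwork-class].
#' @param minSize integer >= 1.
#' @return character vector of qualifying TF identifiers (roster order).
#' @examples
#' candidateTFs(toyNetwork())
#' @export
candidateTFs <- function(net, minSize = 4L) {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (minSize < 1L) stop("minSize must be >= 1")
  keep <- vapply(net@tfRoster, function(tf) {
    sets <- .buildAllSets(net, tf)$sets
    max(vapply(sets, length, integer(1))) >= minSize
  }, logical(1))
  net@tfRoster[keep]
}

#' Export mediator bookkeeping as a table
#'
#' @param sets a [DownstreamSets-class] or list of them.
#' @return `data.frame(tf, model, role, mediator)`, one row per mediator.
#' @export
mediatorTable <- function(sets) {
  if (is(sets, "DownstreamSets")) sets <- list(sets)
  rows <- list()
  for (ds in sets) {
    for (m in MODEL_IDS) {
      med <- ds@mediators[[m]]
      for (role in names(med)) {
        if (length(med[[role]]))
          rows[[length(rows) + 1L]] <- data.frame(
            tf = ds@tf, model = m, role = role, mediator = med[[role]],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(tf = character(), model = character(),
                      role = character(), mediator = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
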