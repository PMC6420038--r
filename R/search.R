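.asQueryRecord <- function(query, index) {
  if (is(query, "StructureRecord")) return(query)
  makeStructureRecord(query, params = index@params)
}

# candidate shortlist ranked by estimated Jaccard, capped
.fastShortlist <- function(query, index, candidateCap, filter) {
  ids <- candidates(index, query, filter = filter)
  if (length(ids) == 0L) {
    return(data.frame(id = character(0), jaccardEst = numeric(0)))
  }
  est <- colMeans(index@sigMatrix[, ids, drop = FALSE] ==
                    query@signature@hashes)
  ord <- order(-est, ids)
  keep <- ord[seq_len(min(candidateCap, length(ord)))]
  data.frame(id = ids[keep], jaccardEst = unname(est[keep]),
             stringsAsFactors = FALSE)
}

.rankHits <- function(df, by, decreasing = TRUE, cap = nrow(df)) {
  ord <- if (decreasing) order(-df[[by]], df$id) else order(df[[by]], df$id)
  out <- df[ord[seq_len(min(cap, nrow(df)))], , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank")), drop = FALSE]
}

#' Fast-mode structure search
#'
#' Generates candidates by single-band LSH match, ranks them by the
#' min-hash Jaccard estimate, keeps the top `candidateCap` (default 8000),
#' rescores those with the LCS-adjusted Jaccard similarity against the
#' stored encoded hash sequences, and returns the top `resultCap` (default
#' 400) sorted by adjusted Jaccard (descending, ties by id).
#'
#' @param query a [StructureRecord-class], [BackboneChain-class] or
#'   [DescriptorSequence-class]; records must use the index seed set.
#' @param index a [StructureIndex-class].
#' @param candidateCap shortlist size retained from the LSH filtering.
#' @param resultCap number of hits returned.
#' @param filter optional metadata predicate, see [candidates()].
#' @return data.frame with columns `rank`, `id`, `jaccardEst`,
#'   `jaccardAdj`, `nResidues`.
#' @export
fastSearch <- function(query, index, candidateCap = 8000L,
                       resultCap = 400L, filter = NULL) {
  query <- .asQueryRecord(query, index)
  short <- .fastShortlist(query, index, candidateCap, filter)
  if (nrow(short) == 0L) {
    return(data.frame(rank = integer(0), id = character(0),
                      jaccardEst = numeric(0), jaccardAdj = numeric(0),
                      nResidues = integer(0)))
  }
  short$jaccardAdj <- vapply(short$id, function(id) {
    adjustedJaccard(query@bag, index@records[[id]]@bag)
  }, numeric(1))
  short$nResidues <- vapply(short$id, function(id) {
    index@records[[id]]@nResidues
  }, integer(1))
  .rankHits(short, "jaccardAdj", decreasing = TRUE, cap = resultCap)
}

.alignShortlist <- function(query, index, ids, iterations, normalization) {
  qca <- query@ca
  if (nrow(qca) == 0L) {
    stop("top-aligned mode needs CA coordinates on the query record")
  }
  res <- lapply(ids, function(id) {
    rec <- index@records[[id]]
    if (nrow(rec@ca) == 0L) {
      stop(sprintf("record '%s' has no CA coordinates; top-aligned mode ",
                   id), "requires coordinate-bearing records")
    }
    tmAlignPair(qca, rec@ca, iterations = iterations,
                normalization = normalization, ssA = query@ss,
                ssB = rec@ss)
  })
  data.frame(id = ids,
             tmScore = vapply(res, function(r) r@tmScore, numeric(1)),
             rmsd = vapply(res, function(r) r@rmsd, numeric(1)),
             alignedLength = vapply(res, function(r) r@alignedLength,
                                    integer(1)),
             stringsAsFactors = FALSE)
}

#' Top-aligned structure search
#'
#' Re-ranks the fast-mode shortlist by structure alignment: stage 1 aligns
#' all (up to `candidateCap`) LSH candidates with a reduced number of
#' dynamic-programming rounds and sorts by the chosen criterion; stage 2
#' realigns the surviving top `resultCap` with the full number of rounds
#' and returns them sorted by the criterion (TM-score descending or RMSD
#' ascending, ties by id).
#'
#' @inheritParams fastSearch
#' @param sortBy `"tm"` (TM-score) or `"rmsd"`.
#' @param normalization TM-score length normalization, see [tmAlignPair()].
#' @param reducedRounds,fullRounds dynamic-programming round caps for the
#'   two stages.
#' @return data.frame with columns `rank`, `id`, `jaccardEst`,
#'   `jaccardAdj`, `tmScore`, `rmsd`, `alignedLength`, `nResidues`; the
#'   stage-1 table is attached as attribute `"stage1"`.
#' @export
topAlignedSearch <- function(query, index, sortBy = c("tm", "rmsd"),
                             candidateCap = 8000L, resultCap = 400L,
                             normalization = c("average", "query"),
                             reducedRounds = 2L, fullRounds = 30L,
                             filter = NULL) {
  sortBy <- match.arg(sortBy)
  normalization <- match.arg(normalization)
  query <- .asQueryRecord(query, index)
  short <- .fastShortlist(query, index, candidateCap, filter)
  empty <- data.frame(rank = integer(0), id = character(0),
                      jaccardEst = numeric(0), jaccardAdj = numeric(0),
                      tmScore = numeric(0), rmsd = numeric(0),
                      alignedLength = integer(0), nResidues = integer(0))
  if (nrow(short) == 0L) return(empty)
  short$jaccardAdj <- vapply(short$id, function(id) {
    adjustedJaccard(query@bag, index@records[[id]]@bag)
  }, numeric(1))
  crit <- if (sortBy == "tm") "tmScore" else "rmsd"
  dec <- sortBy == "tm"
  stage1 <- merge(short,
                  .alignShortlist(query, index, short$id, reducedRounds,
                                  normalization),
                  by = "id")
  stage1 <- .rankHits(stage1, crit, decreasing = dec, cap = resultCap)
  stage2 <- merge(stage1[, c("id", "jaccardEst", "jaccardAdj")],
                  .alignShortlist(query, index, stage1$id, fullRounds,
                                  normalization),
                  by = "id")
  stage2$nResidues <- vapply(stage2$id, function(id) {
    index@records[[id]]@nResidues
  }, integer(1))
  out <- .rankHits(stage2, crit, decreasing = dec, cap = resultCap)
  out <- out[, c("rank", "id", "jaccardEst", "jaccardAdj", "tmScore",
                 "rmsd", "alignedLength", "nResidues")]
  attr(out, "stage1") <- stage1
  out
}
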