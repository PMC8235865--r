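#' Chaining and clustering configuration
#'
#' Tunable thresholds of the integration-event reconstruction. Collinear
#' chaining links host-adjacent fragments whose viral-vs-host gap pair is
#' nearly equal: `|g_v - g_h| <= max(gapTolAbs, gapTolRel * max(g_v, g_h))`
#' with both gaps at most `maxChainGap`. Overlap/identity clustering merges
#' units sharing a viral-interval overlap above `minOverlap` bp and (when
#' sequence identity is available) identity above `minIdentity` percent.
#' Duplicate fragments are flagged at `dupIdentity` percent identity and
#' `dupCoverage` percent mutual coverage. Cross-region adjacency merging
#' joins events whose viral spans abut within `adjacencyTol` bases, gated
#' on piRNA orientation evidence unless `allowUnevidencedMerge` is set.
#'
#' @param gapTolAbs Absolute gap-discrepancy tolerance in bases (300).
#' @param gapTolRel Relative gap-discrepancy tolerance (0.5).
#' @param maxChainGap Maximum chainable gap on either genome, bases (5000).
#' @param minOverlap Minimum viral-interval overlap in bp (50).
#' @param minIdentity Minimum identity percent for clustering (94).
#' @param dupIdentity Minimum identity percent for duplicate flagging (99).
#' @param dupCoverage Minimum mutual coverage percent for duplicates (100).
#' @param adjacencyTol Maximum viral adjacency gap for event merging (50).
#' @param allowUnevidencedMerge Merge adjacent events without orientation
#'   evidence (default FALSE).
#' @return A classed list of validated parameters.
#' @export
chainConfig <- function(gapTolAbs = 300, gapTolRel = 0.5,
                        maxChainGap = 5000, minOverlap = 50,
                        minIdentity = 94, dupIdentity = 99,
                        dupCoverage = 100, adjacencyTol = 50,
                        allowUnevidencedMerge = FALSE) {
  stopifnot(gapTolAbs >= 0, gapTolRel >= 0, gapTolRel <= 1,
            maxChainGap >= 0, minOverlap >= 0,
            minIdentity >= 0, minIdentity <= 100,
            dupIdentity >= 0, dupIdentity <= 100, dupCoverage >= 0,
            dupCoverage <= 100, adjacencyTol >= 0,
            is.logical(allowUnevidencedMerge))
  structure(list(gapTolAbs = gapTolAbs, gapTolRel = gapTolRel,
                 maxChainGap = maxChainGap, minOverlap = minOverlap,
                 minIdentity = minIdentity, dupIdentity = dupIdentity,
                 dupCoverage = dupCoverage, adjacencyTol = adjacencyTol,
                 allowUnevidencedMerge = allowUnevidencedMerge),
            class = "chainConfig")
}

# per-record geometry used throughout the module
.eveGeom <- function(x) {
  mc <- S4Vectors::mcols(x@granges)
  data.frame(identifier = mc$identifier,
             chrom = as.character(GenomicRanges::seqnames(x@granges)),
             hMin = GenomicRanges::start(x@granges),
             hMax = GenomicRanges::end(x@granges),
             vMin = mc$vStart, vMax = mc$vEnd, virus = mc$virus,
             strand = as.character(BiocGenerics::strand(x@granges)),
             stringsAsFactors = FALSE)
}

# gap pair between two geometry rows; a/b in arbitrary order
.gapPair <- function(gA, gB) {
  if (gA$chrom != gB$chrom)
    stop("cannot compute a gap across contigs (",
         gA$chrom, " vs ", gB$chrom, ")")
  if (gA$hMin > gB$hMin) { tmp <- gA; gA <- gB; gB <- tmp }
  gh <- gB$hMin - gA$hMax
  gv <- if (gA$strand == "+") gB$vMin - gA$vMax else gA$vMin - gB$vMax
  c(viral = gv, host = gh)
}

#' Gap pair between two consecutive EVE fragments
#'
#' Computes the signed viral-genome and host-genome distances between the
#' nearest interval ends of two fragments on the same contig, in the
#' coordinate-difference convention of curated EVE tables. The fragment
#' with the smaller host coordinate is taken as the left member; on the
#' minus strand the viral gap is measured against the reversed viral
#' order, so both gaps come out as the printed non-negative distances for
#' sequentially spaced fragments. Near-equality of the two gaps is the
#' collinearity signature of a single decayed insertion.
#'
#' @param x An [EveSet-class].
#' @param a,b Identifiers of the two fragments.
#' @return Named numeric vector `c(viral=, host=)`; values may be negative
#'   when intervals overlap.
#' @examples
#' computeGap(aegyptiEveTable(), "AE2.2", "AE3.2")  # viral 359, host 260
#' @export
computeGap <- function(x, a, b) {
  stopifnot(methods::is(x, "EveSet"))
  g <- .eveGeom(x)
  ia <- match(a, g$identifier); ib <- match(b, g$identifier)
  if (is.na(ia) || is.na(ib))
    stop("unknown identifier(s): ",
         paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  .gapPair(g[ia, ], g[ib, ])
}

.gapWithinTol <- function(gv, gh, config) {
  gv > 0 && gv <= config$maxChainGap &&
    gh >= 0 && gh <= config$maxChainGap &&
    abs(gv - gh) <= max(config$gapTolAbs,
                        config$gapTolRel * max(gv, gh))
}

# region index per record (single-linkage footprint merge)
.regionAssignment <- function(x, regionMergeDist) {
  regions <- buildRegions(x, regionMergeDist)
  ov <- GenomicRanges::findOverlaps(hostRanges(x), regions,
                                    ignore.strand = TRUE)
  reg <- integer(length(x))
  reg[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  names(reg) <- eveIds(x)
  reg
}

#' Chain collinear EVE fragments within regions
#'
#' Sorts the fragments of each region by host coordinate and links each
#' adjacent pair whose orientation is shared and whose viral/host gap pair
#' passes the near-equality rule of [chainConfig()]. Chains are maximal
#' runs of linked pairs; unlinked fragments form singleton chains.
#'
#' @param x An [EveSet-class].
#' @param config A [chainConfig()].
#' @param regionMergeDist Single-linkage distance defining regions (1e5).
#' @return list with `chains` (list of identifier vectors in host order),
#'   `evidence` (data.frame `id_a`, `id_b`, `kind`, `score` with the gap
#'   discrepancy in bases as score) and `regions` (named region index).
#' @export
chainCollinear <- function(x, config = chainConfig(),
                           regionMergeDist = 1e5) {
  stopifnot(methods::is(x, "EveSet"), inherits(config, "chainConfig"))
  g <- .eveGeom(x)
  reg <- .regionAssignment(x, regionMergeDist)
  chains <- list(); ev <- list()
  for (r in sort(unique(reg))) {
    gi <- g[reg[g$identifier] == r, , drop = FALSE]
    gi <- gi[order(gi$hMin, gi$identifier), , drop = FALSE]
    cur <- gi$identifier[1L]
    for (k in seq_len(nrow(gi) - 1L)) {
      A <- gi[k, ]; B <- gi[k + 1L, ]
      gp <- .gapPair(A, B)
      linked <- A$strand == B$strand &&
        .gapWithinTol(gp[["viral"]], gp[["host"]], config)
      if (linked) {
        cur <- c(cur, B$identifier)
        ev[[length(ev) + 1L]] <- data.frame(
          id_a = A$identifier, id_b = B$identifier, kind = "collinear",
          score = abs(gp[["viral"]] - gp[["host"]]),
          stringsAsFactors = FALSE)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- B$identifier
      }
    }
    chains[[length(chains) + 1L]] <- cur
  }
  list(chains = chains,
       evidence = if (length(ev)) do.call(rbind, ev) else
         data.frame(id_a = character(), id_b = character(),
                    kind = character(), score = numeric(),
                    stringsAsFactors = FALSE),
       regions = reg)
}

# deterministic union-find with index-ordered union
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# identity lookup helpers -----------------------------------------------

.identityFromTable <- function(tab, ids) {
  stopifnot(all(c("id_a", "id_b", "identity_pct") %in% colnames(tab)))
  unknown <- setdiff(unique(c(tab$id_a, tab$id_b)), ids)
  if (length(unknown))
    stop("identity table references unknown identifier(s): ",
         paste(unknown, collapse = ", "))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- stats::setNames(tab$identity_pct, key(tab$id_a, tab$id_b))
  function(a, b) {
    v <- lut[key(a, b)]
    if (is.na(v)) NA_real_ else unname(v)
  }
}

.identityFromSeqs <- function(seqs, ids) {
  stopifnot(!is.null(names(seqs)))
  miss <- setdiff(ids, names(seqs))
  if (length(miss))
    stop("sequences missing for identifier(s): ",
         paste(miss, collapse = ", "))
  function(a, b) pairwiseIdentity(seqs[[a]], seqs[[b]])$identity
}

#' Cluster chains and singletons into integration events
#'
#' Union-find over the chains from [chainCollinear()]: two units merge
#' when some member pair within the same region shares a viral-interval
#' overlap above `minOverlap` bp and — when sequence identity is available
#' — identity above `minIdentity` percent. When no identity source is
#' supplied, the same-region viral overlap alone suffices (proximal EVE
#' fragments overlapping on the virus consistently exceed the identity
#' threshold, so coordinates alone reproduce the clustering). Merges never
#' cross regions at this stage; use [mergeAdjacentEvents()] for that.
#' Events are numbered by chromosome and leftmost host coordinate.
#'
#' @param x An [EveSet-class].
#' @param chains Output of [chainCollinear()]; computed if `NULL`.
#' @param identity Optional identity source: a data.frame with columns
#'   `id_a`, `id_b`, `identity_pct` (and optionally `overlap_len`), or a
#'   named [Biostrings::DNAStringSet] of fragment sequences, or `NULL`.
#' @param config A [chainConfig()].
#' @param regionMergeDist Single-linkage distance defining regions (1e5).
#' @return An [IntegrationEvents-class].
#' @examples
#' ev <- identityCluster(aegyptiEveTable())
#' eventCount(ev)  # five putative events
#' @export
identityCluster <- function(x, chains = NULL, identity = NULL,
                            config = chainConfig(),
                            regionMergeDist = 1e5) {
  stopifnot(methods::is(x, "EveSet"))
  if (is.null(chains))
    chains <- chainCollinear(x, config, regionMergeDist)
  g <- .eveGeom(x)
  ids <- g$identifier
  n <- length(ids)
  idIdx <- stats::setNames(seq_len(n), ids)
  reg <- chains$regions
  idFun <- if (is.null(identity)) NULL
  else if (is.data.frame(identity)) .identityFromTable(identity, ids)
  else .identityFromSeqs(identity, ids)

  parent <- seq_len(n)
  unite <- function(i, j) {
    ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (ch in chains$chains) {
    ki <- idIdx[ch]
    for (k in seq_len(length(ki) - 1L)) unite(ki[k], ki[k + 1L])
  }
  ev <- list()
  ord <- order(g$chrom, g$hMin, g$identifier)
  for (aPos in seq_len(n - 1L)) for (bPos in seq((aPos + 1L), n)) {
    i <- ord[aPos]; j <- ord[bPos]
    if (reg[ids[i]] != reg[ids[j]]) next
    ovl <- min(g$vMax[i], g$vMax[j]) - max(g$vMin[i], g$vMin[j]) + 1L
    if (ovl <= config$minOverlap) next
    if (is.null(idFun)) {
      unite(i, j)
      ev[[length(ev) + 1L]] <- data.frame(
        id_a = ids[i], id_b = ids[j], kind = "overlap_identity",
        score = NA_real_, stringsAsFactors = FALSE)
    } else {
      pid <- idFun(ids[i], ids[j])
      if (!is.na(pid) && pid > config$minIdentity) {
        unite(i, j)
        ev[[length(ev) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], kind = "overlap_identity",
          score = pid, stringsAsFactors = FALSE)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  # canonical numbering by (chrom, leftmost host coordinate)
  comp <- split(seq_len(n), roots)
  firstPos <- vapply(comp, function(m) {
    o <- order(g$chrom[m], g$hMin[m])[1L]
    m[o]
  }, integer(1))
  compOrd <- order(g$chrom[firstPos], g$hMin[firstPos])
  evId <- integer(n)
  for (k in seq_along(compOrd)) evId[comp[[compOrd[k]]]] <- k
  membership <- stats::setNames(evId, ids)
  evidence <- rbind(chains$evidence,
                    if (length(ev)) do.call(rbind, ev) else NULL)
  rownames(evidence) <- NULL
  methods::new("IntegrationEvents", eves = x, membership = membership,
               evidence = evidence,
               params = list(config = config,
                             regionMergeDist = regionMergeDist,
                             identityMode = if (is.null(identity)) "overlap"
                             else if (is.data.frame(identity)) "table"
                             else "sequence"))
}

#' Infer integration events from an EveSet
#'
#' Convenience wrapper running [chainCollinear()] then [identityCluster()].
#'
#' @inheritParams identityCluster
#' @return An [IntegrationEvents-class].
#' @export
inferEvents <- function(x, identity = NULL, config = chainConfig(),
                        regionMergeDist = 1e5) {
  chains <- chainCollinear(x, config, regionMergeDist)
  identityCluster(x, chains, identity, config, regionMergeDist)
}

#' Flag duplicate EVE fragment pairs
#'
#' Fragments arising by host genomic duplication of an already-integrated
#' segment show near-total identity and full mutual coverage, unlike
#' independent insertions of related viruses. Pairs at or above
#' `dupIdentity` percent identity whose mutual coverage (percent of each
#' fragment covered by the aligned segment, rounded to the nearest
#' percent) reaches `dupCoverage` are flagged. Requires an identity
#' source; coordinates alone cannot distinguish duplication from
#' independent insertion.
#'
#' @param x An [EveSet-class].
#' @param identity A data.frame with columns `id_a`, `id_b`,
#'   `identity_pct`, `overlap_len`, or a named
#'   [Biostrings::DNAStringSet] of fragment sequences.
#' @param config A [chainConfig()].
#' @return data.frame of flagged pairs (`id_a` < `id_b`): `id_a`, `id_b`,
#'   `identity_pct`, `coverage_a`, `coverage_b`.
#' @export
flagDuplicates <- function(x, identity, config = chainConfig()) {
  stopifnot(methods::is(x, "EveSet"))
  if (missing(identity) || is.null(identity))
    stop("identity required: duplicate flagging needs a pairwise identity ",
         "table or fragment sequences")
  ids <- eveIds(x)
  len <- eveLengths(x)
  out <- list()
  addPair <- function(a, b, pid, covA, covB) {
    if (pid >= config$dupIdentity &&
        round(covA) >= config$dupCoverage &&
        round(covB) >= config$dupCoverage)
      out[[length(out) + 1L]] <<- data.frame(
        id_a = min(a, b), id_b = max(a, b), identity_pct = pid,
        coverage_a = covA, coverage_b = covB, stringsAsFactors = FALSE)
  }
  if (is.data.frame(identity)) {
    stopifnot(all(c("id_a", "id_b", "identity_pct", "overlap_len") %in%
                    colnames(identity)))
    unknown <- setdiff(unique(c(identity$id_a, identity$id_b)), ids)
    if (length(unknown))
      stop("identity table references unknown identifier(s): ",
           paste(unknown, collapse = ", "))
    for (r in seq_len(nrow(identity))) {
      a <- identity$id_a[r]; b <- identity$id_b[r]
      addPair(a, b, identity$identity_pct[r],
              100 * identity$overlap_len[r] / len[[a]],
              100 * identity$overlap_len[r] / len[[b]])
    }
  } else {
    miss <- setdiff(ids, names(identity))
    if (length(miss))
      stop("sequences missing for identifier(s): ",
           paste(miss, collapse = ", "))
    for (i in seq_len(length(ids) - 1L)) for (j in seq((i + 1L),
                                                       length(ids))) {
      pw <- pairwiseIdentity(identity[[ids[i]]], identity[[ids[j]]])
      addPair(ids[i], ids[j], pw$identity, pw$coverageA, pw$coverageB)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[!duplicated(paste(res$id_a, res$id_b)), , drop = FALSE]
    rownames(res) <- NULL
    res
  } else {
    data.frame(id_a = character(), id_b = character(),
               identity_pct = numeric(), coverage_a = numeric(),
               coverage_b = numeric(), stringsAsFactors = FALSE)
  }
}

#' Merge adjacent events on viral-genome adjacency plus orientation evidence
#'
#' Two events merge when the viral span of one ends within `adjacencyTol`
#' bases of the other's start (same donor virus, no viral overlap) and the
#' orientation evidence marks both events consistent — i.e. both show the
#' anti-EVE piRNA bias expected of a once-contiguous insertion (see
#' [orientationVerdict()]). When no evidence is supplied, merging requires
#' `allowUnevidencedMerge` in the config. The result is still a partition,
#' renumbered by genomic position.
#'
#' @param events An [IntegrationEvents-class].
#' @param orientation Optional named character vector mapping event ids
#'   (as character) to `"consistent"`, `"inconsistent"` or
#'   `"indeterminate"`.
#' @param config A [chainConfig()].
#' @return An [IntegrationEvents-class].
#' @export
mergeAdjacentEvents <- function(events, orientation = NULL,
                                config = chainConfig()) {
  stopifnot(methods::is(events, "IntegrationEvents"))
  x <- events@eves
  g <- .eveGeom(x)
  mem <- events@membership[g$identifier]
  k <- max(mem)
  span <- do.call(rbind, lapply(seq_len(k), function(e) {
    gi <- g[mem == e, , drop = FALSE]
    data.frame(event = e, vMin = min(gi$vMin), vMax = max(gi$vMax),
               virus = if (length(unique(gi$virus)) == 1L)
                 gi$virus[1L] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  okEvidence <- function(e) {
    if (is.null(orientation)) return(config$allowUnevidencedMerge)
    v <- orientation[as.character(e)]
    !is.na(v) && v == "consistent"
  }
  parent <- seq_len(k)
  unite <- function(i, j) {
    ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  ev <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (is.na(span$virus[i]) || is.na(span$virus[j]) ||
        span$virus[i] != span$virus[j]) next
    gap <- span$vMin[j] - span$vMax[i]
    if (gap > 0 && gap <= config$adjacencyTol &&
        okEvidence(i) && okEvidence(j)) {
      unite(i, j)
      ev[[length(ev) + 1L]] <- data.frame(
        id_a = paste0("event", i), id_b = paste0("event", j),
        kind = "cross_region_adjacency", score = gap,
        stringsAsFactors = FALSE)
    }
  }
  roots <- vapply(seq_len(k), function(i) .ufFind(parent, i), integer(1))
  newOf <- match(roots, sort(unique(roots)))
  newMem <- newOf[mem]
  # renumber by (chrom, leftmost host coordinate)
  firstPos <- vapply(seq_len(max(newMem)), function(e) {
    m <- which(newMem == e)
    m[order(g$chrom[m], g$hMin[m])[1L]]
  }, integer(1))
  relabel <- match(seq_len(max(newMem)),
                   order(g$chrom[firstPos], g$hMin[firstPos]))
  membership <- stats::setNames(relabel[newMem], g$identifier)
  methods::new("IntegrationEvents", eves = x,
               membership = membership,
               evidence = rbind(events@evidence,
                                if (length(ev)) do.call(rbind, ev) else
                                  NULL),
               params = c(events@params,
                          list(adjacencyMerged = TRUE)))
}

#' Best local alignment identity between two sequences
#'
#' Smith-Waterman local alignment under megablast-like scoring (match +2,
#' mismatch -3, gap open 5, gap extend 2 by default) via
#' [Biostrings::pairwiseAlignment]. Identity is matches divided by
#' alignment columns (gaps included) times 100.
#'
#' @param a,b Sequences (`DNAString`, `character`, or length-1
#'   `DNAStringSet`) over A, C, G, T, N.
#' @param match,mismatch Substitution scores.
#' @param gapOpening,gapExtension Gap penalties (positive costs).
#' @return list with `identity` (percent), `overlap` (alignment columns),
#'   `coverageA`, `coverageB` (percent of each sequence inside the aligned
#'   segment).
#' @export
pairwiseIdentity <- function(a, b, match = 2, mismatch = -3,
                             gapOpening = 5, gapExtension = 2) {
  asDna <- function(s, nm) {
    if (methods::is(s, "DNAStringSet")) s <- s[[1L]]
    s <- Biostrings::DNAString(as.character(s))
    if (length(s) == 0L) stop("empty sequence: ", nm)
    s
  }
  a <- asDna(a, "a"); b <- asDna(b, "b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension)
  cols <- Biostrings::nchar(aln)
  list(identity = 100 * Biostrings::nmatch(aln) / cols,
       overlap = cols,
       coverageA = 100 * IRanges::width(aln@pattern@range) / length(a),
       coverageB = 100 * IRanges::width(aln@subject@range) / length(b))
}
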