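#' Filter-cascade configuration for raw alignment hits
#'
#' Thresholds for reducing a raw viral-vs-host hit list to candidate EVE
#' loci: the e-value ceiling, the minimum viral genome length recorded as
#' search metadata (near-complete genomes only), the minimum number of
#' distinct viral accessions whose hits must overlap a locus for retention
#' (independent hits from related viruses at one locus are the retention
#' principle), and the single-linkage distance used when merging retained
#' footprints into regions.
#'
#' @param maxEvalue E-value ceiling (default 0.001).
#' @param minViralGenomeLen Minimum query genome length in bp, recorded as
#'   metadata of the search database (default 10000).
#' @param minSupportAccessions Minimum distinct viral accessions overlapping
#'   a hit's host footprint, counting the hit's own accession (default 2).
#' @param regionMergeDist Merge distance in bases for [buildRegions()]
#'   (default 100000).
#' @return A classed list of validated thresholds.
#' @export
filterConfig <- function(maxEvalue = 0.001, minViralGenomeLen = 10000,
                         minSupportAccessions = 2, regionMergeDist = 1e5) {
  stopifnot(maxEvalue >= 0, minViralGenomeLen >= 0,
            minSupportAccessions >= 0, regionMergeDist >= 0)
  structure(list(maxEvalue = maxEvalue,
                 minViralGenomeLen = minViralGenomeLen,
                 minSupportAccessions = minSupportAccessions,
                 regionMergeDist = regionMergeDist),
            class = "filterConfig")
}

#' Apply the hit filter cascade
#'
#' Two ordered stages: (1) drop hits with e-value above `maxEvalue`;
#' (2) drop hits whose host footprint is not overlapped by hits from at
#' least `minSupportAccessions` distinct viral accessions (its own
#' included), computed on the survivors of stage 1. The returned ledger
#' reports the count removed per stage, in stage order; further user
#' stages can be appended by re-running with stricter configs.
#'
#' @param hits Hit data.frame from [readBlastTab()].
#' @param config A [filterConfig()].
#' @return list with elements `hits` (retained rows) and `ledger`
#'   (data.frame `stage`, `n_in`, `n_removed`, `n_out`).
#' @export
filterHits <- function(hits, config = filterConfig()) {
  stopifnot(inherits(config, "filterConfig"))
  ledger <- data.frame(stage = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer(),
                       stringsAsFactors = FALSE)
  n0 <- nrow(hits)
  keep1 <- if (n0) hits$evalue <= config$maxEvalue else logical()
  h1 <- hits[keep1, , drop = FALSE]
  ledger <- rbind(ledger, data.frame(
    stage = "evalue", n_in = n0, n_removed = n0 - nrow(h1),
    n_out = nrow(h1), stringsAsFactors = FALSE))
  if (nrow(h1)) {
    gr <- GenomicRanges::GRanges(h1$subject_id,
                                 IRanges::IRanges(h1$s_min, h1$s_max))
    ov <- GenomicRanges::findOverlaps(gr, gr)
    accBy <- split(h1$query_acc[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov))
    support <- integer(nrow(h1))
    support[as.integer(names(accBy))] <-
      vapply(accBy, function(a) length(unique(a)), integer(1))
    keep2 <- support >= config$minSupportAccessions
  } else {
    keep2 <- logical()
  }
  h2 <- h1[keep2, , drop = FALSE]
  ledger <- rbind(ledger, data.frame(
    stage = "multi_accession_support", n_in = nrow(h1),
    n_removed = nrow(h1) - nrow(h2), n_out = nrow(h2),
    stringsAsFactors = FALSE))
  rownames(h2) <- NULL
  list(hits = h2, ledger = ledger)
}

.regionsFromGRanges <- function(gr, acc, mergeDist) {
  red <- GenomicRanges::reduce(
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::ranges(gr)),
    min.gapwidth = mergeDist + 1)
  red <- GenomicRanges::sort(red, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  nh <- integer(length(red)); na <- integer(length(red))
  byReg <- split(acc[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
  idx <- as.integer(names(byReg))
  nh[idx] <- lengths(byReg)
  na[idx] <- vapply(byReg, function(a) length(unique(a)), integer(1))
  S4Vectors::mcols(red) <- S4Vectors::DataFrame(
    region_id = paste0("R", seq_along(red)), n_hits = nh,
    n_accessions = na)
  red
}

#' @rdname buildRegions
#' @export
setMethod("buildRegions", "data.frame", function(x, mergeDist = 1e5) {
  stopifnot(mergeDist >= 0,
            all(c("subject_id", "s_min", "s_max", "query_acc") %in%
                  colnames(x)))
  gr <- GenomicRanges::GRanges(x$subject_id,
                               IRanges::IRanges(x$s_min, x$s_max))
  .regionsFromGRanges(gr, x$query_acc, mergeDist)
})

#' @rdname buildRegions
#' @export
setMethod("buildRegions", "EveSet", function(x, mergeDist = 1e5) {
  stopifnot(mergeDist >= 0)
  .regionsFromGRanges(hostRanges(x), virusNames(x), mergeDist)
})

#' @rdname buildRegions
#' @export
setMethod("buildRegions", "GRanges", function(x, mergeDist = 1e5) {
  stopifnot(mergeDist >= 0)
  acc <- S4Vectors::mcols(x)$virus
  if (is.null(acc)) acc <- rep("NA", length(x))
  .regionsFromGRanges(x, acc, mergeDist)
})

#' Pick the representative viral accession of a region
#'
#' Among hits overlapping the region, returns the accession maximizing the
#' total non-redundant host bases covered within the region; ties break
#' lexicographically. This mirrors selecting the longest, most complete
#' related virus as the coordinate system for a locus.
#'
#' @param hits Hit data.frame from [readBlastTab()].
#' @param region One region: a length-1 `GRanges` (as returned by
#'   [buildRegions()]) or a list with `chrom`, `start`, `end`.
#' @return The representative accession (character scalar).
#' @export
selectRepresentative <- function(hits, region) {
  if (methods::is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    rs <- GenomicRanges::start(region); re <- GenomicRanges::end(region)
  } else {
    chrom <- region$chrom; rs <- region$start; re <- region$end
  }
  h <- hits[hits$subject_id == chrom & hits$s_min <= re & hits$s_max >= rs,
            , drop = FALSE]
  if (!nrow(h)) stop("no hits overlap the region")
  cov <- vapply(split(h, h$query_acc), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(pmax(d$s_min, rs),
                                           pmin(d$s_max, re)))
    sum(IRanges::width(ir))
  }, numeric(1))
  names(cov)[order(-cov, names(cov))][1L]
}

#' Convert filtered hits to an EveSet of candidate fragments
#'
#' Builds regions from the hits, selects the representative accession per
#' region, and keeps that accession's hits as EVE fragment records (one
#' per hit), giving the dual-coordinate records on which event inference
#' operates. Identifiers are `R<region>.H<k>` in host order.
#'
#' @param hits Hit data.frame (typically the `hits` element of
#'   [filterHits()] output).
#' @param mergeDist Region merge distance in bases (default 100000).
#' @return An [EveSet-class].
#' @export
evesFromHits <- function(hits, mergeDist = 1e5) {
  stopifnot(nrow(hits) > 0)
  regions <- buildRegions(hits, mergeDist)
  out <- list()
  for (r in seq_along(regions)) {
    acc <- selectRepresentative(hits, regions[r])
    chrom <- as.character(GenomicRanges::seqnames(regions[r]))
    rs <- GenomicRanges::start(regions[r])
    re <- GenomicRanges::end(regions[r])
    h <- hits[hits$subject_id == chrom & hits$query_acc == acc &
                hits$s_min <= re & hits$s_max >= rs, , drop = FALSE]
    h <- h[order(h$s_min), , drop = FALSE]
    out[[r]] <- data.frame(
      identifier = sprintf("R%d.H%d", r, seq_len(nrow(h))),
      virus = h$query_acc, v_start = h$q_start, v_end = h$q_end,
      chrom = chrom, h_start = h$s_start, h_end = h$s_end,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  EveSet(df$identifier, df$virus, df$v_start, df$v_end, df$chrom,
         df$h_start, df$h_end)
}
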