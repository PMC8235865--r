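#' Construct an EveSet from dual-coordinate fragment descriptions
#'
#' Builds the package's central container from vectors matching a curated
#' EVE table: one row per fragment, with viral coordinates on the donor
#' genome and host coordinates as printed (descending host coordinates
#' encode the minus strand). The curated `length` convention is the host
#' coordinate difference `|hEnd - hStart|`; if a supplied length disagrees
#' with that difference a warning is raised and the supplied value is kept.
#'
#' @param identifier Character, unique fragment identifiers.
#' @param virus Character, donor virus accession or short name per fragment.
#' @param vStart,vEnd Integer viral coordinates, `vStart <= vEnd`.
#' @param chrom Character host contig per fragment.
#' @param hStart,hEnd Integer host coordinates in printed order
#'   (`hStart > hEnd` encodes minus strand).
#' @param length Optional curated lengths; defaults to `abs(hEnd - hStart)`.
#' @return An [EveSet-class] object.
#' @examples
#' es <- EveSet("X1.1", "XAFV", 100L, 400L, "2", 5000L, 5300L)
#' hostRanges(es)
#' @export
EveSet <- function(identifier, virus, vStart, vEnd, chrom, hStart, hEnd,
                   length = NULL) {
  n <- base::length(identifier)
  identifier <- as.character(identifier)
  virus <- rep_len(as.character(virus), n)
  chrom <- rep_len(as.character(chrom), n)
  vStart <- as.integer(vStart); vEnd <- as.integer(vEnd)
  hStart <- as.numeric(hStart); hEnd <- as.numeric(hEnd)
  stopifnot(base::length(vStart) == n, base::length(vEnd) == n,
            base::length(hStart) == n, base::length(hEnd) == n)
  diffLen <- abs(hEnd - hStart)
  if (is.null(length)) {
    length <- diffLen
  } else {
    length <- as.numeric(length)
    bad <- which(length != diffLen)
    if (base::length(bad))
      warning(sprintf(
        "length differs from |hEnd - hStart| for %d record(s) (%s); keeping supplied values",
        base::length(bad),
        paste(utils::head(identifier[bad], 3L), collapse = ", ")))
  }
  strand <- ifelse(hStart <= hEnd, "+", "-")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = pmin(hStart, hEnd),
                              end = pmax(hStart, hEnd)),
    strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    identifier = identifier, virus = virus, vStart = vStart, vEnd = vEnd,
    hStart = hStart, hEnd = hEnd, evLength = length)
  names(gr) <- identifier
  methods::new("EveSet", granges = gr)
}

#' Accessors for EveSet objects
#'
#' `eveIds()` returns fragment identifiers; `hostRanges()` the host
#' footprints as a `GRanges`; `viralRanges()` the viral intervals as a
#' named `IRanges`; `virusNames()` the donor virus per fragment;
#' `eveLengths()` the curated lengths (host coordinate differences).
#'
#' @param x An [EveSet-class].
#' @name EveSet-accessors
NULL

#' @rdname EveSet-accessors
#' @export
setMethod("eveIds", "EveSet", function(x)
  S4Vectors::mcols(x@granges)$identifier)

#' @rdname EveSet-accessors
#' @export
setMethod("hostRanges", "EveSet", function(x) x@granges)

#' @rdname EveSet-accessors
#' @export
setMethod("viralRanges", "EveSet", function(x) {
  mc <- S4Vectors::mcols(x@granges)
  IRanges::IRanges(start = mc$vStart, end = mc$vEnd, names = mc$identifier)
})

#' @rdname EveSet-accessors
#' @export
setMethod("virusNames", "EveSet", function(x) {
  v <- S4Vectors::mcols(x@granges)$virus
  names(v) <- S4Vectors::mcols(x@granges)$identifier
  v
})

#' @rdname EveSet-accessors
#' @export
setMethod("eveLengths", "EveSet", function(x) {
  v <- S4Vectors::mcols(x@granges)$evLength
  names(v) <- S4Vectors::mcols(x@granges)$identifier
  v
})

#' @rdname EveSet-accessors
#' @export
setMethod("length", "EveSet", function(x) base::length(x@granges))

#' @rdname EveSet-accessors
#' @param i Index or identifier vector.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "EveSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    idx <- match(i, eveIds(x))
    if (anyNA(idx))
      stop("unknown identifier(s): ",
           paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  methods::initialize(x, granges = x@granges[i])
})

#' @rdname EveSet-accessors
#' @export
setMethod("as.data.frame", "EveSet", function(x, ...) {
  mc <- as.data.frame(S4Vectors::mcols(x@granges))
  data.frame(identifier = mc$identifier,
             virus = mc$virus,
             v_start = mc$vStart, v_end = mc$vEnd,
             chrom = as.character(GenomicRanges::seqnames(x@granges)),
             h_start = mc$hStart, h_end = mc$hEnd,
             length = mc$evLength,
             strand = as.character(BiocGenerics::strand(x@granges)),
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "EveSet", function(object) {
  n <- length(object)
  cat(sprintf("EveSet with %d fragment(s) on %d contig(s)\n", n,
              base::length(unique(as.character(
                GenomicRanges::seqnames(object@granges))))))
  if (n) {
    df <- as.data.frame(object)
    print(utils::head(df, 6L), row.names = FALSE)
    if (n > 6L) cat(sprintf("... and %d more\n", n - 6L))
  }
})

#' Accessors for IntegrationEvents objects
#'
#' `eventCount()` returns the number of events K; `eventMembership()` the
#' named integer vector mapping each identifier to its event;
#' `eventMembers()` a list of identifier vectors per event (host order);
#' `linkEvidence()` the pairwise link table supporting the partition.
#'
#' @param x An [IntegrationEvents-class].
#' @name IntegrationEvents-accessors
NULL

#' @rdname IntegrationEvents-accessors
#' @export
setMethod("eventCount", "IntegrationEvents", function(x)
  max(x@membership))

#' @rdname IntegrationEvents-accessors
#' @export
setMethod("eventMembership", "IntegrationEvents", function(x) x@membership)

#' @rdname IntegrationEvents-accessors
#' @export
setMethod("eventMembers", "IntegrationEvents", function(x) {
  ord <- order(as.character(GenomicRanges::seqnames(x@eves@granges)),
               GenomicRanges::start(x@eves@granges))
  ids <- eveIds(x@eves)[ord]
  ev <- x@membership[ids]
  split(ids, ev)
})

#' @rdname IntegrationEvents-accessors
#' @export
setMethod("linkEvidence", "IntegrationEvents", function(x) x@evidence)

#' @rdname IntegrationEvents-accessors
#' @export
setMethod("length", "IntegrationEvents", function(x) max(x@membership))

setMethod("show", "IntegrationEvents", function(object) {
  k <- eventCount(object)
  cat(sprintf("IntegrationEvents: %d event(s) over %d EVE fragment(s)\n",
              k, length(object@eves)))
  mem <- eventMembers(object)
  for (e in names(mem)) {
    ids <- mem[[e]]
    if (base::length(ids) > 4L)
      ids <- c(utils::head(ids, 2L), "...", utils::tail(ids, 1L))
    cat(sprintf("  event %s: %s (%d member(s))\n", e,
                paste(ids, collapse = ", "),
                base::length(mem[[e]])))
  }
})

#' Event assignments as a plain table
#'
#' @param x An [IntegrationEvents-class].
#' @return data.frame with columns `identifier`, `event_id`.
#' @export
eventTable <- function(x) {
  stopifnot(methods::is(x, "IntegrationEvents"))
  ord <- order(as.character(GenomicRanges::seqnames(x@eves@granges)),
               GenomicRanges::start(x@eves@granges))
  ids <- eveIds(x@eves)[ord]
  data.frame(identifier = ids, event_id = unname(x@membership[ids]),
             stringsAsFactors = FALSE)
}
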