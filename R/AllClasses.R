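#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' EveSet: a curated set of endogenous viral element fragments
#'
#' An `EveSet` stores one row per EVE fragment with dual coordinates: a host
#' footprint (a [GenomicRanges::GRanges] with strand implied by the printed
#' coordinate order of the source table) and a viral interval on the donor
#' virus genome. Host ranges are kept as 1-based inclusive `[min, max]`
#' intervals; the original printed coordinate order is preserved in the
#' `hStart`/`hEnd` metadata columns, where `hStart > hEnd` encodes the minus
#' strand. The `evLength` column keeps the curated length, by convention the
#' coordinate difference `|hEnd - hStart|` (not the inclusive span).
#'
#' @slot granges A `GRanges` of host footprints with metadata columns
#'   `identifier`, `virus`, `vStart`, `vEnd`, `hStart`, `hEnd`, `evLength`.
#'
#' @seealso [EveSet()], [readEveTable()], [inferEvents()]
#' @export
setClass("EveSet", slots = c(granges = "GRanges"))

setValidity("EveSet", function(object) {
  gr <- object@granges
  mc <- S4Vectors::mcols(gr)
  need <- c("identifier", "virus", "vStart", "vEnd", "hStart", "hEnd",
            "evLength")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(mc$identifier))
    return("identifiers must be unique")
  if (any(mc$vStart > mc$vEnd))
    return("vStart must be <= vEnd")
  if (any(mc$vStart < 1) || any(mc$hStart < 1) || any(mc$hEnd < 1))
    return("coordinates must be >= 1")
  if (!all(as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
    return("strand must be '+' or '-'")
  ok <- ifelse(mc$hStart <= mc$hEnd,
               as.character(BiocGenerics::strand(gr)) == "+",
               as.character(BiocGenerics::strand(gr)) == "-")
  if (!all(ok))
    return("strand inconsistent with hStart/hEnd order")
  TRUE
})

#' IntegrationEvents: a partition of EVE fragments into insertion events
#'
#' Produced by [identityCluster()] / [inferEvents()] and refined by
#' [mergeAdjacentEvents()]. Each EVE fragment of the underlying [EveSet]
#' belongs to exactly one event; events are numbered 1..K by the genomic
#' position (chromosome, then leftmost host coordinate) of their leftmost
#' member. The `evidence` slot records every pairwise link that supported
#' the partition, with its kind (`collinear`, `overlap_identity`,
#' `duplicate`, `cross_region_adjacency`) and score (gap discrepancy in
#' bases for collinear links, identity percent otherwise).
#'
#' @slot eves The clustered `EveSet`.
#' @slot membership Named integer vector: event id per identifier.
#' @slot evidence data.frame with columns `id_a`, `id_b`, `kind`, `score`.
#' @slot params List of the clustering parameters used.
#'
#' @export
setClass("IntegrationEvents",
         slots = c(eves = "EveSet", membership = "integer",
                   evidence = "data.frame", params = "list"))

setValidity("IntegrationEvents", function(object) {
  ids <- eveIds(object@eves)
  m <- object@membership
  if (length(m) != length(ids))
    return("membership length must equal number of EVE records")
  if (!identical(sort(names(m)), sort(ids)))
    return("membership names must match EVE identifiers")
  if (any(is.na(m)) || any(m < 1L))
    return("event ids must be positive integers")
  if (!setequal(unique(m), seq_len(max(m))))
    return("event ids must be consecutive 1..K")
  TRUE
})
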