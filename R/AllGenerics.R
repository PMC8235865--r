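#' @rdname EveSet-accessors
#' @export
setGeneric("eveIds", function(x) standardGeneric("eveIds"))

#' @rdname EveSet-accessors
#' @export
setGeneric("hostRanges", function(x) standardGeneric("hostRanges"))

#' @rdname EveSet-accessors
#' @export
setGeneric("viralRanges", function(x) standardGeneric("viralRanges"))

#' @rdname EveSet-accessors
#' @export
setGeneric("virusNames", function(x) standardGeneric("virusNames"))

#' @rdname EveSet-accessors
#' @export
setGeneric("eveLengths", function(x) standardGeneric("eveLengths"))

#' @rdname IntegrationEvents-accessors
#' @export
setGeneric("eventCount", function(x) standardGeneric("eventCount"))

#' @rdname IntegrationEvents-accessors
#' @export
setGeneric("eventMembership", function(x) standardGeneric("eventMembership"))

#' @rdname IntegrationEvents-accessors
#' @export
setGeneric("eventMembers", function(x) standardGeneric("eventMembers"))

#' @rdname IntegrationEvents-accessors
#' @export
setGeneric("linkEvidence", function(x) standardGeneric("linkEvidence"))

#' Single-linkage merging of hit or EVE footprints into genomic regions
#'
#' Merges host-genome intervals on the same contig into regions whenever the
#' gap between footprints does not exceed `mergeDist` (single linkage, as
#' done when collapsing alignment hits into candidate integration loci).
#' Returns a `GRanges` sorted by (chromosome, start) with metadata columns
#' `region_id`, `n_hits` and `n_accessions` (distinct viral accessions among
#' the members).
#'
#' @param x A hit `data.frame` from [readBlastTab()] or an [EveSet].
#' @param mergeDist Maximum gap in bases between footprints for two
#'   intervals to join one region (default 100000).
#' @return A `GRanges` of regions.
#' @examples
#' eves <- aegyptiEveTable()
#' buildRegions(eves)  # five regions on three chromosomes
#' @export
setGeneric("buildRegions", function(x, mergeDist = 1e5)
  standardGeneric("buildRegions"))
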