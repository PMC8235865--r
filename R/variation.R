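#' Per-region variant density with breadth masking
#'
#' Counts variants (SNPs plus InDels, unfiltered — deliberately no quality
#' filtering, so supply pre-filtered calls if a filter is wanted) inside
#' each region per sample and converts to density per kbp. Regions whose
#' 1x coverage breadth in a sample falls below `minBreadth1x` are masked:
#' low breadth deflates apparent density because variants cannot be called
#' on uncovered bases, so masked cells report `NA` density rather than a
#' biased value. Region length is the inclusive span `end - start + 1`,
#' which makes density additive under region splitting.
#'
#' @param variants data.frame from [readVariants()] (rows from several
#'   samples may be concatenated; the `sample_id` column assigns them).
#' @param depths Named list of depth data.frames; names are sample ids.
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), or an [EveSet-class] (footprints become
#'   regions named by identifier).
#' @param minBreadth1x Mask threshold on 1x breadth (default 0.85).
#' @return data.frame with one row per (region, sample): `region_id`,
#'   `sample_id`, `n_variants`, `length`, `breadth_1x`, `masked`,
#'   `density` (per kbp; `NA` when masked).
#' @export
snpDensity <- function(variants, depths, regions, minBreadth1x = 0.85) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  if (methods::is(regions, "EveSet")) {
    g <- .eveGeom(regions)
    regions <- data.frame(region_id = g$identifier, chrom = g$chrom,
                          start = g$hMin, end = g$hMax,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("region_id", "chrom", "start", "end") %in%
                  colnames(regions)))
  if (any(regions$end < regions$start))
    stop("region with end < start")
  if (any(regions$end - regions$start + 1 < 1))
    stop("region of length 0")
  out <- list()
  for (s in names(depths)) {
    vs <- variants[variants$sample_id == s, , drop = FALSE]
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      len <- rg$end - rg$start + 1
      n <- sum(vs$chrom == rg$chrom & vs$pos >= rg$start &
                 vs$pos <= rg$end)
      b1 <- .breadthAt(depths[[s]], rg$chrom, rg$start, rg$end, 1)
      masked <- b1 < minBreadth1x
      out[[length(out) + 1L]] <- data.frame(
        region_id = rg$region_id, sample_id = s, n_variants = n,
        length = len, breadth_1x = b1, masked = masked,
        density = if (masked) NA_real_ else n / len * 1000,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Density ratio to a baseline locus
#'
#' Divides each region's per-sample variant density by the density of a
#' baseline region (typically the mitochondrial cox1 gene) in the same
#' sample. Masked regions propagate as `NA`; a masked or zero-density
#' baseline is an error because the ratio is undefined.
#'
#' @param records Output of [snpDensity()].
#' @param baselineId `region_id` of the baseline region.
#' @return `records` without the baseline rows, with an added
#'   `density_ratio` column.
#' @export
densityRatio <- function(records, baselineId) {
  base <- records[records$region_id == baselineId, , drop = FALSE]
  if (!nrow(base)) stop("baseline region not found: ", baselineId)
  if (any(base$masked))
    stop("baseline region is masked in sample(s): ",
         paste(base$sample_id[base$masked], collapse = ", "))
  if (any(base$density == 0))
    stop("undefined ratio: baseline density 0 in sample(s): ",
         paste(base$sample_id[base$density == 0], collapse = ", "))
  bmap <- stats::setNames(base$density, base$sample_id)
  res <- records[records$region_id != baselineId, , drop = FALSE]
  res$density_ratio <- res$density / bmap[res$sample_id]
  rownames(res) <- NULL
  res
}
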