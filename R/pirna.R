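#' Windowed forward-strand ratio of piRNA-sized small-RNA alignments
#'
#' Tiles the queried interval with fixed windows and, counting only reads
#' whose length lies in `[minLen, maxLen]` nt (25-29 by default, the piRNA
#' size class) and assigning each read to the window containing its
#' 5'-most coordinate, reports per window the forward-read count, total
#' count and forward ratio (`NA` in empty windows).
#'
#' @param alignments data.frame from [readSmallRna()].
#' @param chrom Contig of the queried interval.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param window Window width in bp (default 500).
#' @param minLen,maxLen Read-length bounds in nt (defaults 25, 29).
#' @return data.frame with columns `contig`, `start`, `end`, `n_forward`,
#'   `n_total`, `ratio`.
#' @export
strandRatioTrack <- function(alignments, chrom, start, end, window = 500,
                             minLen = 25, maxLen = 29) {
  if (end < start) stop("inverted interval: end < start")
  stopifnot(window >= 1)
  a <- alignments[alignments$contig == chrom &
                    alignments$pos >= start & alignments$pos <= end &
                    alignments$read_length >= minLen &
                    alignments$read_length <= maxLen, , drop = FALSE]
  starts <- seq(start, end, by = window)
  ends <- pmin(starts + window - 1, end)
  idx <- findInterval(a$pos, starts)
  nFwd <- integer(length(starts)); nTot <- integer(length(starts))
  if (nrow(a)) {
    tTot <- table(factor(idx, levels = seq_along(starts)))
    tFwd <- table(factor(idx[a$strand == "+"],
                         levels = seq_along(starts)))
    nTot <- as.integer(tTot); nFwd <- as.integer(tFwd)
  }
  data.frame(contig = chrom, start = starts, end = ends,
             n_forward = nFwd, n_total = nTot,
             ratio = ifelse(nTot > 0, nFwd / nTot, NA_real_),
             stringsAsFactors = FALSE)
}

# aggregate genomic-forward ratio of a track
.trackRatio <- function(track) {
  tot <- sum(track$n_total)
  if (tot == 0) return(NA_real_)
  sum(track$n_forward) / tot
}

.dominanceLabel <- function(ratio, dominance) {
  if (is.na(ratio)) "indeterminate"
  else if (ratio >= dominance) "forward"
  else if (ratio <= 1 - dominance) "reverse"
  else "indeterminate"
}

#' Orientation-consistency verdict for two EVE blocks
#'
#' piRNAs from an EVE-containing cluster are expected to align antisense
#' to the EVEs they silence. For each block, the aggregate forward ratio
#' of its strand-ratio track is labeled forward-dominant (ratio at or
#' above `dominance`), reverse-dominant (at or below `1 - dominance`) or
#' indeterminate. The pair is `"consistent"` when both blocks' dominant
#' piRNA orientations are antisense to their respective EVE strands —
#' the pattern expected if the two blocks descend from one insertion —
#' `"indeterminate"` when either block lacks a dominant orientation, and
#' `"inconsistent"` otherwise.
#'
#' @param trackA,trackB Tracks from [strandRatioTrack()] over the two
#'   blocks.
#' @param eveStrandA,eveStrandB Genomic strand (`"+"`/`"-"`) of the EVEs
#'   in each block.
#' @param dominance Dominance threshold on the aggregate ratio (0.8).
#' @return list with `verdict` (`"consistent"`, `"inconsistent"` or
#'   `"indeterminate"`), `ratioA`, `ratioB`, `labelA`, `labelB`.
#' @export
orientationVerdict <- function(trackA, trackB, eveStrandA, eveStrandB,
                               dominance = 0.8) {
  stopifnot(nrow(trackA) > 0, nrow(trackB) > 0,
            eveStrandA %in% c("+", "-"), eveStrandB %in% c("+", "-"),
            dominance > 0.5, dominance <= 1)
  rA <- .trackRatio(trackA); rB <- .trackRatio(trackB)
  lA <- .dominanceLabel(rA, dominance)
  lB <- .dominanceLabel(rB, dominance)
  antiEve <- function(label, strand)
    (strand == "+" && label == "reverse") ||
    (strand == "-" && label == "forward")
  verdict <- if (lA == "indeterminate" || lB == "indeterminate")
    "indeterminate"
  else if (antiEve(lA, eveStrandA) && antiEve(lB, eveStrandB))
    "consistent"
  else "inconsistent"
  list(verdict = verdict, ratioA = rA, ratioB = rB,
       labelA = lA, labelB = lB)
}
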