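#' Organelle-breadth sample quality control
#'
#' Computes, per sample, the fraction of organelle-genome positions with
#' read depth of at least 1 and flags samples below `minBreadth`. Library
#' mix-ups and failed extractions show up as drastically reduced
#' mitochondrial breadth (e.g. 35% versus the >96% of sound libraries),
#' so a 0.90 cutoff separates the two groups with margin.
#'
#' @param depths Named list of depth data.frames (see [readDepthTable()]);
#'   names are sample ids.
#' @param organelleContig Name of the organelle contig.
#' @param organelleLength Length of the organelle genome in bp.
#' @param minBreadth Pass threshold on breadth (default 0.90).
#' @return data.frame with columns `sample_id`, `breadth_1x`, `pass`.
#' @export
sampleQc <- function(depths, organelleContig, organelleLength,
                     minBreadth = 0.90) {
  stopifnot(is.list(depths), !is.null(names(depths)),
            organelleLength >= 1)
  res <- lapply(names(depths), function(s) {
    d <- depths[[s]]
    d <- d[d$contig == organelleContig & d$depth >= 1, , drop = FALSE]
    if (!nrow(depths[[s]][depths[[s]]$contig == organelleContig, ,
                          drop = FALSE]) && nrow(depths[[s]]))
      stop("organelle contig '", organelleContig,
           "' absent from depth table of sample ", s)
    b <- length(unique(d$pos[d$pos >= 1 & d$pos <= organelleLength])) /
      organelleLength
    data.frame(sample_id = s, breadth_1x = b, pass = b >= minBreadth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# fraction of footprint positions with depth >= threshold
.breadthAt <- function(depth, chrom, start, end, threshold) {
  d <- depth[depth$contig == chrom & depth$pos >= start &
               depth$pos <= end & depth$depth >= threshold, ,
             drop = FALSE]
  length(unique(d$pos)) / (end - start + 1)
}

#' EVE-by-sample presence matrix from read depth
#'
#' For every EVE fragment and sample, the fraction of host-footprint
#' positions covered at or above `depthThreshold` (breadth). An EVE is
#' called present in a sample when its breadth reaches `presenceBreadth`
#' (default 0.99, tolerating edge effects at fragment boundaries). EVEs on
#' contigs absent from a sample's depth table get breadth 0 with a
#' warning. Apply [sampleQc()] first and pass only QC-passing samples.
#'
#' @param depths Named list of depth data.frames; names are sample ids.
#' @param eves An [EveSet-class].
#' @param depthThreshold Minimum read depth for a position to count
#'   (default 5).
#' @param presenceBreadth Minimum breadth calling an EVE present
#'   (default 0.99).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `breadth` (numeric in [0, 1]) and `present` (logical), rows = EVEs,
#'   columns = samples.
#' @export
presenceMatrix <- function(depths, eves, depthThreshold = 5,
                           presenceBreadth = 0.99) {
  stopifnot(is.list(depths), !is.null(names(depths)),
            methods::is(eves, "EveSet"))
  g <- .eveGeom(eves)
  samples <- names(depths)
  breadth <- matrix(0, nrow = nrow(g), ncol = length(samples),
                    dimnames = list(g$identifier, samples))
  for (s in samples) {
    d <- depths[[s]]
    missing <- setdiff(unique(g$chrom), unique(d$contig))
    if (length(missing))
      warning("sample ", s, ": contig(s) absent from depth table: ",
              paste(missing, collapse = ", "), "; breadth set to 0")
    for (i in seq_len(nrow(g)))
      breadth[i, s] <- if (g$chrom[i] %in% missing) 0 else
        .breadthAt(d, g$chrom[i], g$hMin[i], g$hMax[i], depthThreshold)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(breadth = breadth,
                  present = breadth >= presenceBreadth),
    rowData = S4Vectors::DataFrame(identifier = g$identifier,
                                   chrom = g$chrom, start = g$hMin,
                                   end = g$hMax),
    colData = S4Vectors::DataFrame(sample_id = samples,
                                   row.names = samples),
    metadata = list(depthThreshold = depthThreshold,
                    presenceBreadth = presenceBreadth))
}

.presentMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "present")
  else {
    stopifnot(is.matrix(x))
    if (is.numeric(x)) x >= 0.99 else x
  }
}

#' Cohort core-conservation summary
#'
#' Exact counts over the presence matrix: the fraction of samples in which
#' every EVE is present, the fraction missing all EVEs, and the number of
#' samples missing each EVE.
#'
#' @param x A presence [SummarizedExperiment::SummarizedExperiment] from
#'   [presenceMatrix()] or a logical/numeric matrix (rows = EVEs).
#' @return list with `fractionAllPresent`, `fractionMissingAll`,
#'   `perEveMissing` (named integer), `nSamples`.
#' @export
coreConservation <- function(x) {
  p <- .presentMatrix(x)
  stopifnot(ncol(p) >= 1, nrow(p) >= 1)
  list(fractionAllPresent = mean(colSums(p) == nrow(p)),
       fractionMissingAll = mean(colSums(p) == 0),
       perEveMissing = stats::setNames(as.integer(rowSums(!p)),
                                       rownames(p)),
       nSamples = ncol(p))
}

#' Mean pairwise Jaccard distance between sample presence vectors
#'
#' Quantifies cohort heterogeneity: 0 when every sample carries the same
#' EVE complement, approaching 1 for disjoint complements. Pairs of
#' all-absent samples have distance 0 by convention.
#'
#' @inheritParams coreConservation
#' @return Numeric scalar in [0, 1].
#' @export
heterogeneityScore <- function(x) {
  p <- .presentMatrix(x)
  n <- ncol(p)
  if (n < 2) stop("heterogeneity needs at least 2 samples")
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    a <- p[, i]; b <- p[, j]
    un <- sum(a | b)
    d <- if (un == 0) 0 else 1 - sum(a & b) / un
    tot <- tot + d; cnt <- cnt + 1L
  }
  tot / cnt
}

# ---- exact t-SNE (O(n^2)); suitable for the tens of rows embedded here --

.tsnePerplexityP <- function(D2, perplexity, tol = 1e-5, maxIter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (it in seq_len(maxIter)) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi == 0) sumPi <- .Machine$double.xmin
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P
}

.tsneExact <- function(X, perplexity, maxIter = 1000L, eta = 100,
                       exaggeration = 4, exagIter = 100L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsnePerplexityP(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (iter in seq_len(maxIter)) {
    Puse <- if (iter <= exagIter) Pe else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' 2-D embedding of coverage profiles
#'
#' Embeds the rows of a breadth matrix (EVEs by default; set
#' `margin = "column"` for samples) in two dimensions with an exact
#' t-distributed stochastic neighbor embedding, deterministic for a fixed
#' seed. When event labels are supplied, the mean silhouette width of the
#' labels in the embedding is reported — a number for the visual claim
#' that EVE coverage clusters by integration event.
#'
#' @param x A [SummarizedExperiment::SummarizedExperiment] from
#'   [presenceMatrix()] (the `breadth` assay is embedded) or a numeric
#'   matrix.
#' @param seed Random seed for the embedding initialization (default 0).
#' @param perplexity t-SNE perplexity; must be below the number of
#'   embedded rows (default 5).
#' @param labels Optional grouping labels (e.g. event ids per EVE) for the
#'   silhouette score.
#' @param margin `"row"` (default) or `"column"`.
#' @param maxIter Gradient-descent iterations (default 1000).
#' @return list with `coords` (matrix n x 2) and `silhouette` (mean
#'   silhouette width, or `NA` when labels are absent or degenerate).
#' @export
embedCoverage <- function(x, seed = 0, perplexity = 5, labels = NULL,
                          margin = c("row", "column"), maxIter = 1000L) {
  margin <- match.arg(margin)
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "breadth") else x
  stopifnot(is.matrix(m))
  if (margin == "column") m <- t(m)
  if (nrow(m) < 4) stop("need at least 4 rows to embed")
  # exactly identical rows are embedded as one point and share
  # coordinates: identical inputs must map to identical outputs, and
  # stochastic neighbor embeddings do not otherwise guarantee it
  key <- apply(m, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  if (perplexity >= nrow(m) || perplexity >= sum(uniq))
    stop("perplexity must be smaller than the number of embedded rows")
  Yu <- withr::with_seed(seed,
                         .tsneExact(m[uniq, , drop = FALSE], perplexity,
                                    maxIter = maxIter))
  Y <- Yu[match(key, key[uniq]), , drop = FALSE]
  rownames(Y) <- rownames(m)
  colnames(Y) <- c("x", "y")
  sil <- NA_real_
  if (!is.null(labels)) {
    lab <- as.integer(factor(labels))
    if (length(lab) != nrow(m))
      stop("labels length must match embedded rows")
    if (length(unique(lab)) >= 2 && length(unique(lab)) < nrow(m)) {
      sw <- cluster::silhouette(lab, stats::dist(Y))
      sil <- mean(sw[, "sil_width"])
    }
  }
  list(coords = Y, silhouette = sil)
}
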