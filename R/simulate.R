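#' Configuration for the integration/fragmentation simulator
#'
#' Describes the generative model used for end-to-end validation: a random
#' host genome at mosquito-like GC (0.38) receives `nEvents` insertions of
#' a contiguous full-length slice of a random flavivirus-like genome
#' (11 kbp, GC 0.49). Each insertion is then fragmented by internal
#' deletions whose host-side replacement length equals the viral-side
#' deletion length plus Gaussian jitter (`gapJitterSd`, default 50 nt,
#' consistent with the 12-243 nt discrepancies of curated gap pairs),
#' optionally duplicated to a nearby locus with extra divergence, and
#' decayed by random substitutions to `1 - decayDivergence` identity
#' (default 70%) against the extant virus. The cohort model draws
#' per-sample per-base depth from a negative binomial, drops EVEs per
#' sample with configurable probabilities, seeds variants at Poisson rates
#' per region, and emits piRNA-sized small-RNA reads with an anti-EVE
#' strand bias. Substitution-only decay keeps coordinate truth exact.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param hostLen,hostGc,hostContig Host genome length, GC, contig name.
#' @param virusLen,virusGc,virusAcc Virus genome length, GC, accession.
#' @param nEvents Number of true integration events K.
#' @param fragmentsPerEvent Fragments each insertion decays into.
#' @param deletionLenRange Viral-side deletion length range (bases).
#' @param gapJitterSd SD of the host-minus-viral gap difference (nt).
#' @param dupProb Per-event probability of one segmental duplication.
#' @param dupDistRange Distance range of the duplicate downstream of its
#'   source event footprint (bases; kept within one region).
#' @param dupDivergence Extra substitution divergence of the duplicate.
#' @param decayDivergence Global substitution divergence d of all
#'   viral-derived sequence.
#' @param minFragLen Minimum surviving fragment length emitted as a hit.
#' @param identityNoiseSd SD of the noise added to emitted hit identities.
#' @param nQueryViruses Number of related viral accessions emitting hits
#'   over each fragment (multi-virus support at true loci).
#' @param nDecoyHits Number of isolated decoy hits from unrelated viruses.
#' @param nSamples,dropout Cohort size and per-EVE dropout probability
#'   (scalar or vector recycled over fragments).
#' @param depthMean,depthSize Negative binomial depth (mean, size).
#' @param flankDepthFactor,flankLen Optional depth inflation of EVE flanks
#'   (factor 0 disables; transposon-rich flanks run 5-10x deeper).
#' @param organelleContig,organelleLen Organelle contig for sample QC.
#' @param cox1Start,cox1Len Baseline locus on the organelle contig.
#' @param variantRatePerKbp,baselineRatePerKbp Poisson variant rates.
#' @param smallRnaPerEvent Small-RNA reads emitted per event.
#' @param pirnaAntisenseProb Probability a read is antisense to its EVE.
#' @param nFailSamples Leading samples simulated as failed libraries
#'   (organelle breadth ~0.35).
#' @param preset `"aegypti"` (conserved cohort, dropout 0.02) or
#'   `"albopictus"` (heterogeneous cohort, dropout 0.45); overridden by an
#'   explicit `dropout`.
#' @return A classed list of validated parameters.
#' @export
simulationConfig <- function(seed = 1L,
                             hostLen = 2e6, hostGc = 0.38,
                             hostContig = "chrS1",
                             virusLen = 11000, virusGc = 0.49,
                             virusAcc = "VSIM_1",
                             nEvents = 3L, fragmentsPerEvent = 4L,
                             deletionLenRange = c(200, 1500),
                             gapJitterSd = 50,
                             dupProb = 0.25,
                             dupDistRange = c(5000, 30000),
                             dupDivergence = 0.005,
                             decayDivergence = 0.30,
                             minFragLen = 50,
                             identityNoiseSd = 0.5,
                             nQueryViruses = 2L,
                             nDecoyHits = 0L,
                             nSamples = 20L, dropout = NULL,
                             depthMean = 20, depthSize = 50,
                             flankDepthFactor = 0, flankLen = 500,
                             organelleContig = "MT", organelleLen = 15000,
                             cox1Start = 1000, cox1Len = 1500,
                             variantRatePerKbp = 1,
                             baselineRatePerKbp = 1,
                             smallRnaPerEvent = 2000,
                             pirnaAntisenseProb = 0.8,
                             nFailSamples = 0L,
                             preset = c("aegypti", "albopictus")) {
  preset <- match.arg(preset)
  if (is.null(dropout))
    dropout <- if (preset == "aegypti") 0.02 else 0.45
  stopifnot(hostLen >= 1000, virusLen >= 1000,
            hostGc > 0, hostGc < 1, virusGc > 0, virusGc < 1,
            nEvents >= 1, fragmentsPerEvent >= 1,
            length(deletionLenRange) == 2,
            deletionLenRange[1] >= 1,
            deletionLenRange[2] >= deletionLenRange[1],
            gapJitterSd >= 0, dupProb >= 0, dupProb <= 1,
            dupDivergence >= 0, dupDivergence <= 0.75,
            decayDivergence >= 0, decayDivergence <= 0.75,
            all(dropout >= 0), all(dropout <= 1),
            pirnaAntisenseProb >= 0, pirnaAntisenseProb <= 1,
            depthMean > 0, depthSize > 0, nSamples >= 1,
            nFailSamples >= 0, nFailSamples <= nSamples)
  if (fragmentsPerEvent > 1 &&
      virusLen / fragmentsPerEvent <= deletionLenRange[2] + 2 * minFragLen)
    stop("virusLen too short for fragmentsPerEvent at this deletion size")
  structure(as.list(environment()), class = "simulationConfig")
}

.baseProbs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                             G = gc / 2, T = (1 - gc) / 2)

.randSeq <- function(len, gc)
  sample(c("A", "C", "G", "T"), len, replace = TRUE,
         prob = .baseProbs(gc))

# substitute each base with probability d (always to a different base);
# returns list(seq, nsub)
.decaySeq <- function(seq, d) {
  if (d <= 0) return(list(seq = seq, nsub = 0L))
  hit <- which(stats::runif(length(seq)) < d)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(seq[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    seq[hit] <- repl
  }
  list(seq = seq, nsub = length(hit))
}

.revcompChars <- function(seq)
  rev(chartr("ACGT", "TGCA", seq))

#' Simulate host and virus genomes
#'
#' I.i.d. bases at the configured GC contents; reproducible from the seed.
#'
#' @param config A [simulationConfig()].
#' @return list with `host` and `virus`, each a named
#'   [Biostrings::DNAStringSet] of one sequence.
#' @export
simulateGenomes <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  withr::with_seed(config$seed, {
    host <- Biostrings::DNAStringSet(
      paste(.randSeq(config$hostLen, config$hostGc), collapse = ""))
    names(host) <- config$hostContig
    virus <- Biostrings::DNAStringSet(
      paste(.randSeq(config$virusLen, config$virusGc), collapse = ""))
    names(virus) <- config$virusAcc
    list(host = host, virus = virus)
  })
}

#' Simulate viral integration, fragmentation, duplication and decay
#'
#' Inserts `nEvents` full-length viral slices at well-separated host
#' sites (random orientation), fragments each by internal deletions whose
#' host-side filler length tracks the viral-side deletion length plus
#' jitter, optionally duplicates one fragment per event to a nearby locus
#' with extra divergence, and applies global substitution decay. The
#' returned truth table records every fragment's exact dual coordinates,
#' event id, duplicate-of pointer and realized divergence.
#'
#' @param host,virus Named `DNAStringSet`s from [simulateGenomes()].
#' @param config A [simulationConfig()].
#' @return list with `host` (modified genome, `DNAStringSet`) and `truth`
#'   (list with `fragments` data.frame — `identifier`, `event_id`,
#'   `virus`, `v_start`, `v_end`, `chrom`, `h_start`, `h_end`, `strand`,
#'   `duplicate_of`, `divergence` — and `events` data.frame).
#' @export
simulateIntegration <- function(host, virus,
                                config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  hostSeq <- strsplit(as.character(host[[1L]]), "")[[1L]]
  virusSeq <- strsplit(as.character(virus[[1L]]), "")[[1L]]
  hostLen <- length(hostSeq); virusLen <- length(virusSeq)
  K <- config$nEvents
  blockLen <- hostLen %/% K
  need <- virusLen + (config$fragmentsPerEvent - 1) *
    (config$deletionLenRange[2] + 4 * config$gapJitterSd) +
    config$dupDistRange[2] + virusLen
  if (blockLen * 5 / 12 < need)
    stop("hostLen too short to separate ", K, " events; need about ",
         ceiling(need * 12 / 5 * K), " bases")
  withr::with_seed(config$seed + 1L, {
    sites <- vapply(seq_len(K), function(k)
      (k - 1L) * blockLen +
        round(blockLen * (0.5 + stats::runif(1, -1 / 12, 1 / 12))),
      numeric(1))
    inserts <- list()   # site, seq (chars), frag offsets metadata
    fragRows <- list()
    evRows <- list()
    for (ev in seq_len(K)) {
      strand <- sample(c("+", "-"), 1L)
      nDel <- config$fragmentsPerEvent - 1L
      # deletion intervals centred on equispaced boundaries of the slice
      bnd <- round(seq_len(nDel) * virusLen / (nDel + 1L))
      delLen <- if (nDel) round(stats::runif(
        nDel, config$deletionLenRange[1], config$deletionLenRange[2]))
      else integer()
      delStart <- bnd - delLen %/% 2L
      delEnd <- delStart + delLen - 1L
      fragV <- cbind(start = c(1L, delEnd + 1L),
                     end = c(delStart - 1L, virusLen))
      fillerLen <- pmax(0L, round(delLen +
                                    stats::rnorm(nDel, 0,
                                                 config$gapJitterSd)))
      # build cassette in viral order
      pieces <- list(); meta <- list(); pos <- 1L
      for (f in seq_len(nrow(fragV))) {
        fs <- fragV[f, "start"]; fe <- fragV[f, "end"]
        dec <- .decaySeq(virusSeq[fs:fe], config$decayDivergence)
        pieces[[length(pieces) + 1L]] <- dec$seq
        meta[[length(meta) + 1L]] <- list(
          vS = fs, vE = fe, off = pos, len = fe - fs + 1L,
          div = dec$nsub / (fe - fs + 1L), seq = dec$seq)
        pos <- pos + (fe - fs + 1L)
        if (f <= nDel) {
          pieces[[length(pieces) + 1L]] <-
            .randSeq(fillerLen[f], config$hostGc)
          pos <- pos + fillerLen[f]
        }
      }
      cassette <- unlist(pieces)
      Lc <- length(cassette)
      if (strand == "-") cassette <- .revcompChars(cassette)
      inserts[[length(inserts) + 1L]] <- list(site = sites[ev],
                                              seq = cassette)
      insIdx <- length(inserts)
      for (f in seq_along(meta)) {
        m <- meta[[f]]
        offS <- if (strand == "+") m$off else Lc - (m$off + m$len - 1L) + 1L
        fragRows[[length(fragRows) + 1L]] <- data.frame(
          identifier = sprintf("E%dF%d", ev, f), event_id = ev,
          virus = config$virusAcc, v_start = m$vS, v_end = m$vE,
          chrom = config$hostContig,
          insert = insIdx, offMin = offS, offLen = m$len,
          strand = strand, duplicate_of = NA_character_,
          divergence = m$div, stringsAsFactors = FALSE)
      }
      # optional segmental duplication of one fragment, nearby
      if (stats::runif(1) < config$dupProb) {
        src <- sample(seq_along(meta), 1L)
        m <- meta[[src]]
        dup <- .decaySeq(m$seq, config$dupDivergence)
        dupStrand <- sample(c("+", "-"), 1L)
        dseq <- if (dupStrand == "+") dup$seq else .revcompChars(dup$seq)
        dupSite <- sites[ev] + round(stats::runif(
          1, config$dupDistRange[1], config$dupDistRange[2]))
        inserts[[length(inserts) + 1L]] <- list(site = dupSite,
                                                seq = dseq)
        fragRows[[length(fragRows) + 1L]] <- data.frame(
          identifier = sprintf("E%dD1", ev), event_id = ev,
          virus = config$virusAcc, v_start = m$vS, v_end = m$vE,
          chrom = config$hostContig,
          insert = length(inserts), offMin = 1L, offLen = m$len,
          strand = dupStrand,
          duplicate_of = sprintf("E%dF%d", ev, src),
          divergence = m$div + dup$nsub / m$len,
          stringsAsFactors = FALSE)
      }
      evRows[[length(evRows) + 1L]] <- data.frame(
        event_id = ev, strand = strand, site = sites[ev],
        stringsAsFactors = FALSE)
    }
    # assemble final host and convert insert offsets to host coordinates
    ord <- order(vapply(inserts, `[[`, numeric(1), "site"))
    segs <- list(); shift <- numeric(length(inserts)); prev <- 0L
    cum <- 0L
    for (k in ord) {
      s <- inserts[[k]]$site
      segs[[length(segs) + 1L]] <- hostSeq[(prev + 1L):s]
      shift[k] <- cum + s
      segs[[length(segs) + 1L]] <- inserts[[k]]$seq
      cum <- cum + length(inserts[[k]]$seq)
      prev <- s
    }
    segs[[length(segs) + 1L]] <- hostSeq[(prev + 1L):hostLen]
    finalHost <- unlist(segs)
    frag <- do.call(rbind, fragRows)
    rownames(frag) <- NULL
    hMin <- shift[frag$insert] + frag$offMin
    hMax <- hMin + frag$offLen - 1L
    frag$h_start <- ifelse(frag$strand == "+", hMin, hMax)
    frag$h_end <- ifelse(frag$strand == "+", hMax, hMin)
    frag$insert <- NULL; frag$offMin <- NULL; frag$offLen <- NULL
    modified <- Biostrings::DNAStringSet(paste(finalHost, collapse = ""))
    names(modified) <- config$hostContig
    list(host = modified,
         truth = list(fragments = frag,
                      events = do.call(rbind, evRows)))
  })
}

#' Emit a hit table from simulation truth
#'
#' One alignment hit per surviving fragment of at least `minFragLen`
#' bases, with exact coordinates from the truth and identity
#' `100 * (1 - divergence)` plus Gaussian noise, repeated for
#' `nQueryViruses` related viral accessions (independent hits from
#' related viruses over the same locus are what the support filter
#' retains). Optionally adds isolated decoy hits from unrelated
#' accessions to exercise the filter cascade.
#'
#' @param truth Truth list from [simulateIntegration()].
#' @param config A [simulationConfig()].
#' @return Hit data.frame in [readBlastTab()] layout.
#' @export
simulateHitTable <- function(truth, config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  frag <- truth$fragments
  frag <- frag[frag$v_end - frag$v_start + 1L >= config$minFragLen, ,
               drop = FALSE]
  withr::with_seed(config$seed + 2L, {
    rows <- list()
    for (q in seq_len(config$nQueryViruses)) {
      acc <- if (q == 1L) config$virusAcc else
        sprintf("%s_rel%d", config$virusAcc, q - 1L)
      for (i in seq_len(nrow(frag))) {
        f <- frag[i, ]
        len <- f$v_end - f$v_start + 1L
        pid <- min(100, max(50, 100 * (1 - f$divergence) +
                              stats::rnorm(1, 0, config$identityNoiseSd)))
        rows[[length(rows) + 1L]] <- data.frame(
          query_acc = acc, subject_id = f$chrom, identity_pct = pid,
          aln_len = len, mismatches = round(len * f$divergence),
          gap_opens = 0L, q_start = f$v_start, q_end = f$v_end,
          s_start = f$h_start, s_end = f$h_end, evalue = 1e-30,
          bitscore = 2 * len, stringsAsFactors = FALSE)
      }
    }
    if (config$nDecoyHits > 0) {
      occupied <- IRanges::IRanges(pmin(frag$h_start, frag$h_end) - 1000,
                                   pmax(frag$h_start, frag$h_end) + 1000)
      for (k in seq_len(config$nDecoyHits)) {
        repeat {
          len <- sample(100:800, 1L)
          s <- sample.int(config$hostLen - len, 1L)
          if (!any(IRanges::overlapsAny(
            IRanges::IRanges(s, s + len - 1L), occupied))) break
        }
        qs <- sample.int(5000, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          query_acc = sprintf("DECOY_%d", k), subject_id = frag$chrom[1L],
          identity_pct = stats::runif(1, 70, 90), aln_len = len,
          mismatches = round(len * 0.2), gap_opens = 0L,
          q_start = qs, q_end = qs + len - 1L,
          s_start = s, s_end = s + len - 1L,
          evalue = 10^stats::runif(1, -10, -4), bitscore = 1.5 * len,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$s_min <- pmin(df$s_start, df$s_end)
    df$s_max <- pmax(df$s_start, df$s_end)
    df$strand <- ifelse(df$s_start <= df$s_end, "+", "-")
    rownames(df) <- NULL
    df
  })
}

#' Simulate a sequencing cohort over the integrated genome
#'
#' Per sample: organelle depth for QC (failed libraries get ~35%
#' breadth), per-EVE presence by Bernoulli dropout with negative binomial
#' per-base depth when present (optionally inflated flanks), Poisson
#' variant counts per EVE and for the organelle baseline locus, and
#' piRNA-sized small-RNA reads with an anti-EVE strand bias per event.
#'
#' @param truth Truth list from [simulateIntegration()].
#' @param config A [simulationConfig()].
#' @return list with `depths` (named list of depth data.frames),
#'   `variants` (data.frame in [readVariants()] layout), `smallRna`
#'   (data.frame in [readSmallRna()] layout), `baselineRegion`
#'   (data.frame usable with [snpDensity()]) and `truth` (list with
#'   `presence` logical matrix fragments x samples and `dropout`).
#' @export
simulateCohort <- function(truth, config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  frag <- truth$fragments
  nF <- nrow(frag)
  dropout <- rep_len(config$dropout, nF)
  samples <- sprintf("S%02d", seq_len(config$nSamples))
  hMin <- pmin(frag$h_start, frag$h_end)
  hMax <- pmax(frag$h_start, frag$h_end)
  withr::with_seed(config$seed + 3L, {
    presence <- matrix(FALSE, nF, config$nSamples,
                       dimnames = list(frag$identifier, samples))
    depths <- list(); varRows <- list(); srRows <- list()
    for (si in seq_along(samples)) {
      s <- samples[si]
      rowsD <- list()
      # organelle
      orgPos <- seq_len(config$organelleLen)
      if (si <= config$nFailSamples)
        orgPos <- sort(sample(orgPos, round(0.35 * length(orgPos))))
      rowsD[[1L]] <- data.frame(
        contig = config$organelleContig, pos = orgPos,
        depth = stats::rnbinom(length(orgPos), size = config$depthSize,
                               mu = config$depthMean),
        stringsAsFactors = FALSE)
      for (f in seq_len(nF)) {
        here <- stats::runif(1) >= dropout[f]
        presence[f, si] <- here
        if (!here) next
        span <- hMin[f]:hMax[f]
        rowsD[[length(rowsD) + 1L]] <- data.frame(
          contig = frag$chrom[f], pos = span,
          depth = stats::rnbinom(length(span), size = config$depthSize,
                                 mu = config$depthMean),
          stringsAsFactors = FALSE)
        if (config$flankDepthFactor > 0) {
          fl <- c(max(1, hMin[f] - config$flankLen):(hMin[f] - 1L),
                  (hMax[f] + 1L):(hMax[f] + config$flankLen))
          rowsD[[length(rowsD) + 1L]] <- data.frame(
            contig = frag$chrom[f], pos = fl,
            depth = stats::rnbinom(length(fl), size = config$depthSize,
                                   mu = config$depthMean *
                                     config$flankDepthFactor),
            stringsAsFactors = FALSE)
        }
        # variants inside the present EVE
        spanLen <- length(span)
        nv <- stats::rpois(1, config$variantRatePerKbp * spanLen / 1000)
        nv <- min(nv, spanLen)
        if (nv > 0) {
          pos <- sort(sample(span, nv))
          ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
          indel <- stats::runif(nv) < 0.1
          alt <- vapply(seq_len(nv), function(k) {
            a <- sample(setdiff(c("A", "C", "G", "T"), ref[k]), 1L)
            if (indel[k]) paste0(ref[k], a) else a
          }, character(1))
          varRows[[length(varRows) + 1L]] <- data.frame(
            chrom = frag$chrom[f], pos = pos, ref = ref, alt = alt,
            type = ifelse(indel, "InDel", "SNP"), sample_id = s,
            stringsAsFactors = FALSE)
        }
      }
      # baseline locus variants
      nb <- stats::rpois(1, config$baselineRatePerKbp *
                           config$cox1Len / 1000)
      if (nb > 0) {
        pos <- sort(sample(config$cox1Start:(config$cox1Start +
                                               config$cox1Len - 1L), nb))
        ref <- sample(c("A", "C", "G", "T"), nb, replace = TRUE)
        alt <- vapply(ref, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        varRows[[length(varRows) + 1L]] <- data.frame(
          chrom = config$organelleContig, pos = pos, ref = ref,
          alt = alt, type = "SNP", sample_id = s,
          stringsAsFactors = FALSE)
      }
      d <- do.call(rbind, rowsD)
      d <- d[d$depth > 0, , drop = FALSE]
      rownames(d) <- NULL
      depths[[s]] <- d
    }
    # small RNA over each event footprint
    for (e in seq_len(nrow(truth$events))) {
      ids <- frag$event_id == truth$events$event_id[e]
      lo <- min(hMin[ids]); hi <- max(hMax[ids])
      n <- config$smallRnaPerEvent
      evStrand <- truth$events$strand[e]
      anti <- stats::runif(n) < config$pirnaAntisenseProb
      readStrand <- ifelse(anti,
                           ifelse(evStrand == "+", "-", "+"),
                           evStrand)
      inClass <- stats::runif(n) < 0.9
      len <- ifelse(inClass, sample(25:29, n, replace = TRUE),
                    sample(c(20:24, 30:33), n, replace = TRUE))
      srRows[[length(srRows) + 1L]] <- data.frame(
        contig = frag$chrom[which(ids)[1L]],
        pos = sample(lo:hi, n, replace = TRUE),
        strand = readStrand, read_length = len,
        stringsAsFactors = FALSE)
    }
    variants <- if (length(varRows)) do.call(rbind, varRows) else
      data.frame(chrom = character(), pos = numeric(),
                 ref = character(), alt = character(),
                 type = character(), sample_id = character(),
                 stringsAsFactors = FALSE)
    rownames(variants) <- NULL
    list(depths = depths, variants = variants,
         smallRna = do.call(rbind, srRows),
         baselineRegion = data.frame(
           region_id = "cox1", chrom = config$organelleContig,
           start = config$cox1Start,
           end = config$cox1Start + config$cox1Len - 1L,
           stringsAsFactors = FALSE),
         truth = list(presence = presence, dropout = dropout))
  })
}

#' EveSet view of simulation truth fragments
#'
#' @param truth Truth list from [simulateIntegration()].
#' @param minFragLen Drop fragments shorter than this (default 1).
#' @return An [EveSet-class] of the true fragments.
#' @export
truthEveSet <- function(truth, minFragLen = 1L) {
  f <- truth$fragments
  f <- f[f$v_end - f$v_start + 1L >= minFragLen, , drop = FALSE]
  EveSet(f$identifier, f$virus, f$v_start, f$v_end, f$chrom,
         f$h_start, f$h_end)
}

#' Write every simulated input to a directory
#'
#' Emits the modified host and virus FASTA, the hit table, per-sample
#' depth TSVs, a sites-only VCF per sample, the small-RNA TSV and the
#' truth as JSON, all in the formats the package readers accept.
#'
#' @param genomes Output of [simulateGenomes()] (or a list with `virus`).
#' @param integration Output of [simulateIntegration()].
#' @param hits Output of [simulateHitTable()].
#' @param cohort Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSimulation <- function(genomes, integration, hits, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(integration$host,
                              file.path(dir, "host_modified.fasta"))
  Biostrings::writeXStringSet(genomes$virus,
                              file.path(dir, "virus.fasta"))
  writeHitTable(hits, file.path(dir, "hits.tsv"))
  for (s in names(cohort$depths))
    writeDepthTable(cohort$depths[[s]],
                    file.path(dir, sprintf("depth_%s.tsv", s)))
  for (s in unique(cohort$variants$sample_id))
    writeVcfMinimal(cohort$variants[cohort$variants$sample_id == s, ],
                    file.path(dir, sprintf("variants_%s.vcf", s)))
  writeSmallRna(cohort$smallRna, file.path(dir, "small_rna.tsv"))
  jsonlite::write_json(
    list(fragments = integration$truth$fragments,
         events = integration$truth$events,
         presence = as.data.frame(cohort$truth$presence)),
    file.path(dir, "truth.json"), dataframe = "columns", na = "null")
  invisible(dir)
}
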