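# shared fixtures built in code

# curated worked-example table bundled with the package
table2 <- aegyptiEveTable()

# small simulator configuration used where full-scale genomes are not the
# point of the test (generator defaults keep the study-scale values)
smallSimConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, hostLen = 6e5, virusLen = 4000,
                   nEvents = 2L, fragmentsPerEvent = 2L,
                   nSamples = 8L, organelleLen = 2000,
                   cox1Start = 100, cox1Len = 1500)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

# random dual-coordinate record set for partition-oracle tests
randomEveSet <- function(n, seed) {
  withr::with_seed(seed, {
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    vs <- sample.int(8000, n)
    ve <- vs + sample.int(1200, n)
    hs <- sample.int(50000, n)
    he <- hs + (ve - vs) + sample(-200:200, n, replace = TRUE)
    he <- pmax(he, hs + 1)
    minus <- runif(n) < 0.4
    EveSet(sprintf("r%02d", seq_len(n)), "V", vs, ve, chrom,
           ifelse(minus, he, hs), ifelse(minus, hs, he))
  })
}

# brute-force single-linkage region labels (independent of buildRegions)
regionLabelsOracle <- function(df, mergeDist) {
  hMin <- pmin(df$h_start, df$h_end); hMax <- pmax(df$h_start, df$h_end)
  lab <- integer(nrow(df)); nxt <- 0L
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    o <- idx[order(hMin[idx])]
    cur <- nxt + 1L
    lab[o[1L]] <- cur
    reach <- hMax[o[1L]]
    for (k in seq_along(o)[-1L]) {
      if (hMin[o[k]] - reach - 1 > mergeDist) cur <- cur + 1L
      lab[o[k]] <- cur
      reach <- max(reach, hMax[o[k]])
    }
    nxt <- cur
  }
  lab
}

# the pairwise link predicate of the event clustering (coordinate mode),
# evaluated pair by pair, independently of the package's union-find
linkMatrixOracle <- function(es, config, regionMergeDist = 1e5) {
  df <- as.data.frame(es)
  n <- nrow(df)
  hMin <- pmin(df$h_start, df$h_end)
  reg <- regionLabelsOracle(df, regionMergeDist)
  L <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || reg[i] != reg[j]) next
    ovl <- min(df$v_end[i], df$v_end[j]) -
      max(df$v_start[i], df$v_start[j]) + 1
    if (ovl > config$minOverlap) { L[i, j] <- TRUE; next }
    # collinear links apply to host-adjacent pairs within the region
    idx <- which(reg == reg[i])
    o <- idx[order(hMin[idx], df$identifier[idx])]
    if (abs(match(i, o) - match(j, o)) != 1) next
    if (df$strand[i] != df$strand[j]) next
    gp <- computeGap(es, df$identifier[i], df$identifier[j])
    gv <- gp[["viral"]]; gh <- gp[["host"]]
    if (gv > 0 && gv <= config$maxChainGap && gh >= 0 &&
        gh <= config$maxChainGap &&
        abs(gv - gh) <= max(config$gapTolAbs,
                            config$gapTolRel * max(gv, gh)))
      L[i, j] <- TRUE
  }
  L | t(L)
}

# transitive closure over an arbitrary link matrix
componentsOracle <- function(linked) {
  n <- nrow(linked)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && linked[i, j] && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# partition equality up to relabeling
samePartition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
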