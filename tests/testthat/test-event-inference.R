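test_that("gap pairs reproduce the curated table's printed distances", {
  expect_equal(computeGap(table2, "AE2.2", "AE3.2"),
               c(viral = 359, host = 260))
  expect_equal(computeGap(table2, "AE3.2", "AE4.2"),
               c(viral = 193, host = 172))
  expect_equal(computeGap(table2, "AE5.2", "AE6.2"),
               c(viral = 407, host = 395))
  # minus-strand pairs report the printed non-negative distances
  expect_equal(computeGap(table2, "AE18.3", "AE19.3"),
               c(viral = 295, host = 481))
  expect_equal(computeGap(table2, "AE20.3", "AE21.3"),
               c(viral = 574, host = 545))
  # argument order does not matter; host position does
  expect_equal(computeGap(table2, "AE19.3", "AE18.3"),
               c(viral = 295, host = 481))
  expect_error(computeGap(table2, "AE1.1", "AE2.2"), "contig")
  expect_error(computeGap(table2, "AE1.1", "nope"), "unknown")
})

test_that("collinear chaining links sequentially spaced fragments of shared orientation", {
  ch <- chainCollinear(table2)
  lens <- vapply(ch$chains, length, integer(1))
  # the plus-strand run of six and two minus-strand runs of four
  expect_true(list(c("AE2.2", "AE3.2", "AE4.2", "AE5.2", "AE6.2",
                     "AE7.2")) %in% ch$chains)
  expect_true(list(c("AE18.3", "AE19.3", "AE20.3", "AE21.3")) %in%
                ch$chains)
  expect_true(list(c("AE22.3", "AE23.3", "AE24.3", "AE25.3")) %in%
                ch$chains)
  # every collinear link satisfies the configured tolerance exactly
  cfg <- chainConfig()
  for (r in seq_len(nrow(ch$evidence))) {
    gp <- computeGap(table2, ch$evidence$id_a[r], ch$evidence$id_b[r])
    expect_lte(abs(gp[["viral"]] - gp[["host"]]),
               max(cfg$gapTolAbs, cfg$gapTolRel * max(gp)))
  }
  # a wildly discrepant gap pair does not link
  es <- EveSet(c("a", "b"), "V", c(100L, 300L), c(200L, 4400L), "c1",
               c(1000, 5300), c(1100, 9400))
  ch2 <- chainCollinear(es)
  expect_equal(length(ch2$chains), 2L)
})

test_that("clustering on coordinates alone yields the five-event partition", {
  ev <- identityCluster(table2)
  expect_equal(eventCount(ev), 5L)
  mem <- eventMembers(ev)
  expect_equal(mem[["1"]], "AE1.1")
  expect_equal(mem[["2"]], paste0("AE", 2:15, ".2"))
  expect_equal(mem[["3"]], c("AE16.2", "AE17.2"))
  expect_equal(mem[["4"]], paste0("AE", 18:25, ".3"))
  expect_equal(mem[["5"]], paste0("AE", 26:29, ".4"))

  # determinism under input permutation
  perm <- withr::with_seed(2, sample(length(table2)))
  evP <- identityCluster(table2[perm])
  expect_true(samePartition(
    eventMembership(ev)[eveIds(table2)],
    eventMembership(evP)[eveIds(table2)]))

  # viral overlap at or below the threshold does not merge
  es <- EveSet(c("a", "b"), "V", c(100L, 360L), c(400L, 700L), "c1",
               c(1000, 9000), c(1300, 9340))
  expect_equal(eventCount(identityCluster(es)), 2L)  # overlap 41 <= 50

  # a partition at every stage: each record in exactly one event
  expect_equal(sort(names(eventMembership(ev))), sort(eveIds(table2)))
})

test_that("identity-table mode gates overlap merges on the identity threshold", {
  es <- EveSet(c("a", "b"), "V", c(100L, 150L), c(400L, 450L), "c1",
               c(1000, 9000), c(1300, 9300))
  idLow <- data.frame(id_a = "a", id_b = "b", identity_pct = 90)
  idHigh <- data.frame(id_a = "a", id_b = "b", identity_pct = 96)
  expect_equal(eventCount(identityCluster(es, identity = idLow)), 2L)
  expect_equal(eventCount(identityCluster(es, identity = idHigh)), 1L)
  bad <- data.frame(id_a = "a", id_b = "zz", identity_pct = 96)
  expect_error(identityCluster(es, identity = bad), "unknown")
})

test_that("event partition equals the brute-force transitive closure on small inputs", {
  for (seed in 1:12) {
    n <- 4L + (seed %% 5L)
    es <- randomEveSet(n, seed)
    cfg <- withr::with_seed(seed * 101L, chainConfig(
      gapTolAbs = sample(c(100, 300, 600), 1),
      gapTolRel = sample(c(0.2, 0.5), 1),
      maxChainGap = sample(c(2000, 5000), 1),
      minOverlap = sample(c(20, 50, 120), 1)))
    ev <- identityCluster(es, config = cfg, regionMergeDist = 5000)
    want <- componentsOracle(linkMatrixOracle(es, cfg, 5000))
    expect_true(samePartition(
      unname(eventMembership(ev)[eveIds(es)]), want),
      label = sprintf("partition oracle, seed %d", seed))
  }
})

test_that("adjacency merging is gated on orientation evidence", {
  ev <- identityCluster(table2)
  # both chromosome-2 events confirmed antisense-biased: five become four
  m <- mergeAdjacentEvents(ev, orientation = c("2" = "consistent",
                                               "3" = "consistent"))
  expect_equal(eventCount(m), 4L)
  mem <- eventMembers(m)
  expect_equal(mem[["2"]], paste0("AE", 2:17, ".2"))
  # inconsistent or missing evidence blocks the merge
  m2 <- mergeAdjacentEvents(ev, orientation = c("2" = "consistent",
                                                "3" = "inconsistent"))
  expect_equal(eventCount(m2), 5L)
  expect_equal(eventCount(mergeAdjacentEvents(ev)), 5L)
  # unevidenced merging can be allowed explicitly
  m3 <- mergeAdjacentEvents(ev, config = chainConfig(
    allowUnevidencedMerge = TRUE))
  expect_equal(eventCount(m3), 4L)
  # distant viral spans never merge
  m4 <- mergeAdjacentEvents(ev, orientation = c(
    "1" = "consistent", "2" = "consistent", "3" = "consistent",
    "4" = "consistent", "5" = "consistent"),
    config = chainConfig(adjacencyTol = 30))
  expect_equal(eventCount(m4), 5L)  # the 31-nt gap exceeds tol 30
  # merging only coarsens the partition: each original event lands
  # wholly inside one merged event
  for (ids in eventMembers(ev))
    expect_equal(length(unique(eventMembership(m)[ids])), 1L)
})

test_that("pairwise local-alignment identity matches count-forced cases", {
  s <- withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 100,
                                        TRUE), collapse = ""))
  self <- pairwiseIdentity(s, s)
  expect_equal(self$identity, 100)
  expect_equal(self$overlap, 100)
  expect_equal(self$coverageA, 100)
  v <- strsplit(s, "")[[1]]
  pos <- c(10, 25, 40, 55, 70, 85)
  v[pos] <- vapply(v[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  expect_equal(pairwiseIdentity(s, paste(v, collapse = ""))$identity, 94)
  expect_error(pairwiseIdentity("", s), "empty")
})

test_that("alignment identity tracks simulated divergence", {
  bases <- c("A", "C", "G", "T")
  for (d in c(0.05, 0.1, 0.2)) {
    ids <- vapply(1:5, function(k) {
      withr::with_seed(1000L * k + round(100 * d), {
        a <- sample(bases, 200, TRUE)
        b <- a
        hit <- which(runif(200) < d)
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(bases, x), 1), character(1))
        pairwiseIdentity(paste(a, collapse = ""),
                         paste(b, collapse = ""))$identity
      })
    }, numeric(1))
    expect_lt(abs(mean(ids) - 100 * (1 - d)), 2)
  }
})

test_that("duplicate flagging requires identity and full mutual coverage", {
  es <- EveSet(c("a", "b", "c"), "V", c(100L, 100L, 100L),
               c(299L, 299L, 299L), "c1",
               c(1000, 20000, 40000), c(1199, 20199, 40199))
  expect_error(flagDuplicates(es, NULL), "identity required")
  tab <- data.frame(id_a = c("a", "a"), id_b = c("b", "c"),
                    identity_pct = c(99.5, 95), overlap_len = c(199, 199))
  fl <- flagDuplicates(es, tab)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$id_a, "a"); expect_equal(fl$id_b, "b")

  # sequence mode: identical pair flagged, 2-substitution 200-mer at 99%
  s <- withr::with_seed(4, sample(c("A", "C", "G", "T"), 200, TRUE))
  s2 <- s; s2[c(50, 150)] <- vapply(s2[c(50, 150)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  s3 <- withr::with_seed(5, sample(c("A", "C", "G", "T"), 200, TRUE))
  seqs <- Biostrings::DNAStringSet(c(a = paste(s, collapse = ""),
                                     b = paste(s2, collapse = ""),
                                     c = paste(s3, collapse = "")))
  es2 <- EveSet(c("a", "b", "c"), "V", c(100L, 100L, 100L),
                c(299L, 299L, 299L), "c1",
                c(1000, 20000, 40000), c(1200, 20200, 40200))
  fl2 <- flagDuplicates(es2, seqs)
  expect_equal(paste(fl2$id_a, fl2$id_b), "a b")
  expect_gte(min(fl2$identity_pct), 99)
})

test_that("simulated duplications are flagged and clustered with their source event", {
  cfg <- smallSimConfig(seed = 21, dupProb = 1)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  frag <- sim$truth$fragments
  expect_true(any(!is.na(frag$duplicate_of)))
  es <- truthEveSet(sim$truth)
  ev <- inferEvents(es)
  expect_true(samePartition(unname(eventMembership(ev)[frag$identifier]),
                            frag$event_id))
  # the duplicate's sequence, extracted from the modified host, is
  # near-identical and full-coverage against its source
  hostSeq <- sim$host[[1]]
  getSeq <- function(id) {
    r <- frag[frag$identifier == id, ]
    s <- Biostrings::subseq(hostSeq, min(r$h_start, r$h_end),
                            max(r$h_start, r$h_end))
    if (r$h_start > r$h_end) s <- Biostrings::reverseComplement(s)
    s
  }
  dup <- frag$identifier[!is.na(frag$duplicate_of)][1]
  src <- frag$duplicate_of[frag$identifier == dup]
  pw <- pairwiseIdentity(getSeq(src), getSeq(dup))
  expect_gte(pw$identity, 99)
  expect_gte(round(pw$coverageA), 99)
})
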