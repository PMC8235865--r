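test_that("genome simulation honours GC content and the seed", {
  cfg <- simulationConfig(seed = 2, hostLen = 10000, hostGc = 0.5,
                          virusLen = 10000, virusGc = 0.5)
  g <- simulateGenomes(cfg)
  gc <- function(s) {
    f <- Biostrings::alphabetFrequency(s[[1]])[c("C", "G")]
    sum(f) / length(s[[1]])
  }
  expect_lt(abs(gc(g$host) - 0.5), 0.02)
  expect_identical(as.character(simulateGenomes(cfg)$host),
                   as.character(g$host))
  # mosquito-like vs flavivirus-like GC separates clearly
  diffs <- vapply(1:20, function(seed) {
    cc <- simulationConfig(seed = seed, hostLen = 10000,
                           virusLen = 10000)
    gg <- simulateGenomes(cc)
    gc(gg$virus) - gc(gg$host)
  }, numeric(1))
  expect_true(all(diffs > 0.05))
  expect_error(simulationConfig(hostGc = 1.2), "hostGc")
})

test_that("a clean single insertion embeds the exact viral slice", {
  cfg <- simulationConfig(seed = 4, hostLen = 2e5, virusLen = 3000,
                          nEvents = 1L, fragmentsPerEvent = 1L,
                          decayDivergence = 0, dupProb = 0)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  frag <- sim$truth$fragments
  expect_equal(nrow(frag), 1L)
  expect_equal(frag$v_start, 1L)
  expect_equal(frag$v_end, 3000L)
  expect_equal(length(sim$host[[1]]), 2e5 + 3000)
  emb <- Biostrings::subseq(sim$host[[1]],
                            min(frag$h_start, frag$h_end),
                            max(frag$h_start, frag$h_end))
  if (frag$strand == "-") emb <- Biostrings::reverseComplement(emb)
  expect_identical(as.character(emb), as.character(g$virus[[1]]))
})

test_that("truth bookkeeping is a valid genealogy with near-equal gap pairs", {
  cfg <- simulationConfig(seed = 10, hostLen = 1.2e6, nEvents = 3L,
                          fragmentsPerEvent = 4L, dupProb = 0)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  frag <- sim$truth$fragments
  expect_equal(sort(unique(frag$event_id)), 1:3)
  expect_equal(nrow(frag), 12L)
  # realized divergence close to the configured decay
  expect_lt(abs(mean(frag$divergence) - 0.30), 0.02)
  # within an event, adjacent gap pairs differ by the jitter only
  es <- truthEveSet(sim$truth)
  discrepancies <- unlist(lapply(split(frag, frag$event_id), function(fr) {
    fr <- fr[order(pmin(fr$h_start, fr$h_end)), ]
    vapply(seq_len(nrow(fr) - 1L), function(k) {
      gp <- computeGap(es, fr$identifier[k], fr$identifier[k + 1L])
      abs(gp[["viral"]] - gp[["host"]])
    }, numeric(1))
  }))
  # folded-normal with sd 50: mean |jitter| is ~40, far below 120
  expect_lte(mean(discrepancies), 120)
  expect_true(all(discrepancies <= 300))
})

test_that("hit emission respects truth coordinates, decay identity and the length floor", {
  cfg <- simulationConfig(seed = 12, hostLen = 1e6, nEvents = 2L,
                          decayDivergence = 0, identityNoiseSd = 0,
                          dupProb = 0)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  hits <- simulateHitTable(sim$truth, cfg)
  expect_true(all(hits$identity_pct == 100))
  expect_true(all(hits$aln_len >= cfg$minFragLen))
  own <- hits[hits$query_acc == cfg$virusAcc, ]
  frag <- sim$truth$fragments
  expect_equal(own$q_start, frag$v_start)
  expect_equal(own$s_start, frag$h_start)
  expect_equal(own$s_end, frag$h_end)
  # decayed run: emitted identity tracks 100 * (1 - divergence)
  cfg2 <- simulationConfig(seed = 12, hostLen = 1e6, nEvents = 2L,
                           identityNoiseSd = 0, dupProb = 0)
  sim2 <- simulateIntegration(g$host, g$virus, cfg2)
  hits2 <- simulateHitTable(sim2$truth, cfg2)
  expect_lt(abs(mean(hits2$identity_pct) - 70), 2)
})

test_that("a zero-dropout cohort is fully present and seed-reproducible", {
  cfg <- smallSimConfig(seed = 14, dropout = 0)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  co <- simulateCohort(sim$truth, cfg)
  es <- truthEveSet(sim$truth)
  pm <- presenceMatrix(co$depths, es)
  expect_true(all(SummarizedExperiment::assay(pm, "present")))
  co2 <- simulateCohort(sim$truth, cfg)
  expect_identical(co, co2)
})

test_that("simulation outputs written to disk survive the readers", {
  cfg <- smallSimConfig(seed = 15, nSamples = 2L, nDecoyHits = 2L)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  hits <- simulateHitTable(sim$truth, cfg)
  co <- simulateCohort(sim$truth, cfg)
  dir <- withr::local_tempdir()
  writeSimulation(g, sim, hits, co, dir)
  expect_true(file.exists(file.path(dir, "host_modified.fasta")))
  d <- readDepthTable(file.path(dir, "depth_S01.tsv"), "S01")
  expect_equal(nrow(d), nrow(co$depths$S01))
  v <- readVariants(file.path(dir, "variants_S01.vcf"), "S01")
  expect_equal(nrow(v),
               sum(co$variants$sample_id == "S01"))
  sr <- readSmallRna(file.path(dir, "small_rna.tsv"))
  expect_equal(nrow(sr), nrow(co$smallRna))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$fragments$identifier,
               sim$truth$fragments$identifier)
})

test_that("the clean emission is invertible: one inferred event per insertion", {
  cfg <- simulationConfig(seed = 16, hostLen = 1.5e6, nEvents = 4L,
                          fragmentsPerEvent = 1L, decayDivergence = 0,
                          dupProb = 0, identityNoiseSd = 0)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  hits <- simulateHitTable(sim$truth, cfg)
  ev <- inferEvents(evesFromHits(filterHits(hits)$hits))
  expect_equal(eventCount(ev), 4L)
})

test_that("pipeline wrapper writes results and a faithful manifest", {
  dir <- withr::local_tempdir()
  res <- runEvePipeline(table2, dir,
                        orientation = c("2" = "consistent",
                                        "3" = "consistent"))
  expect_equal(eventCount(res$events), 4L)
  expect_true(all(file.exists(res$files)))
  man <- jsonlite::read_json(res$files[["manifest"]])
  expect_equal(man$n_events, 4L)
  expect_equal(man$n_records, 29L)
  ev <- utils::read.delim(res$files[["events"]])
  expect_equal(nrow(ev), 29L)
  expect_equal(length(unique(ev$event_id)), 4L)
})
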