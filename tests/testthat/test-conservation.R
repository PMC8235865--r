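mkDepth <- function(contig, pos, depth)
  data.frame(contig = rep_len(contig, length(pos)), pos = pos,
             depth = rep_len(depth, length(pos)),
             stringsAsFactors = FALSE)

test_that("sample QC separates failed from sound libraries by organelle breadth", {
  orgLen <- 1000L
  dGood <- mkDepth("MT", 1:970, 8)
  dBad <- mkDepth("MT", 1:350, 8)
  dEmpty <- mkDepth("MT", integer(), numeric())
  qc <- sampleQc(list(good = dGood, bad = dBad, empty = dEmpty),
                 "MT", orgLen)
  expect_equal(qc$breadth_1x, c(0.97, 0.35, 0))
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE))
  dNoMt <- mkDepth("c1", 1:100, 5)
  expect_error(sampleQc(list(s = dNoMt), "MT", orgLen), "absent")
})

test_that("presence matrix is breadth at the depth threshold", {
  es <- EveSet(c("e1", "e2"), "V", c(1L, 1L), c(100L, 100L), "c1",
               c(101, 301), c(200, 400))
  dA <- mkDepth("c1", 101:400, 10)
  dB <- mkDepth("c1", 101:400, 4)
  suppressWarnings(pm <- presenceMatrix(list(A = dA, B = dB), es))
  b <- SummarizedExperiment::assay(pm, "breadth")
  expect_equal(unname(b[, "A"]), c(1, 1))
  expect_equal(unname(b[, "B"]), c(0, 0))  # depth 4 below threshold 5
  expect_equal(unname(SummarizedExperiment::assay(pm, "present")[, "A"]),
               c(TRUE, TRUE))
  # missing contig: breadth 0 with a warning
  dC <- mkDepth("c9", 1:10, 10)
  expect_warning(pmC <- presenceMatrix(list(C = dC), es), "absent")
  expect_equal(unname(SummarizedExperiment::assay(pmC, "breadth")[, 1]),
               c(0, 0))
})

test_that("presence is monotone non-increasing in the depth threshold", {
  cfg <- smallSimConfig(seed = 8, dropout = 0.3)
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  co <- simulateCohort(sim$truth, cfg)
  es <- truthEveSet(sim$truth)
  b1 <- SummarizedExperiment::assay(suppressWarnings(
    presenceMatrix(co$depths, es, depthThreshold = 1)), "breadth")
  b5 <- SummarizedExperiment::assay(suppressWarnings(
    presenceMatrix(co$depths, es, depthThreshold = 5)), "breadth")
  b30 <- SummarizedExperiment::assay(suppressWarnings(
    presenceMatrix(co$depths, es, depthThreshold = 30)), "breadth")
  expect_true(all(b5 <= b1))
  expect_true(all(b30 <= b5))
})

test_that("programmed dropout is recovered within its binomial interval", {
  cfg <- smallSimConfig(seed = 13, nSamples = 40L,
                        dropout = c(0.2, 0, 0, 0))
  g <- simulateGenomes(cfg)
  sim <- simulateIntegration(g$host, g$virus, cfg)
  co <- simulateCohort(sim$truth, cfg)
  es <- truthEveSet(sim$truth)
  pm <- presenceMatrix(co$depths, es)
  p <- SummarizedExperiment::assay(pm, "present")
  rate <- mean(p[1, ])
  ci <- stats::binom.test(sum(p[1, ]), ncol(p), 0.8)$conf.int
  expect_true(rate >= ci[1] - 1e-9 && rate <= ci[2] + 1e-9)
  expect_true(0.8 >= ci[1] && 0.8 <= ci[2])
  # presence matches the simulator's own bookkeeping
  expect_equal(unname(p), unname(co$truth$presence))
})

test_that("core conservation counts are exact and brute-force checkable", {
  m <- matrix(TRUE, nrow = 10, ncol = 8,
              dimnames = list(paste0("e", 1:10), paste0("s", 1:8)))
  expect_equal(coreConservation(m)$fractionAllPresent, 1)
  m[3, 2] <- FALSE
  cc <- coreConservation(m)
  expect_equal(cc$fractionAllPresent, 7 / 8)
  expect_equal(unname(cc$perEveMissing), c(0, 0, 1, rep(0, 7)))
  m[, 5] <- FALSE
  cc2 <- coreConservation(m)
  expect_equal(cc2$fractionMissingAll, 1 / 8)
  # brute force re-count
  expect_equal(cc2$fractionAllPresent,
               sum(apply(m, 2, all)) / ncol(m))
})

test_that("heterogeneity is the mean pairwise Jaccard distance", {
  ident <- matrix(c(TRUE, FALSE), 2, 4)
  expect_equal(heterogeneityScore(ident), 0)
  compl <- cbind(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(heterogeneityScore(compl), 1)
  expect_error(heterogeneityScore(matrix(TRUE, 2, 1)), "2 samples")
  m <- withr::with_seed(3, matrix(runif(40) > 0.5, 5, 8))
  expect_equal(heterogeneityScore(m),
               heterogeneityScore(m[, withr::with_seed(4, sample(8))]))
})

test_that("conserved cohorts score as more core-conserved and less heterogeneous than patchy ones", {
  hets <- vapply(1:20, function(seed) {
    cfgA <- smallSimConfig(seed = seed, preset = "aegypti")
    cfgB <- smallSimConfig(seed = seed, preset = "albopictus")
    g <- simulateGenomes(cfgA)
    sim <- simulateIntegration(g$host, g$virus, cfgA)
    es <- truthEveSet(sim$truth)
    coA <- simulateCohort(sim$truth, cfgA)
    coB <- simulateCohort(sim$truth, cfgB)
    pmA <- suppressWarnings(presenceMatrix(coA$depths, es))
    pmB <- suppressWarnings(presenceMatrix(coB$depths, es))
    c(aeg = heterogeneityScore(pmA), alb = heterogeneityScore(pmB),
      coreA = coreConservation(pmA)$fractionAllPresent,
      coreB = coreConservation(pmB)$fractionAllPresent)
  }, numeric(4))
  expect_true(all(hets["alb", ] > hets["aeg", ]))
  expect_true(all(hets["coreA", ] >= hets["coreB", ]))
})

test_that("coverage embedding is seeded-deterministic and separates orthogonal blocks", {
  m <- withr::with_seed(6, {
    blocks <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0, 0, 0), 6), 6,
                           byrow = TRUE),
                    matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), 6), 6,
                           byrow = TRUE))
    blocks + matrix(rnorm(96, 0, 0.03), 12, 8)
  })
  lab <- rep(1:2, each = 6)
  e1 <- embedCoverage(m, seed = 0, perplexity = 3, labels = lab)
  e2 <- embedCoverage(m, seed = 0, perplexity = 3, labels = lab)
  expect_identical(e1$coords, e2$coords)
  expect_gt(e1$silhouette, 0.5)
  # duplicate rows land nearly coincident
  md <- rbind(m, m[1, ])
  ed <- embedCoverage(md, seed = 1, perplexity = 3)
  span <- max(stats::dist(ed$coords))
  expect_lt(stats::dist(ed$coords[c(1, 13), ])[1], 0.01 * span)
  expect_error(embedCoverage(m, perplexity = 12), "perplexity")
  expect_error(embedCoverage(m[1:3, ]), "4 rows")
})
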