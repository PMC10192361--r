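test_that("bedGraph intervals expand half-open to per-base scores", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr2L\t100\t103\t1.5", "chr2L\t103\t104\t-0.25"), f)
  tr <- readScores(f)
  pb <- promdiv:::.trackPerBase(tr)
  expect_identical(pb$pos, c(100L, 101L, 102L, 103L))
  expect_equal(pb$score, c(1.5, 1.5, 1.5, -0.25))
  expect_error(readScores(tempfile(fileext = ".bedgraph")), "not found")
})

test_that("fixed-step wiggle reads to consecutive positions", {
  f <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr3R start=11 step=1",
               "0.1", "0.2", "0.3"), f)
  pb <- promdiv:::.trackPerBase(readScores(f))
  expect_identical(pb$pos, c(10L, 11L, 12L))     # 0-based
  expect_equal(pb$score, c(0.1, 0.2, 0.3))
})

test_that("score tracks round-trip through bedGraph", {
  se <- simulateConservationTracks(6, promoterDrop = 0.3, seed = 61,
                                   group = "g")
  pt <- profilesToTrack(se)
  f <- tempfile(fileext = ".bedgraph")
  writeScores(pt$track, f)
  se2 <- anchorScoresToTSS(readScores(f), pt$annotations)
  expect_equal(unname(SummarizedExperiment::assay(se2, "score")),
               unname(SummarizedExperiment::assay(se, "score")),
               tolerance = 1e-9)
})

test_that("strand handling mirrors coordinates around the TSS", {
  # hand-checked toy track: scores 1..10 at positions 0..9 on one contig
  tr <- GenomicRanges::GRanges("c", IRanges::IRanges(1:10, width = 1),
                               score = as.numeric(1:10))
  ann <- data.frame(gene_id = c("plus", "minus"), contig = "c",
                    tss = c(3, 6), strand = c("+", "-"), group = "g")
  se <- anchorScoresToTSS(tr, ann, window = c(-3L, 4L))
  m <- SummarizedExperiment::assay(se, "score")
  # + strand at tss=3: offsets -3..3 -> genome 0..6 -> scores 1..7
  expect_equal(unname(m[, "plus"]), as.numeric(1:7))
  # - strand at tss=6: offset o -> genome 6-o -> positions 9..3
  expect_equal(unname(m[, "minus"]), as.numeric(10:4))
  # mirroring a + strand gene onto - strand of the reversed track
  # reproduces the same vector
  revTr <- GenomicRanges::GRanges("c", IRanges::IRanges(1:10, width = 1),
                                  score = as.numeric(10:1))
  annM <- data.frame(gene_id = "mirr", contig = "c", tss = 6,
                     strand = "-", group = "g")
  seM <- anchorScoresToTSS(revTr, annM, window = c(-3L, 4L))
  expect_equal(unname(SummarizedExperiment::assay(seM, "score")[, 1]),
               unname(m[, "plus"]))
})

test_that("genes with holes in the window are omitted", {
  tr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1:5, 7:12),
                                                     width = 1),
                               score = 1)
  ann <- data.frame(gene_id = c("holed", "ok"), contig = "c",
                    tss = c(4, 9), strand = "+", group = "g")
  expect_message(se <- anchorScoresToTSS(tr, ann, window = c(-2L, 3L)),
                 "omitting holed")
  expect_identical(colnames(se), "ok")
})

test_that("group mean profiles equal brute-force column means", {
  se1 <- simulateConservationTracks(1, seed = 62, group = "solo")
  p1 <- groupMeanProfile(se1)
  expect_equal(unname(p1[, "solo"]),
               unname(SummarizedExperiment::assay(se1, "score")[, 1]))
  seA <- simulateConservationTracks(4, seed = 63, group = "a")
  seB <- simulateConservationTracks(3, seed = 64, group = "b")
  se <- combineProfiles(seA, seB)
  p <- groupMeanProfile(se)
  expect_equal(unname(p[, "b"]),
               unname(rowMeans(SummarizedExperiment::assay(seB, "score"))))
})

test_that("promoter t test separates a depressed cohort", {
  seA <- simulateConservationTracks(200, promoterDrop = 0.5,
                                    noiseSd = 0.1, seed = 65,
                                    group = "nup")
  seB <- simulateConservationTracks(200, promoterDrop = 0,
                                    noiseSd = 0.1, seed = 66,
                                    group = "genome")
  se <- combineProfiles(seA, seB)
  tt <- promoterMeanTTest(se, "nup", "genome")
  expect_lte(tt$pValue, 1e-4)
  expect_lt(tt$meanA, tt$meanB)
  # identical cohorts: p well away from significance
  seSame <- combineProfiles(
    simulateConservationTracks(50, seed = 67, group = "x"),
    simulateConservationTracks(50, seed = 68, group = "y"))
  expect_gt(promoterMeanTTest(seSame, "x", "y")$pValue, 0.01)
  expect_error(promoterMeanTTest(
    combineProfiles(simulateConservationTracks(1, seed = 1, group = "u"),
                    simulateConservationTracks(5, seed = 2, group = "v")),
    "u", "v"), ">= 2 genes")
})

test_that("dP counts strictly-below scores and contrasts proportions", {
  r <- dPStatistic(c(0.1, 0.2, 0.9, 1.1), controlScores = c(0, 1),
                   pC = 0.5)
  expect_identical(r$nBelow, 2L)
  expect_equal(r$dP, 50)
  expect_equal(dPStatistic(c(0.6, 0.7), c(0, 1), pC = 0.5)$dP, 0)
  # observed proportion equal to control: chi2 = 0, p = 1
  same <- dPStatistic(c(0, 1), c(0, 1), pC = 0.5)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # raising every score weakly decreases dP
  set.seed(69)
  sc <- rnorm(300, 1, 0.2)
  ctl <- rnorm(300, 1, 0.2)
  expect_lte(dPStatistic(sc + 0.1, ctl)$dP, dPStatistic(sc, ctl)$dP)
})

test_that("a depressed promoter window shows in the mean profile", {
  drop <- 0.5
  noise <- 0.1
  n <- 100
  se <- combineProfiles(
    simulateConservationTracks(n, promoterDrop = drop, noiseSd = noise,
                               seed = 70, group = "nup"),
    simulateConservationTracks(n, promoterDrop = 0, noiseSd = noise,
                               seed = 71, group = "genome"))
  p <- groupMeanProfile(se)
  offs <- as.integer(rownames(p))
  inWin <- offs >= -380 & offs < -30
  gap <- mean(p[inWin, "genome"]) - mean(p[inWin, "nup"])
  expect_gt(gap, 3 * noise / sqrt(n * sum(inWin)))
  outGap <- mean(p[!inWin, "genome"]) - mean(p[!inWin, "nup"])
  expect_lt(abs(outGap), 0.02)
})
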