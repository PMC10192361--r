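anchoredProfile <- function(channelVec, tssColumn = 1000L,
                            channel = "all") {
  # build a gap-free EventVector carrying the given channel in all slots
  v <- as.integer(channelVec)
  L <- length(v)
  ev <- new("EventVector", geneId = "toy", allChanges = v, indels = v,
            baseChanges = v, refCoord = seq_len(L) - 1L,
            tssOffset = integer(0))
  slidingEventScore(anchorToTSS(ev, tssColumn), channel = channel)
}

test_that("sliding event scores match the direct convolution oracle", {
  expect_true(all(seScores(slidingEventScore(rep(0L, 100))) == 0))
  # single interior event spreads over exactly the 11-position window
  v <- integer(200)
  v[101] <- 1L                       # 0-based position 100
  p <- slidingEventScore(v)
  expect_identical(which(seScores(p) == 1) - 1L, 95:105)
  set.seed(3)
  for (h in c(0L, 2L, 5L)) {
    x <- sample(0:1, 300, replace = TRUE, prob = c(.9, .1))
    expect_equal(seScores(slidingEventScore(x, halfWindow = h)),
                 oracleSlidingSum(x, h))
  }
  expect_error(slidingEventScore(integer(0)), "empty")
})

test_that("Se is computed on the reference grid when insertions add columns", {
  sim <- simulatePromoterAlignment(seed = 21, seqLength = 1000,
                                   indelRate = 4)
  ev <- anchorToTSSByRef(eventVector(sim$alignment), 500L)
  p <- slidingEventScore(ev, channel = "indel")
  expect_identical(sePositions(p), seq.int(-500L, 499L))
  expect_true(all(seScores(p) <= 11))
})

test_that("promoterWindow returns exactly the 350 TATA-distal values", {
  v <- integer(2000)
  p <- anchoredProfile(v)
  expect_length(promoterWindow(p), 350L)
  # brute-force slice agreement on a random profile
  set.seed(8)
  v2 <- sample(0:1, 2000, TRUE)
  p2 <- anchoredProfile(v2)
  grid <- sePositions(p2)
  expect_identical(promoterWindow(p2),
                   seScores(p2)[grid >= -380 & grid < -30])
  # short profile cannot cover the window
  shortP <- anchoredProfile(integer(300), tssColumn = 100L)
  expect_error(promoterWindow(shortP), "coverage")
})

test_that("controlThreshold is the flat mean over pooled window values", {
  z <- anchoredProfile(integer(2000))
  expect_identical(controlThreshold(list(z, z)), 0)
  set.seed(9)
  ps <- lapply(1:4, function(i)
    anchoredProfile(sample(0:1, 2000, TRUE)))
  expect_equal(controlThreshold(ps),
               mean(unlist(lapply(ps, promoterWindow))))
  expect_error(controlThreshold(list()), "control")
})

test_that("the d statistic counts strictly-above values", {
  r <- dStatistic(c(0, 0, 1, 2, 3, 0, 0, 0, 6, 7), 2)
  expect_identical(r$nAbove, 3L)
  expect_identical(r$N, 10L)
  expect_equal(r$d, 30)
  expect_equal(dStatistic(c(0, 1, 2), 5)$d, 0)
  expect_equal(dStatistic(c(6, 7, 8), 5)$d, 100)
  expect_error(dStatistic(numeric(0), 1), "N = 0")
})

test_that("d equals the brute-force strict count on random instances", {
  set.seed(12)
  for (i in 1:200) {
    vals <- sample(0:11, sample(10:400, 1), replace = TRUE)
    thr <- runif(1, 0, 11)
    r <- dStatistic(vals, thr)
    cnt <- 0L
    for (v in vals) if (v > thr) cnt <- cnt + 1L
    expect_identical(r$nAbove, cnt)
    expect_equal(r$d, 100 * cnt / length(vals))
  }
})

test_that("d depends only on the value multiset and is monotone", {
  set.seed(13)
  vals <- sample(0:11, 100, TRUE)
  thr <- 2.5
  expect_equal(dStatistic(sample(vals), thr)$d, dStatistic(vals, thr)$d)
  bumped <- vals
  bumped[7] <- bumped[7] + 5
  expect_gte(dStatistic(bumped, thr)$d, dStatistic(vals, thr)$d)
})

test_that("chi-squared contrast matches the textbook 2-cell formula", {
  r <- chiSquaredVsControl(60, 100, 40)
  expect_equal(r$chi2, 400 / 40 + 400 / 60, tolerance = 1e-12)
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
  expect_equal(r$p, 4.45e-5, tolerance = 2e-3)
  # observed proportion equal to control: chi2 = 0, p = 1
  r0 <- chiSquaredVsControl(40, 100, 40)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  # Bonferroni arithmetic and capping
  expect_equal(chiSquaredVsControl(60, 100, 40, 4)$pAdj,
               min(1, 4 * chiSquaredVsControl(60, 100, 40)$p))
  expect_error(chiSquaredVsControl(10, 100, 0), "degenerate")
  expect_error(chiSquaredVsControl(10, 100, 100), "degenerate")
  set.seed(14)
  for (i in 1:100) {
    N <- sample(10:500, 1)
    k <- sample(0:N, 1)
    cd <- runif(1, 1, 99)
    e1 <- N * cd / 100
    expect_equal(chiSquaredVsControl(k, N, cd)$chi2,
                 (k - e1)^2 / e1 + ((N - k) - (N - e1))^2 / (N - e1))
  }
})

test_that("heatmap rows are per-position group means", {
  set.seed(15)
  p0 <- anchoredProfile(integer(2000))
  p2 <- anchoredProfile(rep(1L, 2000))       # Se = 11 in the interior
  hm <- heatmapMatrix(list(p0, p2), c("a", "b"), window = c(-500, 500))
  expect_identical(rownames(hm), c("a", "b"))
  expect_true(all(hm["a", ] == 0))
  hm2 <- heatmapMatrix(list(p0, p2), c("g", "g"), window = c(-500, 500))
  expect_equal(unname(hm2["g", ]), unname((seScores(p0) + seScores(p2))[
    sePositions(p0) >= -500 & sePositions(p0) < 500] / 2))
  rnd <- lapply(1:6, function(i) anchoredProfile(sample(0:1, 2000, TRUE)))
  grp <- c("x", "x", "y", "y", "y", "x")
  hm3 <- heatmapMatrix(rnd, grp, window = c(-100, 100))
  grid <- -100:99
  for (g in c("x", "y")) {
    man <- rowMeans(vapply(rnd[grp == g], function(p)
      seScores(p)[match(grid, sePositions(p))], numeric(200)))
    expect_equal(unname(hm3[g, ]), man)
  }
})

test_that("regionStats contrasts groups against the control pool", {
  set.seed(16)
  mk <- function(rate) anchoredProfile(rbinom(2000, 1, rate))
  profiles <- c(lapply(1:5, function(i) mk(0.02)),
                lapply(1:5, function(i) mk(0.10)))
  groups <- rep(c("control", "hot"), each = 5)
  rs <- regionStats(profiles, groups, "control")
  expect_identical(rs$group, c("control", "hot"))
  expect_true(rs$d[2] > rs$d[1])
  expect_true(rs$p[2] < 0.05)
  expect_true(is.na(rs$p[1]))
  # per-gene averaging reports the mean of gene-level d values while the
  # chi-squared counts stay pooled
  rsG <- regionStats(profiles, groups, "control", perGene = TRUE)
  expect_equal(rsG$nAbove, rs$nAbove)
  seC <- attr(rs, "seC")
  manual <- mean(vapply(profiles[groups == "hot"], function(p)
    dStatistic(promoterWindow(p), seC)$d, numeric(1)))
  expect_equal(rsG$d[rsG$group == "hot"], manual)
})

test_that("a 3x indel-rate group shows higher d(indel) than control", {
  hits <- 0L
  nSeeds <- 30L
  for (s in seq_len(nSeeds)) {
    profs <- list()
    groups <- character(0)
    idx <- 0L
    for (grp in c("control", "hot")) {
      rate <- if (grp == "hot") 3 else 1
      for (g in 1:20) {
        idx <- idx + 1L
        sim <- simulatePromoterAlignment(
          seqLength = 2000, subProb = 0, indelRate = rate,
          seed = s * 1000L + idx)
        ev <- anchorToTSSByRef(eventVector(sim$alignment), 1000L)
        profs[[idx]] <- slidingEventScore(ev, channel = "indel")
        groups <- c(groups, grp)
      }
    }
    rs <- regionStats(profs, groups, "control")
    if (rs$d[rs$group == "hot"] > rs$d[rs$group == "control"])
      hits <- hits + 1L
  }
  expect_gte(hits / nSeeds, 0.95)
})
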