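toyAln <- function(seqs, reference = names(seqs)[1])
  PromoterAlignment(seqs, reference)

test_that("readAlignment validates shape, reference and alphabet", {
  f <- writeToyFasta(c(a = "ACGTACGT", b = "AC-TACGT", c = "ACGTACGA"),
                     tempfile(fileext = ".fasta"))
  aln <- readAlignment(f, "a")
  expect_s4_class(aln, "PromoterAlignment")
  expect_identical(alnLength(aln), 8L)
  expect_identical(speciesNames(aln), c("a", "b", "c"))

  bad <- writeToyFasta(c(a = "ACGTACGTAA", b = "ACGTACGTA"),
                       tempfile(fileext = ".fasta"))
  expect_error(readAlignment(bad, "a"), "alignment-shape")
  expect_error(readAlignment(f, "zz"), "reference")
  iupac <- writeToyFasta(c(a = "ACGR", b = "ACGT"),
                         tempfile(fileext = ".fasta"))
  expect_error(readAlignment(iupac, "a"), "alphabet")
})

test_that("lower-case input is normalised and two identical records align", {
  aln <- toyAln(c(x = "acgt", y = "ACGT"))
  expect_identical(as.character(aln@seqs[["x"]]), "ACGT")
  expect_identical(alnLength(aln), 4L)
  expect_true(all(callBaseChangeEvents(aln) == 0L))
})

test_that("base-change calling follows the reference-comparison rule", {
  aln <- toyAln(c(ref = "AAAA", s1 = "AAAA", s2 = "AAAA"))
  expect_identical(callBaseChangeEvents(aln), rep(0L, 4))
  aln2 <- toyAln(c(ref = "AAAA", s1 = "AGAA", s2 = "AAAA"))
  expect_identical(callBaseChangeEvents(aln2), c(0L, 1L, 0L, 0L))
  # a gap or N never creates a base-change event
  aln3 <- toyAln(c(ref = "AAAA", s1 = "A-AN", s2 = "AAAA"))
  expect_identical(callBaseChangeEvents(aln3), rep(0L, 4))
})

test_that("base-change channel equals the brute-force column classifier", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    L <- sample(30:60, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                   prob = c(.3, .3, .15, .15, .05, .05)), collapse = ""),
      character(1))
    names(seqs) <- paste0("s", seq_len(n))
    aln <- toyAln(seqs)
    expect_identical(callBaseChangeEvents(aln),
                     oracleBaseChanges(seqs, "s1"))
  }
})

test_that("indel events register once at each gap run's 5' column", {
  aln <- toyAln(c(ref = "ACGTACGTACGTACGT", s1 = "ACGTACGTAC-----T"))
  expect_identical(which(callIndelEvents(aln) == 1L) - 1L, 10L)
  # gap-free alignment: all-zero channel
  expect_true(all(callIndelEvents(
    toyAln(c(a = "ACGT", b = "AGGT"))) == 0L))
  # coincident starts in two species collapse to a single 1
  aln2 <- toyAln(c(ref = "AAAAAAAAAA", s1 = "AAA---AAAA",
                   s2 = "AAA----AAA"))
  expect_identical(which(callIndelEvents(aln2) == 1L) - 1L, 3L)
  # a run touching column 0 registers at column 0
  aln3 <- toyAln(c(ref = "AAAA", s1 = "--AA"))
  expect_identical(which(callIndelEvents(aln3) == 1L) - 1L, 0L)
})

test_that("indel channel equals the gap-run start enumeration oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    L <- sample(30:60, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "-"), L, replace = TRUE,
                   prob = c(.5, .3, .2)), collapse = ""), character(1))
    names(seqs) <- paste0("s", seq_len(n))
    starts <- sort(unique(oracleGapRuns(seqs)$start))
    expect_identical(which(callIndelEvents(toyAln(seqs)) == 1L) - 1L,
                     starts)
  }
})

test_that("combineChannels is position-wise OR and checks lengths", {
  expect_identical(combineChannels(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L)),
                   c(0L, 1L, 1L, 1L))
  set.seed(7)
  a <- sample(0:1, 1000, TRUE)
  b <- sample(0:1, 1000, TRUE)
  expect_identical(combineChannels(a, b), as.integer(a | b))
  expect_error(combineChannels(c(0L), c(0L, 1L)), "mismatch")
})

test_that("TSS anchoring yields signed reference-coordinate offsets", {
  L <- 2000L
  s <- simulatePromoterAlignment(subProb = 0, indelRate = 0, seed = 1,
                                 seqLength = L)
  ev <- anchorToTSS(eventVector(s$alignment), tssColumn = 1000L)
  expect_identical(tssOffset(ev), seq.int(-1000L, L - 1001L))
  ev0 <- anchorToTSS(eventVector(s$alignment), tssColumn = 0L)
  expect_identical(tssOffset(ev0)[1], 0L)
  expect_error(anchorToTSS(eventVector(s$alignment), tssColumn = L),
               "out of range")
  # minus strand flips the sign
  evm <- anchorToTSS(eventVector(s$alignment), 1000L, strand = "-")
  expect_identical(tssOffset(evm), -tssOffset(ev))
})

test_that("reference-gap columns share the preceding reference position", {
  aln <- toyAln(c(ref = "AC-----GTAC", s1 = "ACTTTTTGTAC"))
  ev <- eventVector(aln)
  # hand-walked map: A=0 C=1, five gap columns stay at 1, then 2,3,4,5
  expect_identical(refCoord(ev),
                   c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L))
  an <- anchorToTSS(ev, tssColumn = 8L)  # TSS at reference base 3
  expect_identical(tssOffset(an),
                   c(-3L, -2L, -2L, -2L, -2L, -2L, -2L, -1L, 0L, 1L, 2L))
})

test_that("event recovery on synthetic alignments is exact", {
  for (s in 1:25) {
    sim <- simulatePromoterAlignment(seed = s, seqLength = 1000,
                                     indelRate = 3, subProb = 0.03)
    ev <- eventVector(sim$alignment)
    expect_identical(eventPositions(ev, "indel"),
                     as.integer(sim$truth$indelStartColumns))
    expect_identical(eventPositions(ev, "base"),
                     as.integer(sim$truth$baseChangeColumns))
    expect_identical(eventChannel(ev, "all"),
                     combineChannels(eventChannel(ev, "base"),
                                     eventChannel(ev, "indel")))
  }
})

test_that("column reversal mirrors the event structure", {
  set.seed(17)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "-"), 50, replace = TRUE,
                 prob = c(.4, .3, .2, .1)), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:4)
  rev1 <- vapply(strsplit(seqs, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  names(rev1) <- names(seqs)
  fwd <- toyAln(seqs)
  bwd <- toyAln(rev1)
  L <- 50L
  # base changes are per-column, so the channel mirrors exactly
  expect_identical(callBaseChangeEvents(bwd),
                   rev(callBaseChangeEvents(fwd)))
  # indel events sit at run 5' starts: reversal maps run ends to starts
  runs <- oracleGapRuns(seqs)
  expect_identical(which(callIndelEvents(bwd) == 1L) - 1L,
                   sort(unique(L - 1L - runs$end)))
})
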