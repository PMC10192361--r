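# Independent brute-force oracles used across the suite.  Each re-derives a
# quantity from first principles, without touching the implementation path
# it checks.

# character matrix of an alignment given as named character vector
oracleCharMatrix <- function(seqs) {
  do.call(rbind, strsplit(setNames(toupper(seqs), names(seqs)), "",
                          fixed = TRUE))
}

# per-column base-change classifier: literal restatement of the rule
oracleBaseChanges <- function(seqs, reference) {
  m <- oracleCharMatrix(seqs)
  ref <- m[reference, ]
  others <- m[setdiff(rownames(m), reference), , drop = FALSE]
  vapply(seq_len(ncol(m)), function(i) {
    if (ref[i] %in% c("-", "N")) return(0L)
    hit <- FALSE
    for (s in seq_len(nrow(others))) {
      ch <- others[s, i]
      if (!(ch %in% c("-", "N")) && ch != ref[i]) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

# enumerate every maximal gap run of every record: (row, start, end) 0-based
oracleGapRuns <- function(seqs) {
  m <- oracleCharMatrix(seqs)
  out <- list()
  for (s in rownames(m)) {
    r <- rle(m[s, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      out[[length(out) + 1L]] <- data.frame(
        row = s, start = starts[k] - 1L, end = ends[k] - 1L)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(row = character(0), start = integer(0), end = integer(0))
}

# direct convolution window sum
oracleSlidingSum <- function(v, h) {
  n <- length(v)
  vapply(seq_len(n), function(i)
    sum(v[max(1, i - h):min(n, i + h)]), numeric(1))
}

# naive global G statistic: max over 0 <= j <= k <= n of G_k - G_j, G_0 = 0
oracleGStat <- function(sites, L) {
  n <- length(sites)
  g0 <- c(0, seq_len(n) / n - sites / L)
  best <- -Inf
  for (j in seq_along(g0))
    for (k in j:length(g0))
      best <- max(best, g0[k] - g0[j])
  best
}

# exact null by full enumeration with the naive statistic
oracleExactNull <- function(n, L) {
  apply(combn(L, n), 2L, oracleGStat, L = L)
}

# two-sided Fisher exact p by hypergeometric tail enumeration
# (sum of point probabilities <= observed, with the 1e-7 relative tolerance
# conventional for exact tests on ties)
oracleFisherP <- function(Pn, Ps, Dn, Ds) {
  m1 <- Pn + Ps
  m2 <- Dn + Ds
  n1 <- Pn + Dn
  if (m1 == 0 || m2 == 0 || n1 == 0 || (Ps + Ds) == 0) return(1)
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(support, m1, m2, n1)
  pObs <- dhyper(Pn, m1, m2, n1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# tiny aligned-FASTA writer for read-path tests
writeToyFasta <- function(seqs, path) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}
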