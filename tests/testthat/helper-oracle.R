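# Independent oracles used across tests.

# Exhaustive enumeration of all local alignment paths between two short
# sequences (start and end on an aligned column; affine gaps costing
# gap_open for the first gapped base, gap_extend for each further one; gap
# runs in either order allowed). Returns the best score, 0 if no positive-
# scoring alignment exists. Branch-and-bound pruning only skips paths that
# provably cannot beat the incumbent, so the result equals full enumeration.
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  best <- 0
  rec <- function(i, j, score, state) {
    # state: 1 aligned column, 2 gap consuming A, 3 gap consuming B
    if (state == 1L && score > best) best <<- score
    rem <- match * min(n - i, m - j)
    if (score + rem <= best) return(invisible())
    if (i < n && j < m) {
      s <- if (A[i + 1L] == B[j + 1L]) match else mismatch
      rec(i + 1L, j + 1L, score + s, 1L)
    }
    if (i < n) rec(i + 1L, j, score + if (state == 2L) gap_extend else gap_open, 2L)
    if (j < m) rec(i, j + 1L, score + if (state == 3L) gap_extend else gap_open, 3L)
    invisible()
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s0 <- if (A[i] == B[j]) match else mismatch
      rec(i, j, s0, 1L)
    }
  }
  best
}

# Reverse complement through Biostrings, independent of the package's
# chartr-based internal.
oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Brute-force length of the longest prefix of `extra` matching `flank`
# position by position (clip-versus-flank genomic extension).
oracle_prefix_match <- function(extra, flank) {
  k <- 0L
  for (i in seq_len(min(nchar(extra), nchar(flank)))) {
    if (substr(extra, i, i) == substr(flank, i, i)) k <- k + 1L else break
  }
  k
}
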