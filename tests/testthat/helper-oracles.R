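# Independent oracles used across the suite. These deliberately do not
# share code with the package: plain-R matrix dynamic programming for
# alignment scores, a literal codon-table lookup for translation, and
# hand-rolled counting helpers.

# Gotoh affine-gap alignment score, full three-state DP in plain R.
# Gap of length L costs go + L * ge. mode: "local" or "global".
oracle_align_score <- function(a, b, match = 2, mismatch = -3, go = 5,
                               ge = 2, mode = "local") {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
    for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (mode == "local") best <- max(best, 0)
      M[i, j] <- best + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  if (mode == "local") max(0, M) else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                          Y[n + 1, m + 1])
}

# literal standard-code codon table (independent of Biostrings)
oracle_codon_table <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  aa <- oracle_codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# point-mutate exactly k positions (substitutions to a different base)
mutate_at <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  list(seq = paste(s, collapse = ""), pos = pos)
}
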