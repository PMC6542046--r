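# Pairwise alignment wrappers around the compiled Gotoh DP, plus
# Karlin-Altschul score statistics and six-frame translation.

#' Scoring schemes
#'
#' A scoring scheme bundles substitution scores, affine gap penalties (a gap
#' of length L costs `gap_open + L * gap_extend`) and the Karlin-Altschul
#' parameters lambda and K used to convert raw scores to bitscores and
#' E-values.
#'
#' The nucleotide default is the blastn-like +2/-3 scheme with gap open 5 /
#' extend 2 and the widely published constants lambda = 0.625, K = 0.41 for
#' those scores. The protein default uses BLOSUM62 with gap open 11 /
#' extend 1 and lambda = 0.267, K = 0.041.
#'
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gap_open,gap_extend affine gap penalties (non-negative).
#' @param lambda,k_const Karlin-Altschul parameters (per raw-score unit).
#' @return list of class `scoring_scheme` with a substitution `matrix` and
#'   its `alphabet` (wildcard symbol last).
#' @export
dna_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                       gap_extend = 2L, lambda = 0.625, k_const = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, k_const > 0, k_const < 1)
  alpha <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(m) <- match
  # N never rewards: score as mismatch against everything, itself included
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  structure(list(type = "dna", matrix = m, alphabet = paste(alpha, collapse = ""),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 lambda = lambda, k_const = k_const, kmer = 11L),
            class = "scoring_scheme")
}

#' @rdname dna_scheme
#' @export
protein_scheme <- function(gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, k_const = 0.041) {
  m <- get_blosum62()
  # move wildcard X to the last position so unknown residues map onto it
  alpha <- c(setdiff(rownames(m), "X"), "X")
  m <- m[alpha, alpha]
  structure(list(type = "protein", matrix = m, alphabet = paste(alpha, collapse = ""),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 lambda = lambda, k_const = k_const, kmer = 5L),
            class = "scoring_scheme")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

align_mode <- c(local = 0L, global = 1L, overlap = 2L)

# shared wrapper: returns score, aligned strings, 0-based half-open spans
# and column counts
align_pair <- function(a, b, scheme, mode = "local", band = 0L) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (band > 0) band <- max(band, abs(nchar(a) - nchar(b)) + 5L)
  res <- align_pair_cpp(a, b, scheme$matrix, scheme$alphabet,
                        scheme$gap_open, scheme$gap_extend,
                        align_mode[[mode]], as.integer(band))
  res$a_start <- as.integer(res$a_start); res$a_end <- as.integer(res$a_end)
  res$b_start <- as.integer(res$b_start); res$b_end <- as.integer(res$b_end)
  res
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param a,b sequences (character scalars).
#' @param scheme a [dna_scheme()] or [protein_scheme()].
#' @return list with `score` (0 and an empty alignment if no positive-
#'   scoring local alignment exists), aligned strings `a_aln`/`b_aln`,
#'   0-based half-open spans `a_start..a_end`, `b_start..b_end`, and match/
#'   mismatch/gap counts.
#' @export
smith_waterman <- function(a, b, scheme = dna_scheme()) {
  align_pair(a, b, scheme, "local")
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' Terminal gaps are penalized unless `free_ends = TRUE`, which switches to
#' overlap (ends-free) alignment as used for consensus-vs-consensus
#' comparisons.
#'
#' @inheritParams smith_waterman
#' @param free_ends if TRUE terminal gaps cost nothing.
#' @param band optional DP band half-width around the main diagonal
#'   (0 = full matrix); widened automatically to cover any length
#'   difference.
#' @export
needleman_wunsch <- function(a, b, scheme = dna_scheme(),
                             free_ends = FALSE, band = 0L) {
  align_pair(a, b, scheme, if (free_ends) "overlap" else "global", band)
}

#' Six-frame translation
#'
#' Standard genetic code, stops as `*`, ambiguous codons as `X`. Frames are
#' named `+1,+2,+3` (forward offsets 0..2) and `-1,-2,-3` (same offsets on
#' the reverse complement).
#'
#' @param seq nucleotide sequence (character scalar).
#' @return named character vector of 6 peptides (empty string when the
#'   frame is shorter than one codon).
#' @export
six_frame_translate <- function(seq) {
  fr <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3
    if (n < 3) return("")
    x <- Biostrings::DNAString(substr(s, off + 1L, off + n))
    as.character(suppressWarnings(
      Biostrings::translate(x, if.fuzzy.codon = "solve", no.init.codon = TRUE)))
  }
  rc <- revcomp(seq)
  c("+1" = fr(seq, 0L), "+2" = fr(seq, 1L), "+3" = fr(seq, 2L),
    "-1" = fr(rc, 0L), "-2" = fr(rc, 1L), "-3" = fr(rc, 2L))
}

#' Karlin-Altschul bitscore and E-value
#'
#' `bitscore = (lambda * S - ln K) / ln 2`;
#' `E = m_eff * n_eff * 2^(-bitscore)`.
#'
#' @param raw_score non-negative raw alignment score.
#' @param scheme scoring scheme supplying lambda and K.
#' @return numeric scalar (vectorized over `raw_score` / `bits`).
#' @export
bitscore <- function(raw_score, scheme = dna_scheme()) {
  stopifnot(all(raw_score >= 0))
  (scheme$lambda * raw_score - log(scheme$k_const)) / log(2)
}

#' @rdname bitscore
#' @param bits bitscore(s).
#' @param m_eff,n_eff effective query and database lengths (positive).
#' @export
evalue <- function(bits, m_eff, n_eff) {
  if (any(m_eff <= 0) || any(n_eff <= 0))
    stop("effective lengths must be positive")
  as.numeric(m_eff) * as.numeric(n_eff) * 2^(-bits)
}
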