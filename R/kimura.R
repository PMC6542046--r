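# CpG-excluded Kimura 2-parameter divergence of element copies from their
# consensus, and the length-weighted repeat landscape.

#' Count transitions and transversions in a pairwise alignment
#'
#' Columns are counted only where both sequences carry an unambiguous
#' A/C/G/T. With `exclude_cpg = TRUE`, both positions of every CpG
#' dinucleotide in the ungapped reference are excluded (CpG sites
#' hypermutate through methylation-driven deamination and inflate apparent
#' age); adjacency is determined on the ungapped reference and mapped
#' through the alignment. `cpg_on = "both"` additionally excludes CpG
#' positions of the second sequence, giving a symmetric count for
#' distance matrices.
#'
#' @param ref_aln,copy_aln aligned (gapped) reference and copy strings of
#'   equal length; the reference is the consensus.
#' @param exclude_cpg exclude reference CpG positions.
#' @param cpg_on `"reference"` (default) or `"both"`.
#' @return list: `p` (transition proportion), `q` (transversion
#'   proportion), `n_sites` (counted columns), `n_excluded_cpg`.
#' @export
count_changes <- function(ref_aln, copy_aln, exclude_cpg = TRUE,
                          cpg_on = c("reference", "both")) {
  cpg_on <- match.arg(cpg_on)
  r <- strsplit(toupper(ref_aln), "", fixed = TRUE)[[1]]
  c_ <- strsplit(toupper(copy_aln), "", fixed = TRUE)[[1]]
  if (length(r) != length(c_)) stop("alignment strings differ in length")
  acgt <- c("A", "C", "G", "T")
  cpg_cols <- rep(FALSE, length(r))
  if (exclude_cpg) {
    cpg_cols <- cpg_cols | cpg_columns(r)
    if (cpg_on == "both") cpg_cols <- cpg_cols | cpg_columns(c_)
  }
  countable <- r %in% acgt & c_ %in% acgt & !cpg_cols
  n_sites <- sum(countable)
  if (n_sites == 0) stop("no informative sites")
  rr <- r[countable]; cc <- c_[countable]
  diff <- rr != cc
  purine <- function(x) x %in% c("A", "G")
  transition <- diff & (purine(rr) == purine(cc))
  list(p = sum(transition) / n_sites,
       q = sum(diff & !transition) / n_sites,
       n_sites = n_sites,
       n_excluded_cpg = sum(cpg_cols & r %in% acgt & c_ %in% acgt))
}

# alignment columns covering CpG dinucleotides of the ungapped sequence
cpg_columns <- function(chars) {
  out <- rep(FALSE, length(chars))
  base_cols <- which(chars != "-")
  if (length(base_cols) < 2) return(out)
  ungapped <- chars[base_cols]
  is_cpg_start <- ungapped[-length(ungapped)] == "C" & ungapped[-1] == "G"
  hit <- which(is_cpg_start)
  out[base_cols[hit]] <- TRUE
  out[base_cols[hit + 1L]] <- TRUE
  out
}

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))` with transition proportion
#' `p` and transversion proportion `q`. When either logarithm argument is
#' non-positive the distance is saturated and returned as `NA` with
#' attribute `saturated = TRUE`.
#'
#' @param p,q transition and transversion proportions.
#' @return numeric distance (substitutions/site), `NA` when saturated.
#' @export
k2p <- function(p, q) {
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0)
    return(structure(NA_real_, saturated = TRUE))
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura estimates of copies against their consensus
#'
#' Each copy is aligned to the consensus (ends-free global alignment, both
#' orientations tried) and its CpG-excluded K2P distance computed.
#'
#' @param copies [seq_tbl()] of copy sequences.
#' @param consensus consensus sequence (character scalar).
#' @param exclude_cpg see [count_changes()].
#' @param scheme nucleotide scoring scheme.
#' @param band DP band half-width (0 = full matrix).
#' @return data.frame: `copy_id`, `p`, `q`, `k2p`, `n_sites`,
#'   `n_excluded_cpg`, `copy_length`, `saturated`.
#' @export
kimura_estimates <- function(copies, consensus, exclude_cpg = TRUE,
                             scheme = dna_scheme(), band = 200L) {
  out <- lapply(seq_len(nrow(copies)), function(i) {
    s <- copies$seq[i]
    fwd <- needleman_wunsch(s, consensus, scheme, free_ends = TRUE,
                            band = band)
    rev <- needleman_wunsch(revcomp(s), consensus, scheme, free_ends = TRUE,
                            band = band)
    aln <- if (rev$score > fwd$score) rev else fwd
    cc <- count_changes(aln$b_aln, aln$a_aln, exclude_cpg)
    k <- k2p(cc$p, cc$q)
    data.frame(copy_id = copies$id[i], p = cc$p, q = cc$q,
               k2p = as.numeric(k), n_sites = cc$n_sites,
               n_excluded_cpg = cc$n_excluded_cpg,
               copy_length = nchar(s),
               saturated = isTRUE(attr(k, "saturated")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Length-weighted repeat landscape
#'
#' Each copy contributes its length to the bin `floor(k2p% / bin_width)`;
#' the landscape is the per-bin summed copy length, annotated with the
#' minimum, length-weighted mean and maximum K2P distance — the relative
#' age profile of the element family (replication bursts appear as peaks).
#'
#' @param estimates data.frame from [kimura_estimates()]; saturated copies
#'   are dropped.
#' @param bin_width bin width in distance-percent units.
#' @return list of class `repeat_landscape`: `bins` (data.frame `bin_lo`,
#'   `bin_hi` in %, `bases`), `min`, `weighted_mean`, `max` (distances as
#'   proportions), the same three in percent (`*_pct`), `bin_width`,
#'   `total_bases`.
#' @export
repeat_landscape <- function(estimates, bin_width = 1.0) {
  est <- estimates[!estimates$saturated & !is.na(estimates$k2p), ,
                   drop = FALSE]
  if (nrow(est) == 0) stop("no unsaturated Kimura estimates")
  pct <- est$k2p * 100
  bin <- floor(pct / bin_width)
  bases <- tapply(est$copy_length, bin, sum)
  bins <- data.frame(bin_lo = as.numeric(names(bases)) * bin_width,
                     bin_hi = (as.numeric(names(bases)) + 1) * bin_width,
                     bases = as.numeric(bases))
  wmean <- sum(est$k2p * est$copy_length) / sum(est$copy_length)
  structure(list(bins = bins, min = min(est$k2p),
                 weighted_mean = wmean, max = max(est$k2p),
                 min_pct = 100 * min(est$k2p),
                 weighted_mean_pct = 100 * wmean,
                 max_pct = 100 * max(est$k2p),
                 bin_width = bin_width,
                 total_bases = sum(est$copy_length)),
            class = "repeat_landscape")
}

#' @export
print.repeat_landscape <- function(x, ...) {
  cat(sprintf(
    "Repeat landscape: %d bins, %d bases; Kimura %% min/weighted-mean/max = %.2f/%.2f/%.2f\n",
    nrow(x$bins), x$total_bases, x$min_pct, x$weighted_mean_pct, x$max_pct))
  invisible(x)
}
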