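# Repeat annotation and masking against a user-supplied repeat library
# (RepeatMasker stand-in). Divergence is computed over aligned columns
# including gap columns: divergence = (mismatches + indel columns) /
# aligned columns * 100 = 100 - identity.

#' Annotate repeat-library matches on a sequence
#'
#' Searches every library consensus against the sequence, converts hits to
#' annotations, merges overlapping annotations of the same family (union;
#' divergence length-weighted, consensus span unioned) and applies the
#' length/divergence filters after merging. Filters keep annotations with
#' merged length `>= min_len` and divergence strictly `< max_divergence`.
#'
#' @param seq a single-row [seq_tbl()] (or the first row is used).
#' @param library repeat-library [seq_tbl()] of family consensus sequences.
#' @param min_len minimum merged annotation length (bp).
#' @param max_divergence keep annotations with divergence below this (%).
#' @param scheme nucleotide scoring scheme.
#' @param evalue_cutoff hit significance threshold.
#' @return data.frame: `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `family`, `divergence_pct`, `score` (bitscore),
#'   `cons_start`, `cons_end` (span on the family consensus).
#' @export
annotate_repeats <- function(seq, library, min_len = 50L,
                             max_divergence = 100, scheme = dna_scheme(),
                             evalue_cutoff = 1e-10) {
  empty <- annotation_tbl()
  if (nrow(library) == 0 || nrow(seq) == 0) return(empty)
  db <- search_database(seq[1, , drop = FALSE], label = "target", type = "dna")
  hits <- search_db(library, db, scheme, evalue_cutoff)
  hits_to_annotations(hits, seq$id[1], min_len, max_divergence)
}

annotation_tbl <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), family = character(),
             divergence_pct = numeric(), score = numeric(),
             cons_start = integer(), cons_end = integer(),
             stringsAsFactors = FALSE)
}

# hits where the subject is the annotated sequence and the query is the
# family consensus -> annotation rows; merging + filtering shared with the
# read-oriented path (subject_on_read = TRUE flips the roles).
hits_to_annotations <- function(hits, seq_id, min_len, max_divergence,
                                subject_on_read = FALSE) {
  if (nrow(hits) == 0) return(annotation_tbl())
  if (subject_on_read) {
    ann <- data.frame(seq_id = seq_id, start = hits$qstart, end = hits$qend,
                      strand = hits$strand, family = hits$subject_id,
                      divergence_pct = 100 - hits$pident, score = hits$bitscore,
                      cons_start = hits$sstart, cons_end = hits$send,
                      stringsAsFactors = FALSE)
  } else {
    ann <- data.frame(seq_id = seq_id, start = hits$sstart, end = hits$send,
                      strand = hits$strand, family = hits$query_id,
                      divergence_pct = 100 - hits$pident, score = hits$bitscore,
                      cons_start = hits$qstart, cons_end = hits$qend,
                      stringsAsFactors = FALSE)
  }
  merged <- lapply(split(ann, paste(ann$family, ann$strand)), merge_family)
  out <- do.call(rbind, c(list(annotation_tbl()), merged))
  out <- out[(out$end - out$start) >= min_len &
               out$divergence_pct < max_divergence, , drop = FALSE]
  out <- out[order(out$start, out$end, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union of overlapping intervals within one family+strand
merge_family <- function(ann) {
  ir <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  red <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, red)
  grp <- S4Vectors::subjectHits(ov)
  w <- ann$end - ann$start
  out <- ann[!duplicated(grp), , drop = FALSE][order(unique(grp)), , drop = FALSE]
  out$start <- IRanges::start(red) - 1L
  out$end <- IRanges::end(red)
  out$divergence_pct <- as.numeric(tapply(ann$divergence_pct * w, grp, sum) /
                                     tapply(w, grp, sum))
  out$score <- as.numeric(tapply(ann$score, grp, max))
  out$cons_start <- as.integer(tapply(ann$cons_start, grp, min))
  out$cons_end <- as.integer(tapply(ann$cons_end, grp, max))
  out
}

#' Annotate one retroelement family on a reference assembly as BED-style
#' intervals
#'
#' [annotate_repeats()] restricted to a single family with the filters used
#' for reference-based read-pair selection: alignments with divergence
#' under 20% and length of at least 200 bp.
#'
#' @param assembly [seq_tbl()] of assembly sequences.
#' @param rte_consensus single-row [seq_tbl()] of the element consensus.
#' @param max_div divergence ceiling (%; strict).
#' @param min_len minimum merged length (bp; inclusive).
#' @param scheme,evalue_cutoff passed to [annotate_repeats()].
#' @return BED-style data.frame `seq_id`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
reference_rte_bed <- function(assembly, rte_consensus, max_div = 20,
                              min_len = 200L, scheme = dna_scheme(),
                              evalue_cutoff = 1e-10) {
  anns <- lapply(seq_len(nrow(assembly)), function(i)
    annotate_repeats(assembly[i, , drop = FALSE], rte_consensus[1, , drop = FALSE],
                     min_len = min_len, max_divergence = max_div,
                     scheme = scheme, evalue_cutoff = evalue_cutoff))
  ann <- do.call(rbind, c(list(annotation_tbl()), anns))
  data.frame(seq_id = ann$seq_id, start = ann$start, end = ann$end,
             name = ann$family, score = ann$score, strand = ann$strand,
             stringsAsFactors = FALSE)
}

#' Mask annotated intervals on a sequence
#'
#' Hard masking replaces annotated bases by `N`, soft masking lowercases
#' them; sequence length is conserved either way. The informative length is
#' the number of unmasked bases.
#'
#' @param seq a single sequence string.
#' @param annotations annotation data.frame with `start`/`end` (0-based
#'   half-open) on this sequence.
#' @param mode `"hard"` or `"soft"`.
#' @return list with `seq` (masked) and `informative_length`.
#' @export
mask_repeats <- function(seq, annotations, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  n <- nchar(seq)
  if (nrow(annotations) == 0)
    return(list(seq = seq, informative_length = n))
  if (any(annotations$start < 0 | annotations$end > n))
    stop("annotation out of sequence bounds")
  ir <- IRanges::reduce(IRanges::IRanges(annotations$start + 1L, annotations$end))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- unlist(lapply(seq_along(ir), function(i)
    IRanges::start(ir)[i]:IRanges::end(ir)[i]))
  chars[idx] <- if (mode == "hard") "N" else tolower(chars[idx])
  list(seq = paste(chars, collapse = ""),
       informative_length = n - length(idx))
}
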