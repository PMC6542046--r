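# Per-species consensus reconstruction (reference-anchored star alignment
# with majority rule), consensus identity matrices, copy defragmentation
# and ORF finding.

#' Build a per-species consensus from element fragments
#'
#' Every fragment is aligned to the family seed sequence (ends-free global
#' alignment, both orientations tried, better score kept). For each seed
#' column the consensus base is the plurality base among aligned fragment
#' bases when the column's coverage reaches `min_coverage`; otherwise the
#' seed base is retained. Insertions relative to the seed are discarded, so
#' the consensus has the seed's length and coordinate system.
#'
#' @param fragments [seq_tbl()] of element fragments/copies (>= 1 row).
#' @param seed single-row [seq_tbl()] of the family seed/reference.
#' @param min_coverage minimum column coverage for a majority call.
#' @param scheme nucleotide scoring scheme.
#' @param band DP band half-width for the fragment-to-seed alignments
#'   (0 = full matrix).
#' @return list of class `consensus_model`: `consensus` (string),
#'   `coverage` (integer per column), `n_fragments`, `seed_id`.
#' @export
build_consensus <- function(fragments, seed, min_coverage = 3L,
                            scheme = dna_scheme(), band = 200L) {
  if (nrow(fragments) == 0) stop("no fragments")
  sseq <- seed$seq[1]
  n <- nchar(sseq)
  counts <- matrix(0L, nrow = 5, ncol = n,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_len(nrow(fragments))) {
    f <- fragments$seq[i]
    fwd <- needleman_wunsch(f, sseq, scheme, free_ends = TRUE, band = band)
    rev <- needleman_wunsch(revcomp(f), sseq, scheme, free_ends = TRUE,
                            band = band)
    aln <- if (rev$score > fwd$score) rev else fwd
    fa <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
    sa <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
    col <- aln$b_start  # 0-based position on the seed
    for (j in seq_along(sa)) {
      if (sa[j] != "-") {
        col <- col + 1L
        if (fa[j] != "-" && fa[j] %in% rownames(counts))
          counts[fa[j], col] <- counts[fa[j], col] + 1L
      }
    }
  }
  counts <- counts[1:4, , drop = FALSE]  # N never wins a column
  coverage <- colSums(counts)
  seed_chars <- strsplit(sseq, "", fixed = TRUE)[[1]]
  # plurality base; ties broken alphabetically for determinism
  maj <- rownames(counts)[apply(counts, 2, which.max)]
  cons <- ifelse(coverage >= min_coverage, maj, seed_chars)
  structure(list(consensus = paste(cons, collapse = ""),
                 coverage = as.integer(coverage),
                 n_fragments = nrow(fragments), seed_id = seed$id[1]),
            class = "consensus_model")
}

#' Pairwise identity matrix of consensus sequences
#'
#' Identities come from ends-free global alignments; terminal overhang
#' columns (the cost-free ends) are excluded, and identity is the fraction
#' of matching columns among the remaining aligned columns, in percent.
#'
#' @param consensuses [seq_tbl()] of consensus sequences (>= 1 row).
#' @param scheme nucleotide scoring scheme.
#' @return symmetric matrix of identities in `[0, 100]`, diagonal 100,
#'   labelled by record id.
#' @export
pairwise_identity <- function(consensuses, scheme = dna_scheme()) {
  n <- nrow(consensuses)
  m <- matrix(100, n, n, dimnames = list(consensuses$id, consensuses$id))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- needleman_wunsch(consensuses$seq[i], consensuses$seq[j],
                              scheme, free_ends = TRUE)
      m[i, j] <- m[j, i] <- 100 * aln$matches / aln$ncols
    }
  }
  m
}

#' Merge collinear repeat fragments into copies (defragmentation)
#'
#' Same-family, same-strand fragments on one sequence are merged when the
#' genomic gap between them is at most `max_gap` and their consensus
#' coordinates are collinear (the next fragment continues on the consensus,
#' allowing `slack` bp of overlap); in strict mode a fragment of a
#' different family lying between two fragments blocks the merge. Two
#' tandem full-length copies are not merged because their consensus
#' coordinates restart.
#'
#' @param annotations data.frame from [annotate_repeats()] (one genome).
#' @param max_gap maximum genomic gap between merged fragments (bp).
#' @param slack allowed consensus-coordinate overlap between consecutive
#'   fragments (bp).
#' @param strict block merges across intervening other-family annotations.
#' @return data.frame of copies: `copy_id`, `seq_id`, `start`, `end`,
#'   `strand`, `family`, `n_fragments`, `merged_length` (sum of fragment
#'   lengths), `mean_divergence_pct` (length-weighted), `cons_start`,
#'   `cons_end`, plus a `fragments` list-column of row indices into
#'   `annotations`.
#' @export
defragment <- function(annotations, max_gap = 5000L, slack = 20L,
                       strict = TRUE) {
  out <- list()
  if (nrow(annotations) == 0) return(copy_tbl(out))
  ann <- annotations
  ann$row <- seq_len(nrow(ann))
  ord <- order(ann$seq_id, ann$start, ann$end)
  ann <- ann[ord, , drop = FALSE]
  for (sid in unique(ann$seq_id)) {
    on_seq <- ann[ann$seq_id == sid, , drop = FALSE]
    for (grp in split(on_seq, paste(on_seq$family, on_seq$strand))) {
      cur <- grp[1, , drop = FALSE]
      rows <- cur$row
      flush <- function(block_rows, block) {
        out[[length(out) + 1L]] <<- block_summary(block_rows, block, annotations)
      }
      if (nrow(grp) > 1) {
        for (i in 2:nrow(grp)) {
          nxt <- grp[i, , drop = FALSE]
          prev <- grp[i - 1, , drop = FALSE]
          gap_ok <- (nxt$start - prev$end) <= max_gap
          collinear <- if (nxt$strand == "+")
            nxt$cons_start >= prev$cons_end - slack
          else
            nxt$cons_end <= prev$cons_start + slack
          blocked <- strict && any(
            on_seq$family != nxt$family &
              on_seq$start < nxt$start & on_seq$end > prev$end)
          if (gap_ok && collinear && !blocked) {
            rows <- c(rows, nxt$row)
          } else {
            flush(rows, annotations[rows, , drop = FALSE])
            rows <- nxt$row
          }
        }
      }
      flush(rows, annotations[rows, , drop = FALSE])
    }
  }
  copy_tbl(out)
}

block_summary <- function(rows, block, annotations) {
  w <- block$end - block$start
  data.frame(seq_id = block$seq_id[1],
             start = min(block$start), end = max(block$end),
             strand = block$strand[1], family = block$family[1],
             n_fragments = nrow(block), merged_length = sum(w),
             mean_divergence_pct = sum(block$divergence_pct * w) / sum(w),
             cons_start = min(block$cons_start),
             cons_end = max(block$cons_end),
             fragments = I(list(rows)), stringsAsFactors = FALSE)
}

copy_tbl <- function(parts) {
  if (length(parts) == 0)
    return(data.frame(copy_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      family = character(), n_fragments = integer(),
                      merged_length = integer(), mean_divergence_pct = numeric(),
                      cons_start = integer(), cons_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  out <- cbind(copy_id = sprintf("%s:%d-%d(%s)", out$seq_id, out$start,
                                 out$end, out$strand), out)
  out$copy_id <- as.character(out$copy_id)
  rownames(out) <- NULL
  out
}

#' Select the longest, least divergent copies
#'
#' Stable sort by merged length (descending) then mean divergence
#' (ascending); the first `n` copies are returned (all of them when fewer
#' exist).
#'
#' @param copies data.frame from [defragment()].
#' @param n number of copies to keep.
#' @export
select_top_copies <- function(copies, n = 100L) {
  ord <- order(-copies$merged_length, copies$mean_divergence_pct)
  head(copies[ord, , drop = FALSE], n)
}

#' Find open reading frames
#'
#' Reports every stop-to-stop run of at least `min_codons` sense codons in
#' all six frames (no start-codon requirement). Coordinates are 0-based
#' half-open on the forward strand of the input.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param min_codons minimum ORF length in codons.
#' @return data.frame: `frame` (`+1`..`-3`), `start`, `end`, `n_codons`,
#'   `peptide`.
#' @export
find_orfs <- function(seq, min_codons = 30L) {
  L <- nchar(seq)
  peps <- six_frame_translate(seq)
  out <- list()
  for (f in names(peps)) {
    p <- peps[[f]]
    if (nchar(p) == 0) next
    off <- as.integer(substr(f, 2, 2)) - 1L
    runs <- gregexpr("[^*]+", p)[[1]]
    if (runs[1] == -1) next
    for (r in seq_along(runs)) {
      aa_start <- runs[r] - 1L
      len <- attr(runs, "match.length")[r]
      if (len < min_codons) next
      nt1 <- off + 3L * aa_start
      nt2 <- off + 3L * (aa_start + len)
      if (startsWith(f, "-")) { tmp <- nt1; nt1 <- L - nt2; nt2 <- L - tmp }
      out[[length(out) + 1L]] <- data.frame(
        frame = f, start = nt1, end = nt2, n_codons = len,
        peptide = substr(p, aa_start + 1L, aa_start + len),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = character(), start = integer(),
                      end = integer(), n_codons = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  frame_order <- c("+1", "+2", "+3", "-1", "-2", "-3")
  res[order(match(res$frame, frame_order), res$start), , drop = FALSE]
}

#' @rdname find_orfs
#' @export
longest_orf <- function(seq, min_codons = 30L) {
  orfs <- find_orfs(seq, min_codons)
  if (nrow(orfs) == 0) return(NULL)
  # longest peptide; ties resolved by frame order (+1..-3) via row order
  orfs[which.max(orfs$n_codons), , drop = FALSE]
}
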