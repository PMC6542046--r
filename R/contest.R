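# The read-based contamination / horizontal-transfer test. TE-bearing long
# reads or read pairs are selected in one of three modes, repeats are
# hard-masked, and the informative (non-repetitive) remainder is classified
# against a "self" and a "non-self" genome database. Dataset-level
# fractions of self vs non-self verdicts yield the call.

#' Select long reads that code for the retroelement
#'
#' A long read is selected when a translated (six-frame) search of the read
#' against the element's ORF protein yields a hit with E-value below the
#' cutoff.
#'
#' @param reads nucleotide [seq_tbl()] of long reads.
#' @param rte_orf_protein single-row protein [seq_tbl()] (or a prebuilt
#'   protein [search_database()]).
#' @param evalue_cutoff selection threshold (default 1e-10).
#' @param scheme protein scoring scheme.
#' @return the selected subset of `reads`.
#' @export
select_long_reads <- function(reads, rte_orf_protein, evalue_cutoff = 1e-10,
                              scheme = protein_scheme()) {
  if (nrow(reads) == 0) return(reads)
  db <- as_protein_db(rte_orf_protein)
  hits <- translated_search(reads, db, scheme, evalue_cutoff)
  reads[reads$id %in% unique(hits$query_id), , drop = FALSE]
}

as_protein_db <- function(x) {
  if (inherits(x, "search_database")) return(x)
  search_database(x, label = "rte_orf", type = "protein")
}

as_dna_db <- function(x, label) {
  if (inherits(x, "search_database")) return(x)
  search_database(x, label = label, type = "dna")
}

#' Select read pairs via a reference assembly (reference-based mode)
#'
#' Keeps pairs where exactly one mate overlaps an annotated retroelement
#' interval on the reference (>= 1 bp overlap); pairs with both mates in
#' element regions are discarded. The overlapping mate must additionally
#' have its best repeat-library hit on the element itself (reciprocal
#' check); the other mate is returned as the informative mate.
#'
#' @param pairs data.frame with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (mate ids are `<pair_id>/1` and `<pair_id>/2`).
#' @param mappings data.frame `read_id`, `seq_id`, `start`, `end`, `mate`
#'   (1/2) with 0-based half-open reference spans, e.g. from
#'   [read_samlite()] (`read_id` may equal the pair id) or from the
#'   simulator's truth.
#' @param rte_bed BED-style data.frame of element intervals on the
#'   reference ([reference_rte_bed()]).
#' @param repeat_library_db repeat-library [search_database()] (or
#'   [seq_tbl()]) used for the reciprocal check.
#' @param rte_name id of the element consensus within the repeat library.
#' @param evalue_cutoff significance threshold for the reciprocal check.
#' @param scheme nucleotide scoring scheme.
#' @return [seq_tbl()] of informative mates (ids `<pair_id>/<mate>`), with
#'   attributes `n_pairs_both_te` and `n_pairs_unmapped`.
#' @export
select_pairs_reference <- function(pairs, mappings, rte_bed,
                                   repeat_library_db, rte_name,
                                   evalue_cutoff = 1e-10,
                                   scheme = dna_scheme()) {
  lib <- as_dna_db(repeat_library_db, "repeats")
  empty <- seq_tbl(character(), character())
  if (nrow(pairs) == 0) return(empty)
  mappings$pair_id <- sub("/[12]$", "", mappings$read_id)
  # overlap of each mapped mate with the element intervals
  if (nrow(rte_bed) > 0 && nrow(mappings) > 0) {
    hit_te <- logical(nrow(mappings))
    for (sid in unique(rte_bed$seq_id)) {
      sel <- mappings$seq_id == sid
      if (!any(sel)) next
      bed <- rte_bed[rte_bed$seq_id == sid, , drop = FALSE]
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(mappings$start[sel] + 1L, mappings$end[sel]),
        IRanges::IRanges(bed$start + 1L, bed$end))
      hit_te[sel] <- ov
    }
  } else hit_te <- logical(nrow(mappings))
  te1 <- mappings$pair_id[hit_te & mappings$mate == 1L]
  te2 <- mappings$pair_id[hit_te & mappings$mate == 2L]
  mapped <- unique(mappings$pair_id)
  both <- intersect(te1, te2)
  one1 <- setdiff(te1, te2)  # mate 1 in TE, mate 2 informative
  one2 <- setdiff(te2, te1)
  unmapped <- sum(!(pairs$pair_id %in% mapped))
  sel <- rbind(
    data.frame(pair_id = one1, te_mate = rep(1L, length(one1)),
               stringsAsFactors = FALSE),
    data.frame(pair_id = one2, te_mate = rep(2L, length(one2)),
               stringsAsFactors = FALSE))
  sel <- sel[sel$pair_id %in% pairs$pair_id, , drop = FALSE]
  if (nrow(sel) == 0) {
    out <- empty
  } else {
    p <- pairs[match(sel$pair_id, pairs$pair_id), , drop = FALSE]
    te_seq <- ifelse(sel$te_mate == 1L, p$seq1, p$seq2)
    te_reads <- seq_tbl(paste0(sel$pair_id, "/", sel$te_mate), te_seq)
    recip <- reciprocal_rte(te_reads, lib, rte_name, evalue_cutoff, scheme)
    keep <- sel$pair_id %in% sub("/[12]$", "", recip)
    sel <- sel[keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
    inf_mate <- 3L - sel$te_mate
    out <- seq_tbl(paste0(sel$pair_id, "/", inf_mate),
                   ifelse(inf_mate == 1L, p$seq1, p$seq2),
                   qual = ifelse(inf_mate == 1L, p$qual1, p$qual2))
  }
  attr(out, "n_pairs_both_te") <- length(both)
  attr(out, "n_pairs_unmapped") <- unmapped
  out
}

# ids of reads whose best repeat-library hit is the element itself
reciprocal_rte <- function(reads, lib_db, rte_name, evalue_cutoff, scheme) {
  hits <- search_db(reads, lib_db, scheme, evalue_cutoff)
  if (nrow(hits) == 0) return(character(0))
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]  # sorted by rank
  best$query_id[best$subject_id == rte_name]
}

#' Select read pairs without a reference (reference-free mode)
#'
#' For each (quality-masked) pair, one mate must have its best
#' repeat-library hit on the element (reciprocal hit, E-value below the
#' cutoff) while the other mate has no element hit at all; that other mate
#' is the informative mate. Pairs where both mates hit the element are
#' dropped and counted.
#'
#' @inheritParams select_pairs_reference
#' @return [seq_tbl()] of informative mates with attribute
#'   `n_pairs_both_te`.
#' @export
select_pairs_noref <- function(pairs, repeat_library_db, rte_name,
                               evalue_cutoff = 1e-10, scheme = dna_scheme()) {
  lib <- as_dna_db(repeat_library_db, "repeats")
  empty <- seq_tbl(character(), character())
  attr(empty, "n_pairs_both_te") <- 0L
  if (nrow(pairs) == 0) return(empty)
  mates <- seq_tbl(c(paste0(pairs$pair_id, "/1"), paste0(pairs$pair_id, "/2")),
                   c(pairs$seq1, pairs$seq2),
                   qual = c(pairs$qual1, pairs$qual2))
  hits <- search_db(mates, lib, scheme, evalue_cutoff)
  rte_any <- unique(hits$query_id[hits$subject_id == rte_name])
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]  # ranked output
  recip <- best$query_id[best$subject_id == rte_name]
  m1 <- paste0(pairs$pair_id, "/1"); m2 <- paste0(pairs$pair_id, "/2")
  r1 <- m1 %in% recip; r2 <- m2 %in% recip
  a1 <- m1 %in% rte_any; a2 <- m2 %in% rte_any
  both <- a1 & a2
  keep1 <- r1 & !a2 & !both  # mate1 is the element mate, mate2 informative
  keep2 <- r2 & !a1 & !both
  out <- seq_tbl(c(m2[keep1], m1[keep2]),
                 c(pairs$seq2[keep1], pairs$seq1[keep2]),
                 qual = c(pairs$qual2[keep1], pairs$qual1[keep2]))
  attr(out, "n_pairs_both_te") <- sum(both)
  out
}

#' Classify informative reads against self and non-self databases
#'
#' Each read is hard-masked against the full repeat library; reads with
#' fewer than `min_informative` unmasked bases are flagged low-quality.
#' The remainder is searched against both databases with a shared effective
#' database size (the larger of the two), hits against the focal species'
#' own genome are discarded, and the surviving hits are pooled and ranked
#' by bitscore (ties: E-value, then subject id). The verdict is the label
#' of the top hit's database; equal top bitscores across the two databases
#' give `ambiguous`; no surviving hits give `unassigned`.
#'
#' @param informative [seq_tbl()] of informative reads/mates.
#' @param self_db,nonself_db [search_database()] objects (or [seq_tbl()]s)
#'   whose records carry `species` tags.
#' @param own_species species tag of the focal species; its hits are
#'   discarded.
#' @param repeat_library_db repeat library for masking (database or
#'   [seq_tbl()]).
#' @param scheme nucleotide scoring scheme.
#' @param evalue_cutoff database-search threshold.
#' @param min_informative minimum unmasked length for classification.
#' @return data.frame: `read_id`, `verdict` (`self`, `non-self`,
#'   `ambiguous`, `unassigned`, `low-quality`), `best_subject`,
#'   `best_species`, `bitscore`, `evalue`, `discarded_own_genome_hits`.
#' @export
classify_reads <- function(informative, self_db, nonself_db, own_species,
                           repeat_library_db, scheme = dna_scheme(),
                           evalue_cutoff = 1e-10, min_informative = 30L) {
  self_db <- as_dna_db(self_db, "self")
  nonself_db <- as_dna_db(nonself_db, "non-self")
  lib <- as_dna_db(repeat_library_db, "repeats")
  if (nrow(self_db$records) == 0 || nrow(nonself_db$records) == 0)
    stop("empty classification database")
  n <- nrow(informative)
  out <- data.frame(read_id = informative$id,
                    verdict = rep("unassigned", n),
                    best_subject = rep(NA_character_, n),
                    best_species = rep(NA_character_, n),
                    bitscore = rep(NA_real_, n), evalue = rep(NA_real_, n),
                    discarded_own_genome_hits = rep(0L, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)

  # 1. mask repeats on every read
  libhits <- search_db(informative, lib, scheme, evalue_cutoff)
  hsplit <- split(seq_len(nrow(libhits)), libhits$query_id)
  masked <- informative
  inf_len <- nchar(informative$seq)
  for (i in seq_len(nrow(informative))) {
    rows <- hsplit[[informative$id[i]]]
    if (is.null(rows)) next
    ann <- hits_to_annotations(libhits[rows, , drop = FALSE],
                               informative$id[i], min_len = 1L,
                               max_divergence = 101, subject_on_read = TRUE)
    m <- mask_repeats(informative$seq[i], ann, "hard")
    masked$seq[i] <- m$seq
    inf_len[i] <- m$informative_length
  }
  low <- inf_len < min_informative
  out$verdict[low] <- "low-quality"
  if (all(low)) return(out)
  q <- masked[!low, , drop = FALSE]

  # 2. search both databases with the shared effective size
  n_eff <- max(self_db$total_length, nonself_db$total_length)
  hs <- search_db(q, self_db, scheme, evalue_cutoff, n_eff = n_eff)
  hn <- search_db(q, nonself_db, scheme, evalue_cutoff, n_eff = n_eff)
  pooled <- rbind(hs, hn)
  if (nrow(pooled) > 0) {
    own <- pooled$subject_species %in% own_species
    ndisc <- tapply(own, pooled$query_id, sum)
    out$discarded_own_genome_hits <-
      as.integer(ifelse(is.na(ndisc[out$read_id]), 0L, ndisc[out$read_id]))
    pooled <- pooled[!own, , drop = FALSE]
  }
  if (nrow(pooled) == 0) return(out)
  pooled <- rank_hits(pooled)
  psplit <- split(seq_len(nrow(pooled)), pooled$query_id)
  for (id in names(psplit)) {
    h <- pooled[psplit[[id]], , drop = FALSE]
    i <- match(id, out$read_id)
    top <- h[1, ]
    tie <- nrow(h) > 1 && any(h$bitscore == top$bitscore &
                                h$db_label != top$db_label)
    out$verdict[i] <- if (tie) "ambiguous" else top$db_label
    out$best_subject[i] <- top$subject_id
    out$best_species[i] <- top$subject_species
    out$bitscore[i] <- top$bitscore
    out$evalue[i] <- top$evalue
  }
  out
}

#' Summarize classifications into a contamination/HTT call
#'
#' Fractions are computed over assigned reads only (self + non-self). The
#' call is `contamination` when the non-self fraction reaches
#' `call_threshold`, `endogenous/HTT-consistent` when the self fraction
#' does, and `inconclusive` otherwise (always inconclusive, with a warning,
#' when no read was assigned).
#'
#' @param classifications data.frame from [classify_reads()], or a named
#'   vector/list of counts (`self`, `nonself`).
#' @param call_threshold majority fraction required for a call.
#' @return list of class `contest_summary`: counts per verdict class,
#'   `frac_self`, `frac_nonself`, `call`.
#' @export
summarize_contest <- function(classifications, call_threshold = 0.80) {
  if (is.data.frame(classifications)) {
    v <- classifications$verdict
    counts <- c(self = sum(v == "self"), nonself = sum(v == "non-self"),
                ambiguous = sum(v == "ambiguous"),
                unassigned = sum(v == "unassigned"),
                low_quality = sum(v == "low-quality"))
  } else {
    cl <- as.list(classifications)
    counts <- c(self = cl$self %||% 0, nonself = cl$nonself %||% 0,
                ambiguous = cl$ambiguous %||% 0,
                unassigned = cl$unassigned %||% 0,
                low_quality = cl$low_quality %||% 0)
  }
  assigned <- counts[["self"]] + counts[["nonself"]]
  if (assigned == 0) {
    warning("no assigned reads; call is inconclusive")
    frac_self <- NA_real_; frac_nonself <- NA_real_
    call <- "inconclusive"
  } else {
    frac_self <- counts[["self"]] / assigned
    frac_nonself <- counts[["nonself"]] / assigned
    call <- if (frac_nonself >= call_threshold) "contamination"
    else if (frac_self >= call_threshold) "endogenous/HTT-consistent"
    else "inconclusive"
  }
  structure(list(n_selected = sum(counts), counts = counts,
                 n_assigned = assigned, frac_self = frac_self,
                 frac_nonself = frac_nonself, call = call,
                 call_threshold = call_threshold),
            class = "contest_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contest_summary <- function(x, ...) {
  cat("Contamination/HTT test summary\n")
  cat(sprintf("  selected reads: %d (self %d, non-self %d, ambiguous %d, unassigned %d, low-quality %d)\n",
              x$n_selected, x$counts[["self"]], x$counts[["nonself"]],
              x$counts[["ambiguous"]], x$counts[["unassigned"]],
              x$counts[["low_quality"]]))
  if (x$n_assigned > 0)
    cat(sprintf("  frac self %.3f / non-self %.3f over %d assigned reads\n",
                x$frac_self, x$frac_nonself, x$n_assigned))
  cat("  call:", x$call, "\n")
  invisible(x)
}

#' Run the full contamination/HTT test
#'
#' Orchestrates selection (per mode), masking, classification and
#' summarization.
#'
#' @param mode `"long"` (long reads, translated selection), `"ref"`
#'   (read pairs against a reference assembly) or `"noref"` (read pairs,
#'   reference-free).
#' @param reads long-read [seq_tbl()] (mode `"long"`).
#' @param pairs pair data.frame (modes `"ref"`/`"noref"`).
#' @param rte_consensus single-row [seq_tbl()]: the element's nucleotide
#'   consensus; must also be present (same id) in the repeat library.
#' @param rte_orf_protein single-row protein [seq_tbl()] (mode `"long"`).
#' @param self_db,nonself_db databases for [classify_reads()].
#' @param own_species focal species tag.
#' @param repeat_library [seq_tbl()] of repeat consensus sequences.
#' @param reference assembly [seq_tbl()] (mode `"ref"`).
#' @param mappings read-to-reference placements (mode `"ref"`), see
#'   [select_pairs_reference()].
#' @param quality_min Phred threshold for pre-masking (`"noref"` mode; 0
#'   disables).
#' @param evalue_cutoff significance threshold used throughout.
#' @param call_threshold majority fraction for the final call.
#' @param min_informative minimum unmasked read length to classify.
#' @return list with `summary` ([summarize_contest()]), `per_read`
#'   (classifications), `informative` (selected mates/reads) and
#'   `n_input`.
#' @export
run_contest <- function(mode = c("long", "ref", "noref"),
                        reads = NULL, pairs = NULL,
                        rte_consensus, rte_orf_protein = NULL,
                        self_db, nonself_db, own_species,
                        repeat_library, reference = NULL, mappings = NULL,
                        quality_min = 20L, evalue_cutoff = 1e-10,
                        call_threshold = 0.80, min_informative = 30L) {
  mode <- match.arg(mode)
  scheme <- dna_scheme()
  lib_db <- as_dna_db(repeat_library, "repeats")
  rte_name <- rte_consensus$id[1]
  if (mode == "long") {
    stopifnot(!is.null(reads), !is.null(rte_orf_protein))
    n_input <- nrow(reads)
    informative <- select_long_reads(reads, rte_orf_protein, evalue_cutoff)
  } else if (mode == "ref") {
    stopifnot(!is.null(pairs), !is.null(reference), !is.null(mappings))
    n_input <- nrow(pairs)
    rte_bed <- reference_rte_bed(reference, rte_consensus,
                                 scheme = scheme,
                                 evalue_cutoff = evalue_cutoff)
    informative <- select_pairs_reference(pairs, mappings, rte_bed, lib_db,
                                          rte_name, evalue_cutoff, scheme)
  } else {
    stopifnot(!is.null(pairs))
    n_input <- nrow(pairs)
    if (quality_min > 0 && !any(is.na(pairs$qual1))) {
      m1 <- quality_mask(seq_tbl(paste0(pairs$pair_id, "/1"), pairs$seq1,
                                 qual = pairs$qual1), quality_min)
      m2 <- quality_mask(seq_tbl(paste0(pairs$pair_id, "/2"), pairs$seq2,
                                 qual = pairs$qual2), quality_min)
      pairs$seq1 <- m1$seq; pairs$seq2 <- m2$seq
    }
    informative <- select_pairs_noref(pairs, lib_db, rte_name,
                                      evalue_cutoff, scheme)
  }
  per_read <- classify_reads(informative, self_db, nonself_db, own_species,
                             lib_db, scheme, evalue_cutoff, min_informative)
  list(summary = summarize_contest(per_read, call_threshold),
       per_read = per_read, informative = informative, n_input = n_input)
}
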