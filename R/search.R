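# Seed-and-extend database search: exact k-mer seeds (11 nt / 5 aa) located
# through a data.table index, clustered per subject, then Smith-Waterman
# extension over the seeded window. Stands in for blastn/DIAMOND at desk
# scale; external engines can be substituted via the BLAST tabular
# interface (read_tabular_hits()).

#' Build a search database
#'
#' Indexes every record's k-mers (forward strand; queries are searched on
#' both strands) for seed lookup. The index is built once so repeated
#' [search_db()] calls against the same database are cheap.
#'
#' @param records [seq_tbl()]; every record should carry a `species` tag
#'   when the database is used for self/non-self classification.
#' @param label database label, e.g. `"self"` or `"non-self"`.
#' @param type `"dna"` (k = 11) or `"protein"` (k = 5).
#' @return object of class `search_database`.
#' @export
search_database <- function(records, label = "db", type = c("dna", "protein")) {
  type <- match.arg(type)
  if (nrow(records) == 0) stop("empty database")
  k <- if (type == "dna") 11L else 5L
  idx <- kmer_index(records$seq, k, type)
  structure(list(records = records, label = label, type = type, k = k,
                 index = idx, total_length = sum(nchar(records$seq))),
            class = "search_database")
}

kmer_index <- function(seqs, k, type) {
  tabs <- lapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i])
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    km <- substring(seqs[i], starts, starts + k - 1L)
    data.table::data.table(kmer = km, rec = i, pos = starts - 1L)
  })
  idx <- data.table::rbindlist(tabs)
  if (nrow(idx) > 0) {
    drop <- if (type == "dna") grepl("[^ACGT]", idx$kmer) else grepl("[X*]", idx$kmer)
    idx <- idx[!drop]
    data.table::setkey(idx, kmer)
  }
  idx
}

#' Search queries against a database
#'
#' Reports the best local alignment per seeded cluster with Karlin-Altschul
#' statistics. All reported hits satisfy `evalue <= evalue_cutoff` computed
#' with `n_eff` as the effective database size; passing the same `n_eff`
#' for two databases makes their E-values directly comparable (the
#' self/non-self contract). Hits are sorted per query by bitscore
#' (descending), then E-value, then subject id.
#'
#' @param queries [seq_tbl()] (or single sequence via `seq_tbl`).
#' @param db a [search_database()].
#' @param scheme scoring scheme matching the database type.
#' @param evalue_cutoff report hits with E-value at or below this.
#' @param n_eff effective database length for E-values (defaults to the
#'   database's own total length).
#' @return hit data.frame: `query_id`, `subject_id`, `subject_species`,
#'   `raw_score`, `bitscore`, `evalue`, `pident`, `length`, `mismatch`,
#'   `gapopen`, `qstart`/`qend` and `sstart`/`send` (0-based half-open,
#'   start < end; query span on the original query orientation), `strand`,
#'   `db_label`. Queries shorter than the seed size contribute no hits and
#'   are listed in `attr(, "short_queries")`.
#' @export
search_db <- function(queries, db, scheme = NULL, evalue_cutoff = 1e-10,
                      n_eff = NULL) {
  if (is.null(scheme))
    scheme <- if (db$type == "dna") dna_scheme() else protein_scheme()
  if (is.null(n_eff)) n_eff <- db$total_length
  k <- db$k
  qlen <- nchar(queries$seq)
  short <- queries$id[qlen < k]
  keep <- queries[qlen >= k, , drop = FALSE]
  out <- search_core(keep, db, scheme, evalue_cutoff, n_eff)
  attr(out, "short_queries") <- short
  out
}

search_core <- function(queries, db, scheme, evalue_cutoff, n_eff,
                        chunk = 2000L) {
  res <- list()
  if (nrow(queries) > 0) {
    for (lo in seq(1L, nrow(queries), by = chunk)) {
      qs <- queries[lo:min(lo + chunk - 1L, nrow(queries)), , drop = FALSE]
      res[[length(res) + 1L]] <-
        search_chunk(qs, db, scheme, evalue_cutoff, n_eff)
    }
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0) return(hit_tbl())
  out <- unique(out, by = c("query_id", "subject_id", "sstart", "send", "strand"))
  data.table::setorder(out, query_id, -bitscore, evalue, subject_id)
  out <- as.data.frame(out)
  out$db_label <- db$label
  out
}

search_chunk <- function(queries, db, scheme, evalue_cutoff, n_eff) {
  k <- db$k
  strands <- if (db$type == "dna") c("+", "-") else "+"
  qlen <- nchar(queries$seq)
  nk <- pmax(qlen - k + 1L, 0L)
  qtabs <- list()
  for (st in strands) {
    seqs <- if (st == "+") queries$seq else revcomp(queries$seq)
    qi <- rep.int(seq_len(nrow(queries)), nk)
    qpos <- unlist(lapply(nk, seq_len), use.names = FALSE) - 1L
    km <- substring(seqs[qi], qpos + 1L, qpos + k)
    qtabs[[st]] <- data.table::data.table(kmer = km, qi = qi, qpos = qpos,
                                          strand = st)
  }
  qdt <- data.table::rbindlist(qtabs)
  drop <- if (db$type == "dna") grepl("[^ACGT]", qdt$kmer) else grepl("[X*]", qdt$kmer)
  qdt <- qdt[!drop]
  if (nrow(qdt) == 0) return(NULL)
  cand <- db$index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0) return(NULL)
  cand[, ql := qlen[qi]]
  # cluster seeds by diagonal (tolerating indel drift) and then by subject
  # gap, so tandem or nearby repeat copies extend separately and windows
  # stay bounded
  cand[, diag := pos - qpos]
  data.table::setorder(cand, qi, strand, rec, diag, pos)
  cand[, cl := cumsum(c(1L, as.integer(diff(diag) > 200L |
                                         diff(pos) > ql[-1] + 50L))),
       by = .(qi, strand, rec)]
  groups <- cand[, .(smin = min(pos), smax = max(pos) + k,
                     qmin = min(qpos), qmax = max(qpos) + k, ql = ql[1],
                     dmin = min(diag), dmax = max(diag),
                     q1 = qpos[1], s1 = pos[1],
                     q2 = qpos[.N %/% 2L + 1L], s2 = pos[.N %/% 2L + 1L],
                     q3 = qpos[.N], s3 = pos[.N]),
                 by = .(qi, strand, rec, cl)]
  ng <- nrow(groups)
  g_qi <- groups$qi; g_st <- groups$strand; g_rec <- groups$rec
  g_smin <- groups$smin; g_smax <- groups$smax
  g_qmin <- groups$qmin; g_qmax <- groups$qmax; g_ql <- groups$ql
  g_dmin <- groups$dmin; g_dmax <- groups$dmax
  g_q1 <- groups$q1; g_s1 <- groups$s1
  g_q2 <- groups$q2; g_s2 <- groups$s2
  g_q3 <- groups$q3; g_s3 <- groups$s3
  # pre-allocated accumulators (cheaper than one data.table per group)
  o_keep <- logical(ng)
  o_score <- integer(ng); o_bits <- numeric(ng); o_ev <- numeric(ng)
  o_pid <- numeric(ng); o_len <- integer(ng); o_mm <- integer(ng)
  o_go <- integer(ng); o_q1 <- integer(ng); o_q2 <- integer(ng)
  o_s1 <- integer(ng); o_s2 <- integer(ng)
  pad <- 30L
  rc_cache <- list()
  for (g in seq_len(ng)) {
    subj <- db$records$seq[g_rec[g]]
    ws <- max(0L, g_smin[g] - g_qmin[g] - pad)
    we <- min(nchar(subj), g_smax[g] + (g_ql[g] - g_qmax[g]) + pad)
    # hard cap keeps any single extension's DP matrix bounded
    if (we - ws > g_ql[g] + 5000L) we <- ws + g_ql[g] + 5000L
    if (g_st[g] == "+") {
      qseq <- queries$seq[g_qi[g]]
    } else {
      key <- as.character(g_qi[g])
      if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(queries$seq[g_qi[g]])
      qseq <- rc_cache[[key]]
    }
    # cheap ungapped X-drop prefilter over three representative seeds
    # (first/middle/last of the cluster, so a stray near-diagonal chance
    # seed cannot hide a real cluster): chance singleton seeds (abundant
    # on long queries) never reach a gapped extension, while any hit
    # capable of passing the E-value cutoff sails through this bound
    ung <- ungapped_extend_cpp(qseq, subj, scheme$matrix, scheme$alphabet,
                               g_q1[g], g_s1[g], k, 20L)
    if (g_q2[g] != g_q1[g] || g_s2[g] != g_s1[g])
      ung <- max(ung, ungapped_extend_cpp(qseq, subj, scheme$matrix,
                                          scheme$alphabet, g_q2[g], g_s2[g],
                                          k, 20L))
    if (g_q3[g] != g_q2[g] || g_s3[g] != g_s2[g])
      ung <- max(ung, ungapped_extend_cpp(qseq, subj, scheme$matrix,
                                          scheme$alphabet, g_q3[g], g_s3[g],
                                          k, 20L))
    if (evalue(bitscore(max(ung, 0L), scheme), g_ql[g], n_eff) > 1)
      next
    if (as.numeric(g_ql[g]) * (we - ws) > 4e6) {
      # large extension: banded DP along the seeded diagonals, linear
      # memory in the query length
      drift <- 150L
      aln <- align_banded_cpp(qseq, subj, scheme$matrix, scheme$alphabet,
                              scheme$gap_open, scheme$gap_extend,
                              g_dmin[g] - drift, g_dmax[g] + drift)
      ws <- 0L
    } else {
      aln <- align_pair(qseq, substr(subj, ws + 1L, we), scheme, "local")
    }
    if (aln$score <= 0) next
    bits <- bitscore(aln$score, scheme)
    ev <- evalue(bits, g_ql[g], n_eff)
    if (ev > evalue_cutoff) next
    o_keep[g] <- TRUE
    o_score[g] <- aln$score; o_bits[g] <- bits; o_ev[g] <- ev
    o_pid[g] <- 100 * aln$matches / aln$ncols
    o_len[g] <- aln$ncols; o_mm[g] <- aln$mismatches; o_go[g] <- aln$gap_opens
    if (g_st[g] == "+") {
      o_q1[g] <- aln$a_start; o_q2[g] <- aln$a_end
    } else {  # map back onto the original query orientation
      o_q1[g] <- g_ql[g] - aln$a_end; o_q2[g] <- g_ql[g] - aln$a_start
    }
    o_s1[g] <- ws + aln$b_start; o_s2[g] <- ws + aln$b_end
  }
  if (!any(o_keep)) return(NULL)
  w <- which(o_keep)
  data.table::data.table(
    query_id = queries$id[g_qi[w]],
    subject_id = db$records$id[g_rec[w]],
    subject_species = db$records$species[g_rec[w]],
    raw_score = o_score[w], bitscore = o_bits[w], evalue = o_ev[w],
    pident = o_pid[w], length = o_len[w], mismatch = o_mm[w],
    gapopen = o_go[w], qstart = o_q1[w], qend = o_q2[w],
    sstart = o_s1[w], send = o_s2[w], strand = g_st[w])
}

#' Translated (six-frame) search of nucleotide reads against proteins
#'
#' Each read is translated in all six frames and every frame's peptide is
#' searched against the protein database (BLOSUM62 by default, k = 5 seed).
#' Hit query coordinates are mapped back to nucleotide positions on the
#' original read; E-values use the translated query length and the total
#' database protein length.
#'
#' @param reads nucleotide [seq_tbl()].
#' @param protein_db [search_database()] of type `"protein"`.
#' @param scheme protein scoring scheme.
#' @param evalue_cutoff maximum reported E-value.
#' @return hit data.frame as [search_db()] plus a `frame` column; `qstart`/
#'   `qend` are nucleotide coordinates on the read, `strand` the coding
#'   strand.
#' @export
translated_search <- function(reads, protein_db, scheme = protein_scheme(),
                              evalue_cutoff = 1e-10) {
  if (protein_db$type != "protein") stop("protein database required")
  ids <- character(0); seqs <- character(0); meta <- list()
  for (i in seq_len(nrow(reads))) {
    if (nchar(reads$seq[i]) < 3) next
    pep <- six_frame_translate(reads$seq[i])
    for (f in names(pep)) {
      if (nchar(pep[[f]]) == 0) next
      ids <- c(ids, paste0(reads$id[i], "\r", f))
      seqs <- c(seqs, pep[[f]])
    }
  }
  if (length(ids) == 0) {
    out <- hit_tbl(); out$frame <- character(0); return(out)
  }
  hits <- search_db(seq_tbl(ids, seqs), protein_db, scheme, evalue_cutoff)
  if (nrow(hits) == 0) { hits$frame <- character(0); return(hits) }
  parts <- strsplit(hits$query_id, "\r", fixed = TRUE)
  hits$query_id <- vapply(parts, `[[`, "", 1)
  hits$frame <- vapply(parts, `[[`, "", 2)
  rl <- setNames(nchar(reads$seq), reads$id)[hits$query_id]
  off <- as.integer(substr(hits$frame, 2, 2)) - 1L
  fwd <- startsWith(hits$frame, "+")
  nt1 <- off + 3L * hits$qstart
  nt2 <- off + 3L * hits$qend
  hits$qstart <- ifelse(fwd, nt1, rl - nt2)
  hits$qend <- ifelse(fwd, nt2, rl - nt1)
  hits$strand <- ifelse(fwd, "+", "-")
  data.table::setorder(data.table::setDT(hits),
                       query_id, -bitscore, evalue, subject_id)
  as.data.frame(hits)
}

# deterministic ranking shared by classification and reciprocal checks
rank_hits <- function(hits) {
  hits[order(-hits$bitscore, hits$evalue, hits$subject_id), , drop = FALSE]
}
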