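# Readers/writers for FASTA, FASTQ, BED, BLAST-style tabular and a SAM
# subset. Internal coordinates are 0-based half-open everywhere; 1-based
# inclusive external dialects (BLAST, SAM) are shifted at these boundaries
# only.

#' Read / write FASTA
#'
#' @param path file path.
#' @param species optional species tag applied to all records.
#' @return [seq_tbl()] (empty for an empty file).
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (file.size(path) == 0) return(seq_tbl(character(), character()))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1])
  seq_tbl(ids, toupper(as.character(x)), species = species)
}

#' @rdname read_fasta
#' @param records a [seq_tbl()].
#' @param width line-wrap width (0 for single-line records).
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    if (width > 0 && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @inheritParams read_fasta
#' @return [seq_tbl()] with `qual` populated.
#' @export
read_fastq <- function(path, species = NA_character_) {
  if (file.size(path) == 0) return(seq_tbl(character(), character()))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0) stop("truncated FASTQ record in ", path)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[seq(1, length(lines), 4)]))
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  quals <- lines[seq(4, length(lines), 4)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("sequence/quality length mismatch for record: ", ids[bad][1])
  seq_tbl(ids, seqs, qual = quals, species = species)
}

#' @rdname read_fastq
#' @param records a [seq_tbl()] with qualities.
#' @export
write_fastq <- function(records, path) {
  if (any(is.na(records$qual))) stop("records lack qualities")
  out <- character(4L * nrow(records))
  out[seq(1, length(out), 4)] <- paste0("@", records$id)
  out[seq(2, length(out), 4)] <- records$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- records$qual
  writeLines(out, path)
  invisible(path)
}

#' Mask low-quality bases
#'
#' Replaces bases with Phred quality below `min_q` by `N` (length
#' conserved), the masking analogue of `seqtk seq -q20`. Reads left with
#' more than half of their bases masked are flagged low-quality
#' (`low_quality` column) so downstream classification can exclude them.
#'
#' @param reads [seq_tbl()] with qualities.
#' @param min_q minimum Phred score to keep a base (default 20).
#' @return the sequence table with masked `seq` and a `low_quality` flag.
#' @export
quality_mask <- function(reads, min_q = 20L) {
  if (nrow(reads) == 0) { reads$low_quality <- logical(0); return(reads) }
  if (any(is.na(reads$qual))) stop("reads lack qualities")
  thr <- as.raw(min_q + 33L)
  N <- charToRaw("N")
  n_masked <- integer(nrow(reads))
  masked <- vapply(seq_len(nrow(reads)), function(i) {
    r <- charToRaw(reads$seq[i])
    low <- charToRaw(reads$qual[i]) < thr
    r[low] <- N
    n_masked[i] <<- sum(r == N)
    rawToChar(r)
  }, character(1))
  reads$seq <- masked
  reads$low_quality <- n_masked > nchar(masked) / 2
  reads
}

#' Read / write BED intervals
#'
#' BED3/BED6; BED is already 0-based half-open so coordinates pass through
#' unchanged. Missing strand is recorded as `+`.
#'
#' @param path file path.
#' @return data.frame with `seq_id`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED needs at least 3 columns: ", path)
  out <- data.frame(seq_id = as.character(x[[1]]),
                    start = as.integer(x[[2]]), end = as.integer(x[[3]]),
                    name = if (ncol(x) >= 4) as.character(x[[4]]) else ".",
                    score = if (ncol(x) >= 5) suppressWarnings(as.numeric(x[[5]])) else 0,
                    strand = if (ncol(x) >= 6) as.character(x[[6]]) else "+",
                    stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$start >= out$end))
    stop("invalid interval (need 0 <= start < end) in ", path)
  out
}

#' @rdname read_bed
#' @param intervals data.frame as returned by [read_bed()].
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$seq_id, intervals$start, intervals$end,
                   if (!is.null(intervals$name)) intervals$name else ".",
                   if (!is.null(intervals$score)) intervals$score else 0,
                   if (!is.null(intervals$strand)) intervals$strand else "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BLAST-style 12-column tabular hits
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Subject coordinates with sstart > send denote a
#' minus-strand hit; they are normalized to start < end plus a strand flag,
#' and all coordinates are shifted from 1-based inclusive to 0-based
#' half-open on reading (and back on writing).
#'
#' @param path file path.
#' @return hit data.frame (see [search_db()] for columns).
#' @export
read_tabular_hits <- function(path) {
  empty <- hit_tbl()
  if (file.size(path) == 0) return(empty)
  nf <- count.fields(path, sep = "\t", comment.char = "#")
  if (any(nf != 12))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12][1],
         " on line ", which(nf != 12)[1], " of ", path)
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  minus <- x[[9]] > x[[10]]
  s1 <- ifelse(minus, x[[10]], x[[9]])
  s2 <- ifelse(minus, x[[9]], x[[10]])
  data.frame(query_id = as.character(x[[1]]), subject_id = as.character(x[[2]]),
             subject_species = NA_character_,
             raw_score = NA_integer_, bitscore = x[[12]], evalue = x[[11]],
             pident = x[[3]], length = x[[4]], mismatch = x[[5]],
             gapopen = x[[6]],
             qstart = x[[7]] - 1L, qend = x[[8]],
             sstart = as.integer(s1) - 1L, send = as.integer(s2),
             strand = ifelse(minus, "-", "+"),
             stringsAsFactors = FALSE)
}

#' @rdname read_tabular_hits
#' @param hits hit data.frame.
#' @export
write_tabular_hits <- function(hits, path) {
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$send, hits$sstart + 1L)
  s2 <- ifelse(minus, hits$sstart + 1L, hits$send)
  df <- data.frame(hits$query_id, hits$subject_id,
                   sprintf("%.3f", hits$pident), hits$length, hits$mismatch,
                   hits$gapopen, hits$qstart + 1L, hits$qend, s1, s2,
                   format(hits$evalue, digits = 3, scientific = TRUE),
                   sprintf("%.1f", hits$bitscore))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# empty hit table shared by readers and the search engine
hit_tbl <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_species = character(), raw_score = integer(),
             bitscore = numeric(), evalue = numeric(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read / write a SAM subset
#'
#' Parses only the fields the pipeline needs (QNAME, FLAG, RNAME, POS,
#' CIGAR) from an uncompressed SAM file; the 1-based POS is shifted to
#' 0-based, the aligned reference span is derived from the CIGAR
#' (M/D/N/=/X consume reference), and mate/strand information is decoded
#' from FLAG bits 0x40/0x80/0x10.
#'
#' @param path SAM file path.
#' @return data.frame `read_id`, `seq_id`, `start`, `end`, `strand`, `mate`
#'   (1, 2 or NA), unmapped records dropped.
#' @export
read_samlite <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(read_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), mate = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 6))
    stop("malformed SAM line ", which(nfield < 6)[1], ": fewer than 6 fields")
  flag <- as.integer(vapply(f, `[[`, "", 2))
  pos <- as.integer(vapply(f, `[[`, "", 4))
  cigar <- vapply(f, `[[`, "", 6)
  reflen <- vapply(cigar, cigar_reflen, integer(1), USE.NAMES = FALSE)
  out <- data.frame(read_id = vapply(f, `[[`, "", 1),
                    seq_id = vapply(f, `[[`, "", 3),
                    start = pos - 1L, end = pos - 1L + reflen,
                    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
                    mate = ifelse(bitwAnd(flag, 64L) > 0, 1L,
                                  ifelse(bitwAnd(flag, 128L) > 0, 2L, NA_integer_)),
                    stringsAsFactors = FALSE)
  out[bitwAnd(flag, 4L) == 0 & out$seq_id != "*", , drop = FALSE]
}

#' @rdname read_samlite
#' @param mappings data.frame as returned by [read_samlite()], with an
#'   optional `seq` column written as the SEQ field.
#' @export
write_samlite <- function(mappings, path) {
  flag <- ifelse(is.na(mappings$mate), 0L,
                 ifelse(mappings$mate == 1L, 64L + 1L, 128L + 1L))
  flag <- flag + ifelse(mappings$strand == "-", 16L, 0L)
  len <- mappings$end - mappings$start
  seqf <- if (!is.null(mappings$seq)) mappings$seq else "*"
  df <- data.frame(mappings$read_id, flag, mappings$seq_id,
                   mappings$start + 1L, 60L, paste0(len, "M"),
                   "*", 0L, 0L, seqf, "*")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# reference-consuming length of a CIGAR string
cigar_reflen <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}
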