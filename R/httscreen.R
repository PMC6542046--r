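# Reciprocal best-hit screening of a retroelement library against genome
# sets: the primary-screen hits are extracted from the genomes,
# de-duplicated, searched back against the full element library, and only
# loci whose best reciprocal hit is the originating element are counted.

#' Screen genomes for retroelement candidates
#'
#' For every element and every genome: (1) search the element against the
#' genome, keeping hits with E-value at or below `evalue_cutoff` and
#' alignment length of at least `min_len`; (2) extract the hit
#' subsequences, de-duplicating identical loci (same sequence, coordinates
#' and strand); (3) search each extracted locus back against the full
#' element library and keep it only when its best hit (bitscore ranking) is
#' the originating element; (4) count reciprocal loci per element/species.
#' A species passes for an element when at least `min_hits` reciprocal loci
#' remain.
#'
#' @param rte_library [seq_tbl()] of element consensus sequences.
#' @param genomes [seq_tbl()] of genome sequences with `species` tags.
#' @param evalue_cutoff significance threshold (default 1e-10).
#' @param min_len minimum alignment length in bp (inclusive).
#' @param min_hits minimum reciprocal loci per species (inclusive).
#' @param scheme nucleotide scoring scheme.
#' @return data.frame: `rte`, `species`, `n_hits`, `n_reciprocal`,
#'   `passes`; the reciprocal loci are attached as `attr(, "loci")`.
#' @export
screen_rte <- function(rte_library, genomes, evalue_cutoff = 1e-10,
                       min_len = 100L, min_hits = 10L,
                       scheme = dna_scheme()) {
  empty <- data.frame(rte = character(), species = character(),
                      n_hits = integer(), n_reciprocal = integer(),
                      passes = logical(), stringsAsFactors = FALSE)
  if (nrow(rte_library) == 0 || nrow(genomes) == 0) return(empty)
  lib_db <- search_database(rte_library, label = "rte_library", type = "dna")
  gen_db <- search_database(genomes, label = "genomes", type = "dna")
  hits <- search_db(rte_library, gen_db, scheme, evalue_cutoff)
  hits <- hits[hits$length >= min_len, , drop = FALSE]
  if (nrow(hits) == 0) {
    loci <- NULL
  } else {
    # one row per (element, locus); identical coordinates extracted by the
    # same element are counted once
    hits$locus_id <- sprintf("%s:%d-%d(%s)", hits$subject_id, hits$sstart,
                             hits$send, hits$strand)
    loci <- hits[!duplicated(paste(hits$query_id, hits$locus_id)), ,
                 drop = FALSE]
    loci$species <- genomes$species[match(loci$subject_id, genomes$id)]
    # reciprocal search of each distinct locus back against the library;
    # a locus counts toward the element whose best reciprocal hit it is
    uniq <- loci[!duplicated(loci$locus_id), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(uniq)), function(i) {
      g <- genomes$seq[match(uniq$subject_id[i], genomes$id)]
      s <- substr(g, uniq$sstart[i] + 1L, uniq$send[i])
      if (uniq$strand[i] == "-") revcomp(s) else s
    }, character(1))
    back <- search_db(seq_tbl(uniq$locus_id, seqs), lib_db, scheme,
                      evalue_cutoff)
    best <- back[!duplicated(back$query_id), , drop = FALSE]
    origin <- setNames(best$subject_id, best$query_id)[loci$locus_id]
    loci$reciprocal <- !is.na(origin) & origin == loci$query_id
  }
  species <- unique(genomes$species)
  grid <- expand.grid(rte = rte_library$id, species = species,
                      stringsAsFactors = FALSE)
  grid$n_hits <- 0L; grid$n_reciprocal <- 0L
  if (!is.null(loci) && nrow(loci) > 0) {
    for (i in seq_len(nrow(grid))) {
      sel <- loci$query_id == grid$rte[i] & loci$species == grid$species[i]
      grid$n_hits[i] <- sum(sel)
      grid$n_reciprocal[i] <- sum(sel & loci$reciprocal)
    }
  }
  grid$passes <- grid$n_reciprocal >= min_hits
  grid <- grid[order(grid$rte, grid$species), , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "loci") <- loci
  grid
}

#' Translated screening of raw reads for the element ORF
#'
#' Searches reads in six frames against the element ORF protein and keeps
#' hits with amino-acid identity above `min_identity` percent and E-value
#' below `evalue_cutoff` — the read-level presence/absence check used for
#' close relatives of a putative HTT recipient.
#'
#' @param reads nucleotide [seq_tbl()].
#' @param rte_orf_protein protein [seq_tbl()] (or protein database).
#' @param evalue_cutoff E-value threshold (strict).
#' @param min_identity percent amino-acid identity threshold (strict).
#' @param scheme protein scoring scheme.
#' @return hit data.frame ([translated_search()] columns).
#' @export
screen_reads_translated <- function(reads, rte_orf_protein,
                                    evalue_cutoff = 1e-10,
                                    min_identity = 75,
                                    scheme = protein_scheme()) {
  db <- as_protein_db(rte_orf_protein)
  hits <- translated_search(reads, db, scheme, evalue_cutoff)
  hits[hits$pident > min_identity & hits$evalue < evalue_cutoff, ,
       drop = FALSE]
}
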