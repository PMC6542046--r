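# Seeded simulator of TE-bearing genomes, HTT vs contamination read sets
# and divergent copy families. Everything is driven by R's RNG from the
# config seed, so outputs are byte-identical across runs.

#' Scenario configuration
#'
#' Defaults describe the study regime the package targets: a ~3 kb
#' ORF-bearing retroelement, 30 copies in donor and recipient at 10%
#' copy divergence, 100 kb genome backgrounds separated by 20% between-
#' taxon divergence (deep host-parasite split) and 5% within-taxon
#' divergence, 2x150 read pairs at 20x coverage with 0.5% error, long
#' reads with 8 kb mean length, and 5% contaminating reads in the
#' contamination scenario.
#'
#' @param seed integer RNG seed.
#' @param scenario `"HTT"`, `"contamination"` or `"negative"`.
#' @param te_length element length (bp; rounded to whole codons).
#' @param n_copies_donor,n_copies_recipient planted copy numbers.
#' @param copy_divergence per-copy divergence from the family founder
#'   (substitutions/site, K2P process).
#' @param kappa transition/transversion rate ratio.
#' @param indel_rate per-site indel probability for copy evolution.
#' @param genome_length background genome length (bp); planted copies add
#'   to it.
#' @param background_divergence between-taxon background divergence
#'   (substitutions/site).
#' @param within_taxon_divergence focal-to-sister background divergence.
#' @param read_length,insert_mean,insert_sd,coverage paired-read model.
#' @param long_read_mean,long_read_coverage long-read model (exponential
#'   lengths).
#' @param error_rate per-base sequencing error probability.
#' @param contamination_fraction fraction of donor reads mixed in
#'   (contamination scenario).
#' @param n_db_genomes sister genomes per database.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            scenario = c("HTT", "contamination", "negative"),
                            te_length = 3000L, n_copies_donor = 30L,
                            n_copies_recipient = 30L, copy_divergence = 0.10,
                            kappa = 2.0, indel_rate = 0.002,
                            genome_length = 100000L,
                            background_divergence = 0.20,
                            within_taxon_divergence = 0.05,
                            read_length = 150L, insert_mean = 500L,
                            insert_sd = 50L, coverage = 20,
                            long_read_mean = 8000L, long_read_coverage = 5,
                            error_rate = 0.005,
                            contamination_fraction = 0.05,
                            n_db_genomes = 2L) {
  cfg <- list(seed = as.integer(seed), scenario = match.arg(scenario),
              te_length = te_length, n_copies_donor = n_copies_donor,
              n_copies_recipient = n_copies_recipient,
              copy_divergence = copy_divergence, kappa = kappa,
              indel_rate = indel_rate, genome_length = genome_length,
              background_divergence = background_divergence,
              within_taxon_divergence = within_taxon_divergence,
              read_length = read_length, insert_mean = insert_mean,
              insert_sd = insert_sd, coverage = coverage,
              long_read_mean = long_read_mean,
              long_read_coverage = long_read_coverage,
              error_rate = error_rate,
              contamination_fraction = contamination_fraction,
              n_db_genomes = n_db_genomes)
  rates <- c(cfg$copy_divergence, cfg$indel_rate, cfg$error_rate,
             cfg$contamination_fraction, cfg$background_divergence,
             cfg$within_taxon_divergence)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$te_length <= 0 || cfg$genome_length <= 0 || cfg$read_length <= 0)
    stop("lengths must be positive")
  class(cfg) <- "scenario_config"
  cfg
}

#' Evolve a sequence under the Kimura 2-parameter process
#'
#' Substitutions follow the closed-form K80 transition probabilities for
#' branch length `d` (expected substitutions/site), so multiple hits are
#' modelled and K2P estimates of evolved copies recover `d`. Indels
#' (insertions/deletions of 1-3 bp, equal probability) occur at
#' `indel_rate` per site.
#'
#' @param seq nucleotide string.
#' @param d branch length (substitutions/site).
#' @param kappa transition/transversion rate ratio.
#' @param indel_rate per-site indel probability.
#' @return list: `seq` (evolved), `realized_divergence` (observed mismatch
#'   fraction vs the input, before indels).
#' @export
evolve_seq <- function(seq, d, kappa = 2.0, indel_rate = 0) {
  L <- nchar(seq)
  mut <- k80_mutate_cpp(seq, d, kappa, runif(L), runif(L))
  realized <- mismatch_fraction(seq, mut)
  if (indel_rate > 0) {
    n_events <- stats::rbinom(1, L, indel_rate)
    if (n_events > 0) {
      chars <- strsplit(mut, "", fixed = TRUE)[[1]]
      pos <- sort(sample.int(length(chars), n_events), decreasing = TRUE)
      for (p in pos) {
        len <- sample.int(3L, 1L)
        if (runif(1) < 0.5) {  # deletion
          chars <- chars[-(p:min(p + len - 1L, length(chars)))]
        } else {               # insertion after p
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          chars <- append(chars, ins, after = p)
        }
      }
      mut <- paste(chars, collapse = "")
    }
  }
  list(seq = mut, realized_divergence = realized)
}

mismatch_fraction <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  sum(av != bv) / length(av)
}

#' Evolve a family of element copies from an ancestor
#'
#' @param ancestor ancestral element sequence (string).
#' @param n number of copies.
#' @param divergence per-copy branch length (substitutions/site).
#' @param kappa transition/transversion ratio.
#' @param indel_rate per-site indel probability.
#' @param prefix id prefix for the copies.
#' @return list: `copies` ([seq_tbl()]), `divergence` (data.frame `id`,
#'   `model_d`, `realized` observed mismatch fraction).
#' @export
evolve_te_family <- function(ancestor, n, divergence, kappa = 2.0,
                             indel_rate = 0, prefix = "copy") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  seqs <- character(n); realized <- numeric(n)
  for (i in seq_len(n)) {
    ev <- evolve_seq(ancestor, divergence, kappa, indel_rate)
    seqs[i] <- ev$seq
    realized[i] <- ev$realized_divergence
  }
  list(copies = seq_tbl(ids, seqs),
       divergence = data.frame(id = ids, model_d = divergence,
                               realized = realized,
                               stringsAsFactors = FALSE))
}

# random element whose forward frame is one long ORF (ATG ... TAA)
random_orf_te <- function(len) {
  n_codons <- max(10L, len %/% 3L - 2L)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), 3 * (n_codons + 20),
                                replace = TRUE), nrow = 3), 2, paste,
                  collapse = "")
  codons <- codons[!codons %in% stops][seq_len(n_codons)]
  paste(c("ATG", codons, "TAA"), collapse = "")
}

# insert copies into a background at random, non-overlapping points;
# returns the final sequence plus the planted spans in its coordinates
insert_copies <- function(background, copies, families, strands = NULL) {
  n <- nrow(copies)
  if (n == 0)
    return(list(seq = background,
                planted = data.frame(copy_id = character(), family = character(),
                                     start = integer(), end = integer(),
                                     strand = character(),
                                     stringsAsFactors = FALSE)))
  if (is.null(strands)) strands <- sample(c("+", "-"), n, replace = TRUE)
  points <- sort(sample.int(nchar(background) - 1L, n))
  ins <- ifelse(strands == "-", revcomp(copies$seq), copies$seq)
  pieces <- character(2 * n + 1)
  planted_start <- integer(n)
  prev <- 0L; off <- 0L
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- substr(background, prev + 1L, points[i])
    pieces[2 * i] <- ins[i]
    planted_start[i] <- points[i] + off
    off <- off + nchar(ins[i])
    prev <- points[i]
  }
  pieces[2 * n + 1] <- substr(background, prev + 1L, nchar(background))
  list(seq = paste(pieces, collapse = ""),
       planted = data.frame(copy_id = copies$id, family = families,
                            start = planted_start,
                            end = planted_start + nchar(ins),
                            strand = strands, stringsAsFactors = FALSE))
}

#' Simulate paired-end reads
#'
#' Fragment starts are uniform, insert lengths Normal(`insert_mean`,
#' `insert_sd`) truncated to at least twice the read length, mate 2 is the
#' reverse complement of the fragment end (FR orientation). Per-base errors
#' occur at `error_rate`; error positions get Phred 11 qualities (`,`),
#' all other bases Phred 40 (`I`).
#'
#' @param genome genome string.
#' @param coverage target read coverage (both mates counted).
#' @param cfg [scenario_config()].
#' @param prefix pair-id prefix.
#' @return list: `pairs` (data.frame `pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), `coords` (data.frame `read_id`, `mate`, `start`, `end`
#'   0-based half-open fragment-mate spans on the genome).
#' @export
simulate_paired_reads <- function(genome, coverage, cfg, prefix = "p") {
  G <- nchar(genome); rl <- cfg$read_length
  if (G < 2 * rl) stop("genome shorter than one read pair")
  n <- max(1L, round(coverage * G / (2 * rl)))
  ins <- round(rnorm(n, cfg$insert_mean, cfg$insert_sd))
  ins <- pmin(pmax(ins, 2L * rl), G)
  start <- floor(runif(n, 0, G - ins + 1))  # 0-based fragment start
  s1 <- substring(genome, start + 1L, start + rl)
  s2 <- revcomp(substring(genome, start + ins - rl + 1L, start + ins))
  e1 <- add_errors(s1, cfg$error_rate)
  e2 <- add_errors(s2, cfg$error_rate)
  pid <- sprintf("%s%06d", prefix, seq_len(n))
  list(pairs = data.frame(pair_id = pid, seq1 = e1$seq, qual1 = e1$qual,
                          seq2 = e2$seq, qual2 = e2$qual,
                          stringsAsFactors = FALSE),
       coords = data.frame(
         read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
         mate = rep(1:2, each = n),
         start = c(start, start + ins - rl),
         end = c(start + rl, start + ins),
         stringsAsFactors = FALSE))
}

#' Simulate long reads
#'
#' Exponential read lengths (mean `long_read_mean`, clipped to
#' `[500, genome]`), uniform starts, random strand, same error model as
#' [simulate_paired_reads()].
#'
#' @inheritParams simulate_paired_reads
#' @return list: `reads` ([seq_tbl()]), `coords` (data.frame `read_id`,
#'   `start`, `end`, `strand`).
#' @export
simulate_long_reads <- function(genome, coverage, cfg, prefix = "L") {
  G <- nchar(genome)
  n <- max(1L, round(coverage * G / cfg$long_read_mean))
  len <- pmin(pmax(round(rexp(n, 1 / cfg$long_read_mean)), 500L), G)
  start <- floor(runif(n, 0, G - len + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  s <- substring(genome, start + 1L, start + len)
  s <- ifelse(strand == "-", revcomp(s), s)
  e <- add_errors(s, cfg$error_rate)
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  list(reads = seq_tbl(ids, e$seq, qual = e$qual),
       coords = data.frame(read_id = ids, start = start, end = start + len,
                           strand = strand, stringsAsFactors = FALSE))
}

add_errors <- function(seqs, error_rate) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  if (error_rate > 0) {
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[i])
      ne <- stats::rbinom(1, n, error_rate)
      if (ne == 0) next
      pos <- sample.int(n, ne)
      sc <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      qc <- strsplit(qual[i], "", fixed = TRUE)[[1]]
      for (p in pos) {
        sc[p] <- sample(setdiff(c("A", "C", "G", "T"), sc[p]), 1)
        qc[p] <- ","  # Phred 11
      }
      seqs[i] <- paste(sc, collapse = "")
      qual[i] <- paste(qc, collapse = "")
    }
  }
  list(seq = seqs, qual = qual)
}

#' Build a full test scenario
#'
#' Generates the element family, donor and recipient genomes, self/non-self
#' sister-genome databases, paired and long reads with per-read truth
#' labels, and reference mappings, under one of three scenarios:
#'
#' * `HTT`: the element is planted in both genomes (the recipient family
#'   seeded from the donor lineage); all reads come from the recipient.
#' * `contamination`: the element is planted only in the donor; donor reads
#'   are mixed into the recipient read set at `contamination_fraction`, and
#'   the "assembly" additionally contains the donor sequence as a
#'   co-assembled contaminant contig.
#' * `negative`: no shared element; only a decoy repeat family is planted.
#'
#' Backgrounds descend from a common root (between-taxon divergence
#' `background_divergence`, within-taxon `within_taxon_divergence`), so
#' self vs non-self classification is learnable but not trivial. The decoy
#' repeat family exercises reciprocal checks and masking.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `scenario`: `config`, `repeat_library`,
#'   `rte_consensus`, `rte_orf_protein`, `recipient_genome`,
#'   `donor_genome`, `assembly`, `self_db`, `nonself_db`, `own_species`,
#'   `pairs`, `long_reads`, `mappings`, `truth` (per-pair/long-read origin
#'   and TE-overlap flags), `planted` (copy registry with realized
#'   divergences).
#' @export
build_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  te_anc <- random_orf_te(cfg$te_length)
  decoy_anc <- random_dna(800L)
  rte_name <- "RTE1_SIM"
  repeat_library <- seq_tbl(c(rte_name, "DECOY_SIM"), c(te_anc, decoy_anc))
  orf <- sub("\\*$", "", six_frame_translate(te_anc)[["+1"]])
  rte_orf_protein <- seq_tbl(paste0(rte_name, "_1p"), orf)

  # backgrounds: root -> taxon ancestors -> focal + sister species
  root <- random_dna(cfg$genome_length)
  half <- cfg$background_divergence / 2
  rec_taxon <- evolve_seq(root, half, cfg$kappa)$seq
  don_taxon <- evolve_seq(root, half, cfg$kappa)$seq
  rec_bg <- evolve_seq(rec_taxon, cfg$within_taxon_divergence, cfg$kappa)$seq
  don_bg <- evolve_seq(don_taxon, cfg$within_taxon_divergence, cfg$kappa)$seq
  sisters <- function(taxon, tag) {
    seq_tbl(paste0(tag, seq_len(cfg$n_db_genomes)),
            vapply(seq_len(cfg$n_db_genomes), function(i)
              evolve_seq(taxon, cfg$within_taxon_divergence, cfg$kappa)$seq,
              character(1)),
            species = paste0(tag, seq_len(cfg$n_db_genomes)))
  }
  self_recs <- sisters(rec_taxon, "self_sp")
  nonself_recs <- sisters(don_taxon, "nonself_sp")

  # element copies per scenario
  donor_has_te <- cfg$scenario %in% c("HTT", "contamination")
  recipient_has_te <- cfg$scenario == "HTT"
  don_fam <- if (donor_has_te)
    evolve_te_family(te_anc, cfg$n_copies_donor, cfg$copy_divergence,
                     cfg$kappa, cfg$indel_rate, prefix = "donTE")
  rec_founder <- if (recipient_has_te)
    evolve_seq(te_anc, 0.02, cfg$kappa)$seq  # recent transfer from the donor lineage
  rec_fam <- if (recipient_has_te)
    evolve_te_family(rec_founder, cfg$n_copies_recipient,
                     cfg$copy_divergence, cfg$kappa, cfg$indel_rate,
                     prefix = "recTE")
  decoys <- function(prefix) evolve_te_family(decoy_anc, 5L, 0.10, cfg$kappa,
                                              cfg$indel_rate, prefix = prefix)

  plant <- function(bg, fam, decoy_fam) {
    copies <- rbind(if (!is.null(fam)) fam$copies else NULL,
                    decoy_fam$copies)
    families <- c(if (!is.null(fam)) rep(rte_name, nrow(fam$copies)),
                  rep("DECOY_SIM", nrow(decoy_fam$copies)))
    insert_copies(bg, copies, families)
  }
  rec_ins <- plant(rec_bg, rec_fam, decoys("recDec"))
  don_ins <- plant(don_bg, don_fam, decoys("donDec"))
  recipient_genome <- seq_tbl("recipient", rec_ins$seq, species = "recipient")
  donor_genome <- seq_tbl("donor", don_ins$seq, species = "donor")

  # reads
  rp <- simulate_paired_reads(rec_ins$seq, cfg$coverage, cfg, prefix = "rec_p")
  rl <- simulate_long_reads(rec_ins$seq, cfg$long_read_coverage, cfg,
                            prefix = "rec_L")
  pairs <- rp$pairs; pair_src <- rep("recipient", nrow(rp$pairs))
  pair_coords <- cbind(rp$coords, seq_id = "recipient",
                       stringsAsFactors = FALSE)
  long_reads <- rl$reads
  long_src <- rep("recipient", nrow(rl$reads))
  long_coords <- cbind(rl$coords, seq_id = "recipient",
                       stringsAsFactors = FALSE)
  assembly <- recipient_genome
  if (cfg$scenario == "contamination") {
    # donor coverage chosen so donor pairs make up contamination_fraction
    # of the pooled pair set regardless of the two genome lengths
    cf <- cfg$contamination_fraction
    n_don <- max(1L, round(cf / (1 - cf) * nrow(rp$pairs)))
    cov_don <- n_don * 2 * cfg$read_length / nchar(don_ins$seq)
    n_don_long <- max(1L, round(cf / (1 - cf) * nrow(rl$reads)))
    cov_don_long <- n_don_long * cfg$long_read_mean / nchar(don_ins$seq)
    dp <- simulate_paired_reads(don_ins$seq, cov_don, cfg, prefix = "don_p")
    dl <- simulate_long_reads(don_ins$seq, cov_don_long, cfg,
                              prefix = "don_L")
    pairs <- rbind(pairs, dp$pairs)
    pair_src <- c(pair_src, rep("donor", nrow(dp$pairs)))
    pair_coords <- rbind(pair_coords,
                         cbind(dp$coords, seq_id = "donor_contig",
                               stringsAsFactors = FALSE))
    long_reads <- rbind(long_reads, dl$reads)
    long_src <- c(long_src, rep("donor", nrow(dl$reads)))
    long_coords <- rbind(long_coords,
                         cbind(dl$coords, seq_id = "donor_contig",
                               stringsAsFactors = FALSE))
    # contaminant reads co-assemble into an extra contig
    assembly <- rbind(assembly,
                      seq_tbl("donor_contig", don_ins$seq,
                              species = "recipient"))
    class(assembly) <- c("seq_tbl", "data.frame")
  }

  te_iv <- function(planted, genome_id) {
    p <- planted[planted$family == rte_name, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    cbind(p, seq_id = genome_id, stringsAsFactors = FALSE)
  }
  te_spans <- rbind(te_iv(rec_ins$planted, "recipient"),
                    te_iv(don_ins$planted, "donor_contig"))
  overlaps_te <- function(seq_ids, starts, ends) {
    if (is.null(te_spans)) return(rep(FALSE, length(starts)))
    out <- rep(FALSE, length(starts))
    for (sid in unique(te_spans$seq_id)) {
      sel <- seq_ids == sid |
        (sid == "donor_contig" & seq_ids == "donor")
      if (!any(sel)) next
      sp <- te_spans[te_spans$seq_id == sid, , drop = FALSE]
      out[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(starts[sel] + 1L, ends[sel]),
        IRanges::IRanges(sp$start + 1L, sp$end))
    }
    out
  }
  pc <- pair_coords
  pc$te <- overlaps_te(pc$seq_id, pc$start, pc$end)
  pair_te <- tapply(pc$te, sub("/[12]$", "", pc$read_id), any)
  truth_pairs <- data.frame(pair_id = pairs$pair_id, origin = pair_src,
                            te_overlap = as.logical(pair_te[pairs$pair_id]),
                            stringsAsFactors = FALSE)
  truth_long <- data.frame(read_id = long_reads$id, origin = long_src,
                           te_overlap = overlaps_te(long_coords$seq_id,
                                                    long_coords$start,
                                                    long_coords$end),
                           stringsAsFactors = FALSE)

  planted <- rbind(
    cbind(genome = "recipient", rec_ins$planted, stringsAsFactors = FALSE),
    cbind(genome = "donor", don_ins$planted, stringsAsFactors = FALSE))
  div <- rbind(if (!is.null(don_fam)) don_fam$divergence,
               if (!is.null(rec_fam)) rec_fam$divergence)
  planted$true_divergence <-
    if (is.null(div)) NA_real_ else div$realized[match(planted$copy_id, div$id)]

  structure(list(
    config = cfg, repeat_library = repeat_library,
    rte_consensus = repeat_library[1, , drop = FALSE],
    rte_orf_protein = rte_orf_protein,
    recipient_genome = recipient_genome, donor_genome = donor_genome,
    assembly = assembly, self_db = self_recs, nonself_db = nonself_recs,
    own_species = "recipient",
    pairs = pairs, long_reads = long_reads, mappings = pair_coords,
    truth = list(pairs = truth_pairs, long_reads = truth_long),
    planted = planted,
    te_ancestor = te_anc,
    recipient_te_founder = if (recipient_has_te) rec_founder else NULL,
    donor_copies = if (donor_has_te) don_fam$copies else NULL,
    recipient_copies = if (recipient_has_te) rec_fam$copies else NULL),
    class = "scenario")
}

#' Simulate a multi-lineage element panel for topology tests
#'
#' Four donor-taxon lineages diverge along a ladder from the family
#' ancestor; the recipient's family is seeded from the most recently
#' diverged lineage (a recent horizontal transfer). Per-species copy sets
#' are evolved from each founder, mirroring the situation where a
#' horizontally transferred element nests inside the donor clade of the
#' element tree.
#'
#' @param seed RNG seed.
#' @param n_per_species copies evolved per species.
#' @param te_length element length (bp).
#' @param copy_divergence per-copy branch length.
#' @param kappa,indel_rate evolution parameters.
#' @return list: `ancestor`, `founders` (named), `copies` (named list of
#'   [seq_tbl()]), `seeding_lineage` (`"D4"`), `recipient` (`"REC"`).
#' @export
simulate_lineage_panel <- function(seed = 1L, n_per_species = 15L,
                                   te_length = 3000L, copy_divergence = 0.05,
                                   kappa = 2.0, indel_rate = 0.002) {
  set.seed(seed)
  anc <- random_orf_te(te_length)
  d1 <- evolve_seq(anc, 0.15, kappa)$seq
  t1 <- evolve_seq(anc, 0.05, kappa)$seq
  d2 <- evolve_seq(t1, 0.10, kappa)$seq
  t2 <- evolve_seq(t1, 0.05, kappa)$seq
  d3 <- evolve_seq(t2, 0.05, kappa)$seq
  d4 <- evolve_seq(t2, 0.05, kappa)$seq
  rec <- evolve_seq(d4, 0.02, kappa)$seq  # recent transfer off lineage D4
  founders <- c(D1 = d1, D2 = d2, D3 = d3, D4 = d4, REC = rec)
  copies <- lapply(names(founders), function(sp)
    evolve_te_family(founders[[sp]], n_per_species, copy_divergence,
                     kappa, indel_rate, prefix = paste0(sp, "_"))$copies)
  names(copies) <- names(founders)
  list(ancestor = anc, founders = founders, copies = copies,
       seeding_lineage = "D4", recipient = "REC")
}

#' Write a scenario to disk
#'
#' FASTA genomes/databases/library, FASTQ reads, SAM mappings, truth TSV
#' and a JSON config — the on-disk layout consumed by the command-line
#' interface.
#'
#' @param scn a [build_scenario()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta(scn$assembly, p("assembly.fa"))
  write_fasta(scn$self_db, p("self_db.fa"))
  write_fasta(scn$nonself_db, p("nonself_db.fa"))
  write_fasta(scn$repeat_library, p("repeat_library.fa"))
  write_fasta(scn$rte_orf_protein, p("rte_orf.faa"))
  m1 <- seq_tbl(paste0(scn$pairs$pair_id, "/1"), scn$pairs$seq1,
                qual = scn$pairs$qual1)
  m2 <- seq_tbl(paste0(scn$pairs$pair_id, "/2"), scn$pairs$seq2,
                qual = scn$pairs$qual2)
  write_fastq(m1, p("reads_1.fq"))
  write_fastq(m2, p("reads_2.fq"))
  write_fastq(scn$long_reads, p("long_reads.fq"))
  mp <- scn$mappings
  mp$strand <- "+"
  write_samlite(mp, p("mappings.sam"))
  write.table(scn$truth$pairs, p("truth_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(scn$truth$long_reads, p("truth_long_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(scn$config), p("config.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}
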