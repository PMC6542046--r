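# Small hand-built fixtures: a 600 bp element with a decoy family, tiny
# self/non-self databases, and reads constructed directly from known
# sources, so every verdict can be predicted.

make_fixture <- function(seed = 51) {
  set.seed(seed)
  te <- rand_dna(600)
  decoy <- rand_dna(400)
  lib <- seq_tbl(c("RTE_X", "DECOY"), c(te, decoy))
  self_bg <- rand_dna(4000)
  nonself_bg <- rand_dna(4000)
  # sister genomes: lightly mutated focal backgrounds
  self_db <- seq_tbl(c("sA", "sB"),
                     c(mutate_at(self_bg, 200)$seq, mutate_at(self_bg, 200)$seq),
                     species = c("sA", "sB"))
  nonself_db <- seq_tbl(c("nA", "nB"),
                        c(mutate_at(nonself_bg, 200)$seq,
                          mutate_at(nonself_bg, 200)$seq),
                        species = c("nA", "nB"))
  list(te = te, decoy = decoy, lib = lib, self_bg = self_bg,
       nonself_bg = nonself_bg, self_db = self_db, nonself_db = nonself_db)
}

test_that("pair selection without a reference returns the informative mate
           and drops both-element pairs", {
  fx <- make_fixture()
  q <- strrep("I", 150)
  pairs <- data.frame(
    pair_id = c("p1", "p2", "p3"),
    seq1 = c(substr(fx$te, 1, 150),          # element mate
             substr(fx$te, 101, 250),        # element mate
             substr(fx$self_bg, 1, 150)),    # background pair
    qual1 = q,
    seq2 = c(substr(fx$self_bg, 201, 350),   # informative flank
             substr(fx$te, 301, 450),        # second element mate -> drop
             substr(fx$self_bg, 501, 650)),
    qual2 = q, stringsAsFactors = FALSE)
  sel <- select_pairs_noref(pairs, fx$lib, "RTE_X")
  expect_equal(sel$id, "p1/2")
  expect_equal(sel$seq, pairs$seq2[1])
  expect_equal(attr(sel, "n_pairs_both_te"), 1L)
})

test_that("a mate whose best repeat hit is the decoy is not selected", {
  fx <- make_fixture(52)
  q <- strrep("I", 150)
  pairs <- data.frame(pair_id = "p1",
                      seq1 = substr(fx$decoy, 1, 150),
                      qual1 = q,
                      seq2 = substr(fx$self_bg, 1, 150),
                      qual2 = q, stringsAsFactors = FALSE)
  sel <- select_pairs_noref(pairs, fx$lib, "RTE_X")
  expect_equal(nrow(sel), 0)
})

test_that("reference-based selection keeps exactly-one-mate pairs and
           discards both-in-element pairs", {
  fx <- make_fixture(53)
  # reference: background with one element copy at 1000
  ref_seq <- paste0(substr(fx$self_bg, 1, 1000), fx$te,
                    substr(fx$self_bg, 1001, 4000))
  reference <- seq_tbl("chr", ref_seq)
  rte_bed <- reference_rte_bed(reference, seq_tbl("RTE_X", fx$te))
  expect_equal(nrow(rte_bed), 1)
  q <- strrep("I", 150)
  pairs <- data.frame(
    pair_id = c("in1", "both", "out"),
    seq1 = c(substr(ref_seq, 1101, 1250),   # inside element
             substr(ref_seq, 1101, 1250),
             substr(ref_seq, 1, 150)),      # background
    qual1 = q,
    seq2 = c(substr(ref_seq, 601, 750),     # flank -> informative
             substr(ref_seq, 1301, 1450),   # also inside element
             substr(ref_seq, 401, 550)),
    qual2 = q, stringsAsFactors = FALSE)
  mappings <- data.frame(
    read_id = c("in1/1", "in1/2", "both/1", "both/2", "out/1", "out/2"),
    seq_id = "chr",
    start = c(1100L, 600L, 1100L, 1300L, 0L, 400L),
    end = c(1250L, 750L, 1250L, 1450L, 150L, 550L),
    mate = c(1L, 2L, 1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  sel <- select_pairs_reference(pairs, mappings, rte_bed, fx$lib, "RTE_X")
  expect_equal(sel$id, "in1/2")
  expect_equal(attr(sel, "n_pairs_both_te"), 1L)
})

test_that("long-read selection requires a translated element hit", {
  set.seed(54)
  # an element that codes for protein: use a random ORF
  codons <- names(oracle_codon_table)[!oracle_codon_table %in% "*"]
  te <- paste(c("ATG", sample(codons, 200, TRUE), "TAA"), collapse = "")
  orf <- seq_tbl("orf", sub("\\*$", "", oracle_translate(te)))
  bg <- rand_dna(2000)
  reads <- seq_tbl(c("te_read", "bg_read"),
                   c(paste0(substr(bg, 1, 300), substr(te, 1, 350),
                            substr(bg, 301, 600)),
                     substr(bg, 601, 1550)))
  sel <- select_long_reads(reads, orf)
  expect_equal(sel$id, "te_read")
})

test_that("classification decides by best-database origin; own-species hits
           are discarded; database record order and read orientation do not
           matter", {
  fx <- make_fixture(55)
  reads <- seq_tbl(c("selfish", "alien"),
                   c(substr(fx$self_bg, 801, 950),
                     substr(fx$nonself_bg, 801, 950)))
  cl <- classify_reads(reads, fx$self_db, fx$nonself_db, "me", fx$lib)
  expect_equal(cl$verdict, c("self", "non-self"))
  # order of database records is irrelevant
  self_rev <- fx$self_db[2:1, , drop = FALSE]
  nonself_rev <- fx$nonself_db[2:1, , drop = FALSE]
  cl2 <- classify_reads(reads, self_rev, nonself_rev, "me", fx$lib)
  expect_equal(cl2$verdict, cl$verdict)
  expect_equal(cl2$bitscore, cl$bitscore)
  # reverse-complemented reads classify identically
  rc <- seq_tbl(reads$id, revcomp(reads$seq))
  cl3 <- classify_reads(rc, fx$self_db, fx$nonself_db, "me", fx$lib)
  expect_equal(cl3$verdict, cl$verdict)
  expect_equal(cl3$bitscore, cl$bitscore)
})

test_that("a read whose only hit is the focal species' own genome ends up
           unassigned; removing the own genome from the database changes no
           verdict", {
  fx <- make_fixture(56)
  own_private <- rand_dna(2000)  # sequence present only in the own genome
  self_with_own <- rbind(fx$self_db,
                         seq_tbl("own", own_private, species = "me"))
  class(self_with_own) <- c("seq_tbl", "data.frame")
  reads <- seq_tbl(c("own_only", "selfish"),
                   c(substr(own_private, 501, 650),
                     substr(fx$self_bg, 801, 950)))
  cl <- classify_reads(reads, self_with_own, fx$nonself_db, "me", fx$lib)
  expect_equal(cl$verdict[cl$read_id == "own_only"], "unassigned")
  expect_gt(cl$discarded_own_genome_hits[cl$read_id == "own_only"], 0)
  cl_no_own <- classify_reads(reads, fx$self_db, fx$nonself_db, "me", fx$lib)
  expect_equal(cl_no_own$verdict, cl$verdict)
})

test_that("element-covered reads are masked to nothing and flagged
           low-quality rather than classified", {
  fx <- make_fixture(57)
  reads <- seq_tbl("te_read", substr(fx$te, 101, 250))
  cl <- classify_reads(reads, fx$self_db, fx$nonself_db, "me", fx$lib)
  expect_equal(cl$verdict, "low-quality")
})

test_that("every selected read lands in exactly one verdict class", {
  fx <- make_fixture(58)
  reads <- seq_tbl(paste0("r", 1:6),
                   c(substr(fx$self_bg, 1, 150),
                     substr(fx$self_bg, 1001, 1150),
                     substr(fx$nonself_bg, 1, 150),
                     substr(fx$te, 1, 150),
                     rand_dna(150),
                     substr(fx$self_bg, 2001, 2150)))
  cl <- classify_reads(reads, fx$self_db, fx$nonself_db, "me", fx$lib)
  expect_equal(nrow(cl), 6)
  expect_true(all(cl$verdict %in%
    c("self", "non-self", "ambiguous", "unassigned", "low-quality")))
  s <- summarize_contest(cl)
  expect_equal(s$n_selected, 6)
  expect_equal(sum(s$counts), 6)
})

test_that("summary fractions follow the printed-count arithmetic", {
  s <- summarize_contest(list(self = 169, nonself = 5309))
  expect_equal(s$n_assigned, 5478)
  expect_equal(s$frac_nonself, 5309 / 5478, tolerance = 1e-12)
  expect_equal(round(s$frac_nonself, 2), 0.97)
  expect_equal(s$call, "contamination")

  s2 <- summarize_contest(list(self = 10, nonself = 0))
  expect_equal(s2$frac_self, 1.0)
  expect_equal(s2$call, "endogenous/HTT-consistent")

  expect_warning(s3 <- summarize_contest(list(self = 0, nonself = 0)),
                 "inconclusive")
  expect_equal(s3$call, "inconclusive")

  set.seed(59)
  for (i in 1:20) {
    k <- sample(0:500, 2)
    if (sum(k) == 0) next
    s <- summarize_contest(list(self = k[1], nonself = k[2]))
    expect_equal(s$frac_self, k[1] / sum(k))
    expect_equal(s$frac_self + s$frac_nonself, 1)
  }
})

test_that("a majority below the call threshold is inconclusive", {
  s <- summarize_contest(list(self = 60, nonself = 40), call_threshold = 0.8)
  expect_equal(s$call, "inconclusive")
  s2 <- summarize_contest(list(self = 60, nonself = 40), call_threshold = 0.6)
  expect_equal(s2$call, "endogenous/HTT-consistent")
})
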