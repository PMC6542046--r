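# Reciprocal best-hit screening on toy genome sets with planted truth.

plant_many <- function(genome, copies, gap = 700) {
  pos <- seq(400, by = gap + max(nchar(copies)),
             length.out = length(copies))
  for (i in seq_along(copies)) {
    p <- pos[i] + sum(nchar(copies[seq_len(i - 1)]))
    genome <- paste0(substr(genome, 1, p), copies[i],
                     substr(genome, p + 1, nchar(genome)))
  }
  genome
}

test_that("planted copies pass at 10+ reciprocal hits and fail at 9", {
  set.seed(61)
  rte <- rand_dna(500)
  other <- rand_dna(500)  # a second, unrelated library element
  lib <- seq_tbl(c("RTE_A", "RTE_B"), c(rte, other))
  mk_copies <- function(n) vapply(seq_len(n), function(i)
    mutate_at(rte, 25)$seq, character(1))
  g_pass <- plant_many(rand_dna(15000), mk_copies(12))
  g_fail <- plant_many(rand_dna(15000), mk_copies(9))
  genomes <- seq_tbl(c("gp", "gf"), c(g_pass, g_fail),
                     species = c("sp_pass", "sp_fail"))
  rep <- screen_rte(lib, genomes)
  row_pass <- rep[rep$rte == "RTE_A" & rep$species == "sp_pass", ]
  row_fail <- rep[rep$rte == "RTE_A" & rep$species == "sp_fail", ]
  expect_equal(row_pass$n_reciprocal, 12)
  expect_true(row_pass$passes)
  expect_equal(row_fail$n_reciprocal, 9)
  expect_false(row_fail$passes)
  # the unrelated element sees nothing
  expect_true(all(!rep$passes[rep$rte == "RTE_B"]))
})

test_that("the 100 bp alignment-length cutoff is inclusive", {
  set.seed(62)
  rte <- rand_dna(500)
  lib <- seq_tbl("RTE_A", rte)
  # fragments planted with flanks chosen to break extension: the base after
  # each fragment differs from the element continuation
  mk_frag <- function(len) substr(rte, 1, len)
  bg <- rand_dna(6000)
  stopper <- function(after) {
    # two bases that mismatch the element continuation at that point
    nxt <- substr(rte, after + 1, after + 2)
    chartr("ACGT", "GTAC", nxt)
  }
  g99 <- paste0(substr(bg, 1, 2000), mk_frag(99), stopper(99),
                substr(bg, 2001, 6000))
  g100 <- paste0(substr(bg, 1, 2000), mk_frag(100), stopper(100),
                 substr(bg, 2001, 6000))
  genomes <- seq_tbl(c("g99", "g100"), c(g99, g100),
                     species = c("s99", "s100"))
  rep <- screen_rte(lib, genomes, min_hits = 1L)
  expect_equal(rep$n_hits[rep$species == "s99"], 0)
  expect_equal(rep$n_hits[rep$species == "s100"], 1)
})

test_that("a copy closer to a different library element fails reciprocality", {
  set.seed(63)
  rte_a <- rand_dna(500)
  rte_b <- mutate_at(rte_a, 60)$seq  # related element, 12% apart
  lib <- seq_tbl(c("RTE_A", "RTE_B"), c(rte_a, rte_b))
  # copies derived from B (3% off B, ~13% off A): hit A's search too, but
  # reciprocally match B
  copies <- vapply(1:5, function(i) mutate_at(rte_b, 15)$seq, character(1))
  g <- plant_many(rand_dna(8000), copies)
  genomes <- seq_tbl("g", g, species = "sp")
  rep <- screen_rte(lib, genomes, min_hits = 1L)
  a <- rep[rep$rte == "RTE_A", ]
  b <- rep[rep$rte == "RTE_B", ]
  expect_equal(b$n_reciprocal, 5)
  expect_equal(a$n_reciprocal, 0)  # all loci reciprocally match B
})

test_that("raising min_hits never adds candidates; empty inputs yield
           empty reports", {
  set.seed(64)
  rte <- rand_dna(400)
  lib <- seq_tbl("RTE_A", rte)
  g <- plant_many(rand_dna(12000),
                  vapply(1:6, function(i) mutate_at(rte, 20)$seq,
                         character(1)))
  genomes <- seq_tbl("g", g, species = "sp")
  passes <- vapply(c(1L, 3L, 6L, 7L, 10L), function(mh)
    sum(screen_rte(lib, genomes, min_hits = mh)$passes), integer(1))
  expect_true(all(diff(passes) <= 0))
  expect_equal(nrow(screen_rte(lib[0, ], genomes)), 0)
  # zero planted copies -> zero candidates at any threshold
  clean <- seq_tbl("c", rand_dna(5000), species = "clean")
  rep <- screen_rte(lib, clean, min_hits = 1L)
  expect_equal(sum(rep$n_hits), 0)
})

test_that("translated read screening applies both the identity and E-value
           filters", {
  set.seed(65)
  codons <- names(oracle_codon_table)[!oracle_codon_table %in% "*"]
  te <- paste(c("ATG", sample(codons, 150, TRUE), "TAA"), collapse = "")
  orf <- seq_tbl("orf", sub("\\*$", "", oracle_translate(te)))
  # reads: exact element fragment, heavily mutated fragment (~70% aa
  # identity), and background
  frag <- substr(te, 4, 303)
  bad_frag <- mutate_at(frag, 60)$seq  # 20% nt -> well under 75% aa identity
  reads <- seq_tbl(c("good", "bad", "bg"),
                   c(frag, bad_frag, rand_dna(300)))
  hits <- screen_reads_translated(reads, orf)
  expect_true("good" %in% hits$query_id)
  expect_false("bg" %in% hits$query_id)
  if ("bad" %in% hits$query_id)
    expect_true(all(hits$pident[hits$query_id == "bad"] > 75))
})

test_that("planted ORF fragments at ~85% identity are all recovered", {
  set.seed(66)
  codons <- names(oracle_codon_table)[!oracle_codon_table %in% "*"]
  te <- paste(c("ATG", sample(codons, 300, TRUE), "TAA"), collapse = "")
  orf <- seq_tbl("orf", sub("\\*$", "", oracle_translate(te)))
  n_planted <- 20
  planted <- vapply(seq_len(n_planted), function(i) {
    s <- sample(1:500, 1)
    frag <- substr(te, s - (s - 1) %% 3, s - (s - 1) %% 3 + 299)
    # ~5% nt divergence -> ~85-90% aa identity
    mutate_at(frag, 15)$seq
  }, character(1))
  reads <- seq_tbl(c(sprintf("pl%02d", 1:n_planted), sprintf("bg%02d", 1:30)),
                   c(planted, vapply(rep(300, 30), rand_dna, character(1))))
  hits <- screen_reads_translated(reads, orf)
  expect_setequal(unique(hits$query_id), sprintf("pl%02d", 1:n_planted))
})
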