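test_that("identical fragments reproduce themselves; low-coverage columns
           fall back to the seed", {
  set.seed(71)
  anc <- rand_dna(300)
  frags <- seq_tbl(paste0("f", 1:10), rep(anc, 10))
  seed_rec <- seq_tbl("seed", mutate_at(anc, 30)$seq)
  cm <- build_consensus(frags, seed_rec)
  expect_equal(cm$consensus, anc)
  expect_equal(cm$coverage, rep(10L, 300))
  # with only 2 fragments the majority rule cannot fire (min_coverage 3)
  cm2 <- build_consensus(frags[1:2, ], seed_rec)
  expect_equal(cm2$consensus, seed_rec$seq)
})

test_that("the ancestor is recovered from diverged copies", {
  set.seed(72)
  anc <- rand_dna(1000)
  fam <- evolve_te_family(anc, 30, 0.10, kappa = 2, indel_rate = 0.002)
  seed_rec <- seq_tbl("seed", evolve_seq(anc, 0.15)$seq)
  cm <- build_consensus(fam$copies, seed_rec)
  ident <- pairwise_identity(seq_tbl(c("anc", "cons"),
                                     c(anc, cm$consensus)))["anc", "cons"]
  expect_gte(ident, 99)
})

test_that("pairwise identity matches hand-counted and oracle values", {
  m <- pairwise_identity(seq_tbl(c("a", "b"), c("ACGT", "ACGA")))
  expect_equal(m["a", "b"], 75)
  expect_equal(diag(m), c(a = 100, b = 100))
  expect_equal(m, t(m))
  set.seed(73)
  for (i in 1:20) {
    x <- rand_dna(100)
    y <- mutate_at(x, sample(5:30, 1))$seq
    m <- pairwise_identity(seq_tbl(c("x", "y"), c(x, y)))
    # equal lengths, substitutions only: identity tracks the matching
    # positions (the optimal alignment may trade a gap pair for a column
    # or two at high divergence)
    expected <- 100 * sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]]) / 100
    expect_lt(abs(m["x", "y"] - expected), 2.5)
  }
})

make_ann <- function(start, end, cons_start, cons_end, strand = "+",
                     family = "F", seq_id = "chr", div = 5) {
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             family = family, divergence_pct = div, score = 100,
             cons_start = cons_start, cons_end = cons_end,
             stringsAsFactors = FALSE)
}

test_that("a copy split by an insertion merges into one record; tandem
           copies and opposite strands stay apart", {
  split_copy <- rbind(make_ann(1000, 1400, 0, 400),
                      make_ann(1700, 2300, 400, 1000))
  d <- defragment(split_copy)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_fragments, 2)
  expect_equal(d$merged_length, 1000)

  tandem <- rbind(make_ann(1000, 2000, 0, 1000),
                  make_ann(2001, 3000, 0, 999))  # consensus restarts
  d2 <- defragment(tandem)
  expect_equal(nrow(d2), 2)

  opposite <- rbind(make_ann(1000, 1400, 0, 400, strand = "+"),
                    make_ann(1700, 2300, 400, 1000, strand = "-"))
  expect_equal(nrow(defragment(opposite)), 2)
})

test_that("strict mode refuses to merge across an intervening foreign
           annotation; fragment counts are conserved", {
  blocked <- rbind(make_ann(1000, 1400, 0, 400),
                   make_ann(1500, 1600, 0, 100, family = "OTHER"),
                   make_ann(1700, 2300, 400, 1000))
  d <- defragment(blocked)
  expect_equal(sort(d$n_fragments[d$family == "F"]), c(1, 1))
  d2 <- defragment(blocked, strict = FALSE)
  expect_equal(d2$n_fragments[d2$family == "F"], 2)
  # conservation across a random fixture
  set.seed(74)
  anns <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(1e5, 1)
    make_ann(s, s + 300, sample(c(0, 500), 1), 900,
             strand = sample(c("+", "-"), 1))
  }))
  d3 <- defragment(anns)
  expect_equal(sum(d3$n_fragments), nrow(anns))
})

test_that("minus-strand fragments merge when consensus coordinates run
           backwards along the genome", {
  rev_copy <- rbind(make_ann(1000, 1400, 600, 1000, strand = "-"),
                    make_ann(1700, 2300, 0, 620, strand = "-"))
  d <- defragment(rev_copy)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_fragments, 2)
})

test_that("top-copy selection sorts by length then divergence and matches a
           brute-force oracle", {
  copies <- data.frame(copy_id = c("a", "b", "c"),
                       merged_length = c(500, 400, 400),
                       mean_divergence_pct = c(5, 2, 9))
  top <- select_top_copies(copies, 3)
  expect_equal(top$copy_id, c("a", "b", "c"))
  expect_equal(nrow(select_top_copies(copies, 10)), 3)
  set.seed(75)
  for (i in 1:20) {
    n <- sample(5:120, 1)
    cp <- data.frame(copy_id = paste0("c", 1:n),
                     merged_length = sample(100:2000, n, TRUE),
                     mean_divergence_pct = round(runif(n, 0, 30), 1))
    top <- select_top_copies(cp, 100)
    oracle <- cp[order(-cp$merged_length, cp$mean_divergence_pct), ]
    expect_equal(top$copy_id, head(oracle$copy_id, 100))
  }
})

test_that("ORF finding matches its examples and an exhaustive scan", {
  seq1 <- paste0("ATG", strrep("AAA", 50), "TAA")
  orfs <- find_orfs(seq1)
  plus1 <- orfs[orfs$frame == "+1", ]
  expect_equal(plus1$n_codons, 51)
  expect_equal(plus1$start, 0)
  expect_equal(plus1$end, 153)

  # reverse-strand ORF reported with forward coordinates
  rc <- oracle_revcomp(seq1)
  orfs_rc <- find_orfs(rc)
  m1 <- orfs_rc[orfs_rc$frame == "-1", ]
  expect_equal(m1$n_codons, 51)
  expect_equal(m1$start, nchar(rc) - 153)

  set.seed(76)
  for (i in 1:20) {
    x <- rand_dna(600)
    orfs <- find_orfs(x, min_codons = 10)
    # exhaustive oracle: stop-split runs per frame
    expected <- 0L
    for (off in 0:2) {
      for (s in list(x, oracle_revcomp(x))) {
        p <- oracle_translate(substr(s, off + 1, nchar(s)))
        runs <- nchar(strsplit(p, "*", fixed = TRUE)[[1]])
        expected <- expected + sum(runs >= 10)
      }
    }
    expect_equal(nrow(orfs), expected)
    if (nrow(orfs) > 0) {
      lo <- longest_orf(x, min_codons = 10)
      expect_equal(lo$n_codons, max(orfs$n_codons))
    }
  }
})
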