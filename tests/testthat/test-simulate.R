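small_cfg <- function(scenario = "HTT", seed = 101, ...) {
  scenario_config(seed = seed, scenario = scenario, te_length = 900L,
                  n_copies_donor = 6L, n_copies_recipient = 6L,
                  genome_length = 20000L, coverage = 4,
                  long_read_coverage = 2, long_read_mean = 3000L, ...)
}

test_that("evolution at divergence 0 is the identity; realized divergence
           matches the process expectation; infinite kappa kills
           transversions", {
  set.seed(102)
  anc <- rand_dna(2000)
  expect_equal(evolve_seq(anc, 0)$seq, anc)

  d <- 0.08; kappa <- 2
  fam <- evolve_te_family(anc, 100, d, kappa = kappa)
  # closed-form expected observed mismatch fraction under K80
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  p_obs <- (0.25 + 0.25 * exp(-4 * beta * d) -
              0.5 * exp(-2 * (alpha + beta) * d)) +
    (0.5 - 0.5 * exp(-4 * beta * d))
  se <- sqrt(p_obs * (1 - p_obs) / (2000 * 100))
  expect_lt(abs(mean(fam$divergence$realized) - p_obs), 3 * se + 1e-4)

  big_kappa <- evolve_seq(anc, 0.2, kappa = 1e9)$seq
  a <- strsplit(anc, "")[[1]]; b <- strsplit(big_kappa, "")[[1]]
  purine <- a %in% c("A", "G")
  changed <- a != b
  transversion <- changed & (purine != (b %in% c("A", "G")))
  expect_equal(sum(transversion), 0)
})

test_that("paired-read simulation respects coverage, orientation and the
           zero-error limit", {
  set.seed(103)
  cfg <- small_cfg(error_rate = 0)
  g <- rand_dna(50000)
  rp <- simulate_paired_reads(g, 10, cfg)
  total <- sum(nchar(rp$pairs$seq1)) + sum(nchar(rp$pairs$seq2))
  expect_lt(abs(total - 10 * 50000) / (10 * 50000), 0.05)
  # all mates are exact substrings; mate 2 reverse-complemented (FR)
  idx <- sample(nrow(rp$pairs), 50)
  for (i in idx) {
    c1 <- rp$coords[rp$coords$read_id == paste0(rp$pairs$pair_id[i], "/1"), ]
    c2 <- rp$coords[rp$coords$read_id == paste0(rp$pairs$pair_id[i], "/2"), ]
    expect_equal(rp$pairs$seq1[i], substr(g, c1$start + 1, c1$end))
    expect_equal(rp$pairs$seq2[i], revcomp(substr(g, c2$start + 1, c2$end)))
    expect_lte(c1$start, c2$start)
  }
})

test_that("sequencing errors carry low quality scores so masking removes
           them", {
  set.seed(104)
  cfg <- small_cfg(error_rate = 0.05)
  g <- rand_dna(20000)
  rp <- simulate_paired_reads(g, 2, cfg)
  reads <- seq_tbl(paste0(rp$pairs$pair_id, "/1"), rp$pairs$seq1,
                   qual = rp$pairs$qual1)
  masked <- quality_mask(reads)
  for (i in sample(nrow(reads), 20)) {
    c1 <- rp$coords[rp$coords$read_id == reads$id[i], ]
    truth <- substr(g, c1$start + 1, c1$end)
    kept <- strsplit(masked$seq[i], "")[[1]] != "N"
    expect_equal(strsplit(masked$seq[i], "")[[1]][kept],
                 strsplit(truth, "")[[1]][kept])
  }
})

test_that("scenario generation is byte-identical under a fixed seed", {
  s1 <- build_scenario(small_cfg())
  s2 <- build_scenario(small_cfg())
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$long_reads, s2$long_reads)
  expect_identical(s1$recipient_genome, s2$recipient_genome)
  expect_identical(s1$planted, s2$planted)
  s3 <- build_scenario(small_cfg(seed = 202))
  expect_false(identical(s1$pairs, s3$pairs))
})

test_that("scenario construction matches its labels: element placement,
           read origins and contamination fraction", {
  htt <- build_scenario(small_cfg("HTT"))
  expect_true(any(htt$planted$genome == "recipient" &
                    htt$planted$family == "RTE1_SIM"))
  expect_true(any(htt$planted$genome == "donor" &
                    htt$planted$family == "RTE1_SIM"))
  expect_true(all(htt$truth$pairs$origin == "recipient"))

  cont <- build_scenario(small_cfg("contamination"))
  expect_false(any(cont$planted$genome == "recipient" &
                     cont$planted$family == "RTE1_SIM"))
  frac <- mean(cont$truth$pairs$origin == "donor")
  expect_lt(abs(frac - cont$config$contamination_fraction), 0.01)
  # contaminant contig rides along in the assembly
  expect_true("donor_contig" %in% cont$assembly$id)

  neg <- build_scenario(small_cfg("negative"))
  expect_false(any(neg$planted$family == "RTE1_SIM"))
})

test_that("annotating the synthetic genome with the true ancestor recovers
           the planted copy registry", {
  scn <- build_scenario(small_cfg(copy_divergence = 0.08))
  ann <- annotate_repeats(scn$recipient_genome,
                          scn$rte_consensus, min_len = 200)
  planted <- scn$planted[scn$planted$genome == "recipient" &
                           scn$planted$family == "RTE1_SIM", ]
  hit <- vapply(seq_len(nrow(planted)), function(i)
    any(ann$start < planted$end[i] & ann$end > planted$start[i]),
    logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("truth TE-overlap flags match an independent interval check", {
  scn <- build_scenario(small_cfg())
  planted <- scn$planted[scn$planted$genome == "recipient" &
                           scn$planted$family == "RTE1_SIM", ]
  coords <- scn$mappings
  for (pid in sample(scn$pairs$pair_id, 40)) {
    spans <- coords[sub("/[12]$", "", coords$read_id) == pid, ]
    ov <- any(vapply(seq_len(nrow(spans)), function(j)
      any(planted$start < spans$end[j] & planted$end > spans$start[j]),
      logical(1)))
    expect_equal(scn$truth$pairs$te_overlap[scn$truth$pairs$pair_id == pid],
                 ov, info = pid)
  }
})

test_that("written scenarios round-trip through the on-disk formats", {
  scn <- build_scenario(small_cfg())
  dir <- withr::local_tempdir()
  write_scenario(scn, dir)
  lib <- read_fasta(file.path(dir, "repeat_library.fa"))
  expect_equal(lib$seq, scn$repeat_library$seq)
  r1 <- read_fastq(file.path(dir, "reads_1.fq"))
  expect_equal(nrow(r1), nrow(scn$pairs))
  expect_equal(r1$seq, scn$pairs$seq1)
  maps <- read_samlite(file.path(dir, "mappings.sam"))
  expect_equal(nrow(maps), nrow(scn$mappings))
  expect_equal(maps$start, scn$mappings$start)
})

test_that("the lineage panel seeds the recipient from the stated donor
           lineage", {
  pan <- simulate_lineage_panel(seed = 7, n_per_species = 3,
                                te_length = 600L)
  expect_setequal(names(pan$copies), c("D1", "D2", "D3", "D4", "REC"))
  # recipient founder is much closer to the seeding lineage than to others
  d_rec <- vapply(c("D1", "D2", "D3", "D4"), function(sp)
    1 - pairwise_identity(seq_tbl(c("r", "d"),
                                  c(pan$founders[["REC"]],
                                    pan$founders[[sp]])))["r", "d"] / 100,
    numeric(1))
  expect_equal(names(which.min(d_rec)), pan$seeding_lineage)
})
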