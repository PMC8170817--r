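# The synthetic-data generator: determinism, planted divergence, error
# statistics and truth-log completeness.

small_cfg <- function(seed = 5, ...) {
  sim_config(genome_len = 20000, gene_lengths = c(3000, 5000),
             coverage = 20, seed = seed, ...)
}

test_that("the generator is fully reproducible from its seed", {
  a <- simulate_dataset(small_cfg())
  b <- simulate_dataset(small_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$individual, b$individual)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$genome, c$genome))
})

test_that("gene records match their intervals and fixed intervals are honoured", {
  g <- make_genome(small_cfg())
  expect_equal(nchar(g$genes$seq), c(3000L, 5000L))
  expect_equal(g$genes$seq,
               substring(g$genome, g$genes$start + 1L, g$genes$end))
  expect_true(all(g$genes$start[-1] >= g$genes$end[-nrow(g$genes)] + 200L))

  fixed <- make_genome(small_cfg(gene_intervals = list(c(100L, 600L),
                                                       c(1000L, 1800L))))
  expect_equal(fixed$genes$start, c(100L, 1000L))
  expect_equal(fixed$genes$end, c(600L, 1800L))
  expect_error(make_genome(small_cfg(gene_intervals = list(c(0L, 500L),
                                                           c(400L, 900L)))),
               "overlap")
})

test_that("a decoy repeat duplicates a gene subsequence at a distant locus", {
  cfg <- small_cfg(decoy_repeat = list(gene = 1, length = 400, pos = 15000))
  g <- make_genome(cfg)
  piece <- substr(g$genes$seq[1], 1, 400)
  expect_equal(substr(g$genome, 15001, 15400), piece)
  expect_equal(length(gregexpr(piece, g$genome, fixed = TRUE)[[1]]), 2L)
})

test_that("SNP planting hits the binomial expectation and only genes", {
  g <- make_genome(small_cfg())
  zero <- plant_snps(g$genome, g$genes, 0, seed = 5)
  expect_identical(zero$individual, g$genome)
  expect_equal(nrow(zero$snps), 0L)

  counts <- vapply(1:5, function(s)
    nrow(plant_snps(g$genome, g$genes, 0.01, seed = s)$snps), integer(1))
  expected <- 8000 * 0.01 # 8 kb of gene sequence
  sigma <- sqrt(8000 * 0.01 * 0.99)
  expect_true(all(abs(counts - expected) <= 3 * sigma))

  one <- plant_snps(g$genome, g$genes, 0.01, seed = 1)
  in_gene <- unlist(mapply(seq.int, g$genes$start, g$genes$end - 1L,
                           SIMPLIFY = FALSE))
  expect_true(all(one$snps$pos %in% in_gene))
  expect_true(all(one$snps$ref_base != one$snps$alt_base))
  # outside the genes the individual equals the reference
  expect_equal(substr(one$individual, 1, g$genes$start[1]),
               substr(g$genome, 1, g$genes$start[1]))
})

# Strand-aware origin substring of the individual genome for a read.
origin_seq <- function(individual, start0, strand, rl) {
  s <- substr(individual, start0 + 1L, start0 + rl)
  if (strand == "-") revcomp(s) else s
}

test_that("error-free simulation gives exact substrings and an empty truth log", {
  cfg <- small_cfg(error_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth), 0L)
  i <- withr::with_seed(1, sample(nrow(sim$reads), 50))
  ok <- vapply(i, function(j) {
    sim$reads$seq[j] == origin_seq(sim$individual, sim$origins$start[j],
                                   sim$origins$strand[j], cfg$read_len)
  }, logical(1))
  expect_true(all(ok))
})

test_that("injected error counts match the binomial expectation", {
  cfg <- sim_config(genome_len = 10000, gene_lengths = 2000, coverage = 100,
                    error_rate = 0.01, seed = 9)
  sim <- simulate_dataset(cfg)
  n_bases <- sum(nchar(sim$reads$seq))
  expect_gte(n_bases, 1e6)
  sigma <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(nrow(sim$truth) - n_bases * 0.01), 3 * sigma)
  expect_true(all(sim$truth$true_base != sim$truth$observed_base))
})

test_that("the truth log is complete: every read/origin mismatch is logged", {
  cfg <- sim_config(genome_len = 5000, gene_lengths = 1000, coverage = 10,
                    error_rate = 0.02, seed = 3)
  sim <- simulate_dataset(cfg)
  logged <- split(sim$truth$pos_in_read, sim$truth$read_id)
  for (j in seq_len(nrow(sim$reads))) {
    true_seq <- origin_seq(sim$individual, sim$origins$start[j],
                           sim$origins$strand[j], cfg$read_len)
    mism <- which(strsplit(sim$reads$seq[j], "")[[1]] !=
                    strsplit(true_seq, "")[[1]]) - 1L
    expect_equal(sort(mism),
                 sort(logged[[sim$reads$read_id[j]]] %||% integer(0)))
  }
})

test_that("coverage over the gene body is near the requested depth", {
  cfg <- sim_config(genome_len = 30000, gene_lengths = 20000, coverage = 30,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  g <- sim$genes[1, ]
  mid <- seq(g$start + 1000L, g$end - 1000L, by = 500L)
  depth <- vapply(mid, function(p)
    sum(sim$origins$start < p & sim$origins$start + cfg$read_len > p),
    integer(1))
  expect_lt(abs(mean(depth) - 30) / 30, 0.1)
})

test_that("paired layout emits synchronized innie mates with sane inserts", {
  cfg <- small_cfg(layout = "paired")
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$reads$mate == "first"), sum(sim$reads$mate == "second"))
  expect_true(all(grepl("/1$", sim$reads$read_id[sim$reads$mate == "first"])))
  m1 <- sim$origins[grepl("/1$", sim$origins$read_id), ]
  m2 <- sim$origins[grepl("/2$", sim$origins$read_id), ]
  expect_true(all(m1$strand != m2$strand))
  frag <- abs(m2$start - m1$start) + cfg$read_len
  expect_lt(abs(mean(frag) - cfg$insert_mean), 5)
  expect_lt(abs(stats::sd(frag) - cfg$insert_sd), 5)
})
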