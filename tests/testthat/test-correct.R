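# The corrector on small hand-built alignment arrays.

# Mapped-read tibble from explicit cells/offsets ("+" strand, no indels).
mk_subset <- function(cells, offsets, ids = sprintf("r%02d", seq_along(cells))) {
  tibble::tibble(
    read_id = ids, seq = cells, qual = strrep("I", nchar(cells)),
    mate = "unpaired", strand = "+", offset = as.integer(offsets),
    cells = cells, mismatches = 0L, identity_pct = 100
  )
}

# Eight staggered error-free reads over a reference, like the usual
# workflow illustration.
eight_reads <- function(seed = 21) {
  ref <- random_dna(130, seed)
  ext <- extend_reference(list(gene_id = "g8", seq = ref))
  offs <- seq(0L, 70L, by = 10L)
  cells <- substring(ref, offs + 1L, offs + 60L)
  list(ext = ext, subset = mk_subset(cells, offs))
}

test_that("the alignment array sorts rows by offset, stably", {
  f <- eight_reads()
  arr <- build_alignment_array(f$subset[sample(8), ], f$ext)
  expect_equal(nrow(arr$rows), 8L)
  expect_true(!is.unsorted(arr$rows$offset))

  # ties keep their incoming order
  tie <- f$subset[c(3, 1, 2), ]
  tie$offset <- c(5L, 0L, 5L)
  arr2 <- build_alignment_array(tie, f$ext)
  expect_equal(arr2$rows$read_id, c("r01", "r03", "r02"))

  # empty subset is a no-op array
  arr0 <- build_alignment_array(f$subset[0, ], f$ext)
  expect_equal(nrow(arr0$rows), 0L)
  expect_equal(consensus_sequence(arr0), f$ext$core_seq)

  bad <- f$subset[1, ]
  bad$offset <- 100L
  expect_error(build_alignment_array(bad, f$ext), "overruns")
})

test_that("annotate_bases scores minor bases as f + p and nothing else", {
  # one-type column at depth 200 with a single T: score 1/200 + 0.1
  ext1 <- extend_reference(list(gene_id = "c1", seq = "A"))
  sub1 <- mk_subset(c(rep("A", 199), "T"), rep(0L, 200))
  ann1 <- annotate_bases(build_alignment_array(sub1, ext1))
  expect_equal(nrow(ann1), 1L)
  expect_equal(ann1$base, "T")
  expect_equal(ann1$score, 0.005 + 0.1)

  # three-type column (T40 G41 A18 C1): minor C scores 0.01 + 0.3
  ext3 <- extend_reference(list(gene_id = "c3", seq = "T"))
  sub3 <- mk_subset(c(rep("T", 40), rep("G", 41), rep("A", 18), "C"),
                    rep(0L, 100))
  ann3 <- annotate_bases(build_alignment_array(sub3, ext3))
  expect_equal(nrow(ann3), 1L)
  expect_equal(ann3$base, "C")
  expect_equal(ann3$score, 0.01 + 0.3)

  # dominant bases and four-type columns are never scored
  ext4 <- extend_reference(list(gene_id = "c4", seq = "T"))
  sub4 <- mk_subset(c(rep("T", 25), rep("G", 40), rep("A", 30), rep("C", 5)),
                    rep(0L, 100))
  expect_equal(nrow(annotate_bases(build_alignment_array(sub4, ext4))), 0L)
})

test_that("a single erroneous base is corrected to the dominant type", {
  f <- eight_reads()
  sub <- f$subset
  sub$cells[4] <- plant_mismatches(sub$cells[4], 27) # column 30 + 27 - 1
  sub$seq <- sub$cells
  res <- correct_rows(build_alignment_array(sub, f$ext))
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$read_id, "r04")
  expect_equal(res$records$pos_in_read, 26L) # 0-based
  expect_equal(res$records$dominance_at_col, 1L)
  expect_equal(res$records$new_base,
               substr(f$ext$core_seq, res$records$col + 1L, res$records$col + 1L))
  # array is fully repaired
  expect_equal(sort(res$array$rows$cells), sort(f$subset$cells))
  expect_equal(length(res$out_ids), 0L)
})

test_that("error-free rows pass through unchanged", {
  f <- eight_reads()
  res <- correct_rows(build_alignment_array(f$subset, f$ext))
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$array$rows$cells, f$subset$cells[order(f$subset$offset)])
})

test_that("one pass corrects at most ceiling(2% of read length) per row", {
  f <- eight_reads()
  # deepen coverage so a lone error scores below the out threshold
  extra1 <- dplyr::mutate(f$subset, read_id = paste0(read_id, "b"))
  extra2 <- dplyr::mutate(f$subset, read_id = paste0(read_id, "c"))
  sub <- dplyr::bind_rows(f$subset, extra1, extra2)
  sub$cells[5] <- plant_mismatches(sub$cells[5], c(11, 21, 31)) # 3 errors, cap 2
  sub$seq <- sub$cells
  res <- correct_rows(build_alignment_array(sub, f$ext))
  expect_equal(nrow(res$records), 2L) # ceiling(0.02 * 60) = 2

  # the iterated corrector finishes the job
  corr <- correct_reads(sub, f$ext)
  expect_equal(nrow(corr$records), 3L)
  expect_equal(sort(unique(corr$reads$seq)), sort(f$subset$cells))
  expect_gt(corr$passes, 1L)
})

test_that("reads with repeated high-frequency disagreement are labeled out", {
  ref <- random_dna(60, seed = 8)
  ext <- extend_reference(list(gene_id = "gr", seq = ref))
  alien <- plant_mismatches(ref, c(10, 40))
  sub <- mk_subset(c(rep(ref, 4), alien), rep(0L, 5),
                   ids = c(sprintf("k%d", 1:4), "alien"))
  # both minor cells have f = 1/5 = 0.2, score 0.3 > out_threshold
  res <- correct_rows(build_alignment_array(sub, ext))
  expect_equal(res$out_ids, "alien")
  expect_equal(nrow(res$array$rows), 4L)
  expect_equal(nrow(res$records), 0L)

  corr <- correct_reads(sub, ext)
  expect_equal(corr$out_ids, "alien")
  expect_false("alien" %in% corr$reads$read_id)
})

test_that("proportional assignment follows largest-remainder quotas", {
  got <- proportional_assignment(1:98, c(T = 0.40, G = 0.58))
  expect_equal(as.integer(table(got)[c("T", "G")]), c(40L, 58L))

  # degenerate single dominant type
  expect_equal(unname(proportional_assignment(1, c(A = 1))), "A")

  # conservation and determinism under a fixed seed
  withr::with_seed(2, {
    for (i in 1:25) {
      k <- sample.int(30L, 1L)
      fr <- rgamma(sample(2:3, 1), 1)
      names(fr) <- sample(c("A", "C", "G", "T"), length(fr))
      a1 <- proportional_assignment(seq_len(k), fr, seed = 7 + i)
      a2 <- proportional_assignment(seq_len(k), fr, seed = 7 + i)
      expect_identical(a1, a2)
      expect_equal(length(a1), k)
      expect_true(all(a1 %in% names(fr)))
    }
  })
  # 50/50 over 5 candidates: a reproducible 3/2 split
  s1 <- proportional_assignment(1:5, c(A = 0.5, C = 0.5), seed = 1)
  expect_equal(sort(as.integer(table(s1))), c(2L, 3L))
  expect_identical(s1, proportional_assignment(1:5, c(A = 0.5, C = 0.5), seed = 1))
})

test_that("consensus takes the highest-frequency base and falls back to the reference", {
  ext <- extend_reference(list(gene_id = "gc", seq = "AAAAA"))
  # column 2: C30 vs G20 (both dominant in a 2-type column) -> C
  cells <- c(rep("ACA", 30), rep("AGA", 20))
  sub <- mk_subset(cells, rep(0L, 50))
  arr <- build_alignment_array(sub, ext)
  expect_equal(column_profiles(arr)$dominance[2], 2L)
  cons <- consensus_sequence(arr)
  expect_equal(substr(cons, 2, 2), "C")
  # columns 4-5 have no coverage: reference passthrough
  expect_equal(substr(cons, 4, 5), "AA")
})

test_that("error-free deep coverage reproduces the gene exactly", {
  d <- demo_gene()
  sub <- extract_subset(tile_reads(d$ext, step = 3), d$ext)
  corr <- correct_reads(sub, d$ext)
  expect_equal(corr$consensus, d$gene$seq)
  expect_equal(nrow(corr$records), 0L)
})

test_that("after iterated correction, dominance-1 columns are pure", {
  d <- demo_gene()
  reads <- tile_reads(d$ext, step = 4)
  withr::with_seed(31, {
    hit <- sample(nrow(reads), 40)
    reads$seq[hit] <- vapply(reads$seq[hit], function(s)
      plant_mismatches(s, sample(100, sample(1:2, 1))), character(1))
  })
  sub <- extract_subset(reads, d$ext)
  corr <- correct_reads(sub, d$ext)
  prof <- column_profiles(corr$array)
  d1 <- prof[prof$dominance == 1L, ]
  minor_mass <- d1$depth - pmax(d1$A, pmax(d1$C, pmax(d1$G, d1$T)))
  expect_true(all(minor_mass == 0L))
  # per-pass budget: no row ever exceeds ceiling(2%) corrections in one pass
  if (nrow(corr$records) > 0L) {
    per_pass <- dplyr::count(corr$records, .data$read_id, .data$pass)
    expect_true(all(per_pass$n <= 2L))
  }
})

test_that("identical inputs and seed give identical corrections", {
  d <- demo_gene()
  reads <- tile_reads(d$ext, step = 5)
  withr::with_seed(13, {
    hit <- sample(nrow(reads), 25)
    reads$seq[hit] <- vapply(reads$seq[hit], function(s)
      plant_mismatches(s, sample(100, 2)), character(1))
  })
  sub <- extract_subset(reads, d$ext)
  c1 <- correct_reads(sub, d$ext, seed = 42)
  c2 <- correct_reads(sub, d$ext, seed = 42)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$consensus, c2$consensus)
})

test_that("tidy and glance summarise a correction", {
  f <- eight_reads()
  sub <- f$subset
  sub$cells[2] <- plant_mismatches(sub$cells[2], 5)
  sub$seq <- sub$cells
  corr <- correct_reads(sub, f$ext)
  td <- tidy(corr)
  expect_equal(nrow(td), 1L)
  expect_true(all(td$old_base != td$new_base))
  gl <- glance(corr)
  expect_equal(gl$n_reads, 8L)
  expect_equal(gl$n_corrections, 1L)
  expect_equal(gl$consensus_len, nchar(f$ext$core_seq))
})
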