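# Shared fixtures: small deterministic sequences, read tibbles, and the
# independent brute-force dominance oracle used to cross-check the
# vectorised classifier.

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

reads_tbl <- function(seqs, ids = sprintf("t%03d", seq_along(seqs)),
                      qual = NULL, mate = "unpaired") {
  tibble::tibble(
    read_id = ids, seq = seqs,
    qual = qual %||% strrep("I", nchar(seqs)),
    mate = mate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotate the base at 1-based positions `pos` (A->C->G->T->A): a guaranteed
# mismatch without randomness.
plant_mismatches <- function(seq, pos) {
  rot <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (p in pos) substr(seq, p, p) <- rot[[substr(seq, p, p)]]
  seq
}

# Independent dominance oracle: enumerate m = 1..3 (smallest first), take
# the m most frequent non-N types (ties in fixed A<C<G<T order, all with
# positive count), and apply the <=3-count / <=2%-at-depth>=100 rule on the
# remaining mass; otherwise four-type.
oracle_dominance <- function(counts, minor_count = 3, minor_frac = 0.02,
                             min_depth = 100) {
  full <- stats::setNames(numeric(5), c("A", "C", "G", "T", "N"))
  full[names(counts)] <- counts
  depth <- sum(full)
  acgt <- full[c("A", "C", "G", "T")]
  ord <- order(-acgt, seq_along(acgt))
  for (m in 1:3) {
    dom <- ord[seq_len(m)]
    if (any(acgt[dom] == 0)) next
    minor <- depth - sum(acgt[dom])
    if (minor <= minor_count ||
        (depth >= min_depth && minor / depth <= minor_frac)) {
      return(m)
    }
  }
  4L
}

# Random column count vectors spanning depth 1-500, skewed so all four
# dominance classes and the count/fraction rule boundaries are exercised.
random_column_counts <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    depth <- sample.int(500L, 1L)
    ntypes <- sample.int(5L, 1L)
    types <- sample(c("A", "C", "G", "T", "N"), ntypes)
    w <- rgamma(ntypes, shape = sample(c(0.2, 1, 5), 1))
    w <- w / sum(w)
    cnt <- as.integer(stats::rmultinom(1, depth, w))
    names(cnt) <- types
    cnt[cnt > 0]
  }))
}

# A small gene embedded in a genome, with helpers for building mapped reads
# by cutting error-free reads from the extended reference.
demo_gene <- function(gene_len = 400, genome_len = 1200, seed = 11) {
  genome <- random_dna(genome_len, seed)
  start <- 300L
  gene <- list(gene_id = "gdemo", seq = substr(genome, start + 1L, start + gene_len),
               start = start, end = start + gene_len)
  list(genome = genome, gene = gene,
       ext = targetec::extend_reference(gene, genome, flank = 50))
}

# Perfect-coverage error-free reads tiled over the extended reference.
tile_reads <- function(ext, read_len = 100, step = 10) {
  L <- nchar(ext$ext_seq)
  starts <- seq(1L, L - read_len + 1L, by = step)
  reads_tbl(substring(ext$ext_seq, starts, starts + read_len - 1L),
            ids = sprintf("tile%04d", starts))
}
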