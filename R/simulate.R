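# Synthetic whole-genome sequencing: a uniform-random genome with annotated
# gene intervals, an individual genome diverged from the reference by
# planted SNPs inside the genes, and single- or paired-end fixed-length
# reads with uniform substitution errors plus a complete truth log. This is
# the package's stand-in for large-scale read simulations on a real
# chromosome: it reproduces the features the corrector relies on (stable
# coverage, substitution-dominated errors, SNP divergence between the
# individual and the reference) at a scale a laptop can run.

#' Simulation configuration
#'
#' Defaults describe the package's reference experiment: a 1 Mb genome with
#' seven gene-sized targets of 5-60 kb, SNP divergence 0.1%, 100 bp reads at
#' 30x coverage with 1% uniform substitution errors.
#'
#' @param genome_len genome length in bases.
#' @param gene_lengths lengths of the (non-overlapping) gene intervals;
#'   ignored when `gene_intervals` is given.
#' @param gene_intervals optional list/tibble of fixed 0-based half-open
#'   `(start, end)` intervals.
#' @param snp_rate per-base probability that the individual genome differs
#'   from the reference inside a gene interval.
#' @param error_rate per-base substitution-error probability of simulated
#'   reads (Illumina short reads: 0.5-2%).
#' @param read_len read length (bases).
#' @param coverage mean sequencing depth over the genome.
#' @param layout `"single"` or `"paired"`.
#' @param insert_mean,insert_sd fragment-length distribution for paired
#'   layout (Normal, truncated at `read_len`).
#' @param decoy_repeat optional list `(gene, length, pos)`: copy the first
#'   `length` bases of gene number `gene` to position `pos`, creating a
#'   repeat that exercises 'out' labeling.
#' @param seed integer seed; every random choice derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_len = 1e6,
                       gene_lengths = c(5000, 8000, 12000, 20000, 30000,
                                        45000, 60000),
                       gene_intervals = NULL,
                       snp_rate = 0.001, error_rate = 0.01, read_len = 100,
                       coverage = 30, layout = c("single", "paired"),
                       insert_mean = 300, insert_sd = 30,
                       decoy_repeat = NULL, seed = 42) {
  layout <- match.arg(layout)
  stopifnot(genome_len > 0, snp_rate >= 0, snp_rate < 1,
            error_rate >= 0, error_rate < 1, read_len > 0, coverage > 0)
  structure(
    list(genome_len = as.integer(genome_len), gene_lengths = gene_lengths,
         gene_intervals = gene_intervals, snp_rate = snp_rate,
         error_rate = error_rate, read_len = as.integer(read_len),
         coverage = coverage, layout = layout,
         insert_mean = insert_mean, insert_sd = insert_sd,
         decoy_repeat = decoy_repeat, seed = as.integer(seed)),
    class = "sim_config"
  )
}

ints_to_seq <- function(code) {
  # code over 1..4 (A,C,G,T)
  if (length(code) == 0L) return("")
  intToUtf8(CELL_UTF8[code + 1L])
}

seq_to_ints <- function(seq) {
  encode_cells(split_cells(seq)[[1]])
}

#' Generate the reference genome and its gene records
#'
#' The genome is i.i.d. uniform over A/C/G/T. Gene intervals are either
#' taken from the config or placed at seeded-random non-overlapping
#' positions (minimum 200 bp apart and away from the contig ends).
#'
#' @param config a [sim_config()].
#' @return a list with `genome` (string) and `genes` (tibble `gene_id`,
#'   `start`, `end` 0-based half-open, `seq`).
#' @export
make_genome <- function(config) {
  withr::with_seed(child_seed(config$seed, "genome"), {
    L <- config$genome_len
    code <- sample.int(4L, L, replace = TRUE)
    intervals <- config$gene_intervals
    if (is.null(intervals)) {
      lens <- as.integer(config$gene_lengths)
      margin <- 200L
      slack <- L - sum(lens) - margin * (length(lens) + 1L)
      if (slack < 0L) abort("gene lengths do not fit the genome")
      gaps <- if (length(lens) > 0L) {
        cuts <- sort(sample.int(slack + 1L, length(lens) + 1L, replace = TRUE) - 1L)
        (diff(c(0L, cuts)) + margin)[seq_along(lens)]
      } else integer(0)
      start <- cumsum(gaps) + c(0L, cumsum(lens))[seq_along(lens)]
      intervals <- tibble(start = as.integer(start),
                          end = as.integer(start + lens))
    } else {
      intervals <- as_tibble(as.data.frame(do.call(rbind, lapply(intervals, function(iv) {
        if (is.list(iv) || length(iv) == 2L) c(start = iv[[1]], end = iv[[2]]) else iv
      }))))
      intervals <- arrange(intervals, .data$start)
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
      abort("gene intervals overlap")
    }
    if (any(intervals$start < 0L) || any(intervals$end > L)) {
      abort("gene intervals fall outside the genome")
    }
    if (!is.null(config$decoy_repeat)) {
      dr <- config$decoy_repeat
      g <- intervals[dr$gene, ]
      src <- (g$start + 1L):(g$start + dr$length)
      dest <- (dr$pos + 1L):(dr$pos + dr$length)
      if (any(dest > L)) abort("decoy repeat exceeds the genome")
      code[dest] <- code[src]
    }
    genome <- ints_to_seq(code)
    genes <- mutate(intervals,
                    gene_id = sprintf("g%d", dplyr::row_number()),
                    seq = substring(genome, .data$start + 1L, .data$end)) %>%
      select("gene_id", "start", "end", "seq")
    list(genome = genome, genes = genes)
  })
}

#' Plant SNPs to form the individual genome
#'
#' Each base inside a gene interval mutates to a different uniform base with
#' probability `snp_rate`. Reads are later simulated from the individual
#' genome while extraction uses the unmutated reference.
#'
#' @param genome reference genome string.
#' @param gene_intervals tibble with 0-based half-open `start`, `end`.
#' @param snp_rate per-base mutation probability.
#' @param seed integer seed.
#' @return a list with `individual` (string) and `snps` (tibble `pos`
#'   0-based, `ref_base`, `alt_base`).
#' @export
plant_snps <- function(genome, gene_intervals, snp_rate, seed = 42) {
  withr::with_seed(child_seed(seed, "snps"), {
    code <- seq_to_ints(genome)
    in_gene <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                             gene_intervals$start, gene_intervals$end,
                             SIMPLIFY = FALSE))
    hit <- in_gene[stats::runif(length(in_gene)) < snp_rate]
    snps <- tibble(pos = integer(0), ref_base = character(0),
                   alt_base = character(0))
    if (length(hit) > 0L) {
      old <- code[hit]
      new <- ((old - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      code[hit] <- new
      snps <- tibble(pos = hit - 1L, ref_base = BASE_CHARS[old],
                     alt_base = BASE_CHARS[new])
    }
    list(individual = ints_to_seq(code), snps = snps)
  })
}

#' Simulate reads with uniform substitution errors
#'
#' Reads are placed uniformly on both strands of the individual genome.
#' Every base is substituted independently with probability `error_rate`
#' (to a different uniform base); each substitution is recorded in the
#' truth log in read orientation. The paired layout draws fragment lengths
#' from Normal(`insert_mean`, `insert_sd`) truncated at `read_len` and
#' emits an innie pair per fragment with `/1` `/2` id suffixes.
#'
#' @param individual the individual genome string.
#' @param config a [sim_config()].
#' @return a list with `reads` (tibble `read_id`, `seq`, `qual`, `mate`),
#'   `truth` (tibble `read_id`, `pos_in_read` 0-based, `true_base`,
#'   `observed_base`) and `origins` (tibble `read_id`, `start` 0-based,
#'   `strand`).
#' @export
simulate_reads <- function(individual, config) {
  withr::with_seed(child_seed(config$seed, "reads"), {
    L <- nchar(individual)
    rl <- config$read_len
    gcode <- seq_to_ints(individual)
    if (config$layout == "single") {
      n <- ceiling(config$coverage * L / rl)
      start <- sample.int(L - rl + 1L, n, replace = TRUE) # 1-based
      strand <- sample(c("+", "-"), n, replace = TRUE)
      read_id <- sprintf("r%06d", seq_len(n))
      mate <- rep("unpaired", n)
    } else {
      n_pairs <- ceiling(config$coverage * L / (2L * rl))
      frag <- pmax(rl, as.integer(round(stats::rnorm(n_pairs, config$insert_mean,
                                                     config$insert_sd))))
      frag <- pmin(frag, L)
      fstart <- 1L + floor(stats::runif(n_pairs) * (L - frag + 1L)) # 1-based
      fstrand <- sample(c("+", "-"), n_pairs, replace = TRUE)
      # mate1 at the 5' end of the fragment strand, mate2 at the other end
      s1 <- ifelse(fstrand == "+", fstart, fstart + frag - rl)
      s2 <- ifelse(fstrand == "+", fstart + frag - rl, fstart)
      start <- c(s1, s2)
      strand <- c(fstrand, ifelse(fstrand == "+", "-", "+"))
      read_id <- c(sprintf("p%06d/1", seq_len(n_pairs)),
                   sprintf("p%06d/2", seq_len(n_pairs)))
      mate <- rep(c("first", "second"), each = n_pairs)
      n <- 2L * n_pairs
    }
    # read matrix in read orientation
    M <- matrix(gcode[rep(start, each = rl) + rep(0L:(rl - 1L), times = n)],
                nrow = rl, ncol = n)
    minus <- which(strand == "-")
    if (length(minus) > 0L) {
      M[, minus] <- 5L - M[rl:1L, minus, drop = FALSE] # reverse complement
    }
    err <- which(stats::runif(rl * n) < config$error_rate)
    truth <- tibble(read_id = character(0), pos_in_read = integer(0),
                    true_base = character(0), observed_base = character(0))
    if (length(err) > 0L) {
      old <- M[err]
      new <- ((old - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
      M[err] <- new
      ridx <- ((err - 1L) %/% rl) + 1L
      pos0 <- ((err - 1L) %% rl)
      truth <- tibble(read_id = read_id[ridx], pos_in_read = as.integer(pos0),
                      true_base = BASE_CHARS[old], observed_base = BASE_CHARS[new])
    }
    big <- intToUtf8(CELL_UTF8[as.vector(M) + 1L])
    ends <- seq_len(n) * rl
    seqs <- substring(big, ends - rl + 1L, ends)
    list(
      reads = tibble(read_id = read_id, seq = seqs,
                     qual = strrep("I", rl), mate = mate),
      truth = truth,
      origins = tibble(read_id = read_id, start = as.integer(start - 1L),
                       strand = strand)
    )
  })
}

#' Run the full generator
#'
#' Convenience wrapper: [make_genome()], [plant_snps()] and
#' [simulate_reads()] under one config. The per-gene true sequences are the
#' individual-genome substrings of the gene intervals.
#'
#' @param config a [sim_config()].
#' @return a list with `config`, `genome`, `genes` (reference gene records
#'   plus a `true_seq` column), `individual`, `snps`, `reads`, `truth`,
#'   `origins`.
#' @export
simulate_dataset <- function(config) {
  gen <- make_genome(config)
  snp <- plant_snps(gen$genome, gen$genes, config$snp_rate, seed = config$seed)
  rd <- simulate_reads(snp$individual, config)
  genes <- mutate(gen$genes,
                  true_seq = substring(snp$individual, .data$start + 1L, .data$end))
  list(config = config, genome = gen$genome, genes = genes,
       individual = snp$individual, snps = snp$snps,
       reads = rd$reads, truth = rd$truth, origins = rd$origins)
}
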